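pats <- default_patterns()

test_that("default patterns encode the conserved register and its mirror", {
  rbh3 <- pats$rbh3; bh3 <- pats$bh3
  expect_s3_class(rbh3, "motif_pattern")
  expect_identical(rbh3$direction, "reverse_rBH3")
  expect_identical(bh3$direction, "forward_BH3")
  expect_setequal(rbh3$anchor_classes, c("D", "E"))
  # required positions H1-H3 plus anchor; H4 optional in both patterns
  req <- rbh3$offsets[rbh3$offsets$required, ]
  expect_setequal(req$label, c("H1", "H2", "H3"))
  expect_false(rbh3$offsets$required[rbh3$offsets$label == "H4"])
  expect_false(bh3$offsets$required[bh3$offsets$label == "H4"])
  # exact offset negation between the two directions
  o1 <- rbh3$offsets[order(rbh3$offsets$label), ]
  o2 <- bh3$offsets[order(bh3$offsets$label), ]
  expect_identical(o1$offset, -o2$offset)
  expect_identical(o1$allowed, o2$allowed)
  # rBH3 register: H3 +2, H2 +5, H1 +9, H4 -2
  expect_identical(rbh3$offsets$offset[match(c("H4", "H3", "H2", "H1"),
                                             rbh3$offsets$label)],
                   c(-2L, 2L, 5L, 9L))
})

test_that("the PTBP1 rBH3 peptide yields exactly one match with the documented residues", {
  pep <- sequence_record("RRM1_rBH3", "NTEEAANTMVNYYTSVTPVLRGQ",
                         numbering_offset = 102)
  m <- scan_sequence(pep, pats$rbh3)
  expect_identical(nrow(m), 1L)
  expect_identical(m$anchor_position, 105L)
  expect_identical(m$anchor_residue, "E")
  expect_identical(m$H3_position, 107L)
  expect_identical(m$H3_residue, "A")
  expect_identical(m$H2_position, 110L)
  expect_identical(m$H2_residue, "M")
  expect_identical(m$H1_position, 114L)
  expect_identical(m$H1_residue, "Y")
  expect_false(m$h4_satisfied)
  expect_identical(m$score, 0)
})

test_that("the BAK BH3 peptide matches the mirrored register", {
  bak <- sequence_record("BAK", "GQVGRQLAIIGDDINRRYD")
  m <- scan_sequence(bak, pats$bh3)
  expect_identical(nrow(m), 1L)
  expect_identical(m$anchor_position, 12L)  # first D of "GDD"
  expect_identical(m$H2_residue, "L")
  expect_identical(m$H2_position, 7L)
  expect_identical(m$H1_residue, "V")
  expect_identical(m$H1_position, 3L)
  expect_true(m$h4_satisfied)
})

test_that("sequences without an acidic anchor or with bad characters behave as specified", {
  poly_a <- sequence_record("polyA", "AAAAAAAAAAAAAAAA")
  expect_identical(nrow(scan_sequence(poly_a, pats$rbh3)), 0L)
  expect_error(sequence_record("bad", "ACDEFGB"), "non-amino-acid")
  # X is parseable but never matches any class (here at the H2 slot)
  with_x <- sequence_record("withX", "NTEEAANTXVNYYTSVTPVLRGQ")
  expect_identical(nrow(scan_sequence(with_x, pats$rbh3)), 0L)
})

test_that("scan agrees with the brute-force oracle on random short sequences", {
  set.seed(42)
  aa20 <- setdiff(rbh3tools:::AA_ALPHABET, "X")
  for (k in 1:200) {
    len <- sample(10:50, 1)
    rec <- sequence_record(paste0("r", k),
                           paste(sample(aa20, len, replace = TRUE), collapse = ""),
                           numbering_offset = sample(c(1L, 55L, 102L), 1))
    for (pat in pats) {
      expect_identical(scan_sequence(rec, pat)$anchor_position,
                       brute_force_scan(rec, pat),
                       info = paste(rec$id, pat$name))
    }
  }
})

test_that("reversing the sequence and swapping patterns mirrors match coordinates", {
  set.seed(7)
  aa20 <- setdiff(rbh3tools:::AA_ALPHABET, "X")
  for (k in 1:50) {
    len <- sample(15:60, 1)
    s <- paste(sample(aa20, len, replace = TRUE), collapse = "")
    fwd <- sequence_record("fwd", s)
    rev <- sequence_record("rev", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    m_r <- scan_sequence(fwd, pats$rbh3)$anchor_position
    m_b <- scan_sequence(rev, pats$bh3)$anchor_position
    expect_identical(sort(len - m_r + 1L), sort(m_b))
  }
})

test_that("scanning is deterministic and all overlapping matches are reported", {
  # two overlapping anchors: EE with valid downstream registers for both
  s <- sequence_record("olap", "AEELLALLAALLA")
  m1 <- scan_sequence(s, pats$rbh3)
  m2 <- scan_sequence(s, pats$rbh3)
  expect_identical(m1, m2)
  expect_identical(m1$anchor_position, brute_force_scan(s, pats$rbh3))
  expect_gt(nrow(m1), 1L)
})

test_that("only RRM1 of the four PTBP1 RRMs carries the rBH3 register", {
  fa <- system.file("extdata", "ptbp1_p26599.fasta", package = "rbh3tools")
  dt <- system.file("extdata", "ptbp1_rrm_domains.tsv", package = "rbh3tools")
  full <- read_fasta(fa)[[1]]
  doms <- cut_domains(full, read_domain_table(dt))
  res <- scan_domains(doms, pats$rbh3)
  expect_identical(res$summary$domain_id, c("RRM1", "RRM2", "RRM3", "RRM4"))
  expect_identical(res$summary$has_match, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(res$matches$RRM1$anchor_position, 105L)
  expect_identical(res$matches$RRM1$H2_position, 110L)
  expect_identical(res$matches$RRM1$H1_position, 114L)
})

test_that("the helical-context filter keeps only matches inside helices", {
  pep <- sequence_record("pep", "NTEEAANTMVNYYTSVTPVLRGQ")
  helix_all <- strrep("H", 23)
  helix_none <- strrep("C", 23)
  expect_identical(
    nrow(scan_sequence(pep, pats$rbh3, helix = helix_all, require_helix = TRUE)),
    1L)
  expect_identical(
    nrow(scan_sequence(pep, pats$rbh3, helix = helix_none, require_helix = TRUE)),
    0L)
  expect_error(scan_sequence(pep, pats$rbh3, require_helix = TRUE), "helix")
})

test_that("scan_domains rejects an empty domain list", {
  expect_error(scan_domains(list(), pats$rbh3), "empty")
})
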