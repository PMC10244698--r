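make_pl <- function(df, condition = "apo", rep = 1L)
  peak_list(df, condition = condition, replicate_id = rep)

test_that("the CSP statistic is the 15N-scaled euclidean norm", {
  expect_identical(compute_csp(0, 0), 0)
  expect_equal(compute_csp(0.006, 0.040), 0.010)
  expect_equal(compute_csp(-0.01, 0), 0.01)       # sign symmetry
  expect_equal(compute_csp(0.01, 0), compute_csp(0, 0.05))
  expect_error(compute_csp(NA, 0), "non-finite")
  # norm properties: non-negative, zero iff both zero, linear scaling
  set.seed(1)
  dh <- rnorm(100, 0, 0.02); dn <- rnorm(100, 0, 0.1)
  v <- compute_csp(dh, dn)
  expect_true(all(v >= 0))
  expect_true(all(v[dh != 0 | dn != 0] > 0))
  expect_equal(compute_csp(3 * dh, 3 * dn), 3 * v)
})

test_that("mutual-nearest matching pairs, excludes and orphans as specified", {
  apo <- make_pl(data.frame(label = c("A1", "A2"),
                            delta_H = c(8.20, 7.40),
                            delta_N = c(120.0, 112.0), intensity = 100))
  bound <- make_pl(data.frame(label = "", delta_H = c(8.21, 7.40),
                              delta_N = c(120.05, 112.0), intensity = 100),
                   condition = "bound")
  res <- match_peaks(apo, bound, cutoff = 0.05)
  expect_identical(res$pairs$bound_idx, c(1L, 2L))
  expect_equal(res$pairs$distance[1], sqrt(0.01^2 + 0.01^2), tolerance = 1e-12)
  expect_identical(res$orphans, integer(0))

  # identical lists pair at distance zero
  res0 <- match_peaks(apo, make_pl(as.data.frame(apo), condition = "bound"))
  expect_true(all(res0$pairs$distance == 0))

  # nearest bound peak at 0.20 scaled > cutoff 0.05 -> missing in bound
  far <- make_pl(data.frame(label = "", delta_H = 8.40, delta_N = 120.0,
                            intensity = 100), condition = "bound")
  res_far <- match_peaks(make_pl(apo[1, ]), far, cutoff = 0.05)
  expect_true(is.na(res_far$pairs$bound_idx))
  expect_identical(res_far$orphans, 1L)

  expect_error(match_peaks(make_pl(data.frame(label = c("", "A2"),
                                              delta_H = c(8, 8.5),
                                              delta_N = c(110, 111))),
                           bound), "assigned")
})

test_that("matching agrees with the exhaustive assignment oracle on small lists", {
  for (seed in 1:25) {
    n <- sample(2:8, 1)
    base <- separated_peaks(n, sep = 0.3, seed = seed)
    set.seed(seed + 1000)
    jit <- base
    jit$delta_H <- jit$delta_H + rnorm(n, 0, 0.004)
    jit$delta_N <- jit$delta_N + rnorm(n, 0, 0.02)
    shuffle <- sample(n)
    bound_df <- jit[shuffle, ]; bound_df$label <- ""
    oracle <- assignment_oracle(base, bound_df)
    if (is.null(oracle)) next                      # degenerate optimum
    res <- match_peaks(make_pl(base), make_pl(bound_df, condition = "bound"),
                       cutoff = 0.05)
    expect_false(any(is.na(res$pairs$bound_idx)))
    expect_identical(res$pairs$bound_idx, oracle$perm)
  }
})

test_that("summary statistics use matched residues only, sample SD and strict >", {
  recs <- data.frame(residue = c("A1", "A2", "A3", "A4"),
                     csp = c(0.005, 0.005, 0.005, 0.025),
                     status = "matched",
                     delta_H = 0, delta_N = 0, distance = 0)
  class(recs) <- c("csp_table", "data.frame")
  s <- summarize_csp(recs)
  expect_equal(s$mean, 0.010)
  expect_equal(s$sd, 0.010)
  expect_equal(s$threshold_1sd, 0.020)
  expect_equal(s$threshold_2sd, 0.030)
  expect_identical(s$significant_residues, "A4")

  # sentinel rows never enter the statistics
  with_sent <- rbind(recs,
                     data.frame(residue = "A5", csp = -0.005,
                                status = "missing_in_bound",
                                delta_H = NA, delta_N = NA, distance = NA))
  class(with_sent) <- c("csp_table", "data.frame")
  s2 <- summarize_csp(with_sent)
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$sd, s$sd)

  # all-equal CSPs: sd 0, nothing strictly exceeds the mean
  flat <- recs; flat$csp <- 0.01
  s3 <- summarize_csp(flat)
  expect_identical(s3$significant_residues, character(0))

  expect_error(summarize_csp(recs[1, ]), "at least 2")
})

test_that("raising the significance multiplier never enlarges the significant set", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    recs <- data.frame(residue = paste0("A", 1:n),
                       csp = abs(rnorm(n, 0.005, 0.004)),
                       status = "matched", delta_H = 0, delta_N = 0,
                       distance = 0)
    class(recs) <- c("csp_table", "data.frame")
    s1 <- summarize_csp(recs, n_sd = 1)
    s2 <- summarize_csp(recs, n_sd = 2)
    expect_true(all(s2$significant_residues %in% s1$significant_residues))
  }
})

test_that("consensus is the intersection of significant sets", {
  expect_identical(csp_consensus(list(c("A", "B", "C"), c("B", "C"),
                                      c("B", "C", "D"))),
                   c("B", "C"))
  expect_identical(csp_consensus(list(c("Q9", "Q2"))), c("Q2", "Q9"))
  expect_error(csp_consensus(list()), "at least one")
})

test_that("side peaks of near-equivalent intensity flag a conformation shift", {
  apo <- make_pl(data.frame(label = "M110", delta_H = 8.2, delta_N = 120,
                            intensity = 100))
  main <- data.frame(label = "", delta_H = 8.205, delta_N = 120.01,
                     intensity = 100)
  orphan_hi <- data.frame(label = "", delta_H = 8.24, delta_N = 120.2,
                          intensity = 90)
  orphan_lo <- orphan_hi; orphan_lo$intensity <- 10
  b_hi <- make_pl(rbind(main, orphan_hi), condition = "bound")
  b_lo <- make_pl(rbind(main, orphan_lo), condition = "bound")
  p_hi <- match_peaks(apo, b_hi); p_lo <- match_peaks(apo, b_lo)
  expect_identical(detect_conformation_shift(b_hi, p_hi), "M110")
  expect_identical(detect_conformation_shift(b_lo, p_lo), character(0))
  # no orphans anywhere -> empty set
  b_none <- make_pl(main, condition = "bound")
  expect_identical(detect_conformation_shift(b_none, match_peaks(apo, b_none)),
                   character(0))
  # missing intensities -> warning, flagging disabled
  b_na <- b_hi; b_na$intensity <- NA_real_
  expect_warning(out <- detect_conformation_shift(b_na, p_hi), "intensities")
  expect_identical(out, character(0))
  # the flagged residue carries conformation_shift status in the table
  tab <- csp_table(apo, b_hi)
  expect_identical(tab$status[tab$residue == "M110"], "conformation_shift")
})

test_that("csp_table applies the sentinel and missing-in-apo conventions", {
  apo <- make_pl(data.frame(label = c("I61", "H62"),
                            delta_H = c(8.0, 8.9),
                            delta_N = c(115, 125), intensity = 100))
  bound <- make_pl(data.frame(label = "", delta_H = 8.9, delta_N = 125.05,
                              intensity = 100), condition = "bound")
  tab <- csp_table(apo, bound, expected_residues = c("I61", "H62", "V60"))
  expect_identical(tab$status[tab$residue == "I61"], "missing_in_bound")
  expect_identical(tab$csp[tab$residue == "I61"], -0.005)
  expect_identical(tab$status[tab$residue == "V60"], "missing_in_apo")
  expect_true(is.na(tab$csp[tab$residue == "V60"]))
  expect_identical(tab$status[tab$residue == "H62"], "matched")
  expect_equal(tab$csp[tab$residue == "H62"], 0.01)
  # residues are ordered by residue number
  expect_identical(tab$residue, c("V60", "I61", "H62"))
})

test_that("per-residue CSPs land in the B-factor column with a skip report", {
  g <- gen_peaklist_pair(3, shift_residues = character(), start = 109,
                         noise_sd = c(0, 0), seed = 3)
  tab <- csp_table(g$apo, g$bound[[1]])
  tab$csp[1:3] <- c(0.02, 0.75, 0.13)
  extra <- tab[1, ]; extra$residue <- "Z999"; extra$csp <- 0.5
  tab2 <- rbind(tab, extra)
  pdb_in <- tempfile(fileext = ".pdb"); write_tiny_pdb(pdb_in, 109:111)
  pdb_out <- tempfile(fileext = ".pdb")
  res <- map_to_structure(tab2, consensus = tab$residue[1], pdb_in, pdb_out)
  expect_identical(res$skipped, "Z999")
  out <- bio3d::read.pdb(pdb_out)
  expect_equal(unique(out$atom$b[out$atom$resno == 109]), 0.02)
  expect_equal(unique(out$atom$b[out$atom$resno == 110]), 0.75)
  expect_true(any(grepl("csp_consensus", readLines(res$sidecar))))
  # scale = 100 preserves ppm-scale CSPs within the 2-decimal B-factor field
  tab$csp[1:3] <- c(0.012, 0.005, 0.0133)
  res100 <- map_to_structure(tab, consensus = character(), pdb_in,
                             pdb_out, scale = 100)
  out100 <- bio3d::read.pdb(pdb_out)
  expect_equal(out100$atom$b[match(109:111, out100$atom$resno)],
               c(1.2, 0.5, 1.33))
  # empty consensus -> sidecar notes it, B-factors still written
  res2 <- map_to_structure(tab, consensus = character(), pdb_in,
                           tempfile(fileext = ".pdb"))
  expect_true(any(grepl("empty consensus", readLines(res2$sidecar))))
})
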