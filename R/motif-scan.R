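#' Construct a protein sequence record
#'
#' Thin container for a 1-letter amino-acid sequence with the coordinate of
#' its first residue in the parent protein, so that scan results can be
#' reported in parent (e.g. UniProt) numbering. The RRM1 rBH3 peptide, for
#' instance, starts at PTBP1 residue 102.
#'
#' @param id record identifier.
#' @param residues amino-acid string (upper-cased on input); only the 20
#'   standard letters plus `X` are accepted.
#' @param numbering_offset parent-protein coordinate of the first residue
#'   (>= 1; default 1).
#' @param description free-text description.
#' @return an object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, numbering_offset = 1L,
                            description = "") {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  residues <- toupper(as.character(residues))
  if (length(residues) != 1 || !nzchar(residues))
    stop("sequence_record: empty sequence for '", id, "'")
  letters1 <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters1), AA_ALPHABET)
  if (length(bad))
    stop("sequence_record: non-amino-acid character(s) in '", id, "': ",
         paste(bad, collapse = " "))
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1)
    stop("sequence_record: numbering_offset must be >= 1")
  structure(list(id = id, description = description, residues = residues,
                 numbering_offset = numbering_offset),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s [%d residues, starts at %d]\n",
              x$id, nchar(x$residues), x$numbering_offset))
  invisible(x)
}

empty_matches <- function() {
  data.frame(sequence_id = character(), anchor_position = integer(),
             anchor_residue = character(),
             H1_position = integer(), H1_residue = character(),
             H2_position = integer(), H2_residue = character(),
             H3_position = integer(), H3_residue = character(),
             H4_position = integer(), H4_residue = character(),
             h4_satisfied = logical(), score = double(),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for motif register matches
#'
#' Slides the pattern's anchor over every acidic candidate position and
#' reports each placement where the anchor and all required positions fall
#' inside the sequence and carry a residue from their allowed class. All
#' overlapping matches are reported; `X` never matches any class. Optional
#' positions (H4) that fall outside the sequence or carry a disallowed
#' residue leave `h4_satisfied = FALSE` without rejecting the match.
#'
#' @param seq a [sequence_record()].
#' @param pattern a [motif_pattern()].
#' @param helix optional per-residue secondary-structure string of the same
#'   length as the sequence (`"H"` marking helix). Known rBH3 motifs sit in
#'   pre-formed alpha helices, so `require_helix = TRUE` keeps only matches
#'   whose anchor and required positions are all helical.
#' @param require_helix apply the helical-context filter.
#' @return data frame of matches (one row per placement, sorted by
#'   `anchor_position`, reported in parent-protein numbering): anchor and
#'   H1-H4 positions/residues, `h4_satisfied`, and `score` (fraction of
#'   optional positions satisfied; 1 when the pattern has none).
#' @examples
#' pep <- sequence_record("RRM1_rBH3", "NTEEAANTMVNYYTSVTPVLRGQ",
#'                        numbering_offset = 102)
#' scan_sequence(pep, default_patterns()$rbh3)
#' @export
scan_sequence <- function(seq, pattern, helix = NULL, require_helix = FALSE) {
  stopifnot(inherits(seq, "sequence_record"), inherits(pattern, "motif_pattern"))
  aa <- strsplit(seq$residues, "")[[1]]
  n <- length(aa)
  if (require_helix) {
    if (is.null(helix) || nchar(helix) != n)
      stop("scan_sequence: helix string must match sequence length")
    ss <- strsplit(toupper(helix), "")[[1]]
  }
  off <- pattern$offsets
  req <- off[off$required, , drop = FALSE]
  opt <- off[!off$required, , drop = FALSE]
  out <- empty_matches()
  anchors <- which(aa %in% pattern$anchor_classes)
  for (i in anchors) {
    pos_req <- i + req$offset
    if (any(pos_req < 1L | pos_req > n)) next
    ok <- mapply(function(p, allowed) aa[p] %in% allowed,
                 pos_req, req$allowed)
    if (!all(ok)) next
    if (require_helix && !all(ss[c(i, pos_req)] == "H")) next
    row <- list(sequence_id = seq$id,
                anchor_position = i + seq$numbering_offset - 1L,
                anchor_residue = aa[i])
    n_opt_ok <- 0L
    for (lab in c("H1", "H2", "H3", "H4")) {
      j <- match(lab, off$label)
      if (is.na(j)) {
        row[[paste0(lab, "_position")]] <- NA_integer_
        row[[paste0(lab, "_residue")]] <- NA_character_
        next
      }
      p <- i + off$offset[j]
      inb <- p >= 1L && p <= n
      hit <- inb && aa[p] %in% off$allowed[[j]]
      row[[paste0(lab, "_position")]] <- if (inb) p + seq$numbering_offset - 1L else NA_integer_
      row[[paste0(lab, "_residue")]] <- if (inb) aa[p] else NA_character_
      if (!off$required[j] && hit) n_opt_ok <- n_opt_ok + 1L
    }
    j4 <- match("H4", off$label)
    row$h4_satisfied <- if (is.na(j4)) FALSE else {
      p <- i + off$offset[j4]
      p >= 1L && p <= n && aa[p] %in% off$allowed[[j4]]
    }
    row$score <- if (nrow(opt) == 0) 1 else n_opt_ok / nrow(opt)
    out <- rbind(out, as.data.frame(row, stringsAsFactors = FALSE))
  }
  out[order(out$anchor_position), , drop = FALSE]
}

#' Scan a set of domains for motif matches
#'
#' Applies [scan_sequence()] to each domain record and summarises which
#' domains contain at least one match, e.g. to ask which of the four PTBP1
#' RRMs carries an rBH3 register.
#'
#' @param domains non-empty list of [sequence_record()]s.
#' @param pattern a [motif_pattern()].
#' @param ... passed on to [scan_sequence()].
#' @return list with `matches` (named list of match data frames) and
#'   `summary` (data frame: `domain_id`, `n_matches`, `has_match`).
#' @export
scan_domains <- function(domains, pattern, ...) {
  if (!is.list(domains) || length(domains) == 0)
    stop("scan_domains: empty domain list")
  stopifnot(all(vapply(domains, inherits, logical(1), "sequence_record")))
  ids <- vapply(domains, `[[`, character(1), "id")
  matches <- lapply(domains, scan_sequence, pattern = pattern, ...)
  names(matches) <- ids
  summary <- data.frame(
    domain_id = ids,
    n_matches = vapply(matches, nrow, integer(1)),
    stringsAsFactors = FALSE)
  summary$has_match <- summary$n_matches > 0
  rownames(summary) <- NULL
  list(matches = matches, summary = summary)
}

#' Cut domain subsequences out of a full-length record
#'
#' @param record a [sequence_record()] (full-length protein).
#' @param table data frame with columns `id`, `start`, `end` in the
#'   record's parent numbering (1-based, inclusive).
#' @return list of [sequence_record()]s with correct `numbering_offset`.
#' @export
cut_domains <- function(record, table) {
  stopifnot(inherits(record, "sequence_record"),
            all(c("id", "start", "end") %in% names(table)))
  n <- nchar(record$residues)
  lapply(seq_len(nrow(table)), function(i) {
    s <- as.integer(table$start[i]); e <- as.integer(table$end[i])
    s0 <- s - record$numbering_offset + 1L
    e0 <- e - record$numbering_offset + 1L
    if (s0 < 1 || e0 > n || s0 > e0)
      stop("cut_domains: domain '", table$id[i], "' (", s, "-", e,
           ") outside record bounds")
    sequence_record(id = table$id[i],
                    residues = substr(record$residues, s0, e0),
                    numbering_offset = s,
                    description = sprintf("%s residues %d-%d", record$id, s, e))
  })
}

#' Write motif matches as TSV
#'
#' @param matches match data frame from [scan_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
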