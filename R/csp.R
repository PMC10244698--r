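#' Chemical-shift perturbation of one amide
#'
#' The combined amide CSP in ppm, `sqrt(dH^2 + (dN/5)^2)`, where the 15N
#' difference is down-weighted by 5 to place both dimensions on a common
#' ppm scale.
#'
#' @param delta_H 1H shift difference (ppm); vectorised.
#' @param delta_N 15N shift difference (ppm); vectorised.
#' @return non-negative CSP values (ppm).
#' @examples
#' compute_csp(0.006, 0.040)  # 0.010
#' @export
compute_csp <- function(delta_H, delta_N) {
  if (!all(is.finite(delta_H)) || !all(is.finite(delta_N)))
    stop("compute_csp: non-finite input")
  sqrt(delta_H^2 + (delta_N / 5)^2)
}

scaled_dist <- function(h1, n1, h2, n2) {
  sqrt((h1 - h2)^2 + ((n1 - n2) / 5)^2)
}

#' Match apo peaks to bound peaks by mutual nearest neighbour
#'
#' Pairs each assigned apo cross-peak with its nearest bound peak in the
#' scaled coordinate space `d = sqrt(dH^2 + (dN/5)^2)`. A pairing is kept
#' only if it is mutual-nearest (each peak is the other's closest) and
#' `d <= cutoff`; distance ties are broken towards the smaller residue
#' number. Apo peaks with no admissible partner are reported with
#' `bound_idx = NA` (missing in bound); bound peaks left unpaired are
#' returned as orphans (candidate side peaks).
#'
#' @param apo assigned [peak_list()] (all labels present and unique).
#' @param bound [peak_list()]; labels may be absent.
#' @param cutoff maximum admissible scaled distance (ppm); default 0.05.
#' @return list with `pairs` (data frame: `residue`, `apo_idx`,
#'   `bound_idx`, `distance`) and `orphans` (integer indices into `bound`).
#' @export
match_peaks <- function(apo, bound, cutoff = 0.05) {
  stopifnot(inherits(apo, "peak_list"), inherits(bound, "peak_list"))
  if (nrow(apo) == 0 || nrow(bound) == 0)
    stop("match_peaks: empty peak list")
  if (any(!nzchar(apo$label)))
    stop("match_peaks: apo peaks must all be assigned")
  resnum <- label_residue_number(apo$label)
  ord <- order(is.na(resnum), resnum, apo$label)  # tie-break authority
  d <- outer(seq_len(nrow(apo)), seq_len(nrow(bound)),
             function(i, j) scaled_dist(apo$delta_H[i], apo$delta_N[i],
                                        bound$delta_H[j], bound$delta_N[j]))
  pairs <- data.frame(residue = apo$label,
                      apo_idx = seq_len(nrow(apo)),
                      bound_idx = NA_integer_,
                      distance = NA_real_,
                      stringsAsFactors = FALSE)
  taken <- logical(nrow(bound))
  for (i in ord) {
    j <- which.min(d[i, ])
    if (d[i, j] > cutoff) next
    # mutual-nearest: i must be the closest apo peak to j; among equally
    # close apo peaks the smaller residue number wins (ord ensures we ask
    # in that order, and a taken bound peak is never reassigned)
    if (taken[j]) next
    di <- d[, j]
    closest <- which(di == min(di))
    if (!(i %in% closest)) next
    if (length(closest) > 1) {
      first <- ord[ord %in% closest][1]
      if (first != i) next
    }
    pairs$bound_idx[i] <- j
    pairs$distance[i] <- d[i, j]
    taken[j] <- TRUE
  }
  list(pairs = pairs, orphans = which(!taken))
}

#' Flag residues whose bound peak splits into a major/minor pair
#'
#' A shift in the predominant conformation shows up as the emergence of a
#' side peak of near-equivalent intensity next to the main bound peak.
#' For every paired residue, orphan bound peaks within `secondary_cutoff`
#' (scaled ppm) of the paired bound peak are examined; if any has an
#' intensity ratio to the paired peak of at least `min_ratio`, the residue
#' is flagged.
#'
#' @param bound bound [peak_list()] (intensities required for flagging).
#' @param pairing result of [match_peaks()].
#' @param secondary_cutoff scaled-ppm search radius around the paired
#'   bound peak (default 0.10).
#' @param min_ratio minimum orphan/main intensity ratio (default 0.5).
#' @return character vector of flagged residue labels (empty when there
#'   are no orphans; empty with a warning when intensities are missing).
#' @export
detect_conformation_shift <- function(bound, pairing,
                                      secondary_cutoff = 0.10,
                                      min_ratio = 0.5) {
  stopifnot(inherits(bound, "peak_list"))
  orphans <- pairing$orphans
  pairs <- pairing$pairs[!is.na(pairing$pairs$bound_idx), , drop = FALSE]
  if (length(orphans) == 0 || nrow(pairs) == 0) return(character())
  if (any(!is.finite(bound$intensity[c(pairs$bound_idx, orphans)]))) {
    warning("detect_conformation_shift: missing bound intensities; ",
            "side-peak flagging disabled")
    return(character())
  }
  flagged <- character()
  for (k in seq_len(nrow(pairs))) {
    j <- pairs$bound_idx[k]
    dd <- scaled_dist(bound$delta_H[j], bound$delta_N[j],
                      bound$delta_H[orphans], bound$delta_N[orphans])
    ratio <- bound$intensity[orphans] / bound$intensity[j]
    if (any(dd <= secondary_cutoff & ratio >= min_ratio))
      flagged <- c(flagged, pairs$residue[k])
  }
  sort(unique(flagged))
}

#' Per-residue CSP table for an apo/bound spectrum pair
#'
#' Matches peaks, computes the CSP for each paired residue, applies the
#' reporting conventions for unmatchable peaks, and (when intensities are
#' available) flags predominant-conformation shifts:
#' \itemize{
#'   \item matched residues carry their CSP (ppm);
#'   \item residues present in apo but unidentifiable in the bound
#'     spectrum are reported with the sentinel value (default -0.005) and
#'     status `missing_in_bound` — the sentinel is a plotting convention
#'     and never enters statistics;
#'   \item residues expected but absent from the apo list (via
#'     `expected_residues`) get status `missing_in_apo`, carry no CSP and
#'     are excluded from all statistics.
#' }
#'
#' @param apo,bound [peak_list()]s (apo fully assigned).
#' @param cutoff matching cutoff, see [match_peaks()].
#' @param sentinel value reported for `missing_in_bound` residues.
#' @param expected_residues optional character vector of residue labels
#'   expected in the apo spectrum (e.g. from the sequence); labels absent
#'   from apo are reported as `missing_in_apo`.
#' @param secondary_cutoff,min_ratio side-peak parameters, see
#'   [detect_conformation_shift()].
#' @return data frame of class `csp_table`: `residue`, `csp`, `status`
#'   (`matched`, `missing_in_bound`, `missing_in_apo` or
#'   `conformation_shift`), `delta_H`, `delta_N`, `distance`.
#' @export
csp_table <- function(apo, bound, cutoff = 0.05, sentinel = -0.005,
                      expected_residues = NULL,
                      secondary_cutoff = 0.10, min_ratio = 0.5) {
  pairing <- match_peaks(apo, bound, cutoff = cutoff)
  pr <- pairing$pairs
  side <- if (all(is.na(bound$intensity))) character()
          else detect_conformation_shift(bound, pairing,
                                         secondary_cutoff = secondary_cutoff,
                                         min_ratio = min_ratio)
  out <- data.frame(residue = pr$residue,
                    csp = NA_real_,
                    status = NA_character_,
                    delta_H = NA_real_, delta_N = NA_real_,
                    distance = pr$distance,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pr))) {
    if (is.na(pr$bound_idx[i])) {
      out$csp[i] <- sentinel
      out$status[i] <- "missing_in_bound"
    } else {
      j <- pr$bound_idx[i]; a <- pr$apo_idx[i]
      dH <- bound$delta_H[j] - apo$delta_H[a]
      dN <- bound$delta_N[j] - apo$delta_N[a]
      out$csp[i] <- compute_csp(dH, dN)
      out$delta_H[i] <- dH
      out$delta_N[i] <- dN
      out$status[i] <- if (out$residue[i] %in% side) "conformation_shift"
                       else "matched"
    }
  }
  if (!is.null(expected_residues)) {
    absent <- setdiff(expected_residues, out$residue)
    if (length(absent))
      out <- rbind(out, data.frame(residue = absent, csp = NA_real_,
                                   status = "missing_in_apo",
                                   delta_H = NA_real_, delta_N = NA_real_,
                                   distance = NA_real_,
                                   stringsAsFactors = FALSE))
  }
  resnum <- label_residue_number(out$residue)
  out <- out[order(is.na(resnum), resnum, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Summarise a CSP table: mean, SD, thresholds, significant residues
#'
#' The mean and sample standard deviation (n - 1 denominator) are computed
#' over matched residues only — the -0.005 sentinel, residues unassignable
#' in the apo spectrum, and conformation-shift residues (whose CSP
#' measures the main-peak displacement of a split resonance, not a simple
#' perturbation) never enter the statistics. A residue is significant when
#' its CSP strictly exceeds `mean + n_sd * SD` (default 1 SD).
#'
#' @param records a [csp_table()].
#' @param n_sd significance multiplier (default 1).
#' @return object of class `csp_summary`: list with `mean`, `sd`,
#'   `threshold_1sd`, `threshold_2sd`, `threshold` (at `n_sd`),
#'   `significant_residues`, `n_matched`.
#' @export
summarize_csp <- function(records, n_sd = 1) {
  stopifnot(inherits(records, "csp_table") || is.data.frame(records))
  use <- records$status == "matched"
  if (sum(use) < 2)
    stop("summarize_csp: need at least 2 matched residues")
  x <- records$csp[use]
  m <- mean(x); s <- stats::sd(x)
  thr <- m + n_sd * s
  sig <- records$residue[use][x > thr]
  structure(list(mean = m, sd = s,
                 threshold_1sd = m + s, threshold_2sd = m + 2 * s,
                 threshold = thr, n_sd = n_sd,
                 significant_residues = sort(sig),
                 n_matched = sum(use)),
            class = "csp_summary")
}

#' @export
print.csp_summary <- function(x, ...) {
  cat(sprintf("<csp_summary> n=%d matched, mean=%.4f ppm, sd=%.4f ppm\n",
              x$n_matched, x$mean, x$sd))
  cat(sprintf("  thresholds: mean+1SD=%.4f, mean+2SD=%.4f\n",
              x$threshold_1sd, x$threshold_2sd))
  cat(sprintf("  significant (> mean+%gSD): %s\n", x$n_sd,
              paste(x$significant_residues, collapse = ", ")))
  invisible(x)
}

#' Consensus of significant residues across replicate spectra
#'
#' Residues significant in every replicate (set intersection), as used to
#' select the residues mapped onto the structure after triplicate
#' measurement.
#'
#' @param replicates non-empty list of [summarize_csp()] results (or
#'   character vectors of residue labels).
#' @return sorted character vector of consensus residues.
#' @export
csp_consensus <- function(replicates) {
  if (length(replicates) == 0)
    stop("csp_consensus: need at least one replicate")
  sets <- lapply(replicates, function(r)
    if (inherits(r, "csp_summary")) r$significant_residues else as.character(r))
  sort(Reduce(intersect, sets))
}

#' Write a CSP table as CSV
#'
#' @param records a [csp_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csp_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}
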