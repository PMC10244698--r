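#' @name synthetic
#' @title Ground-truthed synthetic data for pipeline validation
#' @description Every generator is fully deterministic under a fixed seed
#'   and returns, alongside the dataset, a `synthetic_truth` record (seed,
#'   kind, and the ground truth: implanted motif anchors, injected-shift
#'   residues and magnitudes, or true model parameters) sufficient to
#'   score the downstream stage without inspecting generator internals.
NULL

synthetic_truth <- function(seed, kind, truth) {
  structure(list(seed = as.integer(seed), kind = kind, truth = truth),
            class = "synthetic_truth")
}

#' Generate random protein sequences with implanted motif registers
#'
#' Backgrounds are uniform over the 20 standard residues (optionally a
#' custom composition). A fraction of sequences receives one implanted
#' window satisfying the pattern exactly (anchor plus all required
#' positions drawn from their allowed sets; optional positions filled from
#' their sets too, so implants score 1). With `clean_background = TRUE`,
#' sequences are rejection-sampled so that the only matches are the
#' implanted ones.
#'
#' @param n number of sequences.
#' @param length sequence length (>= pattern span).
#' @param implant_fraction fraction of sequences carrying an implant
#'   (0..1; the first `round(n * implant_fraction)` sequences).
#' @param pattern a [motif_pattern()].
#' @param seed RNG seed.
#' @param clean_background reject accidental background matches.
#' @param composition optional named probability vector over residues.
#' @return list with `records` (list of [sequence_record()]s) and `truth`
#'   (`synthetic_truth` whose `truth` is a data frame `id`,
#'   `anchor_position`, 0-row for non-implanted sequences).
#' @export
gen_sequences <- function(n, length, implant_fraction, pattern, seed,
                          clean_background = TRUE, composition = NULL) {
  stopifnot(implant_fraction >= 0, implant_fraction <= 1, n >= 1)
  span <- pattern_span(pattern)
  if (length < span)
    stop("gen_sequences: length ", length, " below pattern span ", span)
  set.seed(as.integer(seed))
  aa20 <- setdiff(AA_ALPHABET, "X")
  probs <- if (is.null(composition)) NULL else composition[aa20]
  n_implant <- round(n * implant_fraction)
  off <- pattern$offsets
  req_off <- off$offset[off$required]
  lo <- max(0L, -min(c(0L, req_off)))             # anchor slack on the left
  hi <- max(0L, max(c(0L, req_off)))              # and on the right
  records <- vector("list", n)
  truth_rows <- list()
  for (k in seq_len(n)) {
    implant <- k <= n_implant
    repeat {
      aa <- sample(aa20, length, replace = TRUE, prob = probs)
      anchor <- NA_integer_
      if (implant) {
        slots <- seq.int(1L + lo, as.integer(length) - hi)
        anchor <- slots[sample.int(NROW(slots), 1L)]
        aa[anchor] <- sample(pattern$anchor_classes, 1L)
        for (j in seq_len(nrow(off))) {
          p <- anchor + off$offset[j]
          if (p >= 1L && p <= length)
            aa[p] <- sample(off$allowed[[j]], 1L)
        }
      }
      if (!clean_background) break
      rec <- sequence_record(sprintf("synth_%03d", k), paste(aa, collapse = ""))
      hits <- scan_sequence(rec, pattern)$anchor_position
      if (implant && identical(hits, anchor)) break
      if (!implant && NROW(hits) == 0) break
    }
    records[[k]] <- sequence_record(sprintf("synth_%03d", k),
                                    paste(aa, collapse = ""))
    truth_rows[[k]] <- data.frame(id = sprintf("synth_%03d", k),
                                  anchor_position = anchor,
                                  implanted = implant)
  }
  truth_df <- do.call(rbind, truth_rows)
  list(records = records,
       truth = synthetic_truth(seed, "sequence", truth_df))
}

#' Generate an apo/bound HSQC peak-list pair with known perturbations
#'
#' Apo amide peaks are placed uniformly in the folded-protein amide
#' envelope (1H in 7.0-9.5 ppm, 15N in 105-130 ppm), subject to a minimum
#' pairwise separation in the scaled (dH, dN/5) space: the generator
#' emulates a resolved, assignable spectrum, not overlapped resonances
#' (nearest-neighbour assignment transfer is undefined for coincident
#' peaks). Bound peaks are the
#' apo peaks plus an injected shift at `shift_residues`, plus Gaussian
#' jitter on every residue; `dropout` residues are absent from the bound
#' list (unidentifiable on binding), and `sidepeak` residues get an extra
#' unassigned bound peak near their main peak at a configured intensity
#' ratio (a predominant-conformation shift). The three sets must be
#' disjoint.
#'
#' @param n_residues number of amides.
#' @param shift_residues,dropout,sidepeak disjoint sets of residue labels
#'   (subsets of the generated labels; see `start`).
#' @param shift_magnitude `c(dH, dN)` injected shift (ppm).
#' @param noise_sd `c(dH, dN)` jitter SD (ppm); default
#'   `c(0.002, 0.01)`.
#' @param sidepeak_offset `c(dH, dN)` displacement of the side peak from
#'   its main bound peak (default `c(0.03, 0.15)`, scaled distance ~0.042).
#' @param sidepeak_ratio side-peak/main-peak intensity ratio (default 0.9).
#' @param min_separation minimum scaled distance between apo peaks
#'   (ppm, default 0.06); placement is rejection-sampled.
#' @param replicates number of bound replicates (independent jitter; the
#'   apo list is shared).
#' @param start residue number of the first amide (labels are sampled
#'   residue types + consecutive numbers from `start`).
#' @param seed RNG seed.
#' @return list with `apo` (one [peak_list()]), `bound` (list of
#'   `replicates` bound [peak_list()]s) and `truth` (`synthetic_truth`
#'   carrying the injected sets, magnitudes and the closed-form CSP of the
#'   injected shift).
#' @export
gen_peaklist_pair <- function(n_residues, shift_residues = character(),
                              dropout = character(), sidepeak = character(),
                              shift_magnitude = c(0.006, 0.040),
                              noise_sd = c(0.002, 0.01),
                              sidepeak_offset = c(0.03, 0.15),
                              sidepeak_ratio = 0.9, min_separation = 0.06,
                              replicates = 1L, start = 1L, seed = 1L) {
  sets <- list(shift_residues, dropout, sidepeak)
  if (anyDuplicated(unlist(sets)))
    stop("gen_peaklist_pair: shift, dropout and sidepeak sets must be disjoint")
  set.seed(as.integer(seed))
  aa20 <- setdiff(AA_ALPHABET, c("X", "P"))  # prolines have no amide
  labels <- paste0(sample(aa20, n_residues, replace = TRUE),
                   seq.int(start, start + n_residues - 1L))
  unknown <- setdiff(unlist(sets), labels)
  if (length(unknown))
    stop("gen_peaklist_pair: residue labels not generated: ",
         paste(unknown, collapse = ", "))
  H <- numeric(0); N <- numeric(0)
  while (NROW(H) < n_residues) {
    h <- stats::runif(1, 7.0, 9.5); nn <- stats::runif(1, 105, 130)
    if (NROW(H) == 0 ||
        min(sqrt((H - h)^2 + ((N - nn) / 5)^2)) >= min_separation) {
      H <- c(H, h); N <- c(N, nn)
    }
  }
  apo_df <- data.frame(label = labels, delta_H = H, delta_N = N,
                       intensity = stats::runif(n_residues, 80, 120))
  apo <- peak_list(apo_df, condition = "apo")
  bound <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    b <- apo_df
    b$delta_H <- b$delta_H + stats::rnorm(n_residues, 0, noise_sd[1])
    b$delta_N <- b$delta_N + stats::rnorm(n_residues, 0, noise_sd[2])
    sh <- b$label %in% shift_residues
    b$delta_H[sh] <- b$delta_H[sh] + shift_magnitude[1]
    b$delta_N[sh] <- b$delta_N[sh] + shift_magnitude[2]
    extra <- b[b$label %in% sidepeak, , drop = FALSE]
    if (nrow(extra)) {
      extra$delta_H <- extra$delta_H + sidepeak_offset[1]
      extra$delta_N <- extra$delta_N + sidepeak_offset[2]
      extra$intensity <- extra$intensity * sidepeak_ratio
      extra$label <- ""
    }
    b <- b[!b$label %in% dropout, , drop = FALSE]
    b$label <- ""                         # bound peaks are unassigned
    b <- rbind(b, extra)
    rownames(b) <- NULL
    bound[[r]] <- peak_list(b, condition = "bound", replicate_id = r)
  }
  truth <- synthetic_truth(seed, "peaklist", list(
    labels = labels, shift_residues = sort(shift_residues),
    dropout = sort(dropout), sidepeak = sort(sidepeak),
    shift_magnitude = shift_magnitude,
    injected_csp = compute_csp(shift_magnitude[1], shift_magnitude[2]),
    noise_sd = noise_sd, sidepeak_ratio = sidepeak_ratio))
  list(apo = apo, bound = bound, truth = truth)
}

#' Generate FP titrations from the 4PL with Gaussian noise
#'
#' Signal per point and replicate is `fourpl(log10(conc)) + N(0,
#' noise_sd)`. The default noise of 2 mp reflects typical plate-reader
#' scatter for a well-behaved fluorescein probe.
#'
#' @param mode `"direct"` or `"competitive"`.
#' @param params named list/vector with `bottom`, `top`, `log_ec50`,
#'   `hill` (true generating parameters).
#' @param design concentrations (molar), e.g. from [fp_design()].
#' @param noise_sd Gaussian noise SD (mp); default 2.
#' @param replicates number of replicate curves.
#' @param probe_concentration optional probe concentration (molar),
#'   forwarded to the series.
#' @param seed RNG seed.
#' @return list with `series` (list of `replicates`
#'   [titration_series()]s) and `truth` (`synthetic_truth` with the true
#'   parameters, design and noise).
#' @export
gen_titration <- function(mode, params, design, noise_sd = 2,
                          replicates = 1L, probe_concentration = NULL,
                          seed = 1L) {
  stopifnot(all(c("bottom", "top", "log_ec50", "hill") %in% names(params)))
  set.seed(as.integer(seed))
  X <- log10(design)
  mu <- fourpl(X, params[["bottom"]], params[["top"]],
               params[["log_ec50"]], params[["hill"]])
  series <- lapply(seq_len(replicates), function(r) {
    titration_series(design, mu + stats::rnorm(length(mu), 0, noise_sd),
                     mode = mode, probe_concentration = probe_concentration,
                     replicate = r)
  })
  truth <- synthetic_truth(seed, "titration", list(
    mode = mode, params = as.list(params),
    ec50 = 10^params[["log_ec50"]], design = design, noise_sd = noise_sd,
    replicates = replicates))
  list(series = series, truth = truth)
}

#' Write a list of titration replicates as one CSV
#'
#' @param series list of [titration_series()] (as from [gen_titration()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic-truth record as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
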