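#' Four-parameter logistic dose-response curve
#'
#' `Y = bottom + (top - bottom) / (1 + 10^((log_ec50 - X) * hill_slope))`,
#' the standard Prism-style 4PL on `X = log10(concentration in molar)`.
#' At `X = log_ec50` the curve is at the midpoint `(top + bottom)/2`; with
#' positive Hill slope it rises from `bottom` (low X) to `top` (high X),
#' with negative slope it falls.
#'
#' @param X log10 molar concentration(s).
#' @param bottom,top lower/upper plateau (millipolarization).
#' @param log_ec50 log10 molar EC50 (K_D in direct mode, IC50 in
#'   competitive mode).
#' @param hill_slope Hill slope.
#' @return predicted signal(s), millipolarization.
#' @export
fourpl <- function(X, bottom, top, log_ec50, hill_slope) {
  if (!all(is.finite(c(bottom, top, log_ec50, hill_slope))))
    stop("fourpl: non-finite parameters")
  bottom + (top - bottom) / (1 + 10^((log_ec50 - X) * hill_slope))
}

#' Log-spaced titration design
#'
#' `n` concentrations equally spaced in log10 between `cmin` and `cmax`
#' (inclusive), the plate layout of a serial half-log dilution when the
#' endpoints are half-log multiples.
#'
#' @param cmin,cmax lowest/highest concentration (molar).
#' @param n number of points.
#' @return numeric vector of concentrations (molar), increasing.
#' @export
fp_design <- function(cmin, cmax, n) {
  stopifnot(cmin > 0, cmax > cmin, n >= 2)
  10^seq(log10(cmin), log10(cmax), length.out = n)
}

#' Construct a fluorescence-polarization titration series
#'
#' @param concentration titrant concentrations (molar, > 0).
#' @param signal polarization signals (millipolarization).
#' @param mode `"direct"` (labelled probe + titrated binder; signal rises
#'   on binding) or `"competitive"` (preformed probe complex + titrated
#'   competitor; signal falls on displacement).
#' @param probe_concentration labelled-probe concentration (molar),
#'   required for the tight-binding diagnostic in direct mode.
#' @param replicate replicate index per point (default 1).
#' @return object of class `titration_series` (a data frame with
#'   attributes `mode` and `probe_concentration`).
#' @export
titration_series <- function(concentration, signal,
                             mode = c("direct", "competitive"),
                             probe_concentration = NULL, replicate = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(concentration) == length(signal))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("titration_series: concentrations must be positive and finite")
  df <- data.frame(concentration = concentration, signal = signal,
                   replicate = as.integer(replicate))
  df <- df[order(df$replicate, df$concentration), ]
  rownames(df) <- NULL
  for (r in unique(df$replicate)) {
    conc <- df$concentration[df$replicate == r]
    if (length(conc) < 5)
      stop("titration_series: need at least 5 points per replicate")
    if (anyDuplicated(conc))
      stop("titration_series: duplicated concentrations within a replicate")
  }
  structure(df, mode = mode,
            probe_concentration = probe_concentration,
            class = c("titration_series", "data.frame"))
}

#' Read a titration series from CSV
#'
#' Columns: `concentration` (with unit suffix, e.g. `10nM`, or bare molar
#' numbers), `signal` (mp) and optional `replicate`.
#'
#' @param path CSV file.
#' @param mode,probe_concentration see [titration_series()];
#'   `probe_concentration` may carry a unit suffix.
#' @return a [titration_series()].
#' @export
read_titration_csv <- function(path, mode = c("direct", "competitive"),
                               probe_concentration = NULL) {
  mode <- match.arg(mode)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("concentration", "signal")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_titration_csv: missing column(s): ", paste(miss, collapse = ", "))
  conc <- parse_concentration(tab$concentration)
  rep_ <- if ("replicate" %in% names(tab)) tab$replicate else 1L
  if (is.character(probe_concentration))
    probe_concentration <- parse_concentration(probe_concentration)
  titration_series(conc, tab$signal, mode = mode,
                   probe_concentration = probe_concentration,
                   replicate = rep_)
}

#' Parse concentrations with unit suffixes into molar
#'
#' Accepts `pM`, `nM`, `uM`/`µM`, `mM`, `M` (case-insensitive except M/mM
#' distinction handled explicitly) or bare numbers (already molar).
#'
#' @param x character or numeric vector.
#' @return numeric vector, molar.
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  m <- regexec("^([0-9.eE+-]+)\\s*(pM|nM|uM|µM|mM|M)?$", x)
  g <- regmatches(x, m)
  bad <- vapply(g, length, integer(1)) == 0
  if (any(bad))
    stop("parse_concentration: cannot parse: ",
         paste(x[bad], collapse = ", "))
  val <- vapply(g, function(p) as.numeric(p[2]), numeric(1))
  unit <- vapply(g, function(p) p[3], character(1))
  mult <- c("pM" = 1e-12, "nM" = 1e-9, "uM" = 1e-6, "µM" = 1e-6,
            "mM" = 1e-3, "M" = 1)
  f <- ifelse(unit == "", 1, mult[unit])
  if (any(is.na(f))) stop("parse_concentration: unknown unit")
  unname(val * f)
}

#' Fit the 4PL to a titration series
#'
#' Least-squares fit of [fourpl()] on `X = log10(concentration, molar)`
#' using Levenberg-Marquardt with multi-start over Hill slopes
#' `{+-0.5, +-1, +-2}` (initial bottom/top from the data range, initial
#' log EC50 at the concentration whose signal is closest to the midpoint).
#' The fit is canonicalised to `top >= bottom` (the 4PL is invariant under
#' swapping the plateaus and negating the slope), so direct saturation
#' curves report a positive slope and competitive displacement curves a
#' negative one.
#'
#' In direct mode, when the fitted EC50 is below twice the probe
#' concentration the probe is no longer trace relative to the affinity and
#' the fitted value is only an apparent (upper-bound) K_D; this sets
#' `tight_binding_flag`.
#'
#' @param series a [titration_series()] (replicates are pooled).
#' @param weights optional per-point weights for weighted least squares;
#'   default unweighted.
#' @param noise_floor minimum signal range (mp) regarded as a dose
#'   response (default 5).
#' @return object of class `fp_fit`: list with `bottom`, `top`,
#'   `log_ec50`, `hill_slope`, `ec50` (molar), `se` (named vector of
#'   asymptotic standard errors), `converged`, `tight_binding_flag`,
#'   `extrapolated`, `mode`, `residuals`, `fitted`, `data`, `rss`.
#' @examples
#' conc <- fp_design(1e-10, 3e-7, 7)
#' y <- fourpl(log10(conc), 40, 120, log10(8.8e-8), 1)
#' fit_titration(titration_series(conc, y, mode = "direct",
#'                                probe_concentration = 1e-8))
#' @export
fit_titration <- function(series, weights = NULL, noise_floor = 5) {
  stopifnot(inherits(series, "titration_series"))
  mode <- attr(series, "mode")
  probe <- attr(series, "probe_concentration")
  X <- log10(series$concentration)
  Y <- series$signal
  if (diff(range(Y)) < noise_floor)
    stop("fit_titration: no dose response (signal range ",
         signif(diff(range(Y)), 3), " mp below noise floor)")
  w <- if (is.null(weights)) rep(1, length(Y)) else weights
  b0 <- min(Y); t0 <- max(Y)
  x_mid <- X[which.min(abs(Y - (b0 + t0) / 2))]
  best <- NULL
  for (h0 in c(0.5, -0.5, 1, -1, 2, -2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        Y ~ fourpl(X, bottom, top, log_ec50, hill_slope),
        start = list(bottom = b0, top = t0, log_ec50 = x_mid,
                     hill_slope = h0),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          log_ec50 = NA_real_, hill_slope = NA_real_,
                          ec50 = NA_real_, se = NULL, converged = FALSE,
                          tight_binding_flag = FALSE, extrapolated = NA,
                          mode = mode, residuals = NULL, fitted = NULL,
                          data = series, rss = NA_real_),
                     class = "fp_fit"))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  if (cf[["top"]] < cf[["bottom"]]) {   # canonicalise: top >= bottom
    tmp <- cf[["top"]]; cf[["top"]] <- cf[["bottom"]]; cf[["bottom"]] <- tmp
    tmp <- se[["top"]]; se[["top"]] <- se[["bottom"]]; se[["bottom"]] <- tmp
    cf[["hill_slope"]] <- -cf[["hill_slope"]]
  }
  ec50 <- 10^cf[["log_ec50"]]
  tight <- identical(mode, "direct") && !is.null(probe) &&
    is.finite(ec50) && ec50 < 2 * probe
  structure(list(bottom = cf[["bottom"]], top = cf[["top"]],
                 log_ec50 = cf[["log_ec50"]],
                 hill_slope = cf[["hill_slope"]],
                 ec50 = ec50, se = se, converged = TRUE,
                 tight_binding_flag = isTRUE(tight),
                 extrapolated = ec50 < min(series$concentration) ||
                   ec50 > max(series$concentration),
                 mode = mode,
                 residuals = Y - fourpl(X, cf[["bottom"]], cf[["top"]],
                                        cf[["log_ec50"]], cf[["hill_slope"]]),
                 fitted = fourpl(X, cf[["bottom"]], cf[["top"]],
                                 cf[["log_ec50"]], cf[["hill_slope"]]),
                 data = series, rss = best$rss),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fp_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf("<fp_fit> %s mode: EC50 = %.3g M (log10 = %.3f), hill = %.3f\n",
              x$mode, x$ec50, x$log_ec50, x$hill_slope))
  cat(sprintf("  plateaus: bottom %.1f, top %.1f mp; RSS %.3g%s%s\n",
              x$bottom, x$top, x$rss,
              if (x$tight_binding_flag) "; TIGHT-BINDING (apparent K_D)" else "",
              if (isTRUE(x$extrapolated)) "; EC50 extrapolated" else ""))
  invisible(x)
}

#' Interpret a converged fit as saturation or displacement
#'
#' Labels the curve by its direction of effect (rising signal with
#' concentration = saturation of the labelled probe; falling = probe
#' displacement), reports the EC50 as K_D (direct mode) or IC50
#' (competitive mode) in molar and nM, compares the plateaus against an
#' optional normalised control baseline, and attaches a warning when the
#' Hill-slope sign contradicts the declared mode.
#'
#' @param fit a converged [fit_titration()] result.
#' @param control optional control baseline (mp) drawn as a horizontal
#'   reference (probe-alone in direct mode, uninhibited complex in
#'   competitive mode).
#' @return list with `shape` (`"saturation"`/`"displacement"`),
#'   `constant_name` (`"K_D"`/`"IC50"`), `estimate_molar`, `estimate_nM`,
#'   `tight_binding_flag`, `control_delta` and `warnings`.
#' @export
summarize_displacement <- function(fit, control = NULL) {
  stopifnot(inherits(fit, "fp_fit"))
  if (!fit$converged) stop("summarize_displacement: fit did not converge")
  shape <- if (fit$hill_slope > 0) "saturation" else "displacement"
  warn <- character()
  if (fit$mode == "direct" && shape == "displacement")
    warn <- c(warn, "direct-mode fit has falling signal (negative Hill slope)")
  if (fit$mode == "competitive" && shape == "saturation")
    warn <- c(warn, "competitive-mode fit has rising signal (positive Hill slope)")
  constant <- if (fit$mode == "direct") "K_D" else "IC50"
  ctrl_delta <- if (is.null(control)) NULL else {
    ref <- if (shape == "saturation") fit$bottom else fit$top
    ref - control
  }
  list(shape = shape, constant_name = constant,
       estimate_molar = fit$ec50, estimate_nM = fit$ec50 * 1e9,
       tight_binding_flag = fit$tight_binding_flag,
       control_delta = ctrl_delta, warnings = warn)
}
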