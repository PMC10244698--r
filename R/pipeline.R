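#' Run a configured analysis stage
#'
#' Thin orchestration layer over the package's stages, suitable for
#' scripting and for the bundled command-line wrapper. The config is a
#' named list (or a path to a JSON file of one) with a `stage` field and
#' stage-specific parameters:
#'
#' \describe{
#'   \item{`scan`}{`fasta` (path), `pattern` (`"rbh3"`/`"bh3"`), optional
#'     `domains` (TSV path, see [read_domain_table()]), `out` (TSV path).}
#'   \item{`csp`}{`apo`, `bound` (paths; `bound` may be a vector for
#'     replicates), `dialect` (`"tsv"`/`"nmrstar"`), optional `cutoff`,
#'     `sentinel`, `n_sd`, `pdb`/`pdb_out` for structure mapping, `out`
#'     (CSV prefix).}
#'   \item{`fit`}{`csv` (titration path), `mode`, optional `probe`
#'     (concentration with unit), `out` (JSON report path).}
#'   \item{`simulate`}{`kind` (`"sequences"`/`"peaklists"`/`"titration"`),
#'     `seed`, kind-specific parameters, `out` (output directory).}
#' }
#'
#' Every invocation writes a machine-readable run log
#' (`<out>.runlog.json`) recording the package version, the full config
#' and the seed, so outputs are reproducible bit-for-bit from
#' (inputs, config, seed).
#'
#' @param config named list or path to a JSON config file.
#' @return invisibly, a named list of output paths (plus stage results).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("run_pipeline: no such config: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$stage))
  for (p in intersect(c("fasta", "domains", "apo", "bound", "csv", "pdb"),
                      names(config))) {
    missing <- !vapply(config[[p]], file.exists, logical(1))
    if (any(missing))
      stop("run_pipeline: input path does not exist: ",
           paste(config[[p]][missing], collapse = ", "))
  }
  result <- switch(config$stage,
                   scan = pipeline_scan(config),
                   csp = pipeline_csp(config),
                   fit = pipeline_fit(config),
                   simulate = pipeline_simulate(config),
                   stop("run_pipeline: unknown stage: ", config$stage))
  log_path <- paste0(config$out %||% "run", ".runlog.json")
  jsonlite::write_json(
    list(package = "rbh3tools",
         version = as.character(utils::packageVersion("rbh3tools")),
         timestamp = NULL,  # deliberately omitted: logs must be bit-reproducible
         config = config),
    log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(result, list(runlog = log_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_scan <- function(cfg) {
  pats <- default_patterns()
  pattern <- switch(cfg$pattern %||% "rbh3", rbh3 = pats$rbh3,
                    bh3 = pats$bh3,
                    stop("run_pipeline: pattern must be 'rbh3' or 'bh3'"))
  records <- read_fasta(cfg$fasta)
  if (!is.null(cfg$domains)) {
    tab <- read_domain_table(cfg$domains)
    records <- unlist(lapply(records, cut_domains, table = tab),
                      recursive = FALSE)
  }
  res <- scan_domains(records, pattern)
  out <- cfg$out %||% "matches.tsv"
  all_matches <- do.call(rbind, res$matches)
  write_matches_tsv(all_matches, out)
  list(matches = res$matches, summary = res$summary, out = out)
}

pipeline_csp <- function(cfg) {
  dialect <- cfg$dialect %||% "tsv"
  apo <- read_peaklist(cfg$apo, dialect = dialect, condition = "apo")
  bounds <- lapply(seq_along(cfg$bound), function(i)
    read_peaklist(cfg$bound[[i]], dialect = dialect, condition = "bound",
                  replicate_id = i))
  cutoff <- cfg$cutoff %||% 0.05
  sentinel <- cfg$sentinel %||% -0.005
  n_sd <- cfg$n_sd %||% 1
  tables <- lapply(bounds, function(b)
    csp_table(apo, b, cutoff = cutoff, sentinel = sentinel))
  summaries <- lapply(tables, summarize_csp, n_sd = n_sd)
  consensus <- csp_consensus(summaries)
  out <- cfg$out %||% "csp"
  for (i in seq_along(tables))
    write_csp_csv(tables[[i]], sprintf("%s_replicate%d.csv", out, i))
  summary_df <- data.frame(
    replicate = seq_along(summaries),
    mean = vapply(summaries, `[[`, numeric(1), "mean"),
    sd = vapply(summaries, `[[`, numeric(1), "sd"),
    threshold_1sd = vapply(summaries, `[[`, numeric(1), "threshold_1sd"),
    threshold_2sd = vapply(summaries, `[[`, numeric(1), "threshold_2sd"),
    significant = vapply(summaries, function(s)
      paste(s$significant_residues, collapse = ";"), character(1)))
  utils::write.csv(summary_df, paste0(out, "_summary.csv"), row.names = FALSE)
  writeLines(consensus, paste0(out, "_consensus.txt"))
  mapped <- NULL
  if (!is.null(cfg$pdb)) {
    mapped <- map_to_structure(tables[[1]], consensus, cfg$pdb,
                               cfg$pdb_out %||% paste0(out, "_bfactor.pdb"),
                               offset = cfg$offset %||% 0L)
  }
  list(tables = tables, summaries = summaries, consensus = consensus,
       mapped = mapped, out = out)
}

pipeline_fit <- function(cfg) {
  probe <- if (is.null(cfg$probe)) NULL else parse_concentration(cfg$probe)
  series <- read_titration_csv(cfg$csv, mode = cfg$mode %||% "direct",
                               probe_concentration = probe)
  fit <- fit_titration(series)
  report <- summarize_displacement(fit)
  out <- cfg$out %||% "fit.json"
  jsonlite::write_json(
    list(mode = fit$mode, converged = fit$converged,
         bottom = fit$bottom, top = fit$top, log_ec50 = fit$log_ec50,
         hill_slope = fit$hill_slope, ec50_molar = fit$ec50,
         ec50_nM = fit$ec50 * 1e9, se = as.list(fit$se),
         tight_binding_flag = fit$tight_binding_flag,
         extrapolated = fit$extrapolated, shape = report$shape,
         constant = report$constant_name, warnings = report$warnings),
    out, auto_unbox = TRUE, digits = NA)
  curve_csv <- sub("\\.json$", "_curve.csv", out)
  utils::write.csv(data.frame(concentration = series$concentration,
                              signal = series$signal, fitted = fit$fitted,
                              residual = fit$residuals),
                   curve_csv, row.names = FALSE)
  list(fit = fit, report = report, out = out, curve = curve_csv)
}

pipeline_simulate <- function(cfg) {
  kind <- cfg$kind %||% stop("run_pipeline: simulate needs 'kind'")
  seed <- cfg$seed %||% 1L
  dir <- cfg$out %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "sequences") {
    pats <- default_patterns()
    g <- gen_sequences(n = cfg$n %||% 10L, length = cfg$length %||% 60L,
                       implant_fraction = cfg$implant_fraction %||% 0.5,
                       pattern = pats[[cfg$pattern %||% "rbh3"]], seed = seed)
    write_fasta(g$records, file.path(dir, "sequences.fasta"))
    write_truth_json(g$truth, file.path(dir, "sequences_truth.json"))
    return(list(truth = g$truth, out = dir))
  }
  if (kind == "peaklists") {
    g <- gen_peaklist_pair(
      n_residues = cfg$n_residues %||% 80L,
      shift_residues = unlist(cfg$shift_residues) %||% character(),
      dropout = unlist(cfg$dropout) %||% character(),
      sidepeak = unlist(cfg$sidepeak) %||% character(),
      replicates = cfg$replicates %||% 3L, seed = seed)
    write_peaklist(g$apo, file.path(dir, "apo.tsv"))
    for (i in seq_along(g$bound))
      write_peaklist(g$bound[[i]], file.path(dir, sprintf("bound%d.tsv", i)))
    write_truth_json(g$truth, file.path(dir, "peaklists_truth.json"))
    return(list(truth = g$truth, out = dir))
  }
  if (kind == "titration") {
    params <- list(bottom = cfg$bottom %||% 40, top = cfg$top %||% 120,
                   log_ec50 = cfg$log_ec50 %||% log10(8.8e-8),
                   hill = cfg$hill %||% -1)
    design <- fp_design(cfg$cmin %||% 3e-10, cfg$cmax %||% 3e-6,
                        cfg$n_points %||% 7L)
    g <- gen_titration(cfg$mode %||% "competitive", params, design,
                       noise_sd = cfg$noise_sd %||% 2,
                       replicates = cfg$replicates %||% 1L, seed = seed)
    write_titration_csv(g$series, file.path(dir, "titration.csv"))
    write_truth_json(g$truth, file.path(dir, "titration_truth.json"))
    return(list(truth = g$truth, out = dir))
  }
  stop("run_pipeline: unknown simulate kind: ", kind)
}
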