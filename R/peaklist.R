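#' Construct an assigned 2D amide peak list
#'
#' Represents the cross-peaks of a 2D [1H,15N]-HSQC spectrum. Each row is
#' one amide: `label` is a residue identifier like `"M110"` (empty string
#' for unassigned peaks), `delta_H` / `delta_N` the 1H / 15N chemical
#' shifts in ppm, and `intensity` an optional peak height.
#'
#' @param peaks data frame with columns `label`, `delta_H`, `delta_N` and
#'   optionally `intensity`.
#' @param condition `"apo"` or `"bound"`.
#' @param replicate_id integer replicate index.
#' @return object of class `peak_list` (a data frame with attributes
#'   `condition` and `replicate_id`).
#' @export
peak_list <- function(peaks, condition = c("apo", "bound"), replicate_id = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(peaks),
            all(c("label", "delta_H", "delta_N") %in% names(peaks)))
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  peaks <- peaks[, c("label", "delta_H", "delta_N", "intensity")]
  peaks$label <- as.character(peaks$label)
  peaks$label[is.na(peaks$label)] <- ""
  if (!all(is.finite(peaks$delta_H)) || !all(is.finite(peaks$delta_N)))
    stop("peak_list: non-finite chemical shifts")
  assigned <- peaks$label[nzchar(peaks$label)]
  if (anyDuplicated(assigned))
    stop("peak_list: duplicate assigned labels: ",
         paste(unique(assigned[duplicated(assigned)]), collapse = ", "))
  structure(peaks, condition = condition,
            replicate_id = as.integer(replicate_id),
            class = c("peak_list", "data.frame"))
}

#' Residue number encoded in a peak label
#'
#' Peak labels follow the one-letter-code + residue-number dialect
#' ("M110"); the regex is configurable for other dialects.
#'
#' @param labels character vector of labels.
#' @param regex regular expression with the residue number as first group.
#' @return integer vector (NA where the label does not parse).
#' @export
label_residue_number <- function(labels, regex = "^[A-Za-z]([0-9]+)$") {
  m <- regmatches(labels, regexec(regex, labels))
  vapply(m, function(g) if (length(g) >= 2) as.integer(g[2]) else NA_integer_,
         integer(1))
}

#' Read a peak list from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv`}{tab-delimited with header columns `label`, `delta_H`,
#'     `delta_N` and optional `intensity`.}
#'   \item{`nmrstar`}{an NMR-STAR (BMRB) file; the assigned chemical-shift
#'     loop (`_Atom_chem_shift`) is read and backbone amide `H`/`N` shifts
#'     are paired per residue into one peak per amide.}
#' }
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @param condition,replicate_id metadata attached to the returned list.
#' @return a [peak_list()].
#' @export
read_peaklist <- function(path, dialect = c("tsv", "nmrstar"),
                          condition = "apo", replicate_id = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_peaklist: no such file: ", path)
  peaks <- switch(dialect,
                  tsv = read_peaklist_tsv(path),
                  nmrstar = read_peaklist_nmrstar(path))
  peak_list(peaks, condition = condition, replicate_id = replicate_id)
}

read_peaklist_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("label", "delta_H", "delta_N")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_peaklist: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Minimal NMR-STAR loop extraction
#'
#' Parses `loop_` blocks of an NMR-STAR file into data frames keyed by tag
#' category. Handles whitespace-separated values and single/double-quoted
#' tokens; multiline (semicolon-delimited) values are not needed for
#' chemical-shift loops and are not supported.
#' @keywords internal
nmrstar_loops <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loops <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (identical(lines[i], "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        tags <- c(tags, strsplit(lines[i], "\\s+")[[1]][1])
        i <- i + 1L
      }
      vals <- character()
      while (i <= length(lines) && !identical(lines[i], "stop_")) {
        ln <- lines[i]
        if (nzchar(ln) && !startsWith(ln, "#")) {
          toks <- regmatches(ln, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", ln))[[1]]
          toks <- gsub("^['\"]|['\"]$", "", toks)
          vals <- c(vals, toks)
        }
        i <- i + 1L
      }
      if (length(tags) && length(vals) %% length(tags) == 0 && length(vals)) {
        mat <- matrix(vals, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- tags
        cat_name <- sub("\\..*$", "", tags[1])
        loops[[length(loops) + 1L]] <- df
        names(loops)[length(loops)] <- cat_name
      }
    }
    i <- i + 1L
  }
  loops
}

read_peaklist_nmrstar <- function(path) {
  loops <- nmrstar_loops(path)
  cs <- loops[names(loops) == "_Atom_chem_shift"]
  if (!length(cs))
    stop("read_peaklist: no _Atom_chem_shift loop in ", path)
  cs <- cs[[1]]
  col <- function(stem) {
    hit <- grep(paste0("\\.", stem, "$"), names(cs), value = TRUE)
    if (!length(hit)) stop("read_peaklist: NMR-STAR loop lacks tag .", stem)
    cs[[hit[1]]]
  }
  atom <- col("Atom_ID")
  seqid <- as.integer(col("Seq_ID"))
  comp <- col("Comp_ID")
  val <- as.numeric(col("Val"))
  keep <- atom %in% c("H", "N")
  atom <- atom[keep]; seqid <- seqid[keep]; comp <- comp[keep]; val <- val[keep]
  res1 <- aa3to1(comp)
  split_h <- atom == "H"
  h <- data.frame(seqid = seqid[split_h], res = res1[split_h],
                  delta_H = val[split_h])
  n <- data.frame(seqid = seqid[!split_h], delta_N = val[!split_h])
  merged <- merge(h, n, by = "seqid")
  if (!nrow(merged))
    stop("read_peaklist: no residues with both H and N shifts in ", path)
  merged <- merged[order(merged$seqid), ]
  data.frame(label = paste0(merged$res, merged$seqid),
             delta_H = merged$delta_H, delta_N = merged$delta_N,
             intensity = NA_real_, stringsAsFactors = FALSE)
}

aa3to1 <- function(x) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- map[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Write a peak list as TSV
#'
#' @param peaks a [peak_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  utils::write.table(as.data.frame(peaks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
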