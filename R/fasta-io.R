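#' Read protein sequences from FASTA
#'
#' Reads a (multi-record) FASTA file via Biostrings and returns
#' [sequence_record()]s. Sequences are upper-cased. The parent-protein
#' numbering of the first residue defaults to 1 and can be set per record
#' with a `start=` token in the header, e.g. `>RRM1_rBH3 start=102`.
#'
#' @param path FASTA file.
#' @return list of [sequence_record()]s, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("read_fasta: parse error in '",
                                           path, "': ", conditionMessage(e)))
  if (length(set) == 0) stop("read_fasta: no records in ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    if (is.null(header) || !nzchar(header))
      stop("read_fasta: malformed (empty) header for record ", i)
    fields <- strsplit(header, "\\s+")[[1]]
    id <- fields[1]
    desc <- paste(fields[-1], collapse = " ")
    start <- 1L
    tok <- grep("^start=", fields[-1], value = TRUE)
    if (length(tok)) {
      start <- suppressWarnings(as.integer(sub("^start=", "", tok[1])))
      if (is.na(start)) stop("read_fasta: bad start= token in header: ", header)
    }
    sequence_record(id = id, residues = as.character(set[[i]]),
                    numbering_offset = start, description = desc)
  })
}

#' Write sequence records to FASTA
#'
#' Headers carry a `start=` token whenever the numbering offset is not 1,
#' so that a write/read round trip preserves parent numbering. Output is
#' byte-deterministic for identical input.
#'
#' @param records list of [sequence_record()]s.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(records, function(r) {
    header <- paste0(">", r$id,
                     if (r$numbering_offset != 1L)
                       paste0(" start=", r$numbering_offset) else "",
                     if (nzchar(r$description)) paste0(" ", r$description) else "")
    body <- substring(r$residues,
                      seq(1, nchar(r$residues), by = width),
                      pmin(seq(1, nchar(r$residues), by = width) + width - 1,
                           nchar(r$residues)))
    c(header, body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a domain-definition table
#'
#' TSV with columns `id`, `start`, `end` (parent numbering, 1-based
#' inclusive), used with [cut_domains()] to excise domains from a
#' full-length record.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_domain_table: missing column(s): ", paste(miss, collapse = ", "))
  tab
}
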