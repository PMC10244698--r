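#' Amino-acid alphabet accepted by the scanner
#'
#' The 20 standard one-letter codes plus "X" (unknown). "X" is accepted by
#' the parser but never matches any residue class.
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a BH3/rBH3 motif pattern
#'
#' A motif pattern is a register of residue classes at fixed signed offsets
#' from a conserved acidic anchor (Asp/Glu in the canonical BH3, the salt
#' bridge partner of Arg263 in the MCL1 groove). The hydrophobic positions
#' H1-H4 engage the p1-p4 sub-pockets of the MCL1 BH3-binding groove. In
#' the forward BH3 the hydrophobics precede the anchor (negative offsets);
#' in the reverse rBH3 the same register is read C-to-N, so the
#' hydrophobics follow the anchor (positive offsets).
#'
#' @param name pattern name.
#' @param direction `"reverse_rBH3"` (required offsets positive) or
#'   `"forward_BH3"` (required offsets negative).
#' @param anchor_classes character vector of residues allowed at the anchor
#'   (offset 0), typically `c("D", "E")`.
#' @param offsets data frame with columns `offset` (signed integer),
#'   `label` (one of `"H1".."H4"`), `allowed` (list column of character
#'   vectors) and `required` (logical).
#' @return an object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, direction = c("reverse_rBH3", "forward_BH3"),
                          anchor_classes, offsets) {
  direction <- match.arg(direction)
  stopifnot(is.character(anchor_classes), length(anchor_classes) >= 1)
  stopifnot(is.data.frame(offsets),
            all(c("offset", "label", "allowed", "required") %in% names(offsets)))
  if (anyDuplicated(offsets$offset))
    stop("motif_pattern: offsets must be unique")
  if (!all(offsets$label %in% c("H1", "H2", "H3", "H4")))
    stop("motif_pattern: position labels must be H1..H4")
  req <- offsets[offsets$required, , drop = FALSE]
  if (!all(c("H1", "H2", "H3") %in% req$label))
    stop("motif_pattern: H1, H2 and H3 must be required positions")
  if (direction == "reverse_rBH3" && any(req$offset <= 0))
    stop("motif_pattern: reverse_rBH3 requires positive required offsets")
  if (direction == "forward_BH3" && any(req$offset >= 0))
    stop("motif_pattern: forward_BH3 requires negative required offsets")
  bad <- vapply(offsets$allowed,
                function(a) !all(a %in% setdiff(AA_ALPHABET, "X")),
                logical(1))
  if (any(bad))
    stop("motif_pattern: allowed residue sets must use standard one-letter codes")
  structure(
    list(name = name, direction = direction,
         anchor_classes = sort(unique(anchor_classes)),
         offsets = offsets[order(offsets$offset), , drop = FALSE]),
    class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (%s)\n", x$name, x$direction))
  cat(sprintf("  anchor (offset 0): {%s}\n", paste(x$anchor_classes, collapse = "")))
  for (i in seq_len(nrow(x$offsets))) {
    o <- x$offsets[i, ]
    cat(sprintf("  %s at %+d: {%s}%s\n", o$label, o$offset,
                paste(o$allowed[[1]], collapse = ""),
                if (o$required) "" else " (optional)"))
  }
  invisible(x)
}

#' Default rBH3 and BH3 register patterns
#'
#' Offsets are derived from the labelled PTBP1 rBH3 instance
#' (anchor E105, H3 A107, H2 M110, H1 Y114, i.e. +2/+5/+9) and mirror the
#' BAK BH3 register (H1/H2/H3 at -9/-5/-2 from the conserved Asp). H4 is
#' optional in both: known rBH3 instances (PTBP1, p18/CDKN2C) lack a
#' hydrophobic residue at H4. Allowed sets cover every residue observed at
#' each position across the documented instances (including the
#' D->E anchor and L->M H2 substitutions) without admitting polar residues:
#' anchor {D,E}; H2 {F,I,L,M,V}; H3 {A,F,I,L,M,V,Y}; H1 and H4
#' {A,F,I,L,M,V,W,Y}.
#'
#' @return a named list with elements `rbh3` and `bh3`, both
#'   `motif_pattern` objects whose offsets are exact negations of each
#'   other.
#' @examples
#' pats <- default_patterns()
#' pats$rbh3
#' @export
default_patterns <- function() {
  h1 <- c("L", "I", "V", "M", "F", "Y", "W", "A")
  h2 <- c("L", "M", "I", "V", "F")
  h3 <- c("A", "V", "I", "L", "M", "F", "Y")
  rbh3 <- motif_pattern(
    name = "rBH3", direction = "reverse_rBH3", anchor_classes = c("D", "E"),
    offsets = data.frame(
      offset = c(-2L, 2L, 5L, 9L),
      label = c("H4", "H3", "H2", "H1"),
      allowed = I(list(h1, h3, h2, h1)),
      required = c(FALSE, TRUE, TRUE, TRUE)))
  bh3 <- mirror_pattern(rbh3, name = "BH3")
  list(rbh3 = rbh3, bh3 = bh3)
}

#' Mirror a motif pattern
#'
#' Negates every offset and flips the direction, turning an rBH3 register
#' into the corresponding forward BH3 register (and vice versa). Residue
#' classes are unchanged: the rBH3 is by definition the BH3 register read
#' C-to-N.
#'
#' @param pattern a `motif_pattern`.
#' @param name name for the mirrored pattern; defaults to the original
#'   name with a `*` suffix.
#' @return a `motif_pattern` in the opposite direction.
#' @export
mirror_pattern <- function(pattern, name = paste0(pattern$name, "*")) {
  stopifnot(inherits(pattern, "motif_pattern"))
  off <- pattern$offsets
  off$offset <- -off$offset
  motif_pattern(
    name = name,
    direction = if (pattern$direction == "reverse_rBH3") "forward_BH3" else "reverse_rBH3",
    anchor_classes = pattern$anchor_classes,
    offsets = off)
}

#' Span of a motif pattern
#'
#' Number of residues covered by the anchor plus all required positions.
#' @param pattern a `motif_pattern`.
#' @param include_optional also count optional positions.
#' @return integer span.
#' @export
pattern_span <- function(pattern, include_optional = FALSE) {
  off <- pattern$offsets
  keep <- if (include_optional) rep(TRUE, nrow(off)) else off$required
  rng <- range(c(0L, off$offset[keep]))
  as.integer(rng[2] - rng[1] + 1L)
}
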