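#' Write per-residue CSPs into the B-factor column of a PDB file
#'
#' Produces a coordinate file colourable by CSP in PyMOL/ChimeraX: every
#' atom of a residue with a CSP value gets that value as its B-factor
#' (residues without a value get 0). Consensus residues are additionally
#' written to a sidecar file of PyMOL selection commands. Residues present
#' in the CSP table but absent from the coordinates are collected in a
#' skipped-residue report rather than raising an error.
#'
#' @param records a [csp_table()] (or data frame with `residue`, `csp`,
#'   `status`).
#' @param consensus character vector of consensus residue labels.
#' @param pdb_in input PDB path.
#' @param pdb_out output PDB path.
#' @param sidecar path for the PyMOL selection sidecar (default
#'   `<pdb_out>.pml`).
#' @param offset added to CSP residue numbers to obtain coordinate-file
#'   residue numbers (default 0).
#' @param scale multiplier applied to CSPs before writing (default 1).
#'   The PDB B-factor field holds two decimals, so raw amide CSPs
#'   (~0.01 ppm) lose precision at scale 1; `scale = 100` preserves them
#'   (B-factor = CSP in ppm x 100).
#' @return invisibly, a list with `skipped` (labels not found in the
#'   coordinates), `pdb_out` and `sidecar`.
#' @export
map_to_structure <- function(records, consensus, pdb_in, pdb_out,
                             sidecar = paste0(pdb_out, ".pml"), offset = 0L,
                             scale = 1) {
  pdb <- bio3d::read.pdb(pdb_in)
  resnum <- label_residue_number(records$residue) + as.integer(offset)
  use <- records$status %in% c("matched", "conformation_shift") &
    is.finite(records$csp) & !is.na(resnum)
  pdb$atom$b <- 0
  skipped <- character()
  for (i in which(use)) {
    sel <- pdb$atom$resno == resnum[i]
    if (!any(sel)) {
      skipped <- c(skipped, records$residue[i])
      next
    }
    pdb$atom$b[sel] <- records$csp[i] * scale
  }
  bio3d::write.pdb(pdb, file = pdb_out)
  cons_num <- label_residue_number(consensus) + as.integer(offset)
  cons_num <- cons_num[!is.na(cons_num) & cons_num %in% pdb$atom$resno]
  lines <- c("# PyMOL commands: consensus CSP residues",
             if (length(cons_num))
               sprintf("select csp_consensus, resi %s",
                       paste(sort(cons_num), collapse = "+"))
             else "# empty consensus set",
             "spectrum b, white_red")
  writeLines(lines, sidecar)
  invisible(list(skipped = sort(unique(skipped)), pdb_out = pdb_out,
                 sidecar = sidecar))
}
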