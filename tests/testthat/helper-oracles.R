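# Independent oracles and small fixture builders used across the suite.

# Brute-force motif scan: checks every anchor placement directly against the
# pattern definition, one window at a time, independently of scan_sequence's
# vectorised bookkeeping.
brute_force_scan <- function(seq_rec, pattern) {
  aa <- strsplit(seq_rec$residues, "")[[1]]
  n <- length(aa)
  off <- pattern$offsets
  hits <- integer()
  for (i in seq_len(n)) {
    if (!aa[i] %in% pattern$anchor_classes) next
    ok <- TRUE
    for (j in seq_len(nrow(off))) {
      if (!off$required[j]) next
      p <- i + off$offset[j]
      if (p < 1 || p > n || !aa[p] %in% off$allowed[[j]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i + seq_rec$numbering_offset - 1L)
  }
  hits
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Exhaustive minimum-total-distance assignment between equal-size peak lists
# in the scaled (dH, dN/5) space. Returns NULL unless the optimum is unique.
assignment_oracle <- function(apo, bound) {
  n <- nrow(apo)
  sd2 <- function(i, j) sqrt((apo$delta_H[i] - bound$delta_H[j])^2 +
                             ((apo$delta_N[i] - bound$delta_N[j]) / 5)^2)
  best <- NULL; best_total <- Inf; unique_best <- TRUE
  for (p in all_perms(n)) {
    total <- sum(vapply(seq_len(n), function(i) sd2(i, p[i]), numeric(1)))
    if (total < best_total - 1e-12) {
      best <- p; best_total <- total; unique_best <- TRUE
    } else if (abs(total - best_total) <= 1e-12) {
      unique_best <- FALSE
    }
  }
  if (!unique_best) return(NULL)
  list(perm = unlist(best), total = best_total)
}

# Well-separated random peak coordinates: minimum pairwise scaled distance
# sep, so nearest-neighbour matching under small jitter is unambiguous.
separated_peaks <- function(n, sep = 0.3, seed = 1) {
  set.seed(seed)
  H <- numeric(0); N <- numeric(0)
  while (length(H) < n) {
    h <- runif(1, 7, 9.5); nn <- runif(1, 105, 130)
    if (length(H) == 0 ||
        min(sqrt((H - h)^2 + ((N - nn) / 5)^2)) > sep) {
      H <- c(H, h); N <- c(N, nn)
    }
  }
  data.frame(label = paste0("A", seq_len(n)), delta_H = H, delta_N = N,
             intensity = 100)
}

# Minimal three-residue PDB text fixture (poly-glycine backbone).
write_tiny_pdb <- function(path, resnos = c(109, 110, 111)) {
  lines <- character()
  serial <- 0L
  for (r in resnos) {
    for (at in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, at, r, r * 1.0, serial * 0.5, 0.0, 1.00, 0.00,
        substr(at, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
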