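# Shared fixtures and independent oracles. Oracles here deliberately
# re-derive results from first principles (grid scans, bisection, naive
# text parsing) and never call the code paths they check.

R_KCAL <- 1.9872e-3

# published (dH, dCp, Tm) inputs and the printed derived values they must
# reproduce
table1_rows <- function() {
  data.frame(
    construct = c("Wt", "E89", "E112", "E103"),
    dH = c(19.2, 29.5, 30.0, 31.3),
    dCp = c(2.24, 1.73, 1.73, 1.69),
    Tm_C = c(33.6, 37.2, 37.3, 38.9),
    Tc_C_printed = c(16.8, 4.1, 3.7, 3.1),
    dS_printed = c(0.063, 0.095, 0.097, 0.10),
    folding_printed = c(61, 80, 80, 83))
}

# direct evaluation of the stability curve, independent of the package
oracle_dg <- function(T, dH, dCp, Tm) {
  dH * (1 - T / Tm) + dCp * ((T - Tm) - T * log(T / Tm))
}

# grid-scan argmax of the stability curve
oracle_ts_grid <- function(dH, dCp, Tm, step = 0.001) {
  grid <- seq(200, Tm, by = step)
  grid[which.max(oracle_dg(grid, dH, dCp, Tm))]
}

# plain bisection for the cold root on [200, Ts]
oracle_tc_bisect <- function(dH, dCp, Tm, tol = 1e-4) {
  lo <- 200; hi <- oracle_ts_grid(dH, dCp, Tm, step = 0.01)
  if (oracle_dg(lo, dH, dCp, Tm) >= 0) stop("no cold root for oracle")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oracle_dg(mid, dH, dCp, Tm) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

random_valid_params <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(dH = runif(n, 10, 50), dCp = runif(n, 1, 4),
             Tm = runif(n, 300, 330))
}

# in-memory alignment in the bio3d fasta layout
toy_alignment <- function(rows) {
  ali <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(ali) <- names(rows)
  structure(list(ali = ali, id = names(rows)), class = "fasta")
}

# ---- naive residue-interaction-network re-implementation ----
# Parses the multi-model PDB by fixed-column substring, takes side-chain
# heavy atoms (CA for glycine), minimum pairwise atom distance per frame
# via explicit double loops, strict d < threshold count, and the
# "more than 99% beyond threshold" filter. Shares no code with the
# package.
naive_rin <- function(pdb_path, residues, threshold = 0.6,
                      min_persistence = 0.01) {
  lines <- readLines(pdb_path)
  frames <- list(); cur <- NULL
  for (l in lines) {
    tag <- substr(l, 1, 6)
    if (tag == "MODEL ") cur <- list()
    else if (tag == "ENDMDL") { frames[[length(frames) + 1L]] <- cur; cur <- NULL }
    else if (tag %in% c("ATOM  ", "HETATM") && !is.null(cur)) {
      cur[[length(cur) + 1L]] <- list(
        name = trimws(substr(l, 13, 16)),
        resn = trimws(substr(l, 18, 20)),
        resno = as.integer(substr(l, 23, 26)),
        xyz = c(as.numeric(substr(l, 31, 38)), as.numeric(substr(l, 39, 46)),
                as.numeric(substr(l, 47, 54))))
    }
  }
  sidechain <- function(frame, resno) {
    atoms <- Filter(function(a) a$resno == resno, frame)
    sc <- Filter(function(a) !(a$name %in% c("N", "CA", "C", "O", "OXT")) &&
                   !grepl("^[0-9]*H", a$name), atoms)
    if (!length(sc)) sc <- Filter(function(a) a$name == "CA", atoms)
    sc
  }
  residues <- sort(residues)
  pairs <- t(utils::combn(residues, 2))
  counts <- numeric(nrow(pairs))
  for (f in frames) {
    for (k in seq_len(nrow(pairs))) {
      a <- sidechain(f, pairs[k, 1]); b <- sidechain(f, pairs[k, 2])
      dmin <- Inf
      for (ai in a) for (bi in b)
        dmin <- min(dmin, sqrt(sum((ai$xyz - bi$xyz)^2)) / 10)
      if (dmin < threshold) counts[k] <- counts[k] + 1
    }
  }
  p <- counts / length(frames)
  data.frame(i = pairs[, 1], j = pairs[, 2], persistence = p,
             retained = p >= min_persistence)
}

# all-charged selection over residue numbers, for tests that bypass the
# alignment stage
fake_selection <- function(positions, classes = NULL, residues = NULL) {
  n <- length(positions)
  out <- data.frame(
    position = positions,
    ref_residue = residues %||% rep("E", n),
    charge_class = classes %||% rep("acidic", n),
    provenance = rep("REF1", n), stringsAsFactors = FALSE)
  class(out) <- c("charge_selection", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
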