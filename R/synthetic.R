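# Deterministic generators for every input the pipeline consumes:
# thermograms with known thermodynamic truth, toy multi-model PDB
# trajectories with planted contact persistences, and orthologue
# alignments with planted charged columns. Each generator returns its
# truth record so tests can compute expected pipeline output without
# running the pipeline.

#' Default synthetic CD baselines
#'
#' Plausible 222 nm helicity-loss baselines used by the thermogram
#' generator: a folded baseline near -10 mdeg and a shallower unfolded
#' baseline near -3 mdeg. Fixture values, not measurements.
#' @export
default_baselines <- function() {
  list(folded = c(-10, 0.01), unfolded = c(-3, 0.02))
}

#' Generate a synthetic CD thermogram with known truth
#'
#' Produces `theta(T) = model_signal(T) + N(0, noise_sd^2)` on a regular
#' Celsius grid, emulating a two-state melt with visible cold and heat
#' transitions. Deterministic for a given `seed`.
#'
#' @param params true [stability_params].
#' @param baselines list with `folded` and `unfolded` `c(intercept, slope)`
#'   baselines (mdeg, mdeg/C); defaults to [default_baselines()].
#' @param T_range temperature range `c(lo, hi)` in C (default 0-80).
#' @param step grid step in C.
#' @param noise_sd additive Gaussian noise SD in mdeg.
#' @param seed RNG seed.
#' @param label construct label.
#' @return list with `thermogram` (a [thermogram]) and `truth` (params,
#'   baselines, noise_sd, seed).
#' @export
generate_thermogram <- function(params, baselines = default_baselines(),
                                T_range = c(0, 80), step = 1, noise_sd = 0,
                                seed = 1, label = "synthetic") {
  params <- as_stability_params(params)
  stopifnot(length(T_range) == 2L, T_range[1] < T_range[2], step > 0,
            noise_sd >= 0)
  Tc <- tryCatch(cold_denaturation_temp(params), error = function(e) NA_real_)
  if (is.na(Tc) || Tc - KELVIN_OFFSET < T_range[1])
    warning("cold transition below the temperature range: cold arm not visible",
            call. = FALSE)
  T_C <- seq(T_range[1], T_range[2], by = step)
  clean <- model_signal(T_C, params, baselines)
  noise <- if (noise_sd > 0) {
    # scoped RNG: generators never perturb the caller's random stream
    old <- .Random.seed_exists()
    set.seed(seed)
    n <- stats::rnorm(length(T_C), 0, noise_sd)
    restore_seed(old)
    n
  } else rep(0, length(T_C))
  list(thermogram = thermogram(T_C, clean + noise, label = label),
       truth = list(params = params, baselines = baselines,
                    noise_sd = noise_sd, seed = seed))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a thermogram to CSV
#' @param tg a [thermogram].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  utils::write.csv(data.frame(temperature_C = tg$temperature,
                              ellipticity_mdeg = tg$ellipticity),
                   path, row.names = FALSE)
  invisible(path)
}

# golden-angle fan of unit directions in the y-z plane, used to park
# several contact partners around one target without collisions
contact_direction <- function(k) {
  theta <- 2.399963229728653 * k
  c(0, cos(theta), sin(theta))
}

#' Generate a toy multi-model PDB trajectory with planted contacts
#'
#' Builds a poly-alanine chain whose residues sit 3 nm apart at rest. For
#' each planted edge `(i, j, persistence)`, residue `j` is translated next
#' to residue `i` (side-chain distance 0.55 nm) in exactly
#' `round(persistence * n_frames)` frames chosen reproducibly by seed; in
#' every other frame, and for every non-planted pair, side chains stay at
#' least 0.8 nm apart. The wide margins around the 0.6 nm threshold make
#' planted persistences exact by construction, so network recovery is an
#' equality test. Geometry is verified after construction; conflicting
#' planted edges (e.g. one residue needing two simultaneous distant
#' partners) raise an "infeasible geometry" error.
#'
#' @param n_residues chain length.
#' @param n_frames number of MODEL entries.
#' @param planted_edges `data.frame` with columns `i`, `j`,
#'   `persistence` (each in `[0, 1]`, `i < j`); may have zero rows.
#' @param seed RNG seed for the choice of contact frames.
#' @param path output PDB path (required).
#' @return list with `path`, `truth` (planted edges with realised
#'   `n_contact_frames`, plus `n_residues`, `n_frames`, `seed`).
#' @export
generate_trajectory <- function(n_residues, n_frames, planted_edges = NULL,
                                seed = 1, path) {
  stopifnot(n_residues >= 2L, n_frames >= 1L)
  if (is.null(planted_edges))
    planted_edges <- data.frame(i = integer(), j = integer(),
                                persistence = numeric())
  pe <- as.data.frame(planted_edges)
  if (nrow(pe)) {
    stopifnot(all(c("i", "j", "persistence") %in% names(pe)))
    if (any(pe$i >= pe$j) || any(pe$j > n_residues) || any(pe$i < 1))
      stop("planted edges must satisfy 1 <= i < j <= n_residues")
    if (any(pe$persistence < 0 | pe$persistence > 1))
      stop("planted persistence must lie in [0, 1]")
  }
  spacing <- 30  # Angstrom between residue anchors: 3 nm
  contact_d <- 5.5   # planted side-chain distance, A (0.55 nm)

  # reproducible contact-frame assignment. In each contact frame the
  # higher-numbered residue j is translated next to the stationary i, so a
  # frame is infeasible for an edge iff j is already translated or is the
  # anchor of another translation, or i itself is translated. Several
  # edges may share a stationary anchor i in the same frame (partners fan
  # out on distinct directions).
  old <- .Random.seed_exists(); set.seed(seed)
  as_mover <- vector("list", n_residues)   # frames where residue is translated
  as_anchor <- vector("list", n_residues)  # frames where residue anchors a contact
  active <- vector("list", nrow(pe))
  for (e in seq_len(nrow(pe))) {
    i <- pe$i[e]; j <- pe$j[e]
    m <- round(pe$persistence[e] * n_frames)
    blocked <- unique(c(as_mover[[j]], as_anchor[[j]], as_mover[[i]]))
    free <- setdiff(seq_len(n_frames), blocked)
    if (length(free) < m)
      stop("infeasible geometry: residues ", i, " and ", j,
           " cannot host ", m, " more contact frames")
    active[[e]] <- if (m == 0L) integer(0)
                   else sort(free[sample.int(length(free), m)])
    as_mover[[j]] <- c(as_mover[[j]], active[[e]])
    as_anchor[[i]] <- c(as_anchor[[i]], active[[e]])
  }
  restore_seed(old)

  # alanine-like residue: backbone + CB side chain, offsets from anchor
  atom_offsets <- rbind(N = c(-1.2, 0.8, 0), CA = c(0, 1.5, 0),
                        C = c(1.2, 0.8, 0), O = c(1.9, 1.6, 0),
                        CB = c(0, 0, 0))
  base_anchor <- function(r) c(spacing * r, 0, 0)

  frames_xyz <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    anchors <- t(vapply(seq_len(n_residues), base_anchor, numeric(3)))
    moved <- rep(FALSE, n_residues)
    target <- rep(FALSE, n_residues)
    for (e in seq_len(nrow(pe))) {
      if (!(t %in% active[[e]])) next
      i <- pe$i[e]; j <- pe$j[e]
      if (moved[j] || moved[i] || target[j])
        stop("infeasible geometry: residue ", j,
             " cannot satisfy simultaneous planted contacts in frame ", t)
      anchors[j, ] <- anchors[i, ] + contact_d * contact_direction(e)
      moved[j] <- TRUE; target[i] <- TRUE
    }
    frames_xyz[[t]] <- anchors
  }

  # verify realised side-chain (CB anchor) distances against the truth
  realised <- matrix(0L, n_residues, n_residues)
  for (t in seq_len(n_frames)) {
    d <- as.matrix(stats::dist(frames_xyz[[t]]))
    close <- d < 6 & upper.tri(d)
    if (any(d > 6 & d < 8 & upper.tri(d)))
      stop("infeasible geometry: a pair landed inside the 0.6-0.8 nm guard band")
    realised <- realised + close
  }
  want <- matrix(0L, n_residues, n_residues)
  for (e in seq_len(nrow(pe)))
    want[pe$i[e], pe$j[e]] <- length(active[[e]])
  if (!identical(realised[upper.tri(realised)], want[upper.tri(want)]))
    stop("infeasible geometry: planted contacts conflict with each other")

  # emit multi-model PDB
  con <- file(path, "w"); on.exit(close(con))
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (t in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", t), con)
    serial <- 0L
    for (r in seq_len(n_residues)) {
      for (a in rownames(atom_offsets)) {
        serial <- serial + 1L
        xyz <- frames_xyz[[t]][r, ] + atom_offsets[a, ]
        writeLines(sprintf(fmt, serial, a, "ALA", "A", r,
                           xyz[1], xyz[2], xyz[3], 1, 0,
                           substr(a, 1, 1)), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  truth <- pe
  truth$n_contact_frames <- vapply(active, length, integer(1))
  truth$persistence_exact <- truth$n_contact_frames / n_frames
  list(path = path,
       truth = list(planted_edges = truth, n_residues = n_residues,
                    n_frames = n_frames, seed = seed))
}

NEUTRAL_AA <- c("A", "G", "S", "T", "N", "Q", "L", "V", "I", "F", "M",
                "W", "Y", "P", "C")

#' Generate an orthologue alignment with planted charged columns
#'
#' Random gap-free alignment over a neutral amino-acid alphabet; at each
#' planted column exactly one sequence (chosen by seed) carries a charged
#' residue (D/E/K/R), so the charge-selection rule must recover exactly
#' the planted columns. The first sequence is the reference.
#'
#' @param n_sequences number of aligned sequences (>= 2).
#' @param length alignment length in columns.
#' @param planted_charge_columns integer vector of columns to plant.
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @param reference_id id of the first (reference) sequence.
#' @return list with `alignment` (a `bio3d`-style fasta object), `path`
#'   (or `NULL`), and `truth` (`data.frame`: `column`, `sequence_id`,
#'   `residue`, `charge_class`).
#' @export
generate_alignment <- function(n_sequences, length, planted_charge_columns = integer(),
                               seed = 1, path = NULL, reference_id = "REF1") {
  stopifnot(n_sequences >= 2L, length >= 1L,
            all(planted_charge_columns >= 1L),
            all(planted_charge_columns <= length))
  ids <- c(reference_id, paste0("ORTH", seq_len(n_sequences - 1L) + 1L))
  old <- .Random.seed_exists(); set.seed(seed)
  ali <- matrix(sample(NEUTRAL_AA, n_sequences * length, replace = TRUE),
                nrow = n_sequences, dimnames = list(ids, NULL))
  truth <- lapply(sort(unique(as.integer(planted_charge_columns))), function(col) {
    s <- sample.int(n_sequences, 1L)
    aa <- sample(CHARGED, 1L)
    ali[s, col] <<- aa
    data.frame(column = col, sequence_id = ids[s], residue = aa,
               charge_class = charge_class_of(aa), stringsAsFactors = FALSE)
  })
  restore_seed(old)
  truth <- if (base::length(truth)) do.call(rbind, truth) else
    data.frame(column = integer(), sequence_id = character(),
               residue = character(), charge_class = character())
  if (!is.null(path)) {
    con <- file(path, "w")
    for (s in seq_len(n_sequences)) {
      writeLines(paste0(">", ids[s]), con)
      writeLines(paste(ali[s, ], collapse = ""), con)
    }
    close(con)
  }
  aln <- structure(list(ali = ali, id = ids), class = "fasta")
  list(alignment = aln, path = path, truth = truth)
}
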