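# End-to-end orchestration: a Table-1-style stability report from
# parameter sets or thermograms, a persistence network + cluster report
# from trajectory + alignment, and synthetic-data generation from JSON
# specs. These functions back the command-line front-end shipped in
# inst/cli/coldcurve.R; they log to stderr via message() and write results
# to files only, so pipelines can be composed.

usage_error <- function(msg) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Stability report for a batch of constructs
#'
#' Either recomputes all stability-curve quantities from a CSV of fitted
#' parameters (columns `construct`, `dH`, `dCp`, `Tm_C`), or fits each
#' supplied thermogram file first and then derives the report from the
#' fitted parameters. Exactly one input mode must be used. Per-row
#' failures are reported and the run continues.
#'
#' @param params_csv path to a parameter CSV, or `NULL`.
#' @param thermogram_files character vector of thermogram CSV/TSV paths,
#'   or `NULL`.
#' @param out_dir output directory; `stability_report.csv` and `.json` are
#'   written there (`NULL` skips writing).
#' @return the report `data.frame`, invisibly.
#' @export
cmd_stability <- function(params_csv = NULL, thermogram_files = NULL,
                          out_dir = NULL) {
  if (is.null(params_csv) == is.null(thermogram_files))
    usage_error("supply exactly one of a parameter CSV or thermogram files")
  rows <- list()
  if (!is.null(params_csv)) {
    tab <- utils::read.csv(params_csv, stringsAsFactors = FALSE)
    need <- c("construct", "dH", "dCp", "Tm_C")
    if (!all(need %in% names(tab)))
      usage_error(paste("parameter CSV needs columns:", paste(need, collapse = ", ")))
    if (nrow(tab) == 0L) usage_error("empty parameter table")
    for (r in seq_len(nrow(tab))) {
      rows[[tab$construct[r]]] <- tryCatch(
        stability_report(stability_params(tab$dH[r], tab$dCp[r], tab$Tm_C[r],
                                          celsius = TRUE),
                         construct = tab$construct[r]),
        error = function(e) {
          message("row '", tab$construct[r], "' failed: ", conditionMessage(e))
          NULL
        })
    }
  } else {
    if (length(thermogram_files) == 0L) usage_error("no thermogram files given")
    for (f in thermogram_files) {
      rows[[f]] <- tryCatch({
        tg <- read_thermogram(f)
        fit <- fit_thermogram(tg)
        if (!fit$converged)
          message("fit for '", tg$label, "' did not converge; reporting anyway")
        stability_report(fit$params, construct = tg$label)
      }, error = function(e) {
        message("thermogram '", f, "' failed: ", conditionMessage(e))
        NULL
      })
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("all rows failed")
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stability_report(report,
                           csv = file.path(out_dir, "stability_report.csv"),
                           json = file.path(out_dir, "stability_report.json"))
  }
  invisible(report)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Build a residue interaction network end to end
#'
#' Runs charge-column selection, pair-distance extraction, persistence
#' filtering and acidic-cluster detection, writing `network.graphml`,
#' `network_edges.csv` and `clusters.json` to `out_dir`. Stage names are
#' prefixed to any error; per-stage counts are logged to stderr.
#'
#' @param trajectory multi-model PDB path.
#' @param alignment aligned FASTA path.
#' @param reference_id reference sequence id in the alignment.
#' @param threshold contact threshold, nm.
#' @param min_persistence minimum retained edge persistence.
#' @param secondary_structure optional per-residue annotation
#'   `data.frame(residue, element_label)` or CSV path.
#' @param out_dir output directory (`NULL` skips writing).
#' @return list with `selection`, `distances`, `network`, `clusters`,
#'   invisibly.
#' @export
cmd_build_rin <- function(trajectory, alignment, reference_id,
                          threshold = 0.6, min_persistence = 0.01,
                          secondary_structure = NULL, out_dir = NULL) {
  if (threshold < 0 || min_persistence < 0 || min_persistence > 1)
    usage_error("need threshold >= 0 and min_persistence in [0, 1]")
  sel <- with_stage("select_charged_columns",
                    select_charged_columns(alignment, reference_id))
  message("selected ", nrow(sel), " charged-column residues")
  dist <- with_stage("compute_pair_distances",
                     compute_pair_distances(trajectory, sel))
  message("evaluated ", nrow(dist$pairs), " residue pairs over ",
          dist$n_frames, " frames")
  net <- with_stage("build_network",
                    build_network(dist, sel, threshold, min_persistence))
  message("retained ", igraph::ecount(net$graph), " edges")
  if (is.character(secondary_structure))
    secondary_structure <- utils::read.csv(secondary_structure,
                                           stringsAsFactors = FALSE)
  clusters <- with_stage("cluster_report",
                         cluster_report(net, secondary_structure))
  message("found ", length(clusters), " acidic cluster(s)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_network(net, file.path(out_dir, "network.graphml"), "graphml")
    write_network(net, file.path(out_dir, "network_edges.csv"), "edgelist-csv")
    jsonlite::write_json(clusters, file.path(out_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(selection = sel, distances = dist, network = net,
                 clusters = clusters))
}

#' Generate synthetic datasets from a JSON spec
#'
#' The spec file is a JSON object with a `kind` field
#' (`"thermogram"`, `"trajectory"` or `"alignment"`) plus the fields of
#' the corresponding generator. Data and a `*_truth.json` side-file are
#' written to `out_dir`.
#'
#' @param spec_json path to the spec JSON.
#' @param out_dir output directory.
#' @return list of written paths, invisibly.
#' @export
cmd_simulate <- function(spec_json, out_dir = ".") {
  spec <- jsonlite::read_json(spec_json, simplifyVector = TRUE)
  if (is.null(spec$kind) ||
      !spec$kind %in% c("thermogram", "trajectory", "alignment"))
    usage_error("spec must contain kind: thermogram | trajectory | alignment")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  require_fields <- function(fields) {
    missing <- setdiff(fields, names(spec))
    if (length(missing))
      usage_error(paste0("spec for kind '", spec$kind, "' missing field(s): ",
                         paste(missing, collapse = ", ")))
  }
  seed <- spec$seed %||% 1L
  if (spec$kind == "thermogram") {
    require_fields(c("dH", "dCp", "Tm_C"))
    gen <- generate_thermogram(
      stability_params(spec$dH, spec$dCp, spec$Tm_C, celsius = TRUE),
      baselines = if (!is.null(spec$baselines))
        lapply(spec$baselines, as.numeric) else default_baselines(),
      T_range = spec$T_range %||% c(0, 80), step = spec$step %||% 1,
      noise_sd = spec$noise_sd %||% 0, seed = seed,
      label = spec$label %||% "synthetic")
    data_path <- file.path(out_dir, "thermogram.csv")
    write_thermogram(gen$thermogram, data_path)
    truth <- list(dH = gen$truth$params$dH, dCp = gen$truth$params$dCp,
                  Tm_C = gen$truth$params$Tm - KELVIN_OFFSET,
                  baselines = gen$truth$baselines,
                  noise_sd = gen$truth$noise_sd, seed = seed)
  } else if (spec$kind == "trajectory") {
    require_fields(c("n_residues", "n_frames"))
    data_path <- file.path(out_dir, "trajectory.pdb")
    gen <- generate_trajectory(spec$n_residues, spec$n_frames,
                               planted_edges = spec$planted_edges,
                               seed = seed, path = data_path)
    truth <- gen$truth
  } else {
    require_fields(c("n_sequences", "length"))
    data_path <- file.path(out_dir, "alignment.fasta")
    gen <- generate_alignment(spec$n_sequences, spec$length,
                              planted_charge_columns =
                                spec$planted_charge_columns %||% integer(),
                              seed = seed, path = data_path)
    truth <- gen$truth
  }
  truth_path <- file.path(out_dir, paste0(spec$kind, "_truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  message("wrote ", data_path, " and ", truth_path)
  invisible(list(data = data_path, truth = truth_path))
}
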