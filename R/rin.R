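# Persistence-weighted residue-residue interaction networks from MD
# trajectory snapshots, restricted to residues charged in at least one
# sequence of an orthologue alignment.

ACIDIC <- c("D", "E")
BASIC <- c("K", "R")  # histidine deliberately excluded (pH 7.5)
CHARGED <- c(ACIDIC, BASIC)
GAP_CHARS <- c("-", ".")

charge_class_of <- function(aa) {
  ifelse(aa %in% ACIDIC, "acidic", ifelse(aa %in% BASIC, "basic", NA_character_))
}

#' Select reference positions charged in at least one aligned orthologue
#'
#' Scans a multiple sequence alignment and returns every position of the
#' reference sequence whose alignment column carries an acidic (D/E) or
#' basic (K/R) residue in at least one sequence — the reference itself or
#' any orthologue. Columns where the reference has a gap are skipped.
#' Histidine is not counted as charged.
#'
#' @param alignment path to an aligned FASTA file, or a `bio3d` fasta
#'   object (as from [bio3d::read.fasta()]).
#' @param reference_id identifier of the reference sequence in the
#'   alignment.
#' @return object of class `charge_selection`: a `data.frame` with one row
#'   per selected reference position and columns `position` (1-based index
#'   in the ungapped reference), `ref_residue`, `charge_class` (of the
#'   reference residue if charged, else of the first charged orthologue
#'   residue in the column), and `provenance` (comma-separated ids of the
#'   sequences charged at that column).
#' @export
select_charged_columns <- function(alignment, reference_id) {
  aln <- if (inherits(alignment, "fasta")) alignment else bio3d::read.fasta(alignment)
  ali <- toupper(aln$ali)
  if (is.null(dim(ali)) || any(is.na(ali)))
    stop("format error: ragged alignment (unequal sequence lengths)")
  ids <- rownames(ali)
  if (!(reference_id %in% ids))
    stop("lookup error: reference id '", reference_id, "' not in alignment")
  ref <- ali[reference_id, ]
  nongap <- !(ref %in% GAP_CHARS)
  ref_pos <- cumsum(nongap)  # alignment column -> reference numbering
  rows <- lapply(which(nongap), function(col) {
    column <- ali[, col]
    charged <- column %in% CHARGED & !(column %in% GAP_CHARS)
    if (!any(charged)) return(NULL)
    ref_aa <- ref[col]
    cls <- charge_class_of(ref_aa)
    if (is.na(cls)) cls <- charge_class_of(column[charged][1])
    data.frame(position = ref_pos[col], ref_residue = ref_aa,
               charge_class = cls,
               provenance = paste(ids[charged], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(), ref_residue = character(),
                      charge_class = character(), provenance = character(),
                      stringsAsFactors = FALSE)
  class(out) <- c("charge_selection", "data.frame")
  attr(out, "reference_id") <- reference_id
  out
}

# side-chain heavy atoms of one residue; Calpha fallback for glycine or
# side-chain-less entries
sidechain_atom_rows <- function(atom, resno) {
  in_res <- which(atom$resno == resno)
  if (!length(in_res)) stop("residue ", resno, " not found in trajectory")
  ety <- atom$elety[in_res]
  backbone <- ety %in% c("N", "CA", "C", "O", "OXT")
  hydrogen <- grepl("^[0-9]*H", ety)
  sc <- in_res[!backbone & !hydrogen]
  if (!length(sc)) {
    if (!identical(unique(atom$resid[in_res]), "GLY"))
      warning("residue ", resno, " has no side-chain heavy atoms; using CA",
              call. = FALSE)
    sc <- in_res[ety == "CA"]
  }
  sc
}

#' Per-frame minimum side-chain distances for selected residue pairs
#'
#' For every pair of selected residues and every trajectory frame, computes
#' the minimum distance over the two residues' side-chain heavy atoms (CA
#' for glycine), in nanometres. The trajectory is a multi-model PDB in
#' which every MODEL shares one topology.
#'
#' @param trajectory path to a multi-model PDB file, or a `bio3d` pdb
#'   object read with `multi = TRUE`.
#' @param selection a `charge_selection` (or an integer vector of residue
#'   numbers).
#' @param frame_stride time per frame in ps (metadata only).
#' @return object of class `trajectory_distances`: list with `pairs` (a
#'   `data.frame` of residue-number pairs `i < j`), `distances` (matrix,
#'   frames x pairs, nm), `n_frames`, `frame_stride`.
#' @export
compute_pair_distances <- function(trajectory, selection, frame_stride = NA_real_) {
  pdb <- if (inherits(trajectory, "pdb")) trajectory
         else bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)
  residues <- if (inherits(selection, "charge_selection")) selection$position
              else as.integer(selection)
  residues <- sort(unique(residues))
  if (length(residues) < 2L) stop("need at least two selected residues")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  if (n_frames < 1L) stop("zero frames in trajectory")
  atom_rows <- lapply(residues, function(r) sidechain_atom_rows(pdb$atom, r))
  names(atom_rows) <- residues
  pairs <- utils::combn(residues, 2L)
  npair <- ncol(pairs)
  dmat <- matrix(NA_real_, nrow = n_frames, ncol = npair)
  for (t in seq_len(n_frames)) {
    coords <- matrix(xyz[t, ], ncol = 3L, byrow = TRUE)
    for (k in seq_len(npair)) {
      a <- coords[atom_rows[[as.character(pairs[1L, k])]], , drop = FALSE]
      b <- coords[atom_rows[[as.character(pairs[2L, k])]], , drop = FALSE]
      # min over all atom pairs; Angstrom -> nm
      d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
      dmat[t, k] <- sqrt(max(min(d2), 0)) / 10
    }
  }
  trajectory_distances(pairs_df = data.frame(i = pairs[1L, ], j = pairs[2L, ]),
                       distances = dmat, frame_stride = frame_stride)
}

#' Assemble a trajectory-distance object
#'
#' Container for precomputed per-frame residue-pair distances, e.g. loaded
#' from a CSV produced by an external contact tool. Columns `i < j` are
#' enforced; distances are in nm.
#'
#' @param pairs_df `data.frame` with integer columns `i`, `j`.
#' @param distances numeric matrix, frames x pairs, nm.
#' @param frame_stride ps per frame (metadata).
#' @return object of class `trajectory_distances`.
#' @export
trajectory_distances <- function(pairs_df, distances, frame_stride = NA_real_) {
  stopifnot(is.data.frame(pairs_df), all(c("i", "j") %in% names(pairs_df)))
  distances <- as.matrix(distances)
  if (ncol(distances) != nrow(pairs_df))
    stop("distance matrix must have one column per pair")
  if (any(pairs_df$i >= pairs_df$j)) stop("pairs must satisfy i < j")
  if (any(distances < 0)) stop("distances must be non-negative")
  structure(list(pairs = pairs_df, distances = distances,
                 n_frames = nrow(distances), frame_stride = frame_stride),
            class = "trajectory_distances")
}

#' Read precomputed pair distances from CSV
#'
#' Expects columns `frame`, `i`, `j`, `distance_nm` (long format).
#'
#' @param path CSV path.
#' @inheritParams trajectory_distances
#' @return a `trajectory_distances` object.
#' @export
read_distances_csv <- function(path, frame_stride = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "i", "j", "distance_nm")
  if (!all(need %in% names(df)))
    stop("distance CSV must have columns ", paste(need, collapse = ", "))
  key <- paste(df$i, df$j)
  pairs <- unique(df[, c("i", "j")])
  frames <- sort(unique(df$frame))
  dmat <- matrix(NA_real_, nrow = length(frames), ncol = nrow(pairs))
  pk <- paste(pairs$i, pairs$j)
  dmat[cbind(match(df$frame, frames), match(key, pk))] <- df$distance_nm
  if (anyNA(dmat)) stop("distance CSV is missing frame/pair combinations")
  trajectory_distances(pairs, dmat, frame_stride)
}

#' Contact persistence per residue pair
#'
#' The persistence of a pair is the exact fraction of frames in which its
#' minimum side-chain distance is strictly below the threshold:
#' `p_ij = n_close / n_frames`.
#'
#' @param dist a `trajectory_distances` object.
#' @param threshold contact distance threshold in nm (default 0.6).
#' @return `data.frame` with columns `i`, `j`, `n_close`, `n_frames`,
#'   `persistence`.
#' @export
persistence_matrix <- function(dist, threshold = 0.6) {
  stopifnot(inherits(dist, "trajectory_distances"))
  n_close <- colSums(dist$distances < threshold)
  data.frame(i = dist$pairs$i, j = dist$pairs$j,
             n_close = as.integer(n_close), n_frames = dist$n_frames,
             persistence = n_close / dist$n_frames)
}

#' Build the persistence-weighted residue interaction network
#'
#' Nodes are all selected (charge-bearing) residues; an edge between two
#' residues is retained iff the pair sits farther apart than `threshold`
#' for NOT more than `1 - min_persistence` of the trajectory — with the
#' defaults, approaches beyond 0.6 nm for more than 99% of frames are
#' filtered out, i.e. edges need persistence >= 0.01. Edge weight is the
#' persistence. Isolated nodes are kept and flagged.
#'
#' @param dist a `trajectory_distances` object.
#' @param selection a `charge_selection` covering the residues in `dist`.
#' @param threshold contact distance in nm.
#' @param min_persistence minimum retained persistence (default 0.01).
#' @return object of class `persistence_network`: list with `graph` (an
#'   `igraph` with vertex attributes `name`, `position`, `charge_class`,
#'   `isolated` and edge attribute `persistence`), `threshold`,
#'   `min_persistence`.
#' @export
build_network <- function(dist, selection, threshold = 0.6,
                          min_persistence = 0.01) {
  stopifnot(inherits(selection, "charge_selection"))
  if (nrow(selection) == 0L) stop("empty residue selection")
  pm <- persistence_matrix(dist, threshold)
  keep <- pm$persistence >= min_persistence
  labels <- paste0(selection$ref_residue, selection$position)
  verts <- data.frame(name = labels, position = selection$position,
                      charge_class = selection$charge_class,
                      stringsAsFactors = FALSE)
  lab_of <- function(pos) labels[match(pos, selection$position)]
  edges <- data.frame(from = lab_of(pm$i[keep]), to = lab_of(pm$j[keep]),
                      persistence = pm$persistence[keep],
                      stringsAsFactors = FALSE)
  if (anyNA(edges$from) || anyNA(edges$to))
    stop("distance pairs reference residues outside the selection")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  structure(list(graph = g, threshold = threshold,
                 min_persistence = min_persistence),
            class = "persistence_network")
}

#' @export
print.persistence_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "Persistence network: %d residues, %d edges (threshold %.2f nm, min persistence %.3g)\n",
    igraph::vcount(g), igraph::ecount(g), x$threshold, x$min_persistence))
  invisible(x)
}

#' Write / read a persistence network
#'
#' GraphML keeps all node and edge attributes plus the construction
#' parameters and round-trips losslessly through [read_network()];
#' `edgelist-csv` writes columns (`res_i`, `res_j`, `persistence`); `dot`
#' writes Graphviz DOT.
#'
#' @param network a `persistence_network`.
#' @param path output file.
#' @param format one of `"graphml"`, `"edgelist-csv"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist-csv", "dot")) {
  stopifnot(inherits(network, "persistence_network"))
  format <- match.arg(format)
  g <- network$graph
  if (format == "graphml") {
    g <- igraph::set_graph_attr(g, "threshold_nm", network$threshold)
    g <- igraph::set_graph_attr(g, "min_persistence", network$min_persistence)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist-csv") {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.csv(data.frame(res_i = el$from, res_j = el$to,
                                persistence = el$persistence),
                     path, row.names = FALSE)
  } else {
    igraph::V(g)$isolated <- as.integer(igraph::V(g)$isolated)  # DOT has no booleans
    igraph::write_graph(g, path, format = "dot")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  thr <- igraph::graph_attr(g, "threshold_nm")
  mp <- igraph::graph_attr(g, "min_persistence")
  g <- igraph::delete_graph_attr(g, "threshold_nm")
  g <- igraph::delete_graph_attr(g, "min_persistence")
  if (!is.null(igraph::vertex_attr(g, "position")))
    igraph::V(g)$position <- as.integer(igraph::V(g)$position)
  structure(list(graph = g, threshold = thr, min_persistence = mp),
            class = "persistence_network")
}

#' Candidate like-charge clusters on the protein surface
#'
#' Connected components of the subgraph induced by the acidic nodes,
#' sorted by decreasing size and then by decreasing summed edge
#' persistence. When a per-residue secondary-structure annotation is
#' supplied, each cluster is flagged if its members span more than one
#' secondary-structure element — clusters confined to one helix or strand
#' are unlikely to strain the tertiary fold.
#'
#' @param network a `persistence_network`.
#' @param secondary_structure optional `data.frame` with columns `residue`
#'   (number) and `element_label` (e.g. `"a1"`, `"b2"`).
#' @return list of clusters, each a list with `members` (labels),
#'   `positions`, `size`, `total_persistence` and (when annotation is
#'   given) `spans_multiple_elements`.
#' @export
cluster_report <- function(network, secondary_structure = NULL) {
  stopifnot(inherits(network, "persistence_network"))
  g <- network$graph
  acid <- igraph::V(g)[igraph::V(g)$charge_class == "acidic"]
  if (length(acid) == 0L) return(list())
  sub <- igraph::induced_subgraph(g, acid)
  comp <- igraph::components(sub)
  clusters <- lapply(seq_len(comp$no), function(k) {
    vs <- igraph::V(sub)[comp$membership == k]
    gk <- igraph::induced_subgraph(sub, vs)
    cl <- list(members = vs$name, positions = vs$position,
               size = length(vs),
               total_persistence = sum(igraph::E(gk)$persistence %||% numeric(0)))
    if (!is.null(secondary_structure)) {
      el <- secondary_structure$element_label[
        match(vs$position, secondary_structure$residue)]
      cl$elements <- unique(el[!is.na(el)])
      cl$spans_multiple_elements <- length(cl$elements) > 1L
    }
    cl
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               -vapply(clusters, `[[`, numeric(1), "total_persistence"))
  clusters[ord]
}
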