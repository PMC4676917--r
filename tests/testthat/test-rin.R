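# Charge-column selection, trajectory distances, persistence filtering,
# network serialization and cluster detection.

test_that("columns charged in any orthologue are selected; neutral columns are not", {
  aln <- toy_alignment(c(
    YFH1 = "AGSTESAGLV",   # reference: E at position 5
    CYAY = "AGSTTSAGKV",   # K at position 9 only
    HFRA = "AGSTSSAGLV"))
  sel <- select_charged_columns(aln, "YFH1")
  expect_equal(sel$position, c(5, 9))
  expect_equal(sel$charge_class, c("acidic", "basic"))
  # position 5 is charged only in the reference; 9 only in one orthologue
  expect_equal(sel$provenance, c("YFH1", "CYAY"))
  expect_error(select_charged_columns(aln, "NOPE"), "lookup error")
})

test_that("reference gaps are skipped and numbering follows the ungapped reference", {
  aln <- toy_alignment(c(REF = "AG-TE", ORT = "AGKTD"))
  sel <- select_charged_columns(aln, "REF")
  # column 3 (K in ORT) falls on a reference gap: dropped; column 5 is
  # reference position 4
  expect_equal(sel$position, 4)
  expect_equal(sel$ref_residue, "E")
})

test_that("histidine does not count as charged", {
  aln <- toy_alignment(c(REF = "AHAHA", ORT = "HAHAH"))
  expect_equal(nrow(select_charged_columns(aln, "REF")), 0)
})

test_that("side-chain minimum distances match hand geometry and a brute-force oracle", {
  # two alanines, one frame, CB atoms exactly 4 A apart -> 0.40 nm
  path <- tempfile(fileext = ".pdb")
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  writeLines(c(
    "MODEL        1",
    sprintf(fmt, 1, "CA", "ALA", "A", 1, 0, 1.5, 0, 1, 0, "C"),
    sprintf(fmt, 2, "CB", "ALA", "A", 1, 0, 0, 0, 1, 0, "C"),
    sprintf(fmt, 3, "CA", "ALA", "A", 2, 4, 1.5, 0, 1, 0, "C"),
    sprintf(fmt, 4, "CB", "ALA", "A", 2, 4, 0, 0, 1, 0, "C"),
    "ENDMDL", "END"), path)
  d <- compute_pair_distances(path, c(1, 2))
  expect_equal(dim(d$distances), c(1, 1))
  expect_equal(d$distances[1, 1], 0.40)

  # multi-frame synthetic trajectory against the naive re-implementation
  traj <- tempfile(fileext = ".pdb")
  generate_trajectory(6, 10, data.frame(i = c(1, 2), j = c(3, 5),
                                        persistence = c(0.7, 0.2)),
                      seed = 9, path = traj)
  d6 <- compute_pair_distances(traj, 1:6)
  for (thr in c(0.3, 0.6, 0.9)) {
    pm <- persistence_matrix(d6, threshold = thr)
    nv <- naive_rin(traj, 1:6, threshold = thr)
    expect_equal(pm$persistence, nv$persistence)
  }
  # identical coordinates in every frame give a constant series
  frozen <- tempfile(fileext = ".pdb")
  generate_trajectory(3, 5, NULL, seed = 1, path = frozen)
  dfz <- compute_pair_distances(frozen, 1:3)
  expect_true(all(apply(dfz$distances, 2, function(x) diff(range(x)) == 0)))
})

test_that("persistence is an exact frame count with a strict boundary", {
  mk <- function(dvec) trajectory_distances(data.frame(i = 1, j = 2),
                                            matrix(dvec, ncol = 1))
  expect_equal(persistence_matrix(mk(rep(0.5, 100)))$persistence, 1.0)
  expect_equal(persistence_matrix(mk(c(rep(0.55, 30), rep(0.7, 970))))$persistence,
               0.030)
  # exactly at the threshold is NOT an approach (strict '<')
  expect_equal(persistence_matrix(mk(rep(0.6, 50)))$persistence, 0.0)
})

test_that("persistence is invariant under frame permutation and monotone in threshold", {
  set.seed(11)
  dmat <- matrix(runif(300, 0.2, 1.2), ncol = 3)
  td <- trajectory_distances(data.frame(i = c(1, 1, 2), j = c(2, 3, 3)), dmat)
  td_perm <- trajectory_distances(td$pairs, dmat[sample(nrow(dmat)), ])
  expect_equal(persistence_matrix(td)$persistence,
               persistence_matrix(td_perm)$persistence)
  p_lo <- persistence_matrix(td, threshold = 0.4)$persistence
  p_hi <- persistence_matrix(td, threshold = 0.8)$persistence
  expect_true(all(p_hi >= p_lo))
})

test_that("the >99%-beyond-threshold filter is a strict boundary on retained edges", {
  sel <- fake_selection(1:3)
  series <- cbind(c(rep(0.5, 5), rep(1.0, 995)),    # 5/1000 close: filtered
                  c(rep(0.5, 10), rep(1.0, 990)),   # 10/1000 close: retained
                  rep(1.0, 1000))
  td <- trajectory_distances(data.frame(i = c(1, 1, 2), j = c(2, 3, 3)), series)
  net <- build_network(td, sel)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  expect_equal(nrow(el), 1)
  expect_equal(sort(c(el$from, el$to)), c("E1", "E3"))
  expect_equal(el$persistence, 0.010)
  # raising min_persistence never adds edges
  net2 <- build_network(td, sel, min_persistence = 0.05)
  expect_lte(igraph::ecount(net2$graph), igraph::ecount(net$graph))
  # isolated nodes are kept and flagged
  expect_true(igraph::V(net$graph)$isolated[match("E2", igraph::V(net$graph)$name)])
  expect_error(build_network(td, fake_selection(integer(0))), "empty")
})

test_that("full pipeline equals the naive oracle on small planted trajectories", {
  traj <- tempfile(fileext = ".pdb")
  plant <- data.frame(i = c(1, 2, 4), j = c(2, 5, 7),
                      persistence = c(0.6, 0.012, 0.004))
  generate_trajectory(8, 250, plant, seed = 21, path = traj)
  sel <- fake_selection(1:8)
  d <- compute_pair_distances(traj, sel)
  net <- build_network(d, sel)
  naive <- naive_rin(traj, 1:8)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  got <- sprintf("%s-%s", el$from, el$to)
  want <- sprintf("E%d-E%d", naive$i[naive$retained], naive$j[naive$retained])
  expect_setequal(got, want)
  expect_equal(sort(el$persistence),
               sort(naive$persistence[naive$retained]))
})

test_that("GraphML round-trips losslessly and other formats serialize", {
  sel <- fake_selection(c(3, 8, 12), classes = c("acidic", "acidic", "basic"),
                        residues = c("E", "D", "K"))
  td <- trajectory_distances(
    data.frame(i = c(3, 3, 8), j = c(8, 12, 12)),
    cbind(rep(0.4, 10), rep(0.9, 10), c(rep(0.5, 3), rep(0.9, 7))))
  net <- build_network(td, sel)
  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  back <- read_network(gml)
  expect_equal(back$threshold, net$threshold)
  expect_equal(back$min_persistence, net$min_persistence)
  expect_true(igraph::isomorphic(back$graph, net$graph))
  expect_setequal(igraph::V(back$graph)$name, igraph::V(net$graph)$name)
  expect_equal(sort(igraph::E(back$graph)$persistence),
               sort(igraph::E(net$graph)$persistence))
  expect_equal(igraph::V(back$graph)$charge_class[
    match("D8", igraph::V(back$graph)$name)], "acidic")
  csv <- tempfile(fileext = ".csv")
  write_network(net, csv, "edgelist-csv")
  el <- read.csv(csv)
  expect_named(el, c("res_i", "res_j", "persistence"))
  expect_equal(nrow(el), 2)
  dot <- tempfile(fileext = ".dot")
  write_network(net, dot, "dot")
  expect_true(any(grepl("graph", readLines(dot))))
  expect_error(write_network(net, tempfile(), "gexf"))
})

test_that("acidic clusters are connected components of the acidic subgraph", {
  # planted acidic triangle {1,2,3} plus an isolated basic node
  sel <- fake_selection(1:4, classes = c(rep("acidic", 3), "basic"),
                        residues = c("E", "D", "E", "K"))
  td <- trajectory_distances(
    data.frame(i = c(1, 1, 2, 1), j = c(2, 3, 3, 4)),
    cbind(rep(0.4, 10), rep(0.4, 10), rep(0.5, 10), rep(0.9, 10)))
  net <- build_network(td, sel)
  cl <- cluster_report(net)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, c("E1", "D2", "E3"))
  # two disjoint acidic pairs -> two clusters of size 2
  sel2 <- fake_selection(1:4, classes = rep("acidic", 4))
  td2 <- trajectory_distances(
    data.frame(i = c(1, 3, 1), j = c(2, 4, 3)),
    cbind(rep(0.4, 10), rep(0.4, 10), rep(0.9, 10)))
  cl2 <- cluster_report(build_network(td2, sel2))
  expect_length(cl2, 2)
  expect_true(all(vapply(cl2, `[[`, numeric(1), "size") == 2))
  # no acidic nodes -> empty list
  selb <- fake_selection(1:2, classes = c("basic", "basic"), residues = c("K", "R"))
  tdb <- trajectory_distances(data.frame(i = 1, j = 2), matrix(0.4, 5, 1))
  expect_length(cluster_report(build_network(tdb, selb)), 0)
  # secondary-structure annotation flags clusters spanning elements
  ss <- data.frame(residue = 1:4, element_label = c("b1", "b1", "b2", "a1"))
  cl_ss <- cluster_report(net, secondary_structure = ss)
  expect_true(cl_ss[[1]]$spans_multiple_elements)
})
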