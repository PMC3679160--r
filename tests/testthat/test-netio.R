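test_that("edge list parsing normalizes pairs, drops self-pairs, keeps max score", {
  f <- write_edge_file(c("A\tB\t950", "B\tA\t930", "A\tA\t990"))
  el <- read_edge_list(f)
  expect_equal(nrow(el), 1L)
  expect_equal(el$protein_a, "A")
  expect_equal(el$protein_b, "B")
  expect_equal(el$confidence, 950L)

  # empty file -> empty edge list
  expect_equal(nrow(read_edge_list(write_edge_file(character()))), 0L)

  # header and separator auto-detection (STRING dialect, spaces)
  f2 <- write_edge_file(c("protein1 protein2 combined_score",
                          "P1 P2 900", "P2 P3 800"))
  el2 <- read_edge_list(f2)
  expect_equal(nrow(el2), 2L)
  expect_equal(sort(el2$confidence), c(800L, 900L))
})

test_that("edge list parsing rejects malformed rows, bad scores, 0-1 scale", {
  expect_error(read_edge_list(write_edge_file(c("A\tB\t950", "C\tD"))),
               "line 2")
  expect_error(read_edge_list(write_edge_file("A\tB\t1500")),
               "out of \\[0, 1000\\]")
  expect_error(read_edge_list(write_edge_file("A\tB\tnope")), "not numeric")
  f01 <- write_edge_file(c("A\tB\t0.95", "B\tC\t0.7"))
  expect_error(read_edge_list(f01), "rescale01")
  el <- read_edge_list(f01, rescale01 = TRUE)
  expect_equal(sort(el$confidence), c(700L, 950L))
})

test_that("thresholding keeps exactly the edges at or above the cutoff", {
  el <- normalize_edges(c("A", "B", "C"), c("B", "C", "D"),
                        c(950L, 930L, 945L))
  net <- build_network(el, core = c("A"), min_confidence = 940L)
  expect_equal(igraph::ecount(net), 2L)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C", "D"))
  expect_equal(sum(igraph::V(net)$is_core), 1L)
  # threshold 0 retains everything
  expect_equal(igraph::ecount(build_network(el, min_confidence = 0L)), 3L)
  # monotone: raising the threshold never adds nodes or edges
  prev_nodes <- Inf; prev_edges <- Inf
  for (th in c(0L, 930L, 940L, 950L, 1000L)) {
    g <- build_network(el, min_confidence = th)
    expect_lte(igraph::vcount(g), prev_nodes)
    expect_lte(igraph::ecount(g), prev_edges)
    prev_nodes <- igraph::vcount(g); prev_edges <- igraph::ecount(g)
  }
})

test_that("giant component picks the largest component, ties lexicographic", {
  g <- graph_from_pairs(rbind(c("a", "b"), c("b", "c"), c("x", "y")))
  gc <- giant_component(g)
  expect_setequal(igraph::V(gc)$name, c("a", "b", "c"))
  # a triangle maps to itself
  tri <- graph_from_pairs(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_setequal(igraph::V(giant_component(tri))$name, c("a", "b", "c"))
  # tie on size: lexicographically smallest sorted node list wins
  tie <- graph_from_pairs(rbind(c("x", "y"), c("a", "b")))
  expect_setequal(igraph::V(giant_component(tie))$name, c("a", "b"))
  # empty network
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(igraph::vcount(giant_component(empty)), 0L)
})

test_that("coverage and constitution follow their defining fractions exactly", {
  g <- graph_from_pairs(rbind(c("A", "B"), c("A", "X")))
  cc <- coverage_constitution(g, core = c("A", "B", "C", "D"))
  expect_equal(cc$coverage, 0.5)
  expect_equal(cc$constitution, 2 / 3)
  # identity case
  g2 <- graph_from_pairs(rbind(c("A", "B")))
  cc2 <- coverage_constitution(g2, core = c("A", "B"))
  expect_equal(cc2$coverage, 1)
  expect_equal(cc2$constitution, 1)
  # exact consistency: coverage*|core| == constitution*|nodes| == |hit|
  set.seed(11)
  for (i in 1:20) {
    g3 <- random_graph(8, 0.4)
    core <- sample(igraph::V(g3)$name, sample(2:6, 1))
    cc3 <- coverage_constitution(g3, core)
    expect_equal(cc3$coverage * length(core),
                 cc3$constitution * igraph::vcount(g3))
  }
  expect_error(coverage_constitution(g, core = character()), "empty core")
  expect_error(coverage_constitution(
    igraph::make_empty_graph(0, directed = FALSE), core = "A"),
    "empty network")
})

test_that("ROC points count captured core and attainable non-core proteins", {
  lines <- c("C1\tC2\t900", "C2\tC3\t900", "C3\tC4\t400",
             "C1\tN1\t900", "C2\tN2\t900", "C1\tN3\t400",
             "C3\tN4\t400", "C4\tN5\t400", "C4\tN6\t400")
  el <- read_edge_list(write_edge_file(lines))
  core <- c("C1", "C2", "C3", "C4")
  roc <- roc_points(el, core, thresholds = c(0L, 500L, 1000L))
  expect_equal(roc$tpr[roc$threshold == 0], 1)
  expect_equal(roc$fpr[roc$threshold == 0], 1)
  expect_equal(roc$tpr[roc$threshold == 500], 0.75)
  expect_equal(roc$fpr[roc$threshold == 500], 1 / 3)
  expect_equal(roc$tpr[roc$threshold == 1000], 0)
  expect_equal(roc$fpr[roc$threshold == 1000], 0)
  expect_equal(nrow(roc_points(el, core, integer())), 0L)
  # capture is monotone non-increasing in the threshold
  expect_true(all(diff(roc$tpr) <= 0) && all(diff(roc$fpr) <= 0))
})

test_that("random seed controls are reproducible and saturate at threshold 0", {
  set.seed(5)
  lines <- apply(t(utils::combn(sprintf("P%02d", 1:12), 2))[
    sample(66, 30), ], 1L, paste, collapse = "\t")
  el <- read_edge_list(write_edge_file(paste0(
    lines, "\t", sample(700:1000, 30, replace = TRUE))))
  proteome <- sprintf("P%02d", 1:12)
  t1 <- random_seed_control(proteome, el, seed_sizes = c(4L, 6L),
                            thresholds = c(0L, 900L), reps = 3L,
                            rng_seed = 42L)
  t2 <- random_seed_control(proteome, el, seed_sizes = c(4L, 6L),
                            thresholds = c(0L, 900L), reps = 3L,
                            rng_seed = 42L)
  expect_identical(t1, t2)
  # seed set = proteins with any edge -> full coverage at threshold 0
  present <- sort(unique(c(el$protein_a, el$protein_b)))
  t3 <- random_seed_control(present, el, seed_sizes = length(present),
                            thresholds = 0L, reps = 2L, rng_seed = 1L)
  expect_equal(t3$mean_coverage, 1)
  expect_error(random_seed_control(proteome, el, seed_sizes = 99L,
                                   reps = 1L), "exceeds proteome")
})

test_that("network stats report degree counts and clustering per degree", {
  tri <- graph_from_pairs(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  st <- network_stats(tri)
  expect_equal(st$degree_table$k, 2L)
  expect_equal(st$degree_table$n_k, 3L)
  expect_equal(st$degree_table$mean_C_k, 1)

  path <- graph_from_pairs(rbind(c("a", "b"), c("b", "c")))
  st2 <- network_stats(path)
  expect_equal(st2$degree_table$n_k[st2$degree_table$k == 1], 2L)
  expect_equal(st2$degree_table$n_k[st2$degree_table$k == 2], 1L)
  expect_true(all(st2$degree_table$mean_C_k == 0))

  star <- graph_from_pairs(cbind("hub", paste0("leaf", 1:4)))
  st3 <- network_stats(star)
  expect_equal(st3$degree_table$n_k[st3$degree_table$k == 1], 4L)
  expect_equal(st3$degree_table$n_k[st3$degree_table$k == 4], 1L)
  expect_true(all(st3$degree_table$mean_C_k == 0))

  # invariants: sum n(k) = node count; <C(k)> in [0,1]
  set.seed(3)
  for (i in 1:10) {
    g <- random_graph(9, 0.35)
    st <- network_stats(g)
    expect_equal(sum(st$degree_table$n_k), igraph::vcount(g))
    expect_true(all(st$degree_table$mean_C_k >= 0 &
                      st$degree_table$mean_C_k <= 1))
  }
})

test_that("network round-trips through node/edge tables and GraphML", {
  set.seed(21)
  g <- random_graph(10, 0.3)
  igraph::E(g)$confidence <- sample(900:1000, igraph::ecount(g),
                                    replace = TRUE)
  igraph::V(g)$is_core <- stats::runif(igraph::vcount(g)) < 0.3
  d <- tempfile()
  write_network(g, d)
  g2 <- read_network(d)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  key <- function(gr) {
    el <- igraph::as_data_frame(gr, what = "edges")
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to), el$confidence))
  }
  expect_equal(key(g2), key(g))
  expect_equal(igraph::V(g2)$is_core[match(igraph::V(g)$name,
                                           igraph::V(g2)$name)],
               igraph::V(g)$is_core)
  g3 <- igraph::read_graph(file.path(d, "network.graphml"),
                           format = "graphml")
  expect_setequal(igraph::V(g3)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g3), igraph::ecount(g))
})
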