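# Independent brute-force oracles and small fixture builders, kept free of
# the package code paths they are used to check.

# igraph from a character edge matrix/data.frame with confidence 1000
graph_from_pairs <- function(pairs, nodes = NULL) {
  df <- data.frame(from = pairs[, 1L], to = pairs[, 2L],
                   confidence = 1000L, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$is_core <- FALSE
  g
}

# brute-force maximal clique enumeration via bitmask subsets (n <= 20)
oracle_max_cliques <- function(g, min_size = 2L) {
  n <- igraph::vcount(g)
  stopifnot(n <= 20L)
  names <- igraph::V(g)$name
  adj <- integer(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1L]; j <- el[r, 2L]
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    mem <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(mem) < min_size) next
    is_clique <- all(vapply(mem, function(v) {
      need <- bitwAnd(mask, bitwNot(bitwShiftL(1L, v - 1L)))
      bitwAnd(adj[v], need) == need
    }, TRUE))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), mem)
    maximal <- !any(vapply(outside, function(w) {
      bitwAnd(adj[w], mask) == mask
    }, TRUE))
    if (maximal) out[[length(out) + 1L]] <- sort(names[mem])
  }
  sort(vapply(out, paste, "", collapse = ";"))
}

# Erdos-Renyi random graph over letter-ish node names
random_graph <- function(n, p) {
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  nodes <- sprintf("n%02d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[pairs[keep, 1L]], to = nodes[pairs[keep, 2L]]),
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::V(g)$is_core <- FALSE
  g
}

# direct single-label redundancy from the entropy definition (oracle)
oracle_redundancy <- function(labels, n) {
  f <- as.numeric(table(labels)) / length(labels)
  1 + sum(f * log(f)) / log(n)
}

# exhaustive best non-overlapping configuration: maximize covered proteins
# over every subset of pairwise-disjoint terms; returns the max coverage and
# all argmax term sets (so tie-break-free comparisons are possible)
oracle_best_go <- function(G) {
  t <- nrow(G)
  stopifnot(t <= 16L)
  terms <- rownames(G)
  counts <- diag(G)
  masks <- seq_len(2^t) - 1L
  valid <- masks > 0L
  has <- vapply(seq_len(t), function(i)
    bitwAnd(masks, bitwShiftL(1L, i - 1L)) != 0L, logical(length(masks)))
  if (t >= 2L) {
    for (i in seq_len(t - 1L)) for (j in seq((i + 1L), t)) {
      if (G[i, j] != 0L) valid <- valid & !(has[, i] & has[, j])
    }
  }
  cover <- as.numeric(has %*% counts)
  best <- max(cover[valid])
  arg <- which(valid & cover == best)
  list(coverage = best,
       argmax = lapply(arg, function(m) sort(terms[has[m, ]])))
}

# write a tiny edge-list file and return its path
write_edge_file <- function(lines, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# quick module_scores-like record table
make_records <- function(n, seed, kegg_max = 1) {
  set.seed(seed)
  data.frame(
    module_id = sprintf("M%03d", seq_len(n)),
    N = sample(4:12, n, replace = TRUE),
    size_feature = stats::runif(n),
    R_KEGG = stats::runif(n, 0, kegg_max),
    R_LOC = stats::runif(n),
    R_OMIM = stats::runif(n),
    planted = FALSE,
    S = NA_real_,
    stringsAsFactors = FALSE)
}

# functional_modules-shaped fixture with given member-list sizes
new_modules_fixture <- function(sizes) {
  members <- lapply(seq_along(sizes), function(i)
    sprintf("m%02d_%02d", i, seq_len(sizes[i])))
  ids <- vapply(members, paste, "", collapse = ";")
  o <- order(-sizes, ids)
  df <- data.frame(module_id = ids[o], size = as.integer(sizes[o]),
                   stringsAsFactors = FALSE)
  df$members <- members[o]
  class(df) <- c("functional_modules", "data.frame")
  df
}

# functional_modules-shaped fixture from explicit member lists
new_modules_like <- function(member_lists) {
  members <- lapply(member_lists, sort)
  ids <- vapply(members, paste, "", collapse = ";")
  sizes <- lengths(members)
  o <- order(-sizes, ids)
  df <- data.frame(module_id = ids[o], size = as.integer(sizes[o]),
                   stringsAsFactors = FALSE)
  df$members <- members[o]
  class(df) <- c("functional_modules", "data.frame")
  df
}
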