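#' Read a weighted protein-protein edge list
#'
#' Parses a STRING-style "protein links" file (two protein identifiers plus a
#' combined confidence score on the integer 0--1000 scale) into a normalized
#' edge list. Self-pairs are dropped and duplicate unordered pairs are
#' collapsed keeping the maximum confidence. Identifiers are opaque,
#' case-sensitive strings; no namespace mapping is attempted.
#'
#' @param path Path to the edge-list file. The separator is auto-detected
#'   among whitespace, tab and comma; a header line is detected and skipped
#'   when its third field is not numeric.
#' @param dialect `"auto"` (default), `"string-links"` (whitespace-separated)
#'   or `"tsv"`. All dialects share the same column semantics.
#' @param rescale01 If `TRUE`, scores given as fractions in \[0, 1\] are
#'   multiplied by 1000 and rounded to the STRING integer scale. By default
#'   fractional scores are rejected, because thresholds in this pipeline
#'   (e.g. 940) live on the integer scale.
#' @return A `data.frame` of class `weighted_edge_list` with columns
#'   `protein_a`, `protein_b` (with `protein_a < protein_b`) and `confidence`
#'   (integer in \[0, 1000\]), sorted by pair.
#' @export
read_edge_list <- function(path, dialect = c("auto", "string-links", "tsv"),
                           rescale01 = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(lines_keep) == 0L) {
    return(new_edge_list(character(), character(), integer()))
  }
  sep_split <- switch(dialect,
    "tsv"          = "\t",
    "string-links" = "[ \t]+",
    "auto"         = {
      probe <- lines[lines_keep[1L]]
      if (grepl("\t", probe)) "\t" else if (grepl(",", probe)) "," else "[ \t]+"
    })
  fields <- strsplit(trimws(lines[lines_keep]), sep_split)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop("malformed edge list row at line ", lines_keep[bad[1L]],
         ": expected two identifiers and a score, got '",
         lines[lines_keep[bad[1L]]], "'")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s_raw <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_raw))
  # header row: non-numeric score field on the first kept line, with
  # column-name-looking fields (a malformed data row must error instead)
  if (is.na(s[1L]) &&
      grepl("score|conf|protein|node|id|weight", s_raw[1L],
            ignore.case = TRUE) ||
      (is.na(s[1L]) &&
       grepl("protein|node|id|from|source", a[1L], ignore.case = TRUE))) {
    a <- a[-1L]; b <- b[-1L]; s <- s[-1L]; s_raw <- s_raw[-1L]
    lines_keep <- lines_keep[-1L]
    if (length(s) == 0L) return(new_edge_list(character(), character(), integer()))
  }
  if (anyNA(s)) {
    i <- which(is.na(s))[1L]
    stop("malformed edge list row at line ", lines_keep[i],
         ": score '", s_raw[i], "' is not numeric")
  }
  if (all(s >= 0 & s <= 1) && any(s != round(s))) {
    if (!rescale01) {
      stop("scores look like fractions in [0,1]; pass rescale01 = TRUE to ",
           "rescale to the 0-1000 integer confidence scale")
    }
    s <- round(s * 1000)
  }
  if (any(s < 0 | s > 1000)) {
    i <- which(s < 0 | s > 1000)[1L]
    stop("confidence score out of [0, 1000] at line ", lines_keep[i],
         ": ", s[i])
  }
  normalize_edges(a, b, as.integer(round(s)))
}

new_edge_list <- function(a, b, conf) {
  structure(
    data.frame(protein_a = a, protein_b = b, confidence = conf,
               stringsAsFactors = FALSE),
    class = c("weighted_edge_list", "data.frame"))
}

#' Normalize raw edges into a canonical weighted edge list
#'
#' Drops self-pairs, orients each pair so `protein_a < protein_b`, collapses
#' duplicates keeping the maximum confidence, and sorts rows.
#'
#' @param a,b Character vectors of endpoint identifiers.
#' @param confidence Integer scores in \[0, 1000\].
#' @return A `weighted_edge_list`.
#' @export
normalize_edges <- function(a, b, confidence) {
  stopifnot(length(a) == length(b), length(b) == length(confidence))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; confidence <- as.integer(confidence[keep])
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo) > 0L) {
    key <- paste(lo, hi, sep = "\r")
    conf <- tapply(confidence, key, max)
    parts <- strsplit(names(conf), "\r", fixed = TRUE)
    lo <- vapply(parts, `[[`, "", 1L)
    hi <- vapply(parts, `[[`, "", 2L)
    o <- order(lo, hi)
    return(new_edge_list(lo[o], hi[o], as.integer(conf[o])))
  }
  new_edge_list(character(), character(), integer())
}

#' Read a protein list (one identifier per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique identifiers.
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) stop("protein list file not found: ", path)
  x <- trimws(readLines(path))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read a two-column annotation table (protein, term)
#'
#' Used for the pathway / localization / disease classification schemes and
#' for GO term-protein associations (with `swap = TRUE` when the file is
#' term-first).
#'
#' @param path Path to a TSV with two columns.
#' @param swap If `TRUE` the file columns are (term, protein) and are swapped
#'   on read.
#' @return `data.frame` with columns `protein`, `term`.
#' @export
read_annotation_table <- function(path, swap = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#",
                          col.names = c("protein", "term"))
  # tolerate a header row
  if (nrow(df) > 0L && tolower(df$protein[1L]) %in% c("protein", "id") ) {
    df <- df[-1L, , drop = FALSE]
  }
  if (swap) names(df) <- c("term", "protein")
  df[, c("protein", "term")]
}

#' Build a thresholded functional linkage network
#'
#' Keeps exactly the edges with confidence at or above `min_confidence` and
#' their endpoints; each node is flagged core iff it appears in `core`.
#'
#' @param edges A `weighted_edge_list`.
#' @param core Character vector of core (disease-seed) protein identifiers.
#' @param min_confidence Integer threshold in \[0, 1000\].
#' @return An undirected simple [igraph::igraph] with vertex attributes
#'   `name`, `is_core`, edge attribute `confidence`, and graph attribute
#'   `threshold`.
#' @export
build_network <- function(edges, core = character(), min_confidence = 0L) {
  stopifnot(min_confidence >= 0, min_confidence <= 1000)
  keep <- edges$confidence >= min_confidence
  el <- edges[keep, , drop = FALSE]
  nodes <- sort(unique(c(el$protein_a, el$protein_b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$protein_a, to = el$protein_b,
               confidence = el$confidence, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::V(g)$is_core <- igraph::V(g)$name %in% core
  g <- igraph::set_graph_attr(g, "threshold", as.integer(min_confidence))
  g
}

#' Expand a seed protein set with its first neighbors
#'
#' Thresholds the edge list at `min_confidence`, then takes the subgraph
#' induced on the seeds plus every protein at distance one from a seed (one
#' expansion step, not iterated). Seeds with no retained incident edge do not
#' enter the network.
#'
#' @inheritParams build_network
#' @param seeds Character vector of seed protein identifiers.
#' @return An igraph network with `is_core` flagging the seeds.
#' @export
expand_seeds <- function(edges, seeds, min_confidence = 0L) {
  g <- build_network(edges, core = seeds, min_confidence = min_confidence)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0L) {
    return(igraph::induced_subgraph(g, integer(0)))
  }
  nb <- unique(unlist(igraph::adjacent_vertices(g, present)))
  keep <- union(match(present, igraph::V(g)$name), nb)
  igraph::induced_subgraph(g, sort(keep))
}

#' Remove singletons (degree-zero nodes)
#'
#' @param net An igraph network.
#' @return The network without isolated nodes.
#' @export
drop_singletons <- function(net) {
  igraph::delete_vertices(net, which(igraph::degree(net) == 0))
}

#' Extract the giant (largest) connected component
#'
#' Ties on component size are broken by the lexicographically smallest sorted
#' node list.
#'
#' @param net An igraph network.
#' @return The largest connected component as an igraph network; an empty
#'   network maps to itself.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(ci) {
      paste(sort(igraph::V(net)$name[comp$membership == ci]), collapse = ";")
    }, "")
    cand <- cand[order(keys)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == cand[1L]))
}

#' Coverage and constitution of a network with respect to a core set
#'
#' Coverage is the fraction of the core protein list captured in the network;
#' constitution is the fraction of network nodes that are core proteins.
#'
#' @param net An igraph network.
#' @param core Character vector of core protein identifiers (non-empty).
#' @return Named list with `coverage` and `constitution`, both in \[0, 1\].
#' @export
coverage_constitution <- function(net, core) {
  if (length(core) == 0L) stop("coverage undefined for an empty core set")
  if (igraph::vcount(net) == 0L) {
    stop("constitution undefined for an empty network")
  }
  core <- unique(core)
  hit <- sum(igraph::V(net)$name %in% core)
  list(coverage = hit / length(core),
       constitution = hit / igraph::vcount(net))
}

#' True/false-positive rates of seed-expanded networks over thresholds
#'
#' For each confidence threshold the seed set is expanded with first
#' neighbors; the true-positive rate is the fraction of core proteins
#' captured, and the false-positive rate is the number of captured non-core
#' proteins over the non-core proteins attainable in the unthresholded
#' seed-expanded network (the maximum network this core set can reach).
#'
#' @inheritParams build_network
#' @param thresholds Integer vector of thresholds in \[0, 1000\].
#' @return `data.frame` with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(edges, core, thresholds) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1000))
  if (length(thresholds) == 0L) {
    return(data.frame(threshold = integer(), tpr = numeric(),
                      fpr = numeric()))
  }
  core <- unique(core)
  full <- expand_seeds(edges, core, min_confidence = 0L)
  n_noncore_max <- sum(!(igraph::V(full)$name %in% core))
  rows <- lapply(sort(thresholds), function(th) {
    g <- expand_seeds(edges, core, min_confidence = th)
    nodes <- igraph::V(g)$name
    n_core_hit <- sum(nodes %in% core)
    n_noncore_hit <- length(nodes) - n_core_hit
    data.frame(
      threshold = as.integer(th),
      tpr = n_core_hit / length(core),
      fpr = if (n_noncore_max > 0) n_noncore_hit / n_noncore_max else 0)
  })
  do.call(rbind, rows)
}

#' Coverage of randomly seeded networks (negative control)
#'
#' For each seed size and replicate, a uniformly sampled seed set is expanded
#' and thresholded exactly as the disease seeds; the table summarizes the
#' coverage (fraction of the random seed set captured) per threshold.
#'
#' @inheritParams build_network
#' @param proteome Character vector: the universe to sample seeds from.
#' @param seed_sizes Integer vector of seed-set sizes.
#' @param thresholds Integer vector of thresholds (default the 900--990 sweep).
#' @param reps Number of replicates per seed size (>= 1).
#' @param rng_seed Integer seed for reproducibility.
#' @return `data.frame` with columns `seed_size`, `threshold`,
#'   `mean_coverage`, `sd_coverage`.
#' @export
random_seed_control <- function(proteome, edges, seed_sizes,
                                thresholds = seq(900L, 990L, by = 10L),
                                reps = 10L, rng_seed = 1L) {
  stopifnot(reps >= 1)
  if (any(seed_sizes > length(proteome))) {
    stop("seed size exceeds proteome size")
  }
  set.seed(rng_seed)
  out <- list()
  for (ss in seed_sizes) {
    cov <- matrix(NA_real_, nrow = reps, ncol = length(thresholds))
    for (r in seq_len(reps)) {
      seeds <- sample(proteome, ss)
      for (j in seq_along(thresholds)) {
        g <- expand_seeds(edges, seeds, min_confidence = thresholds[j])
        cov[r, j] <- sum(igraph::V(g)$name %in% seeds) / ss
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      seed_size = as.integer(ss),
      threshold = as.integer(thresholds),
      mean_coverage = colMeans(cov),
      sd_coverage = apply(cov, 2L, stats::sd))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Topological summary of a network
#'
#' Degree distribution `n(k)`, mean local clustering coefficient per degree
#' `<C(k)>` (degree-0/1 nodes contribute clustering 0), and, when core
#' information is available, coverage and constitution.
#'
#' @param net An igraph network with an `is_core` vertex attribute.
#' @param core Optional full core protein list; when supplied, coverage is
#'   computed against it (otherwise `NA`).
#' @return List of class `network_stats`: `degree_table` (`data.frame` with
#'   `k`, `n_k`, `mean_C_k`), `n_nodes`, `n_edges`, `coverage`,
#'   `constitution`.
#' @export
network_stats <- function(net, core = NULL) {
  k <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[k < 2] <- 0
  ks <- sort(unique(k))
  tab <- data.frame(
    k = as.integer(ks),
    n_k = vapply(ks, function(x) sum(k == x), 0L),
    mean_C_k = vapply(ks, function(x) mean(cc[k == x]), 0))
  n_core_in <- if (is.null(igraph::V(net)$is_core)) NA_integer_ else
    sum(igraph::V(net)$is_core)
  structure(list(
    degree_table = tab,
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    coverage = if (!is.null(core) && length(core) > 0L)
      sum(igraph::V(net)$name %in% unique(core)) / length(unique(core))
      else NA_real_,
    constitution = if (igraph::vcount(net) > 0L && !is.na(n_core_in))
      n_core_in / igraph::vcount(net) else NA_real_),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  if (!is.na(x$coverage))
    cat(sprintf("coverage: %.4f\n", x$coverage))
  if (!is.na(x$constitution))
    cat(sprintf("constitution: %.4f\n", x$constitution))
  cat(sprintf("degrees: %d distinct values, max %d\n",
              nrow(x$degree_table),
              if (nrow(x$degree_table)) max(x$degree_table$k) else 0L))
  invisible(x)
}

#' Write a network to a directory (node/edge TSV plus GraphML)
#'
#' @param net An igraph network with `is_core` and `confidence` attributes.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(id = igraph::V(net)$name,
                      is_core = as.integer(igraph::V(net)$is_core))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  el <- igraph::as_data_frame(net, what = "edges")
  if (nrow(el) > 0L) {
    a <- pmin(el$from, el$to); b <- pmax(el$from, el$to)
    ed <- data.frame(a = a, b = b,
                     confidence = if ("confidence" %in% names(el))
                       el$confidence else NA_integer_)
    ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  } else {
    ed <- data.frame(a = character(), b = character(),
                     confidence = integer())
  }
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ed, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(net, file.path(dir, "network.graphml"),
                      format = "graphml")
  invisible(dir)
}

#' Read a network written by [write_network()]
#'
#' @param dir Directory containing `nodes.tsv` and `edges.tsv`.
#' @return An igraph network.
#' @export
read_network <- function(dir) {
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c("character", "integer"))
  ed <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(ed) > 0L)
      data.frame(from = as.character(ed$a), to = as.character(ed$b),
                 confidence = ed$confidence, stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character(),
                    confidence = integer()),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, stringsAsFactors = FALSE))
  igraph::V(g)$is_core <- as.logical(
    nodes$is_core[match(igraph::V(g)$name, nodes$id)])
  g
}

#' Write a network stats summary (TSV table plus JSON)
#'
#' @param stats A `network_stats` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_network_stats <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(stats$degree_table, file.path(dir, "degree_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(nodes = stats$n_nodes, edges = stats$n_edges,
         coverage = stats$coverage, constitution = stats$constitution),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
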