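#' Assemble the condensed network from the top-k ranked modules
#'
#' Takes the union of the member sets of the first `k` modules of the ranking
#' and returns the subgraph of the source network induced on it (so edges
#' between members of different modules are retained). With
#' `induced = FALSE`, only within-module edges are kept (sensitivity mode).
#'
#' @param net The source igraph network.
#' @param ranking Ranking `data.frame` from [rank_modules()] (needs
#'   `module_id` with semicolon-joined members), or a `functional_modules`
#'   data frame in ranked order.
#' @param k Number of top modules to assemble (>= 1, <= nrow(ranking)).
#' @param induced Keep all edges among the selected proteins (default) or
#'   only within-module edges.
#' @return The condensed network as an igraph object (core flags inherited).
#' @export
assemble_condensed <- function(net, ranking, k, induced = TRUE) {
  stopifnot(k >= 1L)
  members <- ranking_members(ranking)
  if (k > length(members)) {
    stop("k = ", k, " exceeds the ranking length (", length(members), ")")
  }
  top <- members[seq_len(k)]
  prots <- sort(unique(unlist(top)))
  idx <- match(prots, igraph::V(net)$name)
  if (anyNA(idx)) {
    stop("ranked module members missing from the network: ",
         paste(utils::head(prots[is.na(idx)], 3L), collapse = ", "))
  }
  g <- igraph::induced_subgraph(net, idx)
  if (!induced) {
    keep_pairs <- unique(do.call(rbind, lapply(top, function(m) {
      if (length(m) < 2L) return(NULL)
      cmb <- utils::combn(sort(m), 2L)
      data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
    })))
    el <- igraph::as_data_frame(g, what = "edges")
    ek <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
    wanted <- paste(keep_pairs$a, keep_pairs$b)
    g <- igraph::delete_edges(g, which(!(ek %in% wanted)))
  }
  g
}

ranking_members <- function(ranking) {
  if (is.data.frame(ranking) && "members" %in% names(ranking)) {
    ranking$members
  } else if (is.data.frame(ranking) && "module_id" %in% names(ranking)) {
    strsplit(ranking$module_id, ";", fixed = TRUE)
  } else if (is.list(ranking)) {
    ranking
  } else {
    stop("ranking must carry module members (module_id or members column)")
  }
}

#' Selection curve over candidate numbers of top modules
#'
#' For each `k`, assembles the condensed network and records its size, core
#' content and number of connected components; used to pick the assembly size
#' at which core-protein capture saturates.
#'
#' @inheritParams assemble_condensed
#' @param ks Integer vector of candidate `k` values (default the canonical
#'   25/50/75/100/150/250 sweep, truncated to the ranking length).
#' @param core Full core protein list; `core_capture` is the fraction of it
#'   present in each condensed network.
#' @return `data.frame` of class `selection_curve` with columns `k`,
#'   `n_proteins`, `n_core`, `n_edges`, `n_components`, `core_capture`,
#'   sorted by ascending `k`.
#' @export
selection_curve <- function(net, ranking, core,
                            ks = c(25L, 50L, 75L, 100L, 150L, 250L),
                            induced = TRUE) {
  stopifnot(length(ks) > 0L)
  members <- ranking_members(ranking)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks > length(members))) {
    stop("selection curve k exceeds the ranking length")
  }
  core <- unique(core)
  rows <- lapply(ks, function(k) {
    g <- assemble_condensed(net, ranking, k, induced = induced)
    nc <- sum(igraph::V(g)$name %in% core)
    data.frame(k = k,
               n_proteins = igraph::vcount(g),
               n_core = nc,
               n_edges = igraph::ecount(g),
               n_components = igraph::components(g)$no,
               core_capture = if (length(core) > 0L) nc / length(core)
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("selection_curve", "data.frame")
  out
}

#' Choose the number of top modules by core-capture saturation
#'
#' Returns the smallest `k` whose core capture is within `tol` (relative) of
#' the maximum capture over the curve, i.e. the point where adding further
#' modules no longer brings in materially more core proteins.
#'
#' @param curve A [selection_curve()] result.
#' @param tol Relative tolerance in \[0, 1); default 0.05.
#' @return The selected `k` (integer).
#' @export
choose_k <- function(curve, tol = 0.05) {
  stopifnot(nrow(curve) > 0L, tol >= 0, tol < 1)
  target <- (1 - tol) * max(curve$core_capture)
  curve$k[which(curve$core_capture >= target)[1L]]
}
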