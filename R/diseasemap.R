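#' Disease annotation container
#'
#' @param protein_disease `data.frame` with columns `protein`, `term`
#'   (multi-valued protein -> disease-term associations).
#' @param term_class Optional `data.frame` with columns `term`, `class`
#'   mapping each disease term to one of the disease classes.
#' @return Object of class `disease_annotation`.
#' @export
disease_annotation <- function(protein_disease, term_class = NULL) {
  stopifnot(all(c("protein", "term") %in% names(protein_disease)))
  if (!is.null(term_class)) {
    stopifnot(all(c("term", "class") %in% names(term_class)))
    miss <- setdiff(unique(protein_disease$term), term_class$term)
    if (length(miss) > 0L) {
      stop("disease term(s) without a class: ",
           paste(utils::head(miss, 3L), collapse = ", "))
    }
  }
  structure(list(
    associations = unique(data.frame(
      protein = as.character(protein_disease$protein),
      term = as.character(protein_disease$term),
      stringsAsFactors = FALSE)),
    term_class = term_class), class = "disease_annotation")
}

#' Map an analysis protein set to disease terms
#'
#' Restricts each disease term's protein set to the given analysis set
#' (typically the condensed-network proteins); terms left with no protein are
#' dropped.
#'
#' @param proteins Character vector of analysis proteins.
#' @param annot A [disease_annotation()].
#' @return Named list: disease term -> character vector of proteins.
#' @export
disease_protein_map <- function(proteins, annot) {
  df <- annot$associations
  df <- df[df$protein %in% proteins, , drop = FALSE]
  if (nrow(df) == 0L) return(stats::setNames(list(), character()))
  sp <- lapply(split(df$protein, df$term), function(x) sort(unique(x)))
  sp[order(names(sp))]
}

do_score <- function(shared, ni, nj, form) {
  switch(form,
         "jaccard"   = shared / (ni + nj - shared),
         "overlap"   = shared / pmin(ni, nj),
         "geometric" = shared / sqrt(ni * nj),
         stop("unknown DO form: ", form))
}

#' Pairwise disease-overlap (DO) scores
#'
#' Scores every unordered pair of disease terms sharing at least one protein
#' by the normalized overlap of their protein sets. The default form is the
#' Jaccard index |d_i intersect d_j| / |d_i union d_j|; the overlap
#' coefficient (|intersection| / min) and geometric normalization
#' (|intersection| / sqrt(|d_i| |d_j|)) are selectable.
#'
#' @param dmap Named list disease term -> protein set, from
#'   [disease_protein_map()].
#' @param form `"jaccard"` (default), `"overlap"` or `"geometric"`.
#' @return `data.frame` of class `disease_overlaps` with columns `term_a`,
#'   `term_b` (with `term_a < term_b`), `n_a`, `n_b`, `shared`, `DO`, and
#'   empty `p`/`q` columns (filled by [permutation_fdr()]).
#' @export
overlap_scores <- function(dmap, form = c("jaccard", "overlap",
                                          "geometric")) {
  form <- match.arg(form)
  if (length(dmap) == 0L) stop("empty disease-protein map")
  terms <- names(dmap)
  prots <- sort(unique(unlist(dmap)))
  M <- matrix(0L, length(terms), length(prots),
              dimnames = list(terms, prots))
  for (i in seq_along(terms)) M[i, dmap[[i]]] <- 1L
  SH <- tcrossprod(M)
  sizes <- diag(SH)
  idx <- which(upper.tri(SH) & SH >= 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- data.frame(term_a = character(), term_b = character(),
                      n_a = integer(), n_b = integer(), shared = integer(),
                      DO = numeric(), p = numeric(), q = numeric())
    class(out) <- c("disease_overlaps", "data.frame")
    return(out)
  }
  shared <- SH[idx]
  ni <- sizes[idx[, 1L]]
  nj <- sizes[idx[, 2L]]
  out <- data.frame(term_a = terms[idx[, 1L]], term_b = terms[idx[, 2L]],
                    n_a = as.integer(ni), n_b = as.integer(nj),
                    shared = as.integer(shared),
                    DO = do_score(shared, ni, nj, form),
                    p = NA_real_, q = NA_real_,
                    stringsAsFactors = FALSE)
  swap <- out$term_a > out$term_b
  if (any(swap)) {
    tmp <- out$term_a[swap]; out$term_a[swap] <- out$term_b[swap]
    out$term_b[swap] <- tmp
    tmp <- out$n_a[swap]; out$n_a[swap] <- out$n_b[swap]
    out$n_b[swap] <- tmp
  }
  out <- out[order(out$term_a, out$term_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("disease_overlaps", "data.frame")
  out
}

#' Permutation p-values and FDR for disease-overlap scores
#'
#' Each null replicate re-annotates the disease terms at random over the
#' analysis protein set and recomputes every observed pair's DO score. With
#' the default `unit = "term-resample"`, each term independently draws a
#' protein set of its observed size, uniformly without replacement, from the
#' analysis proteins (preserving every term's protein count and the protein
#' universe). `unit = "edge-shuffle"` instead permutes the protein column of
#' the association list and deduplicates. Empirical p-values use the add-one
#' convention `p = (1 + #\{null DO >= observed\}) / (reps + 1)`;
#' Benjamini-Hochberg `q` values are computed over all tested pairs.
#'
#' @param pairs `disease_overlaps` from [overlap_scores()].
#' @param dmap The disease -> protein map the pairs were computed from.
#' @param reps Number of null replicates (default 1000).
#' @param rng_seed Integer seed.
#' @param form DO form (must match the one used for `pairs`).
#' @param unit Null-model unit (see Details).
#' @param stat Test statistic: `"DO"` (default) or `"shared"` (raw shared
#'   count).
#' @return `pairs` with `p` and `q` filled.
#' @export
permutation_fdr <- function(pairs, dmap, reps = 1000L, rng_seed = 1L,
                            form = c("jaccard", "overlap", "geometric"),
                            unit = c("term-resample", "edge-shuffle"),
                            stat = c("DO", "shared")) {
  form <- match.arg(form)
  unit <- match.arg(unit)
  stat <- match.arg(stat)
  stopifnot(reps >= 1)
  if (nrow(pairs) == 0L) return(pairs)
  terms <- names(dmap)
  prots <- sort(unique(unlist(dmap)))
  sizes <- lengths(dmap)
  ia <- match(pairs$term_a, terms)
  ib <- match(pairs$term_b, terms)
  obs <- if (stat == "DO") pairs$DO else pairs$shared
  cnt <- integer(nrow(pairs))
  set.seed(rng_seed)
  np <- length(prots)
  for (r in seq_len(reps)) {
    M <- matrix(0L, length(terms), np)
    if (unit == "term-resample") {
      for (i in seq_along(terms)) {
        M[i, sample.int(np, sizes[i])] <- 1L
      }
    } else {
      el_term <- rep.int(seq_along(terms), sizes)
      el_prot <- sample(match(unlist(dmap), prots))
      M[unique(cbind(el_term, el_prot))] <- 1L
    }
    SH <- tcrossprod(M)
    sh <- SH[cbind(ia, ib)]
    nullstat <- if (stat == "DO") {
      na <- diag(SH)[ia]; nb <- diag(SH)[ib]
      ifelse(sh > 0L, do_score(sh, na, nb, form), 0)
    } else {
      sh
    }
    cnt <- cnt + (nullstat >= obs - 1e-12)
  }
  pairs$p <- (1 + cnt) / (reps + 1)
  pairs$q <- stats::p.adjust(pairs$p, method = "BH")
  pairs
}

#' Significance-filtered disease-disease network
#'
#' Keeps the pairs sharing at least `min_shared` proteins with permutation
#' `p < alpha` (or `q < alpha` with `use_q = TRUE`) and returns them as a
#' graph over disease terms, annotated with disease class and degree.
#'
#' @param pairs `disease_overlaps` with `p` filled.
#' @param annot A [disease_annotation()] supplying term -> class labels
#'   (optional; class `NA` if absent).
#' @param min_shared Minimum shared-protein count (default 2).
#' @param alpha Significance cutoff (default 0.01).
#' @param use_q Filter on BH `q` instead of raw `p`.
#' @return An igraph graph whose vertices carry `disease_class` and `degree`
#'   attributes and whose edges carry `shared`, `DO`, `p`, `q`.
#' @export
disease_network <- function(pairs, annot = NULL, min_shared = 2L,
                            alpha = 0.01, use_q = FALSE) {
  stopifnot(min_shared >= 1L, alpha > 0, alpha < 1)
  crit <- if (use_q) pairs$q else pairs$p
  keep <- pairs$shared >= min_shared & !is.na(crit) & crit < alpha
  el <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$term_a, to = el$term_b, shared = el$shared,
               DO = el$DO, p = el$p, q = el$q, stringsAsFactors = FALSE),
    directed = FALSE)
  cls <- rep(NA_character_, igraph::vcount(g))
  if (!is.null(annot) && !is.null(annot$term_class)) {
    cls <- annot$term_class$class[match(igraph::V(g)$name,
                                        annot$term_class$term)]
  }
  igraph::V(g)$disease_class <- cls
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Write a disease-overlap pair table and network
#'
#' @param pairs `disease_overlaps` table.
#' @param net Disease network from [disease_network()] (optional).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_disease_results <- function(pairs, net = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(pairs, file.path(dir, "disease_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(net)) {
    igraph::write_graph(net, file.path(dir, "disease_network.graphml"),
                        format = "graphml")
    utils::write.table(
      data.frame(term = igraph::V(net)$name,
                 class = igraph::V(net)$disease_class,
                 degree = igraph::V(net)$degree),
      file.path(dir, "disease_nodes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}
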