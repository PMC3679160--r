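#' GO term x protein incidence matrix
#'
#' @param assoc `data.frame` with columns `term` and `protein` (one row per
#'   association), e.g. from [read_annotation_table()] with `swap = TRUE`.
#' @param proteins Optional protein set to restrict to (terms left with no
#'   protein are dropped; all-zero rows never appear).
#' @return Binary matrix `B` with terms as (sorted) rows and proteins as
#'   (sorted) columns.
#' @export
term_incidence <- function(assoc, proteins = NULL) {
  stopifnot(all(c("term", "protein") %in% names(assoc)))
  df <- unique(data.frame(term = as.character(assoc$term),
                          protein = as.character(assoc$protein),
                          stringsAsFactors = FALSE))
  if (!is.null(proteins)) df <- df[df$protein %in% proteins, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(matrix(0L, 0L, 0L))
  }
  terms <- sort(unique(df$term))
  prots <- sort(unique(df$protein))
  B <- matrix(0L, length(terms), length(prots),
              dimnames = list(terms, prots))
  B[cbind(match(df$term, terms), match(df$protein, prots))] <- 1L
  B
}

#' Term co-occurrence matrix
#'
#' The incidence matrix multiplied with its transpose: diagonal entries count
#' the proteins associated with each term; off-diagonal entries count the
#' proteins shared between two terms, so zero off-diagonal entries identify
#' non-overlapping term pairs.
#'
#' @param B Binary term x protein incidence matrix from [term_incidence()].
#' @return Symmetric integer term x term matrix `G = B B^T`.
#' @export
cooccurrence <- function(B) {
  stopifnot(is.matrix(B), all(B %in% c(0L, 1L)))
  G <- tcrossprod(B)
  storage.mode(G) <- "integer"
  G
}

#' Compatibility graph of non-overlapping terms
#'
#' Terms are connected exactly when they share no protein (the zero
#' off-diagonal entries of the co-occurrence matrix); this is the complement
#' of the overlap graph.
#'
#' @param G Symmetric co-occurrence matrix from [cooccurrence()].
#' @return An igraph graph over the terms.
#' @export
compatibility_graph <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  if (!isSymmetric(unname(G))) stop("co-occurrence matrix must be symmetric")
  A <- (G == 0L) * 1L
  diag(A) <- 0L
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Select the best non-overlapping term configuration
#'
#' Candidate configurations are the maximal cliques of the compatibility
#' graph (fully mutually non-overlapping term groups); each is scored by the
#' total number of proteins its terms cover (the sum of the corresponding
#' diagonal counts, exact because the terms are pairwise disjoint). The
#' maximum-coverage configuration is returned, with ties broken by fewer
#' terms, then by the lexicographically smallest sorted term list. An
#' exhaustive mode enumerates every pairwise-compatible subset instead
#' (guarded by `max_exhaustive_terms`, since the candidate count grows
#' exponentially).
#'
#' @param compat Compatibility graph from [compatibility_graph()].
#' @param G Co-occurrence matrix over the same terms.
#' @param method `"cliques"` (default) or `"exhaustive"`.
#' @param max_exhaustive_terms Refuse exhaustive search above this many terms
#'   (default 20).
#' @return List of class `go_configuration`: `terms` (sorted), `per_term`
#'   (named protein counts), `assigned_count`.
#' @export
select_best_configuration <- function(compat, G,
                                      method = c("cliques", "exhaustive"),
                                      max_exhaustive_terms = 20L) {
  method <- match.arg(method)
  terms <- rownames(G)
  if (is.null(terms)) stop("co-occurrence matrix must carry term names")
  if (!setequal(igraph::V(compat)$name, terms)) {
    stop("compatibility graph and co-occurrence matrix term sets differ")
  }
  counts <- diag(G)
  names(counts) <- terms
  if (length(terms) == 0L) {
    return(structure(list(terms = character(), per_term = integer(),
                          assigned_count = 0L), class = "go_configuration"))
  }
  if (method == "exhaustive") {
    if (length(terms) > max_exhaustive_terms) {
      stop("exhaustive configuration search refused above ",
           max_exhaustive_terms, " terms (", length(terms), " given)")
    }
    t <- length(terms)
    masks <- seq_len(2^t) - 1L
    bits <- 2L^(seq_len(t) - 1L)
    has <- vapply(bits, function(b) bitwAnd(masks, b) > 0L,
                  logical(length(masks)))
    valid <- masks > 0L
    for (i in seq_len(t - 1L)) {
      for (j in seq((i + 1L), t)) {
        if (G[i, j] != 0L) valid <- valid & !(has[, i] & has[, j])
      }
    }
    cand <- apply(has[valid, , drop = FALSE], 1L,
                  function(r) terms[r], simplify = FALSE)
  } else {
    # maximal cliques of the compatibility graph; isolated terms appear as
    # singleton maximal cliques, so an edgeless graph still yields the best
    # single term
    cl <- igraph::max_cliques(compat, min = 1L)
    cand <- lapply(cl, function(v) sort(igraph::V(compat)$name[v]))
  }
  cover <- vapply(cand, function(ts) sum(counts[ts]), 0)
  sizes <- lengths(cand)
  keys <- vapply(lapply(cand, sort), paste, "", collapse = ";")
  best <- order(-cover, sizes, keys)[1L]
  ts <- sort(cand[[best]])
  structure(list(terms = ts, per_term = counts[ts],
                 assigned_count = as.integer(sum(counts[ts]))),
            class = "go_configuration")
}

#' @export
print.go_configuration <- function(x, ...) {
  cat(sprintf("non-overlapping GO configuration: %d terms covering %d proteins\n",
              length(x$terms), x$assigned_count))
  invisible(x)
}

#' Full non-overlapping GO decomposition of a protein set
#'
#' Convenience wrapper running [term_incidence()], [cooccurrence()],
#' [compatibility_graph()] and [select_best_configuration()], and reporting
#' the proteins the chosen configuration leaves uncovered (a protein left out
#' is typically associated with many terms, not with none).
#'
#' @inheritParams term_incidence
#' @inheritParams select_best_configuration
#' @return List of class `go_decomposition` with `configuration`, `members`
#'   (named list term -> covered proteins), `uncovered` (annotated proteins
#'   not covered), `cooccurrence` (the `G` matrix) and `incidence`.
#' @export
go_decompose <- function(assoc, proteins = NULL,
                         method = c("cliques", "exhaustive"),
                         max_exhaustive_terms = 20L) {
  method <- match.arg(method)
  B <- term_incidence(assoc, proteins)
  G <- cooccurrence(B)
  compat <- compatibility_graph(G)
  cfg <- select_best_configuration(compat, G, method = method,
                                   max_exhaustive_terms = max_exhaustive_terms)
  members <- lapply(cfg$terms, function(t) colnames(B)[B[t, ] == 1L])
  names(members) <- cfg$terms
  covered <- unique(unlist(members))
  structure(list(configuration = cfg,
                 members = members,
                 uncovered = setdiff(colnames(B), covered),
                 cooccurrence = G,
                 incidence = B),
            class = "go_decomposition")
}

#' Write a GO decomposition (configuration TSV, uncovered list, co-occurrence)
#'
#' @param decomp A `go_decomposition`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_go_decomposition <- function(decomp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- decomp$configuration
  utils::write.table(
    data.frame(term = cfg$terms,
               n_proteins = as.integer(cfg$per_term),
               members = vapply(decomp$members[cfg$terms],
                                function(m) paste(sort(m), collapse = ";"),
                                "")),
    file.path(dir, "configuration.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(decomp$uncovered, file.path(dir, "uncovered_proteins.txt"))
  utils::write.table(decomp$cooccurrence,
                     file.path(dir, "cooccurrence.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(dir)
}
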