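#' Construct a classification scheme
#'
#' A classification scheme maps proteins to one or more class labels drawn
#' from a fixed universe of `n` classes (e.g. biological pathways,
#' subcellular compartments, or disease classes). Unannotated proteins are
#' simply absent from the mapping.
#'
#' @param annotations `data.frame` with columns `protein` and `term` (one row
#'   per protein-class assignment), as returned by [read_annotation_table()].
#' @param scheme_id Scheme identifier, conventionally one of `"KEGG"`,
#'   `"LOC"`, `"OMIM"` (`"DISEASE"` is accepted as an alias of `"OMIM"`).
#' @param universe Optional character vector fixing the class universe;
#'   defaults to the distinct terms observed in `annotations`.
#' @return An object of class `classification_scheme`: list with `scheme_id`,
#'   `sets` (named list protein -> character vector of classes), `universe`,
#'   `n`.
#' @export
classification_scheme <- function(annotations, scheme_id,
                                  universe = NULL) {
  stopifnot(all(c("protein", "term") %in% names(annotations)))
  if (identical(toupper(scheme_id), "DISEASE")) scheme_id <- "OMIM"
  if (is.null(universe)) universe <- sort(unique(annotations$term))
  universe <- sort(unique(as.character(universe)))
  if (!all(annotations$term %in% universe)) {
    stop("annotation terms outside the declared class universe")
  }
  sets <- lapply(split(as.character(annotations$term),
                       as.character(annotations$protein)), unique)
  structure(list(scheme_id = scheme_id, sets = sets,
                 universe = universe, n = length(universe)),
            class = "classification_scheme")
}

#' @export
print.classification_scheme <- function(x, ...) {
  cat(sprintf("classification scheme %s: %d classes, %d annotated proteins\n",
              x$scheme_id, x$n, length(x$sets)))
  invisible(x)
}

# Internal evaluator shared by redundancy(), permutation p-values and
# score_table(): precomputes index structures once, then scores every module
# for an arbitrary permutation of the protein -> label-set assignment.
#
# Returns list(eval = function(perm) numeric R per module, n_annot,
# identity_perm).
scheme_engine <- function(member_lists, scheme) {
  if (scheme$n < 2L) stop("classification scheme must have n >= 2 classes")
  prot <- names(scheme$sets)
  lab_sets <- lapply(scheme$sets, function(x) match(x, scheme$universe))
  set_len <- lengths(lab_sets)
  n_mod <- length(member_lists)
  mem_idx <- lapply(member_lists, function(m) {
    i <- match(m, prot)
    i[!is.na(i)]
  })
  m_annot <- lengths(mem_idx)
  modmem <- unlist(mem_idx, use.names = FALSE)
  modrow <- rep.int(seq_len(n_mod), m_annot)
  valid <- m_annot >= 2L
  logn <- log(scheme$n)
  n_cls <- scheme$n
  flat_labs <- lab_sets
  evalfun <- function(perm) {
    R <- numeric(n_mod)
    if (length(modmem) == 0L) return(R)
    ids <- perm[modmem]
    len <- set_len[ids]
    labs <- unlist(flat_labs[ids], use.names = FALSE)
    gm <- rep.int(modrow, len)
    w <- rep.int(1 / len, len)
    key <- (gm - 1) * n_cls + labs
    wsum <- rowsum(w, key)
    kmod <- (as.numeric(rownames(wsum)) - 1) %/% n_cls + 1
    f <- wsum[, 1L] / m_annot[kmod]
    contrib <- rowsum(f * log(f), kmod)
    r_valid <- 1 + contrib[, 1L] / logn
    R[as.integer(rownames(contrib))] <- r_valid
    R[!valid] <- 0
    pmin(pmax(R, 0), 1)
  }
  list(eval = evalfun, n_annot = length(prot),
       identity_perm = seq_along(prot))
}

#' Annotation redundancy (homogeneity) of a functional module
#'
#' Measures how concentrated the class labels of a module's annotated members
#' are, as one minus the normalized Shannon entropy of the class frequency
#' profile: `R = 1 + sum(f_k log f_k) / log n`, with `0 log 0 = 0`, where
#' `f_k` is the relative frequency of class `k` among annotated members and
#' `n` the total number of classes in the scheme. `R = 1` when all annotated
#' members share a single class; `R = 0` at maximal dispersion. Proteins with
#' `L` labels contribute weight `1/L` to each (default), or are reduced to a
#' single label by a majority heuristic with `multi_label = "best"`. Modules
#' with fewer than two annotated members score 0, preventing vacuous
#' homogeneity.
#'
#' @param members Character vector of module member identifiers.
#' @param scheme A [classification_scheme()].
#' @param multi_label `"fractional"` (default) or `"best"` (each multi-label
#'   protein is assigned the single label most frequent across the module's
#'   members, ties broken lexicographically).
#' @return Redundancy `R` in \[0, 1\].
#' @export
redundancy <- function(members, scheme,
                       multi_label = c("fractional", "best")) {
  multi_label <- match.arg(multi_label)
  if (scheme$n < 2L) stop("classification scheme must have n >= 2 classes")
  sets <- scheme$sets[intersect(members, names(scheme$sets))]
  m <- length(sets)
  if (m < 2L) return(0)
  if (multi_label == "best") {
    votes <- table(unlist(lapply(sets, unique), use.names = FALSE))
    pick <- vapply(sets, function(ls) {
      v <- votes[ls]
      ls[order(-as.numeric(v), ls)][1L]
    }, "")
    f <- as.numeric(table(pick)) / m
  } else {
    w <- unlist(lapply(sets, function(ls) rep(1 / length(ls), length(ls))),
                use.names = FALSE)
    labs <- unlist(sets, use.names = FALSE)
    f <- as.numeric(rowsum(w, labs)) / m
  }
  r <- 1 + sum(f * log(f)) / log(scheme$n)
  min(max(r, 0), 1)
}

#' Permutation p-values for module redundancies under a scheme
#'
#' Null replicates permute the protein -> label-set assignment as a whole
#' across the scheme's annotated proteins (each protein's label multiset is
#' preserved, only its carrier changes), recomputing every module's
#' redundancy. Empirical p-values use the add-one convention
#' `p = (1 + #\{null R >= observed R\}) / (reps + 1)`, so `p > 0` always.
#'
#' @param modules A `functional_modules` data frame (or list of member
#'   vectors).
#' @param scheme A [classification_scheme()].
#' @param reps Number of permutations (>= 1), default 1000.
#' @param rng_seed Integer seed.
#' @return Named list with `R` (observed redundancies) and `p` (empirical
#'   p-values), both named by `module_id`.
#' @export
scheme_permutation_pvalues <- function(modules, scheme, reps = 1000L,
                                       rng_seed = 1L) {
  stopifnot(reps >= 1)
  member_lists <- module_member_lists(modules)
  eng <- scheme_engine(member_lists, scheme)
  obs <- eng$eval(eng$identity_perm)
  cnt <- integer(length(obs))
  set.seed(rng_seed)
  for (r in seq_len(reps)) {
    perm <- sample.int(eng$n_annot)
    cnt <- cnt + (eng$eval(perm) >= obs)
  }
  p <- (1 + cnt) / (reps + 1)
  ids <- module_ids(modules, member_lists)
  list(R = stats::setNames(obs, ids), p = stats::setNames(p, ids))
}

module_member_lists <- function(modules) {
  if (is.data.frame(modules)) modules$members else modules
}

module_ids <- function(modules, member_lists) {
  if (is.data.frame(modules) && "module_id" %in% names(modules)) {
    modules$module_id
  } else {
    vapply(member_lists, paste, "", collapse = ";")
  }
}

#' Score every module under the three classification schemes
#'
#' Produces the per-module feature table used by the nonlinear ranking model:
#' a normalized size feature `log(N)/log(N_max)` plus the redundancy and
#' permutation p-value under each scheme (pathway, localization, disease).
#'
#' @param modules A `functional_modules` data frame.
#' @param schemes List of [classification_scheme()] objects covering scheme
#'   ids `KEGG`, `LOC` and `OMIM` (in any order; `DISEASE` aliases `OMIM`).
#' @param reps Permutations per scheme (default 1000).
#' @param rng_seed Integer seed; scheme k uses `rng_seed + k - 1`.
#' @return `data.frame` of class `module_scores`, ordered as the input
#'   modules, with columns `module_id`, `N`, `size_feature`, `R_KEGG`,
#'   `p_KEGG`, `R_LOC`, `p_LOC`, `R_OMIM`, `p_OMIM`, `planted` (all `FALSE`)
#'   and `S` (`NA`, filled by [rank_modules()]).
#' @export
score_table <- function(modules, schemes, reps = 1000L, rng_seed = 1L) {
  ids_have <- vapply(schemes, function(s) s$scheme_id, "")
  need <- c("KEGG", "LOC", "OMIM")
  miss <- setdiff(need, ids_have)
  if (length(miss) > 0L) {
    stop("missing classification scheme(s): ", paste(miss, collapse = ", "))
  }
  member_lists <- module_member_lists(modules)
  n_sizes <- lengths(member_lists)
  size_feature <- if (length(n_sizes) > 0L && max(n_sizes) > 1L) {
    log(n_sizes) / log(max(n_sizes))
  } else {
    rep(1, length(n_sizes))
  }
  out <- data.frame(
    module_id = module_ids(modules, member_lists),
    N = as.integer(n_sizes),
    size_feature = size_feature,
    stringsAsFactors = FALSE)
  for (k in seq_along(need)) {
    sch <- schemes[[which(ids_have == need[k])[1L]]]
    res <- scheme_permutation_pvalues(modules, sch, reps = reps,
                                      rng_seed = rng_seed + k - 1L)
    out[[paste0("R_", need[k])]] <- unname(res$R)
    out[[paste0("p_", need[k])]] <- unname(res$p)
  }
  out$planted <- FALSE
  out$S <- NA_real_
  class(out) <- c("module_scores", "data.frame")
  out
}
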