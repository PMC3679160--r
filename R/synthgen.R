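#' Synthetic-bundle configuration
#'
#' Parameters of the fully synthetic input bundle: a background interaction
#' graph with planted cliques whose confidences sit above the threshold while
#' background confidences straddle it, annotation schemes with tunable
#' within-module homogeneity, GO term blocks with a certified optimal
#' non-overlapping configuration, and disease annotations with planted
#' overlapping pairs.
#'
#' @param rng_seed Integer seed (below 2^31); the single source of
#'   randomness.
#' @param proteome_size Number of proteins in the synthetic proteome.
#' @param core_fraction Fraction of the proteome flagged as core seeds.
#' @param n_planted_modules Number of planted (disjoint) cliques.
#' @param module_size_range Planted clique sizes (inclusive range).
#' @param background_edge_model `"preferential-attachment"` or
#'   `"configuration"` (Poisson degree sequence).
#' @param background_mean_degree Mean degree of the background graph.
#' @param confidence_threshold Confidence threshold the pipeline will apply.
#' @param planted_confidence_range Confidence range of planted clique edges
#'   (must sit at or above the threshold).
#' @param background_confidence_range Confidence range of background edges
#'   (deliberately straddles the threshold).
#' @param n_classes Named integer vector: classes per scheme
#'   (`KEGG`, `LOC`, `OMIM`).
#' @param p_hom Probability that a planted-module member carries its module's
#'   home class (per member, per scheme).
#' @param annotated_fraction Fraction of non-planted proteins annotated per
#'   scheme.
#' @param multi_label_fraction Fraction of annotated proteins receiving a
#'   second label.
#' @param go_n_terms Number of disjoint base GO term blocks.
#' @param go_overlap_fraction Extra deliberately overlapping terms, as a
#'   fraction of `go_n_terms`.
#' @param n_diseases Number of disease terms (including planted-pair terms).
#' @param planted_pairs Integer vector of shared-protein counts, one planted
#'   disease pair per entry.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(rng_seed = 1L,
                         proteome_size = 1000L,
                         core_fraction = 0.2,
                         n_planted_modules = 20L,
                         module_size_range = c(3L, 10L),
                         background_edge_model = c("preferential-attachment",
                                                   "configuration"),
                         background_mean_degree = 4,
                         confidence_threshold = 940L,
                         planted_confidence_range = c(945L, 1000L),
                         background_confidence_range = c(700L, 999L),
                         n_classes = c(KEGG = 50L, LOC = 30L, OMIM = 23L),
                         p_hom = 0.8,
                         annotated_fraction = 0.8,
                         multi_label_fraction = 0.1,
                         go_n_terms = 12L,
                         go_overlap_fraction = 0.3,
                         n_diseases = 40L,
                         planted_pairs = c(5L, 4L, 3L)) {
  background_edge_model <- match.arg(background_edge_model)
  stopifnot(proteome_size >= 10, core_fraction > 0, core_fraction <= 1,
            n_planted_modules >= 1, length(module_size_range) == 2L,
            module_size_range[1L] >= 2L,
            module_size_range[1L] <= module_size_range[2L],
            background_mean_degree > 0,
            p_hom >= 0, p_hom <= 1,
            annotated_fraction > 0, annotated_fraction <= 1,
            multi_label_fraction >= 0, multi_label_fraction <= 1,
            go_n_terms >= 1, go_overlap_fraction >= 0,
            n_diseases >= 2L * length(planted_pairs) + 2L,
            all(planted_pairs >= 1))
  if (planted_confidence_range[1L] < confidence_threshold) {
    stop("planted confidence range must sit at or above the threshold")
  }
  if (n_planted_modules * module_size_range[2L] > proteome_size) {
    stop("planted modules cannot exceed the proteome: ",
         n_planted_modules, " modules of size up to ",
         module_size_range[2L], " in a proteome of ", proteome_size)
  }
  stopifnot(setequal(names(n_classes), c("KEGG", "LOC", "OMIM")),
            all(n_classes >= 2))
  structure(list(rng_seed = as.integer(rng_seed),
                 proteome_size = as.integer(proteome_size),
                 core_fraction = core_fraction,
                 n_planted_modules = as.integer(n_planted_modules),
                 module_size_range = as.integer(module_size_range),
                 background_edge_model = background_edge_model,
                 background_mean_degree = background_mean_degree,
                 confidence_threshold = as.integer(confidence_threshold),
                 planted_confidence_range =
                   as.integer(planted_confidence_range),
                 background_confidence_range =
                   as.integer(background_confidence_range),
                 n_classes = n_classes[c("KEGG", "LOC", "OMIM")],
                 p_hom = p_hom,
                 annotated_fraction = annotated_fraction,
                 multi_label_fraction = multi_label_fraction,
                 go_n_terms = as.integer(go_n_terms),
                 go_overlap_fraction = go_overlap_fraction,
                 n_diseases = as.integer(n_diseases),
                 planted_pairs = as.integer(planted_pairs)),
            class = "synth_config")
}

rand_int <- function(n, lo, hi) {
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
}

#' Generate a synthetic input bundle with known ground truth
#'
#' Writes the full set of pipeline inputs to `dir` -- edge list, core protein
#' list, three classification-scheme tables with class universes, GO
#' association table, protein-disease table with term classes -- plus a
#' `truth.json` recording the planted structure. Outputs are byte-identical
#' under identical configuration. Planted cliques are asserted to survive
#' thresholding intact and to be maximal (background edges that would extend
#' a planted clique are removed), and the optimal non-overlapping GO
#' configuration is certified by exhaustive search at generation time.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the truth bundle: list with `planted_modules`,
#'   `module_class` (per scheme), `go_optimum`, `planted_disease_pairs`,
#'   `files`.
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  prot <- sprintf("P%05d", seq_len(config$proteome_size))

  ## planted cliques over disjoint member sets
  sizes <- rand_int(config$n_planted_modules, config$module_size_range[1L],
                    config$module_size_range[2L])
  pool <- sample(prot)
  offs <- cumsum(c(0L, sizes))
  planted <- lapply(seq_along(sizes), function(i) {
    sort(pool[(offs[i] + 1L):offs[i + 1L]])
  })
  names(planted) <- vapply(planted, paste, "", collapse = ";")
  planted_edges <- do.call(rbind, lapply(planted, function(m) {
    cmb <- utils::combn(m, 2L)
    data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
  }))
  planted_edges$conf <- rand_int(nrow(planted_edges),
                                 config$planted_confidence_range[1L],
                                 config$planted_confidence_range[2L])
  # chain consecutive planted modules with single above-threshold anchor
  # edges so all planted cliques live in one (the giant) component after
  # thresholding; an anchor touches one member only, so maximality of the
  # cliques is unaffected
  if (length(planted) > 1L) {
    anchors <- data.frame(
      a = vapply(planted[-length(planted)], `[[`, "", 1L),
      b = vapply(planted[-1L], `[[`, "", 1L),
      stringsAsFactors = FALSE)
    anchors$conf <- rand_int(nrow(anchors),
                             config$planted_confidence_range[1L],
                             config$planted_confidence_range[2L])
    planted_edges <- rbind(planted_edges, anchors)
  }

  ## background graph
  n <- config$proteome_size
  if (config$background_edge_model == "preferential-attachment") {
    m_pa <- max(1L, round(config$background_mean_degree / 2))
    bg <- igraph::sample_pa(n, m = m_pa, directed = FALSE)
  } else {
    deg <- stats::rpois(n, config$background_mean_degree)
    deg[deg < 1L] <- 1L
    if (sum(deg) %% 2L == 1L) deg[1L] <- deg[1L] + 1L
    bg <- igraph::sample_degseq(deg, method = "fast.heur.simple")
  }
  bel <- igraph::as_edgelist(bg, names = FALSE)
  # randomize which proteins carry the background topology
  relab <- sample(prot)
  bedges <- data.frame(a = relab[bel[, 1L]], b = relab[bel[, 2L]],
                       stringsAsFactors = FALSE)
  bedges$conf <- rand_int(nrow(bedges),
                          config$background_confidence_range[1L],
                          config$background_confidence_range[2L])

  edges <- normalize_edges(c(planted_edges$a, bedges$a),
                           c(planted_edges$b, bedges$b),
                           c(planted_edges$conf, bedges$conf))
  # re-impose planted confidences (a coincident background edge must not
  # drag a planted edge below the threshold)
  pk <- paste(pmin(planted_edges$a, planted_edges$b),
              pmax(planted_edges$a, planted_edges$b))
  ek <- paste(edges$protein_a, edges$protein_b)
  hit <- match(ek, pk)
  edges$confidence <- ifelse(!is.na(hit),
                             pmax(edges$confidence,
                                  planted_edges$conf[hit]),
                             edges$confidence)

  ## enforce maximality of planted cliques in the thresholded graph:
  ## drop any thresholded background edge from a vertex adjacent to ALL
  ## members of a planted clique
  repeat {
    gth <- build_network(edges, min_confidence = config$confidence_threshold)
    drop_keys <- character()
    for (m in planted) {
      idx <- match(m, igraph::V(gth)$name)
      if (anyNA(idx)) stop("planted clique lost below threshold (bug)")
      nb <- lapply(idx, function(v)
        igraph::V(gth)$name[igraph::neighbors(gth, v)])
      ext <- setdiff(Reduce(intersect, nb), m)
      if (length(ext) > 0L) {
        v <- ext[1L]
        drop_keys <- c(drop_keys, paste(pmin(v, m[1L]), pmax(v, m[1L])))
      }
    }
    if (length(drop_keys) == 0L) break
    edges <- edges[!(paste(edges$protein_a, edges$protein_b) %in%
                       drop_keys), , drop = FALSE]
    class(edges) <- c("weighted_edge_list", "data.frame")
  }
  # planted cliques intact above threshold
  gth <- build_network(edges, min_confidence = config$confidence_threshold)
  for (m in planted) {
    sub <- igraph::induced_subgraph(gth, match(m, igraph::V(gth)$name))
    stopifnot(igraph::ecount(sub) == choose(length(m), 2L))
  }

  ## core list: planted members enriched, topped up at random
  core <- unique(unlist(planted)[stats::runif(sum(sizes)) < 0.7])
  n_core <- max(length(core), round(config$core_fraction * n))
  core <- sort(c(core, sample(setdiff(prot, core), n_core - length(core))))

  ## classification schemes
  scheme_ids <- c("KEGG", "LOC", "OMIM")
  scheme_files <- list()
  module_class <- list()
  for (sid in scheme_ids) {
    ncls <- config$n_classes[[sid]]
    classes <- sprintf("%s_C%03d", sid, seq_len(ncls))
    home <- sample(classes, length(planted), replace = TRUE)
    names(home) <- names(planted)
    rows_p <- lapply(seq_along(planted), function(i) {
      mem <- planted[[i]]
      lab <- ifelse(stats::runif(length(mem)) < config$p_hom, home[i],
                    sample(classes, length(mem), replace = TRUE))
      data.frame(protein = mem, term = lab, stringsAsFactors = FALSE)
    })
    others <- setdiff(prot, unlist(planted))
    ann <- others[stats::runif(length(others)) < config$annotated_fraction]
    rows_b <- data.frame(protein = ann,
                         term = sample(classes, length(ann),
                                       replace = TRUE),
                         stringsAsFactors = FALSE)
    tab <- rbind(do.call(rbind, rows_p), rows_b)
    # second labels only on background proteins, so planted-module
    # homogeneity stays a pure function of p_hom
    extra <- rows_b$protein[stats::runif(nrow(rows_b)) <
                              config$multi_label_fraction]
    if (length(extra) > 0L) {
      tab <- rbind(tab, data.frame(
        protein = extra,
        term = sample(classes, length(extra), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    tab <- unique(tab[order(tab$protein, tab$term), , drop = FALSE])
    f <- file.path(dir, paste0(tolower(sid), ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(classes, file.path(dir, paste0(tolower(sid),
                                              "_classes.txt")))
    scheme_files[[sid]] <- f
    module_class[[sid]] <- as.list(home)
  }

  ## GO associations: disjoint blocks + deliberately overlapping terms
  n_extra <- round(config$go_overlap_fraction * config$go_n_terms)
  go_pool <- sample(prot)
  block_sizes <- rand_int(config$go_n_terms, 3L, 8L)
  goffs <- cumsum(c(0L, block_sizes))
  blocks <- lapply(seq_along(block_sizes), function(i) {
    sort(go_pool[(goffs[i] + 1L):goffs[i + 1L]])
  })
  base_terms <- sprintf("GO:%07d", seq_len(config$go_n_terms))
  assoc <- data.frame(
    term = rep(base_terms, block_sizes),
    protein = unlist(blocks), stringsAsFactors = FALSE)
  if (n_extra > 0L) {
    for (e in seq_len(n_extra)) {
      src <- sample(config$go_n_terms, 2L)
      picked <- c(sample(blocks[[src[1L]]], 1L),
                  sample(blocks[[src[2L]]],
                         min(2L, length(blocks[[src[2L]]]))))
      assoc <- rbind(assoc, data.frame(
        term = sprintf("GO:%07d", config$go_n_terms + e),
        protein = unique(picked), stringsAsFactors = FALSE))
    }
  }
  assoc <- assoc[order(assoc$term, assoc$protein), , drop = FALSE]
  utils::write.table(assoc, file.path(dir, "go_assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # certify the optimum by exhaustive search
  B <- term_incidence(data.frame(term = assoc$term,
                                 protein = assoc$protein))
  G <- cooccurrence(B)
  go_opt <- select_best_configuration(compatibility_graph(G), G,
                                      method = "exhaustive",
                                      max_exhaustive_terms = 20L)

  ## disease annotations with planted overlapping pairs
  np <- length(config$planted_pairs)
  dterms <- sprintf("DIS%03d", seq_len(config$n_diseases))
  pair_terms <- dterms[seq_len(2L * np)]
  bg_terms <- dterms[(2L * np + 1L):config$n_diseases]
  dz <- data.frame(protein = character(), term = character(),
                   stringsAsFactors = FALSE)
  carriers <- prot[stats::runif(n) < 0.3]
  if (length(carriers) > 0L) {
    cnt <- rand_int(length(carriers), 1L, 2L)
    dz <- data.frame(
      protein = rep(carriers, cnt),
      term = sample(bg_terms, sum(cnt), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  planted_pairs_df <- data.frame(term_a = character(), term_b = character(),
                                 shared = integer(),
                                 stringsAsFactors = FALSE)
  avail <- sample(prot)
  cursor <- 0L
  for (i in seq_len(np)) {
    s <- config$planted_pairs[i]
    ta <- pair_terms[2L * i - 1L]; tb <- pair_terms[2L * i]
    shared_p <- avail[(cursor + 1L):(cursor + s)]; cursor <- cursor + s
    only_a <- avail[(cursor + 1L):(cursor + 2L)]; cursor <- cursor + 2L
    only_b <- avail[(cursor + 1L):(cursor + 2L)]; cursor <- cursor + 2L
    dz <- rbind(dz,
                data.frame(protein = c(shared_p, only_a),
                           term = ta, stringsAsFactors = FALSE),
                data.frame(protein = c(shared_p, only_b),
                           term = tb, stringsAsFactors = FALSE))
    planted_pairs_df <- rbind(planted_pairs_df, data.frame(
      term_a = min(ta, tb), term_b = max(ta, tb), shared = s,
      stringsAsFactors = FALSE))
  }
  dz <- unique(dz[order(dz$protein, dz$term), , drop = FALSE])
  utils::write.table(dz, file.path(dir, "protein_disease.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  dclass <- data.frame(term = dterms,
                       class = sprintf("DCLASS%02d",
                                       rand_int(length(dterms), 1L, 23L)),
                       stringsAsFactors = FALSE)
  utils::write.table(dclass, file.path(dir, "disease_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  ## edge list + core list
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(core, file.path(dir, "core_proteins.txt"))

  truth <- list(
    planted_modules = unname(lapply(planted, identity)),
    module_class = module_class,
    go_optimum = list(terms = go_opt$terms,
                      assigned_count = go_opt$assigned_count),
    planted_disease_pairs = planted_pairs_df,
    config = unclass(config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(truth, list(files = list.files(dir))))
}

#' Read the truth bundle written by [generate_bundle()]
#'
#' @param dir Bundle directory.
#' @return The truth list.
#' @export
read_truth <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  tr$planted_modules <- lapply(tr$planted_modules, as.character)
  tr
}

#' Run the full modular-analysis pipeline on an input bundle
#'
#' Reads a bundle directory (as written by [generate_bundle()], or assembled
#' from real exports in the same formats), thresholds the network, extracts
#' the singleton-free giant component, enumerates and scores modules, fits
#' the ranking model by GA, assembles the condensed network at the
#' saturation-selected k, decomposes it into non-overlapping GO terms, and
#' derives the disease-disease overlap network.
#'
#' @param dir Bundle directory.
#' @param min_confidence Confidence threshold (default 940).
#' @param min_module_size Module size cut for scoring (default 4).
#' @param reps Permutation replicates for scheme p-values and disease
#'   overlaps (default 1000).
#' @param rng_seed Integer seed driving permutations and the GA.
#' @param n_plant Planted ideal records for the GA (default 10).
#' @param ga Optional [ga_config()] (defaults to `ga_config(rng_seed =
#'   rng_seed)`).
#' @param ks Candidate top-k values for the selection curve (values beyond
#'   the ranking length are dropped; the ranking length itself is always a
#'   candidate).
#' @param tol Saturation tolerance for [choose_k()].
#' @return List with every intermediate artifact: `network`, `giant`,
#'   `modules`, `module_stats`, `scores`, `fit`, `ranking`, `curve`, `k`,
#'   `condensed`, `go` (decomposition restricted to the condensed proteins),
#'   `go_full` (decomposition over the whole association table, the universe
#'   on which a synthetic truth is certified), `disease_map`,
#'   `disease_pairs`, `disease_net`.
#' @export
run_pipeline <- function(dir, min_confidence = 940L, min_module_size = 4L,
                         reps = 1000L, rng_seed = 1L, n_plant = 10L,
                         ga = NULL, ks = c(5L, 10L, 15L, 20L, 25L, 40L),
                         tol = 0.05) {
  edges <- read_edge_list(file.path(dir, "edges.tsv"))
  core <- read_protein_list(file.path(dir, "core_proteins.txt"))
  net <- build_network(edges, core, min_confidence)
  giant <- giant_component(drop_singletons(net))
  modules <- enumerate_maximal_cliques(giant)
  filt <- size_filter_and_stats(modules, min_size = min_module_size)
  schemes <- lapply(c("KEGG", "LOC", "OMIM"), function(sid) {
    f <- file.path(dir, paste0(tolower(sid), ".tsv"))
    uf <- file.path(dir, paste0(tolower(sid), "_classes.txt"))
    classification_scheme(read_annotation_table(f), sid,
                          universe = if (file.exists(uf))
                            read_protein_list(uf) else NULL)
  })
  scores <- score_table(filt$modules, schemes, reps = reps,
                        rng_seed = rng_seed)
  with_planted <- plant_ideal_modules(scores, n_plant = n_plant)
  if (is.null(ga)) ga <- ga_config(rng_seed = rng_seed)
  fit <- ga_fit(with_planted, config = ga)
  ranking <- rank_modules(with_planted, fit$params)
  ks <- sort(unique(c(ks[ks <= nrow(ranking)], nrow(ranking))))
  curve <- selection_curve(giant, ranking, core, ks = ks)
  k <- choose_k(curve, tol = tol)
  condensed <- assemble_condensed(giant, ranking, k)
  cond_prot <- igraph::V(condensed)$name
  go_assoc <- read_annotation_table(file.path(dir, "go_assoc.tsv"),
                                    swap = TRUE)
  go <- go_decompose(go_assoc, proteins = cond_prot)
  # decomposition over the full association table (the synthetic truth is
  # certified on it, irrespective of which proteins the ranking condenses)
  go_full <- go_decompose(go_assoc)
  annot <- disease_annotation(
    read_annotation_table(file.path(dir, "protein_disease.tsv")),
    term_class = stats::setNames(
      read_annotation_table(file.path(dir, "disease_classes.tsv")),
      c("term", "class")))
  dmap <- disease_protein_map(cond_prot, annot)
  disease_pairs <- NULL
  disease_net <- NULL
  if (length(dmap) >= 2L) {
    disease_pairs <- overlap_scores(dmap)
    if (nrow(disease_pairs) > 0L) {
      disease_pairs <- permutation_fdr(disease_pairs, dmap, reps = reps,
                                       rng_seed = rng_seed)
      disease_net <- disease_network(disease_pairs, annot)
    }
  }
  list(network = net, giant = giant, modules = modules,
       module_stats = filt$stats, scores = scores, fit = fit,
       ranking = ranking, curve = curve, k = k, condensed = condensed,
       go = go, go_full = go_full, disease_map = dmap,
       disease_pairs = disease_pairs, disease_net = disease_net)
}

#' Check pipeline outputs against a synthetic truth bundle
#'
#' @param truth Truth bundle from [generate_bundle()] / [read_truth()].
#' @param results Pipeline outputs, e.g. from [run_pipeline()]; must contain
#'   `modules`, `ranking`, `go` and `disease_pairs`.
#' @return List of class `truth_report`: `module_recovery` (fraction of
#'   planted cliques found among the maximal cliques), `planted_rank_median`
#'   and `planted_rank_pctile` (ranks of planted modules in the fitted
#'   ranking), `go_matched` (logical), `disease_pair_pvalues` and
#'   `disease_pair_recovery` (fraction with p < 0.01).
#' @export
verify_truth <- function(truth, results) {
  need <- c("modules", "ranking", "go", "disease_pairs")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0L) {
    stop("missing pipeline output(s): ", paste(miss, collapse = ", "))
  }
  ids <- vapply(truth$planted_modules,
                function(m) paste(sort(m), collapse = ";"), "")
  module_recovery <- mean(ids %in% results$modules$module_id)
  rk <- results$ranking$rank[match(ids, results$ranking$module_id)]
  rk <- rk[!is.na(rk)]
  planted_rank_median <- if (length(rk)) stats::median(rk) else NA_real_
  planted_rank_pctile <- if (length(rk))
    stats::median(rk) / nrow(results$ranking) else NA_real_
  go_matched <- setequal(results$go$configuration$terms,
                         truth$go_optimum$terms)
  pd <- truth$planted_disease_pairs
  pv <- rep(NA_real_, nrow(pd))
  if (!is.null(results$disease_pairs) && nrow(pd) > 0L) {
    key <- paste(results$disease_pairs$term_a, results$disease_pairs$term_b)
    pv <- results$disease_pairs$p[match(paste(pd$term_a, pd$term_b), key)]
  }
  structure(list(module_recovery = module_recovery,
                 planted_rank_median = planted_rank_median,
                 planted_rank_pctile = planted_rank_pctile,
                 go_matched = go_matched,
                 disease_pair_pvalues = pv,
                 disease_pair_recovery = mean(!is.na(pv) & pv < 0.01)),
            class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat(sprintf("planted module recovery: %.1f%%\n", 100 * x$module_recovery))
  cat(sprintf("planted rank median: %s (percentile %.3f)\n",
              format(x$planted_rank_median), x$planted_rank_pctile))
  cat(sprintf("GO optimum matched: %s\n", x$go_matched))
  cat(sprintf("planted disease pairs at p<0.01: %.1f%%\n",
              100 * x$disease_pair_recovery))
  invisible(x)
}
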