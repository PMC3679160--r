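#' Nonlinear model parameters
#'
#' The module-ranking model combines four features -- the normalized size
#' feature and the three redundancies (pathway, localization, disease) -- into
#' a single score through per-feature weights `alpha` (non-negative, summing
#' to 1) and exponents `beta` (positive, bounded above by `beta_max`).
#'
#' @param alpha Numeric vector of 4 non-negative weights; renormalized to the
#'   simplex.
#' @param beta Numeric vector of 4 positive exponents.
#' @param beta_max Upper bound of the exponent box (default 5).
#' @return Object of class `model_params`.
#' @export
model_params <- function(alpha, beta, beta_max = 5) {
  stopifnot(length(alpha) == 4L, length(beta) == 4L)
  if (any(alpha < 0)) stop("alpha weights must be non-negative")
  if (sum(alpha) <= 0) stop("alpha weights must not all be zero")
  alpha <- alpha / sum(alpha)
  if (any(beta <= 0) || any(beta > beta_max)) {
    stop("beta exponents must lie in (0, beta_max]")
  }
  structure(list(alpha = alpha, beta = beta, beta_max = beta_max,
                 features = c("size_feature", "R_KEGG", "R_LOC", "R_OMIM")),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("nonlinear module-scoring model\n")
  cat("  alpha:", paste(sprintf("%.4f", x$alpha), collapse = " "), "\n")
  cat("  beta: ", paste(sprintf("%.4f", x$beta), collapse = " "), "\n")
  invisible(x)
}

feature_matrix <- function(records) {
  feats <- c("size_feature", "R_KEGG", "R_LOC", "R_OMIM")
  miss <- setdiff(feats, names(records))
  if (length(miss) > 0L) {
    stop("score records missing feature column(s): ",
         paste(miss, collapse = ", "))
  }
  m <- as.matrix(records[, feats])
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("module features must all lie in [0, 1]")
  }
  m
}

#' Combined module score
#'
#' Default form: a weighted power sum `S = sum_j alpha_j * S_j^beta_j` over
#' the four features; with simplex weights and features in \[0, 1\] the score
#' stays in \[0, 1\]. A multiplicative alternative
#' `S = prod_j S_j^(alpha_j * beta_j)` is selectable via `form = "product"`.
#'
#' @param records A `module_scores` data frame (or any data frame with the
#'   four feature columns).
#' @param params A [model_params()] object.
#' @param form `"power-sum"` (default) or `"product"`.
#' @return Numeric vector of scores `S` in \[0, 1\], one per record row.
#' @export
combined_score <- function(records, params,
                           form = c("power-sum", "product")) {
  form <- match.arg(form)
  m <- feature_matrix(records)
  score_matrix(m, params$alpha, params$beta, form)
}

score_matrix <- function(m, alpha, beta, form) {
  if (form == "product") {
    ex <- alpha * beta
    s <- exp(log(pmax(m, .Machine$double.xmin)) %*% ex)
    s[apply(m == 0 & rep(ex > 0, each = nrow(m)), 1L, any)] <- 0
    as.numeric(s)
  } else {
    pw <- m
    for (j in seq_len(ncol(m))) pw[, j] <- m[, j]^beta[j]
    as.numeric(pw %*% alpha)
  }
}

#' Plant ideal module records
#'
#' Appends artificial score records representing the best achievable modules:
#' every redundancy at 1 and the size feature at the top of the observed
#' range. They are flagged `planted = TRUE` so that ranking can locate them;
#' the genetic algorithm uses their ranks as its supervision signal. The
#' `"per-scheme"` variant instead maximizes one feature per planted record,
#' cycling over the four features.
#'
#' @param records A `module_scores` data frame of real modules.
#' @param n_plant Number of planted records (default 10).
#' @param mode `"all-max"` (default) or `"per-scheme"`.
#' @return The records with `n_plant` planted rows appended.
#' @export
plant_ideal_modules <- function(records, n_plant = 10L,
                                mode = c("all-max", "per-scheme")) {
  mode <- match.arg(mode)
  stopifnot(n_plant >= 1L, nrow(records) > 0L)
  top_size <- max(records$size_feature)
  top_n <- max(records$N)
  base <- records[rep(1L, n_plant), , drop = FALSE]
  base$module_id <- sprintf("PLANTED_%03d", seq_len(n_plant))
  base$N <- top_n
  base$size_feature <- top_size
  base$R_KEGG <- base$R_LOC <- base$R_OMIM <- 1
  for (p in c("p_KEGG", "p_LOC", "p_OMIM")) {
    if (p %in% names(base)) base[[p]] <- NA_real_
  }
  if (mode == "per-scheme") {
    feats <- c("size_feature", "R_KEGG", "R_LOC", "R_OMIM")
    for (i in seq_len(n_plant)) {
      f <- feats[((i - 1L) %% 4L) + 1L]
      base$size_feature[i] <- min(records$size_feature)
      base$R_KEGG[i] <- base$R_LOC[i] <- base$R_OMIM[i] <- 0
      base[[f]][i] <- if (f == "size_feature") top_size else 1
    }
  }
  base$planted <- TRUE
  base$S <- NA_real_
  rownames(base) <- NULL
  out <- rbind(records, base)
  class(out) <- class(records)
  out
}

#' Genetic-algorithm configuration
#'
#' @param population_size Number of chromosomes (>= 4; default 100).
#' @param generations Number of generations (default 100).
#' @param crossover_rate Probability of blend crossover per mating (default
#'   0.8).
#' @param mutation_rate Per-gene Gaussian mutation probability (default 0.1).
#' @param mutation_sd Gaussian mutation standard deviation (default 0.1).
#' @param tournament_size Tournament selection size (default 3).
#' @param elitism Number of elites copied unchanged (default 1).
#' @param beta_max Upper bound of the exponent box (default 5).
#' @param rng_seed Integer seed (mandatory for reproducibility).
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      mutation_sd = 0.1, tournament_size = 3L,
                      elitism = 1L, beta_max = 5, rng_seed = 1L) {
  stopifnot(population_size >= 4L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_sd > 0, elitism >= 0, beta_max > 0)
  if (tournament_size > population_size) {
    stop("tournament size exceeds population size")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 beta_max = beta_max,
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

# repair a raw chromosome onto the constraint set: alpha on the simplex,
# beta clipped to (0, beta_max]
repair_chromosome <- function(ch, beta_max) {
  a <- pmax(ch[1:4], 0)
  if (sum(a) <= 0) a <- rep(0.25, 4)
  a <- a / sum(a)
  b <- pmin(pmax(ch[5:8], 1e-6), beta_max)
  c(a, b)
}

#' Fit the nonlinear model coefficients with a genetic algorithm
#'
#' Real-valued chromosomes encode `(alpha, beta)`; after every operator the
#' weights are renormalized to the simplex and the exponents clipped to their
#' box. The fitness of a chromosome is the mean rank of the planted records
#' when all records are scored and sorted by descending `S` (ties by
#' `module_id`); lower is better, so the search drives the planted ideal
#' modules toward the top of the ranking. Bit-reproducible under a fixed
#' `rng_seed`.
#'
#' @param records Real module score records, or records already containing
#'   planted rows (then `planted = NULL`).
#' @param planted Planted records (flagged `planted = TRUE`) to append, or
#'   `NULL` if `records` already contains them.
#' @param config A [ga_config()].
#' @param form Score form passed to [combined_score()].
#' @return List of class `ga_fit` with `params` ([model_params()]),
#'   `fitness` (best fitness), `trace` (best fitness per generation) and
#'   `config`.
#' @export
ga_fit <- function(records, planted = NULL, config = ga_config(),
                   form = c("power-sum", "product")) {
  form <- match.arg(form)
  if (!is.null(planted)) {
    records <- rbind(records, planted)
  }
  if (!"planted" %in% names(records) || !any(records$planted)) {
    stop("no planted records: the GA fitness needs flagged ideal modules")
  }
  m <- feature_matrix(records)
  is_planted <- records$planted
  tie_order <- order(records$module_id)
  tie_rank <- integer(nrow(records))
  tie_rank[tie_order] <- seq_len(nrow(records))
  fitness_of <- function(ch) {
    s <- score_matrix(m, ch[1:4], ch[5:8], form)
    # descending S; deterministic tie-break by module_id
    rk <- integer(length(s))
    rk[order(-s, tie_rank)] <- seq_along(s)
    mean(rk[is_planted])
  }
  set.seed(config$rng_seed)
  np <- config$population_size
  pop <- lapply(seq_len(np), function(i) {
    repair_chromosome(c(stats::runif(4), stats::runif(4, 0.1,
                                                      config$beta_max)),
                      config$beta_max)
  })
  fit <- vapply(pop, fitness_of, 0)
  trace <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(config$elitism)]]
    while (length(newpop) < np) {
      pick <- function() {
        cand <- sample.int(np, config$tournament_size)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      if (stats::runif(1) < config$crossover_rate) {
        u <- stats::runif(8)
        child <- u * p1 + (1 - u) * p2
      } else {
        child <- p1
      }
      mut <- stats::runif(8) < config$mutation_rate
      child[mut] <- child[mut] + stats::rnorm(sum(mut),
                                              sd = config$mutation_sd)
      newpop[[length(newpop) + 1L]] <- repair_chromosome(child,
                                                         config$beta_max)
    }
    pop <- newpop
    fit <- vapply(pop, fitness_of, 0)
    trace[gen] <- min(fit)
  }
  best <- pop[[which.min(fit)]]
  structure(list(
    params = model_params(best[1:4], best[5:8], beta_max = config$beta_max),
    fitness = min(fit),
    trace = trace,
    config = config,
    form = form), class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("GA fit: best mean planted rank %.2f after %d generations\n",
              x$fitness, x$config$generations))
  print(x$params)
  invisible(x)
}

#' Rank modules under fitted model parameters
#'
#' @param records Module score records (planted rows are excluded from the
#'   returned ranking).
#' @param params A [model_params()].
#' @param form Score form passed to [combined_score()].
#' @return `data.frame` with `rank`, `module_id`, `N`, `S`, sorted by
#'   descending `S`, ties broken by larger `N` then lexicographic
#'   `module_id`.
#' @export
rank_modules <- function(records, params, form = c("power-sum", "product")) {
  form <- match.arg(form)
  s <- combined_score(records, params, form)
  keep <- if ("planted" %in% names(records)) !records$planted else
    rep(TRUE, nrow(records))
  df <- data.frame(module_id = records$module_id[keep],
                   N = records$N[keep], S = s[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$S, -df$N, df$module_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "module_id", "N", "S")]
}

#' Write a GA fit (parameters, config, fitness trace) to JSON
#'
#' @param fit A `ga_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ga_fit <- function(fit, path) {
  jsonlite::write_json(
    list(alpha = fit$params$alpha, beta = fit$params$beta,
         form = fit$form, fitness = fit$fitness, trace = fit$trace,
         config = unclass(fit$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
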