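test_that("combined score evaluates the weighted power sum", {
  rec <- data.frame(module_id = "m", N = 5L,
                    size_feature = 0.5, R_KEGG = 1, R_LOC = 0, R_OMIM = 0.5)
  p <- model_params(rep(0.25, 4), rep(1, 4))
  expect_equal(combined_score(rec, p), 0.5)
  ones <- transform(rec, size_feature = 1, R_KEGG = 1, R_LOC = 1,
                    R_OMIM = 1)
  zeros <- transform(rec, size_feature = 0, R_KEGG = 0, R_LOC = 0,
                     R_OMIM = 0)
  set.seed(2)
  for (i in 1:10) {
    pr <- model_params(stats::runif(4), stats::runif(4, 0.1, 5))
    expect_equal(combined_score(ones, pr), 1)
    expect_equal(combined_score(zeros, pr), 0)
    expect_equal(combined_score(ones, pr, form = "product"), 1)
    expect_equal(combined_score(zeros, pr, form = "product"), 0)
  }
  bad <- transform(rec, R_KEGG = 1.2)
  expect_error(combined_score(bad, p), "\\[0, 1\\]")
})

test_that("combined score is monotone non-decreasing in every feature", {
  set.seed(4)
  feats <- c("size_feature", "R_KEGG", "R_LOC", "R_OMIM")
  for (i in 1:25) {
    pr <- model_params(stats::runif(4), stats::runif(4, 0.1, 5))
    base <- make_records(1, seed = i)
    for (f in feats) {
      lo <- base; hi <- base
      hi[[f]] <- min(1, base[[f]] + stats::runif(1, 0, 1 - base[[f]]))
      expect_gte(combined_score(hi, pr), combined_score(lo, pr))
    }
  }
})

test_that("model params enforce the simplex and exponent box", {
  p <- model_params(c(2, 1, 1, 0), c(1, 2, 3, 4))
  expect_equal(sum(p$alpha), 1)
  expect_equal(p$alpha, c(0.5, 0.25, 0.25, 0))
  expect_error(model_params(c(-1, 1, 1, 1), rep(1, 4)), "non-negative")
  expect_error(model_params(rep(0.25, 4), c(0, 1, 1, 1)), "beta")
  expect_error(model_params(rep(0.25, 4), c(9, 1, 1, 1)), "beta")
})

test_that("planted ideal records dominate every real record", {
  rec <- make_records(40, seed = 9)
  out <- plant_ideal_modules(rec, n_plant = 10L)
  expect_equal(sum(out$planted), 10L)
  expect_equal(nrow(out), 50L)
  pl <- out[out$planted, ]
  expect_true(all(pl$R_KEGG == 1 & pl$R_LOC == 1 & pl$R_OMIM == 1))
  expect_equal(pl$size_feature, rep(max(rec$size_feature), 10))
  # single plant Pareto-dominates every real record
  one <- plant_ideal_modules(rec, n_plant = 1L)
  p1 <- one[one$planted, ]
  for (f in c("size_feature", "R_KEGG", "R_LOC", "R_OMIM")) {
    expect_true(all(p1[[f]] >= rec[[f]]))
  }
  # under beta = 1 and any simplex alpha, a plant with size_feature = 1
  # scores exactly 1
  rec2 <- rec; rec2$size_feature[1] <- 1
  pl2 <- plant_ideal_modules(rec2, n_plant = 2L)
  pr <- model_params(c(0.1, 0.2, 0.3, 0.4), rep(1, 4))
  expect_equal(combined_score(pl2[pl2$planted, ], pr), c(1, 1))
  # per-scheme variant maximizes one feature per record
  ps <- plant_ideal_modules(rec, n_plant = 4L, mode = "per-scheme")
  plp <- ps[ps$planted, ]
  expect_equal(plp$R_KEGG, c(0, 1, 0, 0))
  expect_equal(plp$R_LOC, c(0, 0, 1, 0))
})

test_that("GA fitting is deterministic and respects constraints", {
  rec <- plant_ideal_modules(make_records(60, seed = 1), n_plant = 5L)
  cfg <- ga_config(population_size = 20L, generations = 10L, rng_seed = 77L)
  f1 <- ga_fit(rec, config = cfg)
  f2 <- ga_fit(rec, config = cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace, f2$trace)
  expect_equal(sum(f1$params$alpha), 1, tolerance = 1e-9)
  expect_true(all(f1$params$beta > 0 & f1$params$beta <= 5))
  expect_error(ga_config(population_size = 4L, tournament_size = 9L),
               "tournament")
  expect_error(ga_fit(make_records(10, seed = 2), config = cfg),
               "planted")
})

test_that("GA recovers a single separating feature", {
  # R_KEGG alone separates planted (=1) from real (<= 0.5); other features
  # overlap freely, so the fit must concentrate weight on R_KEGG
  rec <- make_records(150, seed = 5, kegg_max = 0.5)
  withp <- plant_ideal_modules(rec, n_plant = 8L, mode = "per-scheme")
  withp <- withp[!withp$planted, ]
  plants <- rec[1:8, ]
  plants$module_id <- sprintf("PLANTED_%03d", 1:8)
  plants$size_feature <- stats::runif(8)
  plants$R_LOC <- stats::runif(8)
  plants$R_OMIM <- stats::runif(8)
  plants$R_KEGG <- 1
  plants$planted <- TRUE
  all_rec <- rbind(rec, plants)
  fit <- ga_fit(all_rec, config = ga_config(population_size = 40L,
                                            generations = 30L,
                                            rng_seed = 11L))
  rk_all <- rank_modules(transform(all_rec, planted = FALSE), fit$params)
  planted_ranks <- rk_all$rank[grepl("^PLANTED", rk_all$module_id)]
  expect_true(all(planted_ranks <= 8L))
})

test_that("ranking sorts by score with size and id tie-breaks", {
  rec <- data.frame(
    module_id = c("mB", "mA", "mC"), N = c(4L, 5L, 4L),
    size_feature = c(0.5, 0.5, 0.9), R_KEGG = c(0.5, 0.5, 0.1),
    R_LOC = c(0.5, 0.5, 0.1), R_OMIM = c(0.5, 0.5, 0.1),
    planted = FALSE, S = NA_real_, stringsAsFactors = FALSE)
  p <- model_params(rep(0.25, 4), rep(1, 4))
  rk <- rank_modules(rec, p)
  # mB and mA tie on S = 0.5; larger N wins, then module_id
  expect_equal(rk$module_id[1:2], c("mA", "mB"))
  expect_true(all(diff(rk$S) <= 0))
  # planted records never appear in the ranking
  withp <- plant_ideal_modules(rec, n_plant = 3L)
  rk2 <- rank_modules(withp, p)
  expect_equal(nrow(rk2), 3L)
  expect_false(any(grepl("PLANTED", rk2$module_id)))
})
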