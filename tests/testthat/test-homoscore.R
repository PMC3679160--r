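scheme_from <- function(proteins, labels, n_total, id = "KEGG") {
  universe <- sprintf("CL%02d", seq_len(n_total))
  classification_scheme(
    data.frame(protein = proteins, term = labels,
               stringsAsFactors = FALSE),
    id, universe = universe)
}

test_that("redundancy is 1 for a single shared class, 0 at uniform spread", {
  sch <- scheme_from(paste0("p", 1:4), rep("CL01", 4), 10)
  expect_equal(redundancy(paste0("p", 1:4), sch), 1)
  # members uniformly spread over all n classes -> 0
  sch2 <- scheme_from(paste0("p", 1:10), sprintf("CL%02d", 1:10), 10)
  expect_equal(redundancy(paste0("p", 1:10), sch2), 0)
})

test_that("redundancy matches the entropy formula on mixed profiles", {
  # classes {A,A,A,B}, n = 10
  sch <- scheme_from(paste0("p", 1:4), c("CL01", "CL01", "CL01", "CL02"), 10)
  r <- redundancy(paste0("p", 1:4), sch)
  expect_equal(r, 1 + (0.75 * log(0.75) + 0.25 * log(0.25)) / log(10),
               tolerance = 1e-12)
  expect_equal(round(r, 4), 0.7558)
  expect_equal(r, oracle_redundancy(c("A", "A", "A", "B"), 10),
               tolerance = 1e-12)
  # randomized single-label profiles against the oracle
  set.seed(17)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    m <- sample(2:12, 1)
    labs <- sprintf("CL%02d", sample(n, m, replace = TRUE))
    sch_i <- scheme_from(paste0("q", 1:m), labs, n)
    expect_equal(redundancy(paste0("q", 1:m), sch_i),
                 oracle_redundancy(labs, n), tolerance = 1e-12)
  }
})

test_that("redundancy handles multi-label, sparse annotation and bad schemes", {
  # fractional weights: p1 has {A,B}, p2 has {A}; f = (0.75, 0.25)
  ann <- data.frame(protein = c("p1", "p1", "p2"),
                    term = c("CL01", "CL02", "CL01"))
  sch <- classification_scheme(ann, "KEGG",
                               universe = sprintf("CL%02d", 1:10))
  expect_equal(redundancy(c("p1", "p2"), sch),
               1 + (0.75 * log(0.75) + 0.25 * log(0.25)) / log(10),
               tolerance = 1e-12)
  # fewer than two annotated members -> 0, not vacuously 1
  expect_equal(redundancy(c("p1", "zzz"), sch), 0)
  expect_equal(redundancy(character(), sch), 0)
  # best-single-label mode collapses p1 onto the majority class
  expect_equal(redundancy(c("p1", "p2"), sch, multi_label = "best"), 1)
  # a scheme with a single class is rejected
  sch1 <- classification_scheme(
    data.frame(protein = c("p1", "p2"), term = "X"), "KEGG")
  expect_error(redundancy(c("p1", "p2"), sch1), "n >= 2")
})

test_that("redundancy depends only on the frequency profile", {
  set.seed(23)
  labs <- sprintf("CL%02d", sample(8, 6, replace = TRUE))
  prots <- paste0("p", 1:6)
  sch <- scheme_from(prots, labs, 20)
  r1 <- redundancy(prots, sch)
  # member order irrelevant
  expect_equal(redundancy(rev(prots), sch), r1)
  # relabeling classes leaves R unchanged
  relab <- setNames(sprintf("CL%02d", c(9:16)), sprintf("CL%02d", 1:8))
  sch2 <- scheme_from(prots, unname(relab[labs]), 20)
  expect_equal(redundancy(prots, sch2), r1)
})

test_that("uniform spread over m of n classes gives R = 1 - log(m)/log(n)", {
  for (n in c(2L, 5L, 17L, 50L)) {
    prev <- 1.000001
    for (m in 2:n) {
      prots <- paste0("p", seq_len(m))
      sch <- scheme_from(prots, sprintf("CL%02d", seq_len(m)), n)
      r <- redundancy(prots, sch)
      expect_equal(r, 1 - log(m) / log(n), tolerance = 1e-12)
      expect_lt(r, prev)  # strictly decreasing in m
      expect_gte(r, 0); expect_lte(r, 1)
      prev <- r
    }
  }
})

test_that("permutation p-values hit the add-one bounds and are reproducible", {
  # homogeneous module whose class is unique to it: observed R = 1 beats
  # essentially every shuffle
  prots <- paste0("p", 1:20)
  labs <- c(rep("CL01", 4), sprintf("CL%02d", 2:17))
  sch <- scheme_from(prots, labs, 20)
  mod <- list(paste0("p", 1:4))
  res <- scheme_permutation_pvalues(mod, sch, reps = 200, rng_seed = 1)
  expect_equal(unname(res$R), 1)
  expect_gte(unname(res$p), 1 / 201)
  expect_lt(unname(res$p), 0.05)
  res2 <- scheme_permutation_pvalues(mod, sch, reps = 200, rng_seed = 1)
  expect_identical(res, res2)

  # observed R = 0 (two classes, n = 2) -> every null is >= 0 -> p = 1
  sch2 <- scheme_from(c("a", "b"), c("CL01", "CL02"), 2)
  res0 <- scheme_permutation_pvalues(list(c("a", "b")), sch2,
                                     reps = 50, rng_seed = 3)
  expect_equal(unname(res0$R), 0)
  expect_equal(unname(res0$p), 1)
})

test_that("the vectorized permutation engine agrees with redundancy()", {
  set.seed(41)
  prots <- sprintf("p%03d", 1:60)
  ann <- data.frame(protein = prots,
                    term = sprintf("CL%02d", sample(12, 60, replace = TRUE)))
  sch <- classification_scheme(ann, "LOC",
                               universe = sprintf("CL%02d", 1:12))
  mods <- lapply(1:30, function(i) sample(prots, sample(2:8, 1)))
  res <- scheme_permutation_pvalues(mods, sch, reps = 1, rng_seed = 1)
  direct <- vapply(mods, redundancy, 0, scheme = sch)
  expect_equal(unname(res$R), direct, tolerance = 1e-12)
})

test_that("score_table assembles features, normalizes size, flags schemes", {
  prots <- paste0("p", 1:9)
  mk <- function(id) scheme_from(prots, rep("CL01", 9), 10, id = id)
  schemes <- list(mk("KEGG"), mk("LOC"), mk("OMIM"))
  mods <- list(paste0("p", 1:4), paste0("p", 1:8), paste0("p", 1:2))
  tab <- score_table(new_modules_like(mods), schemes, reps = 20,
                     rng_seed = 2)
  expect_equal(tab$R_KEGG, rep(1, 3))
  expect_equal(tab$R_LOC, rep(1, 3))
  expect_equal(tab$R_OMIM, rep(1, 3))
  expect_equal(tab$size_feature[tab$N == 8], 1)
  expect_equal(tab$size_feature[tab$N == 2], log(2) / log(8))
  expect_error(score_table(new_modules_like(mods), schemes[1:2],
                           reps = 5, rng_seed = 1),
               "OMIM")
})
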