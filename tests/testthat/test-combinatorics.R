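test_that("enumerate_subsets counts and order", {
  f33 <- sprintf("f%02d", 1:33)
  expect_equal(length(enumerate_subsets(f33, 3)), 5456L)
  expect_equal(length(enumerate_subsets(f33, 1)), 33L)

  s <- enumerate_subsets(c("D", "B", "A", "C"), 2)
  expect_equal(vapply(s, paste, "", collapse = ""),
               c("AB", "AC", "AD", "BC", "BD", "CD"))

  expect_error(enumerate_subsets(f33, 0))
  expect_error(enumerate_subsets(f33, 34))
})

test_that("subset counts match the factorial formula for all F <= 12", {
  for (f in 1:12) {
    nms <- sprintf("x%02d", 1:f)
    for (k in 1:f) {
      want <- factorial(f) / (factorial(k) * factorial(f - k))
      expect_equal(length(enumerate_subsets(nms, k)), want)
    }
  }
})

test_that("evaluate_combinations is definitionally consistent with
           kfold_cv and ranks informative features first", {
  fm <- make_latent_matrix(300, c(0.4, 0.8), seed = 21)
  ev <- evaluate_combinations(fm, 1, model_config("lm"), folds = 5,
                              seed = 3)
  folds <- make_folds(300, 5, seed = 3)
  for (i in seq_along(ev$subsets)) {
    expect_equal(ev$results$R[i],
                 kfold_cv(fm, ev$subsets[[i]], model_config("lm"),
                          folds = folds)$R)
  }
  expect_equal(ev$R_full,
               kfold_cv(fm, config = model_config("lm"), folds = folds)$R)
  # sorted by decreasing R
  expect_true(!is.unsorted(rev(ev$results$R)))

  # one informative feature among noise: subsets containing it win
  fm2 <- make_latent_matrix(2000, c(0.2, 1, 1, 1), seed = 31,
                            informative = c(TRUE, FALSE, FALSE, FALSE))
  ev2 <- evaluate_combinations(fm2, 2, model_config("lm"), folds = 5,
                               seed = 3)
  has_a <- grepl("f01", ev2$results$features)
  expect_true(min(ev2$results$R[has_a]) > max(ev2$results$R[!has_a]))
})

test_that("top_combinations applies a strict threshold on R", {
  combos <- list(results = data.frame(features = c("a", "b", "c"),
                                      R = c(0.80, 0.73, 0.71),
                                      relative_power = c(1, 0.9125, 0.8875)),
                 subsets = list("a", "b", "c"), R_full = 0.80)
  top <- top_combinations(combos, 0.90)
  expect_equal(top$results$features, c("a", "b"))

  # boundary: R exactly at threshold*R_full is excluded
  combos$results$R[2] <- 0.72
  expect_equal(top_combinations(combos, 0.90)$results$features, "a")

  expect_equal(nrow(top_combinations(
    list(results = data.frame(features = "a", R = 0.7,
                              relative_power = 0.875),
         subsets = list("a"), R_full = 0.8), 1.0)$results), 0L)
})

test_that("feature_enrichment matches the worked F=4/k=2 example", {
  feats <- c("A", "B", "C", "D")
  top <- list(subsets = list(c("A", "B"), c("A", "C")))
  enr <- feature_enrichment(top, feats, 2)
  a <- enr[enr$feature == "A", ]
  expect_equal(a$x, 2L)
  expect_equal(a$K, 3)
  expect_equal(a$M, 6)
  expect_equal(a$p_value, 0.2, tolerance = 1e-12) # C(3,2)C(3,0)/C(6,2)*...
  expect_equal(enr[enr$feature == "D", ]$p_value, 1)

  # saturated draw: every feature has x = K, p = 1
  all_top <- list(subsets = enumerate_subsets(feats, 2))
  enr2 <- feature_enrichment(all_top, feats, 2)
  expect_true(all(enr2$x == 3))
  expect_true(all(enr2$p_value == 1))

  # each model contributes k memberships
  expect_equal(sum(enr$x), 2 * length(top$subsets))

  expect_error(feature_enrichment(list(subsets = list("A", c("A", "B"))),
                                  feats, 2), "mixed size")
  expect_error(feature_enrichment(list(subsets = list()), feats, 2),
               "empty")
})

test_that("enrichment p-values agree with exhaustive enumeration
           (M <= 20)", {
  set.seed(17)
  cases <- list(list(f = 5, k = 2, N = 3),   # M = 10
                list(f = 6, k = 1, N = 2),   # M = 6
                list(f = 6, k = 5, N = 4),   # M = 6
                list(f = 4, k = 2, N = 2))   # M = 6
  for (cs in cases) {
    feats <- LETTERS[seq_len(cs$f)]
    models <- enumerate_subsets(feats, cs$k)
    top <- list(subsets = sample(models, cs$N))
    enr <- feature_enrichment(top, feats, cs$k)
    for (i in seq_len(nrow(enr))) {
      want <- brute_enrichment_p(feats, cs$k, cs$N, enr$feature[i],
                                 enr$x[i])
      expect_equal(enr$p_value[i], want, tolerance = 1e-12)
    }
  }
})

test_that("sample_size_curve: determinism, degenerate reps, monotone mean", {
  fm <- make_latent_matrix(2000, c(0.8, 1.0, 1.2, 1.2, 1.5), seed = 9,
                           y_noise = 0.5)
  one <- sample_size_curve(fm, 200, reps = 1, config = model_config("lm"),
                           folds = 5, seed = 4)
  expect_equal(one$sd_R, 0)

  c1 <- sample_size_curve(fm, c(200, 2000), reps = 5,
                          config = model_config("lm"), folds = 5, seed = 4)
  c2 <- sample_size_curve(fm, c(200, 2000), reps = 5,
                          config = model_config("lm"), folds = 5, seed = 4)
  expect_equal(c1, c2)
  expect_gte(c1$mean_R[c1$size == 2000], c1$mean_R[c1$size == 200])

  expect_error(sample_size_curve(fm, 3000, reps = 1), "exceeds")
  expect_error(sample_size_curve(fm, 3, reps = 1), "smaller than fold")
})
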