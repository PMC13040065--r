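toy_meta <- function(n = 40, seed = 1L) {
  set.seed(seed)
  data.frame(sex = sample(c("female", "male"), n, replace = TRUE),
             site = sample(c("Oxford", "Turin", "Nagpur"), n, replace = TRUE),
             hemisphere = sample(c("left", "right"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("confound encoding produces demeaned indicator columns", {
  meta <- toy_meta()
  enc <- encode_confounds(meta)
  expect_equal(unname(colSums(enc$V)), rep(0, ncol(enc$V)), tolerance = 1e-12)
  # two-level confounds give one column, the 3-level site gives three
  expect_equal(sum(enc$groups == "sex"), 1)
  expect_equal(sum(enc$groups == "hemisphere"), 1)
  expect_equal(sum(enc$groups == "site"), 3)
  expect_error(encode_confounds(meta, "nope"), "missing confound")
  flat <- meta; flat$sex <- "female"
  expect_warning(enc2 <- encode_confounds(flat, c("sex", "site")),
                 "single level")
  expect_true(all(enc2$groups == "site"))
  # every requested confound degenerate: nothing left to project on
  expect_error(suppressWarnings(encode_confounds(flat, "sex")),
               "no usable confound")
})

test_that("training centers reapply to new data without re-estimation", {
  meta <- toy_meta(60)
  tr <- meta[1:40, ]; te <- meta[41:60, ]
  enc_tr <- encode_confounds(tr)
  enc_te <- encode_confounds(te, centers = enc_tr$centers)
  expect_equal(colnames(enc_te$V), colnames(enc_tr$V))
  # test-split columns are demeaned with *training* means: test indicator
  # minus the training proportion
  expect_equal(unname(enc_te$V[1, "sex_male"]),
               as.numeric(te$sex[1] == "male") - mean(tr$sex == "male"),
               tolerance = 1e-12)
})

test_that("projection deconfounding equals per-column residualisation", {
  set.seed(11)
  meta <- toy_meta(80, seed = 2L)
  # demeaned features, as produced by the pipeline's standardisation step
  X <- scale(matrix(rnorm(80 * 6), 80, 6), center = TRUE, scale = FALSE)
  enc <- encode_confounds(meta)
  dc <- deconfound(X, enc$V)
  # brute force: residuals of lm of each feature on the confound columns
  for (j in 1:6) {
    r <- residuals(lm(X[, j] ~ enc$V))
    expect_lt(max(abs(dc$X_hat[, j] - r)), 1e-8)
  }
  # residuals orthogonal to every confound column, and idempotent
  expect_lt(max(abs(crossprod(enc$V, dc$X_hat))), 1e-8)
  dc2 <- deconfound(dc$X_hat, enc$V)
  expect_lt(max(abs(dc2$X_hat - dc$X_hat)), 1e-10)
  expect_error(deconfound(X[1:10, ], enc$V), "row counts differ")
})

test_that("variance explained obeys the 100/0 and orthogonality identities", {
  set.seed(12)
  n <- 200
  v1 <- rnorm(n); v2 <- rnorm(n)
  v2 <- residuals(lm(v2 ~ v1))           # make the confounds orthogonal
  V <- cbind(a = v1 - mean(v1), b = v2 - mean(v2))
  X <- cbind(pure = V[, 1],              # exactly the first confound
             orth = residuals(lm(rnorm(n) ~ V)),  # orthogonal to both
             mixed = V[, 1] + 0.5 * V[, 2] + rnorm(n))
  ve <- variance_explained(X, V, which_cols = 1)
  expect_equal(ve$pct_ve[1], 100, tolerance = 1e-8)
  expect_equal(ve$pct_ve[2], 0, tolerance = 1e-8)
  expect_equal(ve$pct_uve[2], 0, tolerance = 1e-8)
  # orthogonal confounds: unique VE equals marginal VE for every feature
  expect_equal(ve$pct_uve, ve$pct_ve, tolerance = 1e-8)
  # selecting by group name matches selecting by index
  ve2 <- variance_explained(X, V, "a", groups = c("a", "b"))
  expect_equal(ve2$pct_ve, ve$pct_ve)
})

test_that("grouped cross-validation never splits a fetus across folds", {
  tab <- simulate_idp_table(sim_table_config(400, seed = 5L))
  mm <- fit_maturation_model(tab, seed = 13L)
  folds_per_fetus <- tapply(mm$fold, mm$fetus_id,
                            function(f) length(unique(f)))
  expect_equal(max(folds_per_fetus), 1)
  expect_setequal(unique(mm$fold), 1:3)
  expect_false(any(is.na(mm$predictions)))
  expect_equal(mm$mtry, ceiling(0.15 * 28))
})

test_that("the maturation model predicts age accurately on synthetic IDPs", {
  tab <- simulate_idp_table(sim_table_config(1500, seed = 4L))
  mm <- fit_maturation_model(tab, seed = 13L)
  rep <- evaluate_maturation(mm)
  expect_gt(rep$pearson_r, 0.95)
  expect_gt(rep$icc, 0.95)
  expect_lt(rep$mae_days, 7)
  # brain-age deltas are centred and reproduce predicted - chronological
  expect_lt(abs(mean(rep$deltas$brain_age_delta_days)), 1)
  expect_equal(rep$deltas$brain_age_delta_days,
               (rep$deltas$predicted_ga - rep$deltas$ga_weeks) * 7)
  expect_output(print(rep), "Maturation index")
})

test_that("model fitting is deterministic in the seed", {
  tab <- simulate_idp_table(sim_table_config(300, seed = 6L))
  m1 <- fit_maturation_model(tab, seed = 13L)
  m2 <- fit_maturation_model(tab, seed = 13L)
  expect_identical(m1$predictions, m2$predictions)
  m3 <- fit_maturation_model(tab, seed = 14L)
  expect_false(identical(m1$predictions, m3$predictions))
})

test_that("feature importance covers all features and ranks by impurity", {
  tab <- simulate_idp_table(sim_table_config(300, seed = 7L))
  mm <- fit_maturation_model(tab, seed = 13L)
  fi <- feature_importance(mm, n_perm = 1L)
  expect_setequal(fi$feature, idp_names())
  expect_equal(sum(fi$importance_impurity), 1, tolerance = 1e-9)
  expect_false(is.unsorted(rev(fi$importance_impurity)))
})

test_that("intraclass correlation matches its ANOVA definition", {
  expect_equal(icc_agreement(cbind(1:10, 1:10)), 1)
  set.seed(8)
  a <- rnorm(50)
  r <- cbind(a, a + rnorm(50, 0, 2))
  icc <- icc_agreement(r)
  expect_true(icc > -1 && icc < 0.7)
  # invariant to exchanging the raters
  expect_equal(icc_agreement(r[, 2:1]), icc)
})

test_that("fitting guards against degenerate inputs", {
  tab <- simulate_idp_table(sim_table_config(300, seed = 9L))
  expect_error(fit_maturation_model(tab[1:20, ]), "at least 50")
  few <- tab[tab$fetus_id %in% unique(tab$fetus_id)[1:2], ]
  few <- few[rep(seq_len(nrow(few)), length.out = 60), ]
  expect_error(fit_maturation_model(few, n_folds = 3L), "subject-level folds")
})
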