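test_that("standardization implements z = (x - mu)/sigma with training moments only", {
  x <- cbind(a = c(1, 2, 3))
  sp <- standardize_fit(x)
  expect_equal(unname(sp$mean), 2)
  expect_equal(unname(sp$sd), 1)   # sample SD, n-1 denominator

  # fit-then-apply standardizes its own input exactly
  set.seed(5)
  X <- matrix(rnorm(60, 10, 3), 20, 3)
  colnames(X) <- c("f1", "f2", "f3")
  sp <- standardize_fit(X)
  Z <- standardize_apply(sp, X)
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-10)

  # closed-form points on the calibrated ADC scale
  sp <- list(mean = c(adc = 0.970), sd = c(adc = 0.251))
  class(sp) <- "standardization_params"
  expect_equal(unname(drop(standardize_apply(sp, matrix(1.221, 1, 1,
               dimnames = list(NULL, "adc"))))), 1.0)
  expect_equal(unname(drop(standardize_apply(sp, matrix(0.970, 1, 1,
               dimnames = list(NULL, "adc"))))), 0)
  expect_equal(unname(drop(standardize_apply(sp, matrix(0.970 + 2 * 0.251, 1, 1,
               dimnames = list(NULL, "adc"))))), 2)
})

test_that("standardization rejects zero-variance features and mismatched sets", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(standardize_fit(X), "b")
  sp <- standardize_fit(cbind(a = c(1, 2, 3)))
  expect_error(standardize_apply(sp, cbind(a = 1, b = 2)), "mismatch")
})

test_that("a test-fold outlier cannot leak into training standardization", {
  set.seed(8)
  Xtr <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  sp <- standardize_fit(Xtr)
  before <- sp
  Xte <- matrix(c(1e6, -1e6), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  z <- standardize_apply(sp, Xte)
  expect_identical(sp, before)
  # held-out row standardized with training moments, not refit
  expect_equal(drop(z), drop((Xte - sp$mean) / sp$sd))
})

test_that("attention weights are a softmax over scaled query-key scores", {
  cfg <- model_config(d_k = 1)
  p <- init_fusion_params(2, cfg, seed = 1)
  # engineered scores: q.k = (ln 2, 0) with d_k = 1 gives weights (2/3, 1/3)
  p$q <- 1
  p$K <- matrix(c(log(2), 0), 2, 1)
  expect_equal(attention_weights(p), c(2/3, 1/3), tolerance = 1e-12)

  # equal keys give uniform weights; singleton subsets are degenerate
  p$K <- matrix(c(0.4, 0.4), 2, 1)
  expect_equal(attention_weights(p), c(0.5, 0.5))
  expect_equal(attention_weights(p, active = 2), 1.0)
  expect_error(attention_weights(p, active = integer(0)), "empty")
})

test_that("attention weights are normalized and shift-invariant on random draws", {
  set.seed(33)
  for (i in 1:25) {
    m <- sample(2:7, 1)
    p <- init_fusion_params(m, model_config(d_k = sample(1:8, 1)), seed = i)
    w <- attention_weights(p)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # adding a constant to every score leaves the softmax unchanged
    shift <- rnorm(1, 0, 5)
    p2 <- p
    # scores s_i = K q / sqrt(d_k); append a column contributing the shift
    p2$K <- cbind(p$K, rep(shift, m))
    p2$q <- c(p$q, sqrt(p$d_k) / 1)
    expect_equal(attention_weights(p2), w, tolerance = 1e-9)
  }
})

test_that("fusion matches hand computation and a naive summation oracle", {
  # weighted-scalar mode with uniform weights halves a two-feature row
  cfg <- model_config(mode = "weighted-scalar", d_k = 2)
  p <- init_fusion_params(2, cfg, seed = 1)
  p$K <- matrix(0, 2, 2)   # equal scores -> uniform weights
  expect_equal(fuse(p, c(2, -2)), c(1, -1))

  # embed-sum with a single active feature and zero offset is z * e
  cfg <- model_config(d_k = 4)
  p <- init_fusion_params(3, cfg, seed = 2)
  p$B[] <- 0
  expect_equal(fuse(p, 1.7, active = 1), 1.7 * p$E[1, ])

  # naive per-feature loop oracle on random parameters
  set.seed(21)
  for (i in 1:20) {
    m <- sample(2:7, 1)
    p <- init_fusion_params(m, model_config(d_k = 8), seed = i)
    z <- rnorm(m)
    w <- attention_weights(p)
    oracle <- rep(0, p$d_v)
    for (j in seq_len(m)) oracle <- oracle + w[j] * (z[j] * p$E[j, ] + p$B[j, ])
    expect_equal(fuse(p, z), oracle, tolerance = 1e-12)
  }
})

test_that("fusion training is seed-deterministic with a non-increasing loss trace", {
  cohort <- small_cohort(n = 40, seed = 2)
  X <- cbind(cohort$pre_adc_value, cohort$pre_sagittal_longest_diameter,
             cohort$pre_n_stage)
  colnames(X) <- c("adc", "diam", "n")
  Z <- standardize_apply(standardize_fit(X), X)
  y <- binarize_trg(cohort$trg)
  f1 <- train_fusion(Z, y, seed = 11)
  f2 <- train_fusion(Z, y, seed = 11)
  expect_identical(f1, f2)
  f3 <- train_fusion(Z, y, seed = 12)
  expect_false(identical(f1$q, f3$q))
  # monotone descent of the recorded trace
  expect_true(all(diff(f1$loss) <= 1e-8))
  expect_lt(f1$loss[length(f1$loss)], f1$loss[1])
  expect_error(train_fusion(Z, factor(rep("pos", 40), c("pos", "neg"))),
               "single-class")
})

test_that("trained fusion plus SVM separates a linearly separable toy cohort", {
  cohort <- separable_cohort(n = 20, gap = 8, seed = 3)
  res <- loocv_evaluate(cohort, subset = c(1, 2), seed = 1)
  expect_equal(res$metrics[["ACC"]], 100)
  expect_equal(res$auc, 1.0)
})

test_that("on signal-free cohorts training cannot beat the best constant predictor", {
  # surrogate loss after training >= entropy of the label marginal - tol,
  # Monte-Carlo over seeds
  losses <- vapply(1:8, function(s) {
    cohort <- generate_cohort(default_config(n_patients = 60,
                                             signal_strength = 0), seed = s)
    X <- ncrtfusion:::.feature_matrix(cohort, 1:7)
    Z <- standardize_apply(standardize_fit(X), X)
    y <- binarize_trg(cohort$trg)
    f <- train_fusion(Z, y, seed = s)
    f$loss[length(f$loss)]
  }, numeric(1))
  # best constant predictor's logistic loss at the marginal responder rate
  const_loss <- vapply(1:8, function(s) {
    cohort <- generate_cohort(default_config(n_patients = 60,
                                             signal_strength = 0), seed = s)
    p <- mean(binarize_trg(cohort$trg) == "pos")
    -(p * log(p) + (1 - p) * log(1 - p))
  }, numeric(1))
  expect_gt(mean(losses), mean(const_loss) - 0.05)
})

test_that("the batched LOOCV fusion path equals composing the single-stage operations", {
  cohort <- small_cohort(n = 16, seed = 6)
  subset <- c(1, 2, 5)
  cfg <- model_config()
  res <- loocv_evaluate(cohort, subset, cfg, seed = 3)
  # recompute fold 1 by hand through the exported operations
  cohort <- cohort[order(cohort$patient_id), ]
  X <- ncrtfusion:::.feature_matrix(cohort, subset)
  y <- binarize_trg(cohort$trg)
  sp <- standardize_fit(X[-1, , drop = FALSE])
  Ztr <- standardize_apply(sp, X[-1, , drop = FALSE])
  zte <- standardize_apply(sp, X[1, , drop = FALSE])
  full <- init_fusion_params(7, cfg, seed = 3, features = feature_specs()$name)
  init <- ncrtfusion:::.subset_fusion_params(full, subset)
  fit <- ncrtfusion:::.fusion_gd_cpp(Ztr, ifelse(y[-1] == "pos", 1, -1),
                                     init$q, init$K, init$E, init$B,
                                     init$u, init$u0, cfg$epochs, cfg$step,
                                     cfg$lambda, init$mode == "embed-sum")
  p <- init
  p$q <- drop(fit$q); p$K <- fit$K; p$E <- fit$E; p$B <- fit$B
  Ftr <- fuse_matrix(p, Ztr)
  fte <- fuse(p, drop(zte))
  m <- fit_svm(Ftr, y[-1], C = cfg$C, gamma = cfg$gamma)
  expect_equal(unname(res$scores[1]), decision_score(m, fte), tolerance = 1e-10)
})
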