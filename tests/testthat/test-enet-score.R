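test_that("encode_labels follows the ordinal mapping", {
  expect_equal(unname(encode_labels(c(120, 144, 108))), c(0, 1, -1))
  expect_equal(unname(encode_labels(c(120, 120))), c(0, 0))
  expect_equal(encode_labels(integer(0)), numeric(0))
  expect_error(encode_labels(c(120, NA)), "known")
  expect_error(encode_labels(119), "108, 120, 144")
  expect_equal(decode_labels(encode_labels(c(108, 144, 120))),
               c(108L, 144L, 120L))
})

test_that("enet_objective matches its closed forms", {
  set.seed(4)
  X <- matrix(rnorm(30), 10); y <- rnorm(10)
  # beta = 0, intercept = mean(y) -> total sum of squares
  expect_equal(enet_objective(X, y, rep(0, 3), mean(y), 0.5, 2),
               sum((y - mean(y))^2))
  # lam = 0 -> plain RSS
  b <- rnorm(3)
  expect_equal(enet_objective(X, y, b, 0.2, 0.7, 0),
               sum((y - 0.2 - X %*% b)^2))
  # 1-feature toy: X = (1, -1), y = (1, -1), beta = 1, lam = 1, alpha = 1
  expect_equal(enet_objective(matrix(c(1, -1)), c(1, -1), 1, 0, 1, 1), 1)
})

test_that("fit_enet matches OLS, ridge, and soft-threshold oracles", {
  set.seed(5)
  X <- matrix(rnorm(25 * 6), 25); y <- rnorm(25)

  # lam = 0 -> ordinary least squares (normal-equations oracle)
  f0 <- fit_enet(X, y, alpha = 0.3, lam = 0, tol = 1e-12)
  ols <- qr.solve(cbind(1, X), y)
  expect_equal(unname(f0$beta), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(f0$intercept, unname(ols[1]), tolerance = 1e-6)

  # alpha = 1 (pure squared penalty) -> ridge closed form on centered data
  lam <- 2.5
  fr <- fit_enet(X, y, alpha = 1, lam = lam, tol = 1e-12)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  ridge <- solve(crossprod(Xc) + lam * diag(6), crossprod(Xc, yc))[, 1]
  expect_equal(unname(fr$beta), unname(ridge), tolerance = 1e-6)

  # alpha = 0 on an orthonormal design -> soft-threshold closed form
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30)))
  yq <- rnorm(30)
  lam <- 0.8
  fl <- fit_enet(Q, yq, alpha = 0, lam = lam, tol = 1e-12)
  Qty <- crossprod(Q, yq - mean(yq))[, 1]
  # columns are orthonormal but not centered; oracle uses the solver's own
  # fixed point: beta_j = S(q_j'(y - b0), lam/2) with q_j'q_j = 1
  Qtyb <- crossprod(Q, yq - fl$intercept)[, 1]
  expect_equal(unname(fl$beta),
               unname(sign(Qtyb) * pmax(abs(Qtyb) - lam / 2, 0)),
               tolerance = 1e-6)

  # residuals stored
  expect_equal(f0$residuals, y - f0$intercept - as.vector(X %*% f0$beta))
})

test_that("soft-threshold sparsity: beta = 0 exactly at lam >= lam_max", {
  set.seed(6)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 4), 20); y <- rnorm(20)
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    lam_max <- 2 * max(abs(crossprod(Xc, yc)))
    f <- fit_enet(X, y, alpha = 0, lam = lam_max * (1 + 1e-10))
    expect_identical(unname(f$beta), rep(0, 4))
    expect_equal(f$intercept, mean(y))
  }
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30); y <- rnorm(30)
  for (params in list(c(0, 1.5), c(0.5, 3), c(1, 10))) {
    a <- params[1]; l <- params[2]
    objs <- vapply(1:12, function(it) {
      f <- suppressWarnings(fit_enet(X, y, a, l, tol = 0, max_iter = it))
      enet_objective(X, y, f$beta, f$intercept, a, l)
    }, numeric(1))
    expect_true(all(diff(objs) <= 1e-10))
  }
})

test_that("coordinate descent matches a numerical optimizer on random problems", {
  # subset of the oracle-equivalence sweep (the full 50-problem run lives in
  # the acceptance suite)
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:30, 1); p <- sample(2:10, 1)
    X <- matrix(rnorm(n * p), n); y <- rnorm(n)
    a <- runif(1); l <- runif(1, 0, 5)
    fit <- fit_enet(X, y, a, l)
    obj_cd <- enet_objective(X, y, fit$beta, fit$intercept, a, l)
    nm <- stats::optim(rep(0, p + 1), function(th)
      enet_objective(X, y, th[-1], th[1], a, l),
      method = "Nelder-Mead", control = list(maxit = 20000, reltol = 1e-12))
    expect_lte(obj_cd, nm$value + 1e-4)
  }
})

test_that("fit_enet agrees with glmnet under the reparameterised penalty", {
  skip_if_not_installed("glmnet")
  # ours: RSS + lam * (alpha ||b||^2 + (1-alpha) ||b||_1)   (alpha=1 ridge)
  # glmnet: RSS/(2n) + lg * ((1-ag)/2 ||b||^2 + ag ||b||_1) (ag=1 lasso)
  set.seed(10)
  n <- 40; p <- 6
  X <- matrix(rnorm(n * p), n); y <- rnorm(n)
  for (alpha in c(0.25, 0.5, 0.75)) {
    lam <- 1.2
    ag <- (1 - alpha) / (1 + alpha)
    lg <- lam * (1 + alpha) / (2 * n)
    g <- glmnet::glmnet(X, y, alpha = ag, lambda = lg, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-14)
    ours <- fit_enet(X, y, alpha, lam)
    obj <- function(b, b0) enet_objective(X, y, b, b0, alpha, lam)
    expect_equal(obj(ours$beta, ours$intercept),
                 obj(as.numeric(g$beta), as.numeric(g$a0)),
                 tolerance = 1e-4)
  }
})

test_that("predict_score is affine and dimension-checked", {
  set.seed(11)
  f <- fit_enet(matrix(rnorm(20), 10, 2), rnorm(10), 0.5, 0.1)
  expect_equal(unname(predict_score(f, matrix(0, 2, 2))),
               rep(f$intercept, 2))
  X1 <- matrix(rnorm(10), 5, 2); X2 <- matrix(rnorm(10), 5, 2)
  a <- 0.3
  expect_equal(predict_score(f, a * X1 + (1 - a) * X2),
               a * predict_score(f, X1) + (1 - a) * predict_score(f, X2))
  expect_error(predict_score(f, matrix(0, 2, 3)), "coefficients")

  toy <- structure(list(beta = 2, intercept = 0), class = "enet_fit")
  expect_equal(unname(predict_score(toy, matrix(0.75))), 1.5)
})

test_that("score_to_es uses strict inequalities and partitions the line", {
  expect_equal(unname(score_to_es(c(1.2, -1.2, 0))), c(144L, 108L, 120L))
  expect_equal(unname(score_to_es(1.0)), 120L)    # strict score > 1
  expect_equal(unname(score_to_es(-1.0)), 120L)   # strict score < -1
  expect_error(score_to_es(NaN), "finite")
  expect_error(score_to_es(0.5, thresholds = c(1, -1)), "lower < upper")
  # total and piecewise constant: every real maps to exactly one class
  grid <- seq(-3, 3, by = 0.01)
  cls <- score_to_es(grid)
  expect_true(all(cls %in% c(108L, 120L, 144L)))
  expect_equal(sum(rle(as.integer(cls))$lengths > 0), 3)   # two breakpoints
})

test_that("cross_validate is deterministic and honors tie-breaking", {
  set.seed(12)
  vals <- matrix(rnorm(40 * 6), 40,
                 dimnames = list(paste0("P", 1:40), paste0("f", 1:6)))
  y <- encode_labels(sample(c(108, 120, 144), 40, replace = TRUE))
  sm <- feature_matrix(scale(vals), "scaled")
  cv1 <- cross_validate(sm, y, alphas = 0.5, lams = c(0.5, 1), k = 5,
                        variance_targets = 0.9, seed = 3)
  cv2 <- cross_validate(sm, y, alphas = 0.5, lams = c(0.5, 1), k = 5,
                        variance_targets = 0.9, seed = 3)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  expect_identical(cv1$grid, cv2$grid)

  # single-cell grid: best is that cell
  cv3 <- cross_validate(sm, y, alphas = 1, lams = 2, variance_targets = 0.8,
                        k = 4, seed = 1)
  expect_equal(nrow(cv3$grid), 1)
  expect_equal(cv3$best$alpha, 1)

  # every cell has k fold entries
  expect_equal(ncol(cv1$fold_metrics), 5)
  expect_false(anyNA(cv1$fold_metrics))
})

test_that("trained model separates classes and round-trips serialization", {
  co <- generate_cohort(synthetic_config(
    seed = 13, effect_size_cycles = 3, n_mirnas = 60,
    group_sizes = c(`108` = 20, `120` = 40, `144` = 20),
    n_failed = 0, n_informative = 12, n_always_low = 5))
  fm <- average_replicates(co$profiles)
  labs <- stats::setNames(co$metadata$label, co$metadata$patient_id)
  m <- train_small(fm, labs, seed = 13)

  # training-set confusion matrix is diagonal-dominated: better than the
  # majority-class call (0.5 here); the strict +/-1 cutpoints keep shrunken
  # extreme-class scores from all crossing, so near-perfect accuracy is not
  # the contract
  pred <- predict_classifier(m, fm)
  cm <- confusion_matrix(labs[pred$patient_id], pred$predicted_class)
  expect_gt(sum(diag(cm)) / sum(cm), max(table(labs)) / length(labs))
  # fold-held-out CV accuracy also beats the majority baseline
  expect_gt(m$cv$best$mean_metric, max(table(labs)) / length(labs))

  # serialization round trip -> identical predictions
  f <- withr::local_tempfile(fileext = ".json")
  write_score_model(m, f)
  back <- read_score_model(f)
  pred2 <- predict_classifier(back, fm)
  expect_equal(pred2$score, pred$score)
  expect_identical(pred2$predicted_class, pred$predicted_class)

  # end-to-end determinism
  m2 <- train_small(fm, labs, seed = 13)
  expect_identical(m2$beta, m$beta)
  expect_identical(predict_classifier(m2, fm)$score, pred$score)
})

test_that("null training data yields majority-class behaviour held out", {
  co <- generate_cohort(synthetic_config(
    seed = 14, effect_size_cycles = 0, n_mirnas = 50,
    group_sizes = c(`108` = 8, `120` = 44, `144` = 8),
    n_failed = 0, n_informative = 10, n_always_low = 4))
  fm <- average_replicates(co$profiles)
  labs <- stats::setNames(co$metadata$label, co$metadata$patient_id)
  m <- train_small(fm, labs, seed = 14)
  maj <- max(table(labs)) / length(labs)
  # fold-held-out CV accuracy within ~3 binomial sd of the majority fraction
  tol <- 3 * sqrt(maj * (1 - maj) / length(labs))
  expect_lt(abs(m$cv$best$mean_metric - maj), tol + 0.05)
})
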