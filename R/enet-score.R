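#' Encode embryo-transfer-time labels as the ordinal response
#'
#' The three transfer-time classes are mapped onto a single ordinal axis:
#' 108 h -> -1, 120 h -> 0, 144 h -> +1. The classifier is a penalized
#' regression on this axis, not a multinomial model; classes reappear only
#' through the score thresholds in [score_to_es()].
#'
#' @param labels integer vector with values in {108, 120, 144}.
#' @return numeric vector in {-1, 0, 1}.
#' @export
encode_labels <- function(labels) {
  if (!length(labels)) return(numeric(0))
  if (anyNA(labels) || !all(labels %in% CLASS_HOURS))
    stop("labels must all be known and in {108, 120, 144}")
  c(`108` = -1, `120` = 0, `144` = 1)[as.character(labels)]
}

#' Inverse of [encode_labels()]
#' @param y numeric vector in {-1, 0, 1}.
#' @return integer hours vector.
#' @export
decode_labels <- function(y) {
  if (!all(y %in% c(-1, 0, 1))) stop("encoded values must be in {-1, 0, 1}")
  CLASS_HOURS[match(y, c(-1, 0, 1))]
}

#' Elastic-net objective (reference implementation)
#'
#' Evaluates `||y - intercept - X beta||^2 +
#' lam * (alpha * ||beta||_2^2 + (1 - alpha) * ||beta||_1)`.
#'
#' NOTE the mixing convention: `alpha` weights the *squared* (ridge) penalty,
#' so `alpha = 1` is pure ridge and `alpha = 0` pure lasso — the reverse of
#' the convention used by glmnet. The residual sum of squares is not divided
#' by n.
#'
#' Kept deliberately naive: this is the testing oracle the coordinate-descent
#' solver is checked against.
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response vector.
#' @param beta coefficient vector (length p).
#' @param intercept scalar intercept.
#' @param alpha ridge-vs-lasso mix in \[0, 1\] (1 = ridge).
#' @param lam overall penalty strength >= 0.
#' @return scalar objective value.
#' @export
enet_objective <- function(X, y, beta, intercept, alpha, lam) {
  stopifnot(alpha >= 0, alpha <= 1, lam >= 0)
  r <- y - intercept - as.vector(X %*% beta)
  sum(r^2) + lam * (alpha * sum(beta^2) + (1 - alpha) * sum(abs(beta)))
}

soft_threshold <- function(z, gamma) sign(z) * pmax(abs(z) - gamma, 0)

#' Fit the elastic-net score by cyclic coordinate descent
#'
#' Minimizes [enet_objective()] with an unpenalized intercept. Each
#' coordinate has the closed-form update
#' `beta_j = S(x_j' r_j, lam * (1 - alpha) / 2) / (x_j' x_j + lam * alpha)`,
#' where `r_j` is the partial residual excluding feature j and `S` the
#' soft-threshold operator; the intercept is re-centered every sweep.
#' Covariance (Gram) updates make each sweep O(p^2). Convergence is declared
#' when the largest coefficient change in a sweep drops below `tol`.
#'
#' @param X numeric matrix (n x p), finite, n >= 2.
#' @param y numeric response.
#' @param alpha ridge-vs-lasso mix in \[0, 1\] (1 = pure ridge; see
#'   [enet_objective()] for the convention).
#' @param lam penalty strength >= 0.
#' @param tol convergence tolerance on the max coefficient change
#'   (default 1e-7).
#' @param max_iter maximum number of full sweeps (default 1e5).
#' @param beta_init optional warm-start coefficients.
#' @return list of class `enet_fit`: `beta` (named), `intercept`,
#'   `residuals`, `alpha`, `lam`, `n_iter`, `converged`.
#' @export
fit_enet <- function(X, y, alpha, lam, tol = 1e-7, max_iter = 1e5,
                     beta_init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, length(y) == n, all(is.finite(X)), all(is.finite(y)),
            alpha >= 0, alpha <= 1, lam >= 0)
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  stopifnot(length(beta) == p)

  XtX <- crossprod(X)              # p x p Gram matrix
  colsum <- colSums(X)
  xt_y <- crossprod(X, y)[, 1]
  xjj <- diag(XtX)
  ybar <- mean(y)
  b0 <- ybar - sum(colsum * beta) / n
  thr <- lam * (1 - alpha) / 2
  denom <- xjj + lam * alpha

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    XtXb <- XtX %*% beta
    for (j in seq_len(p)) {
      if (denom[j] <= 0) next      # constant zero column with no ridge term
      # x_j' (y - b0 - X beta + x_j beta_j)
      zj <- xt_y[j] - b0 * colsum[j] - XtXb[j] + xjj[j] * beta[j]
      bj_new <- soft_threshold(zj, thr) / denom[j]
      d <- bj_new - beta[j]
      if (d != 0) {
        XtXb <- XtXb + XtX[, j] * d
        beta[j] <- bj_new
        delta <- max(delta, abs(d))
      }
    }
    b0_new <- ybar - sum(colsum * beta) / n
    delta <- max(delta, abs(b0_new - b0))
    b0 <- b0_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "coordinate descent did not converge in %d sweeps (last max change %.3g)",
      it, delta))
  names(beta) <- colnames(X)
  structure(list(beta = beta, intercept = b0,
                 residuals = y - b0 - as.vector(X %*% beta),
                 alpha = alpha, lam = lam, n_iter = it,
                 converged = converged),
            class = "enet_fit")
}

# smallest lam at which all coefficients are exactly zero (lasso side of the
# penalty): lam_max = 2 * max |Xc' yc| / (1 - alpha), on centered data
enet_lambda_max <- function(X, y, alpha = 0) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  yc <- y - mean(y)
  2 * max(abs(crossprod(Xc, yc))) / max(1 - alpha, 1e-3)
}

#' Predict the continuous endometrial score
#'
#' `score = intercept + X beta`; around 0 for the 120 h state, pushed toward
#' +1 for 144 h and -1 for 108 h.
#'
#' @param model an `enet_fit` or `score_model`.
#' @param X matrix whose columns match the model coefficients (for a
#'   `score_model`, either PCA scores or a raw-stage [feature_matrix()],
#'   which is preprocessed first).
#' @return named numeric score vector.
#' @export
predict_score <- function(model, X) {
  if (inherits(model, "score_model")) {
    if (inherits(X, "feature_matrix") && X$stage == "raw_mean")
      X <- apply_preprocess(X, model$preprocess)
    if (inherits(X, "feature_matrix")) X <- X$values
    beta <- model$beta; b0 <- model$intercept
  } else {
    beta <- model$beta; b0 <- model$intercept
  }
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop(sprintf("X has %d columns but the model has %d coefficients",
                 ncol(X), length(beta)))
  stats::setNames(b0 + as.vector(X %*% beta), rownames(X))
}

#' Map scores to the endometrial state
#'
#' `score > upper` -> 144 h, `score < lower` -> 108 h, otherwise (boundaries
#' included) -> 120 h. The inequalities are strict, so a score of exactly
#' +1 or -1 is called 120 h.
#'
#' @param score numeric vector, no NaN/NA.
#' @param thresholds numeric `c(lower, upper)`, default `c(-1, 1)`.
#' @return integer vector of hours in {108, 120, 144}.
#' @export
score_to_es <- function(score, thresholds = c(-1, 1)) {
  if (any(!is.finite(score))) stop("scores must be finite (no NaN/NA)")
  lo <- thresholds[1]; hi <- thresholds[2]
  if (!(lo < hi)) stop("thresholds must satisfy lower < upper")
  out <- rep(120L, length(score))
  out[score > hi] <- 144L
  out[score < lo] <- 108L
  stats::setNames(out, names(score))
}

#' k-fold cross-validation over the hyperparameter grid
#'
#' Tunes the penalty mix `alpha`, strength `lam`, and PCA dimensionality on a
#' seeded random fold partition. PCA is refit inside each fold on the
#' fold-training rows only, so held-out rows never influence the transform.
#' The cell metric is mean held-out three-class accuracy after
#' [score_to_es()] (or mean squared error with `metric = "mse"`). Ties are
#' broken toward fewer components, then larger `lam`, then larger `alpha`.
#'
#' @param scaled a [feature_matrix()] at stage `"scaled"` (training data).
#' @param y encoded response from [encode_labels()].
#' @param alphas,lams,variance_targets grid axes; `lams = NULL` builds a
#'   `n_lam`-point log grid from `lam_max` down `lam_decades` decades.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold partition.
#' @param thresholds score cutpoints for the accuracy metric.
#' @param metric `"accuracy"` (default) or `"mse"`.
#' @param n_lam,lam_decades lambda-grid shape when `lams` is NULL.
#' @return object of class `cv_result`: `grid` (data.frame with per-cell mean
#'   metric), `best` (row of `grid`), `fold_assignments`, `warnings`, `seed`.
#' @export
cross_validate <- function(scaled, y,
                           alphas = c(0, 0.25, 0.5, 0.75, 1),
                           lams = NULL,
                           variance_targets = c(0.8, 0.9, 0.95),
                           k = 10, seed = 1L, thresholds = c(-1, 1),
                           metric = c("accuracy", "mse"),
                           n_lam = 30, lam_decades = 4) {
  stopifnot(inherits(scaled, "feature_matrix"), scaled$stage == "scaled")
  metric <- match.arg(metric)
  X <- scaled$values
  n <- nrow(X)
  stopifnot(k >= 2, k <= n, length(y) == n)

  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))

  if (is.null(lams)) {
    lam_max <- enet_lambda_max(X, y, alpha = 0)
    lams <- exp(seq(log(lam_max), log(lam_max) - lam_decades * log(10),
                    length.out = n_lam))
  }
  lams <- sort(lams, decreasing = TRUE)

  warns <- character(0)
  grid <- expand.grid(variance_target = variance_targets, alpha = alphas,
                      lam = lams, KEEP.OUT.ATTRS = FALSE)
  cell_metric <- matrix(NA_real_, nrow = nrow(grid), ncol = k)

  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2)
      warns <- c(warns, sprintf("fold %d training part has a single class", f))
    if (length(unique(y[!tr])) < 2)
      warns <- c(warns, sprintf("fold %d held-out part has a single class", f))
    fm_tr <- feature_matrix(X[tr, , drop = FALSE], "scaled")
    for (vt in variance_targets) {
      pca <- fit_pca(fm_tr, variance_target = vt)
      Ztr <- apply_pca(fm_tr, pca)$values
      Zte <- apply_pca(feature_matrix(X[!tr, , drop = FALSE], "scaled"),
                       pca)$values
      for (a in alphas) {
        beta_warm <- NULL
        for (l in lams) {
          fit <- fit_enet(Ztr, y[tr], alpha = a, lam = l,
                          beta_init = beta_warm)
          beta_warm <- fit$beta
          s <- predict_score(fit, Zte)
          m <- if (metric == "accuracy")
            mean(score_to_es(s, thresholds) == decode_labels(y[!tr]))
          else -mean((s - y[!tr])^2)
          row <- which(grid$variance_target == vt & grid$alpha == a &
                       grid$lam == l)
          cell_metric[row, f] <- m
        }
      }
    }
  }

  grid$mean_metric <- rowMeans(cell_metric)
  # ties: fewer components (smaller variance target), larger lam, larger alpha
  ord <- order(-grid$mean_metric, grid$variance_target, -grid$lam,
               -grid$alpha)
  best <- grid[ord[1], , drop = FALSE]
  structure(list(grid = grid, fold_metrics = cell_metric, best = best,
                 fold_assignments = fold, k = k, seed = seed,
                 metric = metric, warnings = unique(warns)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold CV over %d grid cells (metric: %s)\n",
              x$k, nrow(x$grid), x$metric))
  cat(sprintf("  best: alpha=%.2f lam=%.4g variance_target=%.2f -> %.4f\n",
              x$best$alpha, x$best$lam, x$best$variance_target,
              x$best$mean_metric))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Train the full window-of-implantation classifier
#'
#' End to end: averages replicates (if given a [cq_profile_set()]), freezes
#' the preprocessing chain on the training cohort, tunes hyperparameters by
#' k-fold cross-validation, refits PCA with the chosen dimensionality and the
#' elastic-net score on the full training set, and returns a frozen
#' `score_model`.
#'
#' @param train a [cq_profile_set()] or raw-stage [feature_matrix()].
#' @param labels named (by patient) or aligned integer vector of transfer
#'   times in {108, 120, 144}.
#' @param alphas,lams,variance_targets,k,thresholds,metric,n_lam,lam_decades
#'   see [cross_validate()].
#' @param seed RNG seed for fold assignment.
#' @param max_missing_fraction forwarded to [fit_preprocess()].
#' @return object of class `score_model`.
#' @export
train_classifier <- function(train, labels, seed = 1L,
                             alphas = c(0, 0.25, 0.5, 0.75, 1),
                             lams = NULL,
                             variance_targets = c(0.8, 0.9, 0.95),
                             k = 10, thresholds = c(-1, 1),
                             metric = "accuracy",
                             n_lam = 30, lam_decades = 4,
                             max_missing_fraction = 0.10) {
  fm <- if (inherits(train, "cq_profile_set")) average_replicates(train)
        else train
  stopifnot(inherits(fm, "feature_matrix"), fm$stage == "raw_mean")
  if (!is.null(names(labels))) labels <- labels[rownames(fm$values)]
  if (length(unique(labels)) < 2)
    stop("training data must contain at least 2 classes")
  y <- encode_labels(labels)

  # preprocessing up to the scaled stage; PCA dimensionality is tuned in CV
  pp_scaled <- fit_preprocess(fm, max_missing_fraction = max_missing_fraction,
                              variance_target = max(variance_targets))
  scaled <- apply_preprocess(fm, pp_scaled, stop_at = "scaled")

  cv <- cross_validate(scaled, y, alphas = alphas, lams = lams,
                       variance_targets = variance_targets, k = k,
                       seed = seed, thresholds = thresholds, metric = metric,
                       n_lam = n_lam, lam_decades = lam_decades)

  pca <- fit_pca(scaled, variance_target = cv$best$variance_target)
  pp <- pp_scaled
  pp$pca_means <- pca$means
  pp$pca_loadings <- pca$loadings
  pp$explained_variance_ratio <- pca$explained_variance_ratio
  pp$n_components <- pca$n_components

  Z <- apply_pca(scaled, pca)$values
  fit <- fit_enet(Z, y, alpha = cv$best$alpha, lam = cv$best$lam)

  structure(list(schema_version = 1L,
                 beta = fit$beta, intercept = fit$intercept,
                 residuals = fit$residuals,
                 alpha = cv$best$alpha, lam = cv$best$lam,
                 thresholds = thresholds,
                 preprocess = pp, cv = cv),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf(
    "score_model: %d PCs, alpha=%.2f lam=%.4g, thresholds (%g, %g), %d nonzero coefs\n",
    length(x$beta), x$alpha, x$lam, x$thresholds[1], x$thresholds[2],
    sum(x$beta != 0)))
  invisible(x)
}

#' Predict three-state calls for new profiles
#'
#' @param model a `score_model`.
#' @param newdata [cq_profile_set()] or raw-stage [feature_matrix()].
#' @return data.frame `patient_id, score, predicted_class`.
#' @export
predict_classifier <- function(model, newdata) {
  stopifnot(inherits(model, "score_model"))
  fm <- if (inherits(newdata, "cq_profile_set")) average_replicates(newdata)
        else newdata
  s <- predict_score(model, fm)
  data.frame(patient_id = names(s), score = unname(s),
             predicted_class = unname(score_to_es(s, model$thresholds)),
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize a score model as versioned JSON
#'
#' @param model a `score_model`.
#' @param path JSON file path.
#' @export
write_score_model <- function(model, path) {
  pp_tmp <- tempfile(fileext = ".json")
  on.exit(unlink(pp_tmp))
  write_preprocess_params(model$preprocess, pp_tmp)
  x <- list(schema_version = 1L,
            beta = as.list(model$beta), intercept = model$intercept,
            alpha = model$alpha, lam = model$lam,
            thresholds = model$thresholds,
            residuals = model$residuals,
            preprocess = jsonlite::read_json(pp_tmp, simplifyVector = FALSE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("unknown score_model schema_version: ",
         if (is.null(x$schema_version)) "<absent>" else x$schema_version)
  pp_tmp <- tempfile(fileext = ".json")
  on.exit(unlink(pp_tmp))
  jsonlite::write_json(x$preprocess, pp_tmp, auto_unbox = TRUE, digits = NA)
  structure(list(schema_version = 1L,
                 beta = unlist(x$beta), intercept = as.numeric(x$intercept),
                 residuals = as.numeric(x$residuals),
                 alpha = as.numeric(x$alpha), lam = as.numeric(x$lam),
                 thresholds = as.numeric(x$thresholds),
                 preprocess = read_preprocess_params(pp_tmp),
                 cv = NULL),
            class = "score_model")
}
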