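test_that("quantile normalization matches the hand-executed rank-mean rule", {
  m <- fm_raw(matrix(c(2, 4, 6, 3, 5, 7), nrow = 2, byrow = TRUE,
                     dimnames = list(c("P1", "P2"), paste0("f", 1:3))))
  qn <- quantile_normalize(m)
  # reference = mean of sorted rows = (2.5, 4.5, 6.5); both rows complete
  expect_equal(unname(qn$quantile_reference), c(2.5, 4.5, 6.5))
  expect_equal(unname(qn$matrix$values),
               rbind(c(2.5, 4.5, 6.5), c(2.5, 4.5, 6.5)))
  expect_equal(qn$matrix$stage, "quantile_normalized")
})

test_that("quantile normalization identities and invariants", {
  # identical rows are unchanged
  v <- c(1.5, 3.25, 8, 12)
  m <- fm_raw(matrix(rep(v, 3), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("P", 1:3), paste0("f", 1:4))))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$matrix$values), unname(m$values))

  # complete rows share a sorted multiset; within-row order is preserved
  set.seed(8)
  m2 <- fm_raw(matrix(runif(60, 20, 30), nrow = 5,
                      dimnames = list(paste0("P", 1:5), paste0("f", 1:12))))
  qn2 <- quantile_normalize(m2)
  sorted <- apply(qn2$matrix$values, 1, sort)
  expect_equal(max(apply(sorted, 1, function(r) diff(range(r)))), 0)
  for (i in 1:5)
    expect_equal(order(qn2$matrix$values[i, ]), order(m2$values[i, ]))

  # missing entries stay missing; ties get the mean of tied positions
  m3 <- fm_raw(matrix(c(5, 5, 9, NA,
                        1, 2, 3, 4), nrow = 2, byrow = TRUE,
                      dimnames = list(c("P1", "P2"), paste0("f", 1:4))))
  qn3 <- quantile_normalize(m3)
  expect_true(is.na(qn3$matrix$values["P1", "f4"]))
  expect_equal(qn3$matrix$values["P1", "f1"], qn3$matrix$values["P1", "f2"])

  expect_error(quantile_normalize(fm_raw(matrix(
    c(1, NA, NA, 2, 3, 4), 2, byrow = TRUE,
    dimnames = list(c("P1", "P2"), paste0("f", 1:3))))), "P1")
})

test_that("apply_quantile_reference maps by rank with interpolation", {
  ref <- c(10, 20, 30, 40, 50)
  m <- fm_raw(matrix(c(7, 1, 3), 1, dimnames = list("P1", paste0("f", 1:3))))
  out <- apply_quantile_reference(m, ref)
  # row of length 3 vs reference length 5 -> quantiles 0, 0.5, 1
  expect_equal(unname(out$values["P1", ]), c(50, 10, 30))

  # a row already equal to the reference is unchanged
  m2 <- fm_raw(matrix(ref, 1, dimnames = list("P1", paste0("f", 1:5))))
  expect_equal(unname(apply_quantile_reference(m2, ref)$values["P1", ]), ref)

  # monotone in, monotone out
  set.seed(1)
  r <- sort(runif(9))
  m3 <- fm_raw(matrix(r, 1, dimnames = list("P1", paste0("f", 1:9))))
  expect_false(is.unsorted(apply_quantile_reference(m3, ref)$values["P1", ]))
})

test_that("filter_low_amplification applies the strict >10% rule", {
  vals <- matrix(rnorm(10 * 3, 25), nrow = 10,
                 dimnames = list(paste0("P", 1:10), c("keep20", "edge10", "full")))
  vals[1:2, "keep20"] <- NA   # 20% missing -> removed
  vals[1, "edge10"] <- NA     # exactly 10% -> retained
  fl <- filter_low_amplification(feature_matrix(vals, "quantile_normalized"))
  expect_equal(fl$removed_ids, "keep20")
  expect_equal(colnames(fl$matrix$values), c("edge10", "full"))
  expect_equal(fl$matrix$stage, "filtered")

  # monotone in the threshold: a tighter threshold never retains more
  for (thr in c(0.05, 0.2, 0.5)) {
    a <- filter_low_amplification(feature_matrix(vals, "quantile_normalized"),
                                  thr)$removed_ids
    b <- filter_low_amplification(feature_matrix(vals, "quantile_normalized"),
                                  thr / 2)$removed_ids
    expect_true(all(a %in% b))
  }
  vals[] <- NA
  expect_error(filter_low_amplification(
    feature_matrix(vals, "quantile_normalized")), "all features removed")
})

test_that("impute_missing uses the global max and leaves observed cells alone", {
  vals <- matrix(c(20, 25, NA, 38.2, 30, NA), 2,
                 dimnames = list(c("P1", "P2"), paste0("f", 1:3)))
  obs <- !is.na(vals)
  im <- impute_missing(feature_matrix(vals, "filtered"))
  expect_equal(im$imputation_value, 38.2)
  expect_true(all(im$matrix$values[!obs] == 38.2))
  expect_equal(im$matrix$values[obs], vals[obs])
  expect_true(im$imputation_value >= max(vals, na.rm = TRUE))

  # no missing: identity, value still the global max
  complete <- matrix(c(20, 25, 30, 38.2), 2,
                     dimnames = list(c("P1", "P2"), c("f1", "f2")))
  im2 <- impute_missing(feature_matrix(complete, "filtered"))
  expect_equal(im2$matrix$values, complete)
  expect_equal(im2$imputation_value, 38.2)

  # per-feature option: each missing cell takes its own column's max
  im3 <- impute_missing(feature_matrix(vals, "filtered"), per_feature = TRUE)
  expect_equal(unname(im3$matrix$values["P1", "f2"]), 38.2)
  expect_equal(unname(im3$matrix$values["P2", "f3"]), 30)
})

test_that("scaler matches hand computation and round-trips on new data", {
  vals <- matrix(c(1, 2, 3, 10, 20, 30), 3,
                 dimnames = list(paste0("P", 1:3), c("a", "b")))
  sc <- fit_scaler(feature_matrix(vals, "imputed"))
  expect_equal(unname(sc$means), c(2, 20))
  expect_equal(unname(sc$sds), c(1, 10))   # sample sd, ddof = 1
  scaled <- apply_scaler(feature_matrix(vals, "imputed"), sc)
  expect_equal(unname(scaled$values[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(scaled$values))), 1e-12)

  vals2 <- cbind(vals, const = 5)
  expect_error(fit_scaler(feature_matrix(vals2, "imputed")), "const")
})

test_that("pca respects geometry, orthonormality and the sign convention", {
  # points on the line y = x: PC1 explains everything
  vals <- cbind(a = c(-2, -1, 0, 1, 2), b = c(-2, -1, 0, 1, 2))
  rownames(vals) <- paste0("P", 1:5)
  pca <- fit_pca(feature_matrix(vals, "scaled"), n_components = 1)
  expect_equal(pca$explained_variance_ratio[1], 1)

  set.seed(3)
  vals2 <- matrix(rnorm(20 * 6), 20,
                  dimnames = list(paste0("P", 1:20), paste0("f", 1:6)))
  pca2 <- fit_pca(feature_matrix(vals2, "scaled"), n_components = 4)
  expect_equal(crossprod(pca2$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  evr <- pca2$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-12)
  for (j in 1:4) {
    i <- which.max(abs(pca2$loadings[, j]))
    expect_gt(pca2$loadings[i, j], 0)
  }
  # scores = centered data %*% loadings
  sc <- apply_pca(feature_matrix(vals2, "scaled"), pca2)
  expect_equal(sc$values,
               sweep(vals2, 2, colMeans(vals2)) %*% pca2$loadings)
  expect_error(fit_pca(feature_matrix(vals2, "scaled"), n_components = 7),
               "rank")
})

test_that("fit_preprocess composes the stages and freezes parameters", {
  co <- generate_cohort(synthetic_config(seed = 1))
  fm <- average_replicates(co$profiles)
  pp <- fit_preprocess(fm)

  # composition equals the stagewise pipeline
  qn <- quantile_normalize(fm)
  fl <- filter_low_amplification(qn$matrix)
  im <- impute_missing(fl$matrix)
  sc <- fit_scaler(im$matrix)
  scaled <- apply_scaler(im$matrix, sc)
  pca <- fit_pca(scaled, variance_target = 0.90)
  expect_equal(apply_preprocess(fm, pp)$values,
               apply_pca(scaled, pca)$values)

  # contract: n_components columns, no missing values
  out <- apply_preprocess(fm, pp)
  expect_equal(ncol(out$values), pp$n_components)
  expect_false(anyNA(out$values))
  expect_equal(out$stage, "pca")

  # determinism / idempotence in parameters
  expect_identical(apply_preprocess(fm, pp)$values, out$values)

  # a held-out profile missing a retained miRNA gets the stored imputation
  sub <- fm$values[1:3, , drop = FALSE]
  sub[1, pp$retained_features[1]] <- NA
  held <- apply_preprocess(fm_raw(sub), pp, stop_at = "imputed")
  expect_equal(unname(held$values[1, pp$retained_features[1]]),
               unname(pp$imputation_value))

  # new data lacking a retained feature errors
  lacking <- fm$values[1:3, -match(pp$retained_features[1], colnames(fm$values))]
  expect_error(apply_preprocess(fm_raw(lacking), pp), "lacks retained")
})

test_that("preprocess params survive a JSON round trip at full precision", {
  co <- generate_cohort(synthetic_config(seed = 2, n_mirnas = 40,
                                         group_sizes = c(`108` = 6, `120` = 20,
                                                         `144` = 6),
                                         n_failed = 0, n_informative = 5,
                                         n_always_low = 4))
  fm <- average_replicates(co$profiles)
  pp <- fit_preprocess(fm)
  f <- withr::local_tempfile(fileext = ".json")
  write_preprocess_params(pp, f)
  back <- read_preprocess_params(f)
  expect_equal(back$quantile_reference, pp$quantile_reference)
  expect_equal(back$pca_loadings, pp$pca_loadings)
  expect_equal(back$scaler_means, pp$scaler_means)
  # serialized doubles round-trip to within 1 ulp
  expect_equal(apply_preprocess(fm, back)$values,
               apply_preprocess(fm, pp)$values, tolerance = 1e-12)

  # unknown schema version is rejected
  x <- jsonlite::read_json(f)
  x$schema_version <- 99
  jsonlite::write_json(x, f, auto_unbox = TRUE)
  expect_error(read_preprocess_params(f), "schema_version")
})
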