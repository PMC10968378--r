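FM_STAGES <- c("raw_mean", "quantile_normalized", "filtered", "imputed",
               "scaled", "pca")

#' Construct a feature matrix
#'
#' A patient-by-feature matrix of normalized Cq (deltaCq) values, tagged with
#' the pipeline stage it has reached. Stage transitions must follow the
#' pipeline order raw_mean -> quantile_normalized -> filtered -> imputed ->
#' scaled -> pca; after `imputed` no missing entries remain.
#'
#' @param values numeric matrix with patient row names and feature column
#'   names.
#' @param stage one of `"raw_mean"`, `"quantile_normalized"`, `"filtered"`,
#'   `"imputed"`, `"scaled"`, `"pca"`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, stage = "raw_mean") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stage <- match.arg(stage, FM_STAGES)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix needs patient row names and feature column names")
  if (stage %in% c("imputed", "scaled", "pca") && anyNA(values))
    stop("no missing entries allowed at stage ", stage)
  structure(list(values = values, stage = stage), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d patients x %d features, %d missing\n",
              x$stage, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

advance_stage <- function(x, from, to) {
  if (!identical(x$stage, from))
    stop(sprintf("expected stage '%s' but got '%s'", from, x$stage))
  to
}

# Values a row's ranks 1..m map to on a reference distribution of length L:
# linear interpolation at probabilities (r-1)/(m-1).
rank_values_from_reference <- function(reference, m) {
  L <- length(reference)
  if (m == 1) return(reference[ceiling(L / 2)])
  stats::approx(x = seq(0, 1, length.out = L), y = reference,
                xout = seq(0, 1, length.out = m), method = "linear",
                ties = "ordered")$y
}

# Replace one row's non-missing values with reference values at their
# within-row ranks; tied observations get the mean of the reference values
# at the positions the tie group spans.
map_row_to_reference <- function(row, reference) {
  obs <- which(!is.na(row))
  m <- length(obs)
  if (m == 0) return(row)
  v <- row[obs]
  ref_at_rank <- rank_values_from_reference(reference, m)
  ord_rank <- rank(v, ties.method = "min")
  # positions each value occupies after sorting
  out <- numeric(m)
  for (g in unique(v)) {
    at <- which(v == g)
    span <- ord_rank[at[1]] + seq_along(at) - 1L
    out[at] <- mean(ref_at_rank[span])
  }
  row[obs] <- out
  row
}

#' Quantile-normalize profiles to a common distribution
#'
#' Forces every patient profile (row) to share one value distribution: the
#' reference is the per-quantile mean over rows of the sorted non-missing
#' values, each row first interpolated onto a common grid with as many points
#' as there are features. Each row's non-missing values are then replaced by
#' the reference value at their within-row rank (ties receive the mean of the
#' tied reference positions). Missing (non-amplified) entries stay missing.
#'
#' @param matrix a [feature_matrix()] at stage `"raw_mean"` with >= 2 rows.
#' @return list with `matrix` (stage `"quantile_normalized"`) and
#'   `quantile_reference` (sorted numeric vector).
#' @export
quantile_normalize <- function(matrix) {
  stage <- advance_stage(matrix, "raw_mean", "quantile_normalized")
  vals <- matrix$values
  if (nrow(vals) < 2) stop("quantile normalization needs >= 2 profiles")
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs < 2))
    stop("profile(s) with fewer than 2 non-missing values: ",
         paste(rownames(vals)[n_obs < 2], collapse = ", "))
  L <- ncol(vals)
  grid <- seq(0, 1, length.out = L)
  onto_grid <- t(apply(vals, 1, function(row) {
    v <- sort(row[!is.na(row)])
    if (length(v) == L) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }))
  reference <- colMeans(onto_grid)
  out <- t(apply(vals, 1, map_row_to_reference, reference = reference))
  dimnames(out) <- dimnames(vals)
  list(matrix = feature_matrix(out, stage),
       quantile_reference = reference)
}

#' Map new profiles onto a frozen quantile reference
#'
#' Applies the training-set reference distribution to held-out profiles by
#' rank, interpolating linearly when a row's non-missing count differs from
#' the reference length. Used so test data never influences normalization.
#'
#' @param matrix a [feature_matrix()] at stage `"raw_mean"`.
#' @param quantile_reference sorted reference returned by
#'   [quantile_normalize()].
#' @return [feature_matrix()] at stage `"quantile_normalized"`.
#' @export
apply_quantile_reference <- function(matrix, quantile_reference) {
  stage <- advance_stage(matrix, "raw_mean", "quantile_normalized")
  if (!length(quantile_reference)) stop("empty quantile reference")
  out <- t(apply(matrix$values, 1, map_row_to_reference,
                 reference = quantile_reference))
  dimnames(out) <- dimnames(matrix$values)
  feature_matrix(out, stage)
}

#' Remove miRNAs with too many non-amplified profiles
#'
#' A feature is retained iff it amplified in at least
#' `1 - max_missing_fraction` of profiles (default: present in >= 90%); it is
#' removed iff its missing fraction strictly exceeds the threshold.
#'
#' @param matrix [feature_matrix()] at stage `"quantile_normalized"`.
#' @param max_missing_fraction removal threshold (default 0.10).
#' @return list with `matrix` (stage `"filtered"`) and `removed_ids`.
#' @export
filter_low_amplification <- function(matrix, max_missing_fraction = 0.10) {
  stage <- advance_stage(matrix, "quantile_normalized", "filtered")
  miss_frac <- colMeans(is.na(matrix$values))
  drop <- miss_frac > max_missing_fraction
  if (all(drop)) stop("all features removed by the amplification filter")
  list(matrix = feature_matrix(matrix$values[, !drop, drop = FALSE], stage),
       removed_ids = colnames(matrix$values)[drop])
}

#' Impute non-amplified cells with the global maximum deltaCq
#'
#' Every missing cell is set to the single largest observed value in the
#' matrix — the lowest observed expression — reflecting that a well that
#' failed to amplify holds at most trace amounts of template. The value is
#' recorded for reuse on held-out data.
#'
#' @param matrix [feature_matrix()] at stage `"filtered"`.
#' @param per_feature use each feature's own maximum instead of the global
#'   one (default FALSE).
#' @return list with `matrix` (stage `"imputed"`) and `imputation_value`
#'   (scalar, or per-feature vector when `per_feature = TRUE`).
#' @export
impute_missing <- function(matrix, per_feature = FALSE) {
  stage <- advance_stage(matrix, "filtered", "imputed")
  vals <- matrix$values
  if (all(is.na(vals))) stop("matrix entirely missing; nothing to impute")
  if (per_feature) {
    imp <- apply(vals, 2, max, na.rm = TRUE)
    for (j in seq_len(ncol(vals))) vals[is.na(vals[, j]), j] <- imp[j]
  } else {
    imp <- max(vals, na.rm = TRUE)
    vals[is.na(vals)] <- imp
  }
  list(matrix = feature_matrix(vals, stage), imputation_value = imp)
}

#' Fit and apply zero-mean/unit-variance feature scaling
#'
#' Means and standard deviations (sample sd, n-1 denominator by default) are
#' estimated on the training matrix and replayed on any matrix with the same
#' features.
#'
#' @param matrix [feature_matrix()] at stage `"imputed"`.
#' @param ddof denominator offset for the standard deviation: 1 (sample sd,
#'   default) or 0 (population sd).
#' @return `fit_scaler`: list `means`, `sds` named by feature.
#' @export
fit_scaler <- function(matrix, ddof = 1) {
  if (!identical(matrix$stage, "imputed"))
    stop(sprintf("expected stage 'imputed' but got '%s'", matrix$stage))
  vals <- matrix$values
  means <- colMeans(vals)
  n <- nrow(vals)
  ss <- colSums(sweep(vals, 2, means)^2)
  sds <- sqrt(ss / (n - ifelse(ddof == 1, 1, 0)))
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(vals)[zero], collapse = ", "))
  list(means = means, sds = sds)
}

#' @rdname fit_scaler
#' @param params scaler parameters from [fit_scaler()].
#' @return `apply_scaler`: [feature_matrix()] at stage `"scaled"`.
#' @export
apply_scaler <- function(matrix, params) {
  stage <- advance_stage(matrix, "imputed", "scaled")
  vals <- matrix$values
  feats <- names(params$means)
  if (!all(feats %in% colnames(vals)))
    stop("matrix lacks retained feature(s): ",
         paste(setdiff(feats, colnames(vals)), collapse = ", "))
  vals <- vals[, feats, drop = FALSE]
  out <- sweep(sweep(vals, 2, params$means), 2, params$sds, "/")
  feature_matrix(out, stage)
}

#' Fit and apply a principal component transform
#'
#' Loadings are the top right-singular vectors of the column-centered
#' training matrix, ordered by decreasing explained variance. The sign of
#' each component is fixed so its largest-magnitude loading is positive,
#' making results reproducible across linear-algebra backends. The number of
#' components defaults to the smallest count reaching `variance_target`
#' cumulative explained variance.
#'
#' @param matrix [feature_matrix()] at stage `"scaled"`.
#' @param n_components explicit component count (overrides
#'   `variance_target`).
#' @param variance_target cumulative explained-variance fraction (default
#'   0.90).
#' @return `fit_pca`: list `means`, `loadings` (features x components),
#'   `explained_variance_ratio`, `n_components`.
#' @export
fit_pca <- function(matrix, n_components = NULL, variance_target = 0.90) {
  if (!identical(matrix$stage, "scaled"))
    stop(sprintf("expected stage 'scaled' but got '%s'", matrix$stage))
  vals <- matrix$values
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  max_rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (is.null(n_components)) {
    n_components <- which(cumsum(evr) >= variance_target - 1e-12)[1]
    if (is.na(n_components)) n_components <- max_rank
    n_components <- min(n_components, max_rank)
  } else if (n_components > max_rank) {
    stop(sprintf("n_components (%d) exceeds matrix rank (%d)",
                 n_components, max_rank))
  }
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| element positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  list(means = pc$center, loadings = load,
       explained_variance_ratio = evr[seq_len(n_components)],
       n_components = n_components)
}

#' @rdname fit_pca
#' @param params PCA parameters from [fit_pca()].
#' @return `apply_pca`: [feature_matrix()] at stage `"pca"` whose columns are
#'   component scores.
#' @export
apply_pca <- function(matrix, params) {
  stage <- advance_stage(matrix, "scaled", "pca")
  vals <- matrix$values
  feats <- rownames(params$loadings)
  if (!all(feats %in% colnames(vals)))
    stop("matrix lacks retained feature(s): ",
         paste(setdiff(feats, colnames(vals)), collapse = ", "))
  centered <- sweep(vals[, feats, drop = FALSE], 2, params$means)
  scores <- centered %*% params$loadings
  feature_matrix(scores, stage)
}

#' Fit the full preprocessing chain on training data
#'
#' Runs quantile normalization, the low-amplification filter, maximum-deltaCq
#' imputation, feature scaling, and PCA in order, freezing every parameter so
#' held-out profiles can be transformed identically with
#' [apply_preprocess()].
#'
#' @param train [feature_matrix()] at stage `"raw_mean"`.
#' @param max_missing_fraction filter threshold (default 0.10).
#' @param n_components,variance_target forwarded to [fit_pca()].
#' @param per_feature_imputation forwarded to [impute_missing()].
#' @param ddof forwarded to [fit_scaler()].
#' @return object of class `preprocess_params`.
#' @export
fit_preprocess <- function(train, max_missing_fraction = 0.10,
                           n_components = NULL, variance_target = 0.90,
                           per_feature_imputation = FALSE, ddof = 1) {
  qn <- quantile_normalize(train)
  fl <- filter_low_amplification(qn$matrix, max_missing_fraction)
  im <- impute_missing(fl$matrix, per_feature = per_feature_imputation)
  sc <- fit_scaler(im$matrix, ddof = ddof)
  scaled <- apply_scaler(im$matrix, sc)
  pca <- fit_pca(scaled, n_components = n_components,
                 variance_target = variance_target)
  structure(list(schema_version = 1L,
                 quantile_reference = qn$quantile_reference,
                 retained_features = colnames(fl$matrix$values),
                 removed_features = fl$removed_ids,
                 imputation_value = im$imputation_value,
                 per_feature_imputation = per_feature_imputation,
                 scaler_means = sc$means, scaler_sds = sc$sds,
                 pca_means = pca$means, pca_loadings = pca$loadings,
                 explained_variance_ratio = pca$explained_variance_ratio,
                 n_components = pca$n_components),
            class = "preprocess_params")
}

#' Replay frozen preprocessing on any profile set
#'
#' Applies the stored quantile reference, retained-feature subset, imputation
#' value, scaler, and PCA loadings. Deterministic: the same parameters and
#' input give bit-identical output.
#'
#' @param matrix [feature_matrix()] at stage `"raw_mean"`.
#' @param params a `preprocess_params` object from [fit_preprocess()].
#' @param stop_at return early at an intermediate stage (default `"pca"`).
#' @return [feature_matrix()] at the requested stage.
#' @export
apply_preprocess <- function(matrix, params, stop_at = "pca") {
  stopifnot(inherits(params, "preprocess_params"))
  stop_at <- match.arg(stop_at, c("quantile_normalized", "filtered",
                                  "imputed", "scaled", "pca"))
  qn <- apply_quantile_reference(matrix, params$quantile_reference)
  if (stop_at == "quantile_normalized") return(qn)
  lack <- setdiff(params$retained_features, colnames(qn$values))
  if (length(lack))
    stop("input lacks retained feature(s): ", paste(lack, collapse = ", "))
  sub <- feature_matrix(qn$values[, params$retained_features, drop = FALSE],
                        "filtered")
  if (stop_at == "filtered") return(sub)
  vals <- sub$values
  if (params$per_feature_imputation) {
    for (j in seq_len(ncol(vals)))
      vals[is.na(vals[, j]), j] <- params$imputation_value[[colnames(vals)[j]]]
  } else {
    vals[is.na(vals)] <- params$imputation_value
  }
  imp <- feature_matrix(vals, "imputed")
  if (stop_at == "imputed") return(imp)
  scaled <- apply_scaler(imp, list(means = params$scaler_means,
                                   sds = params$scaler_sds))
  if (stop_at == "scaled") return(scaled)
  apply_pca(scaled, list(means = params$pca_means,
                         loadings = params$pca_loadings))
}

#' Serialize preprocessing parameters to JSON
#'
#' Full-precision (digits = NA) versioned JSON so a frozen pipeline can be
#' re-applied bit-exactly.
#'
#' @param params `preprocess_params` object.
#' @param path output file.
#' @export
write_preprocess_params <- function(params, path) {
  x <- unclass(params)
  x$pca_loadings <- list(features = rownames(params$pca_loadings),
                         components = colnames(params$pca_loadings),
                         values = unname(params$pca_loadings))
  x$scaler_means <- as.list(params$scaler_means)
  x$scaler_sds <- as.list(params$scaler_sds)
  x$pca_means <- as.list(params$pca_means)
  if (params$per_feature_imputation)
    x$imputation_value <- as.list(params$imputation_value)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess_params
#' @export
read_preprocess_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("unknown preprocess_params schema_version: ",
         if (is.null(x$schema_version)) "<absent>" else x$schema_version)
  load <- x$pca_loadings$values
  if (is.list(load)) load <- do.call(rbind, load)
  dimnames(load) <- list(x$pca_loadings$features, x$pca_loadings$components)
  structure(list(schema_version = 1L,
                 quantile_reference = as.numeric(x$quantile_reference),
                 retained_features = as.character(x$retained_features),
                 removed_features = as.character(x$removed_features),
                 imputation_value = if (x$per_feature_imputation)
                   unlist(x$imputation_value) else as.numeric(x$imputation_value),
                 per_feature_imputation = isTRUE(x$per_feature_imputation),
                 scaler_means = unlist(x$scaler_means),
                 scaler_sds = unlist(x$scaler_sds),
                 pca_means = unlist(x$pca_means),
                 pca_loadings = load,
                 explained_variance_ratio = as.numeric(x$explained_variance_ratio),
                 n_components = as.integer(x$n_components)),
            class = "preprocess_params")
}
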