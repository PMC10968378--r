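#' Per-group presence filter for the differential-expression screen
#'
#' A miRNA is excluded only when its non-amplification fraction exceeds
#' `max_absent_fraction` in *every* one of the three transfer-time groups
#' (the default, literal reading); `mode = "any"` applies the stricter rule
#' of excluding when any single group exceeds the threshold.
#'
#' @param matrix [feature_matrix()] at a pre-imputation stage
#'   (missing entries still marked).
#' @param groups vector of class labels (108/120/144) aligned with rows,
#'   or named by patient id.
#' @param max_absent_fraction threshold (default 0.05).
#' @param mode `"all"` (default) or `"any"`.
#' @return character vector of retained feature ids.
#' @export
group_presence_filter <- function(matrix, groups, max_absent_fraction = 0.05,
                                  mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "feature_matrix"))
  vals <- matrix$values
  if (!is.null(names(groups))) groups <- groups[rownames(vals)]
  stopifnot(length(groups) == nrow(vals))
  gl <- unique(groups)
  if (any(vapply(gl, function(g) sum(groups == g), 0L) == 0))
    stop("empty group")
  absent <- vapply(gl, function(g)
    colMeans(is.na(vals[groups == g, , drop = FALSE])), numeric(ncol(vals)))
  over <- absent > max_absent_fraction
  excluded <- if (mode == "all") apply(over, 1, all) else apply(over, 1, any)
  colnames(vals)[!excluded]
}

#' Per-miRNA log2 fold change between two groups, from deltaCq values
#'
#' On the Cq scale a decrease of one cycle is a doubling of template at 100%
#' amplification efficiency, so
#' `log2FC(a vs b) = mean deltaCq(b) - mean deltaCq(a)`: positive values mean
#' group `a` is more abundant. Missing entries are dropped per miRNA per
#' group.
#'
#' @param matrix [feature_matrix()] of deltaCq values (pre-imputation).
#' @param group_a,group_b logical or index vectors selecting rows.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(matrix, group_a, group_b) {
  vals <- matrix$values
  ma <- colMeans(vals[group_a, , drop = FALSE], na.rm = TRUE)
  mb <- colMeans(vals[group_b, , drop = FALSE], na.rm = TRUE)
  mb - ma
}

# two-sided t-test p-value for one feature with the normality-gated variance
# mode; returns c(p, mode) with mode 1 = pooled, 2 = welch
t_pvalue_gated <- function(a, b, normality_alpha) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    return(c(p = NA_real_, mode = NA_real_))
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group variability at all
    return(c(p = if (mean(a) == mean(b)) 1 else 0, mode = 1))
  }
  normal_ok <- function(x) {
    if (length(x) < 3 || stats::var(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > normality_alpha
  }
  pooled <- normal_ok(a) && normal_ok(b)
  p <- tryCatch(
    stats::t.test(a, b, var.equal = pooled)$p.value,
    error = function(e) NA_real_)
  c(p = p, mode = if (pooled) 1 else 2)
}

#' Two-group differential test with a normality-gated variance mode
#'
#' For each miRNA, both groups are checked for normality (Shapiro-Wilk at
#' `normality_alpha`); when both pass, the pooled-variance (equal-variance)
#' Student t-test is used, otherwise the unequal-variance Welch t-test.
#' Two-sided p-values. A feature with zero variance in both groups and equal
#' means gets p = 1 and is flagged.
#'
#' @param matrix [feature_matrix()] of deltaCq values (pre-imputation).
#' @param group_a,group_b row selectors.
#' @param normality_alpha Shapiro-Wilk significance gate (default 0.05).
#' @return data.frame `mirna_id, p, variance_mode` (`"pooled"` or
#'   `"welch"`), plus `degenerate` flag.
#' @export
de_test <- function(matrix, group_a, group_b, normality_alpha = 0.05) {
  vals <- matrix$values
  A <- vals[group_a, , drop = FALSE]
  B <- vals[group_b, , drop = FALSE]
  res <- vapply(seq_len(ncol(vals)), function(j)
    t_pvalue_gated(A[, j], B[, j], normality_alpha), numeric(2))
  degen <- vapply(seq_len(ncol(vals)), function(j) {
    a <- A[, j][!is.na(A[, j])]; b <- B[, j][!is.na(B[, j])]
    length(a) >= 2 && length(b) >= 2 && stats::var(a) == 0 && stats::var(b) == 0
  }, logical(1))
  data.frame(mirna_id = colnames(vals), p = res[1, ],
             variance_mode = c("pooled", "welch")[res[2, ]],
             degenerate = degen, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-expression call from fold change and p-value
#'
#' Selected iff `|log2FC| >= fc_thresh` AND `p <= p_thresh`; both thresholds
#' inclusive. The default fold-change cut of 0.585 corresponds to a 1.5-fold
#' abundance change.
#'
#' @param fc,p aligned numeric vectors.
#' @param fc_thresh,p_thresh inclusive thresholds (defaults 0.585, 0.05).
#' @return logical vector.
#' @export
select_de <- function(fc, p, fc_thresh = 0.585, p_thresh = 0.05) {
  stopifnot(length(fc) == length(p))
  abs(fc) >= fc_thresh & !is.na(p) & p <= p_thresh
}

#' Run the full differential-expression screen
#'
#' Applies the per-group presence filter, then for the two comparisons
#' 120 h vs 108 h and 120 h vs 144 h computes log2 fold changes (120 h group
#' as the abundance-ratio numerator) and normality-gated t-test p-values; a
#' miRNA is selected when it passes both criteria in at least one comparison.
#'
#' @param matrix [feature_matrix()] of normalized, un-imputed deltaCq values.
#' @param groups labels (108/120/144) aligned with rows or named by patient.
#' @param max_absent_fraction,presence_mode see [group_presence_filter()].
#' @param fc_thresh,p_thresh see [select_de()].
#' @param normality_alpha see [de_test()].
#' @return data.frame, one row per retained miRNA: fold changes, p-values,
#'   variance modes, per-group presence fractions, `selected`.
#' @export
de_screen <- function(matrix, groups, max_absent_fraction = 0.05,
                      presence_mode = "all", fc_thresh = 0.585,
                      p_thresh = 0.05, normality_alpha = 0.05) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!is.null(names(groups))) groups <- groups[rownames(matrix$values)]
  keep <- group_presence_filter(matrix, groups, max_absent_fraction,
                                mode = presence_mode)
  sub <- feature_matrix(matrix$values[, keep, drop = FALSE], matrix$stage)
  g108 <- groups == 108; g120 <- groups == 120; g144 <- groups == 144

  fc_108 <- log2_fold_change(sub, g120, g108)
  fc_144 <- log2_fold_change(sub, g120, g144)
  t_108 <- de_test(sub, g120, g108, normality_alpha)
  t_144 <- de_test(sub, g120, g144, normality_alpha)

  pres <- vapply(list(`108` = g108, `120` = g120, `144` = g144),
                 function(g) colMeans(!is.na(sub$values[g, , drop = FALSE])),
                 numeric(ncol(sub$values)))

  sel <- select_de(fc_108, t_108$p, fc_thresh, p_thresh) |
         select_de(fc_144, t_144$p, fc_thresh, p_thresh)

  data.frame(mirna_id = keep,
             log2fc_120v108 = unname(fc_108),
             log2fc_120v144 = unname(fc_144),
             p_120v108 = t_108$p, p_120v144 = t_144$p,
             mode_120v108 = t_108$variance_mode,
             mode_120v144 = t_144$variance_mode,
             presence_108 = pres[, "108"], presence_120 = pres[, "120"],
             presence_144 = pres[, "144"],
             selected = unname(sel),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PCA view of the differentially expressed miRNA subset
#'
#' Scales the DE submatrix, fits a 2-component PCA, and returns per-sample
#' coordinates and per-group centroids for inspection/plotting. No hard
#' cluster assignment is made.
#'
#' @param matrix [feature_matrix()] of deltaCq values restricted to the
#'   samples of interest (missing entries are imputed with the global max
#'   before scaling).
#' @param de_ids >= 2 differentially expressed feature ids.
#' @param groups labels aligned with rows or named by patient.
#' @return list `coordinates` (n x 2), `centroids` (group x 2),
#'   `explained_variance_ratio`.
#' @export
pca_cluster_de <- function(matrix, de_ids, groups) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (length(de_ids) < 2) stop("need >= 2 DE miRNAs for a PCA view")
  if (!is.null(names(groups))) groups <- groups[rownames(matrix$values)]
  vals <- matrix$values[, de_ids, drop = FALSE]
  if (anyNA(vals)) vals[is.na(vals)] <- max(vals, na.rm = TRUE)
  sds <- apply(vals, 2, stats::sd)
  sds[sds == 0] <- 1
  vals <- sweep(sweep(vals, 2, colMeans(vals)), 2, sds, "/")
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # fixed sign convention, as in fit_pca
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) coords[, j] <- -coords[, j]
  }
  cent <- do.call(rbind, lapply(split(seq_len(nrow(coords)), groups),
                                function(i) colMeans(coords[i, , drop = FALSE])))
  evr <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(coordinates = coords, centroids = cent,
       explained_variance_ratio = evr)
}
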