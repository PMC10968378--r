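ASSAY_ROLES <- c("target", "endogenous_control", "spike_in")
CLASS_HOURS <- c(108L, 120L, 144L)

#' Construct a Cq profile set
#'
#' A `cq_profile_set` holds a raw per-replicate Cq matrix from a panel-qPCR
#' run, the role of every assay (miRNA target, endogenous control, or
#' exogenous spike-in), and the patient owning each profile. Wells with no
#' amplification are stored as `NA`, never as a sentinel cycle number.
#'
#' @param cq numeric matrix, assays in rows and profiles (replicates) in
#'   columns; `NA` marks no amplification. Row and column names are used as
#'   assay and profile identifiers when `assay_ids`/`profile_ids` are omitted.
#' @param roles character vector (one of `"target"`, `"endogenous_control"`,
#'   `"spike_in"`) named by assay id, or unnamed in row order.
#' @param patient_of_profile character vector mapping each profile (column)
#'   to a patient id; named by profile id or in column order. Defaults to one
#'   patient per profile.
#' @param assay_ids,profile_ids optional explicit identifiers.
#' @return An object of class `cq_profile_set`.
#' @export
cq_profile_set <- function(cq, roles, patient_of_profile = NULL,
                           assay_ids = rownames(cq),
                           profile_ids = colnames(cq)) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  if (is.null(assay_ids) || is.null(profile_ids))
    stop("cq matrix must carry assay (row) and profile (column) identifiers")
  assay_ids <- as.character(assay_ids)
  profile_ids <- as.character(profile_ids)
  if (anyDuplicated(assay_ids)) stop("duplicate assay ids")
  if (anyDuplicated(profile_ids)) stop("duplicate profile ids")
  if (nrow(cq) != length(assay_ids) || ncol(cq) != length(profile_ids))
    stop("cq dimensions do not match assay_ids x profile_ids")
  dimnames(cq) <- list(assay_ids, profile_ids)

  if (is.null(names(roles))) {
    if (length(roles) != nrow(cq)) stop("roles length must match assays")
    names(roles) <- assay_ids
  }
  roles <- as.character(roles[assay_ids])
  if (anyNA(roles)) stop("every assay needs exactly one role")
  bad <- setdiff(unique(roles), ASSAY_ROLES)
  if (length(bad))
    stop("unknown assay role(s): ", paste(bad, collapse = ", "))
  names(roles) <- assay_ids

  if (is.null(patient_of_profile)) {
    patient_of_profile <- profile_ids
    names(patient_of_profile) <- profile_ids
  }
  if (is.null(names(patient_of_profile))) {
    if (length(patient_of_profile) != ncol(cq))
      stop("patient_of_profile length must match profiles")
    names(patient_of_profile) <- profile_ids
  }
  patient_of_profile <- as.character(patient_of_profile[profile_ids])
  if (anyNA(patient_of_profile))
    stop("every profile must map to exactly one patient")
  names(patient_of_profile) <- profile_ids

  obs <- cq[!is.na(cq)]
  if (length(obs) && any(!is.finite(obs) | obs <= 0))
    stop("all non-missing Cq values must be finite and > 0")

  structure(list(cq = cq, roles = roles,
                 patient_of_profile = patient_of_profile),
            class = "cq_profile_set")
}

#' @export
print.cq_profile_set <- function(x, ...) {
  cat(sprintf("cq_profile_set: %d assays x %d profiles (%d patients), %d missing cells\n",
              nrow(x$cq), ncol(x$cq),
              length(unique(x$patient_of_profile)), sum(is.na(x$cq))))
  tab <- table(factor(x$roles, levels = ASSAY_ROLES))
  cat(sprintf("  roles: %d target, %d endogenous_control, %d spike_in\n",
              tab[["target"]], tab[["endogenous_control"]], tab[["spike_in"]]))
  invisible(x)
}

#' Read a wide Cq table and companion roles file
#'
#' The table has assays in rows, profiles in columns, assay id in the first
#' column. No-amplification wells may be encoded as empty cells, `"NA"`, or a
#' Cq at or above `ceiling` (the instrument reporting limit): all three are
#' converted to the internal missing marker.
#'
#' @param path delimited (TSV/CSV, sniffed from the extension) Cq table.
#' @param roles_path two-column delimited file `assay_id, role`. If `NULL`,
#'   all assays are treated as targets.
#' @param patients optional named character vector profile -> patient id.
#'   When omitted, replicate structure is inferred from the
#'   `<patient>_r<k>` profile naming convention; profiles not matching it
#'   are treated as single-replicate patients.
#' @param ceiling Cq at or above which a well is treated as not amplified
#'   (default 40 cycles).
#' @return A [cq_profile_set()].
#' @export
read_cq_table <- function(path, roles_path = NULL, patients = NULL,
                          ceiling = 40.0) {
  raw <- read_delim_auto(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("Cq table needs an assay id column plus profiles")
  assay_ids <- raw[[1]]
  profile_ids <- colnames(raw)[-1]
  if (anyDuplicated(assay_ids)) stop("duplicate assay ids in ", path)
  if (anyDuplicated(profile_ids)) stop("duplicate profile columns in ", path)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells <- trimws(cells)
  miss <- cells == "" | toupper(cells) == "NA" | is.na(cells)
  num <- suppressWarnings(as.numeric(cells))
  bad <- !miss & is.na(num)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric Cq cell '%s' (assay %s, profile %s)",
                 cells[bad][1], assay_ids[i[1]], profile_ids[i[2]]))
  }
  num[miss] <- NA_real_
  num[!is.na(num) & num >= ceiling] <- NA_real_
  cq <- matrix(num, nrow = length(assay_ids),
               dimnames = list(assay_ids, profile_ids))

  if (!is.null(roles_path)) {
    rtab <- read_delim_auto(roles_path, colClasses = "character")
    roles <- stats::setNames(rtab[[2]], rtab[[1]])
  } else {
    roles <- stats::setNames(rep("target", length(assay_ids)), assay_ids)
  }
  if (is.null(patients))
    patients <- stats::setNames(sub("_r\\d+$", "", profile_ids), profile_ids)
  cq_profile_set(cq, roles, patient_of_profile = patients)
}

#' Write a Cq profile set back to disk
#'
#' Non-missing values round-trip bit-exactly (written with full precision);
#' missing cells are written as `"NA"`.
#'
#' @param x a [cq_profile_set()].
#' @param path output table path (TSV or CSV by extension).
#' @param roles_path optional path for the companion roles file.
#' @export
write_cq_table <- function(x, path, roles_path = NULL) {
  vals <- matrix(vapply(x$cq, function(v)
    if (is.na(v)) "NA" else format(v, digits = 17), character(1)),
    nrow = nrow(x$cq), dimnames = dimnames(x$cq))
  df <- data.frame(assay_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delim_auto(df, path)
  if (!is.null(roles_path))
    write_delim_auto(data.frame(assay_id = names(x$roles), role = x$roles),
                     roles_path)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Expects columns `patient_id, label, outcome, n_pif` and optionally
#' `age, bmi, p4, emt`. `label` is the embryo-transfer-time class in hours
#' (108/120/144) or `unknown`/empty; `outcome` is `success`/`failure` (or
#' TRUE/FALSE) or unknown.
#'
#' @param path delimited metadata file.
#' @return data.frame with one row per patient: `patient_id`, `label`
#'   (integer hours or NA), `implantation_success` (logical), `n_pif`
#'   (integer), plus optional numeric covariates.
#' @export
read_metadata <- function(path) {
  tab <- read_delim_auto(path, colClasses = "character")
  need <- c("patient_id", "label", "outcome", "n_pif")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$patient_id)) stop("duplicate patient_id in metadata")

  lab_chr <- trimws(tab$label)
  lab <- rep(NA_integer_, nrow(tab))
  known <- !(lab_chr %in% c("", "NA", "unknown"))
  lab_num <- suppressWarnings(as.integer(lab_chr[known]))
  if (anyNA(lab_num) || !all(lab_num %in% CLASS_HOURS))
    stop("label values must be one of 108, 120, 144 or unknown")
  lab[known] <- lab_num

  oc <- tolower(trimws(tab$outcome))
  success <- ifelse(oc %in% c("success", "true", "1", "yes"), TRUE,
                    ifelse(oc %in% c("failure", "false", "0", "no"), FALSE, NA))

  n_pif <- suppressWarnings(as.integer(tab$n_pif))
  if (any(!is.na(n_pif) & n_pif < 0)) stop("n_pif must be >= 0")

  out <- data.frame(patient_id = tab$patient_id, label = lab,
                    implantation_success = success, n_pif = n_pif,
                    stringsAsFactors = FALSE)
  for (opt in c("age", "bmi", "p4", "emt"))
    if (opt %in% colnames(tab))
      out[[opt]] <- suppressWarnings(as.numeric(tab[[opt]]))
  out
}

#' Write a metadata table
#' @param meta data.frame as returned by [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$label <- ifelse(is.na(meta$label), "unknown", as.character(meta$label))
  out$outcome <- ifelse(is.na(meta$implantation_success), "unknown",
                        ifelse(meta$implantation_success, "success", "failure"))
  out$implantation_success <- NULL
  out <- out[, c("patient_id", "label", "outcome",
                 setdiff(colnames(out), c("patient_id", "label", "outcome")))]
  write_delim_auto(out, path)
  invisible(path)
}

#' Average technical replicates into a patient-level feature matrix
#'
#' Each cell of the result is the arithmetic mean of that patient's
#' non-missing replicate Cq values for the assay; a cell is missing only when
#' every replicate failed to amplify. Only `target` assays become features;
#' control assays are dropped here (they are consumed by [qc_controls()]).
#'
#' @param profiles a [cq_profile_set()].
#' @param include_controls keep control assays as columns too (default FALSE).
#' @return A [feature_matrix()] at stage `"raw_mean"`, patients in rows.
#' @export
average_replicates <- function(profiles, include_controls = FALSE) {
  stopifnot(inherits(profiles, "cq_profile_set"))
  keep <- if (include_controls) rep(TRUE, nrow(profiles$cq))
          else profiles$roles == "target"
  m <- profiles$cq[keep, , drop = FALSE]
  pat <- profiles$patient_of_profile
  upat <- unique(pat)
  vals <- matrix(NA_real_, nrow = length(upat), ncol = nrow(m),
                 dimnames = list(upat, rownames(m)))
  for (p in upat) {
    sub <- m[, pat == p, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_   # all replicates missing
    vals[p, ] <- mu
  }
  feature_matrix(vals, stage = "raw_mean")
}

#' Per-profile control QC
#'
#' A profile fails when any endogenous or spike-in control assay either did
#' not amplify or fell outside its acceptable Cq range.
#'
#' @param profiles a [cq_profile_set()].
#' @param spec named list: for every control assay id, `c(lo, hi)` acceptable
#'   Cq bounds (inclusive).
#' @return data.frame `profile_id, pass, reasons` (reasons `;`-separated).
#' @export
qc_controls <- function(profiles, spec) {
  stopifnot(inherits(profiles, "cq_profile_set"))
  ctrl <- names(profiles$roles)[profiles$roles != "target"]
  lacking <- setdiff(ctrl, names(spec))
  if (length(lacking))
    stop("QC spec missing control assay(s): ", paste(lacking, collapse = ", "))
  prof <- colnames(profiles$cq)
  reasons <- vapply(prof, function(j) {
    rs <- character(0)
    for (a in ctrl) {
      v <- profiles$cq[a, j]
      kind <- if (profiles$roles[[a]] == "spike_in") "spike-in"
              else "endogenous control"
      if (is.na(v)) {
        rs <- c(rs, sprintf("%s %s not amplified", kind, a))
      } else {
        rng <- spec[[a]]
        if (v < rng[1] || v > rng[2])
          rs <- c(rs, sprintf("%s %s Cq %.2f outside [%g, %g]",
                              kind, a, v, rng[1], rng[2]))
      }
    }
    paste(rs, collapse = "; ")
  }, character(1))
  data.frame(profile_id = prof, pass = reasons == "",
             reasons = reasons, row.names = NULL, stringsAsFactors = FALSE)
}

#' Split patients into training and testing sets
#'
#' Deterministic given `seed`. Either a fraction (train size rounded to the
#' nearest integer) or an explicit integer train size can be given; the
#' explicit size reproduces cohort layouts whose split is not an exact
#' percentage (e.g. 115/35 out of 150). Optional stratification keeps class
#' proportions; by default the split is a simple random partition.
#'
#' @param patients character vector of patient ids.
#' @param fraction_train fraction in (0, 1); ignored when `n_train` given.
#' @param seed integer RNG seed.
#' @param n_train optional explicit number of training patients.
#' @param stratify_by optional vector (aligned with `patients`) of class
#'   labels to stratify on.
#' @return list with `train` and `test` character vectors.
#' @export
split_train_test <- function(patients, fraction_train = 0.75, seed = 1L,
                             n_train = NULL, stratify_by = NULL) {
  n <- length(patients)
  if (n < 2) stop("need at least 2 patients to split")
  if (is.null(n_train)) {
    if (fraction_train <= 0 || fraction_train >= 1)
      stop("fraction_train must be in (0, 1)")
    n_train <- round(fraction_train * n)
  }
  if (n_train < 1 || n_train >= n) stop("train size must leave both sets non-empty")
  set.seed(as.integer(seed))
  if (is.null(stratify_by)) {
    train <- sample(patients, n_train)
  } else {
    stopifnot(length(stratify_by) == n)
    idx <- unlist(lapply(split(seq_len(n), stratify_by), function(ii) {
      k <- min(max(round(length(ii) * n_train / n), 1), length(ii) - 1L)
      ii[sample.int(length(ii), k)]
    }), use.names = FALSE)
    # adjust to the exact requested size
    pool <- setdiff(seq_len(n), idx)
    if (length(idx) > n_train) idx <- idx[sample.int(length(idx), n_train)]
    if (length(idx) < n_train)
      idx <- c(idx, pool[sample.int(length(pool), n_train - length(idx))])
    train <- patients[sort(idx)]
  }
  list(train = train, test = setdiff(patients, train))
}

# --- internal helpers -------------------------------------------------------

read_delim_auto <- function(path, ...) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}
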