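#' Configuration for the synthetic panel-qPCR cohort generator
#'
#' Defaults emulate the cohort the pipeline was designed around: a
#' 200-patient retrospective IVF cohort profiled on a 167-miRNA reproductive
#' panel with 3 endogenous and 3 spike-in controls, 2-3 technical replicates
#' per patient (~526 profiles from 200 patients), three transfer-time classes
#' whose sizes scale the reported training proportions (12/91/12 out of 115)
#' to the full cohort, 21 class-informative miRNAs, 24 chronically
#' low-amplification assays, and expression-dependent non-amplification
#' (dropout probability rising with Cq on a logistic curve).
#'
#' @param n_mirnas number of miRNA target assays (167).
#' @param n_endogenous,n_spikein control assay counts (3 each).
#' @param group_sizes named integer vector `c("108"=, "120"=, "144"=)`
#'   (defaults 21/158/21, total 200).
#' @param n_failed patients marked as failed implantation (default 50),
#'   assigned so each class keeps at least the reported successful-cohort
#'   counts (20/116/14).
#' @param replicates_per_patient candidate replicate counts (default 2:3,
#'   drawn with P(3) = 0.63 so the expected profile/patient ratio is 2.63).
#' @param baseline_cq_mean,baseline_cq_sd per-assay baseline Cq distribution
#'   (cycles; defaults 27, 3).
#' @param n_informative class-shifted miRNAs (default 21).
#' @param effect_size_cycles deltaCq shift per class step for informative
#'   miRNAs (default 1.0 cycle).
#' @param replicate_noise_sd technical replicate noise (default 0.3 cycles).
#' @param patient_sd global patient random effect, shared across assays
#'   (default 0.5 cycles).
#' @param biological_sd per-patient per-miRNA biological variability
#'   (default 1.0 cycle); without it every profile would be a rank-preserving
#'   shift of the same distribution, which no real cohort is.
#' @param dropout_midpoint,dropout_scale logistic non-amplification model:
#'   P(missing) = plogis((cq - midpoint) / scale) (defaults 36, 1.5 cycles).
#' @param n_always_low assays with chronically weak amplification, expected
#'   to fail the 10% filter (default 24); their baselines sit past the
#'   dropout midpoint (37 +/- 0.5 cycles) so they stay >10% missing even
#'   after replicate averaging.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mirnas = 167, n_endogenous = 3, n_spikein = 3,
                             group_sizes = c(`108` = 21, `120` = 158,
                                             `144` = 21),
                             n_failed = 50,
                             replicates_per_patient = 2:3,
                             baseline_cq_mean = 27.0, baseline_cq_sd = 3.0,
                             n_informative = 21, effect_size_cycles = 1.0,
                             replicate_noise_sd = 0.3, patient_sd = 0.5,
                             biological_sd = 1.0,
                             dropout_midpoint = 36, dropout_scale = 1.5,
                             n_always_low = 24, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("n_mirnas", "n_endogenous", "n_spikein")]) > 0),
            all(group_sizes > 0), n_failed >= 0,
            n_informative + n_always_low <= n_mirnas,
            effect_size_cycles >= 0)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic Cq-profile cohort
#'
#' Per patient, true per-assay expression is `baseline + class shift
#' (informative miRNAs only) + patient effect`; each technical replicate adds
#' Gaussian noise, and every well may fail to amplify with probability
#' `plogis((cq - dropout_midpoint) / dropout_scale)` — dropouts concentrate
#' in weakly expressed (high-Cq) assays, the mechanism the amplification
#' filter exists for. Class shifts are symmetric around the 120 h baseline:
#' half of the informative miRNAs go up toward 144 h and down toward 108 h,
#' the other half the reverse, so the ordinal score axis is well-specified.
#' Endogenous controls are near-constant; spike-ins are constant plus noise.
#' Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @return list: `profiles` ([cq_profile_set()]), `metadata` (data.frame as
#'   from [read_metadata()]), `ground_truth` (informative ids, per-class
#'   shifts, always-low ids).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(config$seed))

  n_pat <- sum(config$group_sizes)
  patient_ids <- sprintf("P%03d", seq_len(n_pat))
  labels <- rep(as.integer(names(config$group_sizes)), config$group_sizes)
  labels <- labels[sample.int(n_pat)]   # shuffle class order over ids

  mirna_ids <- sprintf("hsa-mir-syn-%03d", seq_len(config$n_mirnas))
  endo_ids <- c("RNU6B", "RNU43", "18s-rRNA")[seq_len(config$n_endogenous)]
  spike_ids <- sprintf("spike-in-%d", seq_len(config$n_spikein))
  assay_ids <- c(mirna_ids, endo_ids, spike_ids)
  roles <- stats::setNames(c(rep("target", config$n_mirnas),
                             rep("endogenous_control", config$n_endogenous),
                             rep("spike_in", config$n_spikein)), assay_ids)

  # chronically low-amplification assays sit near the dropout midpoint
  always_low <- sample(mirna_ids, config$n_always_low)
  informative <- sample(setdiff(mirna_ids, always_low), config$n_informative)
  baseline <- stats::rnorm(config$n_mirnas, config$baseline_cq_mean,
                           config$baseline_cq_sd)
  names(baseline) <- mirna_ids
  baseline <- pmin(pmax(baseline, 15), 34)   # keep routine assays amplifiable
  baseline[always_low] <- stats::rnorm(config$n_always_low, 37, 0.5)

  # symmetric ordinal shifts: sign +1 means Cq increases toward 144h
  shift_sign <- rep(c(1, -1), length.out = config$n_informative)
  shift_sign <- shift_sign[sample.int(config$n_informative)]
  names(shift_sign) <- informative
  # deltaCq added per class (columns 108/120/144)
  class_shift <- outer(shift_sign * config$effect_size_cycles, c(-1, 0, 1))
  colnames(class_shift) <- as.character(CLASS_HOURS)

  endo_base <- stats::setNames(c(20, 22, 14)[seq_along(endo_ids)], endo_ids)
  spike_base <- stats::setNames(24 + seq_along(spike_ids), spike_ids)

  n_rep <- sample(config$replicates_per_patient, n_pat, replace = TRUE,
                  prob = if (identical(config$replicates_per_patient, 2:3))
                    c(0.37, 0.63) else NULL)
  profile_ids <- unlist(lapply(seq_len(n_pat), function(i)
    sprintf("%s_r%d", patient_ids[i], seq_len(n_rep[i]))))
  patient_of_profile <- rep(patient_ids, n_rep)

  n_prof <- length(profile_ids)
  cq <- matrix(NA_real_, nrow = length(assay_ids), ncol = n_prof,
               dimnames = list(assay_ids, profile_ids))

  patient_effect <- stats::rnorm(n_pat, 0, config$patient_sd)
  truth <- matrix(rep(baseline, n_pat), ncol = n_pat,
                  dimnames = list(mirna_ids, patient_ids))
  truth <- sweep(truth, 2, patient_effect, "+")
  truth <- truth + stats::rnorm(length(truth), 0, config$biological_sd)
  truth[informative, ] <- truth[informative, ] +
    class_shift[, as.character(labels), drop = FALSE]

  col_pat <- match(patient_of_profile, patient_ids)
  mir_vals <- truth[, col_pat, drop = FALSE] +
    stats::rnorm(config$n_mirnas * n_prof, 0, config$replicate_noise_sd)
  drop_p <- stats::plogis((mir_vals - config$dropout_midpoint) /
                          config$dropout_scale)
  dropped <- matrix(stats::runif(length(drop_p)) < drop_p, nrow = nrow(drop_p))
  mir_vals[dropped] <- NA_real_
  mir_vals[!is.na(mir_vals) & mir_vals <= 0] <- 0.1
  cq[mirna_ids, ] <- mir_vals
  cq[endo_ids, ] <- matrix(rep(endo_base, n_prof), ncol = n_prof) +
    stats::rnorm(length(endo_ids) * n_prof, 0, 0.15)
  cq[spike_ids, ] <- matrix(rep(spike_base, n_prof), ncol = n_prof) +
    stats::rnorm(length(spike_ids) * n_prof, 0, 0.1)

  profiles <- cq_profile_set(cq, roles,
                             patient_of_profile = stats::setNames(
                               patient_of_profile, profile_ids))

  # failed-implantation patients: keep at least the successful-cohort class
  # counts (20/116/14) available for the paper-shaped splits
  success <- rep(TRUE, n_pat)
  if (config$n_failed > 0) {
    if (config$n_failed >= n_pat)
      stop("n_failed must leave at least one successful patient")
    min_success <- c(`108` = 20, `120` = 116, `144` = 14)
    reserve <- pmin(min_success[as.character(CLASS_HOURS)],
                    table(factor(labels, levels = CLASS_HOURS)))
    if (sum(labels %in% CLASS_HOURS) - sum(reserve) < config$n_failed) {
      # small cohorts: fall back to a proportional reservation
      reserve <- floor(table(factor(labels, levels = CLASS_HOURS)) *
                         (n_pat - config$n_failed) / n_pat)
    }
    avail <- unlist(lapply(seq_along(CLASS_HOURS), function(i) {
      ii <- which(labels == CLASS_HOURS[i])
      n_spare <- max(length(ii) - reserve[[i]], 0)
      ii[sample.int(length(ii), min(n_spare, length(ii)))]
    }))
    if (length(avail) < config$n_failed)
      stop("not enough spare patients to mark as failed implantation")
    failed <- avail[sample.int(length(avail), config$n_failed)]
    success[failed] <- FALSE
  }
  n_pif <- stats::rpois(n_pat, lambda = ifelse(success, 0.4, 1.2))

  metadata <- data.frame(patient_id = patient_ids, label = labels,
                         implantation_success = success, n_pif = n_pif,
                         age = round(stats::rnorm(n_pat, 37, 4), 1),
                         bmi = round(stats::rnorm(n_pat, 22, 3), 1),
                         stringsAsFactors = FALSE)

  list(profiles = profiles, metadata = metadata,
       ground_truth = list(informative = informative,
                           shift_sign = shift_sign,
                           class_shift = class_shift,
                           always_low = always_low,
                           baseline = baseline))
}

#' Draw training/testing splits with the reported class layout
#'
#' From the successful-implantation patients, draws a 115-patient training
#' set with class sizes 12/91/12 (108/120/144 h) and a 35-patient testing set
#' with class sizes 8/25/2, disjoint by construction.
#'
#' @param cohort list from [generate_cohort()].
#' @param seed RNG seed for the draw.
#' @return list `train`, `test` (character vectors of patient ids).
#' @export
make_paper_shaped_splits <- function(cohort, seed = 1L) {
  meta <- cohort$metadata
  ok <- meta[!is.na(meta$implantation_success) & meta$implantation_success, ]
  want_train <- c(`108` = 12, `120` = 91, `144` = 12)
  want_test <- c(`108` = 8, `120` = 25, `144` = 2)
  set.seed(as.integer(seed))
  train <- character(0); test <- character(0)
  for (cl in names(want_train)) {
    ids <- ok$patient_id[ok$label == as.integer(cl)]
    need <- want_train[[cl]] + want_test[[cl]]
    if (length(ids) < need)
      stop(sprintf("class %s h has %d successful patients; %d needed",
                   cl, length(ids), need))
    pick <- ids[sample.int(length(ids), need)]
    train <- c(train, pick[seq_len(want_train[[cl]])])
    test <- c(test, pick[want_train[[cl]] + seq_len(want_test[[cl]])])
  }
  list(train = train, test = test)
}

#' Write a synthetic cohort in the package's input formats
#'
#' Emits the Cq table, roles file, and metadata table that [read_cq_table()]
#' and [read_metadata()] consume, plus the generator ground truth as JSON.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"tsv"` (default) or `"csv"`.
#' @return invisible named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  paths <- c(cq = file.path(dir, paste0("cq_table.", ext)),
             roles = file.path(dir, paste0("assay_roles.", ext)),
             metadata = file.path(dir, paste0("metadata.", ext)),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_cq_table(cohort$profiles, paths[["cq"]], roles_path = paths[["roles"]])
  write_metadata(cohort$metadata, paths[["metadata"]])
  gt <- cohort$ground_truth
  gt$class_shift <- list(mirna_id = rownames(gt$class_shift),
                         hours = colnames(gt$class_shift),
                         values = unname(gt$class_shift))
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
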