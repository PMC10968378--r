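# small in-code fixtures shared across test files

# a toy profile set: `n_assay` targets + 1 endogenous + 1 spike-in control,
# `patients` patients with `reps` replicates each
toy_profiles <- function(n_assay = 4, patients = c("P1", "P2"), reps = 2,
                         seed = 42) {
  set.seed(seed)
  assays <- c(paste0("mir-", seq_len(n_assay)), "RNU6B", "spike-1")
  roles <- c(rep("target", n_assay), "endogenous_control", "spike_in")
  prof <- unlist(lapply(patients, function(p) paste0(p, "_r", seq_len(reps))))
  cq <- matrix(round(runif(length(assays) * length(prof), 20, 30), 3),
               nrow = length(assays), dimnames = list(assays, prof))
  cq_profile_set(cq, stats::setNames(roles, assays),
                 patient_of_profile = stats::setNames(rep(patients, each = reps),
                                                      prof))
}

# raw-stage feature matrix straight from a numeric matrix
fm_raw <- function(values) feature_matrix(values, "raw_mean")

# the printed training / testing confusion matrices (rows = predicted)
table2_training <- function() as_confusion_matrix3(rbind(c(9, 1, 0),
                                                         c(3, 89, 2),
                                                         c(0, 1, 10)))
table2_testing <- function() as_confusion_matrix3(rbind(c(7, 1, 0),
                                                        c(1, 23, 1),
                                                        c(0, 1, 1)))

# reduced CV grid used wherever full training runs would blow the time budget
small_grid <- list(alphas = c(0, 0.5, 1), variance_targets = c(0.8, 0.9),
                   n_lam = 12, lam_decades = 3)

train_small <- function(fm, labels, seed) {
  train_classifier(fm, labels, seed = seed,
                   alphas = small_grid$alphas,
                   variance_targets = small_grid$variance_targets,
                   n_lam = small_grid$n_lam,
                   lam_decades = small_grid$lam_decades)
}
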