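# Shared fixtures: all synthetic, generated in code at test time.

# Gaussian blobs with known labels
make_blobs <- function(n_per = 10, centers = rbind(c(0, 0), c(10, 10)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[c, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# A short sinusoidal test recording on the full 32-channel montage
sine_recording <- function(freq, amp = 10, fs = 500, duration = 10,
                           subject = "T01") {
  n <- fs * duration
  x <- amp * sin(2 * pi * freq * seq_len(n) / fs)
  session_recording(subject, 1L, matrix(rep(x, each = 32), nrow = 32),
                    eeg_montage(), fs)
}

# Phenotype -> fitted-cluster mapping by majority vote over subjects
phenotype_cluster_map <- function(cohort, profiles) {
  ph <- cohort$truths$phenotype_id[match(profiles$subject_id,
                                         cohort$truths$subject_id)]
  tab <- table(ph, profiles$hard_cluster)
  apply(tab, 1, which.max)
}

# One labeling run on a fresh default cohort; returns pieces used by the
# recovery and null-cohort checks
run_labeling <- function(seed, config = cohort_config()) {
  cohort <- generate_cohort(config, seed = seed)
  model <- fcm_fit(feature_matrix(cohort), k = 4, seed = seed)
  profiles <- average_subject_membership(model$memberships,
                                         cohort$features$subject_id)
  res <- label_responders(profiles, cohort$behavior, cohort$covariates)
  list(cohort = cohort, profiles = profiles, result = res,
       map = phenotype_cluster_map(cohort, profiles))
}

# TRUE when the planted positive and negative phenotype clusters both carry
# the right verdict somewhere and never the opposite one
planted_labels_recovered <- function(run) {
  lab <- run$result$labels
  cls <- run$map
  pos <- lab[lab$cluster == cls[["2"]], "verdict"]
  neg <- lab[lab$cluster == cls[["3"]], "verdict"]
  any(pos == "positive") && !any(pos == "negative") &&
    any(neg == "negative") && !any(neg == "positive")
}
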