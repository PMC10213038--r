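#' Hold-out validation of the clustering stage
#'
#' Repeated (fold-wise) 80/20-style hold-out: the model is fitted on a random
#' train fraction, every held-out sample is assigned to its nearest prototype
#' (Euclidean), and the assignments are compared to a full-data fit after
#' best label matching. On well-separated data the agreement approaches 1.
#'
#' @param X samples x features matrix.
#' @param algorithm `"fcm"` or `"spectral"`.
#' @param k number of clusters.
#' @param frac train fraction in (0, 1) (default 0.8).
#' @param folds number of random splits (default 20).
#' @param seed integer seed.
#' @param ... passed to the fitting function.
#' @return List of class `holdout_report`: `frac`, `folds`, `agreement`
#'   (per-fold test agreement with the full fit), `mean_agreement`,
#'   `train_validity` / `test_validity` (per-fold index tables).
#' @export
clustering_holdout <- function(X, algorithm = c("spectral", "fcm"), k = 4,
                               frac = 0.8, folds = 20, seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  n <- nrow(X)
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  n_train <- floor(frac * n)
  if (n_train < k) stop("train split smaller than k")
  if (n_train >= n) stop("empty test split")
  fit <- function(Xs, s) switch(algorithm,
                                fcm = fcm_fit(Xs, k, seed = s, ...),
                                spectral = spectral_fit(Xs, k, seed = s, ...))
  full <- fit(X, derive_seed(seed, "full"))
  agreement <- numeric(folds)
  train_vi <- test_vi <- vector("list", folds)
  for (f in seq_len(folds)) {
    set.seed(derive_seed(seed, "fold", f))
    tr <- sample.int(n, n_train)
    te <- setdiff(seq_len(n), tr)
    model <- fit(X[tr, , drop = FALSE], derive_seed(seed, "foldfit", f))
    mp <- match_labels(model$hard_labels, full$hard_labels[tr], k)
    test_assign <- nearest_prototype(X[te, , drop = FALSE], model$prototypes)
    agreement[f] <- mean(mp$mapping[test_assign] == full$hard_labels[te])
    train_vi[[f]] <- validity_indices(X[tr, , drop = FALSE],
                                      model$hard_labels, model$prototypes)
    all_assign <- integer(n)
    all_assign[tr] <- model$hard_labels
    all_assign[te] <- test_assign
    test_vi[[f]] <- validity_indices(X, all_assign, model$prototypes)
  }
  structure(list(frac = frac, folds = folds, algorithm = algorithm, k = k,
                 agreement = agreement, mean_agreement = mean(agreement),
                 train_validity = do.call(rbind, lapply(train_vi, as.data.frame)),
                 test_validity = do.call(rbind, lapply(test_vi, as.data.frame))),
            class = "holdout_report")
}

#' Nearest-prototype assignment
#'
#' @param X samples x features matrix.
#' @param prototypes k x features matrix.
#' @return Integer vector of nearest (Euclidean) prototype indices.
#' @export
nearest_prototype <- function(X, prototypes) {
  apply(pairwise_sqdist(as.matrix(X), as.matrix(prototypes)), 1, which.min)
}

#' Repeated hold-out robustness of the correlational analysis
#'
#' For each subsample fraction, draws `M` subject-level subsamples without
#' replacement (stratified by stimulation group by default; all sessions of
#' a subject move together since the analysis is subject-level), reruns the
#' partial Spearman correlation and the members-vs-rest rank-sum test on
#' each, and summarizes the distribution of coefficients, p-values, and the
#' mean absolute vertical distance of the subsample points to the full-data
#' least-squares line of delta versus membership.
#'
#' @param profiles subject profiles ([average_subject_membership()]).
#' @param behavior,covariates as in [label_responders()].
#' @param endpoints data.frame with columns `cluster`, `group`,
#'   `concurrency`, `task`, `metric` selecting the analyses to resample
#'   (e.g. the significant rows of a full [label_responders()] run).
#' @param fractions subsample fractions (default 0.8, 0.6, 0.4; 1 reproduces
#'   the full-data run with zero spread).
#' @param M number of repeats per fraction (default 1000).
#' @param seed integer seed.
#' @param outlier_sd outlier threshold in SDs.
#' @param stratify_by_group preserve group proportions in subsamples.
#' @return List of class `robustness_report`: `summary` (data.frame with
#'   mean/SD of rho, correlation p, Wilcoxon p and fit-line distance per
#'   fraction x endpoint) and `full` (full-data reference values).
#' @export
correlation_holdout <- function(profiles, behavior, covariates, endpoints,
                                fractions = c(0.8, 0.6, 0.4), M = 1000,
                                seed = 1, outlier_sd = 2.5,
                                stratify_by_group = TRUE) {
  deltas <- compute_deltas(behavior)
  deltas <- merge(deltas, covariates, by = "subject_id")
  cov_enc <- covariates
  cov_enc$sex01 <- as.integer(cov_enc$sex == "male")

  prep_endpoint <- function(ep) {
    d <- deltas[deltas$group == ep$group & deltas$concurrency == ep$concurrency &
                  deltas$task == ep$task & deltas$metric == ep$metric, ]
    d <- d[outlier_mask(d$delta, outlier_sd), ]
    m <- merge(d, profiles, by = "subject_id")
    m <- merge(m, cov_enc[, c("subject_id", "sex01")], by = "subject_id")
    m$u <- m[[paste0("u_", ep$cluster)]]
    m
  }
  analyze <- function(m, cluster) {
    Z <- as.matrix(m[, c("age", "sex01", "iq", "handedness")])
    cs <- tryCatch(partial_spearman(m$u, m$delta, Z),
                   error = function(e) list(rho = NA_real_, p = NA_real_))
    wt <- tryCatch(wilcoxon_members_vs_rest(m$delta, m$hard_cluster, cluster),
                   error = function(e) list(p = NA_real_))
    list(rho = cs$rho, p_corr = cs$p, p_wilcoxon = wt$p)
  }

  summary_rows <- list()
  full_rows <- list()
  for (ei in seq_len(nrow(endpoints))) {
    ep <- endpoints[ei, ]
    m_full <- prep_endpoint(ep)
    n_full <- nrow(m_full)
    if (n_full < 7) stop("endpoint has too few subjects for the hold-out")
    full_res <- analyze(m_full, ep$cluster)
    line <- stats::lm(delta ~ u, data = m_full)
    full_rows[[ei]] <- cbind(ep, data.frame(rho = full_res$rho,
                                            p_corr = full_res$p_corr,
                                            p_wilcoxon = full_res$p_wilcoxon,
                                            n = n_full))
    for (frac in fractions) {
      n_sub <- round(frac * n_full)
      if (n_sub < 7) stop("subsample fraction ", frac, " leaves too few subjects")
      rho <- p_corr <- p_wil <- dist_line <- numeric(M)
      for (r in seq_len(M)) {
        set.seed(derive_seed(seed, "holdout", ep$cluster, ep$task, ep$metric,
                             round(100 * frac), r))
        idx <- if (frac >= 1) seq_len(n_full)
        else if (stratify_by_group) {
          unlist(lapply(split(seq_len(n_full), m_full$group), function(ii) {
            ns <- round(frac * length(ii))
            sample(ii, max(min(ns, length(ii)), 1))
          }))
        } else sample.int(n_full, n_sub)
        ms <- m_full[idx, ]
        res <- analyze(ms, ep$cluster)
        rho[r] <- res$rho; p_corr[r] <- res$p_corr; p_wil[r] <- res$p_wilcoxon
        dist_line[r] <- mean(abs(ms$delta - stats::predict(line, ms)))
      }
      summary_rows[[length(summary_rows) + 1L]] <- cbind(
        ep, data.frame(
          fraction = frac, M = M,
          rho_mean = mean(rho, na.rm = TRUE), rho_sd = stats::sd(rho[!is.na(rho)]),
          abs_rho_mean = mean(abs(rho), na.rm = TRUE),
          p_corr_mean = mean(p_corr, na.rm = TRUE),
          p_corr_sd = stats::sd(p_corr[!is.na(p_corr)]),
          p_wilcoxon_mean = mean(p_wil, na.rm = TRUE),
          p_wilcoxon_sd = stats::sd(p_wil[!is.na(p_wil)]),
          dist_mean = mean(dist_line), dist_sd = stats::sd(dist_line)))
    }
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 full = do.call(rbind, full_rows),
                 fractions = fractions, M = M, seed = seed),
            class = "robustness_report")
}

#' Baseline structure check across clusters
#'
#' Kruskal-Wallis test per behavioral endpoint of the pre-treatment baseline
#' values across hard clusters: on cohorts without a planted baseline
#' confound the null should be retained, mirroring the absence of cluster
#' structure in baseline behavior.
#'
#' @param baseline data.frame with `subject_id`, `task`, `metric`, `value`
#'   (e.g. the `stimulation == "baseline"` rows of the behavioral table).
#' @param profiles subject profiles with `subject_id` and `hard_cluster`.
#' @param alpha significance level reported alongside.
#' @param min_cluster clusters with fewer subjects are excluded (logged).
#' @return data.frame per endpoint: `task`, `metric`, `statistic`, `df`,
#'   `p`, `n_clusters`, `skipped` (TRUE when fewer than 2 usable clusters).
#' @export
baseline_structure_check <- function(baseline, profiles, alpha = 0.05,
                                     min_cluster = 2) {
  m <- merge(baseline, profiles[, c("subject_id", "hard_cluster")],
             by = "subject_id")
  rows <- lapply(split(m, interaction(m$task, m$metric, drop = TRUE)),
                 function(ep) {
    sizes <- table(ep$hard_cluster)
    keep_clusters <- names(sizes)[sizes >= min_cluster]
    ep <- ep[ep$hard_cluster %in% keep_clusters, ]
    if (length(keep_clusters) < 2) {
      message("baseline check skipped for ", ep$task[1], "/", ep$metric[1],
              ": fewer than 2 usable clusters")
      return(data.frame(task = ep$task[1], metric = ep$metric[1],
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        n_clusters = length(keep_clusters), skipped = TRUE))
    }
    kt <- stats::kruskal.test(ep$value, factor(ep$hard_cluster))
    data.frame(task = ep$task[1], metric = ep$metric[1],
               statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value,
               n_clusters = length(keep_clusters), skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
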