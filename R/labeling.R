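#' Active-sham behavioral differences
#'
#' One delta per subject x task x metric x concurrency:
#' `value(active) - value(sham)`, computed independently for concurrent and
#' non-concurrent trials. Subjects missing either arm of an endpoint are
#' excluded from that endpoint (counted in the `excluded` attribute).
#' Baseline rows (stimulation `"baseline"`) are ignored.
#'
#' @param records behavioral data.frame with columns `subject_id`, `task`,
#'   `metric`, `stimulation`, `concurrency`, `value`.
#' @return data.frame: `subject_id`, `task`, `metric`, `concurrency`,
#'   `delta`.
#' @export
compute_deltas <- function(records) {
  stopifnot(all(c("subject_id", "task", "metric", "stimulation",
                  "concurrency", "value") %in% names(records)))
  rec <- records[records$stimulation %in% c("active", "sham"), ]
  key <- interaction(rec$subject_id, rec$task, rec$metric, rec$concurrency,
                     drop = TRUE)
  pieces <- split(rec, key)
  n_excluded <- 0L
  rows <- lapply(pieces, function(p) {
    a <- p$value[p$stimulation == "active"]
    s <- p$value[p$stimulation == "sham"]
    if (length(a) != 1 || length(s) != 1) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    data.frame(subject_id = p$subject_id[1], task = p$task[1],
               metric = p$metric[1], concurrency = p$concurrency[1],
               delta = a - s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  attr(out, "excluded") <- n_excluded
  out
}

#' Outlier mask at +/- c standard deviations
#'
#' Single-pass rule: values outside `mean +/- c * sd` of the endpoint's
#' deltas are dropped. When the standard deviation is zero (all values
#' equal) every value is kept.
#'
#' @param x numeric vector.
#' @param c threshold in standard deviations (default 2.5; `Inf` keeps all).
#' @return Logical vector, TRUE = keep.
#' @export
outlier_mask <- function(x, c = 2.5) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(x)))
  abs(x - mean(x)) <= c * s
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both ranked vectors on an
#' intercept plus the covariate matrix `Z` by least squares, and returns the
#' Pearson correlation of the residuals. With `Z = NULL` this reduces to the
#' ordinary Spearman correlation. The p-value uses the t distribution with
#' `n - 2 - ncol(Z)` degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors.
#' @param Z optional numeric covariate matrix/data.frame (rows match `x`).
#' @return List with `rho`, `p`, `n`, `df`; `rho` is NA when either ranked
#'   vector is constant.
#' @export
partial_spearman <- function(x, y, Z = NULL) {
  n <- length(x)
  q <- if (is.null(Z)) 0L else ncol(as.matrix(Z))
  if (length(y) != n || (q > 0 && nrow(as.matrix(Z)) != n))
    stop("x, y and Z must have matching lengths")
  if (n < q + 3) stop("need at least ncol(Z) + 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, df = n - 2 - q))
  M <- cbind(rep(1, n), if (q > 0) as.matrix(Z))
  qr_m <- qr(M)
  rx <- qr.resid(qr_m, rx)
  ry <- qr.resid(qr_m, ry)
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - q
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' Benjamini-Hochberg step-up correction
#'
#' Adjusted p-values per the BH step-up procedure
#' (\eqn{\tilde p_{(i)} = \min_{j \ge i} m p_{(j)} / j}, clipped at 1) with
#' significance flags at level `q`.
#'
#' @param pvals numeric vector in \[0, 1\] (NAs propagate).
#' @param q FDR level (default 0.05).
#' @return List with `p_adj` and logical `significant`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, significant = !is.na(p_adj) & p_adj <= q)
}

#' Rank-sum Wilcoxon test
#'
#' Two-sided rank-sum test of `x` versus `y`: exact null enumeration when
#' the combined sample size is at most `exact_max` and there are no ties,
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_max combined-size cutoff for the exact test (default 12).
#' @return List with `statistic` (Mann-Whitney U of `x`) and `p`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- if (n <= exact_max && !ties) {
    stats::wilcox.test(x, y, exact = TRUE)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  }
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Draft responder verdicts from adjusted correlations
#'
#' For each significant (cluster, condition, endpoint) correlation:
#' *positive* when accuracy correlates positively or RT negatively with
#' cluster membership (better performance under active than sham for
#' high-membership subjects), *negative* for the reverse signs, and *non*
#' for every non-significant correlation.
#'
#' @param correlations data.frame with columns `metric`, `rho`,
#'   `significant`.
#' @return The input with a `verdict` column added.
#' @export
label_clusters <- function(correlations) {
  verdict <- rep("non", nrow(correlations))
  sig <- correlations$significant & !is.na(correlations$rho)
  acc <- correlations$metric == "accuracy"
  verdict[sig & ((acc & correlations$rho > 0) | (!acc & correlations$rho < 0))] <- "positive"
  verdict[sig & ((acc & correlations$rho < 0) | (!acc & correlations$rho > 0))] <- "negative"
  correlations$verdict <- verdict
  correlations
}

#' Wilcoxon comparison of cluster members versus the rest
#'
#' Rank-sum test of the deltas of cluster-`c` members against all other
#' subjects' deltas on the same endpoint.
#'
#' @param deltas numeric vector of per-subject deltas.
#' @param hard_clusters integer cluster per subject (same order).
#' @param c cluster under test.
#' @param exact_max see [rank_sum_test()].
#' @return List with `statistic`, `p`, `n_members`, `n_rest`.
#' @export
wilcoxon_members_vs_rest <- function(deltas, hard_clusters, c,
                                     exact_max = 12) {
  members <- deltas[hard_clusters == c]
  rest <- deltas[hard_clusters != c]
  if (!length(members) || !length(rest))
    stop("cluster ", c, " has an empty members or rest side")
  res <- rank_sum_test(members, rest, exact_max)
  c(res, list(n_members = length(members), n_rest = length(rest)))
}

#' Label phenotype clusters by tDCS response
#'
#' Full labeling stage. For every experimental condition (group x
#' concurrency) and endpoint (task x metric): pair subject-averaged cluster
#' memberships with active-sham deltas, remove per-endpoint outliers beyond
#' `outlier_sd` standard deviations, compute the partial Spearman correlation
#' adjusted for age, sex (0/1), IQ and handedness, and BH-correct within the
#' family of all cluster x endpoint tests of that group-condition matrix.
#' Clusters with at least one significant correlation are then confirmed by
#' a members-vs-rest rank-sum test on the same endpoint (BH-corrected within
#' the condition family); the verdict is kept only when both adjusted tests
#' pass.
#'
#' @param profiles data.frame from [average_subject_membership()]
#'   (`subject_id`, `u_1..u_k`, `hard_cluster`).
#' @param behavior behavioral records (see [compute_deltas()]).
#' @param covariates data.frame with `subject_id`, `group`, `age`, `sex`,
#'   `iq`, `handedness`.
#' @param alpha significance level for both adjusted tests (default 0.05).
#' @param outlier_sd outlier threshold in SDs (default 2.5).
#' @param exclude_subjects optional subject ids dropped before analysis.
#' @return List of class `responder_labels`: `correlations` (with `p_adj`,
#'   `significant`, draft `verdict`), `wilcoxon` (confirmation tests),
#'   `labels` (final verdict per cluster x condition x endpoint), and `log`
#'   (family sizes, exclusion counts).
#' @export
label_responders <- function(profiles, behavior, covariates, alpha = 0.05,
                             outlier_sd = 2.5, exclude_subjects = NULL) {
  k <- sum(grepl("^u_", names(profiles)))
  if (!is.null(exclude_subjects)) {
    profiles <- profiles[!(profiles$subject_id %in% exclude_subjects), ]
    behavior <- behavior[!(behavior$subject_id %in% exclude_subjects), ]
  }
  deltas <- compute_deltas(behavior)
  deltas <- merge(deltas, covariates, by = "subject_id")
  cov_enc <- covariates
  cov_enc$sex01 <- as.integer(cov_enc$sex == "male")

  conditions <- unique(deltas[, c("group", "concurrency")])
  corr_rows <- list()
  fam_sizes <- list()
  n_outliers <- 0L
  for (ci in seq_len(nrow(conditions))) {
    g <- conditions$group[ci]; cc <- conditions$concurrency[ci]
    cond <- deltas[deltas$group == g & deltas$concurrency == cc, ]
    fam <- list()
    for (ep in split(cond, interaction(cond$task, cond$metric, drop = TRUE))) {
      keep <- outlier_mask(ep$delta, outlier_sd)
      n_outliers <- n_outliers + sum(!keep)
      ep <- ep[keep, ]
      m <- merge(ep, profiles, by = "subject_id")
      m <- merge(m, cov_enc[, c("subject_id", "sex01")], by = "subject_id")
      Z <- as.matrix(m[, c("age", "sex01", "iq", "handedness")])
      for (c in seq_len(k)) {
        res <- tryCatch(partial_spearman(m[[paste0("u_", c)]], m$delta, Z),
                        error = function(e) list(rho = NA_real_, p = NA_real_,
                                                 n = nrow(m)))
        fam[[length(fam) + 1L]] <- data.frame(
          cluster = c, group = g, concurrency = cc,
          task = ep$task[1], metric = ep$metric[1],
          rho = res$rho, p_raw = res$p, n_subjects = res$n,
          stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, fam)
    adj <- bh_fdr(fam$p_raw, q = alpha)
    fam$p_adj <- adj$p_adj
    fam$significant <- adj$significant
    fam_sizes[[paste(g, cc, sep = "/")]] <- sum(!is.na(fam$p_raw))
    corr_rows[[ci]] <- fam
  }
  correlations <- label_clusters(do.call(rbind, corr_rows))

  # confirmation: members vs rest, only where a correlation is significant
  wil_rows <- list()
  sig <- correlations[correlations$significant %in% TRUE, ]
  if (nrow(sig)) {
    for (ci in seq_len(nrow(conditions))) {
      g <- conditions$group[ci]; cc <- conditions$concurrency[ci]
      fam <- sig[sig$group == g & sig$concurrency == cc, ]
      if (!nrow(fam)) next
      tests <- lapply(seq_len(nrow(fam)), function(i) {
        row <- fam[i, ]
        ep <- deltas[deltas$group == g & deltas$concurrency == cc &
                       deltas$task == row$task & deltas$metric == row$metric, ]
        ep <- ep[outlier_mask(ep$delta, outlier_sd), ]
        m <- merge(ep, profiles, by = "subject_id")
        wt <- tryCatch(
          wilcoxon_members_vs_rest(m$delta, m$hard_cluster, row$cluster),
          error = function(e) list(statistic = NA_real_, p = NA_real_,
                                   n_members = sum(m$hard_cluster == row$cluster),
                                   n_rest = sum(m$hard_cluster != row$cluster)))
        cbind(row[, c("cluster", "group", "concurrency", "task", "metric",
                      "verdict")],
              data.frame(statistic = wt$statistic, p_raw = wt$p,
                         n_members = wt$n_members, n_rest = wt$n_rest))
      })
      famw <- do.call(rbind, tests)
      adj <- bh_fdr(famw$p_raw, q = alpha)
      famw$p_adj <- adj$p_adj
      famw$significant <- adj$significant
      wil_rows[[length(wil_rows) + 1L]] <- famw
    }
  }
  wilcoxon <- if (length(wil_rows)) do.call(rbind, wil_rows) else NULL
  labels <- confirm_responders(correlations, wilcoxon)
  list(correlations = correlations, wilcoxon = wilcoxon, labels = labels,
       log = list(family_sizes = fam_sizes,
                  wilcoxon_family_sizes = if (is.null(wilcoxon)) list() else
                    table(paste(wilcoxon$group, wilcoxon$concurrency, sep = "/")),
                  n_outliers_removed = n_outliers,
                  n_missing_arm = attr(deltas, "excluded")),
       alpha = alpha)
}

#' Confirm responder verdicts with the rank-sum tests
#'
#' A draft verdict is retained only when both the adjusted correlation and
#' the adjusted members-vs-rest Wilcoxon test are significant; otherwise the
#' cluster is demoted to non-responder for that endpoint.
#'
#' @param correlations output of [label_clusters()] with `p_adj` and
#'   `significant`.
#' @param wilcoxon confirmation table (or NULL when no correlation was
#'   significant).
#' @return data.frame of final labels: `cluster`, `group`, `concurrency`,
#'   `task`, `metric`, `verdict`, `wilcoxon_p_adj`.
#' @export
confirm_responders <- function(correlations, wilcoxon = NULL) {
  out <- correlations[, c("cluster", "group", "concurrency", "task", "metric",
                          "verdict")]
  out$wilcoxon_p_adj <- NA_real_
  if (!is.null(wilcoxon) && nrow(wilcoxon)) {
    key <- function(d) paste(d$cluster, d$group, d$concurrency, d$task,
                             d$metric)
    idx <- match(key(out), key(wilcoxon))
    out$wilcoxon_p_adj <- wilcoxon$p_adj[idx]
    confirmed <- !is.na(idx) & wilcoxon$significant[idx]
  } else {
    confirmed <- rep(FALSE, nrow(out))
  }
  out$verdict[out$verdict != "non" & !confirmed] <- "non"
  rownames(out) <- NULL
  out
}
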