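test_that("FCM separates tight blobs, decreases its objective and reaches its fixed point", {
  blobs <- make_blobs(n_per = 15, sd = 0.3, seed = 3)
  fit <- fcm_fit(blobs$X, k = 2, seed = 5)
  expect_true(all(diff(fit$objective) <= 1e-8))
  own <- fit$memberships[cbind(seq_len(30), fit$hard_labels)]
  expect_true(all(own > 0.99))
  expect_equal(mclust::adjustedRandIndex(fit$hard_labels, blobs$labels), 1)
  # fixed point: memberships recomputed from the final centers agree
  D2 <- outer(rowSums(blobs$X^2), rowSums(fit$prototypes^2), "+") -
    2 * blobs$X %*% t(fit$prototypes)
  W <- pmax(D2, 1e-300)^(-1 / (1.7 - 1))
  expect_lt(max(abs(W / rowSums(W) - fit$memberships)), 1e-6)
  expect_lt(max(abs(rowSums(fit$memberships) - 1)), 1e-9)
})

test_that("FCM memberships flatten toward 1/k as m grows large", {
  blobs <- make_blobs(n_per = 10, sd = 1, seed = 7)
  dev <- vapply(c(1.7, 5, 10, 50), function(m)
    max(abs(fcm_fit(blobs$X, k = 2, m = m, seed = 1)$memberships - 0.5)),
    numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 0.05)
})

test_that("FCM agrees with an independent implementation on separated data", {
  blobs <- make_blobs(n_per = 12, centers = rbind(c(0, 0), c(8, 0), c(4, 7)),
                      sd = 0.4, seed = 11)
  fit <- fcm_fit(blobs$X, k = 3, m = 1.7, seed = 2)
  set.seed(2)
  ref <- e1071::cmeans(blobs$X, centers = 3, m = 1.7)
  ord <- apply(outer(rowSums(fit$prototypes^2), rowSums(ref$centers^2), "+") -
                 2 * fit$prototypes %*% t(ref$centers), 1, which.min)
  expect_equal(unname(fit$prototypes), unname(ref$centers[ord, ]),
               tolerance = 1e-3)
})

test_that("FCM validates its inputs", {
  X <- matrix(rnorm(10), 5)
  expect_error(fcm_fit(X, k = 2, m = 1), "m must be > 1")
  expect_error(fcm_fit(X, k = 6), "at least k samples")
})

test_that("spectral clustering splits blobs and is order invariant", {
  blobs <- make_blobs(n_per = 10, sd = 0.3, seed = 2)
  fit <- spectral_fit(blobs$X, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(fit$hard_labels, blobs$labels), 1)

  set.seed(99)
  perm <- sample(nrow(blobs$X))
  fit2 <- spectral_fit(blobs$X[perm, ], k = 2, seed = 1)
  expect_equal(match_labels(fit2$hard_labels, fit$hard_labels[perm])$agreement, 1)
})

test_that("spectral partition attains the brute-force minimum normalized cut", {
  blobs <- make_blobs(n_per = 6, centers = rbind(c(0, 0), c(5, 5)),
                      sd = 0.3, seed = 13)
  X <- blobs$X
  gamma <- 1 / ncol(X)
  A <- exp(-gamma * as.matrix(dist(X))^2) + 1e-12
  ncut <- function(members) {
    s <- seq_len(nrow(X)) %in% members
    cut <- sum(A[s, !s])
    cut / sum(A[s, ]) + cut / sum(A[!s, ])
  }
  best <- Inf; best_set <- NULL
  for (size in 1:6) {
    sets <- utils::combn(12, size)
    for (j in seq_len(ncol(sets))) {
      v <- ncut(sets[, j])
      if (v < best) { best <- v; best_set <- sets[, j] }
    }
  }
  fit <- spectral_fit(X, k = 2, seed = 1)
  expect_equal(sort(which(fit$hard_labels == fit$hard_labels[best_set[1]])),
               sort(best_set))
})

test_that("spectral clustering agrees with an independent implementation on blobs", {
  blobs <- make_blobs(n_per = 10, sd = 0.3, seed = 21)
  fit <- spectral_fit(blobs$X, k = 2, seed = 1)
  set.seed(1)
  ref <- as.integer(kernlab::specc(blobs$X, centers = 2))
  expect_equal(match_labels(fit$hard_labels, ref)$agreement, 1)
})

test_that("prototypes are cluster means and fail on empty clusters", {
  X <- rbind(c(0, 0), c(2, 0), c(10, 10))
  expect_equal(unname(prototypes_from_labels(X, c(1, 1, 2))),
               rbind(c(1, 0), c(10, 10)))
  expect_equal(unname(prototypes_from_labels(X, c(1, 2, 3))), unname(X))
  dup <- rbind(X, X)
  expect_equal(prototypes_from_labels(dup, rep(c(1, 1, 2), 2)),
               prototypes_from_labels(X, c(1, 1, 2)))
  expect_error(prototypes_from_labels(X, c(1, 1, 1), k = 2), "empty cluster")
})

test_that("inverse-distance memberships follow the probability rule", {
  protos <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  centerpoint <- matrix(c(2, 2), 1)
  expect_equal(as.vector(soft_membership_from_distance(centerpoint, protos)),
               rep(0.25, 4))
  onproto <- matrix(c(4, 0), 1)
  expect_equal(as.vector(soft_membership_from_distance(onproto, protos)),
               c(0, 1, 0, 0))
  two <- rbind(c(0, 0), c(3, 0))          # distances 1 and 2
  pt <- matrix(c(1, 0), 1)
  expect_equal(as.vector(soft_membership_from_distance(pt, two)),
               c(2 / 3, 1 / 3))
  expect_error(soft_membership_from_distance(pt, rbind(c(0, 0), c(0, 0))),
               "degenerate")
  sm <- soft_membership_from_distance(pt, two, method = "softmax", tau = 2)
  expect_equal(sum(sm), 1)
  expect_gt(sm[1], sm[2])
})

test_that("subject membership averaging preserves row-stochasticity", {
  U <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.5, 0.5))
  prof <- average_subject_membership(U, c("a", "a", "b", "b"))
  expect_equal(unname(as.matrix(prof[, c("u_1", "u_2")])),
               rbind(c(0.5, 0.5), c(0.5, 0.5)))
  set.seed(8)
  U4 <- matrix(rexp(4 * 3), 4); U4 <- U4 / rowSums(U4)
  prof4 <- average_subject_membership(U4, rep("s", 4))
  expect_equal(as.numeric(prof4[1, paste0("u_", 1:3)]), colMeans(U4))
  expect_equal(sum(prof4[1, paste0("u_", 1:3)]), 1, tolerance = 1e-9)
  expect_error(average_subject_membership(U, c("a", "a")), "one subject id")
})

test_that("argmax assignment picks the largest membership with low-index ties", {
  expect_equal(hard_assign(c(0.2, 0.3, 0.4, 0.1)), 3)
  expect_equal(hard_assign(c(1, 0)), 1)
  expect_equal(hard_assign(c(0.5, 0.5)), 1)
  expect_error(hard_assign(numeric(0)), "empty")
})

test_that("validity indices match brute-force formulas", {
  blobs <- make_blobs(n_per = 20, centers = rbind(c(0, 0), c(12, 0), c(6, 10)),
                      sd = 0.4, seed = 17)
  vi <- validity_indices(blobs$X, blobs$labels)
  expect_gt(vi$silhouette, 0.9)
  expect_equal(vi$silhouette, silhouette_bruteforce(blobs$X, blobs$labels),
               tolerance = 1e-12)
  # Davies-Bouldin via an independent direct computation
  centers <- prototypes_from_labels(blobs$X, blobs$labels)
  S <- vapply(1:3, function(c)
    mean(sqrt(colSums((t(blobs$X[blobs$labels == c, ]) - centers[c, ])^2))),
    numeric(1))
  M <- as.matrix(dist(centers))
  db <- mean(vapply(1:3, function(i)
    max(vapply(setdiff(1:3, i), function(j) (S[i] + S[j]) / M[i, j],
               numeric(1))), numeric(1)))
  expect_equal(vi$davies_bouldin, db, tolerance = 1e-12)
  # inertia is the within-cluster sum of squares
  expect_equal(vi$inertia,
               sum((blobs$X - centers[blobs$labels, ])^2), tolerance = 1e-12)
  expect_gte(vi$inertia, 0)
  expect_true(is.finite(vi$bic))
  expect_true(vi$silhouette >= -1 && vi$silhouette <= 1)
})

test_that("silhouette brute-force agreement holds on an unstructured cloud", {
  set.seed(23)
  X <- matrix(rnorm(60 * 4), 60)
  labels <- sample(1:3, 60, replace = TRUE)
  vi <- validity_indices(X, labels)
  expect_equal(vi$silhouette, silhouette_bruteforce(X, labels),
               tolerance = 1e-12)
})

test_that("k-means-style inertia is non-increasing in k on the same data", {
  set.seed(31)
  X <- matrix(rnorm(80 * 3), 80)
  inertia <- vapply(2:6, function(k) {
    set.seed(100)
    km <- kmeans(X, k, nstart = 10)
    validity_indices(X, km$cluster, km$centers)$inertia
  }, numeric(1))
  expect_true(all(diff(inertia) <= 1e-8))
})

test_that("the validity scan tabulates all configurations and suggests an elbow", {
  blobs <- make_blobs(n_per = 8,
                      centers = rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8)),
                      sd = 0.4, seed = 19)
  scan <- validity_scan(blobs$X, k_range = 2:6, seed = 1)
  expect_equal(nrow(scan$table), 10)
  expect_setequal(scan$elbow %in% 2:6, TRUE)
  expect_equal(unname(scan$elbow["fcm"]), 4)
  best <- scan$table[scan$table$algorithm == "spectral" & scan$table$k == 4, ]
  expect_gt(best$silhouette, 0.9)
  expect_error(validity_scan(blobs$X, k_range = 2:40), "k_range")
})

test_that("default cohorts are recovered at k = 4 by both algorithms", {
  coh <- generate_cohort(cohort_config(n_subjects = 40), seed = 41)
  X <- feature_matrix(coh)
  truth <- coh$truths$phenotype_id[match(coh$features$subject_id,
                                         coh$truths$subject_id)]
  for (algo in c("fcm", "spectral")) {
    fit <- switch(algo, fcm = fcm_fit(X, 4, seed = 1),
                  spectral = spectral_fit(X, 4, seed = 1))
    expect_gte(mclust::adjustedRandIndex(fit$hard_labels, truth), 0.9)
  }
  # intra-subject spread below between-phenotype centroid separation
  centroids <- rowsum(X, truth) / as.vector(table(truth))
  within <- mean(vapply(unique(coh$features$subject_id), function(s)
    mean(dist(X[coh$features$subject_id == s, ])), numeric(1)))
  between <- mean(dist(centroids))
  expect_lt(within, between)
})
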