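#' Fuzzy c-means clustering
#'
#' Alternating optimization of the fuzzy c-means objective
#' \eqn{J = \sum_{ic} u_{ic}^m d_{ic}^2} with fuzzification exponent `m`:
#' memberships \eqn{u_{ic} \propto (1/d_{ic})^{2/(m-1)}} (row-normalized) and
#' centers \eqn{v_c = \sum_i u_{ic}^m x_i / \sum_i u_{ic}^m}. A sample
#' coinciding with a center receives full membership there (standard
#' singularity rule). The objective is non-increasing across iterations.
#'
#' @param X numeric matrix, samples x features.
#' @param k number of clusters (>= 2).
#' @param m fuzzification exponent (> 1, default 1.7).
#' @param tol convergence tolerance on the maximum center displacement.
#' @param max_iter iteration cap.
#' @param seed integer seed for the random membership initialization.
#' @param nstart number of random restarts; the run with the lowest final
#'   objective is kept (guards against poor local optima of the alternating
#'   updates).
#' @return An object of class `cluster_model` with fields `algorithm`
#'   ("fcm"), `k`, `m`, `prototypes` (k x p), `memberships` (n x k,
#'   row-stochastic), `hard_labels`, `objective` (per-iteration trajectory),
#'   `iterations`, `seed`.
#' @export
fcm_fit <- function(X, k, m = 1.7, tol = 1e-6, max_iter = 300, seed = 1,
                    nstart = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (m <= 1) stop("fuzzification m must be > 1")
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- fcm_single(X, k, m, tol, max_iter,
                      if (r == 1) seed else derive_seed(seed, "restart", r))
    if (is.null(best) || utils::tail(fit$objective, 1) <
        utils::tail(best$objective, 1))
      best <- fit
  }
  best$seed <- seed
  best
}

fcm_single <- function(X, k, m, tol, max_iter, seed) {
  n <- nrow(X)
  set.seed(seed)
  U <- matrix(stats::rexp(n * k), n, k)
  U <- U / rowSums(U)
  centers <- NULL
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    Um <- U^m
    new_centers <- (t(Um) %*% X) / colSums(Um)
    D2 <- pairwise_sqdist(X, new_centers)
    obj <- c(obj, sum(Um * D2))
    U <- fcm_memberships(D2, m)
    if (!is.null(centers) && max(abs(new_centers - centers)) < tol) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  D2 <- pairwise_sqdist(X, centers)
  U <- fcm_memberships(D2, m)
  obj <- c(obj, sum(U^m * D2))
  new_cluster_model("fcm", k, list(m = m), centers, U, seed,
                    objective = obj, iterations = it)
}

# membership update from squared distances; zero-distance singularity rule
fcm_memberships <- function(D2, m) {
  n <- nrow(D2); k <- ncol(D2)
  U <- matrix(0, n, k)
  zero <- D2 <= .Machine$double.eps
  has0 <- rowSums(zero) > 0
  if (any(has0)) {
    U[has0, ] <- zero[has0, , drop = FALSE] / rowSums(zero[has0, , drop = FALSE])
  }
  if (any(!has0)) {
    W <- D2[!has0, , drop = FALSE]^(-1 / (m - 1))
    U[!has0, ] <- W / rowSums(W)
  }
  U
}

pairwise_sqdist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

new_cluster_model <- function(algorithm, k, params, prototypes, memberships,
                              seed, ...) {
  structure(
    c(list(algorithm = algorithm, k = k, params = params,
           prototypes = prototypes, memberships = memberships,
           hard_labels = apply(memberships, 1, which.max), seed = seed),
      list(...)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s, k=%d, n=%d, cluster sizes: %s\n",
              x$algorithm, x$k, nrow(x$memberships),
              paste(tabulate(x$hard_labels, x$k), collapse = "/")))
  invisible(x)
}

#' Spectral clustering with prototype-based soft memberships
#'
#' Normalized-Laplacian spectral clustering: RBF affinity
#' \eqn{A_{ij} = \exp(-\gamma \|x_i - x_j\|^2)} (with a small uniform floor
#' `eps` guaranteeing graph connectivity), symmetric normalization
#' \eqn{D^{-1/2} A D^{-1/2}}, embedding on the top `n_components`
#' eigenvectors with row normalization, and k-means (10 restarts, best
#' inertia) on the embedding. Prototypes are the feature-space means of each
#' cluster and soft memberships follow from inverse Euclidean distance to
#' them ([soft_membership_from_distance()]).
#'
#' @param X numeric matrix, samples x features.
#' @param k number of clusters.
#' @param n_components embedding dimension (default `k`).
#' @param seed integer seed for the k-means step.
#' @param gamma RBF width (default `1 / ncol(X)`).
#' @param eps uniform affinity floor.
#' @param nstart k-means restarts.
#' @return A `cluster_model` (`algorithm = "spectral"`).
#' @export
spectral_fit <- function(X, k, n_components = k, seed = 1,
                         gamma = 1 / ncol(X), eps = 1e-12, nstart = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("need at least k samples")
  A <- exp(-gamma * pairwise_sqdist(X, X)) + eps
  d <- rowSums(A)
  M <- A / sqrt(outer(d, d))
  eg <- eigen(M, symmetric = TRUE)
  emb <- eg$vectors[, seq_len(n_components), drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  norms[norms == 0] <- 1
  emb <- emb / norms
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  prototypes <- prototypes_from_labels(X, labels)
  U <- soft_membership_from_distance(X, prototypes)
  model <- new_cluster_model("spectral", k,
                             list(n_components = n_components, gamma = gamma),
                             prototypes, U, seed)
  model$hard_labels <- labels                 # k-means partition, not argmax
  model
}

#' Cluster prototypes from hard labels
#'
#' Prototype of cluster c is the mean of the samples assigned to c.
#'
#' @param X samples x features matrix.
#' @param labels integer labels in 1..k.
#' @param k number of clusters (default `max(labels)`).
#' @return k x features matrix.
#' @export
prototypes_from_labels <- function(X, labels, k = max(labels)) {
  X <- as.matrix(X)
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) stop("empty cluster: ", which(sizes == 0)[1])
  rowsum(X, labels) / sizes
}

#' Soft membership as a probability function of Euclidean distance
#'
#' Default rule: \eqn{u_{ic} = (1/d_{ic}) / \sum_{c'} (1/d_{ic'})} with
#' Euclidean distance to the prototypes; a point coinciding with a prototype
#' receives membership 1 there. A softmax alternative
#' \eqn{u_{ic} \propto \exp(-d_{ic}^2/\tau)} is available behind
#' `method = "softmax"`.
#'
#' @param X samples x features matrix.
#' @param prototypes k x features matrix (rows distinct).
#' @param method "inverse" (default) or "softmax".
#' @param tau temperature of the softmax variant.
#' @return n x k row-stochastic membership matrix.
#' @export
soft_membership_from_distance <- function(X, prototypes,
                                          method = c("inverse", "softmax"),
                                          tau = 1) {
  method <- match.arg(method)
  X <- as.matrix(X); prototypes <- as.matrix(prototypes)
  if (nrow(prototypes) > 1 &&
      min(stats::dist(prototypes)) <= .Machine$double.eps)
    stop("degenerate (coincident) prototypes")
  D2 <- pairwise_sqdist(X, prototypes)
  if (method == "softmax") {
    W <- exp(-(D2 - apply(D2, 1, min)) / tau)
    return(W / rowSums(W))
  }
  D <- sqrt(D2)
  U <- matrix(0, nrow(D), ncol(D))
  zero <- D <= .Machine$double.eps
  has0 <- rowSums(zero) > 0
  if (any(has0))
    U[has0, ] <- zero[has0, , drop = FALSE] / rowSums(zero[has0, , drop = FALSE])
  if (any(!has0)) {
    W <- 1 / D[!has0, , drop = FALSE]
    U[!has0, ] <- W / rowSums(W)
  }
  U
}

#' Average session memberships into one profile per subject
#'
#' The subject profile is the arithmetic mean of that subject's session
#' membership rows (still row-stochastic); the hard cluster is its argmax.
#'
#' @param memberships n_sessions x k row-stochastic matrix.
#' @param subject_ids character vector, one id per membership row.
#' @return data.frame: `subject_id`, `u_1..u_k`, `hard_cluster`.
#' @export
average_subject_membership <- function(memberships, subject_ids) {
  memberships <- as.matrix(memberships)
  if (length(subject_ids) != nrow(memberships))
    stop("one subject id per membership row is required")
  ids <- unique(subject_ids)
  avg <- rowsum(memberships, factor(subject_ids, levels = ids)) /
    as.vector(table(factor(subject_ids, levels = ids)))
  out <- data.frame(subject_id = ids, avg, stringsAsFactors = FALSE,
                    check.names = FALSE)
  colnames(out) <- c("subject_id", paste0("u_", seq_len(ncol(avg))))
  out$hard_cluster <- apply(avg, 1, hard_assign)
  out
}

#' Hard cluster assignment by argmax
#'
#' Index of the largest membership value; ties are broken toward the lowest
#' index. E.g. memberships (0.2, 0.3, 0.4, 0.1) assign to cluster 3.
#'
#' @param membership_vector numeric membership vector.
#' @return Integer cluster index.
#' @export
hard_assign <- function(membership_vector) {
  if (!length(membership_vector)) stop("empty membership vector")
  which.max(membership_vector)
}

# ---- internal validity indices ------------------------------------------

#' Internal cluster validity indices
#'
#' Silhouette (mean width; singleton clusters contribute 0), Davies-Bouldin,
#' Calinski-Harabasz, a spherical-Gaussian BIC (useful only for relative
#' comparison across k) and inertia (within-cluster sum of squared distances
#' to the prototypes).
#'
#' @param X samples x features matrix.
#' @param labels integer hard labels 1..k.
#' @param prototypes optional k x features matrix (defaults to label means).
#' @return Named list: `silhouette`, `davies_bouldin`, `calinski_harabasz`,
#'   `bic`, `inertia`.
#' @export
validity_indices <- function(X, labels, prototypes = NULL) {
  X <- as.matrix(X)
  k <- max(labels)
  if (is.null(prototypes)) prototypes <- prototypes_from_labels(X, labels, k)
  D2 <- pairwise_sqdist(X, prototypes)
  inertia <- sum(D2[cbind(seq_len(nrow(X)), labels)])
  sil <- if (k >= 2 && k < nrow(X)) {
    mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  } else NA_real_
  list(silhouette = sil,
       davies_bouldin = davies_bouldin(X, labels, prototypes),
       calinski_harabasz = calinski_harabasz(X, labels, prototypes),
       bic = spherical_bic(X, labels, inertia),
       inertia = inertia)
}

davies_bouldin <- function(X, labels, centers) {
  k <- nrow(centers)
  S <- vapply(seq_len(k), function(c) {
    idx <- labels == c
    mean(sqrt(rowSums((X[idx, , drop = FALSE] -
                         matrix(centers[c, ], sum(idx), ncol(X), byrow = TRUE))^2)))
  }, numeric(1))
  Dc <- sqrt(pairwise_sqdist(centers, centers))
  mean(vapply(seq_len(k), function(i) {
    r <- (S[i] + S[-i]) / Dc[i, -i]
    max(r)
  }, numeric(1)))
}

calinski_harabasz <- function(X, labels, centers) {
  n <- nrow(X); k <- nrow(centers)
  gm <- colMeans(X)
  sizes <- tabulate(labels, k)
  B <- sum(sizes * rowSums((centers - matrix(gm, k, ncol(X), byrow = TRUE))^2))
  W <- sum((X - centers[labels, , drop = FALSE])^2)
  (B / (k - 1)) / (W / (n - k))
}

# BIC under a spherical-Gaussian per-cluster model with a shared variance;
# penalty (k*d + k - 1) * log(n).
spherical_bic <- function(X, labels, inertia) {
  n <- nrow(X); d <- ncol(X); k <- max(labels)
  if (n <= k) return(NA_real_)
  sizes <- tabulate(labels, k)
  sigma2 <- max(inertia / (d * (n - k)), .Machine$double.eps)
  ll <- sum(sizes * log(sizes / n)) - n * d / 2 * log(2 * pi * sigma2) -
    d * (n - k) / 2
  -2 * ll + (k * d + k - 1) * log(n)
}

#' Scan algorithms and cluster counts with validity indices
#'
#' Fits every (algorithm, k) combination and tabulates the five internal
#' validity indices on the hard labels, plus a simple elbow suggestion per
#' algorithm (maximum distance of the inertia curve to its end-to-end
#' chord). The suggestion is advisory only: the final k remains a
#' configuration input.
#'
#' @param X samples x features matrix.
#' @param algorithms subset of `c("fcm", "spectral")`.
#' @param k_range candidate cluster counts (default 2:6).
#' @param m FCM fuzzification exponent.
#' @param seed integer seed.
#' @return List with `table` (data.frame of indices per configuration) and
#'   `elbow` (named integer suggestion per algorithm).
#' @export
validity_scan <- function(X, algorithms = c("fcm", "spectral"),
                          k_range = 2:6, m = 1.7, seed = 1) {
  X <- as.matrix(X)
  if (max(k_range) > nrow(X) - 1) stop("k_range must stay within [2, N-1]")
  rows <- list()
  for (algo in algorithms) {
    for (k in k_range) {
      model <- switch(algo,
                      fcm = fcm_fit(X, k, m = m, seed = seed),
                      spectral = spectral_fit(X, k, seed = seed))
      vi <- validity_indices(X, model$hard_labels, model$prototypes)
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = algo, k = k,
                   silhouette = vi$silhouette,
                   davies_bouldin = vi$davies_bouldin,
                   calinski_harabasz = vi$calinski_harabasz,
                   bic = vi$bic, inertia = vi$inertia,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  elbow <- vapply(algorithms, function(algo) {
    sub <- tab[tab$algorithm == algo, ]
    elbow_point(sub$k, sub$inertia)
  }, integer(1))
  list(table = tab, elbow = elbow)
}

# kneedle-style elbow: k maximizing the distance to the chord joining the
# curve's endpoints
elbow_point <- function(k, y) {
  if (length(k) < 3) return(as.integer(k[1]))
  x1 <- k[1]; y1 <- y[1]; x2 <- k[length(k)]; y2 <- y[length(y)]
  dist <- abs((y2 - y1) * k - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  as.integer(k[which.max(dist)])
}

#' Agreement between two labelings up to relabeling
#'
#' Fraction of samples on which `labels` agree with `ref` under the best
#' cluster-label permutation (exhaustive over permutations, practical for
#' k <= 8).
#'
#' @param labels,ref integer label vectors of equal length.
#' @param k number of clusters.
#' @return List with `agreement` (fraction) and `mapping` (permutation
#'   applied to `labels`).
#' @export
match_labels <- function(labels, ref, k = max(c(labels, ref))) {
  if (k > 8) stop("exhaustive label matching is limited to k <= 8")
  perms <- permutations_of(k)
  best <- 0; best_perm <- seq_len(k)
  for (i in seq_len(nrow(perms))) {
    agr <- mean(perms[i, labels] == ref)
    if (agr > best) { best <- agr; best_perm <- perms[i, ] }
  }
  list(agreement = best, mapping = best_perm)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}
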