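#' Agglomerative clustering with group-average (UPGMA) linkage
#'
#' Naive in-package implementation: start with singleton clusters, merge
#' the pair with the smallest average Euclidean inter-cluster distance
#' until `k` clusters remain. Ties are broken by the lexicographically
#' lowest cluster-index pair, making the result deterministic in the
#' input order. Intended for the daily thermal-trait pairs (a few
#' thousand points at most); cost is O(n^3).
#'
#' @param points A numeric matrix (rows = observations) or data frame of
#'   coordinates; duplicate rows are allowed.
#' @param k Number of clusters to return (default 2).
#' @return Integer vector of cluster labels `1..k` in input order;
#'   labelling is arbitrary but consistent (clusters numbered by first
#'   member appearance).
#' @export
#' @examples
#' pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
#' agglomerative_cluster(pts, k = 2) # 1 1 2 2
agglomerative_cluster <- function(points, k = 2) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n < k) stop("agglomerative_cluster: fewer points than clusters")
  if (k < 1) stop("agglomerative_cluster: k must be >= 1")

  # average-linkage distance between clusters A and B is the mean of all
  # pairwise member distances; maintained under merges by size weighting
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  n_active <- n

  while (n_active > k) {
    dv <- d
    dv[!active, ] <- Inf
    dv[, !active] <- Inf
    dv[lower.tri(dv, diag = TRUE)] <- Inf
    # which.min on the transposed matrix scans rows first, so ties resolve
    # to the smallest (i, j) pair in lexicographic order with i < j
    idx <- which.min(t(dv))
    i <- (idx - 1L) %/% n + 1L
    j <- (idx - 1L) %% n + 1L
    # merge j into i (i < j)
    w <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- w
    d[, i] <- w
    d[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer()
    n_active <- n_active - 1L
  }

  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (active[i]) {
      cl <- cl + 1L
      labels[members[[i]]] <- cl
    }
  }
  labels
}
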