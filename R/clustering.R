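#' Mean pairwise compatibility of a cluster
#'
#' Scores a cluster of slot fillers by the mean of the learned pairwise
#' compatibility q over its members. By default self-pairs are excluded and
#' the mean runs over unordered pairs, so a singleton cluster scores 1.0 and
#' the score of a worked similarity matrix with an undefined diagonal is
#' well defined; `include_self = TRUE` restores the literal mean over the
#' full cartesian product (requiring a defined diagonal).
#'
#' @param qmat symmetric numeric similarity matrix over all fillers.
#' @param members integer indices of the cluster members.
#' @param include_self include self-pairs (diagonal) in the mean.
#' @return numeric cluster score in \[0, 1\].
#' @export
cluster_score <- function(qmat, members, include_self = FALSE) {
  k <- length(members)
  if (!k) stop("empty cluster")
  if (include_self) {
    vals <- qmat[members, members, drop = FALSE]
    if (anyNA(vals)) stop("include_self requires a defined diagonal")
    return(mean(vals))
  }
  if (k == 1L) return(1.0)
  pairs <- utils::combn(members, 2L)
  mean(qmat[cbind(pairs[1, ], pairs[2, ])])
}

#' Mean cluster score of a clustering
#'
#' The score of a clustering is the arithmetic mean of its cluster scores.
#'
#' @param qmat similarity matrix.
#' @param clusters list of integer index vectors partitioning the fillers.
#' @param include_self passed to [cluster_score()].
#' @return numeric clustering score.
#' @export
clustering_score <- function(qmat, clusters, include_self = FALSE) {
  if (!length(clusters)) stop("empty clustering")
  mean(vapply(clusters, function(m) cluster_score(qmat, m, include_self),
              numeric(1)))
}

# All partitions of 1..n into exactly m non-empty blocks, enumerated via
# restricted growth strings in lexicographic order.
set_partitions_m <- function(n, m) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxu) {
    if (i > n) {
      if (maxu == m) {
        out[[length(out) + 1L]] <<- lapply(seq_len(m),
                                           function(b) which(rgs == b))
      }
      return(invisible())
    }
    # pruning: remaining positions must be able to reach m blocks
    if (maxu + (n - i + 1L) < m) return(invisible())
    for (b in seq_len(min(maxu + 1L, m))) {
      rgs[i] <<- b
      recurse(i + 1L, max(maxu, b))
    }
    invisible()
  }
  recurse(1L, 0L)
  out
}

#' Exhaustive search for the best clustering with a given cluster count
#'
#' Enumerates every partition of the fillers into `m` non-empty clusters and
#' returns the one maximizing the clustering score. Ties are broken by the
#' enumeration order of restricted growth strings, i.e. the lexicographically
#' smallest partition wins. Intended for small filler sets; the number of
#' partitions grows as the Stirling numbers of the second kind.
#'
#' @param qmat similarity matrix over `n` fillers.
#' @param m number of clusters, `1 <= m <= n`.
#' @param include_self passed to [cluster_score()].
#' @param max_n guard on the enumeration size (default 10 fillers).
#' @return list with `clusters` (list of index vectors) and `score`.
#' @export
best_clustering_exhaustive <- function(qmat, m, include_self = FALSE,
                                       max_n = 10L) {
  n <- nrow(qmat)
  if (n > max_n) {
    stop("exhaustive enumeration limited to ", max_n, " fillers (got ",
         n, ")")
  }
  if (m < 1L || m > n) stop("m must be in [1, ", n, "]")
  best <- NULL
  best_score <- -Inf
  for (p in set_partitions_m(n, m)) {
    sc <- clustering_score(qmat, p, include_self)
    if (sc > best_score) {
      best <- p
      best_score <- sc
    }
  }
  list(clusters = best, score = best_score)
}

#' Fit the clustering threshold from labelled training pairs
#'
#' The threshold separating same-instance from different-instance
#' compatibilities is derived from two training-set averages: the mean
#' compatibility of pairs belonging to the same template instance and the
#' mean of pairs belonging to different instances. The default combining
#' rule is their midpoint.
#'
#' @param q_values numeric vector of pairwise compatibilities.
#' @param same logical vector: does the pair belong to the same instance?
#' @param combine function combining the two means into the threshold
#'   (default midpoint).
#' @return list with `tau`, `same_mean`, `diff_mean`.
#' @export
fit_threshold <- function(q_values, same,
                          combine = function(s, d) (s + d) / 2) {
  stopifnot(length(q_values) == length(same))
  if (!any(same) || !any(!same)) {
    stop("need at least one same-instance and one different-instance pair")
  }
  same_mean <- mean(q_values[same])
  diff_mean <- mean(q_values[!same])
  list(tau = combine(same_mean, diff_mean),
       same_mean = same_mean, diff_mean = diff_mean)
}

#' Threshold-stopped agglomerative clustering of slot fillers
#'
#' Hierarchical agglomerative clustering with average linkage on the
#' similarity q: clusters are merged greedily by highest mean pairwise
#' compatibility, and merging stops as soon as the best inter-cluster mean
#' compatibility falls below the threshold `tau`. The number of clusters —
#' the inferred template cardinality — is thereby induced rather than given.
#' Implemented via [stats::hclust()] on the dissimilarity `1 - q` with a cut
#' at height `1 - tau` (average linkage on dissimilarities realizes exactly
#' the mean-pairwise-compatibility merge criterion).
#'
#' @param qmat symmetric similarity matrix (diagonal ignored).
#' @param tau threshold in \[0, 1\].
#' @return list of integer index vectors (the clusters), ordered by their
#'   smallest member.
#' @export
hac_cluster <- function(qmat, tau) {
  n <- nrow(qmat)
  if (!n) stop("no fillers to cluster")
  if (n == 1L) return(list(1L))
  d <- stats::as.dist(1 - qmat)
  hc <- stats::hclust(d, method = "average")
  memb <- stats::cutree(hc, h = 1 - tau)
  cl <- split(seq_len(n), memb)
  names(cl) <- NULL
  cl[order(vapply(cl, min, integer(1)))]
}
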