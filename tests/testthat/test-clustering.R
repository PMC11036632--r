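test_that("cluster scores reproduce the worked compatibility example", {
  q <- table3_qmat()
  # clusters {16, week 24} and {8, week 12}
  expect_equal(cluster_score(q, c(1, 3)), 0.7)
  expect_equal(cluster_score(q, c(2, 4)), 0.8)
  expect_equal(clustering_score(q, list(c(1, 3), c(2, 4))), 0.75)
  # singleton scores 1 under the self-pair-excluded reading
  expect_equal(cluster_score(q, 2), 1.0)
  expect_error(cluster_score(q, integer(0)), "empty")
  # literal cartesian-product reading needs a defined diagonal
  expect_error(cluster_score(q, c(1, 3), include_self = TRUE), "diagonal")
  qd <- q; diag(qd) <- 1
  expect_equal(cluster_score(qd, c(1, 3), include_self = TRUE),
               mean(c(1, 0.7, 0.7, 1)))
  # constant similarity c gives scores c
  qc <- matrix(0.4, 3, 3)
  expect_equal(cluster_score(qc, 1:3), 0.4)
  expect_equal(clustering_score(qc, list(1:2, 3)), mean(c(0.4, 1)))
})

test_that("threshold clustering yields the two worked clusters", {
  cl <- hac_cluster(table3_qmat(), tau = 0.5)
  expect_identical(cl, list(c(1L, 3L), c(2L, 4L)))
  # all similarities below the threshold: singletons
  lo <- matrix(0.1, 4, 4); diag(lo) <- NA
  expect_length(hac_cluster(lo, 0.5), 4L)
  # all above: one cluster
  hi <- matrix(0.9, 4, 4); diag(hi) <- NA
  expect_length(hac_cluster(hi, 0.5), 1L)
  expect_identical(hac_cluster(matrix(NA, 1, 1), 0.5), list(1L))
})

test_that("cluster count is non-decreasing in the threshold", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    q <- matrix(0, n, n)
    q[upper.tri(q)] <- runif(n * (n - 1) / 2)
    q <- q + t(q); diag(q) <- NA
    sizes <- vapply(seq(0, 1, by = 0.1),
                    function(tau) length(hac_cluster(q, tau)), integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("exhaustive clustering maximizes the clustering score", {
  q <- table3_qmat()
  best <- best_clustering_exhaustive(q, m = 2)
  expect_identical(best$clusters, list(c(1L, 3L), c(2L, 4L)))
  expect_equal(best$score, 0.75)

  # independent check: enumerate the 7 two-block partitions of 4 elements
  # explicitly and score them by direct averaging
  partitions <- list(
    list(1L, c(2L, 3L, 4L)), list(2L, c(1L, 3L, 4L)),
    list(3L, c(1L, 2L, 4L)), list(4L, c(1L, 2L, 3L)),
    list(c(1L, 2L), c(3L, 4L)), list(c(1L, 3L), c(2L, 4L)),
    list(c(1L, 4L), c(2L, 3L)))
  direct_g <- function(mem) {
    if (length(mem) == 1L) return(1.0)
    pairs <- combn(mem, 2)
    mean(q[cbind(pairs[1, ], pairs[2, ])])
  }
  scores <- vapply(partitions,
                   function(p) mean(vapply(p, direct_g, numeric(1))),
                   numeric(1))
  expect_length(picostruct:::set_partitions_m(4L, 2L), 7L)
  expect_equal(best$score, max(scores))
  expect_identical(best$clusters, partitions[[which.max(scores)]])

  # degenerate cluster counts
  expect_identical(best_clustering_exhaustive(q, 1)$clusters, list(1:4))
  expect_identical(best_clustering_exhaustive(q, 4)$clusters,
                   list(1L, 2L, 3L, 4L))
  expect_error(best_clustering_exhaustive(q, 5), "m must be")
  expect_error(best_clustering_exhaustive(matrix(0, 12, 12), 2),
               "limited")
})

test_that("the exhaustive optimum dominates random partitions", {
  set.seed(31)
  n <- 7
  q <- matrix(0, n, n)
  q[upper.tri(q)] <- runif(n * (n - 1) / 2)
  q <- q + t(q); diag(q) <- NA
  for (m in c(2, 3)) {
    best <- best_clustering_exhaustive(q, m)
    for (rep in 1:100) {
      # random partition into m non-empty blocks
      repeat {
        assign <- sample.int(m, n, replace = TRUE)
        if (length(unique(assign)) == m) break
      }
      rand <- split(seq_len(n), assign)
      expect_gte(best$score + 1e-12, clustering_score(q, rand))
    }
  }
})

test_that("the clustering threshold is the midpoint of the class means", {
  fit <- fit_threshold(c(0.8, 0.8, 0.2, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fit$tau, 0.5)
  expect_equal(fit_threshold(c(0.3, 0.3), c(TRUE, FALSE))$tau, 0.3)
  set.seed(8)
  qv <- runif(60)
  lab <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  fit <- fit_threshold(qv, lab)
  expect_equal(fit$same_mean, sum(qv[lab]) / sum(lab))
  expect_equal(fit$diff_mean, sum(qv[!lab]) / sum(!lab))
  expect_equal(fit$tau, (fit$same_mean + fit$diff_mean) / 2)
  expect_error(fit_threshold(qv, rep(TRUE, 60)), "at least one")
})
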