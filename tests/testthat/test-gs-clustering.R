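test_that("separation is zero on the diagonal and for identical MAPs", {
  study <- tiny_study(t_len = 200, seed = 61, n = 3, size = 2)
  sc <- score_study(study$study, max_parents = 2)
  ids <- study$study$subject_id
  expect_identical(pairwise_separation(sc, ids[1], ids[1]), 0)
  n1 <- dag_search_exact(scores_subset(sc, ids[1]))
  n2 <- dag_search_exact(scores_subset(sc, ids[2]))
  d <- pairwise_separation(sc, ids[1], ids[2])
  if (all(n1$parents == n2$parents)) expect_equal(d, 0, tolerance = 1e-9)
  expect_gte(d, 0)
})

test_that("separation properties hold over random two-subject studies", {
  # d symmetric, d >= 0, d = 0 whenever the MAP structures coincide, and
  # the DGM separation decomposes into non-negative per-node differences
  for (k in 1:50) {
    n <- sample(2:5, 1)
    spec <- mdm_sim_spec(
      n_nodes = n, t_len = 60,
      groups = list(list(label = "g", size = 2)),
      shared_fraction = 0
    )
    tr <- simulate_study(spec, seed = 6100 + k)
    sc <- score_study(tr$study, max_parents = n - 1)
    ids <- tr$study$subject_id
    for (variant in c("ipa", "dgm")) {
      d_ij <- pairwise_separation(sc, ids[1], ids[2], variant,
                                  clamp = FALSE)
      d_ji <- pairwise_separation(sc, ids[2], ids[1], variant,
                                  clamp = FALSE)
      expect_equal(d_ij, d_ji, tolerance = 1e-9)
      expect_gte(d_ij, -1e-9)
      m1 <- search_network(scores_subset(sc, ids[1]), variant)
      m2 <- search_network(scores_subset(sc, ids[2]), variant)
      if (all(m1$parents == m2$parents)) {
        expect_equal(d_ij, 0, tolerance = 1e-9)
      }
    }
    # DGM decomposition: per-node max_i + max_j - max_summed, all >= 0
    t1 <- tibble::as_tibble(scores_subset(sc, ids[1]))
    t2 <- tibble::as_tibble(scores_subset(sc, ids[2]))
    per_node <- vapply(seq_len(n), function(r) {
      s1 <- t1$score[t1$node == r]
      s2 <- t2$score[t2$node == r]
      max(s1) + max(s2) - max(s1 + s2)
    }, numeric(1))
    expect_true(all(per_node >= -1e-9))
    expect_equal(pairwise_separation(sc, ids[1], ids[2], "dgm"),
                 sum(per_node), tolerance = 1e-9)
  }
})

test_that("the separation matrix is symmetric with zero diagonal", {
  study <- tiny_study(t_len = 60, seed = 62, n = 3, size = 3)
  sc <- score_study(study$study, max_parents = 2)
  D <- separation_matrix(sc)
  expect_equal(dim(D), c(3, 3))
  expect_identical(unclass(D)[cbind(1:3, 1:3)], rep(0, 3))
  expect_equal(unclass(D), t(unclass(D)))
  expect_true(all(D >= 0))
  # S = 1 gives the 1x1 zero matrix
  D1 <- separation_matrix(scores_subset(sc, study$study$subject_id[1]))
  expect_equal(unclass(D1), matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("average-linkage clustering matches hand agglomeration", {
  set.seed(63)
  # random 6x6 dissimilarity; reproduce hclust average by brute force
  D <- matrix(runif(36, 1, 10), 6, 6)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  hc <- hierarchical_cluster(structure(D, dimnames = list(1:6, 1:6)))
  # brute-force UPGMA
  clusters <- as.list(1:6)
  d <- D
  active <- rep(TRUE, 6)
  heights <- numeric(0)
  merged_sets <- list()
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA)
    bestd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && d[a, b] < bestd) {
        bestd <- d[a, b]
        best <- c(a, b)
      }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bestd)
    new_set <- sort(c(clusters[[a]], clusters[[b]]))
    merged_sets[[length(merged_sets) + 1]] <- new_set
    # UPGMA update: size-weighted average distance
    na_ <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (o in idx) {
      if (o == a || o == b) next
      d[a, o] <- d[o, a] <- (na_ * d[a, o] + nb * d[b, o]) / (na_ + nb)
    }
    clusters[[a]] <- new_set
    active[b] <- FALSE
  }
  expect_equal(hc$height, heights, tolerance = 1e-12)
  # merge contents agree step by step
  hc_sets <- list()
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(x) {
      if (x < 0) -x else hc_sets[[x]]
    }
    hc_sets[[k]] <- sort(c(members(hc$merge[k, 1]),
                           members(hc$merge[k, 2])))
    expect_equal(hc_sets[[k]], merged_sets[[k]])
  }
  # two points merge at their distance
  D2 <- matrix(c(0, 3.5, 3.5, 0), 2, 2)
  expect_equal(hierarchical_cluster(D2)$height, 3.5)
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("ultrametric inputs are reproduced exactly by the tree heights", {
  # three blobs at mutual distance 10, within-distance 2
  D <- matrix(10, 6, 6)
  for (g in list(1:2, 3:4, 5:6)) D[g, g] <- 2
  diag(D) <- 0
  hc <- hierarchical_cluster(D)
  expect_setequal(round(hc$height, 10), c(2, 2, 2, 10, 10))
})

test_that("the adaptive cut recovers separated blobs and respects size", {
  # three well-separated blobs of 6
  D <- matrix(100, 18, 18)
  for (g in list(1:6, 7:12, 13:18)) D[g, g] <- 0
  diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:18), paste0("s", 1:18))
  cl <- cut_tree_dynamic(hierarchical_cluster(D))
  expect_equal(length(unique(cl$cluster)), 3)
  expect_equal(rand_index(cl$cluster, rep(1:3, each = 6)), 1)
  # all distances equal: one cluster
  De <- matrix(7, 10, 10)
  diag(De) <- 0
  cle <- cut_tree_dynamic(hierarchical_cluster(De))
  expect_equal(unique(cle$cluster), 1L)
  # a pair below min_cluster_size splits into singletons
  Dp <- matrix(100, 8, 8)
  Dp[1:6, 1:6] <- 0
  Dp[7:8, 7:8] <- 0
  diag(Dp) <- 0
  clp <- cut_tree_dynamic(hierarchical_cluster(Dp), min_cluster_size = 3)
  expect_equal(sum(clp$singleton), 2)
  expect_equal(length(unique(clp$cluster)), 3)  # one proper + 2 singles
  expect_error(cut_tree_dynamic(hierarchical_cluster(Dp),
                                min_cluster_size = 0), "min_cluster_size")
})

test_that("three-subgroup studies are recovered with Rand index 1", {
  hits <- 0
  n_rep <- 20
  for (k in seq_len(n_rep)) {
    spec <- mdm_sim_spec(
      n_nodes = 8, t_len = 300,
      groups = lapply(1:3, function(g) {
        list(label = paste0("g", g), size = 4)
      })
    )
    tr <- simulate_study(spec, seed = 6400 + k)
    sc <- score_study(tr$study, max_parents = 3)
    cl <- cut_tree_dynamic(
      hierarchical_cluster(separation_matrix(sc)),
      min_cluster_size = 3
    )
    ok <- length(unique(cl$cluster)) == 3 &&
      rand_index(cl$cluster, tr$labels[cl$subject_id]) == 1
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("classical MDS embeds Euclidean configurations exactly", {
  set.seed(65)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(X))
  fit <- classical_mds(D, k = 2)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-9)
  expect_equal(as.matrix(dist(fit$points)), D, tolerance = 1e-9,
               ignore_attr = TRUE)
  # k = S - 1 captures all positive structure
  fit_full <- classical_mds(D, k = 5)
  expect_equal(fit_full$variance_explained, 1, tolerance = 1e-9)
  # embedding distances converge to input distances as k grows
  X3 <- matrix(rnorm(21), 7, 3)
  D3 <- as.matrix(dist(X3))
  err <- vapply(1:3, function(k) {
    max(abs(as.matrix(dist(classical_mds(D3, k)$points)) - D3))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))
  expect_lt(err[3], 1e-9)
  # all-zero matrix: origin embedding, variance_explained defined as 1
  Z <- matrix(0, 4, 4)
  fz <- classical_mds(Z, 2)
  expect_equal(fz$points, matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(fz$variance_explained, 1)
})

test_that("subgroup networks reduce to individual and CS cases", {
  study <- tiny_study(t_len = 80, seed = 66, n = 3, size = 3)
  sc <- score_study(study$study, max_parents = 2)
  ids <- study$study$subject_id
  # singleton subgroup: that subject's individual network
  cl <- tibble::tibble(subject_id = ids, cluster = c(1L, 1L, 2L))
  nets <- subgroup_networks(sc, cl)
  expect_equal(nets[["2"]]$parents,
               dag_search_exact(scores_subset(sc, ids[3]))$parents)
  # G = 1: identical to the CS group network
  cl1 <- tibble::tibble(subject_id = ids, cluster = 1L)
  nets1 <- subgroup_networks(sc, cl1)
  expect_equal(nets1[["1"]]$parents, cs_group(sc)$parents)
})
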