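test_that("parent-set SHD is the symmetric difference size", {
  expect_equal(shd_parent_sets(c(2, 3), c(2, 3)), 0)
  expect_equal(shd_parent_sets(integer(0), c(2, 3)), 2)
  expect_equal(shd_parent_sets(c(1, 2), c(2, 4)), 2)
  expect_equal(shd_parent_sets(5L, 3L, bitmask = TRUE), 2)
})

test_that("lambda odds follow exp(lambda)", {
  lo <- lambda_odds(c(0, 0.7, 3, 5))
  expect_equal(lo$maintain_prob[1], 0.5)
  expect_equal(lo$odds[1], 1)
  expect_equal(lo$odds, exp(c(0, 0.7, 3, 5)))
  expect_equal(lo$maintain_prob, 1 / (1 + exp(-c(0, 0.7, 3, 5))))
  expect_error(lambda_odds(-1))
})

test_that("the structural prior normalizer has its closed form", {
  # full power set over n - 1 = 3 candidates: (n-1) * log(1 + e^-lambda)
  space <- mdmgroup:::enumerate_psets(2:4, 3)
  lam <- 1
  lp_raw <- penalty_log_prior(space, center = 0L, lambda = lam,
                              normalized = FALSE)
  norm_direct <- log(sum(exp(lp_raw)))
  expect_equal(norm_direct, 3 * log(1 + exp(-lam)), tolerance = 1e-12)
  # and the normalizer is centre-independent on the full power set
  for (ctr in space) {
    lpn <- penalty_log_prior(space, ctr, lam)
    expect_equal(logsumexp_ <- log(sum(exp(lpn))), 0, tolerance = 1e-12)
    expect_equal(max(lpn), -3 * log(1 + exp(-lam)) , tolerance = 1e-12)
  }
  # lambda = 0: uniform over the space
  expect_equal(unname(penalty_log_prior(space, 0L, 0)),
               rep(-log(length(space)), length(space)))
  # a distance-1 set sits exactly lambda below the centre
  lpn0 <- penalty_log_prior(space, 0L, lam)
  expect_equal(lpn0[as.character(2L)] - lpn0[as.character(0L)],
               c("2" = -lam), tolerance = 1e-12)
})

test_that("IEMN composes the individual, subgroup and group estimators", {
  study <- tiny_study(t_len = 60, seed = 71, n = 3, size = 2)
  sc <- score_study(study$study, max_parents = 2)
  ids <- study$study$subject_id
  fit <- iemn(sc)
  expect_equal(fit$individual[[ids[1]]]$parents,
               dag_search_exact(scores_subset(sc, ids[1]))$parents)
  expect_equal(fit$group$parents, cs_group(sc)$parents)
  expect_equal(fit$subgroup[["1"]]$parents, fit$group$parents)
  # S = 1, G = 1: all three levels identical
  sc1 <- scores_subset(sc, ids[1])
  f1 <- iemn(sc1)
  expect_equal(f1$individual[[1]]$parents, f1$group$parents)
  expect_equal(f1$subgroup[[1]]$parents, f1$group$parents)
})

test_that("MEMN at lambda 0 reproduces IEMN individuals exactly", {
  study <- tiny_study(t_len = 60, seed = 72, n = 3, size = 3)
  sc <- score_study(study$study, max_parents = 2)
  for (variant in c("ipa", "dgm")) {
    m0 <- memn(sc, lambda = 0, search = variant)
    ie <- iemn(sc, search = variant)
    for (id in names(m0$individual)) {
      expect_identical(m0$individual[[id]]$parents,
                       ie$individual[[id]]$parents)
    }
  }
})

test_that("large lambda pulls a homogeneous subgroup to one structure", {
  study <- tiny_study(t_len = 120, seed = 73, n = 3, size = 3)
  sc <- score_study(study$study, max_parents = 2)
  mL <- memn(sc, lambda = 1000)
  pa <- vapply(mL$individual, function(x) paste(x$parents, collapse = ","),
               character(1))
  expect_equal(length(unique(pa)), 1)
  # and the MEMN subgroup network approaches the IEMN one
  expect_equal(mL$subgroup[["1"]]$parents, iemn(sc)$subgroup[["1"]]$parents)
})

test_that("MEMN posteriors equal brute-force nested summation", {
  for (k in 1:6) {
    n <- 3
    S_g <- sample(2:3, 1)
    spec <- mdm_sim_spec(n_nodes = n, t_len = 40,
                         groups = list(list(label = "g", size = S_g)),
                         shared_fraction = 0)
    tr <- simulate_study(spec, seed = 7300 + k)
    sc <- score_study(tr$study, max_parents = n - 1)
    lam <- sample(c(0.5, 1, 2), 1)
    post <- mdmgroup:::memn_node_posteriors(sc, tr$study$subject_id, lam)
    nsm <- mdmgroup:::node_score_matrices(sc, tr$study$subject_id)
    for (r in seq_len(n)) {
      C <- nsm[[r]]$C
      rownames(C) <- nsm[[r]]$masks
      for (i in seq_len(S_g)) {
        expect_equal(post[[r]]$individual[, i],
                     brute_memn_individual(C, lam, i),
                     tolerance = 1e-8)
      }
      expect_equal(post[[r]]$subgroup, brute_memn_subgroup(C, lam),
                   tolerance = 1e-8)
    }
  }
})

test_that("the lambda sweep shows the density crossover", {
  # heterogeneous study: individual networks get denser with lambda while
  # the group network gets sparser
  spec <- mdm_sim_spec(
    n_nodes = 5, t_len = 150,
    groups = list(list(label = "a", size = 3),
                  list(label = "b", size = 3)),
    shared_fraction = 0.3
  )
  tr <- simulate_study(spec, seed = 74)
  sc <- score_study(tr$study, max_parents = 2)
  grid <- c(0.1, 0.7, 10, 100, 1000)
  gl <- lapply(grid, function(lam) glance(memn(sc, lambda = lam)))
  gl <- dplyr::bind_rows(gl)
  expect_true(all(diff(gl$mean_individual_edges) >= 0))
  expect_true(all(diff(gl$group_edges) <= 0))
})

test_that("lambda selection returns the grid argmax, smallest on ties", {
  study <- tiny_study(t_len = 60, seed = 75, n = 3, size = 2)
  sc <- score_study(study$study, max_parents = 2)
  expect_equal(select_lambda(sc, grid = 0.7)$lambda, 0.7)
  sel <- select_lambda(sc, grid = c(0.1, 0.7, 10))
  expect_equal(sel$lambda, sel$path$lambda[which.max(sel$path$criterion)])
  # criterion recomputed independently for the individual-posterior rule
  fit <- memn(sc, lambda = sel$lambda)
  by_hand <- sum(vapply(names(fit$individual), function(id) {
    tab <- tibble::as_tibble(fit$posteriors$individual_tables[[id]])
    net <- fit$individual[[id]]
    sum(vapply(seq_along(net$parents), function(r) {
      tab$score[tab$node == r & tab$pset == net$parents[r]]
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(max(sel$path$criterion), by_hand, tolerance = 1e-9)
})

test_that("leave-one-out prediction reduces to the other subject at S=2", {
  study <- tiny_study(t_len = 60, seed = 76, n = 3, size = 2)
  sc <- score_study(study$study, max_parents = 2)
  ids <- study$study$subject_id
  pred <- predicted_network(sc, ids[1], method = "iemn")
  expect_equal(pred$parents,
               dag_search_exact(scores_subset(sc, ids[2]))$parents)
  expect_error(predicted_network(scores_subset(sc, ids[1]), ids[1]),
               "at least 2")
  # homogeneous study: predicted close to the estimated individual
  spec <- mdm_sim_spec(n_nodes = 4, t_len = 300,
                       groups = list(list(label = "g", size = 4)))
  tr <- simulate_study(spec, seed = 77)
  sc2 <- score_study(tr$study, max_parents = 3)
  id <- tr$study$subject_id[1]
  est <- dag_search_exact(scores_subset(sc2, id))
  prd <- predicted_network(sc2, id, method = "memn", lambda = 10)
  expect_lte(shd_networks(est, prd), 2)
})
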