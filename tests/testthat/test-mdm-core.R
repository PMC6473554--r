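test_that("standardization centres and scales every region", {
  set.seed(11)
  y <- matrix(rnorm(300, mean = 5, sd = 3), 100, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  st <- standardize_study(mdm_study(list(s1 = y)))
  m <- st$series[[1]]
  expect_true(all(abs(colMeans(m)) < 1e-12))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-12))
  expect_true(attr(st, "standardized"))
  # idempotent up to tolerance
  st2 <- standardize_study(st)
  expect_equal(st2$series[[1]], m, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(scale(matrix(c(1, 2, 3)))[, 1], c(-1, 0, 1))
})

test_that("constant regions are refused by name", {
  y <- cbind(A = rnorm(10), B = rep(2, 10))
  expect_error(standardize_study(mdm_study(list(s1 = y))), "B")
})

test_that("regressor matrices are intercept-plus-contemporaneous-parents", {
  y <- cbind(a = c(1, 2), b = c(5, 7), c = c(9, 4))
  expect_equal(build_regressors(y, 1), cbind(rep(1, 2)),
               ignore_attr = TRUE)
  expect_equal(unname(build_regressors(y, 1, 2)),
               cbind(c(1, 1), c(5, 7)))
  # ordering follows the given parent order
  expect_equal(unname(build_regressors(y, 2, c(3, 1))),
               cbind(1, y[, 3], y[, 1]), ignore_attr = TRUE)
  expect_error(build_regressors(y, 2, c(2, 3)), "own parent")
})

test_that("static-model LPL equals the batch conjugate marginal likelihood", {
  set.seed(21)
  for (p_extra in 0:2) {
    T_len <- 60
    X <- matrix(rnorm(T_len * 2), T_len)
    y <- rnorm(T_len) +
      if (p_extra > 0) {
        as.numeric(X[, seq_len(p_extra), drop = FALSE] %*%
                     rep(0.5, p_extra))
      } else {
        0
      }
    F <- cbind(1, X[, seq_len(p_extra), drop = FALSE])
    pr <- mdm_prior()
    fl <- filter_node(as.numeric(y), F, pr, delta = 1)
    expect_equal(fl$total,
                 nig_batch_logml(as.numeric(y), F, pr$c0_scale, pr$n0,
                                 pr$d0),
                 tolerance = 1e-8)
  }
})

test_that("filter bookkeeping: n_t counts up, d_t stays positive", {
  set.seed(22)
  y <- rnorm(40)
  fl <- filter_node(y, matrix(1, 40, 1), mdm_prior(), delta = 0.9)
  expect_equal(fl$n, 0.001 + 1:40)
  expect_true(all(fl$d > 0))
  expect_equal(fl$total, sum(fl$logf))
})

test_that("zero data with zero prior mean forecasts zero", {
  y <- rep(0, 20)
  fl <- filter_node(y, matrix(1, 20, 1), mdm_prior(), delta = 0.95)
  expect_true(all(abs(fl$f) < 1e-14))
})

test_that("one-step forecast densities are the Student-t they claim", {
  set.seed(23)
  T_len <- 3
  x <- rnorm(T_len)
  y <- 0.4 * x + rnorm(T_len)
  pr <- mdm_prior(c0_scale = 2, n0 = 4, d0 = 2)
  fl <- filter_node(y, cbind(1, x), pr, delta = 0.9)
  for (t in 1:T_len) {
    df <- pr$n0 + t - 1
    expect_equal(fl$logf[t], t_logpdf(y[t], df, fl$f[t], fl$q[t]),
                 tolerance = 1e-12)
  }
  expect_error(filter_node(c(1, NA, 3), matrix(1, 3, 1), pr),
               "non-finite")
})

test_that("smoothing: static limit, single point, and joint-Gaussian oracle", {
  set.seed(24)
  T_len <- 4
  x <- rnorm(T_len)
  y <- 0.5 * x + rnorm(T_len, sd = 0.3)
  F <- cbind(1, x)
  # delta = 1: all smoothed means equal the final filtered mean
  fl1 <- filter_node(y, F, mdm_prior(), delta = 1)
  sm1 <- smooth_node(fl1)
  expect_equal(sm1$theta, matrix(fl1$m[, T_len], 2, T_len),
               tolerance = 1e-12)
  # T = 1 boundary: smoothed = filtered
  flb <- filter_node(y[1], F[1, , drop = FALSE], mdm_prior(), delta = 0.9)
  smb <- smooth_node(flb)
  expect_equal(smb$theta[, 1], fl1b <- flb$m[, 1])
  # discounted case against a dense joint-Gaussian conditional, with the
  # precision effectively known so the joint is Gaussian
  V_true <- 0.09
  pr <- mdm_prior(c0_scale = 2, n0 = 1e8, d0 = 1e8 * V_true)
  delta <- 0.95
  fl <- filter_node(y, F, pr, delta = delta)
  sm <- smooth_node(fl)
  p <- 2
  C0 <- diag(2 * V_true, p)
  W <- lapply(1:T_len, function(t) {
    Cprev <- if (t == 1) C0 else matrix(fl$C[, , t - 1], p, p)
    matrix(fl$R[, , t], p, p) - Cprev
  })
  marg <- list()
  Vt <- C0
  for (t in 1:T_len) {
    Vt <- Vt + W[[t]]
    marg[[t]] <- Vt
  }
  d <- p * T_len
  Sig <- matrix(0, d, d)
  for (t in 1:T_len) for (s in t:T_len) {
    blk <- marg[[t]]
    Sig[(t - 1) * p + 1:p, (s - 1) * p + 1:p] <- blk
    Sig[(s - 1) * p + 1:p, (t - 1) * p + 1:p] <- t(blk)
  }
  H <- matrix(0, T_len, d)
  for (t in 1:T_len) H[t, (t - 1) * p + 1:p] <- F[t, ]
  Syy <- H %*% Sig %*% t(H) + diag(V_true, T_len)
  Sty <- Sig %*% t(H)
  mu_post <- matrix(Sty %*% solve(Syy, y), p, T_len)
  V_post <- Sig - Sty %*% solve(Syy) %*% t(Sty)
  expect_equal(sm$theta, mu_post, tolerance = 1e-6)
  vd <- sapply(1:T_len, function(t) {
    diag(V_post[(t - 1) * p + 1:p, (t - 1) * p + 1:p])
  })
  smv <- sapply(1:T_len, function(t) diag(sm$V[, , t]))
  expect_equal(smv, vd, tolerance = 1e-6)
})

test_that("local scores are additive and permutation invariant", {
  study <- tiny_study(t_len = 60, seed = 31)
  m <- standardize_study(study$study)$series[[1]]
  pr <- mdm_prior()
  s12 <- local_score(m, 3, c(1, 2), pr)
  s21 <- local_score(m, 3, c(2, 1), pr)
  expect_identical(s12, s21)
  # LPL of a network = sum of local scores, and logBF = difference
  net_a <- c(local_score(m, 1, , pr), local_score(m, 2, 1, pr),
             local_score(m, 3, , pr))
  net_b <- c(local_score(m, 1, , pr), local_score(m, 2, , pr),
             local_score(m, 3, , pr))
  lbf <- sum(net_a) - sum(net_b)
  expect_gt(lbf, 0)  # true edge 1 -> 2 favoured
  expect_error(local_score(m, 2, c(2)), "own parent")
})

test_that("a true parent outscores the empty set in almost all replicates", {
  hits <- 0
  n_rep <- 100
  for (k in seq_len(n_rep)) {
    study <- tiny_study(t_len = 300, seed = 5000 + k, n = 2)
    m <- standardize_study(study$study)$series[[1]]
    pr <- mdm_prior()
    hits <- hits + (local_score(m, 2, 1, pr) > local_score(m, 2, , pr))
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("discount selection takes the per-set maximum over the grid", {
  study <- tiny_study(t_len = 80, seed = 33)
  m <- standardize_study(study$study)$series[[1]]
  pr <- mdm_prior(delta_grid = c(0.9, 1.0))
  by_hand <- max(
    filter_node(m[, 2], build_regressors(m, 2, 1), pr, delta = 0.9)$total,
    filter_node(m[, 2], build_regressors(m, 2, 1), pr, delta = 1.0)$total
  )
  expect_equal(local_score(m, 2, 1, pr), by_hand, tolerance = 1e-12)
})
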