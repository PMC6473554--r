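# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: closed forms, dense linear algebra, and
# exhaustive enumeration only.

# Closed-form log marginal likelihood of the batch conjugate normal-gamma
# regression y = F theta + e, theta | phi ~ N(0, phi^-1 C0/S0),
# phi ~ Gamma(n0/2, d0/2). Equals the prequential LPL at delta = 1.
nig_batch_logml <- function(y, F, c0_scale, n0, d0) {
  p <- ncol(F)
  Tn <- length(y)
  S0 <- d0 / n0
  L0 <- solve(diag(c0_scale, p) / S0)
  LT <- L0 + crossprod(F)
  mT <- solve(LT, crossprod(F, y))
  dT <- as.numeric(d0 + sum(y^2) - t(mT) %*% LT %*% mT)
  as.numeric(
    -Tn / 2 * log(pi) + lgamma((n0 + Tn) / 2) - lgamma(n0 / 2) +
      n0 / 2 * log(d0) - (n0 + Tn) / 2 * log(dT) +
      0.5 * (determinant(L0)$modulus - determinant(LT)$modulus)
  )
}

# Student-t log density by direct evaluation (no stats::dt), for spot
# checks of the one-step forecast terms.
t_logpdf <- function(x, df, location, scale2) {
  lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi * scale2) -
    (df + 1) / 2 * log(1 + (x - location)^2 / (df * scale2))
}

# All parent bitmasks over nodes 1..n excluding r, sizes <= max_parents.
all_psets <- function(n, r, max_parents = n - 1) {
  masks <- 0:(2^n - 1)
  masks <- masks[bitwAnd(masks, bitwShiftL(1L, r - 1L)) == 0L]
  masks[mdmgroup:::popcount(masks) <= max_parents]
}

# Random complete score table for n nodes as an mdm_scores object.
random_score_table <- function(n, max_parents = n - 1, subject = "s1",
                               sd = 5, round_to = NULL) {
  rows <- lapply(seq_len(n), function(r) {
    masks <- all_psets(n, r, max_parents)
    masks <- masks[order(mdmgroup:::popcount(masks), masks)]
    sc <- rnorm(length(masks), sd = sd)
    if (!is.null(round_to)) sc <- round(sc, round_to)
    tibble::tibble(subject_id = subject, node = r, pset = as.integer(masks),
                   n_parents = mdmgroup:::popcount(masks), score = sc,
                   delta = 1)
  })
  mdmgroup:::new_mdm_scores(dplyr::bind_rows(rows), n = n,
                            max_parents = as.integer(max_parents),
                            regions = paste0("R", seq_len(n)),
                            prior = mdm_prior())
}

# Exhaustive best-DAG search: enumerate every combination of parent sets
# and keep the acyclic maximum (ties: smaller total parents, then
# lexicographic parent masks).
exhaustive_best_dag <- function(scores) {
  n <- attr(scores, "n")
  tbl <- tibble::as_tibble(scores)
  per_node <- lapply(seq_len(n), function(r) tbl[tbl$node == r, ])
  grid <- do.call(expand.grid, lapply(per_node, function(d) seq_len(nrow(d))))
  best <- NULL
  for (k in seq_len(nrow(grid))) {
    pa <- vapply(seq_len(n), function(r) {
      per_node[[r]]$pset[grid[k, r]]
    }, integer(1))
    if (is.null(mdmgroup:::topological_order(pa))) next
    tot <- sum(vapply(seq_len(n), function(r) {
      per_node[[r]]$score[grid[k, r]]
    }, numeric(1)))
    cand <- list(parents = pa, total = tot,
                 size = sum(mdmgroup:::popcount(pa)))
    if (is.null(best) || tot > best$total + 1e-12) {
      best <- cand
    } else if (abs(tot - best$total) <= 1e-12) {
      if (cand$size < best$size ||
          (cand$size == best$size &&
           paste(pa, collapse = ",") < paste(best$parents, collapse = ","))) {
        best <- cand
      }
    }
  }
  best
}

# Brute-force MEMN posteriors by literal expansion of the nested sums:
# for each candidate individual structure a of subject i at node r,
# p(a | y) proportional to
#   sum_b prior(a|b) exp(c_i(a)) prod_{k != i} sum_ak exp(c_k(ak)) prior(ak|b)
# computed with plain sums of exponentials after one global shift.
brute_memn_individual <- function(C, lambda, i) {
  m <- nrow(C)
  S <- ncol(C)
  masks <- as.integer(rownames(C))
  pri <- function(a, b) {
    lp <- -lambda * mdmgroup:::popcount(bitwXor(masks, masks[b]))
    exp(lp[a] - mdmgroup:::logsumexp(lp))
  }
  shift <- max(C)
  post <- numeric(m)
  for (a in seq_len(m)) {
    tot <- 0
    for (b in seq_len(m)) {
      term <- exp(C[a, i] - shift) * pri(a, b)
      for (k in seq_len(S)) {
        if (k == i) next
        term <- term * sum(exp(C[, k] - shift) * pri(seq_len(m), b))
      }
      tot <- tot + term
    }
    post[a] <- log(tot)
  }
  post - mdmgroup:::logsumexp(post)
}

brute_memn_subgroup <- function(C, lambda) {
  m <- nrow(C)
  S <- ncol(C)
  masks <- as.integer(rownames(C))
  shift <- max(C)
  post <- numeric(m)
  for (b in seq_len(m)) {
    lp <- -lambda * mdmgroup:::popcount(bitwXor(masks, masks[b]))
    pri <- exp(lp - mdmgroup:::logsumexp(lp))
    term <- 1
    for (k in seq_len(S)) {
      term <- term * sum(exp(C[, k] - shift) * pri)
    }
    post[b] <- log(term)
  }
  post - mdmgroup:::logsumexp(post)
}

# Two-subject toy study with a shared single-edge structure.
tiny_study <- function(t_len = 80, seed = 42, n = 3, size = 2,
                       beta = 0.7) {
  dag <- mdm_network(c(0L, 1L, rep(0L, n - 2)))  # 1 -> 2
  spec <- mdm_sim_spec(
    n_nodes = n, t_len = t_len,
    groups = list(list(label = "g", size = size,
                       dag = dag,
                       coef = setNames(beta, "1->2"),
                       coeff_process = "constant"))
  )
  simulate_study(spec, seed = seed)
}
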