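#' Structural Hamming distance between two parent sets
#'
#' The number of nodes that are parents in exactly one of the two sets
#' (size of the symmetric difference).
#'
#' @param a,b Integer vectors of parent node indices (or single bitmasks
#'   if `bitmask = TRUE`).
#' @param bitmask Interpret `a` and `b` as bitmasks.
#' @return Integer distance.
#' @export
#' @examples
#' shd_parent_sets(c(1, 2), c(2, 4)) # 2
shd_parent_sets <- function(a, b, bitmask = FALSE) {
  if (!bitmask) {
    a <- nodes_to_mask(a)
    b <- nodes_to_mask(b)
  }
  popcount(bitwXor(as.integer(a), as.integer(b)))
}

#' Edge-status prior odds implied by the penalty strength lambda
#'
#' Under the structural prior `p(M_i(r) | Mbar_g(r)) proportional to
#' exp(-lambda * SHD)`, the probability that an edge keeps its
#' present/absent status between an individual network and its subgroup
#' network is `1 / (1 + exp(-lambda))`, and the prior odds of keeping
#' versus flipping are `exp(lambda)`.
#'
#' @param lambda Non-negative penalty strength.
#' @return A tibble with `lambda`, `maintain_prob` and `odds`.
#' @export
#' @examples
#' lambda_odds(c(0, 0.7, 3, 5))
lambda_odds <- function(lambda) {
  stopifnot(all(lambda >= 0))
  tibble::tibble(
    lambda = lambda,
    maintain_prob = 1 / (1 + exp(-lambda)),
    odds = exp(lambda)
  )
}

#' Log structural prior over a parent-set space around a centre
#'
#' `log p(Pa | centre) = -lambda * SHD(Pa, centre)`, optionally
#' normalized over the given space. Over the full power set of the other
#' `n - 1` nodes the normalizer is `(n - 1) * log(1 + exp(-lambda))`,
#' independent of the centre; truncated spaces are normalized by direct
#' summation.
#'
#' @param space Integer vector of candidate parent bitmasks.
#' @param center Centre parent bitmask (must be in `space`).
#' @param lambda Non-negative penalty strength.
#' @param normalized Normalize over `space` (default TRUE).
#' @return Named numeric vector of log prior values, in `space` order.
#' @export
penalty_log_prior <- function(space, center, lambda, normalized = TRUE) {
  stopifnot(lambda >= 0, center %in% space)
  lp <- -lambda * popcount(bitwXor(as.integer(space), as.integer(center)))
  if (normalized) lp <- lp - logsumexp(lp)
  setNames(lp, space)
}

# Pairwise -lambda*SHD matrix between parent-set spaces (rows a, cols b),
# column-normalized so each centre b defines a proper prior over rows.
penalty_matrix <- function(space, lambda, normalized = TRUE) {
  D <- outer(as.integer(space), as.integer(space), bitwXor)
  L <- -lambda * matrix(popcount(as.integer(D)), nrow(D), ncol(D))
  if (normalized) L <- sweep(L, 2, col_logsumexp(L))
  L
}

# Per-node score matrices for a set of members: list over nodes of
# (masks, C = |space| x |members| matrix of local scores).
node_score_matrices <- function(scores, members) {
  tbl <- tibble::as_tibble(scores)
  tbl <- tbl[tbl$subject_id %in% members, ]
  n <- attr(scores, "n")
  lapply(seq_len(n), function(r) {
    sub <- tbl[tbl$node == r, ]
    masks <- sort(unique(sub$pset))
    masks <- masks[order(popcount(masks), masks)]
    C <- matrix(NA_real_, length(masks), length(members),
                dimnames = list(masks, members))
    C[cbind(match(sub$pset, masks), match(sub$subject_id, members))] <-
      sub$score
    if (anyNA(C)) stop("incomplete score table for node ", r)
    list(masks = masks, C = C)
  })
}

# MEMN log-posterior machinery for one subgroup. Everything is in log
# space; scores are shifted by their per-node maximum inside the
# log-sum-exps. Returns per node: masks, individual log-posteriors (one
# column per member, normalized over the space), and the subgroup
# log-posterior over centres (normalized).
memn_node_posteriors <- function(scores, members, lambda) {
  nsm <- node_score_matrices(scores, members)
  lapply(nsm, function(ns) {
    L <- penalty_matrix(ns$masks, lambda)         # a x b
    Hk <- apply(ns$C, 2, function(ck) col_logsumexp(ck + L))  # b x S_g
    Hk <- matrix(Hk, ncol = ncol(ns$C))
    H <- rowSums(Hk)                               # sum_k h_k(b)
    indiv <- vapply(seq_len(ncol(ns$C)), function(i) {
      M <- sweep(L, 2, H - Hk[, i], "+")           # L[a,b] + sum_{k!=i}
      ns$C[, i] + apply(M, 1, logsumexp)
    }, numeric(length(ns$masks)))
    indiv <- sweep(matrix(indiv, ncol = ncol(ns$C)), 2,
                   apply(matrix(indiv, ncol = ncol(ns$C)), 2, logsumexp))
    colnames(indiv) <- colnames(ns$C)
    list(masks = ns$masks,
         individual = indiv,
         subgroup = H - logsumexp(H))
  })
}

# Convert per-node posterior vectors into an mdm_scores table so the
# standard searches apply unchanged.
posteriors_to_scores <- function(post, pick, id, template) {
  a <- scores_attrs(template)
  rows <- purrr::imap(post, function(p, r) {
    val <- pick(p)
    tibble::tibble(subject_id = id, node = r, pset = p$masks,
                   n_parents = popcount(p$masks), score = val,
                   delta = NA_real_)
  })
  new_mdm_scores(dplyr::bind_rows(rows), a$n, a$max_parents, a$regions,
                 a$prior)
}

#' Independent estimation of multiple networks (IEMN)
#'
#' Individual networks are searched independently from each subject's
#' scores; each subgroup network from the members' summed scores; and the
#' group network from the all-subject summed scores (the common-structure
#' estimator).
#'
#' @param scores An `mdm_scores` table for the study.
#' @param clusters An `mdm_clusters` assignment (e.g. from
#'   [gs_cluster()]); a single-cluster assignment is built when omitted.
#' @param search `"ipa"` or `"dgm"`.
#' @return A list of class `mdm_multinet` with `individual` (named list),
#'   `subgroup` (named list), `group` (an [mdm_network()]), `method`,
#'   `lambda` (`NA` for IEMN) and `clusters`.
#' @export
iemn <- function(scores, clusters = NULL, search = c("ipa", "dgm")) {
  search <- match.arg(search)
  if (is.null(clusters)) clusters <- trivial_clusters(scores)
  structure(
    list(
      individual = individual_networks(scores, search),
      subgroup = subgroup_networks(scores, clusters, search = search),
      group = search_network(sum_scores(scores), search),
      method = "IEMN", lambda = NA_real_, clusters = clusters
    ),
    class = "mdm_multinet"
  )
}

trivial_clusters <- function(scores) {
  ids <- unique(scores$subject_id)
  tibble::tibble(subject_id = ids, cluster = 1L,
                 singleton = FALSE)
}

#' Marginal estimation of multiple networks (MEMN)
#'
#' Couples the levels through the structural prior
#' `p(M_i(r) | Mbar_g(r)) proportional to exp(-lambda * SHD)`:
#' each subject's per-node posterior marginalizes over the subgroup
#' structure and the other members' structures; each subgroup posterior
#' marginalizes over its members' structures; the group posterior treats
#' all subjects as one subgroup. All sums run over the same capped
#' parent-set space used for scoring, via log-sum-exp. At `lambda = 0`
#' the individual networks coincide with IEMN's; as `lambda` grows, the
#' members of a subgroup are pulled towards a common structure.
#'
#' @inheritParams iemn
#' @param lambda Non-negative penalty strength.
#' @return An `mdm_multinet` (see [iemn()]) with per-node log-posterior
#'   tables attached as `posteriors` (`mdm_scores`-shaped tibbles:
#'   `individual_tables`, `subgroup_tables`, `group_table`).
#' @export
memn <- function(scores, clusters = NULL, lambda,
                 search = c("ipa", "dgm")) {
  search <- match.arg(search)
  stopifnot(lambda >= 0)
  if (is.null(clusters)) clusters <- trivial_clusters(scores)
  ids <- unique(scores$subject_id)
  missing <- setdiff(ids, clusters$subject_id)
  if (length(missing) > 0) {
    stop("subject(s) not in any subgroup: ", paste(missing, collapse = ", "))
  }
  indiv <- list()
  indiv_tables <- list()
  subgroup <- list()
  subgroup_tables <- list()
  for (g in sort(unique(clusters$cluster))) {
    members <- clusters$subject_id[clusters$cluster == g]
    post <- memn_node_posteriors(scores, members, lambda)
    for (i in seq_along(members)) {
      st <- posteriors_to_scores(post, function(p) p$individual[, i],
                                 members[i], scores)
      indiv_tables[[members[i]]] <- st
      indiv[[members[i]]] <- search_network(st, search)
    }
    gst <- posteriors_to_scores(post, function(p) p$subgroup,
                                paste0("<subgroup ", g, ">"), scores)
    subgroup_tables[[as.character(g)]] <- gst
    subgroup[[as.character(g)]] <- search_network(gst, search)
  }
  gpost <- memn_node_posteriors(scores, ids, lambda)
  group_table <- posteriors_to_scores(gpost, function(p) p$subgroup,
                                      "<group>", scores)
  indiv <- indiv[ids]
  structure(
    list(
      individual = indiv,
      subgroup = subgroup,
      group = search_network(group_table, search),
      method = "MEMN", lambda = lambda, clusters = clusters,
      posteriors = list(individual_tables = indiv_tables,
                        subgroup_tables = subgroup_tables,
                        group_table = group_table)
    ),
    class = "mdm_multinet"
  )
}

#' @export
print.mdm_multinet <- function(x, ...) {
  cat("<mdm_multinet> ", x$method,
      if (!is.na(x$lambda)) paste0(" (lambda = ", x$lambda, ")"),
      ": ", length(x$individual), " individual, ", length(x$subgroup),
      " subgroup network(s)\n", sep = "")
  invisible(x)
}

#' @describeIn iemn Edge counts per level of a multi-network result.
#' @param x An `mdm_multinet`.
#' @param ... Unused.
#' @export
glance.mdm_multinet <- function(x, ...) {
  ec <- function(net) sum(popcount(net$parents))
  tibble::tibble(
    method = x$method, lambda = x$lambda,
    mean_individual_edges = mean(vapply(x$individual, ec, numeric(1))),
    mean_subgroup_edges = mean(vapply(x$subgroup, ec, numeric(1))),
    group_edges = ec(x$group)
  )
}

#' Select the penalty strength lambda from data
#'
#' Evaluates each grid value by one of three criteria and returns the
#' maximizer (ties go to the smallest lambda): the summed per-subject
#' individual log posteriors at their MAP networks
#' (`"max_individual_posterior"`), the group log posterior at its MAP
#' (`"max_group_posterior"`), or leave-one-subject-out cross-validation
#' (`"cross_validation"`: the held-out subject's log predictive
#' likelihood under the structure predicted from everyone else, priors
#' refit).
#'
#' @inheritParams memn
#' @param grid Non-negative candidate lambdas; the classical sweep is
#'   `c(0.1, 0.7, 10, 100, 1000)`.
#' @param criterion Selection criterion.
#' @return A list with `lambda` (selected) and `path` (tibble of
#'   per-grid-value criterion values and edge counts per level).
#' @export
select_lambda <- function(scores, clusters = NULL,
                          grid = c(0.1, 0.7, 10, 100, 1000),
                          criterion = c("max_individual_posterior",
                                        "max_group_posterior",
                                        "cross_validation"),
                          search = c("ipa", "dgm")) {
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  stopifnot(length(grid) >= 1, all(grid >= 0))
  if (is.null(clusters)) clusters <- trivial_clusters(scores)
  path <- purrr::map(sort(grid), function(lam) {
    fit <- memn(scores, clusters, lam, search)
    val <- switch(criterion,
      max_individual_posterior = sum(purrr::imap_dbl(
        fit$individual, function(net, id) {
          tab <- fit$posteriors$individual_tables[[id]]
          network_table_score(tab, net)
        })),
      max_group_posterior = network_table_score(
        fit$posteriors$group_table, fit$group),
      cross_validation = loo_cv_score(scores, clusters, lam, search)
    )
    dplyr::mutate(glance(fit), criterion = val)
  }) |> dplyr::bind_rows()
  best <- which.max(path$criterion)  # ties -> smallest lambda (sorted)
  list(lambda = path$lambda[best], path = path)
}

# Total table score of a network: sum over nodes of the table entry at
# the network's parent set.
network_table_score <- function(table, net) {
  tbl <- tibble::as_tibble(table)
  sum(vapply(seq_along(net$parents), function(r) {
    tbl$score[tbl$node == r & tbl$pset == net$parents[r]]
  }, numeric(1)))
}

loo_cv_score <- function(scores, clusters, lambda, search) {
  ids <- unique(scores$subject_id)
  sum(vapply(ids, function(i) {
    pred <- predicted_network(scores, i, method = "memn", lambda = lambda,
                              search = search)
    network_table_score(scores_subset(scores, i), pred)
  }, numeric(1)))
}

#' Leave-one-subject-out predicted network
#'
#' The group-level network estimated from every subject except `i`: the
#' structure one would predict for a new subject from the rest of the
#' study. `"iemn"` sums the remaining score tables (common structure);
#' `"memn"` uses the penalized group posterior at `lambda`.
#'
#' @param scores An `mdm_scores` table (>= 2 subjects).
#' @param i Held-out subject id.
#' @param method `"iemn"` or `"memn"`.
#' @param lambda Penalty strength (MEMN only).
#' @param search `"ipa"` or `"dgm"`.
#' @return An [mdm_network()].
#' @export
predicted_network <- function(scores, i, method = c("iemn", "memn"),
                              lambda = NULL, search = c("ipa", "dgm")) {
  method <- match.arg(method)
  search <- match.arg(search)
  ids <- unique(scores$subject_id)
  if (length(ids) < 2) stop("need at least 2 subjects to predict")
  if (!i %in% ids) stop("unknown subject: ", i)
  rest <- scores_subset(scores, setdiff(ids, i))
  if (method == "iemn") {
    search_network(sum_scores(rest), search)
  } else {
    stopifnot(!is.null(lambda), lambda >= 0)
    post <- memn_node_posteriors(rest, setdiff(ids, i), lambda)
    search_network(
      posteriors_to_scores(post, function(p) p$subgroup, "<pred>", rest),
      search
    )
  }
}
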