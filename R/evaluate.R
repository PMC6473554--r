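#' Sensitivity and specificity of an estimated directed network
#'
#' Directed edges are compared as ordered node pairs. Sensitivity is the
#' proportion of true edges recovered; specificity is the proportion of
#' the `n(n-1) - |true edges|` absent ordered pairs (self-pairs excluded)
#' correctly left out. A truth with no edges has undefined sensitivity
#' (`NA`).
#'
#' @param truth,estimate [mdm_network()]s on the same node set.
#' @return A tibble with `sensitivity`, `specificity`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
#' @examples
#' a <- mdm_network(c(0L, 1L, 2L))  # 1->2, 2->3
#' b <- mdm_network(c(0L, 1L, 0L))
#' sens_spec(a, b)
sens_spec <- function(truth, estimate) {
  n <- length(truth$parents)
  stopifnot(length(estimate$parents) == n)
  tp <- fp <- fn <- tn <- 0L
  for (r in seq_len(n)) {
    t_pa <- truth$parents[r]
    e_pa <- estimate$parents[r]
    tp <- tp + popcount(bitwAnd(t_pa, e_pa))
    fn <- fn + popcount(bitwAnd(t_pa, bitwNot(e_pa)))
    fp <- fp + popcount(bitwAnd(e_pa, bitwNot(t_pa)))
  }
  absent <- n * (n - 1L) - (tp + fn)
  tn <- absent - fp
  tibble::tibble(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (absent == 0) NA_real_ else tn / absent,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Structural Hamming distance between two directed networks
#'
#' Sum over nodes of the symmetric difference of parent sets, i.e. the
#' number of directed edges present in exactly one network.
#'
#' @param a,b [mdm_network()]s on the same node set.
#' @return Non-negative integer.
#' @export
shd_networks <- function(a, b) {
  stopifnot(length(a$parents) == length(b$parents))
  sum(popcount(bitwXor(a$parents, b$parents)))
}

#' Log Bayes factor between two networks on one subject's data
#'
#' `LPL(a) - LPL(b)` on the given series: positive values favour `a`.
#' Structures are transferred and priors refit on this subject.
#'
#' @param series A `T x n` matrix (one subject).
#' @param a,b [mdm_network()]s.
#' @param prior An [mdm_prior()].
#' @param standardize Standardize columns first (default TRUE).
#' @return Scalar log Bayes factor.
#' @export
network_logbf <- function(series, a, b, prior = mdm_prior(),
                          standardize = TRUE) {
  lpl <- function(net) {
    fit_network(series, net, prior, standardize = standardize)$total_score
  }
  lpl(a) - lpl(b)
}

#' Highest-posterior-density interval for a binomial proportion
#'
#' HPD interval of the `Beta(successes + 1, trials - successes + 1)`
#' posterior (uniform prior), found by minimizing the interval width at
#' fixed coverage; for monotone posteriors the interval abuts 0 or 1.
#'
#' @param successes,trials Counts, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Coverage (default 0.95).
#' @return A tibble with `lower`, `upper`, `level`.
#' @export
#' @examples
#' hpd_proportion(5, 10)
hpd_proportion <- function(successes, trials, level = 0.95) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            level > 0, level < 1)
  a <- successes + 1
  b <- trials - successes + 1
  width <- function(p_lo) {
    qbeta(p_lo + level, a, b) - qbeta(p_lo, a, b)
  }
  if (a == 1) {         # mode at 0
    lo <- 0; hi <- qbeta(level, a, b)
  } else if (b == 1) {  # mode at 1
    lo <- qbeta(1 - level, a, b); hi <- 1
  } else {
    opt <- optimize(width, c(0, 1 - level), tol = 1e-10)
    lo <- qbeta(opt$minimum, a, b)
    hi <- qbeta(opt$minimum + level, a, b)
  }
  tibble::tibble(lower = lo, upper = hi, level = level)
}

#' Rand index of two partitions
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  S <- length(a)
  if (S < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

#' Popular-edges reference graph of a simulated design
#'
#' The directed graph formed by the edges present in strictly more than
#' `threshold` of the true per-subject DAGs -- the single reference
#' against which one-network group estimators are judged when the truth
#' has several subgroups.
#'
#' @param truth An `mdm_truth` bundle from [simulate_study()].
#' @param threshold Popularity threshold (default 2/3, strict).
#' @return An [mdm_network()].
#' @export
popular_edges <- function(truth, threshold = 2 / 3) {
  per_subject <- lapply(truth$labels, function(g) truth$dags[[g]])
  is_group(unname(per_subject), threshold = threshold)
}

#' Evaluate the four group estimators on a simulated study
#'
#' Runs VTS, CS and IS against the popular-edges reference graph and the
#' group-structure (GS) pipeline against each true subgroup DAG, on a
#' study with known truth. Reports sensitivity/specificity per method,
#' and cluster recovery (number of subgroups, Rand index) for GS.
#'
#' @param truth An `mdm_truth` bundle from [simulate_study()].
#' @param max_parents,prior Passed to [score_study()].
#' @param search `"ipa"` or `"dgm"`.
#' @param is_threshold Inclusion threshold for the IS vote (default 1/2).
#' @param scores Optional pre-computed `mdm_scores` (skips scoring).
#' @return A list of class `mdm_eval` with `metrics` (tibble: method,
#'   sensitivity, specificity), `gs` (the [gs_cluster()] fit),
#'   `n_subgroups`, `rand_index`, and the estimated networks.
#' @export
table1_harness <- function(truth, max_parents = NULL, prior = mdm_prior(),
                           search = c("ipa", "dgm"), is_threshold = 0.5,
                           scores = NULL) {
  search <- match.arg(search)
  study <- truth$study
  if (is.null(scores)) {
    scores <- score_study(study, max_parents = max_parents, prior = prior)
  }
  ref <- popular_edges(truth)
  vts <- vts_group(study, search, max_parents = attr(scores, "max_parents"),
                   prior = prior)
  cs <- cs_group(scores, search = search)
  indiv <- individual_networks(scores, search)
  isn <- is_group(indiv, threshold = is_threshold)
  gs <- gs_cluster(scores, search = search)

  one <- function(name, est, target) {
    dplyr::mutate(sens_spec(target, est), method = name, .before = 1)
  }
  rows <- dplyr::bind_rows(
    one("VTS", vts, ref), one("CS", cs, ref), one("IS", isn, ref)
  )
  # match each recovered subgroup to the true DAG of the majority of its
  # members, as the reference for that subgroup's network
  truth_of <- function(members) {
    labs <- truth$labels[members]
    truth$dags[[names(sort(table(labs), decreasing = TRUE))[1]]]
  }
  for (g in names(gs$networks)) {
    members <- gs$clusters$subject_id[gs$clusters$cluster == as.integer(g)]
    rows <- dplyr::bind_rows(
      rows, one(paste0("GS-subgroup ", g), gs$networks[[g]],
                truth_of(members))
    )
  }
  ri <- rand_index(truth$labels[gs$clusters$subject_id],
                   gs$clusters$cluster)
  structure(
    list(metrics = rows, gs = gs, n_subgroups = length(gs$networks),
         rand_index = ri,
         networks = list(VTS = vts, CS = cs, IS = isn)),
    class = "mdm_eval"
  )
}

#' @export
print.mdm_eval <- function(x, ...) {
  cat("<mdm_eval> GS found ", x$n_subgroups, " subgroup(s), Rand = ",
      round(x$rand_index, 3), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Session-prediction harness across experimental conditions
#'
#' Given one study per condition on the same subjects, estimates each
#' subject's individual network per condition, and each subject's
#' leave-one-out predicted network per condition; a subject's condition
#' is "predicted correctly" when the distance (log Bayes factor
#' magnitude or SHD) between their estimated network and the predicted
#' network is smallest for the matching condition. Chance level is
#' `1 / n_conditions`.
#'
#' @param scores_by_condition Named list of `mdm_scores`, one per
#'   condition, sharing subject ids.
#' @param method `"iemn"` or `"memn"` for the predicted networks.
#' @param lambda Penalty strength (MEMN only).
#' @param metric `"shd"` or `"logbf"`.
#' @param search `"ipa"` or `"dgm"`.
#' @param studies_by_condition Named list of [mdm_study()] (required for
#'   `metric = "logbf"`, which evaluates on the held-out subject's data).
#' @return A list with `fraction_correct` (per condition), `overall`,
#'   `chance`, and the per-subject decision tibble `details`.
#' @export
session_harness <- function(scores_by_condition, method = c("iemn", "memn"),
                            lambda = NULL, metric = c("shd", "logbf"),
                            search = c("ipa", "dgm"),
                            studies_by_condition = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  search <- match.arg(search)
  conds <- names(scores_by_condition)
  stopifnot(length(conds) >= 2)
  ids <- unique(scores_by_condition[[1]]$subject_id)
  est <- lapply(scores_by_condition, individual_networks, search = search)
  pred <- lapply(scores_by_condition, function(sc) {
    setNames(lapply(ids, function(i) {
      predicted_network(sc, i, method = method, lambda = lambda,
                        search = search)
    }), ids)
  })
  details <- purrr::map(ids, function(i) {
    purrr::map(conds, function(ce) {
      dists <- vapply(conds, function(cp) {
        if (metric == "shd") {
          shd_networks(est[[ce]][[i]], pred[[cp]][[i]])
        } else {
          st <- studies_by_condition[[ce]]
          abs(network_logbf(st$series[[which(st$subject_id == i)]],
                            est[[ce]][[i]], pred[[cp]][[i]]))
        }
      }, numeric(1))
      tibble::tibble(subject_id = i, condition = ce,
                     chosen = conds[which.min(dists)],
                     correct = conds[which.min(dists)] == ce)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  frac <- details |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(fraction_correct = mean(.data$correct),
                     .groups = "drop")
  list(fraction_correct = frac, overall = mean(details$correct),
       chance = 1 / length(conds), details = details)
}
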