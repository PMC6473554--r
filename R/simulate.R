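#' Sample a random DAG by ordered edge inclusion
#'
#' Draws a uniform topological order, then includes each admissible edge
#' (earlier node -> later node) independently, with the inclusion
#' probability chosen so that the mean parent count per node is
#' `expected_parents`. An optional in-degree cap keeps every node's
#' parent set within a bounded search space (estimated connectivity DAGs
#' are themselves found under such a cap, so capped truths keep the
#' generating model inside the model class being searched); when a node
#' draws more parents than the cap, a random subset of size `max_parents`
#' is kept.
#'
#' @param n Number of nodes.
#' @param expected_parents Target mean number of parents per node, in
#'   `[0, n - 1]`.
#' @param seed Integer seed (mandatory; the generator is fully seeded).
#' @param max_parents Optional in-degree cap (default `NULL`, unbounded).
#' @return An [mdm_network()] with `acyclic = TRUE`.
#' @export
random_dag <- function(n, expected_parents = 2, seed, max_parents = NULL) {
  stopifnot(expected_parents >= 0, expected_parents <= n - 1)
  withr_seed(seed, {
    ord <- sample.int(n)
    # a node at position j in the order has j - 1 admissible parents, so
    # the mean count over positions is p * (n - 1) / 2; solve for p
    p_edge <- min(1, 2 * expected_parents / (n - 1))
    parents <- integer(n)
    for (j in seq_len(n)) {
      pred <- ord[seq_len(j - 1)]           # nodes before ord[j]
      pa <- pred[runif(length(pred)) < p_edge]
      if (!is.null(max_parents) && length(pa) > max_parents) {
        pa <- sample(pa, max_parents)
      }
      parents[ord[j]] <- nodes_to_mask(pa)
    }
    mdm_network(parents, search = "fixed")
  })
}

# Evaluate `code` under a temporary RNG seed, restoring the global state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one subject from a contemporaneous structural equation model
#'
#' Nodes are generated in a topological order of the DAG within each time
#' point: `y_t(r) = theta_0 + sum_p theta_t(p) * y_t(p) + e`, with
#' `e ~ N(0, obs_sd^2)`. Coefficients are either constant over time or
#' follow a Gaussian random walk (`coeff_process = "walk"`), reflecting
#' the time-varying-connectivity reading of effective connectivity.
#'
#' @param dag An acyclic [mdm_network()].
#' @param coef Edge coefficients: a named numeric vector
#'   `"from->to" = beta` (a base level per edge), a `t_len x n_edges`
#'   matrix of full trajectories with `"from->to"` column names (used as
#'   given; `coeff_process` is then ignored), or NULL to draw
#'   `|beta| ~ U(0.4, 0.8)` with random sign (drawn under `seed`).
#' @param obs_sd Observation noise standard deviation (scalar or per
#'   node).
#' @param t_len Number of time points (>= 2).
#' @param seed Integer seed.
#' @param coeff_process `"constant"` or `"walk"`.
#' @param walk_sd Innovation standard deviation of the random walk.
#' @param intercept Constant level term per node (default 0).
#' @return A list with `series` (a `t_len x n` matrix), `coef` (the edge
#'   coefficients used, as a named vector for `"constant"` or a matrix of
#'   trajectories for `"walk"`) and `dag`.
#' @export
simulate_subject <- function(dag, coef = NULL, obs_sd = 1, t_len, seed,
                             coeff_process = c("constant", "walk"),
                             walk_sd = 0.01, intercept = 0) {
  coeff_process <- match.arg(coeff_process)
  stopifnot(t_len >= 2)
  n <- length(dag$parents)
  ord <- topological_order(dag$parents)
  if (is.null(ord)) stop("dag must be acyclic to simulate from")
  obs_sd <- rep_len(obs_sd, n)
  intercept <- rep_len(intercept, n)
  ed <- network_edges(dag)
  enames <- edge_names(ed)
  withr_seed(seed, {
    if (is.matrix(coef)) {
      stopifnot(nrow(coef) == t_len, all(enames %in% colnames(coef)))
      traj <- coef[, enames, drop = FALSE]
    } else {
      if (is.null(coef)) {
        coef <- setNames(runif(nrow(ed), 0.4, 0.8) *
                           sample(c(-1, 1), nrow(ed), replace = TRUE),
                         enames)
      } else {
        stopifnot(all(enames %in% names(coef)))
        coef <- coef[enames]
      }
      traj <- matrix(rep(coef, each = t_len), t_len, length(coef),
                     dimnames = list(NULL, enames))
      if (coeff_process == "walk" && length(coef) > 0) {
        steps <- matrix(rnorm(t_len * length(coef), sd = walk_sd),
                        t_len, length(coef))
        traj <- traj + apply(steps, 2, cumsum)
      }
    }
    y <- matrix(0, t_len, n)
    for (r in ord) {
      y[, r] <- intercept[r] + rnorm(t_len, sd = obs_sd[r])
      pa <- mask_to_nodes(dag$parents[r])
      for (p in pa) {
        y[, r] <- y[, r] + traj[, paste0(p, "->", r)] * y[, p]
      }
    }
    colnames(y) <- dag$regions
    list(series = y,
         coef = if (is.matrix(coef) || coeff_process == "walk") traj
                else coef,
         dag = dag)
  })
}

#' Specify a multi-subject generating design
#'
#' Describes a study with known subgroup structure: each subgroup has a
#' true DAG, a number of subjects, and shared true coefficients (drawn
#' once per subgroup unless given). Defaults emulate a multi-subgroup
#' resting-state design: distinct random DAGs of about 2 expected
#' parents per node with in-degree at most 3, base coefficients
#' `|beta| ~ U(0.4, 0.8)` with random sign drifting as a random walk
#' over the session, and unit observation noise. Time-varying
#' coefficients are the default because a stationary Gaussian structural
#' equation model leaves edge directions Markov-unidentifiable; drifting
#' connectivity is both the regime this model class is built for and
#' what makes directions recoverable.
#'
#' @param n_nodes Number of regions.
#' @param t_len Time points per subject.
#' @param groups List of subgroup specs, each a list with `label`,
#'   `size`, and optionally `dag` (an [mdm_network()]), `coef`, `obs_sd`,
#'   `coeff_process`, `walk_sd`.
#' @param expected_parents Density of the random true DAGs.
#' @param dag_max_parents In-degree cap of the random true DAGs (default
#'   3, in line with the in-degree range of estimated effective
#'   connectivity DAGs; keeps the truth inside a capped search space).
#' @param coeff_process Default coefficient process for every subgroup:
#'   `"walk"` (default; connectivity drifts as a Gaussian random walk,
#'   the time-varying regime the model class is built for) or
#'   `"constant"`.
#' @param walk_sd Default random-walk innovation standard deviation per
#'   time step.
#' @param shared_fraction Fraction of each subgroup DAG's expected density
#'   contributed by a backbone of edges common to all subgroups (default
#'   0.6). Real multi-subgroup connectivity studies find the subgroup
#'   networks sharing most edges ("popular" edges) while differing in the
#'   rest; the backbone reproduces that, and is what one-network group
#'   estimators are judged against. Set to 0 for fully independent DAGs.
#' @return An object of class `mdm_sim_spec`.
#' @export
mdm_sim_spec <- function(n_nodes, t_len, groups, expected_parents = 2,
                         dag_max_parents = 3, coeff_process = "walk",
                         walk_sd = 0.05, shared_fraction = 0.6) {
  stopifnot(t_len >= 2, length(groups) >= 1)
  groups <- lapply(groups, function(g) {
    stopifnot(!is.null(g$label), !is.null(g$size), g$size >= 1)
    g
  })
  structure(
    list(n_nodes = n_nodes, t_len = t_len, groups = groups,
         expected_parents = expected_parents,
         dag_max_parents = dag_max_parents,
         coeff_process = coeff_process, walk_sd = walk_sd,
         shared_fraction = shared_fraction),
    class = "mdm_sim_spec"
  )
}

#' Built-in study designs at reference and desk scale
#'
#' `"paper"` is the full three-subgroup design (3 distinct 12-node DAGs,
#' 10 subjects each, 1158 time points); `"desk"` is a scaled-down variant
#' (3 distinct 8-node DAGs, 6 subjects each, 400 time points) with the
#' same density and coefficient distribution, sized for interactive use
#' and testing.
#'
#' @param preset `"paper"` or `"desk"`.
#' @return An `mdm_sim_spec`.
#' @export
sim_preset <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    mdm_sim_spec(n_nodes = 12, t_len = 1158,
                 groups = lapply(1:3, function(g) {
                   list(label = paste0("dag", g), size = 10)
                 }))
  } else {
    mdm_sim_spec(n_nodes = 8, t_len = 400,
                 groups = lapply(1:3, function(g) {
                   list(label = paste0("dag", g), size = 6)
                 }))
  }
}

#' Simulate a full multi-subject study with known truth
#'
#' Subject-level seeds are derived deterministically from the master seed
#' and the subgroup label, so a subject's data do not depend on the order
#' in which subgroups are listed.
#'
#' @param spec An [mdm_sim_spec()] (or [sim_preset()] output).
#' @param seed Master integer seed (mandatory).
#' @return A list of class `mdm_truth` with `study` (an [mdm_study()]
#'   whose `group` column holds the true labels), `dags` (named list of
#'   true [mdm_network()]s), `coef` (named list of true coefficients) and
#'   `labels` (named character vector subject -> subgroup).
#' @export
simulate_study <- function(spec, seed) {
  stopifnot(inherits(spec, "mdm_sim_spec"))
  n <- spec$n_nodes
  sf <- spec$shared_fraction
  if (is.null(sf)) sf <- 0.6
  # shared topological order and backbone of edges common to all
  # subgroups; each subgroup adds private edges on top of it
  ord <- withr_seed(derive_seed(seed, "order"), sample.int(n))
  bb_cap <- spec$dag_max_parents
  if (!is.null(bb_cap)) bb_cap <- max(1L, bb_cap - 1L)  # leave room for
  backbone <- if (sf > 0) {                             # private edges
    sample_ordered_edges(ord, spec$expected_parents * sf, bb_cap,
                         integer(n), derive_seed(seed, "backbone"))
  } else {
    integer(n)
  }
  dags <- list()
  coefs <- list()
  series <- list()
  labels <- character(0)
  for (g in spec$groups) {
    gseed <- derive_seed(seed, paste0("dag:", g$label))
    dag <- g[["dag"]]
    if (is.null(dag)) {
      pa <- sample_ordered_edges(ord, spec$expected_parents * (1 - sf),
                                 spec$dag_max_parents, backbone, gseed)
      dag <- mdm_network(pa)
    }
    coef <- g[["coef"]]
    if (is.null(coef)) {
      ed <- network_edges(dag)
      coef <- withr_seed(derive_seed(seed, paste0("coef:", g$label)), {
        setNames(runif(nrow(ed), 0.4, 0.8) *
                   sample(c(-1, 1), nrow(ed), replace = TRUE),
                 edge_names(ed))
      })
    }
    dags[[g$label]] <- dag
    # one true coefficient trajectory per subgroup: members share the
    # same parameters and differ only in observation noise
    proc <- if (is.null(g[["coeff_process"]])) spec$coeff_process
            else g[["coeff_process"]]
    wsd <- if (is.null(g[["walk_sd"]])) spec$walk_sd else g[["walk_sd"]]
    if (!is.matrix(coef) && proc == "walk" && length(coef) > 0) {
      coef <- withr_seed(derive_seed(seed, paste0("traj:", g$label)), {
        steps <- matrix(rnorm(spec$t_len * length(coef), sd = wsd),
                        spec$t_len, length(coef))
        matrix(rep(coef, each = spec$t_len), spec$t_len, length(coef),
               dimnames = list(NULL, names(coef))) +
          apply(steps, 2, cumsum)
      })
    }
    coefs[[g$label]] <- coef
    for (s in seq_len(g$size)) {
      id <- sprintf("%s_s%02d", g$label, s)
      sseed <- derive_seed(seed, paste0("subj:", g$label, ":", s))
      sim <- simulate_subject(
        dag, coef = coef,
        obs_sd = if (is.null(g[["obs_sd"]])) 1 else g[["obs_sd"]],
        t_len = spec$t_len, seed = sseed,
        coeff_process = proc, walk_sd = wsd
      )
      series[[id]] <- sim$series
      labels[id] <- g$label
    }
  }
  study <- mdm_study(series, group = unname(labels))
  structure(
    list(study = study, dags = dags, coef = coefs, labels = labels),
    class = "mdm_truth"
  )
}

#' @export
print.mdm_truth <- function(x, ...) {
  cat("<mdm_truth> ", nrow(x$study), " subjects in ", length(x$dags),
      " subgroup(s), n = ", length(attr(x$study, "regions")), "\n", sep = "")
  invisible(x)
}

# Add random edges along a fixed topological order on top of existing
# parent sets, targeting `density` expected extra parents per node and
# respecting the per-node cap.
sample_ordered_edges <- function(ord, density, max_parents, base, seed) {
  n <- length(ord)
  withr_seed(seed, {
    p_edge <- min(1, 2 * density / (n - 1))
    parents <- base
    for (j in seq_len(n)) {
      node <- ord[j]
      pred <- setdiff(ord[seq_len(j - 1)], mask_to_nodes(base[node]))
      pa <- pred[runif(length(pred)) < p_edge]
      room <- if (is.null(max_parents)) length(pa) else {
        max_parents - popcount(parents[node])
      }
      if (length(pa) > room) pa <- sample(pa, max(room, 0))
      if (length(pa) > 0) {
        parents[node] <- bitwOr(parents[node], nodes_to_mask(pa))
      }
    }
    parents
  })
}

# "from->to" labels of an edge-list tibble (zero-length safe).
edge_names <- function(ed) {
  if (nrow(ed) == 0) return(character(0))
  paste0(ed$from, "->", ed$to)
}

#' Write a truth bundle: subject CSVs, manifest, and true edge lists
#'
#' Serializes a simulated study so it can be re-read with [read_study()],
#' alongside one `truth_<label>.csv` edge list per subgroup (columns
#' `from`, `to`, region names) describing the generating DAGs.
#'
#' @param truth An `mdm_truth` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_truth <- function(truth, dir) {
  mpath <- write_study(truth$study, dir)
  for (lab in names(truth$dags)) {
    ed <- tidy(truth$dags[[lab]])
    readr::write_csv(ed[, c("from", "to")],
                     file.path(dir, paste0("truth_", lab, ".csv")))
  }
  invisible(mpath)
}
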