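#' Directed network objects
#'
#' A network is stored as one parent bitmask per node, together with the
#' region names, the total score it attained, and whether it is acyclic.
#' Ties during search are always broken in favour of fewer parents, then
#' the smallest bitmask (and, in the DAG program, the smallest sink
#' index), so identical inputs yield identical networks.
#'
#' @param parents Integer vector of parent bitmasks, one per node.
#' @param regions Character vector of region names.
#' @param total_score Total score of the network (sum of local scores),
#'   if known.
#' @param search Label of the search that produced it (`"ipa"`, `"dgm"`,
#'   or `"fixed"`).
#' @return An object of class `mdm_network`.
#' @export
mdm_network <- function(parents, regions = NULL, total_score = NA_real_,
                        search = "fixed") {
  n <- length(parents)
  parents <- as.integer(parents)
  if (is.null(regions)) regions <- paste0("R", seq_len(n))
  for (r in seq_len(n)) {
    if (bitwAnd(parents[r], bitwShiftL(1L, r - 1L)) != 0L) {
      stop("self-loop at node ", r)
    }
  }
  structure(
    list(parents = parents, regions = regions,
         acyclic = is_acyclic(parents),
         total_score = total_score, search = search, strengths = NULL),
    class = "mdm_network"
  )
}

#' @export
print.mdm_network <- function(x, ...) {
  ne <- sum(popcount(x$parents))
  cat("<mdm_network> ", length(x$parents), " nodes, ", ne, " edges, ",
      if (x$acyclic) "acyclic" else "cyclic",
      if (!is.na(x$total_score)) paste0(", score = ",
                                        format(x$total_score)), "\n",
      sep = "")
  invisible(x)
}

#' @export
format.mdm_network <- function(x, ...) {
  ed <- network_edges(x)
  paste0(x$regions[ed$from], "->", x$regions[ed$to], collapse = ", ")
}

# Edge list (integer node indices) of a network.
network_edges <- function(net) {
  n <- length(net$parents)
  from <- to <- integer(0)
  for (r in seq_len(n)) {
    pa <- mask_to_nodes(net$parents[r])
    from <- c(from, pa)
    to <- c(to, rep(r, length(pa)))
  }
  tibble::tibble(from = from, to = to)
}

#' @describeIn mdm_network Edge-list tibble of a network, with smoothed
#'   strength summaries when the network has been fitted.
#' @param x An `mdm_network`.
#' @param ... Unused.
#' @export
tidy.mdm_network <- function(x, ...) {
  ed <- network_edges(x)
  out <- tibble::tibble(
    from = x$regions[ed$from], to = x$regions[ed$to],
    from_node = ed$from, to_node = ed$to
  )
  if (!is.null(x$strengths)) {
    st <- dplyr::filter(x$strengths, !is.na(.data$from_node))
    out <- dplyr::left_join(
      out, dplyr::select(st, "from_node", "to_node",
                         "theta_bar", "sigma2_bar"),
      by = c("from_node", "to_node")
    )
  }
  out
}

#' @describeIn mdm_network One-row summary (nodes, edges, acyclicity,
#'   total score).
#' @export
glance.mdm_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$parents),
    n_edges = sum(popcount(x$parents)),
    acyclic = x$acyclic,
    total_score = x$total_score,
    search = x$search
  )
}

# Single-subject (or summed) score table -> per-node score arrays over the
# full 2^n mask lattice; -Inf where the set is not admissible.
score_arrays <- function(scores) {
  n <- attr(scores, "n")
  N <- bitwShiftL(1L, n)
  tbl <- tibble::as_tibble(scores)
  if (length(unique(tbl$subject_id)) != 1) {
    stop("expected scores of a single subject; use sum_scores() first")
  }
  arr <- matrix(-Inf, N, n)
  arr[cbind(tbl$pset + 1L, tbl$node)] <- tbl$score
  arr
}

#' Unconstrained per-node search (MDM-DGM)
#'
#' Chooses, for every node independently, the parent set with the highest
#' local score. The resulting directed graph may contain cycles; the
#' `acyclic` flag reports whether it happens to be a DAG.
#'
#' @param scores An `mdm_scores` table for a single subject, or a summed
#'   table from [sum_scores()].
#' @return An [mdm_network()].
#' @export
dgm_search <- function(scores) {
  n <- attr(scores, "n")
  tbl <- tibble::as_tibble(scores)
  if (length(unique(tbl$subject_id)) != 1) {
    stop("expected scores of a single subject; use sum_scores() first")
  }
  tbl <- dplyr::arrange(tbl, .data$node, .data$n_parents, .data$pset)
  parents <- integer(n)
  total <- 0
  for (r in seq_len(n)) {
    sub <- tbl[tbl$node == r, ]
    k <- which.max(sub$score)  # rows in canonical order: parsimony tie-break
    parents[r] <- sub$pset[k]
    total <- total + sub$score[k]
  }
  net <- mdm_network(parents, attr(scores, "regions"), total, "dgm")
  net
}

# Best-subset tables: for each node r, the best admissible parent set
# contained in every candidate mask (subset-lattice dynamic program).
best_subset_tables <- function(scores) {
  n <- attr(scores, "n")
  N <- bitwShiftL(1L, n)
  arr <- score_arrays(scores)
  all_masks <- 0:(N - 1L)
  sizes0 <- popcount(all_masks)
  BV <- matrix(-Inf, N, n)
  BM <- matrix(NA_integer_, N, n)
  for (r in seq_len(n)) {
    bv <- arr[, r]
    bm <- ifelse(is.finite(bv), all_masks, NA_integer_)
    bs <- ifelse(is.finite(bv), sizes0, Inf)
    for (b in seq_len(n) - 1L) {
      if (b == r - 1L) next
      bit <- bitwShiftL(1L, b)
      idx <- which(bitwAnd(all_masks, bit) != 0L)
      src <- idx - bit
      better <- (bv[src] > bv[idx]) |
        (bv[src] == bv[idx] &
           (bs[src] < bs[idx] | (bs[src] == bs[idx] & bm[src] < bm[idx])))
      better[is.na(better)] <- FALSE
      upd <- idx[better]
      from <- src[better]
      bv[upd] <- bv[from]
      bm[upd] <- bm[from]
      bs[upd] <- bs[from]
    }
    BV[, r] <- bv
    BM[, r] <- bm
  }
  list(BV = BV, BM = BM)
}

#' Exact score-maximizing DAG search (MDM-IPA-equivalent)
#'
#' Finds the directed acyclic graph maximizing the total score, i.e. the
#' sum over nodes of the local score of their parent sets, by exact
#' dynamic programming over node subsets (best-sink recursion). The
#' optimum equals the integer-programming formulation's; no solver is
#' needed. Feasible up to about 20 nodes.
#'
#' @inheritParams dgm_search
#' @return An [mdm_network()] with `acyclic = TRUE`.
#' @export
dag_search_exact <- function(scores) {
  n <- attr(scores, "n")
  if (n > 20) stop("n = ", n, " exceeds the exact-search cap (20); ",
                   "reduce max_parents and prune, or use dgm_search()")
  N <- bitwShiftL(1L, n)
  bt <- best_subset_tables(scores)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  dp <- rep(-Inf, N)
  dp[1] <- 0
  sink <- integer(N)
  for (S in 1:(N - 1L)) {
    nodes <- mask_to_nodes(S)
    rest <- S - bits[nodes]
    vals <- dp[rest + 1L] + bt$BV[cbind(rest + 1L, nodes)]
    k <- which.max(vals)  # ties -> smallest sink index
    dp[S + 1L] <- vals[k]
    sink[S + 1L] <- nodes[k]
  }
  parents <- integer(n)
  S <- N - 1L
  while (S > 0L) {
    r <- sink[S + 1L]
    rest <- S - bits[r]
    parents[r] <- bt$BM[rest + 1L, r]
    S <- rest
  }
  mdm_network(parents, attr(scores, "regions"), dp[N], "ipa")
}

#' Search a score table with either structure-search variant
#'
#' @param scores An `mdm_scores` table (single subject or summed).
#' @param search `"ipa"` for the exact acyclic search, `"dgm"` for the
#'   unconstrained per-node search.
#' @return An [mdm_network()].
#' @export
search_network <- function(scores, search = c("ipa", "dgm")) {
  search <- match.arg(search)
  if (search == "ipa") dag_search_exact(scores) else dgm_search(scores)
}

#' Individual networks for every subject in a study
#'
#' @param scores An `mdm_scores` table with one or more subjects.
#' @inheritParams search_network
#' @return A named list of [mdm_network()], one per subject.
#' @export
individual_networks <- function(scores, search = c("ipa", "dgm")) {
  search <- match.arg(search)
  ids <- unique(scores$subject_id)
  nets <- lapply(ids, function(id) {
    search_network(scores_subset(scores, id), search)
  })
  setNames(nets, ids)
}

#' Fit a fixed network to one subject and attach smoothed strengths
#'
#' Refits the per-node DLMs under the given structure (choosing each
#' node's discount factor by maximum score), smooths, and attaches the
#' time-averaged coefficient summaries `theta_bar` and `sigma2_bar` per
#' edge (and per intercept).
#'
#' @param series A `T x n` matrix, or an [mdm_study()] row's series.
#' @param network An [mdm_network()].
#' @param prior An [mdm_prior()].
#' @param standardize Standardize columns first (default TRUE).
#' @return The network with a `strengths` tibble (`from_node`, `to_node`,
#'   `theta_bar`, `sigma2_bar`, `delta`; `from_node = NA` marks the
#'   intercept of each node) and `total_score` recomputed for this
#'   subject.
#' @export
fit_network <- function(series, network, prior = mdm_prior(),
                        standardize = TRUE) {
  m <- as.matrix(series)
  n <- ncol(m)
  stopifnot(length(network$parents) == n)
  if (standardize) {
    s <- apply(m, 2, sd)
    if (any(s == 0)) stop("constant column; cannot standardize")
    m <- scale(m, center = TRUE, scale = s)
  }
  rows <- list()
  total <- 0
  for (r in seq_len(n)) {
    pa <- mask_to_nodes(network$parents[r])
    sc <- score_sets_cpp(m, r, network$parents[r], prior$delta_grid,
                         prior$c0_scale, prior$n0, prior$d0)
    kd <- max.col(matrix(as.numeric(sc), 1), ties.method = "last")
    delta <- prior$delta_grid[kd]
    total <- total + max(sc)
    F <- build_regressors(m, r, pa)
    sm <- smooth_node(filter_node(m[, r], F, prior, delta = delta))
    rows[[r]] <- tibble::tibble(
      from_node = c(NA_integer_, pa), to_node = r,
      theta_bar = sm$theta_bar, sigma2_bar = sm$sigma2_bar, delta = delta
    )
  }
  network$strengths <- dplyr::bind_rows(rows)
  network$total_score <- total
  network
}
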