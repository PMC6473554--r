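#' Pairwise log-Bayes-factor separation between two subjects
#'
#' `d(i, j)` compares the best scores the two subjects attain with free
#' individual structures against the best they attain sharing a single
#' pairwise group structure, under the same search variant:
#' `d(i, j) = c_ij(m_I) - c_ij(m_G)`. For the acyclic search this is the
#' log Bayes factor of "different structures" against "shared structure".
#' It is symmetric, non-negative, and zero when the two individual MAP
#' structures coincide. Tiny negative values from floating-point
#' summation are clamped to zero (clamping is reported via a message).
#'
#' @param scores An `mdm_scores` table containing both subjects.
#' @param i,j Subject ids.
#' @param search `"ipa"` or `"dgm"`.
#' @param clamp Clamp small negatives to 0 (default TRUE).
#' @return Scalar separation.
#' @export
pairwise_separation <- function(scores, i, j, search = c("ipa", "dgm"),
                                clamp = TRUE) {
  search <- match.arg(search)
  if (identical(i, j)) return(0)
  best_i <- search_network(scores_subset(scores, i), search)$total_score
  best_j <- search_network(scores_subset(scores, j), search)$total_score
  best_g <- search_network(sum_scores(scores, c(i, j)), search)$total_score
  d <- best_i + best_j - best_g
  if (d < 0 && clamp) {
    if (d < -1e-9) message("negative separation ", format(d),
                           " for (", i, ", ", j, ") clamped to 0")
    d <- 0
  }
  d
}

#' Pairwise separation matrix for a whole study
#'
#' @param scores An `mdm_scores` table for all subjects.
#' @param search `"ipa"` or `"dgm"`.
#' @return A symmetric `S x S` matrix of class `mdm_separation` with zero
#'   diagonal and subject ids as dimnames; the search variant is kept in
#'   the `"search"` attribute.
#' @export
separation_matrix <- function(scores, search = c("ipa", "dgm")) {
  search <- match.arg(search)
  ids <- unique(scores$subject_id)
  S <- length(ids)
  # cache each subject's best score and summed tables pairwise
  best <- vapply(ids, function(id) {
    search_network(scores_subset(scores, id), search)$total_score
  }, numeric(1))
  D <- matrix(0, S, S, dimnames = list(ids, ids))
  if (S >= 2) {
    for (a in 1:(S - 1)) {
      for (b in (a + 1):S) {
        bg <- search_network(sum_scores(scores, ids[c(a, b)]),
                             search)$total_score
        d <- max(best[a] + best[b] - bg, 0)
        D[a, b] <- D[b, a] <- d
      }
    }
  }
  structure(D, class = c("mdm_separation", "matrix", "array"),
            search = search)
}

#' Agglomerative clustering of a separation matrix
#'
#' Thin wrapper over [stats::hclust()] on the separation treated as a
#' dissimilarity; average linkage (UPGMA) by default.
#'
#' @param sep An `mdm_separation` matrix (or any symmetric matrix with
#'   zero diagonal).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(sep,
                                 linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  if (nrow(sep) < 2) stop("need at least 2 subjects to cluster")
  hclust(as.dist(sep), method = linkage)
}

#' Adaptive tree cut with minimum cluster size
#'
#' Descends the dendrogram from the root and splits a branch whenever its
#' join height stands well clear of the internal merge heights of its
#' children -- i.e. whenever the gap between "between-subgroup" and
#' "within-subgroup" joins exceeds `min_gap` times the tree height. The
#' cut height therefore adapts per branch rather than being one global
#' line. Clusters smaller than `min_cluster_size` are not forced into
#' neighbours; each of their members becomes a singleton subgroup, so
#' atypical subjects surface as their own groups rather than
#' contaminating another. A tree with no clear gaps (e.g. all pairwise
#' separations equal) yields a single subgroup.
#'
#' @param tree An `hclust` tree from [hierarchical_cluster()].
#' @param min_cluster_size Smallest cluster kept as a proper subgroup
#'   (default 3).
#' @param min_gap Minimum height gap, as a fraction of the tree height,
#'   for a split (default 0.1: within-subgroup merge heights wobble by a
#'   few logBF units while between-subgroup joins sit an order of
#'   magnitude higher, so one tenth of the tree height separates the two
#'   regimes).
#' @param deep_gap Stricter gap fraction (default 0.3) required for a
#'   split that would carve off a branch smaller than
#'   `min_cluster_size`: an atypical subject must be strongly detached
#'   before it is declared its own subgroup.
#' @return A tibble of class `mdm_clusters` with columns `subject_id`,
#'   `cluster` (labels `1..G`, proper subgroups first, singletons after)
#'   and `singleton`.
#' @export
cut_tree_dynamic <- function(tree, min_cluster_size = 3, min_gap = 0.1,
                             deep_gap = 0.3) {
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  labels <- tree$labels
  if (is.null(labels)) labels <- as.character(seq_along(tree$order))
  S <- length(labels)
  hmax <- max(tree$height)
  memb <- integer(S)
  next_id <- 0L
  if (hmax <= 0) {
    memb[] <- 1L
  } else {
    thr <- min_gap * hmax
    thr_deep <- deep_gap * hmax
    # internal height of a merge-tree child; leaves carry no scale of
    # their own, so they contribute no split evidence (NA)
    child_h <- function(c) if (c < 0) NA_real_ else tree$height[c]
    leaves_of <- function(node) {
      if (node < 0) return(-node)
      unlist(lapply(tree$merge[node, ], leaves_of))
    }
    visit <- function(node) {
      if (node < 0) {  # a split-off leaf is its own cluster
        next_id <<- next_id + 1L
        memb[-node] <<- next_id
        return(invisible())
      }
      ch <- tree$merge[node, ]
      inner <- suppressWarnings(min(child_h(ch[1]), child_h(ch[2]),
                                    na.rm = TRUE))
      gap <- tree$height[node] - inner
      sizes <- vapply(ch, function(c) length(leaves_of(c)), integer(1))
      need <- if (any(sizes < min_cluster_size)) thr_deep else thr
      if (is.finite(inner) && gap > need) {
        visit(ch[1])
        visit(ch[2])
      } else {
        next_id <<- next_id + 1L
        memb[leaves_of(node)] <<- next_id
      }
    }
    visit(nrow(tree$merge))
  }
  sizes <- table(memb)
  proper <- as.integer(names(sizes)[sizes >= min_cluster_size])
  cluster <- integer(length(memb))
  for (g in seq_along(proper)) cluster[memb == proper[g]] <- g
  singles <- which(cluster == 0L)
  cluster[singles] <- length(proper) + seq_along(singles)
  out <- tibble::tibble(
    subject_id = labels,
    cluster = cluster,
    singleton = seq_along(labels) %in% singles
  )
  structure(out, class = c("mdm_clusters", class(tibble::tibble())),
            n_proper = length(proper))
}

#' Classical multidimensional scaling of a separation matrix
#'
#' Double-centred eigendecomposition embedding; the share of the positive
#' eigenvalue mass captured by the first `k` axes measures how faithfully
#' the plane (or k-space) represents the separations.
#'
#' @param sep An `mdm_separation` (or symmetric distance) matrix.
#' @param k Embedding dimension.
#' @return A list with `points` (an `S x k` matrix) and
#'   `variance_explained`; an all-zero matrix embeds at the origin with
#'   `variance_explained = 1`.
#' @export
classical_mds <- function(sep, k = 2) {
  stopifnot(k >= 1)
  S <- nrow(sep)
  k <- min(k, S - 1)
  if (all(sep == 0)) {
    return(list(points = matrix(0, S, k,
                                dimnames = list(rownames(sep), NULL)),
                variance_explained = 1))
  }
  # cmdscale warns when k exceeds the positive-eigenvalue rank; the
  # zero-padding below is the documented behaviour for that case
  fit <- suppressWarnings(cmdscale(as.dist(sep), k = k, eig = TRUE))
  pos <- fit$eig[fit$eig > 1e-12 * max(abs(fit$eig))]
  ve <- sum(head(sort(pos, decreasing = TRUE), k)) / sum(pos)
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate embeddings pad with zeros
    pts <- cbind(pts, matrix(0, S, k - ncol(pts)))
  }
  list(points = pts, variance_explained = ve)
}

#' The full group-structure (GS) pipeline
#'
#' Separation matrix, average-linkage clustering, adaptive tree cut, and
#' one network per recovered subgroup estimated from the members' summed
#' scores.
#'
#' @param scores An `mdm_scores` table for the study.
#' @param study Optional [mdm_study()] for strength fitting.
#' @param search `"ipa"` or `"dgm"`.
#' @param linkage Linkage for [hierarchical_cluster()].
#' @param min_cluster_size Passed to [cut_tree_dynamic()].
#' @return A list of class `mdm_gs` with `separation`, `tree`,
#'   `clusters`, and `networks` (one fitted [mdm_network()] per
#'   subgroup, named by cluster label).
#' @export
gs_cluster <- function(scores, study = NULL, search = c("ipa", "dgm"),
                       linkage = "average", min_cluster_size = 3) {
  search <- match.arg(search)
  sep <- separation_matrix(scores, search)
  tree <- hierarchical_cluster(sep, linkage)
  cl <- cut_tree_dynamic(tree, min_cluster_size)
  nets <- subgroup_networks(scores, cl, study = study, search = search)
  structure(
    list(separation = sep, tree = tree, clusters = cl, networks = nets,
         search = search),
    class = "mdm_gs"
  )
}

#' @export
print.mdm_gs <- function(x, ...) {
  cat("<mdm_gs> ", nrow(x$clusters), " subjects in ",
      length(x$networks), " subgroup(s) [", x$search, "]\n", sep = "")
  invisible(x)
}

#' Per-subgroup networks from a cluster assignment
#'
#' Sums each subgroup's member score tables and searches; a singleton
#' subgroup's network is that subject's individual network. When `study`
#' is given, strengths are averaged over the subgroup members only.
#'
#' @param scores An `mdm_scores` table.
#' @param clusters An `mdm_clusters` assignment (or a tibble with
#'   `subject_id` and `cluster`).
#' @param study Optional [mdm_study()] for strengths.
#' @param search `"ipa"` or `"dgm"`.
#' @return Named list of [mdm_network()], one per cluster label.
#' @export
subgroup_networks <- function(scores, clusters, study = NULL,
                              search = c("ipa", "dgm")) {
  search <- match.arg(search)
  gs <- sort(unique(clusters$cluster))
  nets <- lapply(gs, function(g) {
    members <- clusters$subject_id[clusters$cluster == g]
    net <- search_network(sum_scores(scores, members), search)
    if (!is.null(study)) {
      net <- average_strengths(study, net, members,
                               prior = attr(scores, "prior"))
    }
    net
  })
  setNames(nets, as.character(gs))
}

#' @describeIn separation_matrix Long-format tibble of the separations.
#' @param x An `mdm_separation`.
#' @param ... Unused.
#' @export
tidy.mdm_separation <- function(x, ...) {
  ids <- rownames(x)
  out <- expand.grid(i = ids, j = ids, stringsAsFactors = FALSE)
  out$separation <- as.numeric(x)
  tibble::as_tibble(out[out$i != out$j, ])
}
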