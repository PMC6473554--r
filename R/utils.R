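# Bitmask helpers for parent sets: nodes are 1..n, bit j-1 encodes node j.

#' Convert a parent-set bitmask to a sorted vector of node indices
#'
#' @param mask Integer bitmask (bit `j - 1` set means node `j` is a parent).
#' @return Integer vector of node indices, increasing.
#' @export
#' @examples
#' mask_to_nodes(5L) # nodes 1 and 3
mask_to_nodes <- function(mask) {
  if (mask == 0L) return(integer(0))
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L)
}

#' Convert a vector of node indices to a parent-set bitmask
#'
#' @param nodes Integer vector of node indices (1-based, distinct).
#' @return Integer bitmask.
#' @export
#' @examples
#' nodes_to_mask(c(1, 3))
nodes_to_mask <- function(nodes) {
  if (length(nodes) == 0) return(0L)
  stopifnot(!anyDuplicated(nodes), all(nodes >= 1), all(nodes <= 31))
  sum(bitwShiftL(1L, as.integer(nodes) - 1L))
}

# Number of set bits of each element of an integer vector.
popcount <- function(x) {
  out <- integer(length(x))
  while (any(x > 0L)) {
    out <- out + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  out
}

# All subsets of `universe` (integer node indices) of size <= max_size,
# as bitmasks ordered by (size, mask value) -- the package-wide canonical
# order, which makes which.max() implement the parsimony tie-break.
enumerate_psets <- function(universe, max_size) {
  masks <- 0L
  if (max_size >= 1 && length(universe) >= 1) {
    for (k in seq_len(min(max_size, length(universe)))) {
      # guard combn's scalar-x shorthand: a length-1 universe is a set
      sets <- if (length(universe) == 1) {
        list(as.integer(universe))
      } else {
        combn(as.integer(universe), k, simplify = FALSE)
      }
      masks <- c(masks, vapply(sets, nodes_to_mask, integer(1)))
    }
  }
  masks <- as.integer(masks)
  masks[order(popcount(masks), masks)]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise log-sum-exp of a matrix.
col_logsumexp <- function(M) {
  cm <- apply(M, 2, max)
  cm + log(colSums(exp(sweep(M, 2, cm))))
}

# Topological order of a graph given as a vector of parent bitmasks,
# or NULL if the graph has a directed cycle.
topological_order <- function(parents) {
  n <- length(parents)
  remaining <- seq_len(n)
  placed <- 0L
  order <- integer(0)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(
      remaining,
      function(r) bitwAnd(parents[r], bitwNot(placed)) == 0L,
      logical(1)
    )]
    if (length(ready) == 0) return(NULL)
    order <- c(order, ready)
    placed <- bitwOr(placed, Reduce(bitwOr, bitwShiftL(1L, ready - 1L)))
    remaining <- setdiff(remaining, ready)
  }
  order
}

is_acyclic <- function(parents) !is.null(topological_order(parents))

# Derive a 32-bit-safe child seed from a master seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629 + 1)
}
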