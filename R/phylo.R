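#' Kimura two-parameter distance from transition/transversion proportions
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` the proportion of
#' transition differences (A<->G, C<->T) and `Q` the proportion of
#' transversion differences among compared sites.
#'
#' @param P Transition proportion in `[0, 1)`.
#' @param Q Transversion proportion in `[0, 1)`.
#' @return The K2P distance (substitutions/site).
#' @examples
#' k2p_distance(0.1, 0.05)
#' @export
k2p_distance <- function(P, Q) {
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort_dx(sprintf("K2P distance undefined (saturation): P=%.3f Q=%.3f", P, Q),
             "barcodeDx_saturation_error")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

TRANSITION_PAIRS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

# P, Q and compared-site count for one row pair (pairwise deletion of
# gap/ambiguous columns).
pair_pq <- function(x, y) {
  ok <- x %in% DNA_BASES & y %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) return(list(n = 0L, P = NA_real_, Q = NA_real_))
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  ts <- diff & !is.na(TRANSITION_PAIRS[paste0(xs, ys)])
  list(n = n, P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' Gap and ambiguous columns are deleted pairwise (not listwise), so
#' indel-rich spacers keep most of their signal for each pair.
#'
#' @param aln A `dna_alignment` with >= 2 rows.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- nrow(aln$mat)
  if (n < 2L) abort_dx("distance matrix needs >= 2 rows", "barcodeDx_contract_error")
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pq <- pair_pq(aln$mat[i, ], aln$mat[j, ])
      if (pq$n == 0L) {
        abort_dx(sprintf("no comparable site between '%s' and '%s'",
                         aln$ids[i], aln$ids[j]),
                 "barcodeDx_missing_overlap_error")
      }
      D[i, j] <- D[j, i] <- k2p_distance(pq$P, pq$Q)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`); negative branch
#' lengths, an artifact of noisy distances, are clamped to zero.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) abort_dx("NJ needs >= 3 taxa", "barcodeDx_contract_error")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr$edge.length <- tr$edge.length + 0  # normalize any negative zero
  tr
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Alignment columns are resampled with replacement `replicates` times; each
#' replicate is re-distanced (K2P, pairwise deletion) and re-joined, and each
#' internal bipartition of the original tree receives the percentage of
#' replicate trees containing it. Reproducible for a fixed seed (R's default
#' Mersenne-Twister generator).
#'
#' @param aln A `dna_alignment` with >= 3 rows.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @return An `ape::phylo` tree whose `node.label` holds integer supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(inherits(aln, "dna_alignment"), replicates >= 1L)
  base_tree <- nj_tree(distance_matrix(aln))
  resample_tree <- function(cols) {
    sub <- aln
    sub$mat <- aln$mat[, cols, drop = FALSE]
    sub$L <- length(cols)
    nj_tree(distance_matrix(sub))
  }
  set.seed(seed)
  reps <- lapply(seq_len(replicates), function(i) {
    resample_tree(sample.int(aln$L, aln$L, replace = TRUE))
  })
  counts <- ape::prop.clades(base_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / replicates))
  base_tree$node.label <- c("", as.character(support[-1L]))
  # keep numeric supports reachable without reparsing labels
  attr(base_tree, "support") <- support
  base_tree
}

# Tip-id sets descending from each internal node (arbitrary rooting); every
# internal edge of an unrooted tree corresponds to one such clade.
node_tip_sets <- function(tree) {
  lapply(ape::prop.part(tree), function(idx) tree$tip.label[idx])
}

#' Test whether a taxon set is monophyletic in an unrooted tree
#'
#' True iff some internal edge bipartition separates exactly `group` from
#' all remaining taxa (singletons and the full taxon set are trivially
#' monophyletic). The outgroup, when given, is only checked for disjointness
#' from the group — the split criterion itself is rooting-free.
#'
#' @param tree An `ape::phylo` tree.
#' @param group Character vector of tip labels.
#' @param outgroup Optional character vector of tip labels disjoint from
#'   `group`.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, group, outgroup = NULL) {
  tips <- tree$tip.label
  unknown <- setdiff(c(group, outgroup), tips)
  if (length(unknown)) {
    abort_dx(sprintf("unknown taxa: %s", paste(unknown, collapse = ", ")),
             "barcodeDx_lookup_error")
  }
  if (length(intersect(group, outgroup))) {
    abort_dx("group and outgroup overlap", "barcodeDx_contract_error")
  }
  group <- unique(group)
  if (length(group) <= 1L || length(group) >= length(tips)) return(TRUE)
  gset <- sort(group)
  comp <- sort(setdiff(tips, group))
  for (clade in node_tip_sets(tree)) {
    sc <- sort(clade)
    if (identical(sc, gset) || identical(sc, comp)) return(TRUE)
  }
  FALSE
}
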