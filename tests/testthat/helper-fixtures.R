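# Shared builders for in-code fixtures.

# Alignment from named residue strings; species taken from a parallel vector
# or parsed from names "id|species".
aln_from <- function(seqs, species = NULL) {
  ids <- names(seqs)
  if (is.null(species) && any(grepl("|", ids, fixed = TRUE))) {
    parts <- strsplit(ids, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    species <- vapply(parts, `[`, "", 2L)
  }
  dna_alignment(ids, unname(seqs), species)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force oracle: scan every column for states fixed in the
# target and absent from all non-target rows (exact characters only,
# ambiguity treated by set overlap like the contract requires).
oracle_diagnostic_columns <- function(aln, target) {
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  tg <- aln$mat[aln$species == target, , drop = FALSE]
  bg <- aln$mat[aln$species != target, , drop = FALSE]
  which(vapply(seq_len(aln$L), function(j) {
    states <- unique(tg[, j])
    if (length(states) != 1L) return(FALSE)
    a <- states
    if (!a %in% c("A", "C", "G", "T", "-")) return(FALSE)
    !any(vapply(bg[, j], function(s) {
      if (s == a) return(TRUE)
      if (a == "-" || s == "-") return(FALSE)
      a %in% iupac[[s]]
    }, TRUE))
  }, TRUE))
}

# Least-squares additive-fit oracle for small NJ recovery checks: enumerate
# all unrooted topologies on 4 or 5 taxa and return the best-fitting one as
# a set of non-trivial splits.
oracle_best_topology <- function(dm) {
  taxa <- rownames(dm)
  n <- length(taxa)
  stopifnot(n %in% c(4L, 5L))
  topos <- all_unrooted_topologies(taxa)
  fits <- vapply(topos, function(tr) topology_lsq_rss(tr, dm), 0)
  splits_of_tree(topos[[which.min(fits)]])
}

all_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  if (n == 4L) {
    newicks <- c(
      sprintf("((%s,%s),%s,%s);", taxa[1], taxa[2], taxa[3], taxa[4]),
      sprintf("((%s,%s),%s,%s);", taxa[1], taxa[3], taxa[2], taxa[4]),
      sprintf("((%s,%s),%s,%s);", taxa[1], taxa[4], taxa[2], taxa[3])
    )
    lapply(newicks, function(s) {
      tr <- ape::unroot(ape::read.tree(text = s))
      tr$edge.length <- rep(1, nrow(tr$edge))
      tr
    })
  } else {
    # grow each 4-taxon topology by attaching the fifth taxon to every edge
    base <- all_unrooted_topologies(taxa[1:4])
    out <- list()
    for (tr in base) {
      for (e in seq_len(nrow(tr$edge))) {
        out[[length(out) + 1L]] <- ape::bind.tree(
          tr, ape::read.tree(text = sprintf("(%s:1);", taxa[5])),
          where = tr$edge[e, 2], position = 0.5
        )
      }
    }
    # deduplicate by split set
    sig <- vapply(out, function(t) paste(sort(splits_of_tree(t)), collapse = "&"), "")
    out[!duplicated(sig)]
  }
}

splits_of_tree <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  sig <- vapply(pp, function(idx) {
    grp <- sort(tree$tip.label[idx])
    comp <- sort(setdiff(tips, grp))
    a <- paste(grp, collapse = ","); b <- paste(comp, collapse = ",")
    paste(sort(c(a, b))[1], sort(c(a, b))[2], sep = "|")
  }, "")
  # keep non-trivial splits only
  sizes <- lengths(pp)
  sort(unique(sig[sizes >= 2 & sizes <= length(tips) - 2]))
}

# RSS of the least-squares branch-length fit of dm on a fixed topology.
topology_lsq_rss <- function(tree, dm) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  n <- length(tree$tip.label)
  pairs <- utils::combn(n, 2)
  # design matrix: path indicator over edges for each tip pair
  A <- matrix(0, ncol(pairs), nrow(tree$edge))
  d <- numeric(ncol(pairs))
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- ape::nodepath(tree, i, j)
    for (m in seq_len(length(p) - 1L)) {
      e <- which(edge_key == paste(p[m], p[m + 1]) | edge_key == paste(p[m + 1], p[m]))
      A[k, e] <- 1
    }
    d[k] <- dm[tree$tip.label[i], tree$tip.label[j]]
  }
  fit <- qr.solve(crossprod(A) + diag(1e-10, ncol(A)), crossprod(A, d))
  sum((A %*% fit - d)^2)
}

# Random additive distance matrix from a random topology; returns both.
random_additive_dm <- function(n, seed) {
  set.seed(seed)
  taxa <- paste0("t", seq_len(n))
  tr <- ape::rtree(n, rooted = FALSE, tip.label = sample(taxa))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[taxa, taxa]
  list(dm = dm, tree = tr)
}
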