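test_that("K2P closed form evaluates and saturates as documented", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
  expect_equal(k2p_distance(0.1, 0.05), 0.1701812, tolerance = 1e-6)
  expect_error(k2p_distance(0.5, 0), class = "barcodeDx_saturation_error")
})

test_that("K2P dominates p-distance and is monotone in P and Q", {
  grid <- expand.grid(P = seq(0, 0.3, by = 0.05), Q = seq(0, 0.2, by = 0.05))
  for (i in seq_len(nrow(grid))) {
    P <- grid$P[i]; Q <- grid$Q[i]
    d <- k2p_distance(P, Q)
    expect_gte(d + 1e-12, P + Q)
    if (P + Q > 0) expect_gt(d, P + Q - 1e-12)
    if (P > 0 || Q > 0) expect_gt(d, 0)
    expect_gt(k2p_distance(P + 0.01, Q), d)
    expect_gt(k2p_distance(P, Q + 0.01), d)
  }
})

test_that("distance_matrix reproduces hand computations with pairwise deletion", {
  a <- aln_from(c(x = "AAAA", y = "GAAA"))
  d <- distance_matrix(a)
  expect_equal(d["x", "y"], -0.5 * log(0.5), tolerance = 1e-9)

  ident <- aln_from(c(x = "ACGTACGT", y = "ACGTACGT"))
  expect_equal(distance_matrix(ident)["x", "y"], 0)

  # gap and ambiguous columns are deleted for the pair only
  b <- aln_from(c(x = "AAAA-CGT", y = "GAAANCGT", z = "AAAAACGT"))
  d2 <- distance_matrix(b)
  # pair (x, y) compares 7 sites (one gap, one N dropped), one transition
  expect_equal(d2["x", "y"], -0.5 * log(1 - 2 / 7), tolerance = 1e-9)

  expect_error(distance_matrix(aln_from(c(x = "----", y = "AAAA"))),
               class = "barcodeDx_missing_overlap_error")
})

test_that("distance_matrix agrees with an established K80 implementation", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(4:7, 1)
    base <- strsplit(random_dna(300), "")[[1]]
    rows <- vapply(seq_len(n), function(k) {
      v <- base
      hit <- runif(300) < 0.08
      v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(v, collapse = "")
    }, "")
    names(rows) <- paste0("t", seq_len(n))
    a <- aln_from(rows)
    ours <- distance_matrix(a)
    bin <- ape::as.DNAbin(lapply(strsplit(tolower(rows), ""), identity))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
    expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
  }
})

test_that("distance matrix values are invariant under row reordering", {
  fx <- simulate_panel(fixture_params(seed = 3, intra_rate = 0.02))
  a <- fx$alignment
  d1 <- distance_matrix(a)
  set.seed(2)
  perm <- sample(length(a$ids))
  b <- dna_alignment(a$ids[perm], apply(a$mat[perm, ], 1, paste, collapse = ""),
                     a$species[perm])
  d2 <- distance_matrix(b)
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("three-taxon NJ matches the closed form", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 0.3, tolerance = 1e-9)
  expect_equal(cp["A", "C"], 0.5, tolerance = 1e-9)
  vA <- (0.3 + 0.5 - 0.6) / 2
  ed <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(ed["A"]), vA, tolerance = 1e-9)
  expect_error(nj_tree(dm[1:2, 1:2]), class = "barcodeDx_contract_error")
})

test_that("NJ recovers generating topologies on additive matrices (brute-force oracle)", {
  for (n in c(4L, 5L)) {
    hits <- 0L
    for (seed in 1:25) {
      ra <- random_additive_dm(n, seed = 1000L * n + seed)
      tr <- nj_tree(ra$dm)
      expect_equal(splits_of_tree(tr), splits_of_tree(ra$tree),
                   info = sprintf("n=%d seed=%d (generating tree)", n, seed))
      # and the generating topology is also the least-squares best fit
      expect_equal(splits_of_tree(tr), oracle_best_topology(ra$dm),
                   info = sprintf("n=%d seed=%d (oracle)", n, seed))
      hits <- hits + 1L
    }
    expect_equal(hits, 25L)
  }
})

test_that("NJ reproduces additive path lengths", {
  ra <- random_additive_dm(6, seed = 123)
  tr <- nj_tree(ra$dm)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(ra$dm), colnames(ra$dm)], ra$dm, tolerance = 1e-9)
})

test_that("bootstrap supports are deterministic for a seed and bounded", {
  fx <- simulate_panel(fixture_params(n_species = 5, per_species = 1,
                                      locus_len = 300, interspecies_rate = 0.10,
                                      intra_rate = 0, seed = 8))
  a <- fx$alignment
  t1 <- bootstrap_support(a, replicates = 30, seed = 99)
  t2 <- bootstrap_support(a, replicates = 30, seed = 99)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_true(all(attr(t1, "support") >= 0 & attr(t1, "support") <= 100))

  t3 <- bootstrap_support(a, replicates = 1, seed = 7)
  expect_true(all(attr(t3, "support") %in% c(0L, 100L)))
})

test_that("a planted deep split earns full bootstrap support", {
  # two clades separated by many substitutions, light noise within clades
  set.seed(5)
  L <- 400L
  anc <- strsplit(random_dna(L), "")[[1]]
  derived <- anc
  flip <- sample(L, 80)
  for (j in flip) derived[j] <- setdiff(c("A", "C", "G", "T"), anc[j])[1]
  jitter <- function(v, k) {
    hit <- sample(L, k)
    for (j in hit) v[j] <- setdiff(c("A", "C", "G", "T"), v[j])[1]
    paste(v, collapse = "")
  }
  rows <- c(a1 = jitter(anc, 2), a2 = jitter(anc, 2), a3 = jitter(anc, 2),
            b1 = jitter(derived, 2), b2 = jitter(derived, 2), b3 = jitter(derived, 2))
  a <- aln_from(rows)
  tr <- bootstrap_support(a, replicates = 100, seed = 4)
  expect_true(is_monophyletic(tr, c("a1", "a2", "a3")))
  # the support of the a-clade bipartition is 100
  part <- ape::prop.part(tr)
  lab <- lapply(part, function(idx) sort(tr$tip.label[idx]))
  node <- which(vapply(lab, function(x) identical(x, c("a1", "a2", "a3")) ||
                         identical(x, c("b1", "b2", "b3")), TRUE))
  expect_true(all(attr(tr, "support")[node] == 100L))
})

test_that("monophyly equals exhaustive bipartition enumeration on random trees", {
  expect_true(is_monophyletic(ape::read.tree(text = "((A,B),(C,D));"), c("A", "B")))
  expect_false(is_monophyletic(ape::read.tree(text = "((A,B),(C,D));"), c("A", "C")))

  oracle <- function(tree, group) {
    tree <- ape::unroot(tree)
    tips <- sort(tree$tip.label)
    g <- sort(group)
    if (length(g) <= 1L || length(g) >= length(tips)) return(TRUE)
    any(vapply(splits_of_tree(tree), function(s) {
      sides <- strsplit(s, "|", fixed = TRUE)[[1]]
      paste(g, collapse = ",") %in% sides
    }, TRUE))
  }
  set.seed(10)
  for (i in 1:20) {
    tr <- ape::rtree(8, rooted = FALSE)
    grp <- sample(tr$tip.label, sample(2:6, 1))
    expect_equal(is_monophyletic(tr, grp), oracle(tr, grp),
                 info = paste(sort(grp), collapse = ","))
  }
  expect_error(is_monophyletic(ape::rtree(4), c("zz")),
               class = "barcodeDx_lookup_error")
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(is_monophyletic(tr, c("A", "B"), outgroup = c("B", "C")),
               class = "barcodeDx_contract_error")
})
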