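test_that("Wallace rule matches hand counts on the universal primers", {
  expect_equal(wallace_tm("AAAA"), 8)
  expect_equal(wallace_tm("TCCTCCGCTTATTGATATGC"), 58)  # ITS4: 11 A/T, 9 G/C
  expect_equal(wallace_tm("AATTGCAGAATCCCGCGAAC"), 60)  # 10 A/T, 10 G/C
  expect_error(wallace_tm("ACGN"), class = "barcodeDx_contract_error")
})

# A fixture with a conserved upstream region and one planted diagnostic base
# whose 3' anchor sits at a chosen column.
anchored_fixture <- function(anchor_col = 50L, upstream = NULL, L = 80L) {
  set.seed(404)
  base <- strsplit(random_dna(L), "")[[1]]
  if (!is.null(upstream)) {
    w <- strsplit(upstream, "")[[1]]
    base[(anchor_col - length(w) + 1L):anchor_col] <- w
  }
  other <- base
  allele <- setdiff(c("A", "C", "G", "T"), base[anchor_col])[1]
  tgt <- base; tgt[anchor_col] <- allele
  aln_from(c(
    "t1|target" = paste(tgt, collapse = ""),
    "t2|target" = paste(tgt, collapse = ""),
    "o1|other" = paste(other, collapse = ""),
    "o2|other" = paste(other, collapse = "")
  ))
}

test_that("primer length selection matches exhaustive enumeration of the rule", {
  a <- anchored_fixture(anchor_col = 50L)
  m <- merge_adjacent(find_diagnostic_sites(a, "target"), a)
  cons <- design_constraints(len_range = c(18L, 25L), tm_range = c(48, 62))
  pr <- design_species_primer(a, m[1, ], cons)

  # oracle: enumerate all candidate lengths, apply the selection rule directly
  tgt_row <- strsplit(paste(a$mat["t1", ], collapse = ""), "")[[1]]
  cand <- vapply(18:25, function(L) paste(tgt_row[(50 - L + 1):50], collapse = ""), "")
  tms <- vapply(cand, wallace_tm, 0)
  in_win <- tms >= 48 & tms <= 62
  want <- if (any(in_win)) cand[which(in_win)[1]] else
    cand[which.min(pmax(48 - tms, tms - 62, 0))]
  expect_equal(pr$sequence, unname(want))

  # contract: 3' terminus is the planted allele, length within range
  expect_equal(substring(pr$sequence, nchar(pr$sequence)),
               m$target_allele[1])
  expect_true(nchar(pr$sequence) >= 18 && nchar(pr$sequence) <= 25)
  expect_equal(pr$specific_3prime_len, 1L)
})

test_that("a motif too close to the alignment start yields a no-primer error", {
  a <- anchored_fixture(anchor_col = 5L)
  m <- merge_adjacent(find_diagnostic_sites(a, "target"), a)
  expect_error(design_species_primer(a, m[1, ], design_constraints()),
               class = "barcodeDx_no_primer_error")
})

test_that("a gap-terminal motif cannot anchor a primer", {
  a <- aln_from(c(
    "t1|target" = paste0(random_dna(40, seed = 1), "-", random_dna(10)),
    "o1|other" = paste0(random_dna(40, seed = 1), "A", random_dna(10))
  ))
  m <- merge_adjacent(find_diagnostic_sites(a, "target"), a)
  m <- m[m$target_allele == "-", , drop = FALSE]
  expect_error(design_species_primer(a, m[1, ], design_constraints()),
               class = "barcodeDx_no_primer_error")
})

test_that("polymorphism under the primer window attaches a warning", {
  a <- anchored_fixture(anchor_col = 50L)
  # introduce a within-target polymorphism at column 45 (inside any window)
  mat <- a$mat
  mat["t2", 45] <- setdiff(c("A", "C", "G", "T"), mat["t1", 45])[1]
  b <- dna_alignment(a$ids, apply(mat, 1, paste, collapse = ""), a$species)
  m <- merge_adjacent(find_diagnostic_sites(b, "target"), b)
  m <- m[m$start == 50L, , drop = FALSE]
  pr <- design_species_primer(b, m[1, ], design_constraints())
  expect_false(is.na(pr$warning))
})

test_that("control pair lands in planted invariant blocks and brackets the motifs", {
  set.seed(99)
  L <- 200L
  base <- strsplit(random_dna(L), "")[[1]]
  blockF <- strsplit("GATCATTGCAGACTCCGCAA", "")[[1]]
  blockR <- strsplit("TTGCGGAGTCTGCAATGATC", "")[[1]]
  base[31:50] <- blockF
  base[151:170] <- blockR
  tgt <- base; tgt[100] <- setdiff(c("A", "C", "G", "T"), base[100])[1]
  # make everything outside the blocks variable between the two species so
  # the only fully conserved windows are the planted ones
  other <- base
  vary <- setdiff(seq_len(L), c(31:50, 100, 151:170))
  set.seed(100)
  flip <- sample(vary, 120)
  for (j in flip) other[j] <- setdiff(c("A", "C", "G", "T"), base[j])[1]
  a <- aln_from(c(
    "t1|target" = paste(tgt, collapse = ""),
    "o1|other" = paste(other, collapse = "")
  ))
  pair <- design_control_pair(a, design_constraints())
  fp <- attr(pair, "footprints")
  expect_true(fp$start[1] >= 31 && fp$end[1] <= 50)
  expect_true(fp$start[2] >= 151 && fp$end[2] <= 170)
  # orientation contract: reverse primer is the revcomp of its plus-strand window
  win <- paste(a$mat[1, fp$start[2]:fp$end[2]], collapse = "")
  expect_equal(pair$sequence[pair$role == "universal_reverse"], revcomp(win))
  # control amplicon brackets the species-specific site
  expect_true(fp$end[1] < 100 && fp$start[2] > 100)
})

test_that("an alignment with no invariant window yields a no-primer error", {
  set.seed(55)
  a <- aln_from(c("x|s1" = random_dna(60), "y|s2" = random_dna(60)))
  # ensure not accidentally conserved anywhere long enough
  expect_error(design_control_pair(a, design_constraints()),
               class = "barcodeDx_no_primer_error")
})

test_that("panel_check verifies separations, cross-dimers and symmetry", {
  demo <- krai_krue_demo()
  chk <- panel_check(demo$primer_panel, design_constraints())
  expect_true(chk$passes)
  expect_equal(min(chk$band_separation$separation), 68L)

  # two primers ending ACGT have a 4-base mutual 3' complement (ACGT is its
  # own reverse complement): fails a threshold of 3, passes 4
  pr <- rbind(
    primer_panel_primers <- data.frame(
      name = c("p1", "p2"), sequence = c("AAAAAAAAAAAAAAAACGT", "TTTTTTTTTTTTTTTACGT"),
      orientation = "forward", role = c("species_specific", "universal_reverse"),
      target_species = c("s1", NA), specific_3prime_len = c(1L, 0L),
      tm_wallace = 40, gc_percent = 20, warning = NA, stringsAsFactors = FALSE
    )
  )
  panel <- primer_panel(pr, list(s1 = 100L), 400L)
  chk3 <- panel_check(panel, design_constraints(max_3prime_cross_complement = 3L))
  expect_false(all(chk3$cross_dimers$pass))
  chk4 <- panel_check(panel, design_constraints(max_3prime_cross_complement = 4L))
  expect_true(all(chk4$cross_dimers$pass))

  # symmetry under primer order
  pr2 <- pr[2:1, ]
  panel2 <- primer_panel(pr2, list(s1 = 100L), 400L)
  c1 <- panel_check(panel, design_constraints())
  c2 <- panel_check(panel2, design_constraints())
  expect_equal(sort(c1$cross_dimers$overlap), sort(c2$cross_dimers$overlap))
  expect_equal(c1$passes, c2$passes)
})

test_that("single-band panels trivially pass separation", {
  pr <- data.frame(
    name = c("p1", "pR"), sequence = c("ACGTACGTACGTACGTA", "TGCATGCATGCATGCAT"),
    orientation = c("forward", "reverse"),
    role = c("species_specific", "universal_reverse"),
    target_species = c("s1", NA), specific_3prime_len = c(1L, 0L),
    tm_wallace = 50, gc_percent = 50, warning = NA, stringsAsFactors = FALSE
  )
  panel <- primer_panel(pr[2, ], list(), 400L)
  chk <- panel_check(panel, design_constraints())
  expect_true(all(chk$band_separation$pass))
})

test_that("designed primers hit own species cleanly and mismatch others in the seed", {
  demo <- krai_krue_demo()
  aln <- demo$alignment
  cons <- species_consensus(aln)
  model <- mismatch_model()
  pr <- demo$primer_panel$primers
  sp_primers <- pr[pr$role == "species_specific", ]
  for (i in seq_len(nrow(sp_primers))) {
    for (sp in unique(aln$species)) {
      tpl <- gsub("-", "", paste(cons$mat[sp, ], collapse = ""))
      sites <- find_binding_sites(tpl, sp_primers$sequence[i], model, sp)
      if (sp == sp_primers$target_species[i]) {
        expect_true(any(sites$mismatches == 0 & sites$strand == "+"))
      } else {
        # ARMS: no binding at all under the seed rule for non-targets
        expect_equal(nrow(sites), 0L,
                     info = sprintf("%s on %s", sp_primers$name[i], sp))
      }
    }
  }
})
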