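#' Parameters for the synthetic species-panel simulator
#'
#' The simulator emulates the structure of a barcode locus shared by closely
#' related species: a common ancestral sequence, species-private fixed
#' motifs (substitutions or deletions), background interspecific divergence,
#' intraspecific noise, and conserved blocks that act as primer anchors.
#'
#' Background divergence is planted as two-group column patterns in which
#' each allele is carried by at least two species (possible only for
#' `n_species >= 4`; with fewer species background substitutions modify the
#' shared ancestor instead). This guarantees by construction that the
#' planted motifs are exactly the species-diagnostic columns, so recall and
#' false-discovery bookkeeping against the truth table is exact.
#' Intraspecific noise never hits conserved blocks or planted motif columns:
#' planted motifs are fixed within their species by definition.
#'
#' @param n_species Number of species (>= 2).
#' @param per_species Individuals per species (>= 1).
#' @param locus_len Alignment length in columns.
#' @param diag_spec Data.frame of planted motifs: columns `species` (1-based
#'   species index), `start`, `width`, `type` (`"sub"` or `"del"`). Motifs
#'   must be pairwise non-overlapping, non-adjacent within a species, and
#'   disjoint from conserved blocks.
#' @param intra_rate Per-site intraspecific mutation probability in `[0, 1)`.
#' @param conserved_blocks Data.frame with `start`, `end`: intervals held
#'   invariant across all sequences (primer anchors).
#' @param interspecies_rate Per-column probability of a background
#'   divergence pattern.
#' @param seed Integer RNG seed; the whole fixture is a pure function of it.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(n_species = 4L,
                           per_species = 3L,
                           locus_len = 600L,
                           diag_spec = NULL,
                           intra_rate = 0,
                           conserved_blocks = NULL,
                           interspecies_rate = 0.02,
                           seed = 1L) {
  if (n_species < 2L) abort_dx("need >= 2 species", "barcodeDx_parameter_error")
  if (intra_rate < 0 || intra_rate >= 1 || interspecies_rate < 0 || interspecies_rate >= 1) {
    abort_dx("rates must lie in [0, 1)", "barcodeDx_parameter_error")
  }
  if (is.null(conserved_blocks)) {
    conserved_blocks <- data.frame(
      start = c(31L, locus_len - 60L),
      end = c(60L, locus_len - 31L)
    )
  }
  if (is.null(diag_spec)) {
    # one planted substitution motif per species, spread over the variable core
    core <- (max(conserved_blocks$end[1], 60L) + 40L):(min(conserved_blocks$start[2], locus_len - 60L) - 40L)
    pos <- round(seq(core[1], core[length(core)], length.out = n_species))
    diag_spec <- data.frame(
      species = seq_len(n_species),
      start = as.integer(pos),
      width = rep_len(c(1L, 2L, 3L), n_species),
      type = "sub"
    )
  }
  diag_spec$end <- diag_spec$start + diag_spec$width - 1L
  validate_fixture_geometry(diag_spec, conserved_blocks, locus_len)
  structure(list(
    n_species = as.integer(n_species), per_species = as.integer(per_species),
    locus_len = as.integer(locus_len), diag_spec = diag_spec,
    intra_rate = intra_rate, conserved_blocks = conserved_blocks,
    interspecies_rate = interspecies_rate, seed = as.integer(seed)
  ), class = "fixture_params")
}

validate_fixture_geometry <- function(diag_spec, blocks, L) {
  if (any(diag_spec$start < 1L | diag_spec$end > L)) {
    abort_dx("planted motif outside the locus", "barcodeDx_parameter_error")
  }
  mcols <- unlist(Map(seq, diag_spec$start, diag_spec$end))
  if (anyDuplicated(mcols)) {
    abort_dx("planted motifs overlap", "barcodeDx_parameter_error")
  }
  bcols <- unlist(Map(seq, blocks$start, blocks$end))
  if (length(intersect(mcols, bcols))) {
    abort_dx("planted motifs overlap conserved blocks", "barcodeDx_parameter_error")
  }
  for (sp in unique(diag_spec$species)) {
    d <- diag_spec[diag_spec$species == sp, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] - d$end[-nrow(d)] < 2L)) {
      abort_dx("same-species motifs must be non-adjacent", "barcodeDx_parameter_error")
    }
  }
  invisible(TRUE)
}

other_base <- function(b) {
  sample(setdiff(DNA_BASES, b), 1L)
}

#' Simulate a species panel with planted, known-truth structure
#'
#' See [fixture_params()] for the generative model. Fully reproducible: the
#' same seed yields byte-identical sequences.
#'
#' @param params A [fixture_params()].
#' @return A list of class `fixture`: `panel` (a [species_panel()], rows
#'   de-gapped), `alignment` (a [dna_alignment()] in ancestral coordinates),
#'   and `truth` (planted motifs with target alleles, conserved blocks,
#'   ancestral sequence, species names, background columns, seed echo).
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  L <- params$locus_len
  nsp <- params$n_species
  sp_names <- sprintf("species_%02d", seq_len(nsp))

  anc <- sample(DNA_BASES, L, replace = TRUE)
  blocked <- logical(L)
  for (k in seq_len(nrow(params$conserved_blocks))) {
    blocked[params$conserved_blocks$start[k]:params$conserved_blocks$end[k]] <- TRUE
  }
  motif_col <- logical(L)
  for (k in seq_len(nrow(params$diag_spec))) {
    motif_col[params$diag_spec$start[k]:params$diag_spec$end[k]] <- TRUE
  }

  # species consensus matrix in ancestral coordinates
  spmat <- matrix(rep(anc, each = nsp), nrow = nsp)
  rownames(spmat) <- sp_names

  # background divergence: two-group patterns, each allele in >= 2 species
  free <- which(!blocked & !motif_col)
  bg_cols <- free[runif(length(free)) < params$interspecies_rate]
  if (nsp >= 4L) {
    sizes <- 2:(nsp - 2L)
    for (j in bg_cols) {
      k <- sizes[sample.int(length(sizes), 1L)]
      grp <- sample(seq_len(nsp), k)
      spmat[grp, j] <- other_base(anc[j])
    }
  } else if (length(bg_cols)) {
    # too few species for a non-diagnostic split: divergence goes into the
    # shared ancestor (no interspecific variation outside planted motifs)
    for (j in bg_cols) {
      b <- other_base(anc[j])
      anc[j] <- b
      spmat[, j] <- b
    }
  }

  # planted motifs
  truth_rows <- lapply(seq_len(nrow(params$diag_spec)), function(k) {
    d <- params$diag_spec[k, ]
    cols <- d$start:d$end
    if (d$type == "sub") {
      allele <- vapply(cols, function(j) other_base(spmat[d$species, j]), "")
      spmat[d$species, cols] <<- allele
    } else {
      allele <- rep("-", length(cols))
      spmat[d$species, cols] <<- "-"
    }
    data.frame(
      target_species = sp_names[d$species], start = d$start, end = d$end,
      type = d$type, target_allele = paste(allele, collapse = ""),
      stringsAsFactors = FALSE
    )
  })
  truth_motifs <- do.call(rbind, truth_rows)

  # individuals with intraspecific noise (never in anchors or motif columns)
  noise_ok <- !blocked & !motif_col
  ids <- character(0); species <- character(0); rows <- character(0)
  for (s in seq_len(nsp)) {
    for (i in seq_len(params$per_species)) {
      row <- spmat[s, ]
      if (params$intra_rate > 0) {
        hit <- which(noise_ok & row != "-" & runif(L) < params$intra_rate)
        for (j in hit) row[j] <- other_base(row[j])
      }
      ids <- c(ids, sprintf("%s_ind%02d", sp_names[s], i))
      species <- c(species, sp_names[s])
      rows <- c(rows, paste(row, collapse = ""))
    }
  }
  aln <- dna_alignment(ids, rows, species)
  panel <- species_panel(ids, species, vapply(rows, degap, ""), locus = "synthetic")

  truth <- list(
    motifs = truth_motifs,
    conserved_blocks = params$conserved_blocks,
    ancestral = paste(anc, collapse = ""),
    species = sp_names,
    background_columns = bg_cols,
    seed = params$seed
  )
  structure(list(panel = panel, alignment = aln, truth = truth),
            class = "fixture")
}

# ---- packaged three-species demo ------------------------------------------

DEMO_SEED <- 20180801L

# Craft a 20-column primer window: G/C at window positions 1, 6, 11, 16, 20
# and A/T elsewhere. With the Wallace rule this makes 20 the shortest length
# in 15-25 whose Tm reaches the 48-62 window (Tm(20) = 50, Tm(19) = 46), so
# designed primers are 20-mers and band sizes are fixed by geometry.
demo_window <- function() {
  gc_at <- c(1L, 6L, 11L, 16L, 20L)
  w <- character(20L)
  w[gc_at] <- sample(c("G", "C"), length(gc_at), replace = TRUE)
  w[-gc_at] <- sample(c("A", "T"), 20L - length(gc_at), replace = TRUE)
  w
}

flip_same_class <- function(b) {
  switch(b, A = "T", T = "A", G = "C", C = "G")
}

#' Build the packaged three-species multiplex demo from scratch
#'
#' A synthetic 800-column ITS2-like locus for three target species plus one
#' substitute (non-target) species. Universal control anchors sit at columns
#' 361-380 and 741-760 (the reverse anchor carries the ITS4 universal primer
#' site), and one private substitution motif is planted per target species
#' with its 3'-most column at 657, 589 and 515. Species-specific 20-mer
#' primers designed on those motifs then give band sizes 123, 191 and 265 bp
#' nested inside a 400-bp control product — the band architecture of a
#' published pentaplex Krai-Krue assay, realized on synthetic sequence.
#'
#' Expected band sizes in the returned panel are measured by running the
#' in-silico PCR on each species consensus, not asserted.
#'
#' @param seed Integer seed (default: the recorded generating seed).
#' @return A list: `panel` (a `species_panel`), `alignment`, `primer_panel`,
#'   `truth`.
#' @export
make_krai_krue_demo <- function(seed = DEMO_SEED) {
  set.seed(seed)
  L <- 800L
  species <- c("Aristolochia_pothieri", "Aristolochia_pierrei",
               "Aristolochia_tagala", "Jasminum_substitute")
  anc <- sample(DNA_BASES, L, replace = TRUE)

  ctrl_f <- "AATTGCAGAATCCCGCGAAC"          # universal forward (ITS-Aris-390F site)
  ctrl_r_site <- revcomp("TCCTCCGCTTATTGATATGC")  # plus-strand ITS4 site
  anc[361:380] <- chars(ctrl_f)
  anc[741:760] <- chars(ctrl_r_site)

  motif_ends <- c(Aristolochia_pothieri = 657L,
                  Aristolochia_pierrei = 589L,
                  Aristolochia_tagala = 515L)
  motif_widths <- c(Aristolochia_pothieri = 1L,
                    Aristolochia_pierrei = 2L,
                    Aristolochia_tagala = 3L)
  ctrl_seqs <- c(ctrl_f, revcomp(ctrl_r_site))

  spmat <- matrix(rep(anc, each = length(species)), nrow = length(species),
                  dimnames = list(species, NULL))
  truth_rows <- list()
  accepted <- character(0)
  for (sp in names(motif_ends)) {
    e <- motif_ends[[sp]]; w <- motif_widths[[sp]]
    # redraw until the future primer (the window itself) is multiplex-clean:
    # no 3'-terminal cross-complementarity run above the default threshold
    # against the control pair or previously chosen windows
    for (try in 1:200) {
      win <- demo_window()
      cand <- paste(win, collapse = "")
      ok <- all(vapply(c(ctrl_seqs, accepted),
                       function(x) cross_dimer_3prime(cand, x) <= 4L, TRUE))
      if (ok) break
    }
    accepted <- c(accepted, cand)
    # target species carries the crafted window; the motif columns of the
    # ancestor (hence all other species) are same-GC-class flips of it
    target_cols <- (e - 19L):e
    spmat[, target_cols] <- matrix(rep(anc[target_cols], each = length(species)),
                                   nrow = length(species))
    anc_win <- win
    motif_off <- (20L - w + 1L):20L
    anc_win[motif_off] <- vapply(win[motif_off], flip_same_class, "")
    anc[target_cols] <- anc_win
    for (s2 in species) spmat[s2, target_cols] <- anc_win
    spmat[sp, target_cols] <- win
    truth_rows[[sp]] <- data.frame(
      target_species = sp, start = e - w + 1L, end = e, type = "sub",
      target_allele = paste(win[motif_off], collapse = ""),
      stringsAsFactors = FALSE
    )
  }

  per_species <- 2L
  ids <- character(0); labels <- character(0); rows <- character(0)
  for (sp in species) {
    for (i in seq_len(per_species)) {
      ids <- c(ids, sprintf("%s_ind%02d", sp, i))
      labels <- c(labels, sp)
      rows <- c(rows, paste(spmat[sp, ], collapse = ""))
    }
  }
  aln <- dna_alignment(ids, rows, labels)
  panel <- species_panel(ids, labels, rows, locus = "ITS2")

  cons <- design_constraints()
  rep_ <- diagnostic_report(aln)
  primers <- list()
  for (sp in names(motif_ends)) {
    m <- rep_$motifs[rep_$motifs$target_species == sp &
                       rep_$motifs$end == motif_ends[[sp]], , drop = FALSE]
    primers[[sp]] <- design_species_primer(aln, m[1, ], cons)
  }
  primer_tab <- rbind(
    do.call(rbind, primers),
    primer_record("control-F", ctrl_f, "forward", "universal_forward"),
    primer_record("control-R", revcomp(ctrl_r_site), "reverse", "universal_reverse")
  )
  rownames(primer_tab) <- NULL

  # measure expected bands on the species consensus templates
  consensus_templates <- setNames(
    vapply(species, function(sp) paste(spmat[sp, ], collapse = ""), ""),
    species
  )
  draft <- structure(list(primers = primer_tab,
                          expected_bands = list(),
                          control_band = 0L),
                     class = "primer_panel")
  pcr <- multiplex_pcr(draft, consensus_templates, mismatch_model())
  amp <- pcr$amplicons
  ctrl_sizes <- amp$length_bp[amp$forward_primer == "control-F" &
                                amp$reverse_primer == "control-R"]
  control_band <- as.integer(unique(ctrl_sizes))[1]
  expected <- lapply(names(motif_ends), function(sp) {
    sel <- amp$template_id == sp &
      amp$forward_primer == primers[[sp]]$name & amp$reverse_primer == "control-R"
    as.integer(unique(amp$length_bp[sel]))[1]
  })
  names(expected) <- names(motif_ends)

  ppanel <- primer_panel(primer_tab, expected, control_band)
  truth <- list(
    motifs = do.call(rbind, unname(truth_rows)),
    conserved_blocks = data.frame(start = c(361L, 741L), end = c(380L, 760L)),
    species = species,
    target_species = names(motif_ends),
    seed = seed
  )
  list(panel = panel, alignment = aln, primer_panel = ppanel, truth = truth)
}

#' Load the packaged three-species multiplex demo
#'
#' Returns the synthetic Krai-Krue-style demo committed under
#' `inst/extdata/krai_krue_demo/` (generated by [make_krai_krue_demo()] with
#' the recorded seed; a test asserts the committed files match a fresh
#' regeneration).
#'
#' @return Same structure as [make_krai_krue_demo()].
#' @export
krai_krue_demo <- function() {
  dir <- system.file("extdata", "krai_krue_demo", package = "barcodeDx")
  if (!nzchar(dir)) abort_dx("packaged demo not found", "barcodeDx_io_error")
  panel <- read_fasta(file.path(dir, "demo_synthetic.fasta"))
  aln <- read_alignment(file.path(dir, "demo_synthetic.fasta"), "fasta")
  ppanel <- read_primer_panel(file.path(dir, "demo_primer_panel.json"))
  truth <- jsonlite::read_json(file.path(dir, "demo_truth.json"),
                               simplifyVector = TRUE)
  truth$motifs <- as.data.frame(truth$motifs, stringsAsFactors = FALSE)
  truth$conserved_blocks <- as.data.frame(truth$conserved_blocks)
  list(panel = panel, alignment = aln, primer_panel = ppanel, truth = truth)
}
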