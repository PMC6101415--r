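#' Collapse an alignment to one consensus row per species
#'
#' Majority state per column within each species; ties among bases become the
#' IUPAC ambiguity code of the tied set; gap wins only on strict majority.
#' Mirrors the practice of developing a marker from the within-species
#' consensus when individuals differ at a handful of positions.
#'
#' @param aln A labeled `dna_alignment`.
#' @return A `dna_alignment` with one row per species (row id = species).
#' @export
species_consensus <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(aln$species)) {
    abort_dx("alignment carries no species labels", "barcodeDx_label_error")
  }
  sps <- unique(aln$species)
  rows <- vapply(sps, function(sp) {
    sub <- aln$mat[aln$species == sp, , drop = FALSE]
    paste(apply(sub, 2L, consensus_state), collapse = "")
  }, "")
  dna_alignment(sps, rows, sps)
}

consensus_state <- function(col) {
  tab <- table(col)
  gap_n <- if ("-" %in% names(tab)) tab[["-"]] else 0L
  base_tab <- tab[names(tab) != "-"]
  if (length(base_tab) == 0L) return("-")
  mx <- max(base_tab)
  if (gap_n > mx) return("-")
  top <- names(base_tab)[base_tab == mx]
  if (length(top) == 1L) return(top)
  # tie among observed states; expand any ambiguity codes before encoding
  iupac_code_for(unique(unlist(IUPAC_SETS[top])))
}

#' Find single-column species-diagnostic sites
#'
#' A column is diagnostic for the target species when (i) every target row
#' carries one identical state (the gap `-` is a legal diagnostic state) and
#' (ii) that state is absent from every non-target row. A non-target IUPAC
#' ambiguity whose set contains the candidate allele breaks the diagnosis
#' (conservative: never anchor a primer on an uncertain difference).
#'
#' @param aln A labeled `dna_alignment` with >= 2 species.
#' @param target_species Species to diagnose.
#' @param min_target_freq Minimum fraction of target rows that must carry the
#'   candidate allele (default 1 = strictly fixed). Below 1, the majority
#'   target state is the candidate.
#' @return A data.frame of single-column motifs with columns
#'   `target_species`, `start`, `end` (1-based inclusive alignment columns),
#'   `target_allele`, `background` (comma-joined non-target states) and
#'   `fixed_in_target`.
#' @export
find_diagnostic_sites <- function(aln, target_species, min_target_freq = 1) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(aln$species)) {
    abort_dx("alignment carries no species labels", "barcodeDx_label_error")
  }
  if (length(unique(aln$species)) < 2L) {
    abort_dx("diagnosis needs >= 2 species", "barcodeDx_insufficient_species_error")
  }
  if (!target_species %in% aln$species) {
    abort_dx(sprintf("unknown species '%s'", target_species), "barcodeDx_lookup_error")
  }
  tgt <- aln$mat[aln$species == target_species, , drop = FALSE]
  bgd <- aln$mat[aln$species != target_species, , drop = FALSE]

  hits <- lapply(seq_len(aln$L), function(j) {
    allele <- candidate_allele(tgt[, j], min_target_freq)
    if (is.na(allele)) return(NULL)
    if (any(vapply(bgd[, j], state_overlaps, TRUE, allele = allele))) return(NULL)
    data.frame(
      target_species = target_species, start = j, end = j,
      target_allele = allele,
      background = paste(sort(unique(bgd[, j])), collapse = ","),
      fixed_in_target = TRUE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(
      target_species = character(), start = integer(), end = integer(),
      target_allele = character(), background = character(),
      fixed_in_target = logical(), stringsAsFactors = FALSE
    )
  }
  out
}

# The allele all (or >= freq of) target rows carry, or NA. Ambiguity codes in
# target rows never yield a candidate (exact states only).
candidate_allele <- function(states, min_target_freq) {
  tab <- table(states)
  top <- names(tab)[order(-tab, names(tab))][1]
  if (!top %in% c(DNA_BASES, "-")) return(NA_character_)
  if (tab[[top]] / length(states) < min_target_freq) return(NA_character_)
  if (min_target_freq >= 1 && tab[[top]] != length(states)) return(NA_character_)
  top
}

# Does a background state conflict with the candidate allele? Exact match
# always conflicts; an ambiguity code conflicts when its set contains a base
# allele.
state_overlaps <- function(state, allele) {
  if (state == allele) return(TRUE)
  if (allele == "-" || state == "-") return(FALSE)
  allele %in% IUPAC_SETS[[state]]
}

#' Merge adjacent diagnostic sites into maximal motifs
#'
#' Runs of consecutive diagnostic columns for one target species collapse
#' into a single multi-column motif (e.g. a 2-base or 4-base diagnostic
#' block). Alleles are concatenated in column order.
#'
#' @param sites Data.frame from [find_diagnostic_sites()]; all rows must
#'   share one target species.
#' @param aln Optional source `dna_alignment`; when given, the merged
#'   motif's background strings are recomputed over the full interval.
#' @return A data.frame with the same columns, one row per maximal run.
#' @export
merge_adjacent <- function(sites, aln = NULL) {
  if (nrow(sites) == 0L) return(sites)
  if (length(unique(sites$target_species)) > 1L) {
    abort_dx("merge_adjacent expects sites of a single target species",
             "barcodeDx_contract_error")
  }
  sites <- sites[order(sites$start), , drop = FALSE]
  run <- cumsum(c(1L, diff(sites$start) != 1L))
  out <- do.call(rbind, lapply(split(sites, run), function(grp) {
    s <- min(grp$start); e <- max(grp$end)
    bg <- if (!is.null(aln)) {
      ntg <- aln$mat[aln$species != grp$target_species[1], s:e, drop = FALSE]
      paste(sort(unique(apply(ntg, 1L, paste, collapse = ""))), collapse = ",")
    } else {
      paste(grp$background, collapse = ";")
    }
    data.frame(
      target_species = grp$target_species[1], start = s, end = e,
      target_allele = paste(grp$target_allele, collapse = ""),
      background = bg, fixed_in_target = TRUE, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Per-species diagnostic motif report
#'
#' Runs the diagnostic scan for every species in the alignment, merges
#' adjacent columns, and flags which species are assayable (at least one
#' motif whose 3'-most allele is a real base, usable as a primer 3' anchor).
#'
#' @param aln A labeled `dna_alignment` with >= 2 species.
#' @param min_target_freq Passed to [find_diagnostic_sites()].
#' @return A list of class `diagnostic_report`: `motifs` (one data.frame,
#'   all species) and `assayable` (named logical).
#' @export
diagnostic_report <- function(aln, min_target_freq = 1) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(aln$species) || length(unique(aln$species)) < 2L) {
    abort_dx("diagnostic report needs >= 2 labeled species",
             "barcodeDx_insufficient_species_error")
  }
  sps <- unique(aln$species)
  per <- lapply(sps, function(sp) {
    merge_adjacent(find_diagnostic_sites(aln, sp, min_target_freq), aln)
  })
  motifs <- do.call(rbind, per)
  rownames(motifs) <- NULL
  assayable <- vapply(per, function(m) {
    nrow(m) > 0L && any(substr(m$target_allele, nchar(m$target_allele),
                               nchar(m$target_allele)) != "-")
  }, TRUE)
  structure(list(motifs = motifs, assayable = setNames(assayable, sps)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> %d motifs, %d/%d species assayable\n",
              nrow(x$motifs), sum(x$assayable), length(x$assayable)))
  if (nrow(x$motifs)) print(x$motifs, row.names = FALSE)
  invisible(x)
}
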