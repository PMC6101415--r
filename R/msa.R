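#' Alignment scoring parameters
#'
#' Affine gap model: a gap of length `k` costs `gap_open + gap_extend * (k - 1)`
#' (both penalties are non-positive; the open penalty includes the first
#' gapped position).
#'
#' @param match Match score (default 1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Score of the first position of a gap (default -4).
#' @param gap_extend Score of each further gapped position (default -1).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -4, gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    abort_dx("require gap_open <= gap_extend <= 0", "barcodeDx_contract_error")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# Biostrings charges gapOpening + gapExtension * len per gap; our convention
# charges open + extend * (len - 1). The two agree with
# gapOpening = -(open - extend), gapExtension = -extend.
bios_gap <- function(params) {
  list(opening = -(params$gap_open - params$gap_extend),
       extension = -params$gap_extend)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' @param a,b IUPAC DNA strings (unaligned; A/C/G/T expected for scoring).
#' @param params An [align_params()].
#' @return A list with `a`, `b` (aligned strings, equal length) and `score`.
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) {
    abort_dx("cannot align an empty sequence", "barcodeDx_empty_input_error")
  }
  gp <- bios_gap(params)
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sub,
    gapOpening = gp$opening, gapExtension = gp$extension
  )
  list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

# p-distance between two aligned rows (mismatching non-double-gap columns /
# compared columns); used only for the guide tree.
aligned_pdist <- function(x, y) {
  cx <- chars(x); cy <- chars(y)
  keep <- !(cx == "-" & cy == "-")
  if (!any(keep)) return(1)
  mean(cx[keep] != cy[keep])
}

# Majority consensus of a profile (character matrix); per column the most
# frequent non-gap residue, ties broken lexicographically. Columns are never
# all-gap inside a profile built by progressive merging.
profile_consensus <- function(mat) {
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]
  })
}

# Insert gap columns into every row of a profile. `gapped` is the aligned
# consensus string coming back from pairwise alignment: its gap positions
# are where new all-member gap columns go.
expand_profile <- function(mat, gapped) {
  gpos <- chars(gapped) == "-"
  out <- matrix("-", nrow = nrow(mat), ncol = length(gpos),
                dimnames = list(rownames(mat), NULL))
  out[, !gpos] <- mat
  out
}

#' Progressive multiple alignment for desk-scale barcode panels
#'
#' A lightweight substitute for an external multiple aligner: a UPGMA guide
#' tree is built from pairwise global-alignment p-distances, then profiles
#' are merged along the guide order by globally aligning their majority
#' consensus sequences and propagating the inserted gaps to every member row
#' ("once a gap, always a gap"). Deterministic for fixed input; records are
#' processed in lexicographic id order. Intended for panels of tens of
#' records and loci up to a few kb; use a dedicated aligner beyond that.
#'
#' @param panel A `species_panel` with at least 2 records.
#' @param params An [align_params()].
#' @return A [dna_alignment()] containing every record; de-gapping any row
#'   reproduces its input residues.
#' @export
progressive_align <- function(panel, params = align_params()) {
  stopifnot(inherits(panel, "species_panel"))
  n <- length(panel$ids)
  if (n < 2L) abort_dx("progressive alignment needs >= 2 records", "barcodeDx_contract_error")

  ord <- order(panel$ids)
  ids <- panel$ids[ord]
  species <- panel$species[ord]
  res <- panel$residues[ord]

  # pairwise p-distances for the guide tree
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pa <- pairwise_align(res[i], res[j], params)
      D[i, j] <- D[j, i] <- aligned_pdist(pa$a, pa$b)
    }
  }

  # profiles start as single rows; merge along UPGMA order
  profiles <- lapply(seq_len(n), function(i) {
    matrix(chars(res[i]), nrow = 1L, dimnames = list(ids[i], NULL))
  })
  if (n == 2L) {
    merge_order <- matrix(c(-1L, -2L), nrow = 1L)
  } else {
    merge_order <- hclust(as.dist(D), method = "average")$merge
  }
  merged <- vector("list", nrow(merge_order))
  for (k in seq_len(nrow(merge_order))) {
    pick <- function(idx) if (idx < 0L) profiles[[-idx]] else merged[[idx]]
    A <- pick(merge_order[k, 1L]); B <- pick(merge_order[k, 2L])
    pa <- pairwise_align(paste(profile_consensus(A), collapse = ""),
                         paste(profile_consensus(B), collapse = ""), params)
    merged[[k]] <- rbind(expand_profile(A, pa$a), expand_profile(B, pa$b))
  }
  final <- merged[[length(merged)]]
  # restore the panel's record order
  final <- final[match(panel$ids, rownames(final)), , drop = FALSE]
  dna_alignment(panel$ids, apply(final, 1L, paste, collapse = ""), panel$species)
}
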