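#' GC content of a DNA sequence, in percent
#'
#' Computed on non-gap residues: `100 * (G + C + S) / (non-gap count)`.
#' `S` (C or G) counts toward GC; every other ambiguity code enters the
#' denominator only, so the value is deterministic on IUPAC input.
#'
#' @param residues IUPAC DNA string (gaps allowed, ignored).
#' @return GC percent in `[0, 100]`.
#' @examples
#' gc_percent("ATGC")  # 50
#' @export
gc_percent <- function(residues) {
  cc <- chars(toupper(residues))
  cc <- cc[cc != "-"]
  if (length(cc) == 0L) {
    abort_dx("GC content undefined on all-gap input", "barcodeDx_undefined_value_error")
  }
  100 * sum(cc %in% c("G", "C", "S")) / length(cc)
}

#' Columnwise percent variation of an alignment
#'
#' A column is variable when its rows do not all share one identical state;
#' the gap character is a fifth state (indel columns count as variable), so
#' indel-rich spacers such as ITS2 score high. Columns that are gap in every
#' row are excluded from both numerator and denominator.
#'
#' @param aln A `dna_alignment` with at least 2 rows.
#' @return Percent of retained columns that are variable, in `[0, 100]`.
#' @export
variation_percent <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (nrow(aln$mat) < 2L) {
    abort_dx("variation needs >= 2 aligned rows", "barcodeDx_insufficient_data_error")
  }
  all_gap <- apply(aln$mat, 2L, function(col) all(col == "-"))
  kept <- aln$mat[, !all_gap, drop = FALSE]
  if (ncol(kept) == 0L) {
    abort_dx("alignment has no non-gap column", "barcodeDx_undefined_value_error")
  }
  variable <- apply(kept, 2L, function(col) length(unique(col)) > 1L)
  100 * sum(variable) / ncol(kept)
}

#' Per-species and per-locus barcode descriptors
#'
#' For each species the ungapped length (bp) and GC percent of one
#' representative record (the first id for that species in the panel, i.e.
#' the accessioned record by convention), plus one panel-level columnwise
#' variation percent over all alignment rows.
#'
#' @param panel A `species_panel`.
#' @param aln A `dna_alignment` whose rows correspond to panel records.
#' @param digits Decimal places for reported percentages (half-up rounding).
#' @return A list of class `locus_stats`: `locus`, `per_species` (data.frame
#'   with `species`, `length_bp`, `gc_percent`), `variation_percent`,
#'   `n_columns`.
#' @export
locus_summary <- function(panel, aln, digits = 2L) {
  stopifnot(inherits(panel, "species_panel"), inherits(aln, "dna_alignment"))
  missing_rows <- setdiff(panel$ids, aln$ids)
  if (length(missing_rows)) {
    abort_dx(
      sprintf("panel records absent from alignment: %s",
              paste(missing_rows, collapse = ", ")),
      "barcodeDx_consistency_error"
    )
  }
  sp <- names(panel$species_index)
  rep_ids <- vapply(panel$species_index, `[`, "", 1L)
  res <- panel$residues[match(rep_ids, panel$ids)]
  per_species <- data.frame(
    species = sp,
    length_bp = nchar(vapply(res, degap, "")),
    gc_percent = round_half_up(vapply(res, gc_percent, 0), digits),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      locus = panel$locus,
      per_species = per_species,
      variation_percent = round_half_up(variation_percent(aln), digits),
      n_columns = aln$L
    ),
    class = "locus_stats"
  )
}

# round() in R is banker's rounding; percentages are reported half-up to
# match conventional table precision.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.locus_stats <- function(x, ...) {
  cat(sprintf("<locus_stats> %s: variation %.2f%% over %d columns\n",
              x$locus, x$variation_percent, x$n_columns))
  print(x$per_species, row.names = FALSE)
  invisible(x)
}
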