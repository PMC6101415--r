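#' Construct a species panel
#'
#' A `species_panel` is the unit of downstream analysis: a set of barcode
#' sequence records for one locus, each carrying a species label.
#'
#' @param ids Character vector of unique record identifiers.
#' @param species Character vector of species labels, parallel to `ids`.
#' @param residues Character vector of upper-case IUPAC DNA strings.
#' @param locus Single locus tag (e.g. `"ITS2"`).
#' @return An object of class `species_panel` with elements `locus`, `ids`,
#'   `species`, `residues` and `species_index` (list mapping species to ids).
#' @export
species_panel <- function(ids, species, residues, locus = "locus") {
  stopifnot(length(ids) == length(species), length(ids) == length(residues))
  if (length(ids) == 0L) abort_dx("empty panel", "barcodeDx_empty_input_error")
  if (anyDuplicated(ids)) {
    abort_dx(
      sprintf("duplicate record id '%s'", ids[duplicated(ids)][1]),
      "barcodeDx_duplicate_error"
    )
  }
  residues <- toupper(residues)
  if (any(!nzchar(residues))) {
    abort_dx("record with empty residues", "barcodeDx_empty_input_error")
  }
  Map(check_alphabet, residues, ids)
  if (any(is.na(species) | !nzchar(species))) {
    abort_dx("every record needs a species label (supply a label map)",
             "barcodeDx_label_error")
  }
  structure(
    list(
      locus = locus,
      ids = as.character(ids),
      species = as.character(species),
      residues = unname(residues),
      species_index = split(as.character(ids), as.character(species))
    ),
    class = "species_panel"
  )
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf(
    "<species_panel> locus %s: %d records, %d species\n",
    x$locus, length(x$ids), length(x$species_index)
  ))
  invisible(x)
}

#' Construct a multiple alignment
#'
#' Rows are equal-length residue strings over the IUPAC alphabet plus `-`;
#' columns are addressed 1-based inclusive throughout the package.
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of aligned residue strings (equal length).
#' @param species Optional character vector of species labels per row.
#' @return An object of class `dna_alignment` with a character matrix `mat`
#'   (rows = records, columns = alignment columns), `ids`, `species`, and the
#'   column count `L`.
#' @export
dna_alignment <- function(ids, seqs, species = NULL) {
  stopifnot(length(ids) == length(seqs))
  seqs <- toupper(seqs)
  # normalize the gap dialects BioEdit/Clustal emit
  seqs <- gsub("[.~]", "-", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    short <- ids[lens != max(lens)]
    abort_dx(
      sprintf("ragged alignment: rows of unequal length (%s)",
              paste(short, collapse = ", ")),
      "barcodeDx_alignment_length_error"
    )
  }
  Map(check_alphabet, seqs, ids)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  structure(
    list(
      ids = as.character(ids),
      species = if (is.null(species)) NULL else as.character(species),
      mat = mat,
      L = ncol(mat)
    ),
    class = "dna_alignment"
  )
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf(
    "<dna_alignment> %d rows x %d columns%s\n",
    nrow(x$mat), x$L,
    if (is.null(x$species)) "" else sprintf(" (%d species)", length(unique(x$species)))
  ))
  invisible(x)
}

# Row strings of an alignment.
aln_strings <- function(aln) apply(aln$mat, 1L, paste, collapse = "")

# Subset the rows belonging to one species.
aln_species_rows <- function(aln, sp) {
  if (is.null(aln$species)) {
    abort_dx("alignment carries no species labels", "barcodeDx_label_error")
  }
  which(aln$species == sp)
}

#' Convert an alignment to a species panel (rows de-gapped)
#'
#' @param aln A `dna_alignment` with species labels.
#' @param locus Locus tag for the resulting panel.
#' @return A `species_panel` whose residues are the gap-free row contents.
#' @export
alignment_to_panel <- function(aln, locus = "locus") {
  species_panel(aln$ids, aln$species, vapply(aln_strings(aln), degap, ""), locus)
}
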