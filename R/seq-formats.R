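#' Read a FASTA file into a species panel
#'
#' Species labels come either from a tab-separated label map (columns
#' `id`, `species`, `locus`) or, when no map is given, from headers following
#' the `id|species|locus` convention. Residues are upper-cased; `.` and `~`
#' gap dialects are normalized to `-`.
#'
#' @param path Path to a FASTA file.
#' @param label_map Optional path to a TSV label map.
#' @param locus Locus tag to use when neither headers nor map provide one.
#' @return A [species_panel()].
#' @export
read_fasta <- function(path, label_map = NULL, locus = NULL) {
  if (!file.exists(path)) {
    abort_dx(sprintf("input file not found: %s", path), "barcodeDx_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_dx(
      sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)),
      "barcodeDx_format_error"
    )
  )
  if (length(set) == 0L) {
    abort_dx(sprintf("empty FASTA file: %s", path), "barcodeDx_empty_input_error")
  }
  headers <- sub("\\s.*$", "", names(set))
  seqs <- gsub("[.~]", "-", toupper(as.character(set)))

  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  species <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  loci <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, "")

  if (!is.null(label_map)) {
    map <- read_label_map(label_map)
    hit <- match(ids, map$id)
    species <- ifelse(!is.na(hit), map$species[hit], species)
    if ("locus" %in% names(map)) loci <- ifelse(!is.na(hit), map$locus[hit], loci)
  }
  if (anyDuplicated(ids)) {
    abort_dx(sprintf("duplicate record id '%s' in %s",
                     ids[duplicated(ids)][1], path),
             "barcodeDx_duplicate_error")
  }
  locus_tag <- locus %||% {
    u <- unique(loci[!is.na(loci)])
    if (length(u) == 1L) u else "locus"
  }
  species_panel(ids, species, seqs, locus = locus_tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV label map (columns id, species, and optionally locus)
#' @param path Path to the TSV file.
#' @return A data.frame with character columns.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) {
    abort_dx(sprintf("label map not found: %s", path), "barcodeDx_io_error")
  }
  map <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("id", "species")
  if (!all(need %in% names(map))) {
    abort_dx("label map needs columns 'id' and 'species'", "barcodeDx_format_error")
  }
  map
}

#' Write a species panel (or alignment) as FASTA
#'
#' Headers follow the `id|species|locus` convention so the file round-trips
#' through [read_fasta()] without a label map. Lines wrap at 70 columns.
#'
#' @param x A `species_panel` or `dna_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "dna_alignment")) {
    ids <- x$ids
    species <- x$species %||% rep("NA", length(ids))
    seqs <- aln_strings(x)
    locus <- "locus"
  } else {
    ids <- x$ids; species <- x$species; seqs <- x$residues; locus <- x$locus
  }
  set <- Biostrings::BStringSet(setNames(seqs, paste(ids, species, locus, sep = "|")))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' @param path Path to the alignment file.
#' @param dialect `"fasta"` or `"clustal"`.
#' @param label_map Optional TSV label map assigning species to row ids.
#' @return A [dna_alignment()]; columns are 1-based, gaps normalized to `-`.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal"), label_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_dx(sprintf("input file not found: %s", path), "barcodeDx_io_error")
  }
  if (dialect == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) {
      abort_dx(sprintf("empty alignment file: %s", path), "barcodeDx_empty_input_error")
    }
    headers <- sub("\\s.*$", "", names(set))
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    species <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
    seqs <- as.character(set)
  } else {
    a <- seqinr::read.alignment(path, format = "clustal")
    ids <- a$nam
    species <- rep(NA_character_, length(ids))
    seqs <- toupper(unlist(a$seq))
  }
  if (!is.null(label_map)) {
    map <- read_label_map(label_map)
    hit <- match(ids, map$id)
    species <- ifelse(!is.na(hit), map$species[hit], species)
  }
  if (all(is.na(species))) species <- NULL
  dna_alignment(ids, seqs, species)
}

#' Write an alignment as aligned FASTA
#' @param aln A `dna_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) write_fasta(aln, path)

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are kept; integer bootstrap supports, when present as node
#' labels, are emitted as internal node labels so common tree viewers pick
#' them up.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    abort_dx(sprintf("input file not found: %s", path), "barcodeDx_io_error")
  }
  ape::read.tree(path)
}

#' Read a primer panel from TSV or JSON
#'
#' TSV columns: `name`, `role`, `sequence`, `target_species` (empty for
#' universal primers), `expected_band`. JSON mirrors the structure written by
#' [write_primer_panel()].
#'
#' @param path Path to the panel file; format chosen by extension
#'   (`.json` vs anything else = TSV).
#' @return A [primer_panel()].
#' @export
read_primer_panel <- function(path) {
  if (!file.exists(path)) {
    abort_dx(sprintf("panel file not found: %s", path), "barcodeDx_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    primers <- as.data.frame(obj$primers, stringsAsFactors = FALSE)
    expected <- as.list(obj$expected_bands)
    control <- obj$control_band
  } else {
    tab <- read.delim(path, sep = "\t", colClasses = "character")
    tab$expected_band <- suppressWarnings(as.integer(tab$expected_band))
    primers <- tab
    sp_rows <- tab$role == "species_specific"
    expected <- as.list(setNames(tab$expected_band[sp_rows], tab$target_species[sp_rows]))
    control <- unique(tab$expected_band[tab$role == "universal_forward"])
    control <- control[!is.na(control)][1]
  }
  primer_panel(
    primers = primers,
    expected_bands = lapply(expected, as.integer),
    control_band = as.integer(control)
  )
}

#' Write a primer panel to TSV or JSON
#' @param panel A `primer_panel`.
#' @param path Output path; `.json` selects JSON, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_primer_panel <- function(panel, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        primers = panel$primers,
        expected_bands = panel$expected_bands,
        control_band = panel$control_band
      ),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    tab <- panel$primers
    tab$expected_band <- vapply(seq_len(nrow(tab)), function(i) {
      if (tab$role[i] == "species_specific") {
        as.integer(panel$expected_bands[[tab$target_species[i]]])
      } else {
        as.integer(panel$control_band)
      }
    }, integer(1))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a band report table
#'
#' One row per sample: the observed band sizes (descending,
#' comma-separated) and the species call.
#'
#' @param calls A list of `species_call` objects (see [call_species()]).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_band_report <- function(calls, path) {
  tab <- data.frame(
    sample = vapply(calls, `[[`, "", "sample_id"),
    band_sizes = vapply(calls, function(x) paste(x$bands, collapse = ","), ""),
    call = vapply(calls, `[[`, "", "call"),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
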