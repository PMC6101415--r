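#' @keywords internal
"_PACKAGE"

#' @importFrom stats hclust as.dist setNames runif
#' @importFrom utils read.delim write.table head tail
NULL

# Classed conditions so callers (and tests) can distinguish failure modes.
abort_dx <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "barcodeDx_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy sets, gap included as its own state.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_ALPHABET <- c(names(IUPAC_SETS), "-")

# Map a base set back to its IUPAC code (used by consensus with ties).
iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  "N"
}

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented to their degenerate partners;
#' gaps are preserved.
#'
#' @param x A character scalar of IUPAC DNA.
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- !chars %in% names(COMPLEMENT)
  if (any(bad)) {
    abort_dx(
      sprintf("non-IUPAC character '%s' at offset %d", chars[which(bad)[1]], which(bad)[1]),
      "barcodeDx_format_error"
    )
  }
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

# Split a string into a character vector of single residues.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Validate residues; returns invisible(TRUE) or raises a format error naming
# the record and 1-based offset of the first offending character.
check_alphabet <- function(residues, id, allow_gap = TRUE) {
  allowed <- if (allow_gap) IUPAC_ALPHABET else names(IUPAC_SETS)
  cc <- chars(residues)
  bad <- which(!cc %in% allowed)
  if (length(bad)) {
    abort_dx(
      sprintf("record '%s': non-IUPAC character '%s' at offset %d", id, cc[bad[1]], bad[1]),
      "barcodeDx_format_error"
    )
  }
  invisible(TRUE)
}
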