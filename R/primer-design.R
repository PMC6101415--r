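#' Primer design constraints
#'
#' Defaults suit a single-temperature multiplex (annealing near 52 deg C):
#' 15-25 nt, Wallace Tm 48-62 deg C, GC 30-80%, at most a 4-base 3'-terminal
#' cross-complementarity run between panel primers, and expected bands at
#' least 30 bp apart so an agarose gel resolves them.
#'
#' @param len_range Integer pair, allowed primer length.
#' @param tm_range Numeric pair, allowed Wallace Tm (deg C).
#' @param gc_range Numeric pair, allowed GC percent.
#' @param max_3prime_cross_complement Maximum tolerated 3'-terminal
#'   complementarity run between any two panel primers.
#' @param min_band_separation Minimum expected band size difference (bp).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(len_range = c(15L, 25L),
                               tm_range = c(48, 62),
                               gc_range = c(30, 80),
                               max_3prime_cross_complement = 4L,
                               min_band_separation = 30L) {
  if (diff(len_range) < 0 || diff(tm_range) < 0 || diff(gc_range) < 0) {
    abort_dx("degenerate constraint range", "barcodeDx_contract_error")
  }
  structure(list(
    len_range = as.integer(len_range), tm_range = tm_range,
    gc_range = gc_range,
    max_3prime_cross_complement = as.integer(max_3prime_cross_complement),
    min_band_separation = as.integer(min_band_separation)
  ), class = "design_constraints")
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2 * (A + T) + 4 * (G + C)` deg C; adequate for the 15-25-mers this
#' package designs and fully deterministic (no thermodynamic tables).
#'
#' @param sequence Unambiguous DNA string (A/C/G/T only).
#' @return Tm in deg C.
#' @examples
#' wallace_tm("TCCTCCGCTTATTGATATGC")  # 58
#' @export
wallace_tm <- function(sequence) {
  cc <- chars(toupper(sequence))
  if (length(cc) == 0L || any(!cc %in% DNA_BASES)) {
    abort_dx("Tm needs an unambiguous non-empty DNA sequence",
             "barcodeDx_contract_error")
  }
  2 * sum(cc %in% c("A", "T")) + 4 * sum(cc %in% c("G", "C"))
}

# One primer as a one-row data.frame (primer tables rbind these).
primer_record <- function(name, sequence, orientation, role,
                          target_species = NA_character_,
                          specific_3prime_len = 0L, warning = NA_character_) {
  data.frame(
    name = name, sequence = sequence, orientation = orientation, role = role,
    target_species = target_species,
    specific_3prime_len = as.integer(specific_3prime_len),
    tm_wallace = wallace_tm(sequence),
    gc_percent = gc_percent(sequence),
    warning = warning,
    stringsAsFactors = FALSE
  )
}

#' Construct a primer panel
#'
#' @param primers Data.frame of primers (see [design_species_primer()] /
#'   [design_control_pair()]); must contain exactly one `universal_reverse`.
#' @param expected_bands Named list/vector: species -> expected band size bp.
#' @param control_band Expected internal-control band size bp.
#' @return A list of class `primer_panel`.
#' @export
primer_panel <- function(primers, expected_bands, control_band) {
  if (sum(primers$role == "universal_reverse") != 1L) {
    abort_dx("panel needs exactly one universal_reverse primer",
             "barcodeDx_contract_error")
  }
  bands <- unlist(expected_bands)
  if (anyDuplicated(bands)) {
    abort_dx("species expected bands must be distinct", "barcodeDx_contract_error")
  }
  structure(list(primers = primers,
                 expected_bands = as.list(bands),
                 control_band = as.integer(control_band)),
            class = "primer_panel")
}

#' @export
print.primer_panel <- function(x, ...) {
  cat(sprintf("<primer_panel> %d primers; control %d bp; bands: %s\n",
              nrow(x$primers), x$control_band,
              paste(sprintf("%s=%d", names(x$expected_bands),
                            unlist(x$expected_bands)), collapse = ", ")))
  invisible(x)
}

# Walk left from a motif end over the target-species consensus, skipping
# gaps, and return the primer of length len ending exactly at column `end`.
consensus_window_left <- function(cons_row, end, len) {
  picked <- character(0)
  j <- end
  while (length(picked) < len && j >= 1L) {
    if (cons_row[j] != "-") picked <- c(cons_row[j], picked)
    j <- j - 1L
  }
  if (length(picked) < len) return(NULL)
  paste(picked, collapse = "")
}

#' Design a species-specific ARMS forward primer on a diagnostic motif
#'
#' The primer is the target species's consensus sequence (gaps removed)
#' ending exactly at the motif's 3'-most column, so the 3'-terminal base sits
#' on the diagnostic allele — mismatched templates fail to extend. Length is
#' the shortest in `len_range` whose Wallace Tm falls in `tm_range`; if none
#' qualifies, the length minimizing the Tm-window violation (shortest on
#' ties) is used.
#'
#' @param aln Labeled source `dna_alignment`.
#' @param motif One row of a motif data.frame (see [diagnostic_report()])
#'   whose 3'-most target allele is a base, not a gap.
#' @param constraints A [design_constraints()].
#' @return One-row primer data.frame; column `warning` is non-NA when the
#'   primer window is polymorphic within the target species (majority base
#'   used, ties broken to the lexicographically first base).
#' @export
design_species_primer <- function(aln, motif, constraints = design_constraints()) {
  stopifnot(inherits(aln, "dna_alignment"))
  sp <- motif$target_species
  last_allele <- substr(motif$target_allele, nchar(motif$target_allele),
                        nchar(motif$target_allele))
  if (last_allele == "-") {
    abort_dx("motif's 3'-most allele is a gap; cannot anchor a primer",
             "barcodeDx_no_primer_error")
  }
  tgt <- aln$mat[aln$species == sp, , drop = FALSE]
  if (nrow(tgt) == 0L) abort_dx(sprintf("unknown species '%s'", sp), "barcodeDx_lookup_error")

  # per-column majority within the target species; ties -> first base;
  # any discordant column raises the polymorphism warning
  poly <- FALSE
  cons <- apply(tgt, 2L, function(col) {
    tab <- table(col)
    if (length(tab) > 1L) poly <<- TRUE
    names(tab)[order(-tab, names(tab))][1]
  })
  # a polymorphism warning should only reflect the primer window; recheck below
  lens <- seq(constraints$len_range[1], constraints$len_range[2])
  candidates <- lapply(lens, function(L) consensus_window_left(cons, motif$end, L))
  ok <- !vapply(candidates, is.null, TRUE)
  if (!any(ok)) {
    abort_dx(sprintf("motif at column %d leaves too few upstream residues for a %d-mer",
                     motif$end, constraints$len_range[1]),
             "barcodeDx_no_primer_error")
  }
  lens <- lens[ok]; candidates <- candidates[ok]
  if (any(vapply(candidates, function(s) grepl("[^ACGT]", s), TRUE))) {
    abort_dx("primer window contains unresolved ambiguity in the target consensus",
             "barcodeDx_no_primer_error")
  }
  tms <- vapply(candidates, wallace_tm, 0)
  in_win <- tms >= constraints$tm_range[1] & tms <= constraints$tm_range[2]
  pick <- if (any(in_win)) {
    which(in_win)[1]  # shortest qualifying
  } else {
    viol <- pmax(constraints$tm_range[1] - tms, tms - constraints$tm_range[2], 0)
    which(viol == min(viol))[1]
  }
  seqs <- candidates[[pick]]

  # polymorphism warning restricted to the columns actually under the primer
  win_cols <- primer_footprint_cols(cons, motif$end, lens[pick])
  win_poly <- any(apply(tgt[, win_cols, drop = FALSE], 2L,
                        function(col) length(unique(col)) > 1L))
  primer_record(
    name = sprintf("%s-dxF", gsub("\\s+", "_", sp)),
    sequence = seqs, orientation = "forward", role = "species_specific",
    target_species = sp,
    specific_3prime_len = nchar(gsub("-", "", motif$target_allele)),
    warning = if (win_poly) "target species polymorphic under primer window" else NA_character_
  )
}

# Alignment columns covered by a primer of length len ending at column end
# (skipping consensus gap columns).
primer_footprint_cols <- function(cons_row, end, len) {
  cols <- integer(0)
  j <- end
  while (length(cols) < len && j >= 1L) {
    if (cons_row[j] != "-") cols <- c(j, cols)
    j <- j - 1L
  }
  cols
}

# Maximal runs of columns where every row carries one identical non-gap base.
conserved_runs <- function(aln) {
  cons <- apply(aln$mat, 2L, function(col) {
    u <- unique(col)
    length(u) == 1L && u != "-"
  })
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# First (scan_left = TRUE) or last qualifying primer window inside conserved
# runs restricted to [lo, hi]; returns list(start, end, sequence) or NULL.
find_conserved_primer <- function(aln, runs, lo, hi, constraints, from_left = TRUE) {
  row1 <- aln$mat[1L, ]
  lens <- seq(constraints$len_range[1], constraints$len_range[2])
  positions <- list()
  run_order <- if (from_left) seq_len(nrow(runs)) else rev(seq_len(nrow(runs)))
  for (k in run_order) {
    s <- max(runs$start[k], lo); e <- min(runs$end[k], hi)
    if (e - s + 1L < constraints$len_range[1]) next
    starts <- s:(e - constraints$len_range[1] + 1L)
    for (st in if (from_left) starts else rev(starts)) {
      for (L in lens) {
        if (st + L - 1L > e) break
        sq <- paste(row1[st:(st + L - 1L)], collapse = "")
        tm <- wallace_tm(sq)
        if (tm >= constraints$tm_range[1] && tm <= constraints$tm_range[2]) {
          return(list(start = st, end = st + L - 1L, sequence = sq))
        }
      }
    }
  }
  NULL
}

#' Design the universal internal-control primer pair
#'
#' Both primers are drawn from windows fully conserved across every row: the
#' forward primer from the leftmost qualifying conserved window, the reverse
#' primer (as reverse complement) from the rightmost. The control amplicon
#' therefore spans the variable core of the locus, so species-specific
#' primers anchored on diagnostic motifs between the two windows yield
#' amplicons nested inside the control product.
#'
#' @param aln Labeled `dna_alignment` with >= 2 species.
#' @param constraints A [design_constraints()].
#' @return A two-row primer data.frame (`universal_forward`,
#'   `universal_reverse`), with attribute `footprints` giving the plus-strand
#'   alignment intervals used.
#' @export
design_control_pair <- function(aln, constraints = design_constraints()) {
  runs <- conserved_runs(aln)
  if (nrow(runs) == 0L) {
    abort_dx("no conserved window in alignment", "barcodeDx_no_primer_error")
  }
  fwd <- find_conserved_primer(aln, runs, 1L, aln$L, constraints, from_left = TRUE)
  rev_ <- find_conserved_primer(aln, runs, 1L, aln$L, constraints, from_left = FALSE)
  if (is.null(fwd) || is.null(rev_) || rev_$start <= fwd$end) {
    abort_dx("no conserved window suitable for a control primer on both flanks",
             "barcodeDx_no_primer_error")
  }
  out <- rbind(
    primer_record("control-F", fwd$sequence, "forward", "universal_forward"),
    primer_record("control-R", revcomp(rev_$sequence), "reverse", "universal_reverse")
  )
  attr(out, "footprints") <- data.frame(
    name = c("control-F", "control-R"),
    start = c(fwd$start, rev_$start), end = c(fwd$end, rev_$end)
  )
  out
}

# Longest k such that the 3'-terminal k bases of `a` are the reverse
# complement of the 3'-terminal k bases of `b` (antiparallel 3'-3' dimer).
cross_dimer_3prime <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  kmax <- 0L
  for (k in seq_len(min(length(ca), length(cb)))) {
    sa <- paste(tail(ca, k), collapse = "")
    sb <- paste(tail(cb, k), collapse = "")
    if (sa == revcomp(sb)) kmax <- k
  }
  kmax
}

#' Multiplex compatibility report for a primer panel
#'
#' Checks (i) every pairwise expected-band separation against
#' `min_band_separation`, (ii) the maximal 3'-terminal cross-complementarity
#' run between every primer pair against `max_3prime_cross_complement`, and
#' (iii) the Wallace Tm spread. Report-only; the panel "passes" iff all
#' checks pass. Symmetric in primer order.
#'
#' @param panel A `primer_panel`.
#' @param constraints A [design_constraints()].
#' @return A list of class `panel_check`: `band_separation` (data.frame),
#'   `cross_dimers` (data.frame), `tm_spread`, `passes`.
#' @export
panel_check <- function(panel, constraints = design_constraints()) {
  bands <- c(unlist(panel$expected_bands), control = panel$control_band)
  sep <- NULL
  if (length(bands) >= 2L) {
    cmb <- utils::combn(length(bands), 2L)
    sep <- data.frame(
      a = names(bands)[cmb[1, ]], b = names(bands)[cmb[2, ]],
      separation = abs(bands[cmb[1, ]] - bands[cmb[2, ]]),
      pass = abs(bands[cmb[1, ]] - bands[cmb[2, ]]) >= constraints$min_band_separation,
      row.names = NULL
    )
  } else {
    sep <- data.frame(a = character(), b = character(),
                      separation = integer(), pass = logical())
  }
  pr <- panel$primers
  dim_rows <- list()
  if (nrow(pr) >= 2L) {
    cmb <- utils::combn(nrow(pr), 2L)
    dim_rows <- lapply(seq_len(ncol(cmb)), function(i) {
      k <- cross_dimer_3prime(pr$sequence[cmb[1, i]], pr$sequence[cmb[2, i]])
      data.frame(a = pr$name[cmb[1, i]], b = pr$name[cmb[2, i]],
                 overlap = k, pass = k <= constraints$max_3prime_cross_complement)
    })
  }
  dimers <- if (length(dim_rows)) do.call(rbind, dim_rows) else
    data.frame(a = character(), b = character(), overlap = integer(), pass = logical())
  tm_spread <- diff(range(pr$tm_wallace))
  structure(list(
    band_separation = sep,
    cross_dimers = dimers,
    tm_spread = tm_spread,
    passes = all(sep$pass) && all(dimers$pass)
  ), class = "panel_check")
}

#' @export
print.panel_check <- function(x, ...) {
  cat(sprintf("<panel_check> %s (Tm spread %.1f degC)\n",
              if (x$passes) "PASS" else "FAIL", x$tm_spread))
  invisible(x)
}
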