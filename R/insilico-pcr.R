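#' Mismatch model for in-silico PCR
#'
#' ARMS-style discrimination: a primer may tolerate a few mismatches along
#' its body but none inside the 3'-terminal seed window, so an allele
#' difference under the 3' terminus blocks amplification.
#'
#' @param max_total_mismatches Mismatches tolerated over the whole footprint.
#' @param seed_3prime_len 3'-terminal window (nt) requiring exact match.
#' @param max_amplicon_len Longest product considered (bp).
#' @return A list of class `mismatch_model`.
#' @export
mismatch_model <- function(max_total_mismatches = 2L, seed_3prime_len = 4L,
                           max_amplicon_len = 2000L) {
  stopifnot(max_total_mismatches >= 0, seed_3prime_len >= 0, max_amplicon_len >= 1)
  structure(list(max_total_mismatches = as.integer(max_total_mismatches),
                 seed_3prime_len = as.integer(seed_3prime_len),
                 max_amplicon_len = as.integer(max_amplicon_len)),
            class = "mismatch_model")
}

# Which IUPAC template codes are compatible with each primer base: a
# template ambiguity matches a primer base iff its degeneracy set contains
# that base.
codes_containing <- local({
  tab <- lapply(DNA_BASES, function(b) {
    names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) b %in% s, TRUE)]
  })
  names(tab) <- DNA_BASES
  tab
})

# Mismatch count of `primer_chars` laid on the template at every start
# position (vector over starts 1..n-L+1).
mismatch_profile <- function(template_chars, primer_chars) {
  n <- length(template_chars); L <- length(primer_chars)
  ns <- n - L + 1L
  if (ns < 1L) return(integer(0))
  mm <- integer(ns)
  for (j in seq_len(L)) {
    ok <- template_chars[j:(j + ns - 1L)] %in% codes_containing[[primer_chars[j]]]
    mm <- mm + !ok
  }
  mm
}

#' Find primer binding sites on a linear template
#'
#' Scans both strands for footprints with at most `max_total_mismatches`
#' Hamming mismatches whose 3'-terminal `seed_3prime_len` bases match the
#' template exactly. Template IUPAC ambiguity matches a primer base iff the
#' ambiguity set contains it. Plus-strand sites extend rightward (3' end at
#' `end`); minus-strand sites extend leftward (3' end at `start`).
#'
#' @param template Ungapped IUPAC DNA string (or a single-record list with
#'   `id` and `residues`).
#' @param primer Primer sequence (A/C/G/T) or a one-row primer data.frame.
#' @param model A [mismatch_model()].
#' @param template_id Identifier used in the result.
#' @return Data.frame: `template_id`, `strand` (`+`/`-`), `start`, `end`
#'   (1-based inclusive footprint), `mismatches`, `three_prime_ok`.
#' @export
find_binding_sites <- function(template, primer, model = mismatch_model(),
                               template_id = "template") {
  if (is.list(template)) {
    template_id <- template$id %||% template_id
    template <- template$residues
  }
  if (is.data.frame(primer)) primer <- primer$sequence
  if (grepl("-", template, fixed = TRUE)) {
    abort_dx("template must be ungapped", "barcodeDx_contract_error")
  }
  tc <- chars(toupper(template))
  check_alphabet(template, template_id, allow_gap = FALSE)
  pc <- chars(toupper(primer))
  L <- length(pc)
  seed <- min(model$seed_3prime_len, L)

  site_rows <- function(strand) {
    # on the minus strand the primer binds as its reverse complement on the
    # plus-strand text; its 3' seed maps to the footprint's left end
    qc <- if (strand == "+") pc else chars(revcomp(paste(pc, collapse = "")))
    mm <- mismatch_profile(tc, qc)
    if (!length(mm)) return(NULL)
    seed_off <- if (strand == "+") (L - seed + 1L):L else seq_len(seed)
    seed_ok <- rep(TRUE, length(mm))
    for (j in seed_off) {
      ok <- tc[j:(j + length(mm) - 1L)] %in% codes_containing[[qc[j]]]
      seed_ok <- seed_ok & ok
    }
    keep <- which(mm <= model$max_total_mismatches & (seed == 0L | seed_ok))
    if (!length(keep)) return(NULL)
    data.frame(template_id = template_id, strand = strand,
               start = keep, end = keep + L - 1L,
               mismatches = mm[keep], three_prime_ok = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- rbind(site_rows("+"), site_rows("-"))
  if (is.null(out)) {
    out <- data.frame(template_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), three_prime_ok = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' In-silico multiplex PCR over a set of templates
#'
#' Every plus-strand site of any panel primer pairs with every minus-strand
#' site lying entirely 3' of it on the same template; pairs spanning at most
#' `max_amplicon_len` yield amplicons. A gel lane's bands are the distinct
#' amplicon sizes of its sample (identically sized products co-migrate; the
#' amplicon table keeps them all). Templates sharing a sample id are pooled
#' into one lane, emulating mixed genomic DNA in one reaction.
#'
#' @param panel A `primer_panel`.
#' @param templates A `species_panel`, or a named character vector of
#'   ungapped sequences (names = template ids).
#' @param model A [mismatch_model()].
#' @param samples Optional named list mapping sample id -> template ids;
#'   default: one sample per template.
#' @return A list of class `pcr_result`: `amplicons` (data.frame with
#'   `template_id`, `forward_primer`, `reverse_primer`, `start`, `end`,
#'   `length_bp`) and `lanes` (named list of `gel_lane`: `sample_id`,
#'   `bands` sorted descending).
#' @export
multiplex_pcr <- function(panel, templates, model = mismatch_model(),
                          samples = NULL) {
  if (inherits(templates, "species_panel")) {
    templates <- setNames(templates$residues, templates$ids)
  }
  stopifnot(is.character(templates), !is.null(names(templates)))
  pr <- panel$primers

  amp_rows <- list()
  for (tid in names(templates)) {
    sites <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
      s <- find_binding_sites(templates[[tid]], pr$sequence[i], model, tid)
      if (nrow(s)) s$primer <- pr$name[i]
      s
    }))
    if (is.null(sites) || nrow(sites) == 0L) next
    fwd <- sites[sites$strand == "+", , drop = FALSE]
    rev_ <- sites[sites$strand == "-", , drop = FALSE]
    if (nrow(fwd) == 0L || nrow(rev_) == 0L) next
    for (i in seq_len(nrow(fwd))) {
      for (j in seq_len(nrow(rev_))) {
        if (fwd$end[i] < rev_$start[j]) {
          len <- rev_$end[j] - fwd$start[i] + 1L
          if (len <= model$max_amplicon_len) {
            amp_rows[[length(amp_rows) + 1L]] <- data.frame(
              template_id = tid,
              forward_primer = fwd$primer[i], reverse_primer = rev_$primer[j],
              start = fwd$start[i], end = rev_$end[j], length_bp = len,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  amplicons <- if (length(amp_rows)) do.call(rbind, amp_rows) else
    data.frame(template_id = character(), forward_primer = character(),
               reverse_primer = character(), start = integer(),
               end = integer(), length_bp = integer(), stringsAsFactors = FALSE)

  if (is.null(samples)) {
    samples <- setNames(as.list(names(templates)), names(templates))
  }
  lanes <- lapply(names(samples), function(sid) {
    sizes <- amplicons$length_bp[amplicons$template_id %in% samples[[sid]]]
    structure(list(sample_id = sid,
                   bands = sort(unique(as.integer(sizes)), decreasing = TRUE)),
              class = "gel_lane")
  })
  names(lanes) <- names(samples)
  structure(list(amplicons = amplicons, lanes = lanes), class = "pcr_result")
}

#' Classify a band pattern into a species call
#'
#' Decision rule: internal-control band present and exactly one species band
#' -> that species; control only -> `NON_TARGET`; no control band ->
#' `NO_AMPLIFICATION`; control plus two or more species bands ->
#' `AMBIGUOUS_MIXTURE`. Band matching is relative: a band matches an expected
#' size when `|band - expected| / expected <= size_tolerance`. The result is
#' invariant under band order.
#'
#' @param lane A `gel_lane` (or list with `sample_id` and `bands`).
#' @param panel A `primer_panel` defining `expected_bands` and `control_band`.
#' @param size_tolerance Relative size tolerance (default 0.10).
#' @return A list of class `species_call`: `sample_id`, `call`, `bands`,
#'   `evidence` (data.frame of matched expected bands).
#' @export
call_species <- function(lane, panel, size_tolerance = 0.10) {
  bands <- as.numeric(lane$bands)
  near <- function(expected) any(abs(bands - expected) / expected <= size_tolerance)
  control_ok <- length(bands) > 0L && near(panel$control_band)
  sp_hit <- vapply(panel$expected_bands, near, TRUE)
  matched <- names(panel$expected_bands)[sp_hit]

  call <- if (!control_ok) {
    "NO_AMPLIFICATION"
  } else if (length(matched) == 0L) {
    "NON_TARGET"
  } else if (length(matched) == 1L) {
    matched
  } else {
    "AMBIGUOUS_MIXTURE"
  }
  evidence <- data.frame(
    expected = c(unlist(panel$expected_bands), control = panel$control_band),
    matched = c(sp_hit, control = control_ok)
  )
  structure(list(sample_id = lane$sample_id, call = call,
                 bands = as.integer(bands), evidence = evidence,
                 size_tolerance = size_tolerance),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("<species_call> %s: [%s] -> %s\n",
              x$sample_id, paste(x$bands, collapse = ","), x$call))
  invisible(x)
}

#' Virtual gel migration distance
#'
#' Standard semi-log model: `distance = a - b * log10(length_bp)`; strictly
#' decreasing in fragment length for `b > 0`.
#'
#' @param length_bp Fragment length(s), bp.
#' @param gel Numeric pair `c(a, b)`; defaults place 50-2000 bp fragments on
#'   a 0-75 unit track.
#' @return Migration distance(s), arbitrary units.
#' @export
gel_migration <- function(length_bp, gel = c(a = 140, b = 40)) {
  stopifnot(all(length_bp >= 1))
  gel[["a"]] - gel[["b"]] * log10(length_bp)
}

#' Render gel lanes as ASCII art
#'
#' @param lanes Named list of `gel_lane` objects (see [multiplex_pcr()]).
#' @param ladder Marker sizes (bp) rendered as the first lane.
#' @param height Number of character rows in the track.
#' @param gel Migration parameters, see [gel_migration()].
#' @return Character vector of lines (also printed invisibly-friendly).
#' @export
render_gel <- function(lanes, ladder = c(1000L, 500L, 400L, 300L, 200L, 100L, 50L),
                       height = 24L, gel = c(a = 140, b = 40)) {
  all_sizes <- c(ladder, unlist(lapply(lanes, `[[`, "bands")))
  rng <- range(gel_migration(all_sizes, gel))
  to_row <- function(sizes) {
    d <- gel_migration(sizes, gel)
    pmin(height, pmax(1L, 1L + as.integer(round((d - rng[1]) / diff(rng) * (height - 1L)))))
  }
  cols <- c(list(ladder = ladder), lapply(lanes, `[[`, "bands"))
  width <- 8L
  hdr <- paste(formatC(names(cols), width = width), collapse = "")
  body <- vapply(seq_len(height), function(r) {
    paste(vapply(cols, function(sizes) {
      hit <- length(sizes) && any(to_row(sizes) == r)
      formatC(if (hit) "====" else "", width = width)
    }, ""), collapse = "")
  }, "")
  c(hdr, body)
}
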