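#' Periodic motif patterns
#'
#' A motif pattern is an ordered list of residue classes (the "slots") that
#' tile a sequence tandemly.  Each slot is either `ANY` (written `NULL` or
#' `"*"`), accepting any amino acid, or an explicit set of one-letter codes.
#' The classic basic dipeptide repeat (X-R/K) — every second residue
#' arginine or lysine, the alternating "spacer" unconstrained — is
#' `motif_pattern(list("*", c("R", "K")), "XRK")`, available as
#' [pattern_xrk()].  The tripeptide (X-P-R) used by the herpesvirus US11
#' protein is [pattern_xpr()].
#'
#' At least one slot must be constrained (a proper subset of the alphabet)
#' and the period (number of slots) must be at least 2.
#'
#' @param slots list with one element per slot: `NULL` or `"*"` for ANY, or
#'   a character vector of one-letter codes.
#' @param pattern_id short label carried into hit tables.
#' @return an object of class `motif_pattern` with elements `pattern_id`,
#'   `slots` (list; `NULL` = ANY) and `period`.
#' @examples
#' pattern_xrk()
#' motif_pattern(list("*", "P", "R"), "XPR")
#' @export
motif_pattern <- function(slots, pattern_id) {
  stopifnot(is.list(slots), length(slots) >= 2L,
            is.character(pattern_id), length(pattern_id) == 1L)
  slots <- lapply(slots, function(s) {
    if (is.null(s) || identical(s, "*")) return(NULL)
    s <- toupper(as.character(s))
    bad <- setdiff(s, c(aa_standard(), aa_nonstandard()))
    if (length(bad)) stop("unknown residue code(s) in slot: ",
                          paste(bad, collapse = ", "))
    unique(s)
  })
  if (all(vapply(slots, is.null, logical(1)))) {
    stop("at least one slot must be constrained (a residue set)")
  }
  structure(list(pattern_id = pattern_id, slots = slots,
                 period = length(slots)),
            class = "motif_pattern")
}

#' @rdname motif_pattern
#' @export
pattern_xrk <- function() motif_pattern(list(NULL, c("R", "K")), "XRK")

#' @rdname motif_pattern
#' @export
pattern_xpr <- function() motif_pattern(list(NULL, "P", "R"), "XPR")

#' @export
print.motif_pattern <- function(x, ...) {
  slot_str <- vapply(x$slots, function(s) {
    if (is.null(s)) "X" else paste(s, collapse = "/")
  }, character(1))
  cat("<motif_pattern ", x$pattern_id, "> (",
      paste(slot_str, collapse = "-"), "), period ", x$period, "\n", sep = "")
  invisible(x)
}

# letters accepted by an ANY slot: standard 20, plus nonstandard codes
# unless strict_any
any_slot_letters <- function(strict_any) {
  if (strict_any) aa_standard() else c(aa_standard(), aa_nonstandard())
}

# logical vector over unit start positions 1..L-period+1: TRUE when a full
# unit starting there satisfies every slot
unit_validity <- function(chars, pattern, strict_any) {
  L <- length(chars)
  p <- pattern$period
  n_starts <- L - p + 1L
  if (n_starts < 1L) return(logical(0))
  valid <- rep(TRUE, n_starts)
  for (j in seq_len(p)) {
    allowed <- pattern$slots[[j]]
    if (is.null(allowed)) allowed <- any_slot_letters(strict_any)
    ok <- chars %in% allowed
    valid <- valid & ok[j:(n_starts + j - 1L)]
  }
  valid
}

#' Scan a sequence for maximal tandem repeats of a periodic motif
#'
#' Reports, for each of the `period` possible reading phases, every maximal
#' run of at least `min_units` consecutive valid motif units.  Hits from
#' different phases may overlap (e.g. a homopolymeric arginine run carries
#' an (X-R/K) repeat in both phases); within one phase hits are disjoint and
#' maximal — a reported run can be extended by a full unit in neither
#' direction.
#'
#' Coordinates are 0-based half-open: a hit spans sequence positions
#' `[start, end)` with `end - start = n_units * period`.
#'
#' ANY slots accept the 20 standard residues and, by default, the
#' nonstandard codes B/Z/X/U/O as well (`strict_any = TRUE` restricts ANY
#' to the standard alphabet).  Constrained slots accept exactly their
#' listed residues, so nonstandard letters never satisfy them.
#'
#' @param sequence uppercase amino-acid string.
#' @param pattern a [motif_pattern()].
#' @param min_units minimum number of tandem units per reported hit
#'   (at least 1).
#' @param strict_any if `TRUE`, ANY slots reject nonstandard letters.
#' @return data frame with columns `start`, `end` (0-based half-open),
#'   `n_units`, `phase` (start offset modulo period), `pattern_id`, sorted
#'   by `start` then `phase`.  Zero rows when nothing reaches `min_units`.
#' @examples
#' scan_motif(strrep("PR", 5), pattern_xrk(), min_units = 5)
#' scan_motif(strrep("R", 16), pattern_xrk(), min_units = 5)
#' @export
scan_motif <- function(sequence, pattern, min_units = 1L,
                       strict_any = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(pattern, "motif_pattern"), min_units >= 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  p <- pattern$period
  valid <- unit_validity(chars, pattern, strict_any)
  hits <- empty_hits()
  if (!length(valid)) return(hits)
  for (phase in 0:(p - 1L)) {
    if (phase + 1L > length(valid)) break
    starts <- seq.int(phase + 1L, length(valid), by = p)
    v <- valid[starts]
    r <- rle(v)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & r$lengths >= min_units
    if (!any(keep)) next
    for (i in which(keep)) {
      s <- starts[run_start[i]]
      n <- r$lengths[i]
      hits <- rbind(hits, data.frame(
        start = s - 1L, end = s - 1L + n * p, n_units = n,
        phase = phase, pattern_id = pattern$pattern_id,
        stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$start, hits$phase), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), n_units = integer(0),
             phase = integer(0), pattern_id = character(0),
             stringsAsFactors = FALSE)
}

#' Largest tandem unit count of a motif in one sequence
#'
#' The per-protein "repeat length" statistic: the maximum number of
#' consecutive motif units over all phases, 0 when no single unit matches.
#'
#' @inheritParams scan_motif
#' @return integer scalar.
#' @examples
#' max_units("MKMKMK", pattern_xrk())   # 3
#' max_units("PPPPPP", pattern_xrk())   # 0
#' @export
max_units <- function(sequence, pattern, strict_any = FALSE) {
  hits <- scan_motif(sequence, pattern, min_units = 1L,
                     strict_any = strict_any)
  if (nrow(hits) == 0L) 0L else max(hits$n_units)
}

#' Mine a proteome for periodic repeats
#'
#' Scans every protein, tabulates per-protein repeat statistics, and counts
#' proteins reaching each unit-count threshold (a protein counts at
#' threshold `t` when its maximal run has at least `t` units, so counts are
#' monotone non-increasing in `t`).
#'
#' @param proteome data frame with columns `accession`, `sequence`
#'   (as from [read_fasta()]).
#' @param pattern a [motif_pattern()].
#' @param thresholds ascending integer unit-count thresholds (default the
#'   conventional 5 and 10).
#' @param min_units minimal run length for rows of the returned hit table
#'   (default 1; per-protein statistics always use all maximal runs).
#' @param strict_any see [scan_motif()].
#' @return list with elements
#'   \describe{
#'     \item{per_protein}{data frame: `accession`, `max_units` (largest
#'       run), `total_units` (sum of units over all maximal runs in all
#'       phases), `n_hits`, `spans` (semicolon-joined `start-end` 0-based
#'       spans of hits with at least `min_units` units).}
#'     \item{counts}{named integer vector, one entry per threshold.}
#'     \item{hits}{hit table as [scan_motif()] plus an `accession` column,
#'       restricted to runs with at least `min_units` units.}
#'   }
#' @export
mine_proteome <- function(proteome, pattern, thresholds = c(5L, 10L),
                          min_units = 1L, strict_any = FALSE) {
  stopifnot(is.data.frame(proteome))
  if (is.unsorted(thresholds)) {
    stop("thresholds must be sorted ascending")
  }
  n <- nrow(proteome)
  per <- data.frame(accession = character(0), max_units = integer(0),
                    total_units = integer(0), n_hits = integer(0),
                    spans = character(0), stringsAsFactors = FALSE)
  all_hits <- cbind(accession = character(0), empty_hits())
  if (n > 0L) {
    rows <- vector("list", n)
    hit_tabs <- vector("list", n)
    for (i in seq_len(n)) {
      h <- scan_motif(proteome$sequence[i], pattern, min_units = 1L,
                      strict_any = strict_any)
      keep <- h[h$n_units >= min_units, , drop = FALSE]
      rows[[i]] <- data.frame(
        accession = proteome$accession[i],
        max_units = if (nrow(h)) max(h$n_units) else 0L,
        total_units = sum(h$n_units),
        n_hits = nrow(keep),
        spans = paste(sprintf("%d-%d", keep$start, keep$end),
                      collapse = ";"),
        stringsAsFactors = FALSE)
      if (nrow(keep)) {
        hit_tabs[[i]] <- cbind(accession = proteome$accession[i], keep)
      }
    }
    per <- do.call(rbind, rows)
    hit_tabs <- hit_tabs[!vapply(hit_tabs, is.null, logical(1))]
    if (length(hit_tabs)) all_hits <- do.call(rbind, hit_tabs)
  }
  counts <- vapply(thresholds, function(t) sum(per$max_units >= t),
                   integer(1))
  names(counts) <- as.character(thresholds)
  list(per_protein = per, counts = counts, hits = all_hits)
}

#' Residue census inside repeat regions
#'
#' Counts each amino acid over the union of hit spans, per proteome.
#' Positions covered by overlapping hits from different phases are counted
#' once.  Returns raw counts and frequencies over all counted positions.
#'
#' @param hits hit table with columns `accession`, `start`, `end`
#'   (0-based half-open), e.g. the `hits` element of [mine_proteome()].
#' @param proteome data frame with `accession`, `sequence` covering every
#'   accession in `hits`.
#' @return data frame with columns `residue`, `count`, `frequency`
#'   (frequencies sum to 1 when any position is covered), one row per
#'   standard residue plus any covered nonstandard letters.
#' @export
repeat_residue_census <- function(hits, proteome) {
  stopifnot(is.data.frame(hits),
            all(c("accession", "start", "end") %in% names(hits)))
  missing_acc <- setdiff(hits$accession, proteome$accession)
  if (length(missing_acc)) {
    stop("hits reference accession(s) absent from proteome: ",
         paste(unique(missing_acc), collapse = ", "))
  }
  seq_of <- stats::setNames(proteome$sequence, proteome$accession)
  covered_chars <- character(0)
  for (acc in unique(hits$accession)) {
    s <- seq_of[[acc]]
    L <- nchar(s)
    h <- hits[hits$accession == acc, , drop = FALSE]
    if (any(h$start < 0L) || any(h$end > L)) {
      stop("hit span out of sequence bounds for accession ", acc)
    }
    cov <- logical(L)
    for (i in seq_len(nrow(h))) {
      cov[(h$start[i] + 1L):h$end[i]] <- TRUE
    }
    covered_chars <- c(covered_chars,
                       strsplit(s, "", fixed = TRUE)[[1L]][cov])
  }
  lev <- union(aa_standard(), sort(unique(covered_chars)))
  counts <- table(factor(covered_chars, levels = lev))
  total <- sum(counts)
  data.frame(residue = lev, count = as.integer(counts),
             frequency = if (total > 0) as.numeric(counts) / total
                         else rep(0, length(lev)),
             stringsAsFactors = FALSE)
}
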