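#' Generate a synthetic proteome with planted periodic repeats
#'
#' Draws background residues i.i.d. from a background composition and, for
#' a chosen fraction of proteins, overwrites a uniformly placed window with
#' an exact planted repeat of a periodic motif (constrained slots drawn
#' uniformly from the slot's residue set, ANY slots from the background
#' composition).  When a planted repeat would not fit, the protein is
#' lengthened to the repeat span and a message is logged.  All randomness
#' is governed by a single `seed`, so the emitted proteome is byte-
#' reproducible.
#'
#' The planted repeat is exact (no mutation/degradation model): the
#' scanner is exact-match, so detection sensitivity on planted repeats
#' with at least `min_units` units is 1 by construction.
#'
#' @param n_proteins number of proteins.
#' @param length_range inclusive protein-length bounds, drawn uniformly.
#' @param composition background composition: named frequency vector over
#'   the standard alphabet (see [aa_background()]).
#' @param prevalence fraction of proteins receiving a planted repeat.
#' @param pattern planted [motif_pattern()].
#' @param units_range inclusive bounds of the planted tandem unit count,
#'   drawn uniformly.
#' @param acidic_run_range inclusive bounds of a per-protein planted
#'   acidic (D/E) run, drawn uniformly; emulates the wide spread of
#'   longest-D/E-stretch lengths seen in real proteomes, which an i.i.d.
#'   background alone cannot produce.  `c(0, 0)` disables acidic planting.
#'   The acidic run is placed before the repeat, so a planted repeat can
#'   truncate it; the realized stretch is whatever the final sequence
#'   carries.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param accession_prefix prefix for generated accessions.
#' @return list with elements
#'   \describe{
#'     \item{proteome}{data frame `accession`, `sequence`.}
#'     \item{truth}{data frame `accession`, `has_planted_repeat`,
#'       `planted_units`, `planted_start`, `planted_end` (0-based
#'       half-open; `NA` when nothing was planted), `planted_acidic_run`.}
#'   }
#' @export
simulate_proteome <- function(n_proteins,
                              length_range = c(150L, 600L),
                              composition = aa_background("uniprot"),
                              prevalence = 0,
                              pattern = pattern_xrk(),
                              units_range = c(5L, 15L),
                              acidic_run_range = c(0L, 20L),
                              seed = NULL,
                              accession_prefix = "SYN") {
  stopifnot(n_proteins >= 1L, prevalence >= 0, prevalence <= 1,
            length_range[1L] >= pattern$period,
            units_range[1L] >= 1L, acidic_run_range[1L] >= 0L,
            abs(sum(composition[aa_standard()]) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  comp <- composition[aa_standard()]

  lens <- resample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
  residues <- sample(aa_standard(), sum(lens), replace = TRUE, prob = comp)
  stop_at <- cumsum(lens)
  planted <- stats::runif(n_proteins) < prevalence

  acc <- sprintf("%s%05d", accession_prefix, seq_len(n_proteins))
  seqs <- character(n_proteins)
  units <- rep(NA_integer_, n_proteins)
  starts <- rep(NA_integer_, n_proteins)
  ends <- rep(NA_integer_, n_proteins)
  acid_runs <- integer(n_proteins)
  extended <- 0L

  for (i in seq_len(n_proteins)) {
    chars <- residues[(stop_at[i] - lens[i] + 1L):stop_at[i]]
    a <- resample(acidic_run_range[1L]:acidic_run_range[2L], 1L)
    a <- min(a, length(chars))
    acid_runs[i] <- a
    if (a > 0L) {
      a0 <- resample(0:(length(chars) - a), 1L)
      chars[(a0 + 1L):(a0 + a)] <- sample(c("D", "E"), a, replace = TRUE)
    }
    if (planted[i]) {
      u <- resample(units_range[1L]:units_range[2L], 1L)
      rep_chars <- planted_repeat_chars(pattern, u, comp)
      span <- length(rep_chars)
      if (span > length(chars)) {
        extended <- extended + 1L
        extra <- sample(aa_standard(), span - length(chars),
                        replace = TRUE, prob = comp)
        chars <- c(chars, extra)
      }
      s0 <- resample(0:(length(chars) - span), 1L)
      chars[(s0 + 1L):(s0 + span)] <- rep_chars
      units[i] <- u
      starts[i] <- s0
      ends[i] <- s0 + span
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  if (extended > 0L) {
    message(extended, " protein(s) lengthened to fit the planted repeat")
  }
  list(
    proteome = data.frame(accession = acc, sequence = seqs,
                          stringsAsFactors = FALSE),
    truth = data.frame(accession = acc, has_planted_repeat = planted,
                       planted_units = units, planted_start = starts,
                       planted_end = ends, planted_acidic_run = acid_runs,
                       stringsAsFactors = FALSE))
}

# sample() without the scalar-x surprise: always draws elements of x
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# character vector of one exact tandem repeat of `u` units
planted_repeat_chars <- function(pattern, u, comp) {
  unit <- function() {
    vapply(pattern$slots, function(s) {
      if (is.null(s)) sample(aa_standard(), 1L, prob = comp)
      else if (length(s) == 1L) s
      else sample(s, 1L)
    }, character(1))
  }
  as.vector(vapply(seq_len(u), function(i) unit(),
                   character(pattern$period)))
}

#' Generate localization labels whose odds depend on repeat presence
#'
#' For each protein the probability of carrying the category label is
#' `plogis(qlogis(base_rate) + log(odds_ratio) * has_planted_repeat)`, so
#' repeat-free proteins are labelled at `base_rate` and repeat-bearing
#' proteins at odds multiplied by `odds_ratio`; labels are independent
#' across proteins.  A fraction of proteins can additionally be marked as
#' lacking localization data (`has_data = FALSE`, drawn independently of
#' the label) to exercise the annotation-exclusion rule.
#'
#' @param truth truth table from [simulate_proteome()] (only `accession`
#'   and `has_planted_repeat` are used).
#' @param base_rate category base rate in repeat-free proteins, in (0, 1).
#' @param odds_ratio multiplicative odds of the label given a planted
#'   repeat (> 0; 1 = no association).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param category the category term to emit.
#' @param missing_fraction fraction of proteins marked `has_data = FALSE`.
#' @return localization table shaped like the TSV on disk: data frame
#'   `accession`, `terms` (character; the category or empty), `has_data`
#'   (logical).  Feed directly to [localization_enrichment()] or write
#'   with [write_localization_table()].
#' @export
generate_localization <- function(truth, base_rate, odds_ratio,
                                  seed = NULL, category = "nucleolus",
                                  missing_fraction = 0) {
  stopifnot(base_rate > 0, base_rate < 1, odds_ratio > 0,
            missing_fraction >= 0, missing_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  p <- stats::plogis(stats::qlogis(base_rate) +
                       log(odds_ratio) * truth$has_planted_repeat)
  labelled <- stats::rbinom(n, 1L, p) == 1L
  has_data <- if (missing_fraction > 0) {
    stats::runif(n) >= missing_fraction
  } else {
    rep(TRUE, n)
  }
  data.frame(accession = truth$accession,
             terms = ifelse(labelled & has_data, category, ""),
             has_data = has_data, stringsAsFactors = FALSE)
}

#' Generate a two-condition intensity table driven by acidic stretches
#'
#' Emulates an interactome in which enrichment in condition A over
#' condition B grows with a protein's longest D/E stretch: the log2 ratio
#' of each protein is `effect_per_stretch * longest_DE_stretch +
#' Normal(0, noise_sigma)`; condition B is a fixed baseline and condition
#' A is `baseline * 2^log2_ratio`.
#'
#' @param proteome data frame with `accession`, `sequence`.
#' @param effect_per_stretch enrichment effect, log2 units per stretch
#'   residue.
#' @param noise_sigma standard deviation of the log2-ratio noise.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param baseline condition-B intensity (arbitrary abundance units).
#' @return data frame `accession`, `intensity_a`, `intensity_b`,
#'   `true_log2_ratio`, `stretch`.
#' @export
generate_intensities <- function(proteome, effect_per_stretch = 0.2,
                                 noise_sigma = 0.3, seed = NULL,
                                 baseline = 1e6) {
  stopifnot(noise_sigma >= 0, baseline > 0)
  if (!is.null(seed)) set.seed(seed)
  stretch <- vapply(proteome$sequence, longest_acidic_stretch, integer(1),
                    USE.NAMES = FALSE)
  lr <- effect_per_stretch * stretch +
    stats::rnorm(nrow(proteome), 0, noise_sigma)
  data.frame(accession = proteome$accession,
             intensity_a = baseline * 2^lr,
             intensity_b = baseline,
             true_log2_ratio = lr,
             stretch = stretch,
             stringsAsFactors = FALSE)
}
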