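#' pKa tables for protein charge calculations
#'
#' Named sets of side-chain and terminal pKa values used by [net_charge()]
#' and [isoelectric_point()].  The default `"emboss"` table is the one used
#' by the EMBOSS `iep` program; `"sillero"` (Sillero & Ribeiro) is provided
#' as an alternative.  pI here is used for ordering and group comparison,
#' which is robust to the table choice, but the table must be pinned for
#' reproducibility — hence named, selectable sets.
#'
#' @param name `"emboss"` or `"sillero"`.
#' @return named numeric vector with entries `Nterm`, `Cterm`, `K`, `R`,
#'   `H`, `D`, `E`, `C`, `Y` (pH units).
#' @export
pka_table <- function(name = c("emboss", "sillero")) {
  name <- match.arg(name)
  switch(name,
    emboss = c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
               D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    sillero = c(Nterm = 8.2, Cterm = 3.2, K = 10.4, R = 12.0, H = 6.4,
                D = 4.0, E = 4.5, C = 9.0, Y = 10.0))
}

POSITIVE_GROUPS <- c("K", "R", "H")
NEGATIVE_GROUPS <- c("D", "E", "C", "Y")

# counts of ionizable side chains in one sequence (named integer vector)
ionizable_counts <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  groups <- c(POSITIVE_GROUPS, NEGATIVE_GROUPS)
  stats::setNames(vapply(groups, function(a) sum(chars == a), integer(1)),
                  groups)
}

net_charge_from_counts <- function(counts, pH, pka, include_termini) {
  pos <- sum(counts[POSITIVE_GROUPS] / (1 + 10^(pH - pka[POSITIVE_GROUPS])))
  neg <- sum(counts[NEGATIVE_GROUPS] / (1 + 10^(pka[NEGATIVE_GROUPS] - pH)))
  if (include_termini) {
    pos <- pos + 1 / (1 + 10^(pH - pka[["Nterm"]]))
    neg <- neg + 1 / (1 + 10^(pka[["Cterm"]] - pH))
  }
  unname(pos - neg)
}

#' Henderson-Hasselbalch net charge of a protein at a given pH
#'
#' Sums partial charges over ionizable groups: the N-terminus and K, R, H
#' side chains contribute `+1/(1 + 10^(pH - pKa))`; the C-terminus and D,
#' E, C, Y side chains contribute `-1/(1 + 10^(pKa - pH))`.  Nonstandard
#' residues contribute nothing.  The result is strictly decreasing in pH.
#'
#' @param sequence uppercase amino-acid string (non-empty).
#' @param pH pH at which to evaluate, in `[0, 14]`.
#' @param pka pKa set, see [pka_table()].
#' @param include_termini include the two terminal groups (default `TRUE`;
#'   set `FALSE` for an internal segment).
#' @return net charge in elementary charge units.
#' @examples
#' net_charge(strrep("R", 50), 7)  # close to +50
#' @export
net_charge <- function(sequence, pH = 7, pka = pka_table("emboss"),
                       include_termini = TRUE) {
  stopifnot(length(sequence) == 1L, pH >= 0, pH <= 14)
  if (!nzchar(sequence)) stop("empty sequence")
  net_charge_from_counts(ionizable_counts(sequence), pH, pka,
                         include_termini)
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` at which [net_charge()] vanishes, by bisection
#' (net charge is strictly decreasing in pH, and with termini included it
#' is positive at pH 0 and negative at pH 14, so the bracket always holds).
#' Iteration stops when the absolute net charge drops below `tol` or the
#' bracket narrows below `1e-6` pH units.
#'
#' @inheritParams net_charge
#' @param tol absolute net-charge tolerance (elementary charges).
#' @return pI in pH units.
#' @examples
#' isoelectric_point(strrep("D", 20)) < 4   # acidic homopolymer
#' isoelectric_point(strrep("R", 50)) > 12  # basic homopolymer
#' @export
isoelectric_point <- function(sequence, tol = 1e-4,
                              pka = pka_table("emboss"),
                              include_termini = TRUE) {
  if (!nzchar(sequence)) stop("empty sequence")
  counts <- ionizable_counts(sequence)
  if (!include_termini && sum(counts) == 0L) {
    stop("pI undefined: sequence has no ionizable group")
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge_from_counts(counts, mid, pka, include_termini)
    if (abs(q) < tol || (hi - lo) < 1e-6) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Longest contiguous acidic (D/E) stretch
#'
#' Length of the longest run of consecutive residues all belonging to the
#' acidic set (aspartate/glutamate by default); 0 when none occurs.  Any
#' other letter — including nonstandard codes — breaks a stretch.
#'
#' @param sequence amino-acid string.
#' @param acidic residue set defining "acidic".
#' @return integer run length.
#' @examples
#' longest_acidic_stretch("MDEDAA")  # 3
#' @export
longest_acidic_stretch <- function(sequence, acidic = c("D", "E")) {
  stopifnot(length(sequence) == 1L)
  if (!nzchar(sequence)) return(0L)
  pat <- paste0("[", paste(acidic, collapse = ""), "]+")
  m <- gregexpr(pat, sequence)[[1L]]
  if (m[1L] == -1L) return(0L)
  max(attr(m, "match.length"))
}

#' Amino-acid composition of a pool of sequences
#'
#' Frequencies over the 20 standard residues, pooled across all sequences
#' (residues are concatenated before normalization, so long proteins weigh
#' more — the proteome-occurrence convention).  Nonstandard letters are
#' ignored.
#'
#' @param sequences character vector of sequences.
#' @return named numeric 20-vector summing to 1 (all zero if the pool has
#'   no standard residue).
#' @export
aa_composition <- function(sequences) {
  counts <- count_residues(sequences, aa_standard())
  total <- sum(counts)
  if (total == 0L) return(stats::setNames(rep(0, 20), aa_standard()))
  counts / total
}

#' Composition enrichment of a target pool against a background
#'
#' Per-residue observed frequency in the target pool, background frequency,
#' and their ratio.  Frequencies are pooled (see [aa_composition()]).  A
#' residue absent from the background has an undefined ratio, reported as
#' `NA` with the `undefined` flag set.
#'
#' @param target character vector of target sequences.
#' @param background either a character vector of background sequences or a
#'   named frequency vector over the standard alphabet.
#' @return data frame with columns `residue`, `target_freq`,
#'   `background_freq`, `ratio`, `undefined`.
#' @examples
#' composition_enrichment("DD", "DE")  # D enriched 2-fold
#' @export
composition_enrichment <- function(target, background) {
  tf <- aa_composition(target)
  if (sum(tf) == 0) stop("target pool contains no standard residue")
  bf <- if (is.character(background)) {
    x <- aa_composition(background)
    if (sum(x) == 0) stop("background pool contains no standard residue")
    x
  } else {
    stopifnot(is.numeric(background),
              all(aa_standard() %in% names(background)))
    background[aa_standard()] / sum(background[aa_standard()])
  }
  undef <- bf == 0
  ratio <- ifelse(undef, NA_real_, tf / ifelse(undef, 1, bf))
  data.frame(residue = aa_standard(), target_freq = unname(tf),
             background_freq = unname(bf), ratio = unname(ratio),
             undefined = unname(undef), stringsAsFactors = FALSE)
}

#' Per-protein charge profiles for a proteome
#'
#' Computes, for every protein, its length, isoelectric point, net charge
#' at pH 7, and longest D/E stretch.
#'
#' @param proteome data frame with `accession`, `sequence` columns.
#' @param pka pKa set, see [pka_table()].
#' @param tol pI net-charge tolerance.
#' @return data frame with columns `accession`, `length`, `pI`,
#'   `net_charge_pH7`, `longest_DE_stretch`.
#' @export
charge_profile <- function(proteome, pka = pka_table("emboss"),
                           tol = 1e-4) {
  stopifnot(is.data.frame(proteome))
  data.frame(
    accession = proteome$accession,
    length = nchar(proteome$sequence),
    pI = vapply(proteome$sequence, isoelectric_point, numeric(1),
                tol = tol, pka = pka, USE.NAMES = FALSE),
    net_charge_pH7 = vapply(proteome$sequence, net_charge, numeric(1),
                            pH = 7, pka = pka, USE.NAMES = FALSE),
    longest_DE_stretch = vapply(proteome$sequence, longest_acidic_stretch,
                                integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
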