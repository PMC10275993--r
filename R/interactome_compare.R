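#' Read a two-condition protein intensity table
#'
#' TSV with columns `accession`, `intensity_a`, `intensity_b` (label-free
#' quantification intensities, replicate-averaged upstream).  Intensities
#' must be finite and nonnegative; accessions unique.
#'
#' @param path TSV path.
#' @return data frame with the three columns, intensities numeric.
#' @export
read_intensity_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  required <- c("accession", "intensity_a", "intensity_b")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("intensity table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$intensity_a <- as.numeric(raw$intensity_a)
  raw$intensity_b <- as.numeric(raw$intensity_b)
  validate_intensities(raw)
  raw[required]
}

validate_intensities <- function(tbl) {
  if (anyDuplicated(tbl$accession)) {
    stop("duplicate accession(s) in intensity table: ",
         paste(unique(tbl$accession[duplicated(tbl$accession)]),
               collapse = ", "))
  }
  vals <- c(tbl$intensity_a, tbl$intensity_b)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("intensities must be finite and >= 0")
  }
  invisible(tbl)
}

#' Rank proteins by between-condition intensity ratio
#'
#' Computes `ratio = (intensity_a + pseudocount) / (intensity_b +
#' pseudocount)` and sorts descending, breaking ties by accession
#' lexicographic order so the ranking is deterministic.  A zero intensity
#' with a zero pseudocount is a hard error: the caller must choose a
#' pseudocount explicitly rather than have one imputed silently
#' (`pseudocount = "auto"` uses the smallest nonzero intensity in the
#' table).
#'
#' @param tbl intensity table (see [read_intensity_table()]).
#' @param pseudocount nonnegative abundance added to both conditions, or
#'   `"auto"`.
#' @return `tbl` reordered, with added `ratio` and `log2_ratio` columns.
#' @export
rank_by_ratio <- function(tbl, pseudocount = 0) {
  validate_intensities(tbl)
  if (identical(pseudocount, "auto")) {
    vals <- c(tbl$intensity_a, tbl$intensity_b)
    vals <- vals[vals > 0]
    if (!length(vals)) stop("cannot choose 'auto' pseudocount: ",
                            "all intensities are zero")
    pseudocount <- min(vals)
  }
  stopifnot(is.numeric(pseudocount), pseudocount >= 0)
  if (pseudocount == 0 &&
      any(tbl$intensity_a == 0 | tbl$intensity_b == 0)) {
    stop("zero intensity with zero pseudocount; ",
         "supply a positive pseudocount (e.g. pseudocount = \"auto\")")
  }
  tbl$ratio <- (tbl$intensity_a + pseudocount) /
    (tbl$intensity_b + pseudocount)
  tbl$log2_ratio <- log2(tbl$ratio)
  tbl <- tbl[order(-tbl$ratio, tbl$accession), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}

#' Proteins enriched at least `factor`-fold
#'
#' The boundary is inclusive ("at least doubled" keeps a ratio of exactly
#' 2).  With `factor = 1` every protein with ratio at least 1 is returned.
#'
#' @param ranked output of [rank_by_ratio()].
#' @param factor fold-change threshold (> 0).
#' @return character vector of accessions (in rank order).
#' @export
fold_change_subset <- function(ranked, factor = 2) {
  stopifnot(is.numeric(factor), factor > 0, "ratio" %in% names(ranked))
  ranked$accession[ranked$ratio >= factor]
}

#' Select the most and least enriched extreme groups
#'
#' Takes the top `n` and bottom `n` accessions of a ranking, optionally
#' after restricting to a set of accessions (e.g. proteins annotated to
#' the nucleolus) — the restriction is applied *before* splitting.  When
#' fewer than `2n` proteins remain, both groups shrink symmetrically to
#' `floor(length/2)` and a warning is issued, so the groups never overlap.
#'
#' @param ranked output of [rank_by_ratio()].
#' @param n target group size (default 100).
#' @param restrict_to optional accession set to restrict the ranking to.
#' @return object of class `extreme_groups`: list with `top`, `bottom`
#'   (accession vectors, rank order), `ranked` (the restricted ranking) and
#'   `n` (realized group size).
#' @export
select_extremes <- function(ranked, n = 100L, restrict_to = NULL) {
  stopifnot(n >= 1L, "ratio" %in% names(ranked))
  if (!is.null(restrict_to)) {
    ranked <- ranked[ranked$accession %in% restrict_to, , drop = FALSE]
  }
  len <- nrow(ranked)
  if (len == 0L) stop("no proteins left after restriction")
  if (len < 2L) stop("need at least 2 ranked proteins to form groups")
  m <- min(as.integer(n), len %/% 2L)
  if (m < n) {
    warning("only ", len, " ranked proteins; shrinking extreme groups to ",
            m, "/", m)
  }
  structure(list(top = utils::head(ranked$accession, m),
                 bottom = utils::tail(ranked$accession, m),
                 ranked = ranked, n = m),
            class = "extreme_groups")
}

#' @export
print.extreme_groups <- function(x, ...) {
  cat("<extreme_groups> top/bottom ", x$n, "/", x$n, " of ",
      nrow(x$ranked), " ranked proteins\n", sep = "")
  invisible(x)
}

#' Charge-feature comparison of the extreme groups
#'
#' Reproduces the ranked-interactome comparison: for the most and least
#' enriched groups it computes (i) isoelectric points, sorted ascending per
#' group; (ii) longest D/E stretch per protein, an integer-binned histogram
#' of both groups, and an unpaired two-group test on the stretch lengths;
#' (iii) per-group amino-acid composition enrichment against a background
#' (the whole proteome by default).
#'
#' @param groups an [select_extremes()] result.
#' @param proteome data frame with `accession`, `sequence` covering every
#'   group member.
#' @param background background for composition normalization: character
#'   vector of sequences or named frequency vector; default the pooled
#'   `proteome` sequences.
#' @param welch use the Welch variant for the stretch comparison.
#' @param pka pKa set for pI, see [pka_table()].
#' @return object of class `extremes_report`: list with elements
#'   `pI` (data frame `group`, `accession`, `pI`, sorted ascending within
#'   group), `stretches` (data frame `group`, `accession`, `stretch`),
#'   `histogram` (data frame `stretch`, `top`, `bottom`; unit-width integer
#'   bins from 0 to the observed maximum), `stretch_test` (a
#'   [two_group_test()] row, top vs bottom), and `composition` (data frame
#'   of [composition_enrichment()] rows with a `group` column).
#' @export
compare_extremes <- function(groups, proteome, background = NULL,
                             welch = FALSE, pka = pka_table("emboss")) {
  stopifnot(inherits(groups, "extreme_groups"))
  members <- c(groups$top, groups$bottom)
  missing_acc <- setdiff(members, proteome$accession)
  if (length(missing_acc)) {
    stop("missing sequence for accession(s): ",
         paste(missing_acc, collapse = ", "))
  }
  seq_of <- stats::setNames(proteome$sequence, proteome$accession)
  if (is.null(background)) background <- proteome$sequence

  per_group <- function(accs, label) {
    seqs <- unname(seq_of[accs])
    pi_vals <- vapply(seqs, isoelectric_point, numeric(1), pka = pka,
                      USE.NAMES = FALSE)
    ord <- order(pi_vals)
    list(
      pI = data.frame(group = label, accession = accs[ord],
                      pI = pi_vals[ord], stringsAsFactors = FALSE),
      stretches = data.frame(
        group = label, accession = accs,
        stretch = vapply(seqs, longest_acidic_stretch, integer(1),
                         USE.NAMES = FALSE),
        stringsAsFactors = FALSE),
      composition = cbind(group = label,
                          composition_enrichment(seqs, background)))
  }
  top <- per_group(groups$top, "top")
  bottom <- per_group(groups$bottom, "bottom")

  all_stretch <- c(top$stretches$stretch, bottom$stretches$stretch)
  bins <- 0:max(all_stretch, 0L)
  hist_df <- data.frame(
    stretch = bins,
    top = as.integer(table(factor(top$stretches$stretch, levels = bins))),
    bottom = as.integer(table(factor(bottom$stretches$stretch,
                                     levels = bins))))

  structure(list(
    pI = rbind(top$pI, bottom$pI),
    stretches = rbind(top$stretches, bottom$stretches),
    histogram = hist_df,
    stretch_test = two_group_test(top$stretches$stretch,
                                  bottom$stretches$stretch, welch = welch),
    composition = rbind(top$composition, bottom$composition)),
    class = "extremes_report")
}

#' @export
print.extremes_report <- function(x, ...) {
  st <- x$stretch_test
  cat("<extremes_report>\n",
      "  groups: ", st$n_a, " top vs ", st$n_b, " bottom proteins\n",
      "  median pI: top ",
      format(stats::median(x$pI$pI[x$pI$group == "top"]), digits = 3),
      ", bottom ",
      format(stats::median(x$pI$pI[x$pI$group == "bottom"]), digits = 3),
      "\n",
      "  longest D/E stretch: top mean ", format(st$mean_a, digits = 3),
      ", bottom mean ", format(st$mean_b, digits = 3),
      " (", st$variant, " t = ", format(st$t, digits = 3),
      ", p = ", format(st$p, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Write an extremes report as a TSV bundle
#'
#' Writes `pI.tsv`, `stretches.tsv`, `histogram.tsv`, `stretch_test.tsv`
#' and `composition.tsv` into a directory.
#'
#' @param report an [compare_extremes()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_extremes_report <- function(report, dir) {
  stopifnot(inherits(report, "extremes_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("pI", "stretches", "histogram", "stretch_test",
                 "composition")) {
    write_table(report[[name]], file.path(dir, paste0(name, ".tsv")))
  }
  invisible(dir)
}
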