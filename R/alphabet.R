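#' Amino-acid alphabets and background compositions
#'
#' `aa_standard()` returns the 20 standard one-letter amino-acid codes in
#' alphabetical order; `aa_nonstandard()` the ambiguity/rare codes (B, Z, X,
#' U, O) that may appear in curated proteomes.  `aa_background()` returns a
#' named frequency vector over the standard alphabet, summing to 1.
#'
#' The `"uniprot"` background is the average amino-acid composition of the
#' UniProtKB/Swiss-Prot knowledgebase, the conventional proteome-wide
#' background for composition normalization; `"uniform"` gives each residue
#' probability 1/20.
#'
#' @param name background name, `"uniprot"` or `"uniform"`.
#' @return `aa_standard()`/`aa_nonstandard()`: character vectors;
#'   `aa_background()`: named numeric vector over [aa_standard()] summing to 1.
#' @examples
#' aa_background("uniform")[["R"]]
#' @export
aa_standard <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_standard
#' @export
aa_nonstandard <- function() c("B", "Z", "X", "U", "O")

#' @rdname aa_standard
#' @export
aa_background <- function(name = c("uniprot", "uniform")) {
  name <- match.arg(name)
  if (name == "uniform") {
    p <- rep(1 / 20, 20)
    names(p) <- aa_standard()
    return(p)
  }
  # Swiss-Prot average composition (percent), normalized below
  p <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.71, F = 3.86,
         G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.64,
         M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.52,
         S = 6.65, T = 5.36, V = 6.85, W = 1.10, Y = 2.92)
  p <- p[aa_standard()]
  p / sum(p)
}

# residue counts over a fixed alphabet for a character vector of sequences,
# pooled; returns named integer vector
count_residues <- function(sequences, alphabet = aa_standard()) {
  chars <- unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = alphabet))
  stats::setNames(as.integer(counts), alphabet)
}
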