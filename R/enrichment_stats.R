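#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` category members in a size-`n` sample taken without
#' replacement from a population of `N` containing `K` category members.
#' Computed exactly via the cumulative hypergeometric distribution (log-
#' space accumulation internally); deterministic.
#'
#' @param k observed category members in the sample (`0 <= k <= min(n, K)`).
#' @param K category members in the population.
#' @param n sample size.
#' @param N population size.
#' @return probability in `(0, 1]`; exactly 1 when `k = 0`.
#' @examples
#' hypergeom_upper(2, 2, 3, 5)  # 3/10
#' @export
hypergeom_upper <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    stopifnot(is.numeric(v), v == round(v))
  }
  if (any(K > N)) stop("bound violated: K <= N")
  if (any(n > N)) stop("bound violated: n <= N")
  if (any(k > n)) stop("bound violated: k <= n")
  if (any(k > K)) stop("bound violated: k <= K")
  if (any(c(k, K, n, N) < 0)) stop("bound violated: arguments >= 0")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Localization-category overrepresentation test
#'
#' Tests whether a sample of proteins (e.g. those carrying at least five
#' (X-R/K) repeat units) is overrepresented in a localization category
#' (e.g. nucleolus, nuclear speckle, PML body) relative to a proteome
#' population, with an exact one-sided upper-tail hypergeometric p value.
#'
#' Proteins without localization data (`has_data = FALSE`, or absent from
#' the annotation table) are excluded from *both* the population and the
#' sample before counting, so the annotated-population size is data-driven.
#' A protein is a category hit when its term set intersects
#' `category_terms`; matching is case-insensitive exact term equality after
#' trimming.  If no sample member survives the exclusion the category is
#' untestable and reported with `not_determined = TRUE` rather than
#' dropped.
#'
#' @param sample_accessions accessions of the sample; must all occur in
#'   `population_accessions`.
#' @param population_accessions accessions of the full population.
#' @param loc annotation table: data frame with columns `accession`,
#'   `terms` (list of character vectors, or raw `|`-separated character)
#'   and `has_data` (see [read_localization_table()]).
#' @param category_terms character vector of terms defining the category.
#' @param category label carried into the result.
#' @return one-row data frame with columns `category`, `N` (annotated
#'   population), `K` (population hits), `n` (annotated sample), `k`
#'   (sample hits), `population_fraction`, `sample_fraction`, `fold`
#'   (sample over population fraction), `p_upper`, `not_determined`.
#' @export
localization_enrichment <- function(sample_accessions,
                                    population_accessions, loc,
                                    category_terms,
                                    category = category_terms[[1L]]) {
  bad <- setdiff(sample_accessions, population_accessions)
  if (length(bad)) {
    stop("sample accession(s) not in population: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  category_terms <- tolower(trimws(category_terms))
  idx <- match(population_accessions, loc$accession)
  known <- !is.na(idx)
  has_data <- known
  has_data[known] <- loc$has_data[idx[known]]

  hit <- rep(FALSE, length(population_accessions))
  if (is.list(loc$terms)) {
    hit[known] <- vapply(loc$terms[idx[known]],
                         function(ts) any(ts %in% category_terms),
                         logical(1))
  } else {
    # raw character column: decide per unique string, then broadcast
    uv <- unique(as.character(loc$terms))
    uv_hit <- vapply(split_terms(uv),
                     function(ts) any(ts %in% category_terms), logical(1))
    hit[known] <- uv_hit[match(as.character(loc$terms)[idx[known]], uv)]
  }
  hit <- hit & has_data

  in_sample <- population_accessions %in% sample_accessions
  N <- sum(has_data)
  K <- sum(hit)
  n <- sum(has_data & in_sample)
  k <- sum(hit & in_sample)

  if (n == 0L) {
    return(data.frame(category = category, N = N, K = K, n = 0L, k = 0L,
                      population_fraction = if (N > 0) K / N else NA_real_,
                      sample_fraction = NA_real_, fold = NA_real_,
                      p_upper = NA_real_, not_determined = TRUE,
                      stringsAsFactors = FALSE))
  }
  pf <- K / N
  sf <- k / n
  data.frame(category = category, N = N, K = K, n = n, k = k,
             population_fraction = pf, sample_fraction = sf,
             fold = if (pf > 0) sf / pf else NA_real_,
             p_upper = hypergeom_upper(k, K, n, N),
             not_determined = FALSE, stringsAsFactors = FALSE)
}

#' Unpaired two-group comparison (t test)
#'
#' Two-sided unpaired t test between two groups of values: pooled-variance
#' Student's test by default, Welch's unequal-variance variant with
#' `welch = TRUE`.  Groups whose pooled data are (numerically) constant
#' have no finite t statistic and raise an error rather than returning a
#' misleading result.
#'
#' @param values_a,values_b numeric vectors, each of length at least 2.
#' @param welch use the Welch variant.
#' @return one-row data frame with columns `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `t`, `df`, `p`, `variant`.
#' @examples
#' two_group_test(c(1, 2, 3), c(4, 5, 7))
#' @export
two_group_test <- function(values_a, values_b, welch = FALSE) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  fit <- tryCatch(
    stats::t.test(values_a, values_b, var.equal = !welch,
                  alternative = "two.sided"),
    error = function(e) {
      stop("degenerate two-group comparison (", conditionMessage(e), ")")
    })
  data.frame(n_a = length(values_a), n_b = length(values_b),
             mean_a = mean(values_a), mean_b = mean(values_b),
             sd_a = stats::sd(values_a), sd_b = stats::sd(values_b),
             t = unname(fit$statistic), df = unname(fit$parameter),
             p = fit$p.value,
             variant = if (welch) "welch" else "student",
             stringsAsFactors = FALSE)
}
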