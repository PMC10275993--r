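# Independent brute-force oracles, deliberately structured unlike the
# package implementations: per-position character checks and explicit
# (start, n_units) stepping, no run-length encoding, no regex.

oracle_slot_ok <- function(ch, slot, strict_any) {
  if (is.null(slot)) {
    allowed <- if (strict_any) aa_standard() else
      c(aa_standard(), aa_nonstandard())
    return(ch %in% allowed)
  }
  ch %in% slot
}

# TRUE if a full motif unit starting at 1-based position s is valid
oracle_unit_ok <- function(chars, pattern, s, strict_any) {
  p <- pattern$period
  if (s < 1L || s + p - 1L > length(chars)) return(FALSE)
  for (j in seq_len(p)) {
    if (!oracle_slot_ok(chars[s + j - 1L], pattern$slots[[j]], strict_any)) {
      return(FALSE)
    }
  }
  TRUE
}

# every maximal (start, n_units): steps unit by unit from each start, keeps
# a start only when the preceding unit (one period earlier) is invalid
oracle_scan <- function(sequence, pattern, min_units = 1L,
                        strict_any = FALSE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  p <- pattern$period
  out <- list()
  for (s in seq_len(max(length(chars) - p + 1L, 0L))) {
    if (oracle_unit_ok(chars, pattern, s - p, strict_any)) next  # not maximal
    n <- 0L
    while (oracle_unit_ok(chars, pattern, s + n * p, strict_any)) {
      n <- n + 1L
    }
    if (n >= min_units) {
      out[[length(out) + 1L]] <- data.frame(
        start = s - 1L, end = s - 1L + n * p, n_units = n,
        phase = (s - 1L) %% p, pattern_id = pattern$pattern_id,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_units = integer(0), phase = integer(0),
                      pattern_id = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$phase), , drop = FALSE]
}

oracle_max_units <- function(sequence, pattern, strict_any = FALSE) {
  h <- oracle_scan(sequence, pattern, 1L, strict_any)
  if (nrow(h) == 0L) 0L else max(h$n_units)
}

# longest acidic run by a single explicit character walk
oracle_longest_stretch <- function(sequence, acidic = c("D", "E")) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  best <- 0L
  cur <- 0L
  for (ch in chars) {
    if (ch %in% acidic) {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else {
      cur <- 0L
    }
  }
  best
}

# upper-tail hypergeometric by enumerating every size-n subset of 1..N
# with categories 1..K; returns P(X >= k)
oracle_hyper_upper <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

random_protein <- function(len, letters = aa_standard(),
                           prob = NULL) {
  paste(sample(letters, len, replace = TRUE, prob = prob), collapse = "")
}

expect_same_hits <- function(got, want) {
  rownames(got) <- NULL
  rownames(want) <- NULL
  expect_equal(got[c("start", "end", "n_units", "phase")],
               want[c("start", "end", "n_units", "phase")])
}
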