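test_that("exact dipeptide tilings give a single full-length hit", {
  h <- scan_motif(strrep("PR", 5), pattern_xrk(), min_units = 5)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 10L)
  expect_equal(h$n_units, 5L)
  expect_equal(h$phase, 0L)

  expect_equal(max_units(strrep("PR", 50), pattern_xrk()), 50L)
})

test_that("homopolymeric arginine carries hits in both phases", {
  h <- scan_motif(strrep("R", 16), pattern_xrk(), min_units = 5)
  expect_equal(sort(unique(h$phase)), c(0L, 1L))
  expect_equal(max(h$n_units), 8L)
  expect_equal(sort(h$n_units), c(7L, 8L))
})

test_that("runs break only when a constrained slot fails", {
  # P R P R A P R P R: the A interrupts phase 0; phase 1 restarts at the P
  h <- scan_motif("PRPRAPRPR", pattern_xrk(), min_units = 2)
  expect_equal(nrow(h), 2L)
  expect_equal(h$n_units, c(2L, 2L))
  expect_same_hits(h, oracle_scan("PRPRAPRPR", pattern_xrk(), 2L))
})

test_that("per-hit maximality and unit arithmetic invariants hold", {
  set.seed(42)
  for (i in 1:40) {
    s <- random_protein(sample(20:150, 1),
                        prob = aa_background("uniform"))
    for (pat in list(pattern_xrk(), pattern_xpr())) {
      h <- scan_motif(s, pat, min_units = 1)
      if (nrow(h) == 0) next
      expect_equal(h$end - h$start, h$n_units * pat$period)
      expect_equal(h$phase, h$start %% pat$period)
      chars <- strsplit(s, "")[[1]]
      for (r in seq_len(nrow(h))) {
        expect_false(oracle_unit_ok(chars, pat, h$start[r] + 1L -
                                      pat$period, FALSE))
        expect_false(oracle_unit_ok(chars, pat, h$end[r] + 1L, FALSE))
      }
    }
  }
})

test_that("scanner matches the stepping oracle on random sequences", {
  set.seed(7)
  pats <- list(pattern_xrk(), pattern_xpr())
  # enrich basic/proline content so repeats actually occur
  prob <- aa_background("uniform")
  prob[c("R", "K", "P")] <- prob[c("R", "K", "P")] * 4
  prob <- prob / sum(prob)
  for (i in 1:150) {
    s <- random_protein(sample(5:120, 1), prob = prob)
    for (pat in pats) {
      for (mu in c(1L, 2L, 5L)) {
        expect_same_hits(scan_motif(s, pat, mu), oracle_scan(s, pat, mu))
      }
    }
  }
})

test_that("nonstandard letters satisfy ANY slots unless strict_any", {
  # X at a spacer position: allowed by default, rejected under strict_any
  expect_equal(max_units("XRXRXR", pattern_xrk()), 3L)
  expect_equal(max_units("XRXRXR", pattern_xrk(), strict_any = TRUE), 0L)
  # nonstandard letters never satisfy a constrained slot
  expect_equal(max_units("PXPXPX", pattern_xrk()), 0L)
  set.seed(3)
  for (i in 1:25) {
    s <- random_protein(60, letters = c(aa_standard(), aa_nonstandard()))
    for (strict in c(FALSE, TRUE)) {
      expect_same_hits(scan_motif(s, pattern_xrk(), 1L, strict),
                       oracle_scan(s, pattern_xrk(), 1L, strict))
    }
  }
})

test_that("scanning the reversed sequence mirrors coordinates", {
  rev_string <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rev_pattern <- function(p) motif_pattern(rev(p$slots), "rev")
  set.seed(9)
  for (i in 1:20) {
    s <- random_protein(sample(10:80, 1))
    L <- nchar(s)
    fwd <- scan_motif(s, pattern_xpr(), 1L)
    bwd <- scan_motif(rev_string(s), rev_pattern(pattern_xpr()), 1L)
    expect_equal(nrow(fwd), nrow(bwd))
    if (nrow(fwd)) {
      mirrored <- data.frame(start = L - bwd$end, end = L - bwd$start,
                             n_units = bwd$n_units)
      mirrored <- mirrored[order(mirrored$start), ]
      expect_equal(fwd$start, mirrored$start)
      expect_equal(fwd$end, mirrored$end)
      expect_equal(fwd$n_units, mirrored$n_units)
    }
  }
})

test_that("trivial max_units cases behave", {
  expect_equal(max_units("MKMKMK", pattern_xrk()), 3L)
  expect_equal(max_units("PPPPPP", pattern_xrk()), 0L)
  expect_equal(max_units("P", pattern_xrk()), 0L)  # shorter than a unit
})

test_that("mine_proteome counts thresholds correctly and monotonically", {
  proteome <- data.frame(
    accession = c("A", "B", "C"),
    sequence = c(strrep("PR", 4), strrep("PR", 5), strrep("KR", 12)),
    stringsAsFactors = FALSE)
  res <- mine_proteome(proteome, pattern_xrk(), thresholds = c(5L, 10L))
  expect_equal(unname(res$counts), c(2L, 1L))
  expect_equal(res$per_protein$max_units >= 5,
               c(FALSE, TRUE, TRUE))
  expect_true(res$counts[["5"]] >= res$counts[["10"]])

  # threshold 0 counts every protein
  res0 <- mine_proteome(proteome, pattern_xrk(), thresholds = 0L)
  expect_equal(unname(res0$counts), 3L)

  empty <- mine_proteome(proteome[0, ], pattern_xrk())
  expect_equal(nrow(empty$per_protein), 0L)
  expect_equal(unname(empty$counts), c(0L, 0L))
})

test_that("residue census counts union of spans once", {
  proteome <- data.frame(accession = "A", sequence = "DRDRDR",
                         stringsAsFactors = FALSE)
  hits <- data.frame(accession = "A", start = 0L, end = 6L)
  cen <- repeat_residue_census(hits, proteome)
  expect_equal(cen$count[cen$residue == "D"], 3L)
  expect_equal(cen$count[cen$residue == "R"], 3L)
  expect_equal(sum(cen$count), 6L)
  expect_equal(sum(cen$frequency), 1)

  # overlapping phase hits over the same 10 arginines count 10, not 20
  proteome2 <- data.frame(accession = "B", sequence = strrep("R", 10),
                          stringsAsFactors = FALSE)
  hits2 <- scan_motif(proteome2$sequence, pattern_xrk(), min_units = 4)
  hits2 <- cbind(accession = "B", hits2)
  expect_equal(nrow(hits2), 2L)  # both phases present
  cen2 <- repeat_residue_census(hits2, proteome2)
  expect_equal(sum(cen2$count), 10L)
  expect_equal(cen2$count[cen2$residue == "R"], 10L)

  expect_error(
    repeat_residue_census(data.frame(accession = "A", start = 0L,
                                     end = 99L), proteome),
    "out of sequence bounds")
  expect_error(
    repeat_residue_census(data.frame(accession = "Z", start = 0L,
                                     end = 2L), proteome),
    "absent from proteome")
})
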