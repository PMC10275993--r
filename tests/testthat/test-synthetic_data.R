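test_that("the same seed reproduces byte-identical FASTA output", {
  sim1 <- simulate_proteome(30, length_range = c(60, 120),
                            prevalence = 0.3, seed = 101)
  sim2 <- simulate_proteome(30, length_range = c(60, 120),
                            prevalence = 0.3, seed = 101)
  expect_identical(sim1, sim2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(sim1$proteome, f1)
  write_fasta(sim2$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different proteome
  sim3 <- simulate_proteome(30, length_range = c(60, 120),
                            prevalence = 0.3, seed = 102)
  expect_false(identical(sim1$proteome$sequence, sim3$proteome$sequence))
})

test_that("planted repeats are always detected (exact planting)", {
  sim <- simulate_proteome(60, length_range = c(100, 200),
                           prevalence = 1, units_range = c(12, 12),
                           seed = 7)
  res <- mine_proteome(sim$proteome, pattern_xrk(), thresholds = c(5, 10))
  expect_equal(unname(res$counts[["5"]]), 60L)
  expect_true(all(res$per_protein$max_units >= 12))
  # the truth spans really contain the planted repeat
  for (i in seq_len(10)) {
    tr <- sim$truth[i, ]
    seg <- substr(sim$proteome$sequence[i], tr$planted_start + 1,
                  tr$planted_end)
    expect_gte(max_units(seg, pattern_xrk()), tr$planted_units)
  }
})

test_that("without planting, long chance repeats stay near the analytic bound", {
  set.seed(55)
  n <- 150
  len <- c(150, 300)
  sim <- simulate_proteome(n, length_range = len, prevalence = 0,
                           acidic_run_range = c(0L, 0L),
                           composition = aa_background("uniform"))
  res <- mine_proteome(sim$proteome, pattern_xrk(), thresholds = 5)
  # with uniform composition, P(unit) = P(R or K) = 0.1 per start, so the
  # expected number of proteins with a >= 5-unit run is <= n * len * 0.1^5
  lambda <- n * mean(len) * 0.1^5
  expect_lte(unname(res$counts[["5"]]), qpois(0.999, lambda) + 1)
})

test_that("planted-repeat census reflects the planting spacer model", {
  sim <- simulate_proteome(40, length_range = c(120, 200), prevalence = 1,
                           units_range = c(10, 10), seed = 77,
                           acidic_run_range = c(0L, 0L),
                           composition = aa_background("uniform"))
  mined <- mine_proteome(sim$proteome, pattern_xrk(), min_units = 5)
  cen <- repeat_residue_census(mined$hits, sim$proteome)
  rk_freq <- sum(cen$frequency[cen$residue %in% c("R", "K")])
  # constrained slots (half of positions) are all R/K, spacers contribute
  # R/K at the background rate 0.1: expect ~ 0.5 + 0.5 * 0.1
  expect_equal(rk_freq, 0.55, tolerance = 0.05)
})

test_that("localization labels follow the planted odds ratio", {
  sim <- simulate_proteome(400, length_range = c(50, 60), prevalence = 0.5,
                           seed = 11)
  # null: odds ratio 1 leaves the two groups at the same rate
  loc_null <- generate_localization(sim$truth, base_rate = 0.3,
                                    odds_ratio = 1, seed = 12)
  lab <- nzchar(loc_null$terms)
  frac_rep <- mean(lab[sim$truth$has_planted_repeat])
  frac_non <- mean(lab[!sim$truth$has_planted_repeat])
  expect_lt(abs(frac_rep - frac_non), 4 * sqrt(0.3 * 0.7 / 200) * 2)

  # strong positive odds ratio raises the rate in repeat proteins
  loc_or <- generate_localization(sim$truth, base_rate = 0.1,
                                  odds_ratio = 10, seed = 13)
  lab2 <- nzchar(loc_or$terms)
  expect_gt(mean(lab2[sim$truth$has_planted_repeat]),
            mean(lab2[!sim$truth$has_planted_repeat]))

  # missing-data fraction shrinks the annotated population accordingly
  loc_miss <- generate_localization(sim$truth, base_rate = 0.3,
                                    odds_ratio = 1, seed = 14,
                                    missing_fraction = 0.1)
  expect_equal(mean(loc_miss$has_data), 0.9, tolerance = 0.06)
  res <- localization_enrichment(
    sim$truth$accession[sim$truth$has_planted_repeat],
    sim$truth$accession, loc_miss, "nucleolus")
  expect_equal(res$N, sum(loc_miss$has_data))
})

test_that("intensity tables track acidic stretches as configured", {
  sim <- simulate_proteome(1000, length_range = c(150, 400), seed = 41)
  # no effect, no noise: every ratio is exactly 1
  flat <- generate_intensities(sim$proteome, effect_per_stretch = 0,
                               noise_sigma = 0, seed = 42)
  expect_equal(flat$intensity_a, flat$intensity_b)

  tab <- generate_intensities(sim$proteome, effect_per_stretch = 0.2,
                              noise_sigma = 0.3, seed = 43)
  r <- rank_by_ratio(tab[c("accession", "intensity_a", "intensity_b")])
  rho <- cor(tab$stretch, tab$intensity_a / tab$intensity_b,
             method = "spearman")
  expect_gt(rho, 0.8)
  # and the realized ranking puts long stretches near the top
  idx <- match(r$accession, tab$accession)
  expect_lt(cor(seq_len(nrow(r)), tab$stretch[idx], method = "spearman"),
            -0.8)

  expect_identical(tab, generate_intensities(
    sim$proteome, effect_per_stretch = 0.2, noise_sigma = 0.3, seed = 43))
})

test_that("generator output feeds the whole pipeline end-to-end", {
  sim <- simulate_proteome(120, length_range = c(80, 250),
                           prevalence = 0.2, seed = 301)
  loc <- generate_localization(sim$truth, base_rate = 0.05, odds_ratio = 6,
                               seed = 302, missing_fraction = 0.05)
  tab <- generate_intensities(sim$proteome, seed = 303)

  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "proteome.fasta")
  loc_tsv <- file.path(dir, "localization.tsv")
  int_tsv <- file.path(dir, "intensities.tsv")
  write_fasta(sim$proteome, fa)
  write_localization_table(loc, loc_tsv)
  write_table(tab[c("accession", "intensity_a", "intensity_b")], int_tsv)

  proteome <- read_fasta(fa)
  expect_equal(proteome, sim$proteome)
  loc_back <- read_localization_table(loc_tsv)
  mined <- mine_proteome(proteome, pattern_xrk(), thresholds = c(5, 10))
  repeat_acc <- mined$per_protein$accession[mined$per_protein$max_units >= 5]
  enr <- localization_enrichment(repeat_acc, proteome$accession, loc_back,
                                 "nucleolus")
  expect_false(enr$not_determined)
  expect_true(enr$fold > 1)  # planted association points the right way

  ranked <- rank_by_ratio(read_intensity_table(int_tsv))
  groups <- select_extremes(ranked, n = 30)
  report <- compare_extremes(groups, proteome)
  expect_s3_class(report, "extremes_report")
  out_dir <- file.path(dir, "report")
  write_extremes_report(report, out_dir)
  expect_true(all(file.exists(file.path(out_dir,
    c("pI.tsv", "stretches.tsv", "histogram.tsv", "stretch_test.tsv",
      "composition.tsv")))))
})
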