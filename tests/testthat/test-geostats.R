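test_that("long-table construction melts, filters and codes genotypes", {
  tab <- simulate_lme_table(n_subj = 3, times = seq(0, 12.5, by = 0.5))
  long <- build_long_table(tab, "gA", "gB")
  expect_equal(nrow(long), 2 * 3 * 26)
  expect_identical(levels(long$genotype), c("gA", "gB"))
  expect_identical(attr(long, "control"), "gA")
  expect_identical(unique(long$subject[long$genotype == "gA"]),
                   paste0("gA_rep", 1:3))
  # tmax filter
  expect_equal(nrow(build_long_table(tab, "gA", "gB", tmax = 5)),
               2 * 3 * 11)
  expect_error(build_long_table(tab, "gA", "gB", tmax = -1),
               "no observations")
  # unselected genotypes never appear; absent control errors
  tab$replicate[6] <- "gZ_rep1"
  long2 <- build_long_table(tab, "gA", "gB")
  expect_false("gZ" %in% long2$genotype)
  expect_error(build_long_table(tab, "gQ", "gB"), "absent")
  expect_error(build_long_table(tab, "gA", "gA"), "cannot also")
})

test_that("star annotation uses inclusive published thresholds", {
  expect_equal(star_annotation(0.001), "***")
  expect_equal(star_annotation(0.01), "**")
  expect_equal(star_annotation(0.03), "*")
  expect_equal(star_annotation(0.05), "*")
  expect_equal(star_annotation(0.05000001), "NS")
  expect_equal(star_annotation(c(1e-5, 0.2)), c("***", "NS"))
  expect_error(star_annotation(1.2), "\\[0, 1\\]")
  # monotone step function of p
  p <- sort(runif(50))
  lev <- match(star_annotation(p), c("***", "**", "*", "NS"))
  expect_true(all(diff(lev) >= 0))
})

test_that("harmonic mean p combination matches its closed form", {
  expect_equal(harmonic_mean_p(c(0.05, 0.05, 0.05)), 0.05,
               tolerance = 1e-9)
  expect_equal(harmonic_mean_p(1), 1)
  expect_equal(harmonic_mean_p(c(0.01, 0.04, 0.2)), 3 / 130,
               tolerance = 1e-6)
  # zero p-values are guarded by epsilon, not division by zero
  expect_gt(harmonic_mean_p(c(0, 0.5)), 0)
  expect_error(harmonic_mean_p(numeric()), "no p-values")
  expect_error(harmonic_mean_p(c(0.5, 2)), "\\[0, 1\\]")
  # bounds: min(p) <= HMP <= 1
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    h <- harmonic_mean_p(p)
    expect_gte(h, min(p) - 1e-9)
    expect_lte(h, 1)
  }
})

test_that("exact Mann-Whitney p equals brute-force rank enumeration", {
  expect_equal(mwu_test(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  set.seed(13)
  for (i in 1:15) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    vals <- sample(1000, nx + ny) / 7
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(mwu_test(x, y)$p, enumerate_mwu_p(x, y),
                 tolerance = 1e-12)
  }
  # identical groups: p = 1 by convention
  expect_message(res <- mwu_test(c(2, 2), c(2, 2)), "identical")
  expect_equal(res$p, 1)
  # ties force the corrected normal approximation and stay in (0, 1]
  p <- mwu_test(c(1, 1, 2, 3), c(2, 2, 3, 4))$p
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("time-point Mann-Whitney grids expose -log10 significance", {
  tab <- data.frame(replicate = c(paste0("c_rep", 1:3),
                                  paste0("m_rep", 1:3)),
                    `0` = c(1, 2, 3, 1.5, 2.5, 3.5),
                    `1` = c(1, 2, 3, 11, 12, 13),
                    check.names = FALSE)
  grid <- mwu_timepoints(tab, "c", "m")
  expect_equal(grid$time_s, c(0, 1))
  expect_equal(grid$p[2], 0.1) # maximal separation at n = 3 vs 3
  expect_equal(grid$neglog10_p, -log10(grid$p))
  same <- tab; same[4:6, -1] <- same[1:3, -1]
  grid2 <- mwu_timepoints(same, "c", "m")
  expect_true(all(grid2$p > 0.5))
})

test_that("peak metrics take per-replicate maxima within the cutoff", {
  tab <- data.frame(replicate = c("c_rep1", "c_rep2", "m_rep1"),
                    `0` = c(1, 2, 3), `1` = c(4, 5, 6), `2` = c(2, 3, 9),
                    check.names = FALSE)
  pk <- peak_metrics(tab)
  expect_equal(pk$peak, c(4, 5, 9))
  expect_equal(peak_metrics(tab, tmax = 1)$peak, c(4, 5, 6))
  # identical peak sets compare as indistinguishable
  ident <- data.frame(replicate = c(paste0("c_rep", 1:3),
                                    paste0("m_rep", 1:3)),
                      `0` = c(2, 3, 4, 2, 3, 4), check.names = FALSE)
  expect_equal(suppressMessages(mwu_peaks(ident, "c", "m"))$p, 1)
  shifted <- ident; shifted[4:6, 2] <- shifted[4:6, 2] + 10
  expect_equal(mwu_peaks(shifted, "c", "m")$p, 0.1)
})

test_that("the mixed model recovers simulated effects and flags trouble", {
  tab <- simulate_lme_table(n_subj = 12, times = 0:4, effect = 2,
                            sd_b = 0.4, sd_e = 0.3, seed = 21)
  fit <- fit_lme(build_long_table(tab, "gA", "gB"))
  main <- fit$coefficients[fit$coefficients$term == "genotypegB", ]
  expect_lt(abs(main$estimate - 2), 2 * main$se)
  expect_lt(main$p, 0.001)
  expect_equal(fit$genotypes$genotype, "gB")
  expect_lte(fit$genotypes$hmp, 1)
  expect_equal(fit$genotypes$n_terms, 5) # main effect + 4 interactions
  # insufficient replication / time points are errors
  one_t <- simulate_lme_table(n_subj = 5, times = 0)
  expect_error(fit_lme(build_long_table(one_t, "gA", "gB")),
               "2 time points")
  two_subj <- simulate_lme_table(n_subj = 1, times = 0:3)
  expect_error(fit_lme(build_long_table(two_subj, "gA", "gB")),
               "2 subjects")
})

test_that("comparison reports keep the 10-row table shape", {
  tabs <- synth_dissociation_tables(n_replicates = 4,
                                    times = seq(0, 4, by = 0.5),
                                    seed = 9)
  rep <- suppressWarnings(
    comparison_report(tabs, "ctrl", "collapse", tmax = 4))
  expect_equal(nrow(rep$table1), 10)
  expect_equal(names(rep$table1), c("Metrics", "ctrl vs collapse"))
  expect_true(all(grepl("_(LME|Peak)$", rep$table1$Metrics)))
  expect_length(rep$pvalues$collapse, 10)
  # two literally identical genotypes: every entry NS
  null_tabs <- lapply(1:5, function(i) {
    t <- simulate_lme_table(n_subj = 5, times = 0:5, seed = 30 + i)
    t[t$replicate %in% paste0("gB_rep", 1:5), -1] <-
      t[t$replicate %in% paste0("gA_rep", 1:5), -1]
    t
  })
  names(null_tabs) <- c("position", "velocity", "lp", "mp", "hp")
  rep0 <- suppressWarnings(suppressMessages(
    comparison_report(null_tabs, "gA", "gB")))
  ps <- unlist(rep0$pvalues$gB)
  expect_true(all(ps > 0.05, na.rm = TRUE))
})
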