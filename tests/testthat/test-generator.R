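test_that("default configuration reproduces the published cohort composition", {
  cfg <- default_config()
  expect_equal(cfg$n_patients, 149L)
  expect_equal(sum(cfg$trg_probabilities), 1, tolerance = 1e-12)
  expect_equal(cfg$trg_probabilities, c(31, 34, 50, 34) / 149)
  expect_equal(cfg$pre_means[["adc_value"]], 0.970)
  expect_equal(cfg$pre_sds[["adc_value"]], 0.251)
  expect_equal(cfg$treatment_effects[["adc_value"]], 1.223 - 0.970)
  expect_equal(cfg$pre_means[["sagittal_longest_diameter"]], 53.980)
  expect_equal(cfg$categorical_pre_frequencies$emvi, c(35, 14) / 49)
  # transition rows are stochastic
  for (Tm in cfg$transition_matrices)
    expect_equal(rowSums(Tm), rep(1, nrow(Tm)), tolerance = 1e-9)
})

test_that("invalid configurations are rejected with the violated invariant named", {
  cfg <- default_config()
  cfg$trg_probabilities <- c(0.5, 0.5, 0.1, 0.1)
  expect_error(generate_cohort(cfg, seed = 1), "trg_probabilities")
  cfg <- default_config()
  cfg$pre_sds[["adc_value"]] <- 0
  expect_error(generate_cohort(cfg, seed = 1), "SD")
  cfg <- default_config()
  cfg$transition_matrices$emvi[1, ] <- c(0.7, 0.6)
  expect_error(generate_cohort(cfg, seed = 1), "row-stochastic")
  cfg <- default_config()
  cfg$paired_correlation[["adc_value"]] <- 1
  expect_error(generate_cohort(cfg, seed = 1), "paired_correlation")
  cfg <- default_config(signal_features = c(1, 9))
  expect_error(generate_cohort(cfg, seed = 1), "signal_features")
})

test_that("generation is deterministic for a fixed (config, seed) and realizes exact strata", {
  c1 <- generate_cohort(default_config(), seed = 7)
  c2 <- generate_cohort(default_config(), seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(default_config(), seed = 8)))
  expect_equal(nrow(c1), 149)
  # n * trg_probabilities is integral at the default size
  expect_equal(as.vector(table(factor(c1$trg, levels = 0:3))),
               c(31, 34, 50, 34))
  # binary endpoint split implied by the strata
  expect_equal(as.vector(table(binarize_trg(c1$trg))), c(65, 84))
})

test_that("continuous values respect physiologic floors and level sets hold", {
  cohort <- generate_cohort(default_config(), seed = 3)
  for (mk in marker_names("continuous")) {
    expect_true(all(cohort[[paste0("pre_", mk)]] >= 0), label = mk)
    expect_true(all(cohort[[paste0("post_", mk)]] >= 0), label = mk)
  }
  expect_true(all(cohort$pre_adc_value > 0))
  expect_true(all(cohort$pre_n_stage %in% 0:2))
  expect_true(all(cohort$pre_t_stage %in% 2:4))
  expect_true(all(cohort$pre_emvi %in% 0:1))
  expect_true(all(cohort$trg %in% 0:3))
})

test_that("single-cohort marker means sit within CLT bounds of the calibration", {
  cohort <- generate_cohort(default_config(), seed = 1)
  se <- 0.251 / sqrt(149)
  expect_lt(abs(mean(cohort$pre_adc_value) - 0.970), 3 * se)
})

test_that("marker means over 200 cohorts match the configured calibration within 4 SE", {
  cfg <- default_config()
  n <- 149
  sums <- numeric(6)
  names(sums) <- marker_names("continuous")
  for (s in 1:200) {
    cohort <- generate_cohort(cfg, seed = 1000 + s)
    for (mk in names(sums)) sums[mk] <- sums[mk] + mean(cohort[[paste0("pre_", mk)]])
  }
  means <- sums / 200
  for (mk in names(means)) {
    se <- cfg$pre_sds[[mk]] / sqrt(n)
    expect_lt(abs(means[[mk]] - cfg$pre_means[[mk]]), 4 * se, label = mk)
  }
})

test_that("without planted signal, class-conditional baseline means differ only by noise", {
  cfg <- default_config(signal_strength = 0)
  diffs <- vapply(2000 + 1:30, function(s) {
    cohort <- generate_cohort(cfg, seed = s)
    resp <- cohort$trg <= 1
    mean(cohort$pre_adc_value[resp]) - mean(cohort$pre_adc_value[!resp])
  }, numeric(1))
  # standardized class difference centred at zero
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(30)), 4)
})

test_that("planted signal separates classes while preserving the marginal mean", {
  cfg <- default_config(signal_strength = 1.5)
  cohort <- generate_cohort(cfg, seed = 5)
  resp <- cohort$trg <= 1
  # responders have higher baseline ADC, smaller baseline tumors
  expect_gt(mean(cohort$pre_adc_value[resp]),
            mean(cohort$pre_adc_value[!resp]))
  expect_lt(mean(cohort$pre_sagittal_longest_diameter[resp]),
            mean(cohort$pre_sagittal_longest_diameter[!resp]))
  expect_lt(mean(cohort$pre_n_stage[resp]), mean(cohort$pre_n_stage[!resp]))
  # mixture marginal of a signal feature is still calibrated
  means <- vapply(3000 + 1:80, function(s)
    mean(generate_cohort(cfg, seed = s)$pre_adc_value), numeric(1))
  expect_lt(abs(mean(means) - 0.970), 4 * 0.251 / sqrt(149) / sqrt(8))
})

test_that("categorical post marginals converge to pre-marginal times transition matrix", {
  cfg <- default_config(n_patients = 6000, signal_strength = 0)
  cohort <- generate_cohort(cfg, seed = 11)
  for (mk in c("n_stage", "emvi")) {
    levs <- sort(unique(c(cohort[[paste0("pre_", mk)]],
                          cohort[[paste0("post_", mk)]])))
    pre_p <- cfg$categorical_pre_frequencies[[mk]]
    expected <- drop(pre_p %*% cfg$transition_matrices[[mk]])
    lev_all <- if (mk == "n_stage") 0:2 else 0:1
    obs <- as.vector(table(factor(cohort[[paste0("post_", mk)]],
                                  levels = lev_all))) / nrow(cohort)
    expect_equal(obs, expected, tolerance = 0.03, label = mk)
  }
})

test_that("cohort CSV round-trips losslessly and rejects malformed files", {
  cohort <- small_cohort(n = 25, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path, metadata = list(seed = 9))
  back <- read_cohort(path)
  expect_equal(back, cohort)

  # write is byte-deterministic
  path2 <- tempfile(fileext = ".csv")
  write_cohort(cohort, path2, metadata = list(seed = 9))
  expect_identical(readLines(path), readLines(path2))

  # missing trg column
  df <- utils::read.csv(path, comment.char = "#")
  df$trg <- NULL
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "trg")

  # out-of-range trg names the row
  df <- utils::read.csv(path, comment.char = "#")
  df$trg[3] <- 9
  utils::write.csv(df, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "row.*3")

  # empty file is an error, not an empty cohort
  writeLines(character(0), path3)
  expect_error(read_cohort(path3))

  # unknown extra column is rejected
  df <- utils::read.csv(path, comment.char = "#")
  df$mystery <- 1
  utils::write.csv(df, path3, row.names = FALSE)
  expect_error(read_cohort(path3), "mystery")
})
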