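test_that("population parameters match hand-enumerated values", {
  # 4 sequences, 2 allele types at p-distance 0.5, freqs (0.75, 0.25)
  pop <- alignment(c("AATT", "AATT", "AATT", "TTTT"))
  p <- compute_parameters(pop)
  expect_equal(p$pi, 2 * 0.75 * 0.25 * 0.5)
  expect_equal(p$sigma, 0.5)
  expect_equal(p$He, 1 - 0.75^2 - 0.25^2)
  expect_false(p$excluded)

  mono <- compute_parameters(alignment(c("AAA", "AAA", "AAA")))
  expect_true(mono$excluded)
  expect_equal(mono$pi, 0)

  # all-distinct population: sigma = pi * N/(N-1)
  set.seed(6)
  ad <- random_alignment(8, 100)
  pa <- compute_parameters(ad)
  expect_equal(pa$sigma, pa$pi * 8 / 7, tolerance = 1e-12)
})

test_that("sample draws honour the sampling scheme", {
  lay <- assign_sizes(build_grid_layout("linear", 0.1, 10), "even", 50)
  g <- simulate_genealogy(lay, seed = 31)
  pop <- mutate_sequences(g, substitution_model(1e-4), length = 100, seed = 32)

  # spatial: exactly one individual from each chosen deme
  s <- draw_sample(pop, lay, mode = "spatial", k = 4, seed = 5,
                   chosen_demes = c(1, 4, 7, 10))
  expect_equal(s$n, 4L)
  expect_equal(sort(attr(s, "demes")), c(1L, 4L, 7L, 10L))

  # random: k = N returns the whole population (as a permutation)
  r <- draw_sample(pop, mode = "random", k = 50, seed = 6)
  expect_equal(sort(r$ids), sort(pop$ids))
  expect_error(draw_sample(pop, mode = "random", k = 51), "exceeds")
  expect_error(draw_sample(pop, lay, mode = "spatial", k = 11), "exceeds")

  # identical seeds reproduce identical draws
  s1 <- draw_sample(pop, lay, mode = "spatial", k = 3, seed = 9,
                    chosen_demes = c(2, 5, 8))
  s2 <- draw_sample(pop, lay, mode = "spatial", k = 3, seed = 9,
                    chosen_demes = c(2, 5, 8))
  expect_identical(s1$ids, s2$ids)
})

test_that("bias/accuracy summaries match their definitions", {
  base <- data.frame(experiment = 1L, structure = "linear", migration = 0.01,
                     sample_size = 10L, measure = "pi_tilde", reference = "pi")
  # estimates equal to the parameter: SME = SRMSE = 0
  d0 <- rbind(base, base)
  d0$replicate <- 1:2
  d0$estimate <- c(1, 1); d0$parameter <- c(1, 1)
  d0$rel_err <- (d0$estimate - d0$parameter) / d0$parameter
  s0 <- summarize_replicates(d0)
  expect_equal(s0$SME, 0)
  expect_equal(s0$SRMSE, 0)

  # symmetric errors: SME = 0, SRMSE = 0.2
  d1 <- d0
  d1$estimate <- c(1.2, 0.8)
  d1$rel_err <- (d1$estimate - d1$parameter) / d1$parameter
  s1 <- summarize_replicates(d1)
  expect_equal(s1$SME, 0, tolerance = 1e-12)
  expect_equal(s1$SRMSE, 0.2, tolerance = 1e-12)
  expect_equal(s1$n_replicates, 2L)
})

test_that("SRMSE dominates |SME| in every summarised cell", {
  set.seed(40)
  fake <- expand.grid(experiment = 1L, structure = c("a", "b"),
                      migration = c(0.01, 0.1), sample_size = c(5L, 10L),
                      measure = c("m1", "m2"), reference = "x",
                      replicate = 1:6, stringsAsFactors = FALSE)
  fake$parameter <- 1
  fake$estimate <- 1 + rnorm(nrow(fake), 0.1, 0.3)
  fake$rel_err <- (fake$estimate - fake$parameter) / fake$parameter
  s <- summarize_replicates(fake)
  expect_true(all(s$SRMSE >= abs(s$SME) - 1e-12))
  expect_true(all(s$SRMSE >= 0))
})

test_that("a miniature experiment run produces a coherent factorial table", {
  cfg <- scaled_experiment_config(1, N = 120L, n_demes = 9L, mu = 1e-4,
                                  seq_length = 200L,
                                  migration_rates = c(0.01, 0.2),
                                  sample_sizes = c(4L, 6L),
                                  replicates = 2L,
                                  annealing_iterations = 300L)
  # restrict to one structure for speed
  cfg$structures <- "plane"
  res <- run_experiment(cfg, seed = 5)
  reps <- res$replicates
  expect_equal(sort(unique(reps$migration)), c(0.01, 0.2))
  expect_equal(sort(unique(reps$sample_size)), c(4L, 6L))
  expect_setequal(unique(reps$measure),
                  c("pi_tilde", "He_hat", "sigma_hat", "theta_w_site"))
  # excluded replicates contribute no estimate rows
  excl <- res$parameters[res$parameters$excluded, c("migration", "replicate")]
  if (nrow(excl) > 0) {
    for (i in seq_len(nrow(excl))) {
      expect_false(any(reps$migration == excl$migration[i] &
                         reps$replicate == excl$replicate[i]))
    }
  }
  # the summary covers only non-excluded cells and respects the invariant
  expect_true(all(res$summary$SRMSE >= abs(res$summary$SME) - 1e-12))
  # gst/nst diagnostics exist for the multi-deme design
  expect_true(!is.null(res$gst_nst))

  # experiment 5 has no differentiation diagnostics and random sampling
  cfg5 <- scaled_experiment_config(5, N = 200L, mu = 5e-5, seq_length = 200L,
                                   sample_sizes = c(5L, 10L), replicates = 2L)
  res5 <- run_experiment(cfg5, seed = 6)
  expect_null(res5$gst_nst)
  expect_equal(unique(res5$replicates$structure), "single")
})

test_that("experiment runs are reproducible under the same master seed", {
  cfg <- scaled_experiment_config(3, N = 100L, n_demes = 8L, mu = 1e-4,
                                  seq_length = 150L,
                                  migration_rates = 0.05,
                                  sample_sizes = 4L, replicates = 2L,
                                  annealing_iterations = 200L)
  r1 <- run_experiment(cfg, seed = 77)
  r2 <- run_experiment(cfg, seed = 77)
  expect_equal(r1$replicates, r2$replicates)
  expect_equal(r1$summary, r2$summary)
})

test_that("Nst declines with migration on a stepping-stone layout", {
  cfg <- scaled_experiment_config(1, N = 240L, n_demes = 12L, mu = 5e-5,
                                  seq_length = 300L,
                                  migration_rates = c(0.005, 0.5),
                                  sample_sizes = 4L, replicates = 6L,
                                  annealing_iterations = 200L)
  cfg$structures <- "circle"
  res <- run_experiment(cfg, seed = 12)
  nst_means <- tapply(res$gst_nst$nst, res$gst_nst$migration, mean)
  expect_gt(nst_means[["0.005"]], nst_means[["0.5"]])
})
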