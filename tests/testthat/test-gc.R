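test_that("window GC statistics match closed forms on simple inputs", {
  # constant G: every window GC 1, sd 0
  p <- gc_profile(c(x = strrep("G", 1e5)), 1000)
  expect_equal(p$n_windows, 100)
  expect_true(all(p$gc_values == 1))
  expect_equal(p$sd, 0)

  # homogeneous 50% GC: sd ~ sqrt(0.25/w) (binomial closed form)
  cfg <- simulation_config(seed = 61, genome_length = 3e6,
                           isochore_block_length = 3e5,
                           isochore_gc_levels = 0.5)
  ref <- simulate_reference(cfg)
  p3 <- gc_profile(c(x = ref$sequence), 3000)
  expect_equal(p3$n_windows, 1000)
  expect_lt(abs(p3$sd - sqrt(0.25 / 3000)) / sqrt(0.25 / 3000), 0.05)

  # strong two-level isochores (0.3/0.7 blocks >> window): sd ~ 0.2
  cfg2 <- simulation_config(seed = 62, genome_length = 2e6,
                            isochore_block_length = 1e5,
                            isochore_gc_levels = c(0.3, 0.7))
  ref2 <- simulate_reference(cfg2)
  p2 <- gc_profile(c(x = ref2$sequence), 3000)
  # mixture sd: sqrt(0.04 + 0.21/3000) ~ 0.2, with block-sampling noise
  expect_gt(p2$sd, 0.15)
  expect_lt(p2$sd, 0.25)
})

test_that("windows never span contigs and tolerate interior Ns", {
  # two contigs of 1500: no complete 1000-window after position 1500
  s <- c(a = rand_seq(1500), b = rand_seq(1500))
  p <- gc_profile(s, 1000)
  expect_equal(p$n_windows, 2)
  # a window with > 20% N is discarded
  sN <- paste0(rand_seq(700), strrep("N", 300))
  expect_equal(gc_profile(c(x = sN), 1000)$n_windows, 0)
  s2 <- paste0(rand_seq(900), strrep("N", 100))
  expect_equal(gc_profile(c(x = s2), 1000)$n_windows, 1)
  # sd invariant to contig order
  set.seed(63)
  contigs <- vapply(1:5, function(i) rand_seq(5000), character(1))
  p1 <- gc_profile(setNames(contigs, paste0("c", 1:5)), 1000)
  p2 <- gc_profile(setNames(rev(contigs), paste0("c", 1:5)), 1000)
  expect_equal(p1$sd, p2$sd)
  expect_equal(sort(p1$gc_values), sort(p2$gc_values))
})

test_that("insufficient windows is an explicit status, not silent zero", {
  p <- gc_profile(c(x = rand_seq(500)), 1000)
  expect_equal(p$n_windows, 0)
  expect_true(is.na(p$sd))
  expect_equal(p$status, "insufficient windows")
  expect_error(gc_profile(c(x = "ACGT"), 0), "positive")
})

test_that("the scaling curve encodes the homogeneous-genome null", {
  cfg <- simulation_config(seed = 64, genome_length = 4e6,
                           isochore_block_length = 4e5,
                           isochore_gc_levels = 0.5)
  ref <- simulate_reference(cfg)
  curve <- sd_scaling_curve(c(x = ref$sequence), c(3000, 12000))
  # homogeneous: sd(4w)/sd(w) = 0.5 within sampling tolerance
  ratio <- curve$sd[2] / curve$sd[1]
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)
  expect_equal(curve$sd_null[1], curve$sd[1])
  expect_equal(curve$excess[1], 1)
  expect_lt(abs(curve$excess[2] - 1), 0.12)

  # isochore structure inflates sd at large windows relative to the null
  cfg2 <- simulation_config(seed = 65, genome_length = 4e6,
                            isochore_block_length = 2e5,
                            isochore_gc_levels = c(0.3, 0.7))
  ref2 <- simulate_reference(cfg2)
  curve2 <- sd_scaling_curve(c(x = ref2$sequence), c(3000, 12000))
  expect_gt(curve2$sd[2] / curve2$sd[1], 0.8)
  expect_gt(curve2$excess[2], 1.5)

  expect_error(sd_scaling_curve(c(x = rand_seq(10000)), 3000),
               "two window sizes")
})

test_that("subsampled-window KS comparison behaves as a null test", {
  cfg <- simulation_config(seed = 66, genome_length = 2e6,
                           isochore_block_length = 2e5,
                           isochore_gc_levels = 0.5)
  ref <- simulate_reference(cfg)
  p <- gc_profile(c(x = ref$sequence), 3000)

  # the full set against itself: D = 0, p = 1
  full <- compare_window_samples(p, p$n_windows, seed = 1)
  expect_equal(full$D, 0)
  expect_equal(full$p_value, 1)

  # reproducible from the seed
  a <- compare_window_samples(p, 200, seed = 7)
  b <- compare_window_samples(p, 200, seed = 7)
  expect_identical(a$subsample, b$subsample)

  # under the null the comparison must not produce spuriously small
  # p-values: because the subsample is drawn from the full set the test
  # is conservative (p skewed towards 1), so the fraction below any
  # alpha is bounded by alpha itself
  ps <- vapply(1:200, function(s)
    compare_window_samples(p, 300, seed = s)$p_value, numeric(1))
  expect_lte(mean(ps < 0.05), 0.05)
  expect_gt(min(ps), 0.001)
  expect_gt(mean(ps), 0.5)

  # a shifted distribution is detected with high power
  shifted <- p
  shifted$gc_values <- p$gc_values + 0.1
  shifted$n_windows <- p$n_windows
  mixed <- p
  mixed$gc_values <- c(p$gc_values, shifted$gc_values)
  mixed$n_windows <- length(mixed$gc_values)
  ks <- suppressWarnings(ks.test(p$gc_values, shifted$gc_values,
                                 exact = FALSE))
  expect_lt(ks$p.value, 1e-3)

  expect_error(compare_window_samples(p, 0), "positive")
  expect_error(compare_window_samples(p, p$n_windows + 1), "exceeds")
})
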