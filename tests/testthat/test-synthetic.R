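test_that("double-well simulation is a pure function of spec and seed", {
  spec <- double_well_spec()
  z1 <- simulate_double_well(spec, 2, 500, seed = 7)
  z2 <- simulate_double_well(spec, 2, 500, seed = 7)
  expect_identical(z1, z2)
  z3 <- simulate_double_well(spec, 2, 500, seed = 8)
  expect_false(identical(z1, z3))
})

test_that("vanishing noise pins a trajectory at a well center", {
  spec <- double_well_spec(c(2, 4), barrier_height = 1, sigma = 1e-8,
                           dt = 0.01)
  z <- simulate_double_well(spec, 4, 2000, seed = 1)
  expect_lt(max(abs(z - 4)), 1e-4)
})

test_that("too-large integration steps are rejected", {
  spec <- double_well_spec(c(2, 4), barrier_height = 2, dt = 0.2)
  expect_error(simulate_double_well(spec, 3, 10, seed = 1),
               "stability bound")
})

test_that("long trajectories converge to the Fokker-Planck stationary law", {
  spec <- double_well_spec(c(2, 4), barrier_height = 0.2, sigma = 1.5,
                           dt = 0.03)
  st <- double_well_stationary(spec)
  ks_dist <- function(z) {
    Fz <- approx(st$grid, st$cdf, xout = sort(z), rule = 2)$y
    n <- length(z)
    max(abs(Fz - (seq_len(n) - 0.5) / n)) + 0.5 / n
  }
  z_short <- simulate_double_well(spec, 3, 2e4, seed = 3)[-1]
  z_long <- simulate_double_well(spec, 3, 2e5, seed = 3)[-1]
  ks_short <- ks_dist(z_short)
  ks_long <- ks_dist(z_long)
  expect_lt(ks_short, 0.1)
  expect_lt(ks_long, 0.02)
  expect_lt(ks_long, ks_short)
})

test_that("cross-sectional draws match their planted per-taxon laws", {
  sim <- generate_cross_section(1000, list(
    taxon_spec("sym", "symmetric", mean = 4, sd = 0.5),
    taxon_spec("bim", "bimodal", means = c(2.5, 4.5),
               sds = c(0.3, 0.3), weights = c(0.5, 0.5))
  ), seed = 21)
  expect_identical(dim(sim$matrix), c(2L, 1000L))
  expect_lt(abs(e1071::skewness(sim$matrix["sym", ])), 0.2)

  # oracle KDE on the bimodal sample: two modes separated by an antimode
  # near the planted tipping point
  d <- density(sim$matrix["bim", ], bw = "nrd")
  dy <- d$y
  idx <- 2:(length(dy) - 1)
  mins <- idx[dy[idx] < dy[idx - 1] & dy[idx] < dy[idx + 1] &
                dy[idx] > 0.01]
  mins <- mins[d$x[mins] > 2.5 & d$x[mins] < 4.5]
  expect_length(mins, 1)
  expect_lt(abs(d$x[mins] - sim$truth$tipping_point[2]), 0.2)

  sim_small <- generate_cross_section(10, list(taxon_spec("t", "rare")),
                                      seed = 1)
  expect_identical(dim(sim_small$matrix), c(1L, 10L))
})

test_that("per-taxon substreams are stable under scenario growth", {
  s1 <- generate_cross_section(50, list(
    taxon_spec("a", "symmetric"), taxon_spec("b", "rare")), seed = 4)
  s2 <- generate_cross_section(50, list(
    taxon_spec("a", "symmetric"), taxon_spec("b", "rare"),
    taxon_spec("c", "bimodal")), seed = 4)
  expect_identical(s1$matrix["a", ], s2$matrix["a", ])
  expect_identical(s1$matrix["b", ], s2$matrix["b", ])
})

test_that("longitudinal cohorts respect the visit schedule contract", {
  coh <- generate_longitudinal_cohort(25, n_timepoints = 3, seed = 2)
  expect_identical(nrow(coh$metadata), 75L)
  expect_true(all(table(coh$metadata$subject_id) == 3))
  base <- coh$metadata$time_months[!duplicated(coh$metadata$subject_id)]
  expect_true(all(tapply(coh$metadata$time_months,
                         coh$metadata$subject_id, min) == 0))
  expect_error(generate_longitudinal_cohort(10, n_timepoints = 7),
               "2..5")
})

test_that("a high barrier with weak noise yields no state shifts", {
  spec <- double_well_spec(c(2, 4), barrier_height = 2, sigma = 0.05,
                           dt = 0.005)
  coh <- generate_longitudinal_cohort(40, n_timepoints = 3, spec = spec,
                                      seed = 9)
  ser <- subject_series(coh$matrix, coh$metadata, "bistable_1")
  km <- km_state_survival(ser, coh$truth$tipping_point[1])
  expect_identical(km$n_events, 0L)
  expect_equal(km$survival, 1)
})

test_that("null metadata effects leave states independent of covariates", {
  n_sig <- 0
  for (s in 1:20) {
    base_states <- rbinom(100, 1, 0.5)
    res <- attach_metadata_effects(base_states,
                                   effects = c(age_decade = 0, bmi = 0,
                                               sex_male = 0),
                                   seed = s)
    p <- suppressWarnings(
      chisq.test(table(res$states, res$metadata$age > 47))$p.value)
    if (p < 0.01) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 3)  # ~alpha * 20 expected under independence
})

test_that("the default planted age effect is 1.026 odds per decade", {
  res <- attach_metadata_effects(rbinom(50, 1, 0.5), seed = 1)
  expect_equal(exp(unname(res$effects["age_decade"])), 1.026,
               tolerance = 1e-12)
  expect_error(attach_metadata_effects(c(0, 1), effects = c(bmi = Inf)),
               "finite")
})
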