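# helper: build a subject_series directly from per-subject times/values
make_series <- function(times, values) {
  df <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(subject_id = sprintf("P%02d", i),
               time_months = times[[i]], value = values[[i]],
               stringsAsFactors = FALSE)
  }))
  structure(df, class = c("subject_series", "data.frame"))
}

test_that("state survival matches the hand-computed product-limit value", {
  # five subjects, tipping point 3: events at months 1 and 2 (midpoint
  # convention), censorings at 1.5, 4 and 5 -> S(3) = (4/5)(2/3) = 8/15
  ser <- make_series(
    times = list(c(0, 2), c(0, 4), c(0, 1.5), c(0, 4), c(0, 5)),
    values = list(c(2, 4),      # shift in (0,2): event at 1
                  c(2, 4),      # shift in (0,4): event at 2
                  c(2, 2.5),    # censored at 1.5
                  c(4, 3.5),    # censored at 4
                  c(2, 2.2))    # censored at 5
  )
  km <- km_state_survival(ser, tipping_point = 3, horizon_months = 3)
  expect_equal(km$survival, 8 / 15, tolerance = 1e-12)
  expect_identical(km$n_events, 2L)

  # right-endpoint convention: events at months 2 and 4; at t = 2 the
  # risk set is {2, 4, 4, 5}, so S(3) = 3/4
  km_r <- km_state_survival(ser, 3, horizon_months = 3,
                            event_time = "right")
  expect_equal(km_r$survival, 3 / 4, tolerance = 1e-12)
})

test_that("state survival hits its boundary values", {
  ser_stable <- make_series(list(c(0, 4), c(0, 5)),
                            list(c(2, 2.1), c(4, 4.2)))
  expect_equal(km_state_survival(ser_stable, 3)$survival, 1)
  ser_flip <- make_series(list(c(0, 2), c(0, 1)),
                          list(c(2, 4), c(4, 2)))
  expect_equal(km_state_survival(ser_flip, 3)$survival, 0)
})

test_that("intermediate stability rejects degenerate inputs", {
  ser_const <- make_series(
    lapply(1:12, function(i) c(0, 2)),
    lapply(1:12, function(i) c(2 + i / 10, 2 + i / 10)))
  expect_error(intermediate_stability(ser_const), "zero variance")
  ser_few <- make_series(list(c(0, 1)), list(c(2, 3)))
  expect_error(intermediate_stability(ser_few), "at least 10")
})

test_that("instability near the reference produces a negative rho", {
  # deterministic construction: subjects near the median move far,
  # subjects at the extremes barely move
  z0 <- seq(1, 5, length.out = 24)
  ref <- median(z0)
  shift <- 1.2 * exp(-abs(z0 - ref)) + 0.01 * seq_along(z0)
  ser <- make_series(lapply(z0, function(z) c(0, 2)),
                     lapply(seq_along(z0),
                            function(i) c(z0[i], z0[i] + shift[i])))
  st <- intermediate_stability(ser)
  expect_lt(st$rho, -0.5)
  expect_lt(st$p, 0.01)

  # the baseline variant agrees on this construction
  st_b <- intermediate_stability(ser, method = "baseline")
  expect_lt(st_b$rho, -0.5)
})

test_that("follow-up interval length is tested against observed shifts", {
  ser_eq <- make_series(lapply(1:12, function(i) c(0, 2)),
                        lapply(1:12, function(i) c(i / 3, i / 3 + i %% 3)))
  expect_error(followup_confound_check(ser_eq), "zero variance")

  withr::with_seed(21, {
    # shifts independent of interval
    null_ok <- vapply(1:10, function(s) {
      gaps <- runif(100, 1, 6)
      ser <- make_series(lapply(gaps, function(g) c(0, g)),
                         lapply(1:100, function(i) c(3, 3 + rnorm(1, 0, 0.5))))
      abs(followup_confound_check(ser)$rho) < 0.2
    }, logical(1))
    expect_gte(mean(null_ok), 0.9)

    # pure diffusion: shift magnitude grows with the interval
    gaps <- runif(200, 0.5, 9)
    ser_d <- make_series(lapply(gaps, function(g) c(0, g)),
                         lapply(seq_along(gaps), function(i) {
                           c(3, 3 + rnorm(1, 0, 0.4 * sqrt(gaps[i])))
                         }))
    cc <- followup_confound_check(ser_d)
    expect_gt(cc$rho, 0)
    expect_lt(cc$p, 0.05)
  })
})

test_that("enrichment p matches an exact combinatorial oracle", {
  # 60 prevalent taxa, 6 bimodal, 10 with rho below threshold, 5 overlap
  support <- c(rep(0.95, 6), rep(0.2, 54))
  rho <- c(rep(-0.5, 5), -0.1, rep(-0.5, 5), rep(0, 49))
  res <- bimodality_stability_enrichment(support, rho)
  oracle <- sum(vapply(5:6, function(k) {
    choose(10, k) * choose(50, 6 - k) / choose(60, 6)
  }, numeric(1)))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$p, 12810 / 50063860, tolerance = 1e-12)
  expect_identical(res$overlap, 5L)

  # no overlap, small margins: no enrichment
  support2 <- c(rep(0.95, 3), rep(0.2, 37))
  rho2 <- c(rep(0, 3), rep(-0.5, 4), rep(0, 33))
  expect_gt(bimodality_stability_enrichment(support2, rho2)$p, 0.5)

  expect_error(bimodality_stability_enrichment(rep(0.95, 5), rep(-0.5, 5)),
               "margins")
})

test_that("bimodal taxa are more state-stable than quantile-matched nulls", {
  withr::with_seed(22, {
    hits <- vapply(1:5, function(s) {
      coh <- generate_longitudinal_cohort(
        60, n_timepoints = 3, seed = s, n_reference_taxa = 12)
      # full-cohort stand-in: baseline values
      base_ids <- coh$metadata$sample_id[coh$metadata$time_months == 0]
      m_base <- coh$matrix[, base_ids, drop = FALSE]
      res <- simulated_state_null(
        m_base, coh$matrix, coh$metadata, "bistable_1",
        tipping_point = coh$truth$tipping_point[1],
        comparison_taxa = sprintf("reference_%02d", 1:12))
      res$percentile
    }, numeric(1))
  })
  expect_gte(mean(hits >= 0.9), 0.6)
})

test_that("quantile-matched nulls reject out-of-range tipping points", {
  coh <- generate_longitudinal_cohort(20, n_timepoints = 2, seed = 3,
                                      n_reference_taxa = 10)
  base_ids <- coh$metadata$sample_id[coh$metadata$time_months == 0]
  m_base <- coh$matrix[, base_ids, drop = FALSE]
  expect_error(simulated_state_null(
    m_base, coh$matrix, coh$metadata, "bistable_1",
    tipping_point = 99, comparison_taxa = sprintf("reference_%02d", 1:10)),
    "quantile")
})
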