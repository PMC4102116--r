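## Synthetic cohort generation with known ground truth.
##
## Cross-sectional cohorts mix the abundance types seen in population-scale
## microbiota surveys (rare, symmetric, skewed, bimodal log10 abundance
## distributions); longitudinal cohorts are driven by a tilted double-well
## Langevin model so that bistability, tipping points and reduced
## intermediate stability are planted quantities that downstream stages
## must recover.

#' Specify a double-well stochastic model
#'
#' The overdamped Langevin model `dz = -U'(z) dt + sigma dW` with a
#' quartic tilted double-well potential
#' `U(z) = a (z-c)^4 / 4 - b (z-c)^2 / 2 - d (z-c)`,
#' re-parameterized from the well centers, the barrier height and a tilt:
#' `c` is the midpoint of the wells, `a = 4 H / w^4`, `b = 4 H / w^2`
#' (with `w` the half-separation and `H = barrier_height`), and
#' `d = asymmetry` deepens the upper well when positive.
#' `barrier_height = 0` degenerates to a single wide harmonic basin
#' centered at the midpoint whose relaxation time is far longer than a
#' typical follow-up window, so on observational timescales it behaves
#' as near-neutral diffusion: a unimodal control with no intermediate
#' instability structure.
#'
#' @param well_centers Numeric length-2, `(z_low, z_high)` in log10 units,
#'   `z_low < z_high`.
#' @param barrier_height Barrier height H >= 0 of the untilted potential,
#'   in potential units.
#' @param sigma Noise intensity, > 0.
#' @param dt Euler-Maruyama step, in months, > 0.
#' @param asymmetry Tilt d; 0 gives symmetric wells.
#' @return Object of class `"double_well_spec"`.
#' @export
double_well_spec <- function(well_centers = c(2, 4), barrier_height = 1,
                             sigma = 0.4, dt = 0.01, asymmetry = 0) {
  stopifnot(length(well_centers) == 2, is.numeric(well_centers),
            all(is.finite(well_centers)),
            is.finite(barrier_height), is.finite(sigma), is.finite(dt),
            is.finite(asymmetry))
  if (well_centers[1] >= well_centers[2]) {
    stop("well_centers must satisfy z_low < z_high")
  }
  if (sigma <= 0) stop("sigma must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (barrier_height < 0) stop("barrier_height must be >= 0")
  w <- diff(well_centers) / 2
  ctr <- mean(well_centers)
  if (barrier_height > 0) {
    a <- 4 * barrier_height / w^4
    b <- 4 * barrier_height / w^2
    kappa <- NA_real_
  } else {
    a <- 0
    b <- 0
    kappa <- sigma^2 / (12.5 * w^2)  # relaxation >> follow-up window
  }
  structure(
    list(well_centers = well_centers, barrier_height = barrier_height,
         sigma = sigma, dt = dt, asymmetry = asymmetry,
         a = a, b = b, c = ctr, d = asymmetry, kappa = kappa,
         half_separation = w),
    class = "double_well_spec"
  )
}

#' Potential of a double-well spec
#' @param spec A `"double_well_spec"`.
#' @param z Numeric vector of states.
#' @return U(z).
#' @export
double_well_potential <- function(spec, z) {
  stopifnot(inherits(spec, "double_well_spec"))
  dz <- z - spec$c
  if (spec$barrier_height > 0) {
    spec$a * dz^4 / 4 - spec$b * dz^2 / 2 - spec$d * dz
  } else {
    spec$kappa * dz^2 / 2 - spec$d * dz
  }
}

double_well_drift <- function(spec, z) {
  dz <- z - spec$c
  if (spec$barrier_height > 0) {
    -(spec$a * dz^3 - spec$b * dz - spec$d)
  } else {
    -(spec$kappa * dz - spec$d)
  }
}

double_well_curvature_bound <- function(spec) {
  w <- spec$half_separation
  if (spec$barrier_height > 0) {
    ## max |U''| over z in wells +/- one separation: U'' = 3 a dz^2 - b
    max(abs(3 * spec$a * (2 * w)^2 - spec$b), spec$b)
  } else {
    spec$kappa
  }
}

#' Location of the deterministic tipping point (barrier top)
#'
#' The unstable equilibrium between the two wells: the argmax of U on the
#' open interval between the well centers.  Only defined for
#' `barrier_height > 0`.
#' @param spec A `"double_well_spec"`.
#' @return Abundance value of the barrier maximum.
#' @export
double_well_tipping_point <- function(spec) {
  stopifnot(inherits(spec, "double_well_spec"))
  if (spec$barrier_height <= 0) {
    stop("a single-well spec has no tipping point")
  }
  opt <- stats::optimize(function(z) double_well_potential(spec, z),
                         interval = spec$well_centers, maximum = TRUE)
  opt$maximum
}

#' Stationary density of a double-well spec
#'
#' `p(z) = exp(-2 U(z) / sigma^2) / Z`, the stationary solution of the
#' Fokker-Planck equation for the Langevin model.
#'
#' @param spec A `"double_well_spec"`.
#' @param grid Evaluation grid; default covers the wells generously.
#' @return List with `grid`, `density` (normalized by trapezoid), `cdf`.
#' @export
double_well_stationary <- function(spec, grid = NULL) {
  if (is.null(grid)) {
    w <- spec$half_separation
    span <- 2.5 * w + 3 * spec$sigma
    grid <- seq(spec$c - span, spec$c + span, length.out = 2048)
  }
  lp <- -2 * double_well_potential(spec, grid) / spec$sigma^2
  p <- exp(lp - max(lp))
  z <- trapz(grid, p)
  p <- p / z
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  list(grid = grid, density = p, cdf = cdf)
}

#' Simulate the double-well Langevin model
#'
#' Euler-Maruyama integration
#' `z[t+dt] = z[t] - U'(z[t]) dt + sigma sqrt(dt) xi`, with `xi` standard
#' normal.  Multiple trajectories (one per element of `z0`) share the step
#' loop and are returned as columns.  The step size must satisfy
#' `dt <= 1 / L` where `L` bounds `|U''|` over the well region; larger
#' steps make the explicit scheme unstable and are rejected.
#'
#' @param spec A `"double_well_spec"`.
#' @param z0 Initial value(s).
#' @param n_steps Number of Euler steps (>= 1).
#' @param seed Integer seed; the same seed gives a bit-identical
#'   trajectory.
#' @return If `z0` is scalar, a numeric vector of length `n_steps + 1`
#'   beginning at `z0`; otherwise a `(n_steps + 1) x length(z0)` matrix.
#' @export
simulate_double_well <- function(spec, z0, n_steps, seed) {
  stopifnot(inherits(spec, "double_well_spec"), is.numeric(z0),
            all(is.finite(z0)), n_steps >= 1)
  L <- double_well_curvature_bound(spec)
  if (spec$dt > 1 / L) {
    stop(sprintf(paste0("dt = %g exceeds the stability bound 1/max|U''|",
                        " = %g for this spec"), spec$dt, 1 / L))
  }
  n_traj <- length(z0)
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = n_traj)
  out[1, ] <- z0
  sq <- spec$sigma * sqrt(spec$dt)
  with_seed(seed, {
    zc <- z0
    for (i in seq_len(n_steps)) {
      zc <- zc + double_well_drift(spec, zc) * spec$dt +
        sq * stats::rnorm(n_traj)
      out[i + 1, ] <- zc
    }
  })
  if (n_traj == 1) drop(out) else out
}

## ---------------------------------------------------------------------
## Per-taxon generative specifications

#' Per-taxon generative specification
#'
#' Constructs the generative truth record for one synthetic taxon.
#'
#' @param name Taxon name.
#' @param type One of `"rare"`, `"symmetric"`, `"left_skewed"`,
#'   `"right_skewed"`, `"bimodal"`.
#' @param ... Type-specific parameters:
#'   symmetric: `mean`, `sd`;
#'   left/right_skewed: `location`, `scale`, `shape` (skew-normal, shape
#'   sign forced to match the type);
#'   rare: `floor`, `floor_sd`, `tail_prob`, `tail_scale`;
#'   bimodal: either `means`, `sds`, `weights` (two-component normal
#'   mixture in log10 space) or `dw` (a [double_well_spec()] sampled at
#'   stationarity).
#' @return Object of class `"taxon_spec"`.
#' @export
taxon_spec <- function(name, type = c("rare", "symmetric", "left_skewed",
                                      "right_skewed", "bimodal"), ...) {
  type <- match.arg(type)
  pars <- list(...)
  defaults <- switch(type,
    symmetric = list(mean = 4, sd = 0.5),
    left_skewed = list(location = 5.2, scale = 0.8, shape = -8),
    right_skewed = list(location = 3.0, scale = 0.8, shape = 8),
    rare = list(floor = 2.0, floor_sd = 0.15, tail_prob = 0.15,
                tail_scale = 0.8),
    bimodal = list(means = c(2.2, 4.2), sds = c(0.35, 0.35),
                   weights = c(0.45, 0.55))
  )
  pars <- utils::modifyList(defaults, pars)
  if (type %in% c("symmetric")) {
    if (pars$sd <= 0) stop("component sd must be > 0")
  }
  if (type %in% c("left_skewed", "right_skewed")) {
    if (pars$scale <= 0) stop("scale must be > 0")
    pars$shape <- (if (type == "left_skewed") -1 else 1) * abs(pars$shape)
  }
  if (type == "rare" && pars$floor_sd <= 0) stop("floor_sd must be > 0")
  if (type == "bimodal" && is.null(pars$dw)) {
    if (any(pars$sds <= 0)) stop("component sds must be > 0")
    if (pars$means[1] >= pars$means[2]) stop("means must be increasing")
    pars$weights <- pars$weights / sum(pars$weights)
  }
  structure(list(name = name, type = type, params = pars),
            class = "taxon_spec")
}

## True tipping point of a taxon spec: antimode of the generative density
## between the two modes (bimodal taxa only).
taxon_true_tipping <- function(ts) {
  if (ts$type != "bimodal") return(NA_real_)
  p <- ts$params
  if (!is.null(p$dw)) {
    if (p$dw$barrier_height <= 0) return(NA_real_)
    return(double_well_tipping_point(p$dw))
  }
  dens <- function(z) {
    p$weights[1] * stats::dnorm(z, p$means[1], p$sds[1]) +
      p$weights[2] * stats::dnorm(z, p$means[2], p$sds[2])
  }
  stats::optimize(dens, interval = p$means)$minimum
}

## Skew-normal sampler via the delta construction.
r_skew_normal <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- abs(stats::rnorm(n))
  u1 <- stats::rnorm(n)
  location + scale * (delta * u0 + sqrt(1 - delta^2) * u1)
}

sample_taxon <- function(ts, n) {
  p <- ts$params
  switch(ts$type,
    symmetric = stats::rnorm(n, p$mean, p$sd),
    left_skewed = r_skew_normal(n, p$location, p$scale, p$shape),
    right_skewed = r_skew_normal(n, p$location, p$scale, p$shape),
    rare = {
      tail <- stats::runif(n) < p$tail_prob
      v <- stats::rnorm(n, p$floor, p$floor_sd)
      v[tail] <- p$floor + stats::rexp(sum(tail), rate = 1 / p$tail_scale)
      v
    },
    bimodal = {
      if (!is.null(p$dw)) {
        st <- double_well_stationary(p$dw)
        stats::approx(st$cdf, st$grid, xout = stats::runif(n),
                      ties = "ordered")$y
      } else {
        comp <- 1 + (stats::runif(n) < p$weights[2])
        stats::rnorm(n, p$means[comp], p$sds[comp])
      }
    })
}

#' Default 130-taxon scenario
#'
#' The study conditions emulated by the generator: 130 genus-like groups
#' comprising 70 rare, 34 symmetric, 10 left-skewed, 10 right-skewed and 6
#' bimodal taxa, mirroring the composition of a western-adult cohort
#' profiled at genus level (60 prevalent taxa of which 6 robustly
#' bimodal).  Parameters vary deterministically across taxa within
#' realistic log10 signal ranges (roughly 1.8 to 6).
#'
#' @param n_bimodal,n_symmetric,n_left,n_right,n_rare Type counts.
#' @return List of [taxon_spec()] entries.
#' @export
default_taxa_spec <- function(n_bimodal = 6, n_symmetric = 34,
                              n_left = 10, n_right = 10, n_rare = 70) {
  specs <- list()
  for (i in seq_len(n_bimodal)) {
    lo <- 2.0 + 0.1 * (i - 1)
    hi <- lo + 2.0 + 0.1 * ((i - 1) %% 3)
    wlo <- 0.35 + 0.05 * ((i - 1) %% 4)
    specs <- c(specs, list(taxon_spec(
      sprintf("bimodal_%02d", i), "bimodal",
      means = c(lo, hi), sds = c(0.3, 0.35),
      weights = c(wlo, 1 - wlo))))
  }
  for (i in seq_len(n_symmetric)) {
    specs <- c(specs, list(taxon_spec(
      sprintf("symmetric_%02d", i), "symmetric",
      mean = 3.3 + 1.7 * (i - 1) / max(1, n_symmetric - 1),
      sd = 0.4 + 0.3 * ((i - 1) %% 5) / 4)))
  }
  for (i in seq_len(n_left)) {
    specs <- c(specs, list(taxon_spec(
      sprintf("left_skewed_%02d", i), "left_skewed",
      location = 5.0 + 0.08 * (i - 1), scale = 0.8, shape = -8)))
  }
  for (i in seq_len(n_right)) {
    specs <- c(specs, list(taxon_spec(
      sprintf("right_skewed_%02d", i), "right_skewed",
      location = 3.0 + 0.06 * (i - 1), scale = 0.8, shape = 8)))
  }
  for (i in seq_len(n_rare)) {
    specs <- c(specs, list(taxon_spec(
      sprintf("rare_%02d", i), "rare",
      floor = 1.8 + 0.3 * ((i - 1) %% 3) / 2,
      floor_sd = 0.15, tail_prob = 0.10 + 0.05 * ((i - 1) %% 2),
      tail_scale = 0.8)))
  }
  specs
}

truth_table <- function(taxa_spec, seed) {
  structure(
    data.frame(
      taxon = vapply(taxa_spec, `[[`, character(1), "name"),
      type = vapply(taxa_spec, `[[`, character(1), "type"),
      tipping_point = vapply(taxa_spec, taxon_true_tipping, numeric(1)),
      stringsAsFactors = FALSE
    ),
    params = taxa_spec, seed = seed, class = c("synthetic_truth",
                                               "data.frame")
  )
}

#' Generate a cross-sectional synthetic cohort
#'
#' Each taxon is drawn independently from its generative spec using a
#' taxon-specific substream of the global seed, so adding or reordering
#' taxa does not perturb the values of existing ones.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param taxa_spec List of [taxon_spec()] entries
#'   (default [default_taxa_spec()]).
#' @param seed Integer seed.
#' @return List with `matrix` (taxa x samples abundance matrix, samples
#'   `S0001`...) and `truth` (a `"synthetic_truth"` data frame with the
#'   planted type and tipping point per taxon).
#' @export
generate_cross_section <- function(n_subjects,
                                   taxa_spec = default_taxa_spec(),
                                   seed = 1) {
  stopifnot(n_subjects >= 10, length(taxa_spec) >= 1)
  vals <- vapply(seq_along(taxa_spec), function(i) {
    with_seed(substream_seed(seed, i),
              sample_taxon(taxa_spec[[i]], n_subjects))
  }, numeric(n_subjects))
  m <- t(vals)
  rownames(m) <- vapply(taxa_spec, `[[`, character(1), "name")
  colnames(m) <- sprintf("S%04d", seq_len(n_subjects))
  validate_abundance_matrix(m)
  list(matrix = m, truth = truth_table(taxa_spec, seed))
}

#' Generate a longitudinal synthetic cohort
#'
#' One planted bistable taxon driven by the double-well Langevin model,
#' optionally accompanied by unimodal reference taxa driven by single-well
#' (harmonic) dynamics with matched noise.  Each subject receives a
#' baseline at month 0 plus follow-up visits inside `followup_months`;
#' baselines are drawn from an overdispersed mixture around the wells so
#' the cohort includes transitional (intermediate-abundance) subjects.
#'
#' @param n_subjects Number of subjects.
#' @param n_timepoints Either a single count or a length-2 range; each
#'   subject's number of visits (baseline included) is drawn uniformly
#'   from the range.  Must lie within 2..5.
#' @param followup_months Length-2 window (months) for follow-up visits.
#' @param spec [double_well_spec()] driving the bistable taxon.
#' @param seed Integer seed.
#' @param n_reference_taxa Number of additional unimodal reference taxa.
#' @param p_intermediate Fraction of baselines drawn uniformly between the
#'   wells (transitional subjects); the rest start in a well.
#' @return List with `matrix`, `metadata`, `truth`.
#' @export
generate_longitudinal_cohort <- function(n_subjects = 78,
                                         n_timepoints = c(2, 5),
                                         followup_months = c(1, 9),
                                         spec = double_well_spec(),
                                         seed = 1,
                                         n_reference_taxa = 0,
                                         p_intermediate = 0.35) {
  stopifnot(n_subjects >= 2, inherits(spec, "double_well_spec"))
  if (length(n_timepoints) == 1) n_timepoints <- rep(n_timepoints, 2)
  if (n_timepoints[1] < 2 || n_timepoints[2] > 5) {
    stop("n_timepoints must lie within 2..5")
  }
  stopifnot(length(followup_months) == 2,
            followup_months[1] < followup_months[2],
            followup_months[1] > 0)
  ## visit schedule
  sched <- with_seed(substream_seed(seed, "schedule"), {
    ks <- seq(n_timepoints[1], n_timepoints[2])
    k <- ks[sample.int(length(ks), n_subjects, replace = TRUE)]
    lapply(k, function(ki) {
      t_follow <- sort(stats::runif(ki - 1, followup_months[1],
                                    followup_months[2]))
      ## enforce a minimal inter-visit gap of two integration steps
      t_follow <- cummax(t_follow + seq_along(t_follow) * 2 * spec$dt)
      c(0, t_follow)
    })
  })
  max_t <- max(unlist(sched))
  n_steps <- ceiling(max_t / spec$dt)
  w <- spec$half_separation
  z0 <- with_seed(substream_seed(seed, "baseline"), {
    if (spec$barrier_height > 0) {
      mid <- stats::runif(n_subjects) < p_intermediate
      well <- sample(spec$well_centers, n_subjects, replace = TRUE)
      z <- stats::rnorm(n_subjects, well, 0.15 * w)
      z[mid] <- stats::runif(sum(mid), spec$well_centers[1],
                             spec$well_centers[2])
      z
    } else {
      stats::rnorm(n_subjects, spec$c, w)
    }
  })
  paths <- simulate_double_well(spec, z0, n_steps,
                                substream_seed(seed, "paths"))
  taxa_specs <- list(bistable = spec)
  value_rows <- list()
  meta_rows <- list()
  for (s in seq_len(n_subjects)) {
    idx <- pmin(nrow(paths), 1 + round(sched[[s]] / spec$dt))
    value_rows[[s]] <- paths[idx, s]
    meta_rows[[s]] <- data.frame(
      sample_id = sprintf("P%03d_T%d", s, seq_along(idx)),
      subject_id = sprintf("P%03d", s),
      time_months = sched[[s]],
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta_rows)
  values <- matrix(unlist(value_rows), nrow = 1,
                   dimnames = list("bistable_1", meta$sample_id))
  if (n_reference_taxa > 0) {
    ref <- vapply(seq_len(n_reference_taxa), function(j) {
      rspec <- double_well_spec(
        well_centers = spec$well_centers, barrier_height = 0,
        sigma = spec$sigma, dt = spec$dt)
      rz0 <- with_seed(substream_seed(seed, 1000 + j),
                       stats::rnorm(n_subjects, rspec$c, w))
      rpaths <- simulate_double_well(rspec, rz0, n_steps,
                                     substream_seed(seed, 2000 + j))
      unlist(lapply(seq_len(n_subjects), function(s) {
        idx <- pmin(nrow(rpaths), 1 + round(sched[[s]] / spec$dt))
        rpaths[idx, s]
      }))
    }, numeric(nrow(meta)))
    ref <- t(ref)
    rownames(ref) <- sprintf("reference_%02d", seq_len(n_reference_taxa))
    values <- rbind(values, ref)
  }
  meta <- with_seed(substream_seed(seed, "covariates"), {
    cbind(meta, draw_covariate_marginals(meta$subject_id))
  })
  meta <- validate_sample_metadata(meta)
  truth <- truth_table(list(taxon_spec(
    "bistable_1",
    if (spec$barrier_height > 0) "bimodal" else "symmetric",
    dw = spec)), seed)
  attr(truth, "spec") <- spec
  list(matrix = values, metadata = meta, truth = truth)
}

## Documented covariate marginals for synthetic metadata: age uniform on
## 18-77 years, BMI normal(26.7, 5.8) truncated at 15, balanced sex,
## region and extraction frequencies loosely matching a multi-country
## western cohort.  One value per subject, repeated across that subject's
## samples.
draw_covariate_marginals <- function(subject_id) {
  subjects <- unique(subject_id)
  ns <- length(subjects)
  age <- stats::runif(ns, 18, 77)
  bmi <- pmax(15, stats::rnorm(ns, 26.7, 5.8))
  sex <- sample(c("female", "male"), ns, replace = TRUE)
  region <- sample(c("Central Europe", "Nordic", "South Europe",
                     "UK/Ireland", "US", "Eastern Europe"),
                   ns, replace = TRUE,
                   prob = c(0.35, 0.2, 0.15, 0.15, 0.1, 0.05))
  extraction <- sample(c("mechanical", "enzymatic", "unknown"),
                       ns, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  i <- match(subject_id, subjects)
  data.frame(age = age[i], bmi = bmi[i], sex = sex[i],
             region = region[i], extraction = extraction[i],
             health = "none", stringsAsFactors = FALSE)
}

#' Attach planted logistic metadata effects to subject states
#'
#' Draws covariates from the documented marginals and regenerates each
#' subject's binary state from a planted logistic model
#' `P(high) = plogis(b0 + sum(beta * x))`.  The default age effect is an
#' odds multiplier of 1.026 per age decade for the high-abundance state.
#'
#' @param states Binary vector (0/1 or logical), one initial state per
#'   subject; its mean sets the model intercept so the regenerated state
#'   frequency matches.
#' @param effects Named log-odds per covariate unit; supported names:
#'   `age_decade`, `bmi`, `sex_male`.  Missing entries default to
#'   `c(age_decade = log(1.026), bmi = 0, sex_male = 0)`.
#' @param seed Integer seed.
#' @return List with `metadata` (one baseline row per subject), `states`
#'   (regenerated 0/1 vector) and `effects` (the full planted vector,
#'   including the intercept).
#' @export
attach_metadata_effects <- function(states, effects = NULL, seed = 1) {
  states <- as.integer(as.logical(states))
  if (anyNA(states)) stop("states must be binary")
  defaults <- c(age_decade = log(1.026), bmi = 0, sex_male = 0)
  effects <- effects %||% defaults
  if (any(!is.finite(effects))) stop("effects must be finite")
  bad <- setdiff(names(effects), names(defaults))
  if (length(bad)) stop("unsupported effect(s): ",
                        paste(bad, collapse = ", "))
  beta <- defaults
  beta[names(effects)] <- effects
  n <- length(states)
  with_seed(seed, {
    meta <- data.frame(
      sample_id = sprintf("S%04d_T1", seq_len(n)),
      subject_id = sprintf("S%04d", seq_len(n)),
      time_months = 0,
      stringsAsFactors = FALSE
    )
    meta <- cbind(meta, draw_covariate_marginals(meta$subject_id))
    ## intercept centers the linear predictor at the observed frequency
    eta0 <- stats::qlogis(pmin(pmax(mean(states), 0.02), 0.98))
    lin <- beta[["age_decade"]] * (meta$age - mean(meta$age)) / 10 +
      beta[["bmi"]] * (meta$bmi - mean(meta$bmi)) +
      beta[["sex_male"]] * (meta$sex == "male")
    new_states <- stats::rbinom(n, 1, stats::plogis(eta0 + lin))
    meta <- validate_sample_metadata(meta)
    list(metadata = meta, states = new_states,
         effects = c(intercept = eta0, beta))
  })
}
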