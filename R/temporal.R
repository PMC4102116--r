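## Temporal stability of alternative states: intermediate-range
## instability, Kaplan-Meier state survival, simulated-state nulls, and
## the bimodality-instability enrichment test.

#' Build per-subject follow-up series for one taxon
#'
#' @param m Abundance matrix.
#' @param metadata Aligned metadata with `subject_id` and `time_months`.
#' @param taxon Taxon name.
#' @return A `"subject_series"` data.frame with columns `subject_id`,
#'   `time_months`, `value`, ordered by subject and time; every subject's
#'   first visit is the month-0 baseline.
#' @export
subject_series <- function(m, metadata, taxon) {
  stopifnot(taxon %in% rownames(m))
  al <- align_samples(m, metadata)
  df <- data.frame(subject_id = al$metadata$subject_id,
                   time_months = al$metadata$time_months,
                   value = al$matrix[taxon, ],
                   stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$time_months), ]
  rownames(df) <- NULL
  dup <- tapply(df$time_months, df$subject_id,
                function(t) any(duplicated(t)))
  if (any(dup)) stop("duplicate time points within a subject")
  structure(df, class = c("subject_series", "data.frame"),
            taxon = taxon)
}

## consecutive within-subject pairs: value at t_i, value at t_{i+1},
## interval length
consecutive_pairs <- function(series) {
  sp <- split(series[, c("time_months", "value")], series$subject_id)
  pairs <- do.call(rbind, lapply(sp, function(d) {
    k <- nrow(d)
    if (k < 2) return(NULL)
    data.frame(from = d$value[-k], to = d$value[-1],
               interval = diff(d$time_months))
  }))
  rownames(pairs) <- NULL
  pairs
}

#' Intermediate-range stability statistic
#'
#' Tests whether abundances near the intermediate (50%) abundance
#' quantile are less stable than abundances near the states.  The
#' reference is the taxon's `reference_quantile` quantile across
#' baseline observations; for each pair of consecutive visits within a
#' subject the distance of the earlier observation from the reference is
#' correlated (Spearman) against the absolute shift to the next visit.
#' Negative correlations indicate an unstable intermediate region.  The
#' one-sided p-value (AS89-style null, alternative: rho < 0) is
#' returned.
#'
#' With `method = "baseline"` the pairs are (baseline, each later visit)
#' and the shift is the deviation from baseline; this variant matches
#' descriptions in terms of deviation from the baseline rather than
#' between consecutive visits.
#'
#' @param series A `"subject_series"` data.frame.
#' @param reference_quantile Quantile defining the intermediate range
#'   (default 0.5).
#' @param method `"consecutive"` (default) or `"baseline"`.
#' @return List with `rho`, `p`, `n_pairs`, `reference`.
#' @export
intermediate_stability <- function(series, reference_quantile = 0.5,
                                   method = c("consecutive",
                                              "baseline")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "subject_series"),
            reference_quantile > 0, reference_quantile < 1)
  baseline <- series$value[series$time_months == 0]
  reference <- stats::quantile(baseline, reference_quantile, names = FALSE)
  if (method == "consecutive") {
    pr <- consecutive_pairs(series)
  } else {
    sp <- split(series[, c("time_months", "value")], series$subject_id)
    pr <- do.call(rbind, lapply(sp, function(d) {
      if (nrow(d) < 2) return(NULL)
      data.frame(from = d$value[1], to = d$value[-1],
                 interval = d$time_months[-1] - d$time_months[1])
    }))
  }
  if (is.null(pr) || nrow(pr) < 10) {
    stop("need at least 10 consecutive visit pairs")
  }
  x <- abs(pr$from - reference)
  y <- abs(pr$to - pr$from)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in distances or shifts")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "less")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pr),
       reference = reference)
}

#' Follow-up interval confounding check
#'
#' Spearman correlation (two-sided) between the length of the interval
#' separating consecutive visits and the absolute observed shift.  A
#' correlation near zero indicates that differences in follow-up times do
#' not drive the observed fluctuations.
#'
#' @param series A `"subject_series"` data.frame.
#' @return List with `rho`, `p`, `n_pairs`.
#' @export
followup_confound_check <- function(series) {
  stopifnot(inherits(series, "subject_series"))
  pr <- consecutive_pairs(series)
  if (is.null(pr) || nrow(pr) < 10) {
    stop("need at least 10 consecutive visit pairs")
  }
  x <- pr$interval
  y <- abs(pr$to - pr$from)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in intervals or shifts")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided")
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pr))
}

#' Kaplan-Meier state survival
#'
#' Estimates the fraction of subjects remaining in their baseline state
#' as a function of time.  Each subject contributes one spell starting at
#' baseline; the event is the first visit at which the state differs from
#' the baseline state, with the event time placed at the midpoint of the
#' bracketing interval (configurable to the right endpoint).  Subjects
#' with no observed change are censored at their last visit.  The
#' product-limit estimate is evaluated at `horizon_months`.
#'
#' @param series A `"subject_series"` data.frame.
#' @param tipping_point State boundary used to binarize `value`.
#' @param horizon_months Evaluation horizon (default 3 months).
#' @param event_time `"midpoint"` (default) or `"right"`.
#' @return List with `survival` (S(horizon)), `fit` (the
#'   `survival::survfit` object), `n_events`, `n_subjects`.
#' @export
km_state_survival <- function(series, tipping_point, horizon_months = 3,
                              event_time = c("midpoint", "right")) {
  event_time <- match.arg(event_time)
  stopifnot(inherits(series, "subject_series"))
  st <- assign_states(series$value, tipping_point)$states
  sp <- split(data.frame(t = series$time_months, s = st),
              series$subject_id)
  spells <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) < 2) return(NULL)
    chg <- which(d$s[-1] != d$s[1])
    if (length(chg)) {
      j <- chg[1] + 1
      tt <- if (event_time == "midpoint") {
        (d$t[j - 1] + d$t[j]) / 2
      } else {
        d$t[j]
      }
      data.frame(time = tt, event = 1L)
    } else {
      data.frame(time = d$t[nrow(d)], event = 0L)
    }
  }))
  if (is.null(spells) || !nrow(spells)) {
    stop("no subjects with follow-up observations")
  }
  fit <- survival::survfit(
    survival::Surv(spells$time, spells$event) ~ 1
  )
  sm <- summary(fit, times = horizon_months, extend = TRUE)
  list(survival = sm$surv, fit = fit, n_events = sum(spells$event),
       n_subjects = nrow(spells))
}

#' Simulated-state null for state survival
#'
#' Calibrates the observed state stability of a bimodal taxon against
#' unimodal comparison taxa: each comparison taxon is given a
#' pseudo-tipping point at the same population quantile that the bimodal
#' taxon's tipping point occupies in the full cohort, states are
#' assigned, and the 3-month Kaplan-Meier state survival is computed.
#' The null percentile is the fraction of comparison taxa showing lower
#' survival (more state mixing) than the bimodal taxon.
#'
#' @param m Full-cohort abundance matrix (used for the quantile).
#' @param followup_m Follow-up abundance matrix (taxa x samples).
#' @param followup_meta Metadata for the follow-up samples.
#' @param taxon The bimodal taxon.
#' @param tipping_point Its estimated tipping point.
#' @param comparison_taxa Unimodal comparison taxa (>= 10).
#' @param horizon_months Survival horizon (default 3).
#' @return List with `percentile`, `taxon_survival`,
#'   `null_survival` (named vector over comparison taxa), `quantile`.
#' @export
simulated_state_null <- function(m, followup_m, followup_meta, taxon,
                                 tipping_point, comparison_taxa,
                                 horizon_months = 3) {
  stopifnot(taxon %in% rownames(m), length(comparison_taxa) >= 10,
            all(comparison_taxa %in% rownames(m)))
  q <- mean(m[taxon, ] <= tipping_point)
  if (q <= 0 || q >= 1) {
    stop("tipping point quantile must lie strictly inside (0, 1)")
  }
  ser <- subject_series(followup_m, followup_meta, taxon)
  s_obs <- km_state_survival(ser, tipping_point,
                             horizon_months = horizon_months)$survival
  null_surv <- vapply(comparison_taxa, function(tx) {
    pseudo_tip <- stats::quantile(m[tx, ], q, names = FALSE)
    ser_tx <- subject_series(followup_m, followup_meta, tx)
    km_state_survival(ser_tx, pseudo_tip,
                      horizon_months = horizon_months)$survival
  }, numeric(1))
  list(percentile = mean(null_surv < s_obs), taxon_survival = s_obs,
       null_survival = null_surv, quantile = q)
}

#' Enrichment of reduced intermediate stability among bimodal taxa
#'
#' Classifies prevalent taxa into a 2x2 table by (bimodality support >=
#' `support_threshold`) x (intermediate-stability rho < `rho_threshold`)
#' and computes the upper-tail hypergeometric probability of at least the
#' observed overlap.
#'
#' @param support Named numeric vector of bootstrap supports.
#' @param rho Named numeric vector of stability correlations (same taxa).
#' @param support_threshold Bimodality call threshold (default 0.9).
#' @param rho_threshold Instability threshold (default -0.3).
#' @return List with `p`, `overlap`, `n_bimodal`, `n_unstable`, `n`.
#' @export
bimodality_stability_enrichment <- function(support, rho,
                                            support_threshold = 0.9,
                                            rho_threshold = -0.3) {
  stopifnot(length(support) == length(rho))
  bimodal <- support >= support_threshold
  unstable <- rho < rho_threshold
  if (!any(bimodal) || all(bimodal) || !any(unstable) || all(unstable)) {
    stop("degenerate margins: both classifications need two levels")
  }
  n <- length(support)
  k <- sum(bimodal)
  mwhite <- sum(unstable)
  overlap <- sum(bimodal & unstable)
  p <- stats::phyper(overlap - 1, mwhite, n - mwhite, k,
                     lower.tail = FALSE)
  list(p = p, overlap = overlap, n_bimodal = k, n_unstable = mwhite,
       n = n)
}
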