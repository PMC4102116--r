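## Per-taxon bimodality assessment: abundance-type classification,
## bootstrap support for deviation from unimodality, tipping-point
## estimation, prediction-strength validation, and state assignment.

#' Bootstrap bimodality score
#'
#' Resamples the subjects with replacement `n_boot` times and runs the
#' full potential analysis on each replicate.  The support is the
#' fraction of replicates whose filtered potential landscape deviates
#' from unimodality (mode count >= 2); replicates with more than two
#' modes still count as deviation.  For each multimodal replicate the
#' location of the highest retained potential maximum between the two
#' deepest minima is recorded as that replicate's tipping point.
#'
#' @param values Numeric vector of log10 abundances (n >= 10).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the same seed gives identical results.
#' @param ... Passed to [potential_analysis()] (`bw_adjust`, `grid_size`,
#'   `potential_delta`, `min_density`, ...).
#' @return List of class `"bimodality_score"`: `support` (fraction in
#'   `[0, 1]`), `mode_counts` (integer vector per replicate),
#'   `tipping_points` (per multimodal replicate), `n_boot`, `n`.
#' @export
bootstrap_bimodality <- function(values, n_boot = 100, seed = 1, ...) {
  stopifnot(length(values) >= 10, n_boot >= 1)
  counts <- integer(n_boot)
  tips <- rep(NA_real_, n_boot)
  n_fail <- 0
  last_err <- NULL
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      vb <- sample(values, replace = TRUE)
      p <- tryCatch(potential_analysis(vb, ...), error = function(e) e)
      if (inherits(p, "error")) {
        n_fail <- n_fail + 1
        last_err <- p
        counts[b] <- NA_integer_
        next
      }
      counts[b] <- count_modes(p)
      if (counts[b] >= 2) tips[b] <- replicate_tipping(p)
    }
  })
  if (n_fail == n_boot) {
    stop("potential analysis failed in every bootstrap replicate: ",
         conditionMessage(last_err))
  }
  ok <- !is.na(counts)
  structure(
    list(support = mean(counts[ok] >= 2),
         mode_counts = counts,
         tipping_points = tips[!is.na(tips)],
         n_boot = n_boot, n = length(values), seed = seed),
    class = "bimodality_score"
  )
}

## Tipping location of one multimodal landscape: the highest retained
## maximum strictly between the two deepest (lowest-potential) minima.
replicate_tipping <- function(p) {
  mins <- p$minima[order(p$minima$potential), , drop = FALSE][1:2, ]
  lo <- min(mins$grid)
  hi <- max(mins$grid)
  barr <- p$maxima[p$maxima$grid > lo & p$maxima$grid < hi, ,
                   drop = FALSE]
  if (!nrow(barr)) return(NA_real_)
  barr$grid[which.max(barr$potential)]
}

#' @export
print.bimodality_score <- function(x, ...) {
  cat(sprintf("Bootstrap bimodality: support %.2f (%d replicates, n = %d)\n",
              x$support, x$n_boot, x$n))
  if (length(x$tipping_points)) {
    cat(sprintf("  mean tipping point %.3f over %d multimodal replicates\n",
                mean(x$tipping_points), length(x$tipping_points)))
  }
  invisible(x)
}

#' Estimate the tipping point of a bimodal taxon
#'
#' The tipping point is the abundance value maximizing the potential
#' between the two stable states.  For robustness it is averaged over the
#' multimodal bootstrap replicates of [bootstrap_bimodality()].
#'
#' @inheritParams bootstrap_bimodality
#' @return Tipping point in log10 abundance units.
#' @export
estimate_tipping_point <- function(values, n_boot = 100, seed = 1, ...) {
  bs <- bootstrap_bimodality(values, n_boot = n_boot, seed = seed, ...)
  if (!length(bs$tipping_points)) {
    stop("no bootstrap replicate was multimodal; ",
         "state assignment is not advised for this taxon")
  }
  mean(bs$tipping_points)
}

#' Classify the abundance type of a taxon
#'
#' A taxon is `rare` unless its log10 signal exceeds `prevalence_signal`
#' (default 3.0) in more than `prevalence_fraction` (default 20%) of the
#' subjects.  Prevalent taxa are `bimodal` when the bootstrap bimodality
#' support reaches `support_threshold` (default 0.9); the remaining
#' prevalent taxa are `symmetric`, `left_skewed` or `right_skewed` by
#' sample skewness against `+/- skew_threshold` (default 0.5).
#'
#' @param values Numeric vector of log10 abundances (n >= 10).
#' @param prevalence_signal,prevalence_fraction Prevalence rule
#'   thresholds.
#' @param skew_threshold Absolute skewness bound for the symmetric class.
#' @param support_threshold Bootstrap support needed for the bimodal call.
#' @param n_boot,seed Passed to [bootstrap_bimodality()].
#' @param ... Passed on to [potential_analysis()].
#' @return Character scalar type, with attributes `support` (bootstrap
#'   support; NA for rare taxa) and `skewness`.
#' @export
classify_abundance_type <- function(values, prevalence_signal = 3.0,
                                    prevalence_fraction = 0.20,
                                    skew_threshold = 0.5,
                                    support_threshold = 0.9,
                                    n_boot = 100, seed = 1, ...) {
  stopifnot(length(values) >= 10)
  g1 <- e1071::skewness(values)
  if (mean(values > prevalence_signal) <= prevalence_fraction) {
    return(structure("rare", support = NA_real_, skewness = g1))
  }
  bs <- bootstrap_bimodality(values, n_boot = n_boot, seed = seed, ...)
  type <-
    if (bs$support >= support_threshold) "bimodal"
    else if (g1 < -skew_threshold) "left_skewed"
    else if (g1 > skew_threshold) "right_skewed"
    else "symmetric"
  structure(type, support = bs$support, skewness = g1)
}

#' Prediction strength of a k-group split
#'
#' Cluster-validation index of Tibshirani & Walther: the data are split
#' into random halves `n_splits` times; both halves are clustered by
#' partitioning around medoids (PAM, Euclidean distance) and each test
#' point is classified to its nearest training medoid.  For each test
#' cluster the fraction of within-cluster pairs co-assigned by the
#' training classifier is computed; the index for one split is the
#' minimum over test clusters, and the PSI is the mean over splits.
#' `PSI(1) = 1` by convention.  Values above 0.9 are conventionally
#' strong evidence for the candidate cluster number, above 0.8 moderate.
#'
#' @param values Numeric vector (n >= 20).
#' @param n_splits Number of random half-splits (default 20).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return PSI value in `[0, 1]`.
#' @export
prediction_strength <- function(values, n_splits = 20, k = 2, seed = 1) {
  stopifnot(length(values) >= 20, n_splits >= 1, k >= 1)
  if (k == 1) return(1)
  if (length(unique(values)) < k) {
    stop("k exceeds the number of distinct values")
  }
  n <- length(values)
  with_seed(seed, {
    ps <- vapply(seq_len(n_splits), function(s) {
      repeat {
        train_idx <- sample(n, floor(n / 2))
        train <- values[train_idx]
        test <- values[-train_idx]
        if (length(unique(train)) >= k && length(unique(test)) >= k) break
      }
      train_med <- pam_medoids_1d(train, k)
      test_cl <- cluster::pam(test, k, cluster.only = TRUE)
      ## classify test points to the nearest training medoid
      assign_tr <- apply(abs(outer(test, train_med, "-")), 1, which.min)
      min(vapply(seq_len(k), function(j) {
        in_j <- which(test_cl == j)
        nj <- length(in_j)
        if (nj < 2) return(1)
        co <- outer(assign_tr[in_j], assign_tr[in_j], "==")
        (sum(co) - nj) / (nj * (nj - 1))
      }, numeric(1)))
    }, numeric(1))
    mean(ps)
  })
}

## PAM medoids of a 1-D sample; medoid ties broken towards lower values
## (cluster::pam is deterministic; sorting the input fixes the tie order).
pam_medoids_1d <- function(x, k) {
  xs <- sort(x)
  fit <- cluster::pam(xs, k)
  sort(fit$medoids[, 1])
}

#' Assign low/high states against a tipping point
#'
#' A sample is in the `high` state iff its value strictly exceeds the
#' tipping point; values equal to the tipping point are assigned `low`.
#'
#' @param values Named (or unnamed) numeric vector.
#' @param tipping_point Finite numeric scalar.
#' @param taxon Optional taxon name carried in the result.
#' @return Object of class `"state_assignment"`: list with `states`
#'   (factor `low`/`high`, named as `values`), `tipping_point`, `taxon`.
#' @export
assign_states <- function(values, tipping_point, taxon = NULL) {
  stopifnot(is.numeric(values), length(tipping_point) == 1,
            is.finite(tipping_point))
  st <- factor(ifelse(values > tipping_point, "high", "low"),
               levels = c("low", "high"))
  names(st) <- names(values)
  structure(list(states = st, tipping_point = tipping_point,
                 taxon = taxon),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  tab <- table(x$states)
  cat(sprintf("State assignment%s: tipping point %.3f; low %d, high %d\n",
              if (!is.null(x$taxon)) paste0(" (", x$taxon, ")") else "",
              x$tipping_point, tab[["low"]], tab[["high"]]))
  invisible(x)
}

#' Cross-subset consistency of a bimodality call
#'
#' Re-scores bimodality within each DNA-extraction subset to exclude
#' sample-processing artefacts: the verdict is "confirmed" iff the
#' full-cohort support reaches `support_threshold` and at least one
#' extraction subset exceeds 0.90 bootstrap support.  Subsets smaller
#' than `min_subset` subjects are skipped with a warning.
#'
#' @param m Abundance matrix.
#' @param metadata Aligned metadata (see [align_samples()]).
#' @param taxon Taxon name (row of `m`).
#' @param support_threshold Full-cohort support threshold (default 0.9).
#' @param subset_support Subset support threshold (default 0.9, strict
#'   inequality).
#' @param min_subset Minimum subset size (default 30 subjects).
#' @param n_boot,seed,... Passed to [bootstrap_bimodality()].
#' @return List with `full_support`, `subset_supports` (named by
#'   extraction method), `confirmed`.
#' @export
subset_consistency <- function(m, metadata, taxon,
                               support_threshold = 0.9,
                               subset_support = 0.9,
                               min_subset = 30,
                               n_boot = 100, seed = 1, ...) {
  stopifnot(taxon %in% rownames(m))
  al <- align_samples(m, metadata)
  values <- al$matrix[taxon, ]
  full <- bootstrap_bimodality(values, n_boot = n_boot, seed = seed,
                               ...)$support
  subsets <- setdiff(EXTRACTION_LEVELS, "unknown")
  sub_support <- vapply(subsets, function(lev) {
    idx <- al$metadata$extraction == lev
    if (sum(idx) < min_subset) {
      warning(sprintf("extraction subset '%s' has %d < %d samples; skipped",
                      lev, sum(idx), min_subset))
      return(NA_real_)
    }
    bootstrap_bimodality(values[idx], n_boot = n_boot,
                         seed = substream_seed(seed, lev), ...)$support
  }, numeric(1))
  confirmed <- full >= support_threshold &&
    any(sub_support > subset_support, na.rm = TRUE)
  list(full_support = full, subset_supports = sub_support,
       confirmed = confirmed)
}
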