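## Host-factor and health-status association models: multiple logistic
## regression with likelihood-ratio tests, Benjamini-Hochberg FDR, and
## cross-validated ROC AUC.

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j>=i} m p_(j) / j` clipped at 1
#' and mapped back to the input order.  Input values must lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

## reporting sugar: FDR < 5% significant, < 20% trend
fdr_label <- function(q) {
  ifelse(q < 0.05, "significant", ifelse(q < 0.20, "trend", ""))
}

#' Logistic model of a taxon's state against host factors
#'
#' Fits `state ~ predictors` by binomial GLM (iteratively reweighted
#' least squares) on complete cases and evaluates each predictor by the
#' log-ratio chi-squared test between the full model and the model
#' without that predictor.  Constant predictors are dropped with a
#' warning; perfect separation is detected and reported.  Reference
#' levels of categorical predictors are their most frequent level.
#'
#' @param states A `"state_assignment"` (or 0/1 vector) over the samples.
#' @param metadata Metadata data.frame (rows matched to the samples by
#'   `sample_id` when `states` is named).
#' @param predictors Character vector of metadata columns (default age,
#'   bmi, sex, region, extraction).
#' @return Object of class `"association_result"`: data.frame `table`
#'   with per-predictor estimate (log-odds per unit for numeric
#'   predictors), Wald 95% CI, LRT chi-squared, df, p, BH q and FDR
#'   label; plus `model`, `n`, `separation`.
#' @export
state_host_model <- function(states, metadata,
                             predictors = c("age", "bmi", "sex",
                                            "region", "extraction")) {
  y <- if (inherits(states, "state_assignment")) {
    stats::setNames(as.integer(states$states == "high"),
                    names(states$states))
  } else {
    states
  }
  if (!is.null(names(y))) {
    idx <- match(names(y), metadata$sample_id)
    if (anyNA(idx)) stop("states contain samples missing from metadata")
    metadata <- metadata[idx, , drop = FALSE]
  } else if (length(y) != nrow(metadata)) {
    stop("unnamed states must match metadata rows")
  }
  missing_pred <- setdiff(predictors, names(metadata))
  if (length(missing_pred)) {
    stop("predictor(s) not in metadata: ",
         paste(missing_pred, collapse = ", "))
  }
  df <- data.frame(.state = as.integer(y), metadata[predictors],
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  keep <- predictors[vapply(predictors, function(p) {
    length(unique(df[[p]])) > 1
  }, logical(1))]
  dropped <- setdiff(predictors, keep)
  if (length(dropped)) {
    warning("dropping constant predictor(s): ",
            paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no usable predictors")
  if (length(unique(df$.state)) < 2) {
    stop("response has a single state; model not identifiable")
  }
  n_par <- 1 + sum(vapply(keep, function(p) {
    if (is.numeric(df[[p]])) 1L else length(unique(df[[p]])) - 1L
  }, integer(1)))
  if (nrow(df) < 10 * n_par) {
    stop("need at least 10 complete cases per model parameter (",
         nrow(df), " < ", 10 * n_par, ")")
  }
  for (p in keep) {
    if (!is.numeric(df[[p]])) {
      lev <- names(sort(table(df[[p]]), decreasing = TRUE))
      df[[p]] <- factor(df[[p]], levels = lev)
    }
  }
  full_formula <- stats::reformulate(keep, response = ".state")
  fit <- stats::glm(full_formula, family = stats::binomial(), data = df)
  separation <- any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8)
  if (separation) {
    warning("possible perfect separation detected; ",
            "coefficients may be unstable")
  }
  lrt <- lapply(keep, function(p) {
    reduced <- stats::glm(
      stats::reformulate(setdiff(keep, p) %0% "1", response = ".state"),
      family = stats::binomial(), data = df)
    dev <- reduced$deviance - fit$deviance
    dfree <- reduced$df.residual - fit$df.residual
    c(chisq = dev, df = dfree,
      p = stats::pchisq(dev, dfree, lower.tail = FALSE))
  })
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ## first coefficient term per predictor for the summary table
  term_of <- vapply(keep, function(p) {
    grep(paste0("^", p), names(est), value = TRUE)[1]
  }, character(1))
  tab <- data.frame(
    predictor = keep,
    estimate = est[term_of],
    ci_lo = est[term_of] - 1.96 * se[term_of],
    ci_hi = est[term_of] + 1.96 * se[term_of],
    chisq = vapply(lrt, `[[`, numeric(1), "chisq"),
    df = vapply(lrt, `[[`, numeric(1), "df"),
    p = vapply(lrt, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  tab$q <- bh_adjust(tab$p)
  tab$fdr_label <- fdr_label(tab$q)
  rownames(tab) <- NULL
  structure(list(table = tab, model = fit, n = nrow(df),
                 separation = separation),
            class = "association_result")
}

`%0%` <- function(x, y) if (length(x)) x else y

#' @export
print.association_result <- function(x, ...) {
  cat("Logistic association model (n =", x$n, ")\n")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 3)
  tab$p <- signif(tab$p, 3)
  tab$q <- signif(tab$q, 3)
  print(tab[, c("predictor", "estimate", "chisq", "df", "p", "q",
                "fdr_label")], row.names = FALSE)
  if (!is.null(x$auc_with)) {
    cat(sprintf("CV AUC: %.3f with abundance, %.3f without\n",
                x$auc_with, x$auc_without))
  }
  invisible(x)
}

#' Disease model from bacterial abundance
#'
#' Logistic regression predicting disease occurrence from the log10
#' abundance of a bacterial group, adjusting for potentially confounding
#' covariates.  Reports the log-ratio test for the abundance term and
#' the average ROC AUC from stratified 5-fold cross-validation of the
#' model with and without the abundance term.
#'
#' @param disease Binary vector (0/1 or logical), one per subject.
#' @param abundance Log10 abundance vector.
#' @param covariates Data frame of confounders (e.g. age, bmi, sex,
#'   extraction); may be NULL.
#' @param n_folds Cross-validation folds (default 5, stratified by
#'   outcome).
#' @param seed Integer seed for the fold split.
#' @param max_refolds Bounded retries if a fold ends up single-class.
#' @return `"association_result"` with the abundance-term table plus
#'   `auc_with` / `auc_without`.
#' @export
disease_model <- function(disease, abundance, covariates = NULL,
                          n_folds = 5, seed = 1, max_refolds = 10) {
  y <- as.integer(as.logical(disease))
  stopifnot(length(y) == length(abundance))
  df <- data.frame(.disease = y, .abundance = abundance)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.disease)) < 2) {
    stop("disease labels are all one class")
  }
  covs <- setdiff(names(df), c(".disease", ".abundance"))
  covs <- covs[vapply(covs, function(p) length(unique(df[[p]])) > 1,
                      logical(1))]
  f_with <- stats::reformulate(c(".abundance", covs),
                               response = ".disease")
  f_without <- stats::reformulate(covs %0% "1", response = ".disease")
  fit_with <- stats::glm(f_with, family = stats::binomial(), data = df)
  fit_without <- stats::glm(f_without, family = stats::binomial(),
                            data = df)
  dev <- fit_without$deviance - fit_with$deviance
  dfree <- fit_without$df.residual - fit_with$df.residual
  p <- stats::pchisq(dev, dfree, lower.tail = FALSE)
  est <- stats::coef(fit_with)[".abundance"]
  se <- sqrt(diag(stats::vcov(fit_with))[".abundance"])
  aucs <- cv_auc(df, f_with, f_without, n_folds, seed, max_refolds)
  tab <- data.frame(predictor = "abundance", estimate = unname(est),
                    ci_lo = unname(est - 1.96 * se),
                    ci_hi = unname(est + 1.96 * se),
                    chisq = dev, df = dfree, p = p, q = p,
                    fdr_label = fdr_label(p),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, model = fit_with, n = nrow(df),
                 separation = FALSE,
                 auc_with = aucs[["with"]],
                 auc_without = aucs[["without"]]),
            class = "association_result")
}

## Stratified k-fold CV AUC for two nested formulas; refolds with a new
## sub-seed (bounded) if a training fold is single-class.
cv_auc <- function(df, f_with, f_without, n_folds, seed, max_refolds) {
  for (attempt in seq_len(max_refolds)) {
    folds <- with_seed(substream_seed(seed, attempt), {
      fold <- integer(nrow(df))
      for (cls in unique(df$.disease)) {
        idx <- which(df$.disease == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      fold
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(df$.disease[folds != k])) == 2 &&
        length(unique(df$.disease[folds == k])) == 2
    }, logical(1)))
    if (ok) break
    if (attempt == max_refolds) {
      stop("could not build class-balanced folds after ",
           max_refolds, " attempts")
    }
  }
  auc_one <- function(formula) {
    mean(vapply(seq_len(n_folds), function(k) {
      fit <- stats::glm(formula, family = stats::binomial(),
                        data = df[folds != k, , drop = FALSE])
      pr <- stats::predict(fit, newdata = df[folds == k, , drop = FALSE],
                           type = "response")
      as.numeric(pROC::auc(df$.disease[folds == k], pr,
                           levels = c(0, 1), direction = "<",
                           quiet = TRUE))
    }, numeric(1)))
  }
  c(with = auc_one(f_with), without = auc_one(f_without))
}

#' Paired baseline/follow-up change tests
#'
#' Population-level change between paired baseline and follow-up log10
#' abundances: the log10 fold change is `mean(followup) -
#' mean(baseline)`, tested by a paired t-test or paired Wilcoxon
#' signed-rank test.  If all paired differences are zero the signed-rank
#' statistic is undefined and `p = 1` is returned by convention.
#'
#' @param baseline,followup Equal-length paired vectors (n >= 5).
#' @param mode `"t"` or `"wilcoxon_paired"`.
#' @return List with `statistic`, `p`, `log10_fc`, `n`.
#' @export
paired_change_tests <- function(baseline, followup,
                                mode = c("t", "wilcoxon_paired")) {
  mode <- match.arg(mode)
  stopifnot(length(baseline) == length(followup))
  if (length(baseline) < 5) stop("need at least 5 pairs")
  d <- followup - baseline
  fc <- mean(followup) - mean(baseline)
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = 1, log10_fc = fc,
                n = length(d)))
  }
  ht <- if (mode == "t") {
    stats::t.test(followup, baseline, paired = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(followup, baseline,
                                        paired = TRUE))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, log10_fc = fc,
       n = length(d))
}
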