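## The central fitting interface: tipping_analysis() scans every taxon of
## an abundance matrix for alternative stable states and returns a
## classed object with the usual modelling methods.

#' Detect tipping elements across an abundance matrix
#'
#' For every taxon: classifies the abundance type (rare / symmetric /
#' skewed / bimodal) using the prevalence rule, bootstrap potential
#' analysis and sample skewness; for taxa with bimodal support at or
#' above the call threshold, estimates the tipping point (bootstrap
#' average of the potential maximum between the two deepest minima),
#' computes the prediction strength index for two clusters, and assigns
#' each sample to the low or high state.
#'
#' @param x Abundance matrix (taxa x samples, log10 signals) passing
#'   [validate_abundance_matrix()].
#' @param metadata Optional metadata (checked for alignment when given).
#' @param n_boot Bootstrap replicates per taxon (default 100).
#' @param support_threshold Bootstrap support for a bimodal call
#'   (default 0.9).
#' @param psi_splits Random splits for the prediction strength index
#'   (default 20).
#' @param seed Integer seed; per-taxon substreams derive from it.
#' @param ... Passed to [potential_analysis()].
#' @return Object of class `"tipping_analysis"`: list with `results`
#'   (per-taxon data.frame: type, support, skewness, tipping point,
#'   prediction strength), `states` (state factor matrix for the bimodal
#'   taxa), `landscapes` (full-sample potential landscapes of bimodal
#'   taxa), the inputs and control settings.
#' @seealso [print.tipping_analysis()], [summary.tipping_analysis()],
#'   [coef.tipping_analysis()], [predict.tipping_analysis()],
#'   [plot.tipping_analysis()], [simulate.tipping_analysis()]
#' @examples
#' sim <- generate_cross_section(200, list(
#'   taxon_spec("b1", "bimodal"),
#'   taxon_spec("s1", "symmetric")), seed = 7)
#' fit <- tipping_analysis(sim$matrix, n_boot = 25, seed = 7)
#' coef(fit)
#' @export
tipping_analysis <- function(x, metadata = NULL, n_boot = 100,
                             support_threshold = 0.9, psi_splits = 20,
                             seed = 1, ...) {
  validate_abundance_matrix(x)
  if (!is.null(metadata)) {
    al <- align_samples(x, metadata)
    x <- al$matrix
    metadata <- al$metadata
  }
  taxa <- rownames(x)
  res <- vector("list", length(taxa))
  states <- list()
  landscapes <- list()
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    values <- x[tx, ]
    tseed <- substream_seed(seed, i)
    type <- classify_abundance_type(values,
                                    support_threshold = support_threshold,
                                    n_boot = n_boot, seed = tseed, ...)
    tip <- NA_real_
    psi <- NA_real_
    if (type == "bimodal") {
      tip <- estimate_tipping_point(values, n_boot = n_boot,
                                    seed = tseed, ...)
      psi <- prediction_strength(values, n_splits = psi_splits, k = 2,
                                 seed = substream_seed(seed, -i))
      states[[tx]] <- assign_states(values, tip, taxon = tx)
      landscapes[[tx]] <- potential_analysis(values, ...)
    }
    res[[i]] <- data.frame(
      taxon = tx, type = as.character(type),
      support = attr(type, "support") %||% NA_real_,
      skewness = attr(type, "skewness"),
      tipping_point = tip, psi = psi,
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  structure(
    list(results = results, states = states, landscapes = landscapes,
         matrix = x, metadata = metadata,
         control = list(n_boot = n_boot,
                        support_threshold = support_threshold,
                        psi_splits = psi_splits, seed = seed,
                        dots = list(...)),
         call = match.call()),
    class = "tipping_analysis"
  )
}

bimodal_taxa <- function(object) {
  object$results$taxon[object$results$type == "bimodal"]
}

#' @export
print.tipping_analysis <- function(x, ...) {
  cat("Tipping-element analysis:", nrow(x$results), "taxa,",
      ncol(x$matrix), "samples\n")
  tab <- table(factor(x$results$type,
                      levels = c("bimodal", "symmetric", "left_skewed",
                                 "right_skewed", "rare")))
  cat("  abundance types:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  bt <- bimodal_taxa(x)
  if (length(bt)) {
    cat("  bimodal taxa (support >= ",
        x$control$support_threshold, "):\n", sep = "")
    sub <- x$results[x$results$type == "bimodal", ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-20s support %.2f  tipping %.3f  PSI %.2f\n",
                  sub$taxon[i], sub$support[i], sub$tipping_point[i],
                  sub$psi[i]))
    }
  } else {
    cat("  no bimodal taxa detected\n")
  }
  invisible(x)
}

#' Summarize a tipping-element analysis
#' @param object A `"tipping_analysis"` object.
#' @param ... Unused.
#' @return The per-taxon results data.frame, with per-state sample
#'   counts appended for bimodal taxa.
#' @export
summary.tipping_analysis <- function(object, ...) {
  res <- object$results
  res$n_low <- NA_integer_
  res$n_high <- NA_integer_
  for (tx in names(object$states)) {
    tab <- table(object$states[[tx]]$states)
    res$n_low[res$taxon == tx] <- tab[["low"]]
    res$n_high[res$taxon == tx] <- tab[["high"]]
  }
  res
}

#' Tipping points of the detected bimodal taxa
#' @param object A `"tipping_analysis"` object.
#' @param ... Unused.
#' @return Named numeric vector of tipping points (log10 units).
#' @export
coef.tipping_analysis <- function(object, ...) {
  sub <- object$results[object$results$type == "bimodal", ]
  stats::setNames(sub$tipping_point, sub$taxon)
}

#' Assign states for new samples
#'
#' Applies the fitted tipping points to a new abundance matrix (which
#' must contain the fitted bimodal taxa as rows).
#'
#' @param object A `"tipping_analysis"` object.
#' @param newdata Abundance matrix; defaults to the training matrix.
#' @param ... Unused.
#' @return Named list of `"state_assignment"` objects, one per bimodal
#'   taxon.
#' @export
predict.tipping_analysis <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$states)
  validate_abundance_matrix(newdata)
  tips <- coef(object)
  missing_tx <- setdiff(names(tips), rownames(newdata))
  if (length(missing_tx)) {
    stop("newdata lacks fitted bimodal taxa: ",
         paste(missing_tx, collapse = ", "))
  }
  out <- lapply(names(tips), function(tx) {
    assign_states(newdata[tx, ], tips[[tx]], taxon = tx)
  })
  stats::setNames(out, names(tips))
}

#' Plot the potential landscape of a fitted taxon
#' @param x A `"tipping_analysis"` object.
#' @param taxon Taxon to plot (default: first bimodal taxon).
#' @param ... Passed to [plot.potential_landscape()].
#' @export
plot.tipping_analysis <- function(x, taxon = NULL, ...) {
  taxon <- taxon %||% bimodal_taxa(x)[1]
  if (is.na(taxon)) stop("no bimodal taxon to plot; give `taxon`")
  p <- x$landscapes[[taxon]] %||% potential_analysis(x$matrix[taxon, ])
  plot(p, ...)
  invisible(x)
}

#' Simulate new cohorts from a fitted analysis
#'
#' Draws new samples per taxon by the smoothed bootstrap: resampling the
#' observed values and adding Gaussian kernel noise at the fitted
#' bandwidth, i.e. sampling from each taxon's kernel density estimate.
#'
#' @param object A `"tipping_analysis"` object.
#' @param nsim Number of simulated cohorts (default 1).
#' @param seed Integer seed.
#' @param n_samples Samples per cohort (default: as fitted).
#' @param ... Unused.
#' @return A list of `nsim` abundance matrices.
#' @export
simulate.tipping_analysis <- function(object, nsim = 1, seed = 1,
                                      n_samples = NULL, ...) {
  n_samples <- n_samples %||% ncol(object$matrix)
  m <- object$matrix
  lapply(seq_len(nsim), function(s) {
    vals <- vapply(seq_len(nrow(m)), function(i) {
      with_seed(substream_seed(seed, s * 10000 + i), {
        v <- m[i, ]
        h <- 0.8 * 1.06 * stats::sd(v) / length(v)^(1 / 5)
        sample(v, n_samples, replace = TRUE) +
          stats::rnorm(n_samples, 0, h)
      })
    }, numeric(n_samples))
    out <- t(vals)
    dimnames(out) <- list(rownames(m), sprintf("sim%d_%04d", s,
                                               seq_len(n_samples)))
    out
  })
}
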