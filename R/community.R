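## Ecosystem-level context: state-combination census, covariation
## screening, ordination, community clustering with Jensen-Shannon
## dissimilarity, and diversity-state association.

#' Census of co-occurring state combinations
#'
#' With G bimodal groups each sample occupies one of 2^G low/high state
#' combinations.  The census counts each observed combination across the
#' common samples.
#'
#' @param assignments Named list of `"state_assignment"` objects (one per
#'   bimodal group) over the identical sample set.
#' @return Data frame (class `"state_census"`) with one row per observed
#'   combination: the per-group states, `count` and `frequency`, ordered
#'   by decreasing frequency.  Frequencies sum to 1.
#' @export
state_combination_census <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 1)
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    stop("assignments must be a named list (one name per bimodal group)")
  }
  states <- lapply(assignments, function(a) {
    stopifnot(inherits(a, "state_assignment"))
    a$states
  })
  ns <- lengths(states)
  if (length(unique(ns)) != 1) {
    stop("state assignments cover different sample sets")
  }
  nm <- lapply(states, names)
  if (!is.null(nm[[1]])) {
    same <- vapply(nm, function(x) identical(sort(x), sort(nm[[1]])),
                   logical(1))
    if (!all(same)) stop("state assignments cover different sample sets")
    states <- lapply(states, function(s) s[sort(names(s))])
  }
  df <- as.data.frame(lapply(states, as.character),
                      stringsAsFactors = FALSE)
  combo <- apply(df, 1, paste, collapse = "/")
  tab <- sort(table(combo), decreasing = TRUE)
  out <- do.call(rbind, strsplit(names(tab), "/", fixed = TRUE))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- names(assignments)
  out$count <- as.integer(tab)
  out$frequency <- out$count / sum(out$count)
  structure(out, class = c("state_census", "data.frame"),
            n_samples = ns[[1]])
}

#' Screen for consistent covariation with the bimodal groups
#'
#' For each (focal bimodal group, other taxon) pair the Pearson
#' correlation is evaluated in each DNA-extraction subset and in
#' bootstrap resamples of the full cohort.  A pair is flagged consistent
#' iff `|r| > r_threshold` with two-sided `p < alpha` in every extraction
#' subset and in at least `consistency` of the bootstrap resamples (both
#' inequalities strict).
#'
#' @param m Abundance matrix.
#' @param metadata Aligned metadata (extraction labels used for subsets).
#' @param focal Character vector of bimodal group names.
#' @param r_threshold Correlation magnitude threshold (default 0.25).
#' @param alpha Significance threshold (default 0.05).
#' @param n_boot Bootstrap resamples of the full cohort (default 100).
#' @param consistency Required fraction of passing resamples
#'   (default 0.95).
#' @param min_subset Minimum subset size (default 30).
#' @param seed Integer seed.
#' @return Data frame with one row per pair: `focal`, `taxon`, `r_full`,
#'   per-subset correlations and p-values, `boot_fraction`, `consistent`.
#' @export
covariation_screen <- function(m, metadata, focal, r_threshold = 0.25,
                               alpha = 0.05, n_boot = 100,
                               consistency = 0.95, min_subset = 30,
                               seed = 1) {
  al <- align_samples(m, metadata)
  m <- al$matrix
  metadata <- al$metadata
  stopifnot(all(focal %in% rownames(m)))
  others <- setdiff(rownames(m), focal)
  subsets <- setdiff(EXTRACTION_LEVELS, "unknown")
  subset_idx <- lapply(subsets, function(lev) {
    which(metadata$extraction == lev)
  })
  names(subset_idx) <- subsets
  usable <- vapply(subset_idx, length, integer(1)) >= min_subset
  if (sum(usable) < 2) {
    warning("fewer than two usable extraction subsets; ",
            "falling back to bootstrap-only consistency")
  }
  subset_idx <- subset_idx[usable]
  pass_rule <- function(x, y) {
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  n <- ncol(m)
  boot_idx <- with_seed(substream_seed(seed, "boot"), {
    lapply(seq_len(n_boot), function(b) sample(n, replace = TRUE))
  })
  rows <- list()
  for (f in focal) {
    xf <- m[f, ]
    for (tx in others) {
      yt <- m[tx, ]
      full <- pass_rule(xf, yt)
      sub <- lapply(subset_idx, function(idx) {
        pass_rule(xf[idx], yt[idx])
      })
      sub_pass <- vapply(sub, function(s) {
        abs(s[["r"]]) > r_threshold && s[["p"]] < alpha
      }, logical(1))
      bf <- mean(vapply(boot_idx, function(idx) {
        s <- pass_rule(xf[idx], yt[idx])
        abs(s[["r"]]) > r_threshold && s[["p"]] < alpha
      }, logical(1)))
      consistent <- (if (length(sub)) all(sub_pass) else TRUE) &&
        bf >= consistency
      row <- data.frame(focal = f, taxon = tx, r_full = full[["r"]],
                        p_full = full[["p"]], boot_fraction = bf,
                        consistent = consistent,
                        stringsAsFactors = FALSE)
      for (lev in names(sub)) {
        row[[paste0("r_", lev)]] <- sub[[lev]][["r"]]
        row[[paste0("p_", lev)]] <- sub[[lev]][["p"]]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal component overview with per-component bimodality
#'
#' PCA of the taxa-centered log10 matrix with samples as observations.
#' Reports the variance-explained fractions and, for each of the leading
#' components, the bootstrap bimodality of the sample scores: a bimodal
#' score distribution on a major axis indicates an ecosystem-level split.
#'
#' @param m Abundance matrix (>= 3 taxa, >= 10 samples).
#' @param n_components Number of leading components to scan (default 5).
#' @param n_boot Bootstrap replicates for score bimodality (default 100).
#' @param seed Integer seed.
#' @return List with `variance_fraction` (all components),
#'   `score_support` (bootstrap bimodality support of the leading
#'   scores), `scores` (sample scores of the leading components), `fit`.
#' @export
pca_overview <- function(m, n_components = 5, n_boot = 100, seed = 1) {
  validate_abundance_matrix(m)
  if (nrow(m) < 3 || ncol(m) < 10) {
    stop("pca_overview needs at least 3 taxa and 10 samples")
  }
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  supp <- vapply(seq_len(k), function(j) {
    bootstrap_bimodality(fit$x[, j], n_boot = n_boot,
                         seed = substream_seed(seed, j))$support
  }, numeric(1))
  names(supp) <- colnames(fit$x)[seq_len(k)]
  list(variance_fraction = vf, score_support = supp,
       scores = fit$x[, seq_len(k), drop = FALSE], fit = fit)
}

#' Jensen-Shannon dissimilarity between composition profiles
#'
#' `JSD(x, y) = sqrt(JS divergence)` with natural logarithm and the
#' `0 * log 0 = 0` convention; a metric on the probability simplex.
#'
#' @param r Relative abundance matrix (taxa x samples).
#' @return A `dist` object over samples.
#' @export
jsd_dist <- function(r) {
  if (any(r < 0)) stop("relative abundances must be nonnegative")
  n <- ncol(r)
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  hs <- colSums(xlx(r))  # negative entropy per sample
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    pi <- r[, i]
    for (j in (i + 1):n) {
      mm <- (pi + r[, j]) / 2
      js <- (hs[i] + hs[j]) / 2 - sum(xlx(mm))
      d[j, i] <- d[i, j] <- sqrt(max(js, 0))
    }
  }
  dimnames(d) <- list(colnames(r), colnames(r))
  stats::as.dist(d)
}

#' Community clustering with prediction strength
#'
#' Partitioning around medoids over the Jensen-Shannon dissimilarity of
#' relative abundance profiles, with the prediction strength index per
#' candidate cluster number: the sample set is split into random halves,
#' both halves are clustered, test samples are classified to the nearest
#' training medoid under JSD, and the per-split index is the minimum
#' over test clusters of the fraction of co-assigned within-cluster
#' pairs.  Medoid ties are broken by `cluster::pam`'s deterministic
#' build/swap order on the sample ordering of the input.
#'
#' @param r Relative abundance matrix.
#' @param k_max Largest cluster number to evaluate (>= 2).
#' @param n_splits Random half-splits per k (default 20).
#' @param seed Integer seed.
#' @return List with `psi` (named vector over k = 1..k_max, PSI(1) = 1),
#'   `best_k` (largest k with PSI > 0.9, else 1), `clustering` (PAM
#'   assignment at `best_k`, NULL for k = 1).
#' @export
community_clusters <- function(r, k_max = 4, n_splits = 20, seed = 1) {
  stopifnot(k_max >= 2)
  if (any(abs(colSums(r) - 1) > 1e-6)) {
    stop("columns must sum to 1; see to_relative_abundance()")
  }
  n <- ncol(r)
  if (n < 20) stop("need at least 20 samples")
  psi <- c(1, vapply(2:k_max, function(k) {
    with_seed(substream_seed(seed, k), {
      mean(vapply(seq_len(n_splits), function(s) {
        tr <- sample(n, floor(n / 2))
        te <- setdiff(seq_len(n), tr)
        dtr <- jsd_dist(r[, tr, drop = FALSE])
        fit_tr <- cluster::pam(dtr, k)
        med_cols <- tr[fit_tr$id.med]
        dte <- jsd_dist(r[, te, drop = FALSE])
        cl_te <- cluster::pam(dte, k, cluster.only = TRUE)
        ## classify test samples to nearest training medoid under JSD
        assign_tr <- vapply(te, function(jcol) {
          dd <- vapply(med_cols, function(mc) {
            jsd_pair(r[, jcol], r[, mc])
          }, numeric(1))
          which.min(dd)
        }, integer(1))
        min(vapply(seq_len(k), function(j) {
          in_j <- which(cl_te == j)
          nj <- length(in_j)
          if (nj < 2) return(1)
          co <- outer(assign_tr[in_j], assign_tr[in_j], "==")
          (sum(co) - nj) / (nj * (nj - 1))
        }, numeric(1)))
      }, numeric(1)))
    })
  }, numeric(1)))
  names(psi) <- as.character(seq_len(k_max))
  cands <- which(psi > 0.9)
  best_k <- if (length(cands)) max(cands) else 1L
  clustering <- if (best_k > 1) {
    cluster::pam(jsd_dist(r), best_k, cluster.only = TRUE)
  } else {
    NULL
  }
  list(psi = psi, best_k = best_k, clustering = clustering)
}

jsd_pair <- function(p, q) {
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  mm <- (p + q) / 2
  sqrt(max((sum(xlx(p)) + sum(xlx(q))) / 2 - sum(xlx(mm)), 0))
}

#' Association between community diversity and a taxon's states
#'
#' Two-sample Wilcoxon rank-sum test of diversity between the low and
#' high state, plus (optionally) the Spearman correlation of diversity
#' against the taxon's continuous log10 abundance with an upper-tail
#' (AS89) p-value.
#'
#' @param diversity Named per-sample diversity values.
#' @param states A `"state_assignment"` over the same samples.
#' @param abundance Optional continuous log10 abundance vector.
#' @return List with `wilcoxon` (statistic, p), group medians, and if
#'   `abundance` is given `spearman` (rho, upper-tail p).
#' @export
diversity_state_association <- function(diversity, states,
                                        abundance = NULL) {
  stopifnot(inherits(states, "state_assignment"))
  st <- states$states
  if (!is.null(names(diversity)) && !is.null(names(st))) {
    common <- intersect(names(diversity), names(st))
    diversity <- diversity[common]
    st <- st[common]
    if (!is.null(abundance)) abundance <- abundance[common]
  }
  tab <- table(st)
  if (any(tab < 5)) {
    stop("each state needs at least 5 samples (low: ", tab[["low"]],
         ", high: ", tab[["high"]], ")")
  }
  wt <- suppressWarnings(stats::wilcox.test(diversity ~ st))
  ## fully tied diversity: no rank information, p = 1 by convention
  wp <- if (is.na(wt$p.value)) 1 else wt$p.value
  out <- list(
    wilcoxon = list(statistic = unname(wt$statistic), p = wp),
    median_low = stats::median(diversity[st == "low"]),
    median_high = stats::median(diversity[st == "high"])
  )
  if (!is.null(abundance)) {
    ct <- suppressWarnings(
      stats::cor.test(diversity, abundance, method = "spearman",
                      alternative = "greater")
    )
    out$spearman <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  out
}
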