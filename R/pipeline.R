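## End-to-end orchestration: a validated configuration object and a
## driver that runs every stage applicable to the supplied inputs,
## writing TSV result tables plus a JSON run manifest.

#' Build and validate a run configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' prevalence rule (signal 3.0 exceeded in > 20% of subjects), skewness
#' bound 0.5, mode-filter contrast 0.005 and minimum density 0.1,
#' bandwidth adjustment 0.8, 100 bootstrap replicates, bimodality call
#' support 0.90, 20 prediction-strength splits, covariation thresholds
#' |r| > 0.25 at alpha 0.05, instability threshold rho < -0.3, and a
#' 3-month Kaplan-Meier horizon.
#'
#' @param matrix_path,metadata_path Optional input TSV paths (used by
#'   [run_full_analysis()] when matrices are not passed directly).
#' @param output_dir Output directory for result tables and manifest.
#' @param prevalence_signal,prevalence_fraction,skew_threshold,
#'   potential_delta,min_density,bw_adjust,grid_size,n_boot,
#'   support_threshold,psi_splits,r_threshold,alpha,rho_threshold,
#'   km_horizon_months,seed Pipeline parameters; see module functions.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(matrix_path = NULL, metadata_path = NULL,
                       output_dir = NULL,
                       prevalence_signal = 3.0,
                       prevalence_fraction = 0.20,
                       skew_threshold = 0.5,
                       potential_delta = 0.005,
                       min_density = 0.1,
                       bw_adjust = 0.8,
                       grid_size = 200,
                       n_boot = 100,
                       support_threshold = 0.90,
                       psi_splits = 20,
                       r_threshold = 0.25,
                       alpha = 0.05,
                       rho_threshold = -0.3,
                       km_horizon_months = 3,
                       seed = 1) {
  cfg <- list(matrix_path = matrix_path, metadata_path = metadata_path,
              output_dir = output_dir,
              prevalence_signal = prevalence_signal,
              prevalence_fraction = prevalence_fraction,
              skew_threshold = skew_threshold,
              potential_delta = potential_delta,
              min_density = min_density, bw_adjust = bw_adjust,
              grid_size = grid_size, n_boot = n_boot,
              support_threshold = support_threshold,
              psi_splits = psi_splits, r_threshold = r_threshold,
              alpha = alpha, rho_threshold = rho_threshold,
              km_horizon_months = km_horizon_months, seed = seed)
  in_range <- function(v, lo, hi) is.finite(v) && v >= lo && v <= hi
  checks <- c(
    prevalence_fraction = in_range(prevalence_fraction, 0, 1),
    skew_threshold = in_range(skew_threshold, 0, Inf),
    potential_delta = in_range(potential_delta, 0, 1),
    min_density = in_range(min_density, 0, Inf),
    bw_adjust = in_range(bw_adjust, 1e-6, Inf),
    grid_size = in_range(grid_size, 32, Inf),
    n_boot = in_range(n_boot, 1, Inf),
    support_threshold = in_range(support_threshold, 0, 1),
    psi_splits = in_range(psi_splits, 1, Inf),
    r_threshold = in_range(r_threshold, 0, 1),
    alpha = in_range(alpha, 0, 1),
    rho_threshold = in_range(rho_threshold, -1, 1),
    km_horizon_months = in_range(km_horizon_months, 0, Inf),
    seed = in_range(seed, -2^31, 2^31)
  )
  if (any(!checks)) {
    stop("configuration value(s) out of range: ",
         paste(names(checks)[!checks], collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run the full tipping-element analysis
#'
#' Orchestrates the stages on the given inputs: abundance-type
#' classification and bimodality detection for every taxon, tipping
#' points and state assignment for the bimodal taxa, the state
#' combination census, the covariation screen (when extraction labels
#' allow), community PCA, diversity-state association, host-factor
#' association models (when metadata is present), and the temporal
#' stage (when longitudinal samples are present).  Stages whose inputs
#' are unavailable are skipped with a notice in the manifest.  Given the
#' same configuration and seed, outputs are identical.
#'
#' @param config A [run_config()].
#' @param matrix Optional abundance matrix (else read from
#'   `config$matrix_path`).
#' @param metadata Optional metadata (else read from
#'   `config$metadata_path` when set).
#' @return List of class `"bistab_run"` with elements `fit`
#'   (the [tipping_analysis()] object), `census`, `screen`, `pca`,
#'   `diversity`, `associations`, `temporal`, and `manifest`; result
#'   tables and the manifest are written to `config$output_dir` when
#'   set.
#' @export
run_full_analysis <- function(config = run_config(), matrix = NULL,
                              metadata = NULL) {
  stopifnot(inherits(config, "run_config"))
  notices <- character(0)
  if (is.null(matrix)) {
    if (is.null(config$matrix_path)) {
      stop("no abundance matrix: pass `matrix` or set matrix_path")
    }
    matrix <- read_abundance_matrix(config$matrix_path)
  }
  validate_abundance_matrix(matrix)
  if (is.null(metadata) && !is.null(config$metadata_path)) {
    metadata <- read_sample_metadata(config$metadata_path)
  }
  if (!is.null(metadata)) {
    al <- align_samples(matrix, metadata)
    matrix <- al$matrix
    metadata <- al$metadata
  }

  ## longitudinal samples present?  the cross-sectional stages use the
  ## baseline sample of each subject
  baseline_cols <- colnames(matrix)
  has_followup <- FALSE
  if (!is.null(metadata)) {
    has_followup <- any(metadata$time_months > 0)
    baseline_cols <- metadata$sample_id[metadata$time_months == 0]
  }
  xmat <- matrix[, baseline_cols, drop = FALSE]

  fit <- tipping_analysis(
    xmat, n_boot = config$n_boot,
    support_threshold = config$support_threshold,
    psi_splits = config$psi_splits, seed = config$seed,
    bw_adjust = config$bw_adjust, grid_size = config$grid_size,
    potential_delta = config$potential_delta,
    min_density = config$min_density
  )
  bt <- bimodal_taxa(fit)

  census <- NULL
  if (length(bt) >= 1) {
    census <- state_combination_census(fit$states)
  } else {
    notices <- c(notices, "census skipped: no bimodal taxa")
  }

  screen <- NULL
  if (length(bt) >= 1 && !is.null(metadata) &&
      sum(metadata$extraction != "unknown") >= 60) {
    screen <- covariation_screen(
      xmat, metadata[metadata$sample_id %in% baseline_cols, ],
      focal = bt, r_threshold = config$r_threshold,
      alpha = config$alpha, n_boot = config$n_boot,
      seed = config$seed)
  } else {
    notices <- c(notices,
                 "covariation screen skipped: needs bimodal taxa and extraction labels")
  }

  pca <- NULL
  if (nrow(xmat) >= 3) {
    pca <- pca_overview(xmat, n_boot = config$n_boot,
                        seed = config$seed)
  }

  diversity <- NULL
  if (length(bt) >= 1) {
    div <- shannon_diversity(to_relative_abundance(xmat))
    diversity <- lapply(bt, function(tx) {
      tryCatch(
        diversity_state_association(div, fit$states[[tx]],
                                    abundance = xmat[tx, ]),
        error = function(e) conditionMessage(e))
    })
    names(diversity) <- bt
  }

  associations <- NULL
  if (length(bt) >= 1 && !is.null(metadata)) {
    base_meta <- metadata[metadata$sample_id %in% baseline_cols, ]
    associations <- lapply(bt, function(tx) {
      tryCatch(state_host_model(fit$states[[tx]]$states, base_meta),
               error = function(e) conditionMessage(e))
    })
    names(associations) <- bt
  }

  temporal <- NULL
  if (has_followup && length(bt) >= 1) {
    temporal <- lapply(bt, function(tx) {
      ser <- subject_series(matrix, metadata, tx)
      out <- list()
      out$stability <- tryCatch(intermediate_stability(ser),
                                error = function(e) conditionMessage(e))
      out$km <- tryCatch(
        km_state_survival(ser, coef(fit)[[tx]],
                          horizon_months = config$km_horizon_months),
        error = function(e) conditionMessage(e))
      out$confound <- tryCatch(followup_confound_check(ser),
                               error = function(e) conditionMessage(e))
      out
    })
    names(temporal) <- bt
  } else if (!has_followup) {
    notices <- c(notices, "temporal stage skipped: no follow-up samples")
  }

  manifest <- list(
    package = "bistab",
    version = as.character(utils::packageVersion("bistab")),
    r_version = as.character(getRversion()),
    timestamp = NULL,  # deliberately omitted: outputs must be seed-determined
    config = unclass(config),
    n_taxa = nrow(matrix), n_samples = ncol(matrix),
    n_bimodal = length(bt), bimodal_taxa = bt,
    notices = notices
  )

  run <- structure(
    list(fit = fit, census = census, screen = screen, pca = pca,
         diversity = diversity, associations = associations,
         temporal = temporal, manifest = manifest),
    class = "bistab_run"
  )
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.bistab_run <- function(x, ...) {
  cat("bistab pipeline run:", x$manifest$n_taxa, "taxa,",
      x$manifest$n_samples, "samples;",
      x$manifest$n_bimodal, "bimodal taxa\n")
  for (msg in x$manifest$notices) cat("  note:", msg, "\n")
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(summary(run$fit), "taxon_results")
  if (!is.null(run$census)) w(run$census, "state_census")
  if (!is.null(run$screen)) w(run$screen, "covariation_screen")
  if (!is.null(run$pca)) {
    w(data.frame(component = seq_along(run$pca$variance_fraction),
                 variance_fraction = run$pca$variance_fraction),
      "pca_variance")
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
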