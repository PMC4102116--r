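## Data model: abundance matrices (taxa x samples, log10 hybridization
## signal), per-sample metadata, and relative-abundance summaries.
##
## An abundance matrix is an ordinary numeric matrix whose rows are taxa
## (genus-level groups) and whose columns are samples, with unique
## dimnames and finite values.  Metadata is a data.frame with one row per
## sample.  Both are validated, not wrapped in heavy classes, so they
## compose with base R and the rest of the ecosystem.

SEX_LEVELS <- c("female", "male", "unknown")
EXTRACTION_LEVELS <- c("mechanical", "enzymatic", "unknown")
HEALTH_LEVELS <- c("none", "IBS", "MetS", "T2D", "UC", "CVD",
                   "severe_obese")
METADATA_REQUIRED <- c("sample_id", "subject_id", "time_months", "age",
                       "bmi", "sex", "region", "extraction", "health")

## Alias tables for free-text categorical metadata.
SEX_ALIASES <- c(female = "female", f = "female", male = "male",
                 m = "male", unknown = "unknown")
EXTRACTION_ALIASES <- c(mechanical = "mechanical", rbb = "mechanical",
                        bead = "mechanical", enzymatic = "enzymatic",
                        enzyme = "enzymatic", unknown = "unknown")

#' Validate a taxa x samples abundance matrix
#'
#' Checks the core invariants: numeric matrix, unique non-empty row
#' (taxon) and column (sample) names, all values finite.
#'
#' @param m Numeric matrix, taxa in rows, samples in columns.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_abundance_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("abundance matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("abundance matrix must have taxon rownames and sample colnames")
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) {
    stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(m))) stop("abundance matrix values must be finite")
  invisible(m)
}

#' Read a taxa x samples abundance matrix from TSV
#'
#' @param path Path to a UTF-8 tab-separated file with one header row and
#'   one id column ("." decimal separator).
#' @param dialect `"taxa_rows"` (default) if rows are taxa, `"taxa_cols"`
#'   if the file is transposed.
#' @return Validated numeric matrix (taxa x samples), ids in file order.
#' @export
read_abundance_matrix <- function(path, dialect = c("taxa_rows",
                                                    "taxa_cols")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("empty or header-only abundance file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1) {
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields")
  }
  header <- fields[[1]][-1]
  ids <- vapply(fields[-1], `[[`, character(1), 1)
  body <- t(vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(length(header))))
  if (length(header) == 1) body <- matrix(body, ncol = 1)
  if (anyNA(body)) {
    bad <- which(is.na(body), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row '", ids[bad[1]], "', column '",
         header[bad[2]], "' in ", path)
  }
  rownames(body) <- ids
  colnames(body) <- header
  if (dialect == "taxa_cols") body <- t(body)
  validate_abundance_matrix(body)
  body
}

#' Write an abundance matrix to TSV
#'
#' Values are written with full double precision so that a read/write
#' round trip preserves them to better than 1e-12.
#'
#' @param m Validated abundance matrix.
#' @param path Output path.
#' @param dialect As in [read_abundance_matrix()].
#' @export
write_abundance_matrix <- function(m, path,
                                   dialect = c("taxa_rows", "taxa_cols")) {
  dialect <- match.arg(dialect)
  validate_abundance_matrix(m)
  out <- if (dialect == "taxa_cols") t(m) else m
  lines <- c(
    paste(c("id", colnames(out)), collapse = "\t"),
    vapply(seq_len(nrow(out)), function(i) {
      paste(c(rownames(out)[i],
              formatC(out[i, ], format = "g", digits = 17)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Required columns: `sample_id`, `subject_id`, `time_months`, `age`,
#' `bmi`, `sex`, `region`, `extraction`, `health`.  Unknown columns are
#' carried through untouched.  `sex` and `extraction` are normalized via a
#' documented alias table (e.g. `"F"` -> `"female"`, `"rbb"` ->
#' `"mechanical"`); empty strings and NA become `"unknown"` for `sex` and
#' `extraction` and `"none"` stays explicit for `health`.  Missing numeric
#' values are preserved as NA.
#'
#' @param path Path to a tab-separated metadata table.
#' @return A validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  validate_sample_metadata(df)
}

#' Validate (and normalize) a metadata data.frame
#'
#' @param df Data frame with the required metadata columns.
#' @return The normalized data.frame.
#' @export
validate_sample_metadata <- function(df) {
  missing_cols <- setdiff(METADATA_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("missing required metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(dup), collapse = ", "))
  }
  df$time_months <- as.numeric(df$time_months)
  if (any(is.na(df$time_months))) {
    stop("time_months must be present for every sample")
  }
  if (any(df$time_months < 0)) stop("negative time_months not allowed")
  ## exactly one baseline (time 0) per subject
  base_count <- tapply(df$time_months == 0, df$subject_id, sum)
  bad <- names(base_count)[base_count != 1]
  if (length(bad)) {
    stop("each subject needs exactly one time_months == 0 baseline; ",
         "violated by subject(s): ", paste(bad, collapse = ", "))
  }
  df$age <- as.numeric(df$age)
  df$bmi <- as.numeric(df$bmi)
  df$sex <- normalize_levels(df$sex, SEX_ALIASES, "unknown", "sex")
  df$extraction <- normalize_levels(df$extraction, EXTRACTION_ALIASES,
                                    "unknown", "extraction")
  df$health[is.na(df$health)] <- "none"
  bad <- setdiff(unique(df$health), HEALTH_LEVELS)
  if (length(bad)) {
    stop("unknown health level(s): ", paste(bad, collapse = ", "))
  }
  df$region <- as.character(df$region)
  df
}

normalize_levels <- function(x, aliases, missing_level, what) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- missing_level
  bad <- setdiff(unique(x), names(aliases))
  if (length(bad)) {
    stop("unknown ", what, " value(s): ", paste(bad, collapse = ", "))
  }
  unname(aliases[x])
}

#' Write metadata to TSV
#' @param df Metadata data.frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Align an abundance matrix with sample metadata
#'
#' @param m Abundance matrix.
#' @param metadata Metadata data.frame.
#' @param mode `"strict"` (default): every matrix sample must have a
#'   metadata row and vice versa, otherwise an error.  `"intersect"`:
#'   restrict both to the common samples; samples lacking metadata are
#'   flagged with a warning.
#' @return List with aligned `matrix` and `metadata` (metadata rows in
#'   matrix column order).
#' @export
align_samples <- function(m, metadata, mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  validate_abundance_matrix(m)
  orphans <- setdiff(colnames(m), metadata$sample_id)
  extra <- setdiff(metadata$sample_id, colnames(m))
  if (mode == "strict") {
    if (length(orphans)) {
      stop("matrix sample(s) missing from metadata: ",
           paste(orphans, collapse = ", "))
    }
    if (length(extra)) {
      stop("metadata sample(s) missing from matrix: ",
           paste(extra, collapse = ", "))
    }
    common <- colnames(m)
  } else {
    if (length(orphans)) {
      warning("dropping matrix sample(s) without metadata: ",
              paste(orphans, collapse = ", "))
    }
    common <- intersect(colnames(m), metadata$sample_id)
    if (!length(common)) stop("no samples in common")
  }
  list(matrix = m[, common, drop = FALSE],
       metadata = metadata[match(common, metadata$sample_id), ,
                           drop = FALSE])
}

#' Convert log10 signals to relative abundances
#'
#' Per sample, `relative = 10^value / sum(10^value)` over taxa: the
#' fraction of the total signal attributable to each taxon.  The result is
#' invariant to adding a constant to all log10 signals of a sample.
#'
#' @param m Abundance matrix of log10 signals.
#' @return Matrix of the same shape with columns summing to 1.
#' @export
to_relative_abundance <- function(m) {
  validate_abundance_matrix(m)
  lin <- 10^m
  cs <- colSums(lin)
  if (any(cs == 0) || any(!is.finite(cs))) {
    stop("cannot normalize: zero or non-finite total signal in a sample")
  }
  sweep(lin, 2, cs, "/")
}

#' Shannon diversity per sample
#'
#' `H = -sum(p * log(p))` with natural logarithm, over taxa with p > 0.
#' The index is maximal, `log(k)`, for a uniform composition over k taxa.
#'
#' @param r Relative abundance matrix (columns sum to 1).
#' @return Named numeric vector, one diversity value per sample.
#' @export
shannon_diversity <- function(r) {
  validate_abundance_matrix(r)
  if (any(r < 0)) stop("relative abundances must be nonnegative")
  if (any(abs(colSums(r) - 1) > 1e-9)) {
    stop("columns must sum to 1: not a relative abundance matrix")
  }
  apply(r, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}
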