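# Shared fixtures: tiny matrices, metadata frames and file writers used
# across the test files.  All randomness is seeded at the call site.

tiny_matrix <- function(n_taxa = 3, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_taxa * n_samples, 4, 1), nrow = n_taxa)
  })
  rownames(m) <- sprintf("taxon_%d", seq_len(n_taxa))
  colnames(m) <- sprintf("S%03d", seq_len(n_samples))
  m
}

tiny_metadata <- function(sample_ids, subject_ids = sample_ids,
                          time_months = 0,
                          extraction = "mechanical") {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids,
    subject_id = subject_ids,
    time_months = rep_len(time_months, n),
    age = seq(25, 70, length.out = n),
    bmi = rep_len(c(22, 27, 31), n),
    sex = rep_len(c("female", "male"), n),
    region = rep_len(c("Nordic", "Central Europe"), n),
    extraction = rep_len(extraction, n),
    health = "none",
    stringsAsFactors = FALSE
  )
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# mixture sampler used by several oracle checks
rmix2 <- function(n, means, sds, w1 = 0.5) {
  comp <- 1 + (runif(n) >= w1)
  rnorm(n, means[comp], sds[comp])
}
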