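mk_assign <- function(values, tip, nm) {
  assign_states(values, tip, taxon = nm)
}

test_that("the state census conserves counts and frequencies", {
  v <- c(s1 = 2, s2 = 4, s3 = 2)
  a1 <- mk_assign(v, 3, "g1")
  a2 <- mk_assign(c(s1 = 4, s2 = 4, s3 = 2), 3, "g2")
  cen <- state_combination_census(list(g1 = a1, g2 = a2))
  expect_equal(sum(cen$count), 3)
  expect_equal(sum(cen$frequency), 1, tolerance = 1e-12)
  expect_lte(nrow(cen), 4)

  one <- state_combination_census(list(g1 = mk_assign(c(s1 = 2), 3, "g1")))
  expect_identical(nrow(one), 1L)
  expect_equal(one$frequency, 1)

  a_bad <- mk_assign(c(s1 = 2, s9 = 4, s3 = 2), 3, "g3")
  expect_error(state_combination_census(list(g1 = a1, g3 = a_bad)),
               "different sample sets")
})

test_that("independent groups yield the product-form top combination", {
  withr::with_seed(31, {
    n <- 1000
    p1 <- 0.3
    p2 <- 0.4
    s1 <- mk_assign(setNames(ifelse(runif(n) < p1, 4, 2),
                             sprintf("s%04d", 1:n)), 3, "g1")
    s2 <- mk_assign(setNames(ifelse(runif(n) < p2, 4, 2),
                             sprintf("s%04d", 1:n)), 3, "g2")
  })
  cen <- state_combination_census(list(g1 = s1, g2 = s2))
  expected_top <- max(p1, 1 - p1) * max(p2, 1 - p2)
  se <- sqrt(expected_top * (1 - expected_top) / 1000)
  expect_lt(abs(cen$frequency[1] - expected_top), 4 * se)
})

test_that("the covariation screen flags planted pairs and respects strictness", {
  withr::with_seed(32, {
    n <- 800
    f <- rnorm(n, 3, 0.8)
    other_cor <- 0.6 * scale(f)[, 1] + sqrt(1 - 0.36) * rnorm(n)
    other_null <- rnorm(n)
    m <- rbind(focal = f, cor_taxon = 4 + 0.5 * other_cor,
               null_taxon = 4 + 0.5 * other_null)
    colnames(m) <- sprintf("S%04d", 1:n)
  })
  md <- tiny_metadata(colnames(m),
                      extraction = rep(c("mechanical", "enzymatic"),
                                       length.out = n))
  scr <- covariation_screen(m, md, focal = "focal", n_boot = 100,
                            seed = 1)
  expect_true(scr$consistent[scr$taxon == "cor_taxon"])
  expect_false(scr$consistent[scr$taxon == "null_taxon"])

  # strict inequality at the threshold: setting the threshold to the
  # observed |r| itself must drop the flag
  r_obs <- abs(scr$r_full[scr$taxon == "cor_taxon"])
  scr2 <- covariation_screen(m, md, focal = "focal",
                             r_threshold = r_obs, n_boot = 20, seed = 1)
  expect_false(scr2$consistent[scr2$taxon == "cor_taxon"])
})

test_that("PCA variance fractions are conserved and recover planted shares", {
  m <- tiny_matrix(6, 30)
  pc <- pca_overview(m, n_boot = 20)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)

  withr::with_seed(33, {
    # one-factor model: share of PC1 = var(loading*f) / total variance
    n <- 1000
    p <- 10
    f <- rnorm(n)
    lam <- rep(1, p)
    noise_sd <- 0.5
    x <- outer(lam, f) + matrix(rnorm(p * n, 0, noise_sd), p, n)
    dimnames(x) <- list(paste0("t", 1:p), sprintf("S%04d", 1:n))
  })
  pc1 <- pca_overview(x, n_boot = 10)
  planted_share <- (p * 1 + noise_sd^2) / (p + p * noise_sd^2)
  expect_lt(abs(pc1$variance_fraction[1] - planted_share), 0.02)
})

test_that("a planted bimodal factor is flagged on its component", {
  withr::with_seed(34, {
    n <- 600
    p <- 8
    f1 <- rnorm(n, 0, 2)                      # strong continuous axis
    f2 <- sample(c(-1.2, 1.2), n, TRUE) + rnorm(n, 0, 0.25)
    load1 <- rep(1.5, p)                       # var 72 on PC1
    load2 <- rep(c(1, -1), p / 2)              # orthogonal, var ~12 on PC2
    x <- outer(load1, f1) + outer(load2, f2) +
      matrix(rnorm(p * n, 0, 0.2), p, n)
    dimnames(x) <- list(paste0("t", 1:p), sprintf("S%04d", 1:n))
  })
  pc <- pca_overview(x, n_components = 3, n_boot = 50, seed = 2)
  expect_gte(pc$score_support[[2]], 0.9)
  expect_lt(pc$score_support[[1]], 0.9)
})

test_that("Jensen-Shannon dissimilarity is a metric on compositions", {
  withr::with_seed(35, {
    comps <- matrix(rexp(5 * 9), 5, 9)
    comps <- sweep(comps, 2, colSums(comps), "/")
    dimnames(comps) <- list(paste0("t", 1:5), paste0("s", 1:9))
  })
  d <- as.matrix(jsd_dist(comps))
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d), tolerance = 1e-12)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      for (k in (j + 1):9) {
        expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
      }
    }
  }
  expect_equal(jsd_pair(comps[, 1], comps[, 1]), 0)
})

test_that("prediction strength identifies community cluster structure", {
  withr::with_seed(36, {
    # two well-separated composition blobs
    n_half <- 30
    p <- 6
    base1 <- c(10, 1, 1, 1, 1, 1)
    base2 <- c(1, 1, 1, 1, 1, 10)
    mk <- function(base, n) {
      vapply(seq_len(n), function(i) {
        x <- base * exp(rnorm(p, 0, 0.15))
        x / sum(x)
      }, numeric(p))
    }
    r2 <- cbind(mk(base1, n_half), mk(base2, n_half))
    dimnames(r2) <- list(paste0("t", 1:p), sprintf("s%02d", 1:(2 * n_half)))
  })
  cc <- community_clusters(r2, k_max = 2, n_splits = 10, seed = 1)
  expect_gte(cc$psi[["2"]], 0.9)
  expect_identical(cc$best_k, 2L)
  expect_equal(cc$psi[["1"]], 1)

  withr::with_seed(37, {
    lowpsi <- vapply(1:10, function(s) {
      r1 <- mk(rep(2, p), 60)
      dimnames(r1) <- list(paste0("t", 1:p), sprintf("s%02d", 1:60))
      community_clusters(r1, k_max = 2, n_splits = 10,
                         seed = s)$psi[["2"]] < 0.8
    }, logical(1))
  })
  expect_gte(mean(lowpsi), 0.9)
})

test_that("diversity differs between states when and only when planted", {
  withr::with_seed(38, {
    n <- 200
    st_vals <- setNames(ifelse(runif(n) < 0.5, 4, 2),
                        sprintf("s%03d", 1:n))
    states <- assign_states(st_vals, 3)
    div_shift <- rnorm(n, 2 + 0.6 * (st_vals > 3), 0.5)
    names(div_shift) <- names(st_vals)
  })
  res <- diversity_state_association(div_shift, states,
                                     abundance = st_vals)
  expect_lt(res$wilcoxon$p, 0.01)
  expect_gt(res$spearman$rho, 0)
  expect_lt(res$spearman$p, 0.01)

  div_tied <- setNames(rep(1.5, n), names(st_vals))
  res_tied <- diversity_state_association(div_tied, states)
  expect_gt(res_tied$wilcoxon$p, 0.9)

  small <- assign_states(setNames(c(rep(2, n - 2), 4, 4),
                                  names(st_vals)), 3)
  expect_error(diversity_state_association(div_shift, small),
               "at least 5")
})
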