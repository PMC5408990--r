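test_that("the PRS is the weighted allele-count sum, with 2f imputation", {
  wt <- make_weight_table(2, weights = c(0.1, 0.2), freqs = c(0.3, 0.4))
  g <- matrix(c(2, 1), 1, 2, dimnames = list("a", wt$variant_id))
  prs <- compute_prs(wt, g, standardize = FALSE)
  expect_equal(prs$prs_raw, 0.4)
  # all-zero weights
  wt0 <- make_weight_table(3, weights = c(0, 0, 0))
  g0 <- matrix(rbinom(30, 2, 0.5), 10, 3,
               dimnames = list(NULL, wt0$variant_id))
  expect_equal(compute_prs(wt0, g0, standardize = FALSE)$prs_raw, rep(0, 10))
  # missing dosage imputed at 2f: f = 0.3, beta = 0.5 -> 0.3
  wt1 <- make_weight_table(1, weights = 0.5, freqs = 0.3)
  g1 <- matrix(NA_real_, 1, 1, dimnames = list("a", wt1$variant_id))
  p1 <- compute_prs(wt1, g1, standardize = FALSE)
  expect_equal(p1$prs_raw, 0.3)
  expect_equal(p1$n_missing_imputed, 1L)
  expect_true(p1$flagged_missing)
})

test_that("compute_prs equals a naive per-individual loop oracle", {
  set.seed(41)
  for (rep in 1:5) {
    k <- sample(2:8, 1)
    n <- sample(5:20, 1)
    wt <- make_weight_table(k)
    g <- matrix(rbinom(n * k, 2, 0.5), n, k,
                dimnames = list(NULL, wt$variant_id))
    g[sample(length(g), 3)] <- NA
    prs <- compute_prs(wt, g, standardize = FALSE)
    oracle <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (l in seq_len(k)) {
        d <- g[i, l]
        if (is.na(d)) d <- 2 * wt$effect_allele_freq[l]
        s <- s + wt$weight[l] * d
      }
      oracle[i] <- s
    }
    expect_equal(prs$prs_raw, oracle, tolerance = 1e-12)
  }
})

test_that("harmonization flips dosages counted on the other allele", {
  wt <- make_weight_table(2, weights = c(0.3, 0.3), freqs = c(0.5, 0.5),
                          effect = c("A", "C"), other = c("G", "T"))
  g <- matrix(c(2, 2), 1, 2, dimnames = list("a", wt$variant_id))
  # counted allele = effect allele -> contributes 2*beta
  attr(g, "alleles") <- data.frame(variant_id = wt$variant_id,
                                   counted = c("A", "C"),
                                   other = c("G", "T"))
  h <- harmonize_genotypes(wt, g)
  expect_equal(unname(h$dosages[1, ]), c(2, 2))
  # counted allele = other allele -> dosage flipped to 0, contributes 0
  attr(g, "alleles") <- data.frame(variant_id = wt$variant_id,
                                   counted = c("G", "T"),
                                   other = c("A", "C"))
  h2 <- harmonize_genotypes(wt, g)
  expect_equal(unname(h2$dosages[1, ]), c(0, 0))
  expect_true(all(h2$report$flipped))
  # flip property: the same underlying genotype reported on the other
  # allele (dosage 2 - g) yields an identical PRS after harmonization
  g_other <- 2 - g
  attr(g_other, "alleles") <- data.frame(variant_id = wt$variant_id,
                                         counted = c("G", "T"),
                                         other = c("A", "C"))
  h3 <- harmonize_genotypes(wt, g_other)
  p1 <- compute_prs(h$weights, h$dosages, standardize = FALSE)
  p3 <- compute_prs(h3$weights, h3$dosages, standardize = FALSE)
  expect_equal(p1$prs_raw, p3$prs_raw)
})

test_that("strand-ambiguous variants are flagged and used as-is", {
  wt <- make_weight_table(1, effect = "A", other = "T")
  g <- matrix(1.2, 1, 1, dimnames = list("a", wt$variant_id))
  attr(g, "alleles") <- data.frame(variant_id = wt$variant_id,
                                   counted = "T", other = "A")
  h <- harmonize_genotypes(wt, g)
  expect_true(h$report$ambiguous)
  expect_equal(unname(h$dosages[1, 1]), 1.2)
})

test_that("unmatched weight variants warn, and mostly-unmatched files fail", {
  wt <- make_weight_table(4)
  g <- matrix(1, 2, 3,
              dimnames = list(NULL, c(wt$variant_id[1:3])))
  expect_warning(h <- harmonize_genotypes(wt, g), "not in the genotypes")
  expect_equal(nrow(h$weights), 3)
  g2 <- matrix(1, 2, 1, dimnames = list(NULL, wt$variant_id[1]))
  expect_error(harmonize_genotypes(wt, g2), "more than 50%")
})

test_that("standardization yields mean 0, SD 1 and is idempotent", {
  prs <- structure(data.frame(individual_id = c("a", "b"),
                              prs_raw = c(1, 3)),
                   class = c("prs_result", "data.frame"))
  s <- standardize_prs(prs)
  expect_equal(s$prs_std, c(-sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(standardize_prs(s)$prs_std, s$prs_std)
  set.seed(5)
  wt <- make_weight_table(20)
  g <- matrix(rbinom(2000 * 20, 2, 0.4), 2000, 20,
              dimnames = list(NULL, wt$variant_id))
  p <- compute_prs(wt, g)
  expect_lt(abs(mean(p$prs_std)), 1e-10)
  expect_lt(abs(sd(p$prs_std) - 1), 1e-10)
  p$prs_raw <- rep(1, 2000)
  expect_error(standardize_prs(p), "zero variance")
})

test_that("the fitted sample moments track the PRS distribution", {
  # a normally distributed PRS with mean 0.10 and SD 0.41 (the scale of the
  # ER-negative score) is recovered in the stored moments
  set.seed(6)
  prs <- structure(data.frame(individual_id = as.character(1:50000),
                              prs_raw = rnorm(50000, 0.10, 0.41)),
                   class = c("prs_result", "data.frame"))
  s <- standardize_prs(prs)
  expect_lt(abs(attr(s, "sample_mean") - 0.10), 3 * 0.41 / sqrt(50000))
  expect_lt(abs(attr(s, "sample_sd") - 0.41), 0.01)
})

test_that("percentile categories use fitted-normal boundaries", {
  set.seed(7)
  prs <- structure(data.frame(individual_id = as.character(1:20000),
                              prs_raw = rnorm(20000, 2, 3)),
                   class = c("prs_result", "data.frame"))
  s <- standardize_prs(prs)
  cats <- assign_categories(s)
  # the exact sample median sits in the reference band
  i0 <- which.min(abs(s$prs_std))
  expect_equal(as.character(cats[i0]), "40-60")
  # occupancy of the 0-5 band is 5% within 3 binomial SEs on normal data
  occ <- mean(cats == "0-5")
  expect_lt(abs(occ - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
  # a point just above the 97th normal percentile lands in 95-100
  s2 <- s
  s2$prs_raw[1] <- attr(s, "sample_mean") +
    attr(s, "sample_sd") * (qnorm(0.97) + 1e-9)
  expect_equal(as.character(assign_categories(s2)[1]), "95-100")
})

test_that("category assignment is invariant to affine transformation", {
  set.seed(8)
  prs <- structure(data.frame(individual_id = as.character(1:500),
                              prs_raw = rnorm(500)),
                   class = c("prs_result", "data.frame"))
  a <- assign_categories(standardize_prs(prs))
  prs2 <- prs
  prs2$prs_raw <- 3.2 * prs$prs_raw - 5
  b <- assign_categories(standardize_prs(prs2))
  expect_identical(a, b)
})
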