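test_that("minor allele frequency follows its definition", {
  expect_equal(minor_allele_frequency(c(1, 1, rep(0, 8))), 0.2)
  expect_equal(minor_allele_frequency(rep(0, 6)), 0)
  expect_equal(minor_allele_frequency(c(rep(1, 18), rep(0, 82))), 0.18)
  expect_equal(minor_allele_frequency(c(1, 1, 1, 0, NA)), 0.25)
  expect_error(minor_allele_frequency(c(NA, NA)), "missing")
})

test_that("MAF filter removes strictly below threshold", {
  set.seed(14)
  n <- 40
  m_low <- c(rep(1, 1), rep(0, n - 1))        # MAF 0.025
  m_edge <- c(rep(1, 2), rep(0, n - 2))       # MAF 0.05 exactly
  M <- cbind(low = m_low, edge = m_edge,
             common = rbinom(n, 1, 0.4))
  rownames(M) <- sprintf("g%02d", 1:n)
  flt <- filter_markers(M, maf_min = 0.05)
  expect_false("low" %in% colnames(flt$markers))
  expect_true(all(c("edge", "common") %in% colnames(flt$markers)))
  expect_equal(flt$dropped$marker, "low")

  # counting oracle on uniform MAFs
  freqs <- runif(1000, 0.01, 0.5)
  M2 <- vapply(freqs, function(f) rbinom(60, 1, f), integer(60))
  rownames(M2) <- sprintf("g%02d", 1:60)
  colnames(M2) <- sprintf("m%04d", 1:1000)
  flt2 <- filter_markers(M2, 0.05)
  maf2 <- apply(M2, 2, function(g) min(mean(g), 1 - mean(g)))
  expect_equal(ncol(flt2$markers), sum(maf2 >= 0.05))
})

test_that("scan recovers a perfectly predictive marker and its invariants", {
  set.seed(15)
  n <- 30
  g <- rbinom(n, 1, 0.3)
  M <- cbind("1:100" = g, "2:200" = rbinom(n, 1, 0.4),
             "3:300" = rep(1, n))
  rownames(M) <- sprintf("g%02d", 1:n)
  trait <- setNames(as.numeric(g), rownames(M))
  sc <- gi_scan(trait, M, maf_min = 0)
  row1 <- sc[sc$marker == "1:100", ]
  expect_equal(row1$r2, 1, tolerance = 1e-12)
  expect_lt(row1$p, 1e-12)
  expect_false(sc$testable[sc$marker == "3:300"])  # monomorphic
  expect_equal(row1$chr, "1"); expect_equal(row1$pos, 100)

  # r2 = F / (F + n - 2) for every testable marker
  ok <- sc$testable & sc$F < 1e12
  expect_equal(sc$r2[ok], sc$F[ok] / (sc$F[ok] + n - 2), tolerance = 1e-10)

  # flipping dosage coding flips the effect sign only
  trait2 <- setNames(rnorm(n), rownames(M))
  sc_a <- gi_scan(trait2, M, maf_min = 0)
  Mf <- M; Mf[, "2:200"] <- 1 - Mf[, "2:200"]
  sc_b <- gi_scan(trait2, Mf, maf_min = 0)
  i <- which(sc_a$marker == "2:200")
  expect_equal(sc_b$effect[i], -sc_a$effect[i], tolerance = 1e-10)
  expect_equal(sc_b$F[i], sc_a$F[i], tolerance = 1e-10)
  expect_equal(sc_b$r2[i], sc_a$r2[i], tolerance = 1e-10)

  # genotype-order invariance
  perm <- sample.int(n)
  sc_c <- gi_scan(trait2[perm], M[perm, ], maf_min = 0)
  expect_equal(sc_c$F, sc_a$F, tolerance = 1e-10)
})

test_that("scan supports a covariate hook and marker-wise complete cases", {
  set.seed(16)
  n <- 40
  covar <- matrix(rnorm(n), dimnames = list(sprintf("g%02d", 1:n), "pc1"))
  g <- rbinom(n, 1, 0.4)
  M <- cbind("1:1" = g)
  rownames(M) <- rownames(covar)
  trait <- setNames(0.5 * covar[, 1] + 0.3 * g + rnorm(n, 0, 0.2),
                    rownames(covar))
  plain <- gi_scan(trait, M, maf_min = 0)
  adj <- gi_scan(trait, M, maf_min = 0, covariates = covar)
  expect_true(adj$testable[1])
  # adjusting for the covariate changes the marker test
  expect_false(isTRUE(all.equal(plain$F[1], adj$F[1])))

  Mna <- M; Mna[1:5, 1] <- NA
  sc_na <- gi_scan(trait, Mna, maf_min = 0)
  expect_true(sc_na$testable[1])
})

test_that("variance explained equals the squared correlation", {
  g <- setNames(c(1, 1, 1, 0, 0, 0), paste0("g", 1:6))
  tr <- setNames(as.numeric(g), names(g))
  expect_equal(variance_explained(tr, g), 1)
  # null bound: independent dosage explains < (3/sqrt(n))^2 at n large
  set.seed(17)
  n <- 400
  tr2 <- setNames(rnorm(n), paste0("g", 1:n))
  g2 <- setNames(rbinom(n, 1, 0.3), names(tr2))
  expect_lt(variance_explained(tr2, g2), (3 / sqrt(n))^2)
  expect_error(variance_explained(setNames(rep(1, 6), names(g)), g), "variance")
})

test_that("trait regression: exact slope and RSS-oracle F", {
  gi <- c(-0.2, -0.1, 0, 0.1, 0.2)
  out <- trait_regression(gi, -2 * gi)
  expect_equal(out$slope, -2, tolerance = 1e-12)

  set.seed(18)
  x <- rnorm(5); y <- 1 + 0.5 * x + rnorm(5, 0, 0.3)
  out2 <- trait_regression(x, y)
  Fo <- rss_F_oracle(y, cbind(1, x), matrix(1, 5, 1))
  expect_equal(out2$F, Fo, tolerance = 1e-10)
  expect_error(trait_regression(1:2, 1:2), "at least 3")
})

test_that("allele ANOVA reports the percent effect size", {
  tr <- c(0.9, 1.0, 1.1, 0.9, 1.0, 1.1)   # identical class means
  al <- rep(c("A", "C"), each = 3)
  out <- allele_trait_anova(tr, al)
  expect_equal(out$F, 0, tolerance = 1e-12)
  expect_equal(unname(out$effect_pct), 0)

  tr2 <- c(rep(1.00, 3), rep(0.81, 3))
  out2 <- allele_trait_anova(tr2, rep(c("A", "C"), each = 3))
  expect_equal(unname(out2$effect_pct), 19, tolerance = 1e-10)

  set.seed(19)
  tr3 <- c(rnorm(50, 1, 0.1), rnorm(50, 0.8, 0.1))
  out3 <- allele_trait_anova(tr3, rep(c("A", "C"), each = 50))
  expect_lt(abs(unname(out3$effect_pct) - 20), 3)
  expect_error(allele_trait_anova(tr, rep("A", 6)), "two")
})

test_that("resistance contingency matches hypergeometric enumeration", {
  t1 <- matrix(c(5, 0, 0, 5), 2)
  out <- resistance_contingency(t1)
  expect_equal(out$p, fisher_enum_oracle(t1), tolerance = 1e-12)
  expect_equal(out$p, 2 / choose(10, 5), tolerance = 1e-12)

  expect_equal(resistance_contingency(matrix(3, 2, 2))$p, 1)

  set.seed(20)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(resistance_contingency(tab)$p, fisher_enum_oracle(tab),
                 tolerance = 1e-12)
  }

  # 2x3 tables collapse intermediate + resistant before testing
  t3 <- matrix(c(8, 1, 2, 4, 1, 5), nrow = 2)
  out3 <- resistance_contingency(t3)
  expect_equal(dim(out3$table), c(2L, 2L))
  expect_equal(out3$table[, 2], c(3, 9), ignore_attr = TRUE)
  expect_error(resistance_contingency(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("resistance class ANOVA matches the sum-of-squares oracle", {
  gi <- c(0.1, 0.2, 0.15, -0.05, 0.0, 0.05, -0.2, -0.1, -0.15)
  cl <- rep(c("s", "i", "r"), each = 3)
  out <- resistance_class_anova(gi, cl)
  expect_equal(out$F, anova_ss_oracle(gi, cl), tolerance = 1e-10)
  expect_equal(unname(out$df), c(2, 6))

  # identical class means (each class holds the same three values) -> F = 0
  same <- resistance_class_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_error(resistance_class_anova(1:3, c("a", "b", "c")), "singleton")
})

test_that("class-label permutation p agrees with the F test on normal data", {
  set.seed(22)
  n <- 60
  cl <- rep(c("s", "i", "r"), each = n / 3)
  gi <- rnorm(n, mean = c(0, 0.08, 0.16)[as.integer(factor(cl))], sd = 0.15)
  out <- resistance_class_anova(gi, cl)
  perm <- replicate(1000, anova_ss_oracle(gi, sample(cl)))
  p_perm <- mean(perm >= out$F)
  expect_lt(abs(p_perm - out$p), 3 * sqrt(out$p * (1 - out$p) / 1000) + 0.02)
})
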