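# Independent oracles used across the suite. Each one recomputes a quantity
# by a route the implementation does not take.

# Dense-grid search for the foot point of (x, y) on q(t): coarse pass over
# [lo, hi], then refinement around the coarse optimum down to `step`.
grid_foot_oracle <- function(beta, x, y, lo = -5, hi = 5, step = 1e-5) {
  qf <- function(t) beta[1] + beta[2] * t + beta[3] * t^2
  D <- function(t) (t - x)^2 + (qf(t) - y)^2
  tt <- seq(lo, hi, by = 1e-2)
  t0 <- tt[which.min(D(tt))]
  tt <- seq(t0 - 2e-2, t0 + 2e-2, by = step)
  t1 <- tt[which.min(D(tt))]
  list(t_star = t1, dist = sqrt(D(t1)))
}

# Least-squares means via explicit normal equations: solve the block +
# genotype model X'X b = X'y (treatment contrasts), then average the fitted
# genotype values over all block levels with equal weight.
lsmeans_oracle <- function(mass, block, genotype) {
  block <- factor(block); genotype <- factor(genotype)
  X <- stats::model.matrix(~ block + genotype)
  b <- solve(crossprod(X), crossprod(X, mass))
  grid <- expand.grid(block = levels(block), genotype = levels(genotype))
  Xg <- stats::model.matrix(~ block + genotype, data = grid)
  pred <- as.vector(Xg %*% b)
  out <- tapply(pred, grid$genotype, mean)
  stats::setNames(as.numeric(out), names(out))
}

# Partial F by explicit residual-sum-of-squares comparison of two nested
# OLS fits (computed from scratch via qr).
rss_F_oracle <- function(y, X_full, X_reduced) {
  rss <- function(X) sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  r1 <- rss(X_full); r0 <- rss(X_reduced)
  df2 <- length(y) - ncol(X_full)
  ((r0 - r1) / (ncol(X_full) - ncol(X_reduced))) / (r1 / df2)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration: sum the probabilities of all tables with the same margins
# whose probability does not exceed that of the observed table.
fisher_enum_oracle <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1]; n <- sum(tab)
  ks <- max(0, c1 - r[2]):min(r[1], c1)
  pr <- stats::dhyper(ks, r[1], r[2], c1)
  p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# One-way ANOVA F from between/within sums of squares, from scratch.
anova_ss_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  m <- tapply(y, g, mean); n <- tabulate(g)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((y - m[as.integer(g)])^2)
  k <- nlevels(g)
  (ssb / (k - 1)) / (ssw / (length(y) - k))
}

# Minimal hand-built panel for generator limit tests.
make_panel <- function(truth, config) {
  markers <- matrix(truth$allele, ncol = 1,
                    dimnames = list(truth$genotype, "3:15294955"))
  structure(list(truth = truth, markers = markers,
                 causal_marker = "3:15294955", config = config),
            class = "gi_panel")
}
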