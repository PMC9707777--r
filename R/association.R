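# Single-marker association scan of the G-I trade-off value and the
# companion trait/resistance tests. Deliberately no kinship or population
# structure correction: the synthetic panel is unstructured. A `covariates`
# argument provides a hook for pre-computed structure covariates.

#' Minor allele frequency of a binary dosage vector
#'
#' @param dosages 0/1 dosages; missing values are excluded.
#' @return `min(f, 1 - f)` where `f` is the mean dosage.
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0) stop("all dosages missing")
  f <- mean(d)
  min(f, 1 - f)
}

#' Remove markers below a minor-allele-frequency threshold
#'
#' Markers with MAF strictly below `maf_min` are removed (a marker at
#' exactly the threshold is retained).
#'
#' @param markers genotype x marker 0/1 matrix.
#' @param maf_min threshold (default 0.05).
#' @return List with `markers` (retained columns), `maf` (named MAF of the
#'   retained markers) and `dropped` (data frame of removed marker ids and
#'   their MAF).
#' @export
filter_markers <- function(markers, maf_min = 0.05) {
  maf <- apply(markers, 2, minor_allele_frequency)
  keep <- maf >= maf_min
  if (!any(keep)) warning("no markers pass the MAF threshold")
  list(markers = markers[, keep, drop = FALSE],
       maf = maf[keep],
       dropped = data.frame(marker = colnames(markers)[!keep],
                            maf = unname(maf[!keep]),
                            stringsAsFactors = FALSE))
}

#' Single-marker association scan
#'
#' Per marker, ordinary least squares of the trait on the dosage (plus any
#' supplied covariates), with the marker's F test on (1, n - 2 - ncov)
#' degrees of freedom and the fraction of trait variance it explains.
#' Genotypes missing the trait or the dosage are dropped marker-wise;
#' markers monomorphic after subsetting are flagged not testable.
#'
#' @param trait named numeric vector (names = genotype ids), e.g. the
#'   `gi_value` column of a [gi_tradeoff()] fit.
#' @param markers genotype x marker dosage matrix with rownames.
#' @param maf_min minor-allele-frequency filter applied first (set 0 to
#'   disable).
#' @param covariates optional numeric matrix of per-genotype covariates
#'   (rownames = genotype ids), e.g. population-structure axes.
#' @return Data frame, one row per retained marker: `marker`, `chr`, `pos`
#'   (parsed from `chr:pos` ids when possible), `maf`, `effect` (grams per
#'   allele), `F`, `p`, `r2`, `testable`.
#' @export
gi_scan <- function(trait, markers, maf_min = 0.05, covariates = NULL) {
  shared <- intersect(names(trait), rownames(markers))
  if (length(shared) < 3)
    stop("need at least 3 genotypes shared between trait and markers")
  y_all <- trait[shared]
  if (!all(is.finite(y_all))) {
    shared <- shared[is.finite(y_all)]
    y_all <- trait[shared]
  }
  M <- markers[shared, , drop = FALSE]
  flt <- filter_markers(M, maf_min)
  M <- flt$markers
  cov <- NULL
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)[shared, , drop = FALSE]
  }

  res <- lapply(seq_len(ncol(M)), function(j) {
    g <- M[, j]
    ok <- !is.na(g)
    y <- y_all[ok]; gj <- g[ok]
    n <- length(y)
    ncov <- if (is.null(cov)) 0L else ncol(cov)
    if (stats::var(gj) == 0 || n < 3 + ncov)
      return(c(effect = NA, F = NA, p = NA, r2 = NA, testable = 0))
    X <- cbind(1, gj, if (!is.null(cov)) cov[ok, , drop = FALSE])
    fit <- stats::lm.fit(X, y)
    X0 <- X[, -2, drop = FALSE]
    fit0 <- stats::lm.fit(X0, y)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum(fit0$residuals^2)
    df2 <- n - ncol(X)
    Fj <- (rss0 - rss1) / (rss1 / df2)
    c(effect = unname(fit$coefficients[2]), F = Fj,
      p = stats::pf(Fj, 1, df2, lower.tail = FALSE),
      r2 = (rss0 - rss1) / rss0, testable = 1)
  })
  res <- do.call(rbind, res)
  ids <- colnames(M)
  parts <- strsplit(ids, ":", fixed = TRUE)
  chr <- vapply(parts, function(p) if (length(p) == 2) p[1] else NA_character_,
                character(1))
  pos <- vapply(parts, function(p)
    if (length(p) == 2) suppressWarnings(as.numeric(p[2])) else NA_real_,
    numeric(1))
  data.frame(marker = ids, chr = chr, pos = pos, maf = unname(flt$maf),
             effect = res[, "effect"], F = res[, "F"], p = res[, "p"],
             r2 = res[, "r2"], testable = res[, "testable"] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of trait variance explained by a single marker
#'
#' Squared Pearson correlation between trait and dosage over shared
#' genotypes.
#'
#' @param trait named numeric vector.
#' @param dosage named 0/1 vector.
#' @export
variance_explained <- function(trait, dosage) {
  shared <- intersect(names(trait), names(dosage))
  if (length(shared) < 3) stop("need at least 3 shared genotypes")
  x <- trait[shared]; g <- dosage[shared]
  if (stats::var(x) == 0 || stats::var(g) == 0)
    stop("zero variance in trait or dosage")
  stats::cor(x, g)^2
}

#' Linear regression of a trait on the G-I value (or vice versa)
#'
#' Ordinary least squares with the slope's F test on (1, n - 2) degrees of
#' freedom; axes untransformed.
#'
#' @param x,y paired numeric vectors (predictor, response).
#' @return List with `slope`, `intercept`, `F`, `df`, `p`, `r2`.
#' @export
trait_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite values")
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  Fv <- (rss0 - rss1) / (rss1 / (n - 2))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = Fv, df = c(1, n - 2L),
       p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE),
       r2 = if (rss0 > 0) 1 - rss1 / rss0 else NA_real_)
}

#' Two-level allele ANOVA for a trait, with percent effect size
#'
#' One-way ANOVA of the trait between the two allele classes, plus the
#' percent difference of class means, `100 * (1 - mean_C / mean_A)` — e.g.
#' a 19 percent lower root-to-shoot ratio in cooperative-allele carriers.
#'
#' @param trait numeric vector.
#' @param allele factor-like with exactly two levels; the percent effect is
#'   the second level's mean relative to the first (reference) level's.
#' @return List with `F`, `df`, `p`, `means` (per class), `effect_pct`.
#' @export
allele_trait_anova <- function(trait, allele) {
  allele <- factor(allele)
  ok <- is.finite(trait) & !is.na(allele)
  trait <- trait[ok]; allele <- droplevels(allele[ok])
  if (nlevels(allele) != 2) stop("need exactly two nonempty allele classes")
  fit <- stats::aov(trait ~ allele)
  an <- summary(fit)[[1]]
  m <- tapply(trait, allele, mean)
  list(F = an$`F value`[1], df = c(1L, length(trait) - 2L),
       p = an$`Pr(>F)`[1], means = m,
       effect_pct = 100 * (1 - m[[2]] / m[[1]]))
}

#' Exact test of allele-by-resistance association
#'
#' Two-sided Fisher exact test of a 2 x k contingency table of allele by
#' resistance class. Tables with three resistance classes (susceptible /
#' intermediate / resistant) are collapsed to susceptible versus the rest
#' before the 2 x 2 exact test.
#'
#' @param tab 2 x 2 or 2 x 3 matrix of counts (rows: alleles; columns:
#'   resistance classes ordered susceptible first).
#' @return List with `p`, `table` (the 2 x 2 table tested).
#' @export
resistance_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || !(ncol(tab) %in% 2:3))
    stop("expected a 2 x 2 or 2 x 3 count table")
  if (ncol(tab) == 3)
    tab <- cbind(susceptible = tab[, 1], resistant = tab[, 2] + tab[, 3])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  list(p = stats::fisher.test(tab)$p.value, table = tab)
}

#' One-way ANOVA of G-I values across resistance classes
#'
#' @param gi numeric G-I trade-off values.
#' @param classes factor-like resistance classes (k >= 2).
#' @return List with `F`, `df` (k - 1, n - k), `p`, `means`.
#' @export
resistance_class_anova <- function(gi, classes) {
  classes <- factor(classes)
  ok <- is.finite(gi) & !is.na(classes)
  gi <- gi[ok]; classes <- droplevels(classes[ok])
  k <- nlevels(classes)
  if (k < 2) stop("need at least two resistance classes")
  if (all(tabulate(classes) == 1))
    stop("all classes are singletons; no residual degrees of freedom")
  fit <- stats::aov(gi ~ classes)
  an <- summary(fit)[[1]]
  list(F = an$`F value`[1], df = c(k - 1L, length(gi) - k),
       p = an$`Pr(>F)`[1], means = tapply(gi, classes, mean))
}

#' Manhattan-style plot of a scan result
#'
#' @param scan a [gi_scan()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot_scan <- function(scan, ...) {
  sc <- scan[scan$testable & !is.na(scan$chr), ]
  sc <- sc[order(sc$chr, sc$pos), ]
  col <- as.integer(factor(sc$chr)) %% 2 + 1
  graphics::plot(seq_len(nrow(sc)), -log10(sc$p),
                 col = c("grey40", "steelblue")[col], pch = 16,
                 xlab = "marker index (by chromosome)",
                 ylab = expression(-log[10](p)), ...)
  invisible(sc)
}
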