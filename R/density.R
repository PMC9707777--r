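# Density-gradient analysis: monoculture productivity as a function of
# realized ground area per individual, allele, and their interaction, with
# genotype random intercepts and random area slopes.

#' Exclude pots whose realized density exceeds the sown density
#'
#' Pots holding more plants than were sown were evidently not thinned as
#' intended and are removed before modelling.
#'
#' @param records density-gradient records (see [simulate_density()]).
#' @return List with `records` (retained) and `log` (dropped pots).
#' @export
exclude_overdense <- function(records) {
  over <- records$realized_n > records$sown_n
  list(records = records[!over, , drop = FALSE],
       log = records[over, c("pot", "sown_n", "realized_n"), drop = FALSE])
}

#' Mixed model for monoculture productivity along the density gradient
#'
#' Fits pot-level shoot biomass against the fixed effects area per
#' individual, allele, and their interaction, with the genotype's individual
#' mixture performance as a covariate (it was used to stratify the genotype
#' sample by size), and random terms for genotype and genotype-by-area.
#' F tests for the fixed terms use Satterthwaite denominator degrees of
#' freedom. If the random-effects fit is singular or fails, the model falls
#' back to fixed effects only (flagged in the result).
#'
#' @param records density records with columns `genotype`, `allele`,
#'   `area_per_individual_cm2`, `shoot_mass_g`, `mixture_covariate`.
#' @param per_individual model per-plant rather than per-pot biomass
#'   (divides the response by `realized_n`).
#' @return List with `fit`, `anova` (F table for the fixed terms), `fixef`,
#'   `singular`, `fallback`.
#' @export
fit_density_model <- function(records, per_individual = FALSE) {
  needed <- c("genotype", "allele", "area_per_individual_cm2",
              "shoot_mass_g", "mixture_covariate")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("density records lack column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(
    y = if (per_individual) records$shoot_mass_g / records$realized_n
        else records$shoot_mass_g,
    area = records$area_per_individual_cm2,
    allele = factor(records$allele),
    genotype = factor(records$genotype),
    covar = records$mixture_covariate)
  if (nlevels(d$allele) < 2) stop("need both allele classes")
  if (length(unique(d$area)) < 2) stop("need at least 2 distinct areas")

  # with fewer than 4 genotypes the random terms are confounded with the
  # allele contrast; degrade gracefully to the fixed-effects model
  fallback <- FALSE; singular <- FALSE
  fit <- if (nlevels(d$genotype) < 4) NULL else tryCatch(
    lmerTest::lmer(y ~ area * allele + covar +
                     (1 | genotype) + (0 + area | genotype),
                   data = d,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  if (!is.null(fit)) singular <- lme4::isSingular(fit, tol = 1e-4)
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- stats::lm(y ~ area * allele + covar, data = d)
  }
  an <- if (fallback) {
    a <- stats::anova(fit)
    a[rownames(a) != "Residuals", , drop = FALSE]
  } else {
    stats::anova(fit, type = 3)  # lmerTest: Satterthwaite F tests
  }
  fx <- if (fallback) stats::coef(fit) else lme4::fixef(fit)
  list(fit = fit, anova = an, fixef = fx,
       singular = singular, fallback = fallback)
}

#' Percent allele contrast in pot biomass at one sown density
#'
#' `100 * (mean_C - mean_A) / mean_A` of pot shoot biomass among pots sown
#' at the given density: the productivity advantage of cooperative-allele
#' monocultures.
#'
#' @param records density records.
#' @param density sown plants per pot.
#' @return Percent difference (positive = cooperative allele more
#'   productive).
#' @export
allele_contrast_at_density <- function(records, density) {
  rows <- records[records$sown_n == density, , drop = FALSE]
  m <- tapply(rows$shoot_mass_g, rows$allele, mean)
  if (!all(c("A", "C") %in% names(m)))
    stop("both allele classes must be present at density ", density)
  100 * (m[["C"]] - m[["A"]]) / m[["A"]]
}
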