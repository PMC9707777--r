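# From plant-level competition records to per-genotype performance points:
# x = block-adjusted mean individual shoot biomass across mixtures,
# y = monoculture shoot biomass per individual.

check_competition_records <- function(records) {
  needed <- c("block", "pot", "genotype", "composition", "shoot_mass_g")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("competition records lack column(s): ", paste(miss, collapse = ", "))
  records
}

#' Apply the pot-level exclusion rules of the competition experiment
#'
#' Pots containing single plants, and pots in which a plant died at the
#' seedling stage (missing shoot biomass, or a logical `died` column),
#' are excluded from the performance analysis. Singles are returned
#' separately because the payoff workflow needs them. A pot with more than
#' two plants is a data-integrity error.
#'
#' @param records plant-level competition records (see
#'   [simulate_competition()] for the column contract).
#' @return A list with `records` (retained complete two-plant pots),
#'   `singles` (complete single-plant pots), and `log` (data frame of
#'   excluded pot ids and reasons).
#' @export
filter_records <- function(records) {
  check_competition_records(records)
  if (nrow(records) == 0)
    return(list(records = records, singles = records,
                log = data.frame(pot = character(), reason = character(),
                                 stringsAsFactors = FALSE)))
  died <- if ("died" %in% names(records)) records$died %in% TRUE else
    rep(FALSE, nrow(records))
  died <- died | !is.finite(records$shoot_mass_g)

  n_per_pot <- table(records$pot)
  if (any(n_per_pot > 2))
    stop("pot(s) with more than two plants: ",
         paste(names(n_per_pot)[n_per_pot > 2], collapse = ", "))

  pot_of <- records$pot
  dead_pots <- unique(pot_of[died])
  is_single <- records$composition == "single"
  single_pots <- unique(pot_of[is_single])
  # a pair pot with only one record present is incomplete
  pair_pots <- setdiff(names(n_per_pot), single_pots)
  incomplete <- pair_pots[n_per_pot[pair_pots] < 2]

  reason <- character(0); pots <- character(0)
  if (length(dead_pots)) {
    pots <- c(pots, dead_pots)
    reason <- c(reason, rep("dead plant", length(dead_pots)))
  }
  inc <- setdiff(incomplete, dead_pots)
  if (length(inc)) {
    pots <- c(pots, inc); reason <- c(reason, rep("incomplete pot", length(inc)))
  }
  sgl <- setdiff(single_pots, dead_pots)
  if (length(sgl)) {
    pots <- c(pots, sgl); reason <- c(reason, rep("single plant", length(sgl)))
  }
  drop <- pot_of %in% c(dead_pots, incomplete)
  keep <- records[!drop & !is_single, , drop = FALSE]
  singles <- records[!drop & is_single, , drop = FALSE]
  rownames(keep) <- rownames(singles) <- NULL
  list(records = keep, singles = singles,
       log = data.frame(pot = pots, reason = reason, stringsAsFactors = FALSE))
}

focal_mixture_rows <- function(records, testers) {
  records$composition == "mixture" &
    !(records$genotype %in% testers) &
    records$neighbour_genotype %in% testers
}

#' Block-adjusted mixture performance per genotype (least-squares means)
#'
#' Fits `shoot_mass_g ~ block + genotype` by ordinary least squares to the
#' focal plants in mixture pots and returns each genotype's adjusted mean
#' evaluated at equally weighted block levels. With a single block this is
#' the arithmetic mean.
#'
#' @param records filtered competition records.
#' @param testers character vector of tester genotype ids; focal plants are
#'   the non-tester plants grown against a tester.
#' @return Named numeric vector of adjusted means (grams), one per focal
#'   genotype observed in mixtures.
#' @export
mixture_ls_means <- function(records, testers) {
  check_competition_records(records)
  rows <- records[focal_mixture_rows(records, testers), , drop = FALSE]
  if (nrow(rows) == 0) stop("no focal mixture records")
  rows$block <- factor(rows$block)
  rows$genotype <- factor(rows$genotype)
  if (nlevels(rows$genotype) < 2)
    stop("need at least two focal genotypes in mixtures")
  fml <- if (nlevels(rows$block) > 1) shoot_mass_g ~ block + genotype
         else shoot_mass_g ~ genotype
  fit <- stats::lm(fml, data = rows)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient block/genotype design; aliased: ",
         paste(bad, collapse = ", "))
  }
  grid <- expand.grid(block = levels(rows$block),
                      genotype = levels(rows$genotype))
  pred <- stats::predict(fit, newdata = grid)
  out <- tapply(pred, grid$genotype, mean)
  stats::setNames(as.numeric(out), names(out))[levels(rows$genotype)]
}

#' Monoculture biomass per individual
#'
#' For each genotype, the mean over its complete monoculture pots of the pot
#' total divided by two.
#'
#' @inheritParams mixture_ls_means
#' @return Named numeric vector (grams per individual).
#' @export
monoculture_means <- function(records) {
  check_competition_records(records)
  mono <- records[records$composition == "monoculture", , drop = FALSE]
  if (nrow(mono) == 0) stop("no monoculture records")
  pot_half <- tapply(mono$shoot_mass_g, mono$pot, sum) / 2
  pot_geno <- tapply(mono$genotype, mono$pot, function(g) g[[1]])
  out <- tapply(pot_half, pot_geno[names(pot_half)], mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Assemble per-genotype performance points
#'
#' Combines [mixture_ls_means()] (x: individual performance in mixtures) and
#' [monoculture_means()] (y: group performance per individual) into the
#' point cloud on which the G-I trade-off is defined. Genotypes missing
#' either context are dropped with a message.
#'
#' @inheritParams mixture_ls_means
#' @return Data frame: `genotype`, `x`, `y`, `n_mix`, `n_mono`.
#' @export
genotype_performance <- function(records, testers) {
  x <- mixture_ls_means(records, testers)
  y <- monoculture_means(records)
  rows <- records[focal_mixture_rows(records, testers), , drop = FALSE]
  n_mix <- table(rows$genotype)
  mono <- records[records$composition == "monoculture", , drop = FALSE]
  n_mono <- table(unique(mono[c("pot", "genotype")])$genotype)
  shared <- intersect(names(x), names(y))
  missing <- setdiff(union(names(x), names(y)), shared)
  if (length(missing))
    message("dropping genotype(s) lacking one context: ",
            paste(missing, collapse = ", "))
  data.frame(genotype = shared,
             x = unname(x[shared]), y = unname(y[shared]),
             n_mix = as.integer(n_mix[shared]),
             n_mono = as.integer(n_mono[shared]),
             stringsAsFactors = FALSE)
}

#' Test the effect of tester size on focal performance
#'
#' Computes each tester genotype's mean shoot biomass across all pots in
#' which it grew, then regresses focal-plant shoot biomass in mixtures on
#' that tester mean (plus block). Returns the F test of the tester-mean
#' term; a negative slope indicates that large testers suppress their
#' neighbours.
#'
#' @inheritParams mixture_ls_means
#' @return A list with `F`, `df`, `p`, `slope`.
#' @export
tester_effect_test <- function(records, testers) {
  check_competition_records(records)
  if (length(unique(testers)) < 2) stop("need at least two testers")
  t_rows <- records$genotype %in% testers
  t_mean <- tapply(records$shoot_mass_g[t_rows], records$genotype[t_rows], mean)
  if (length(unique(round(t_mean, 12))) < 2)
    stop("testers have identical mean biomass; effect not estimable")
  rows <- records[focal_mixture_rows(records, testers), , drop = FALSE]
  rows$tester_mean <- unname(t_mean[rows$neighbour_genotype])
  rows$block <- factor(rows$block)
  if (nlevels(rows$block) > 1) {
    full <- stats::lm(shoot_mass_g ~ block + tester_mean, data = rows)
    red <- stats::lm(shoot_mass_g ~ block, data = rows)
  } else {
    full <- stats::lm(shoot_mass_g ~ tester_mean, data = rows)
    red <- stats::lm(shoot_mass_g ~ 1, data = rows)
  }
  an <- stats::anova(red, full)
  list(F = an$F[2], df = c(1, full$df.residual),
       p = an$`Pr(>F)`[2],
       slope = unname(stats::coef(full)["tester_mean"]))
}
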