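# Payoff matrices from near-isogenic-line competition: the payoff of a
# focal line against a given neighbour is its shoot-biomass reduction
# relative to growth alone (small reduction = large benefit). Propagated
# standard errors and a game-structure classification follow.

#' Standard error of a payoff by error propagation
#'
#' The payoff is a difference of two means (single-plant mean minus
#' competition mean), so its standard error is
#' `sqrt(sem_single^2 + sem_comp^2)` with each `sem = sd / sqrt(n)`.
#'
#' @param sd_single,n_single standard deviation and sample size of the
#'   single-plant biomass.
#' @param sd_comp,n_comp same for the competition cell.
#' @export
payoff_sem <- function(sd_single, n_single, sd_comp, n_comp) {
  if (any(c(n_single, n_comp) < 1)) stop("sample sizes must be >= 1")
  if (any(c(sd_single, sd_comp) < 0)) stop("standard deviations must be >= 0")
  sqrt(sd_single^2 / n_single + sd_comp^2 / n_comp)
}

#' Payoff matrix of one near-isogenic-line background
#'
#' For each focal allele f and neighbour allele nb, the mean biomass
#' reduction `mean(single-plant mass of f) - mean(mass of f grown with nb)`
#' with its propagated SEM and the competition cell's sample size. In
#' monoculture pots both plants observe the (f, f) cell; in mixture pots
#' each plant contributes to its own (f, other) cell. With
#' `pool_monoculture = FALSE` the diagonal cells use mixture-design records
#' only (there are none in the standard design, so the default pools).
#'
#' @param records NIL records (see [simulate_nil()]).
#' @param background background identifier to analyse.
#' @param alleles the two allele labels, cooperative first.
#' @param pool_monoculture include monoculture pots in the same-allele cells.
#' @return Object of class `payoff_matrix`: 2 x 2 matrices `reduction`,
#'   `sem`, `n` (rows: focal allele; columns: neighbour allele).
#' @export
payoff_matrix <- function(records, background, alleles = c("Bay", "Sha"),
                          pool_monoculture = TRUE) {
  rec <- records[records$background == background, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for background ", background)
  red <- sem <- nn <- matrix(NA_real_, 2, 2,
                             dimnames = list(focal = alleles,
                                             neighbour = alleles))
  singles <- rec[rec$community == "single", , drop = FALSE]
  for (f in alleles) {
    s <- singles$shoot_mass_g[singles$allele == f]
    if (length(s) == 0)
      stop("no single-plant baseline for allele ", f,
           " in background ", background)
    for (nb in alleles) {
      cells <- if (f == nb) {
        if (pool_monoculture)
          rec$allele == f & rec$neighbour_allele == nb &
            rec$community %in% c("monoculture", "mixture")
        else rec$allele == f & rec$neighbour_allele == nb &
          rec$community == "mixture"
      } else rec$allele == f & rec$neighbour_allele == nb &
        rec$community == "mixture"
      m <- rec$shoot_mass_g[cells]
      if (length(m) == 0)
        stop("empty competition cell ", f, " vs ", nb,
             " in background ", background)
      red[f, nb] <- mean(s) - mean(m)
      sd_s <- stats::sd(s); sd_m <- stats::sd(m)
      sem[f, nb] <- if (length(s) > 1 && length(m) > 1)
        payoff_sem(sd_s, length(s), sd_m, length(m)) else NA_real_
      nn[f, nb] <- length(m)
    }
  }
  structure(list(background = background, reduction = red, sem = sem, n = nn,
                 alleles = alleles),
            class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Payoff matrix, background %s (biomass reduction +/- SEM, g)\n",
              x$background))
  out <- matrix(sprintf("%.*f (%.*f)", digits, x$reduction, digits, x$sem),
                2, 2, dimnames = dimnames(x$reduction))
  print(out, quote = FALSE)
  invisible(x)
}

#' Classify the game structure of a payoff matrix
#'
#' Payoff-as-benefit is minus the biomass reduction (a small reduction is a
#' large benefit). With cooperative allele `coop` and competitive allele
#' `comp`: Temptation T = benefit(comp facing coop), Reward R = benefit(coop
#' facing coop), Punishment P = benefit(comp facing comp), Sucker's payoff
#' S = benefit(coop facing comp). Returns `"prisoners_dilemma"` iff
#' T > R > P > S, `"neutral"` if all four payoffs are equal, otherwise the
#' observed ordering string (e.g. `"R>T>P>S"`).
#'
#' @param matrix a [payoff_matrix()].
#' @return List with `label`, `payoffs` (named T, R, P, S, benefit scale)
#'   and `ordering`.
#' @export
classify_game <- function(matrix) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  red <- matrix$reduction
  if (any(!is.finite(red))) stop("payoff matrix has missing cells")
  coop <- matrix$alleles[1]; comp <- matrix$alleles[2]
  pay <- c(T = -red[comp, coop], R = -red[coop, coop],
           P = -red[comp, comp], S = -red[coop, comp])
  if (length(unique(pay)) == 1)
    return(list(label = "neutral", payoffs = pay, ordering = "T=R=P=S"))
  ord <- names(sort(pay, decreasing = TRUE))
  ordering <- paste(ord, collapse = ">")
  label <- if (pay["T"] > pay["R"] && pay["R"] > pay["P"] &&
               pay["P"] > pay["S"]) "prisoners_dilemma" else ordering
  list(label = label, payoffs = pay, ordering = ordering)
}

#' Proportional-odds model for root browning scores
#'
#' Cumulative-logit (proportional-odds) regression of the ordinal root
#' browning score on community type (single plant or monoculture), genetic
#' background, and allele. Mixture pots are excluded before fitting. The
#' allele coefficient's Wald test is reported; a positive Sha coefficient
#' means competitive-allele plants show more root browning.
#'
#' @param records NIL records with a `root_score` column in 0/1/2.
#' @return List with `fit` (the `polr` object), `allele_coef`, `allele_se`,
#'   `allele_p` (Wald), `coefficients`.
#' @export
root_score_model <- function(records) {
  d <- records[records$community != "mixture", , drop = FALSE]
  d <- d[!is.na(d$root_score), , drop = FALSE]
  if (length(unique(d$root_score)) < 2)
    stop("root scores are constant; ordinal model is degenerate")
  d$score <- factor(d$root_score, ordered = TRUE)
  d$allele <- factor(d$allele)
  d$background <- factor(d$background)
  d$community <- factor(d$community)
  rhs <- c("allele",
           if (nlevels(d$background) > 1) "background",
           if (nlevels(d$community) > 1) "community")
  fml <- stats::reformulate(rhs, response = "score")
  fit <- tryCatch(
    MASS::polr(fml, data = d, Hess = TRUE),
    error = function(e) stop("proportional-odds fit failed (possibly ",
                             "complete separation): ", conditionMessage(e)))
  ct <- summary(fit)$coefficients
  arow <- grep("^allele", rownames(ct), value = TRUE)[1]
  if (is.na(arow)) stop("allele term dropped from the model")
  z <- ct[arow, "t value"]
  list(fit = fit,
       allele_coef = ct[arow, "Value"],
       allele_se = ct[arow, "Std. Error"],
       allele_p = 2 * stats::pnorm(-abs(z)),
       coefficients = ct)
}
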