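#' Configuration for the synthetic competition-experiment generator
#'
#' Collects and validates all parameters of the generative model used by
#' [simulate_panel()], [simulate_competition()], [simulate_density()] and
#' [simulate_nil()]. The defaults encode the study conditions the generator
#' emulates: a 98-focal x 10-tester pairwise competition design in two
#' blocks, a binary causal locus at minor allele frequency 0.18 whose rarer
#' allele lowers competitiveness (i.e., increases cooperation), and a
#' tragedy-of-the-commons interaction structure in which the cost a plant
#' imposes on its neighbour (`theta_neigh`) exceeds the benefit it retains
#' for itself (`theta_self`).
#'
#' @param n_focal number of focal genotypes (grown in monoculture and
#'   against every tester).
#' @param n_tester number of dedicated tester genotypes; the panel contains
#'   `n_tester + n_focal` genotypes, the first `n_tester` being testers.
#' @param n_blocks number of complete experimental blocks.
#' @param n_markers total number of binary markers, including the causal one.
#' @param causal_maf frequency of the cooperation-associated allele, in (0, 0.5).
#' @param mu_v,sigma_v mean and standard deviation (grams) of baseline
#'   individual vigor; draws are truncated below at `0.1 * mu_v`.
#' @param s0 baseline competitiveness (dimensionless).
#' @param gamma_a reduction in competitiveness conferred by the causal
#'   (cooperative) allele.
#' @param sigma_s standard deviation of residual competitiveness.
#' @param theta_self gain in own biomass per unit own competitiveness.
#' @param theta_neigh loss in biomass per unit neighbour competitiveness;
#'   must exceed `theta_self` for a group-versus-individual trade-off to exist.
#' @param sigma_e residual biomass standard deviation (grams) per plant.
#' @param block_effect additive shift (grams) applied to block 2 (and, for
#'   more blocks, accumulated per block beyond the first).
#' @param b_max saturation ceiling (grams) of the concave biomass transform
#'   `sat(u) = b_max * u / (b_max + u)`.
#' @param pot_area pot ground area in cm^2 (density gradient).
#' @param area_halfsat area scale A0 (cm^2) of the per-plant crowding response.
#' @param mortality per-seedling early mortality probability (density
#'   gradient only).
#' @param rts_base baseline root-to-shoot ratio.
#' @param rts_allele_effect fractional reduction of the root-to-shoot ratio in
#'   cooperative-allele carriers (0.19 = 19 percent lower).
#' @param rts_cv lognormal noise sd of the root-to-shoot ratio.
#' @param include_singles also generate one single-plant pot per tester and
#'   block, as in the original design.
#' @param nil_backgrounds identifiers of the near-isogenic line backgrounds.
#' @param nil_v named baseline vigor (grams) per background.
#' @param nil_penalty named disease penalty (grams) suffered under
#'   competition by competitive-allele (Sha) plants in susceptible
#'   backgrounds; backgrounds not named are unaffected.
#' @param nil_n_single,nil_n_mono,nil_n_mix replicate pots per background and
#'   cell: single plants (per line), monocultures (per line), and mixtures.
#' @param score_allele_shift cumulative log-odds shift towards higher root
#'   browning scores for competitive-allele plants.
#' @param score_bg_shift named cumulative log-odds shift per background.
#' @param score_community_shift shift for plants grown in company
#'   (monoculture or mixture) relative to singles.
#' @param score_cutpoints cutpoints of the cumulative-logit score model
#'   (scores 0/1/2).
#' @param seed integer seed; each table generator uses its own offset stream
#'   so tables can be regenerated independently (panel +0, competition +1,
#'   density +2, NIL +3).
#'
#' @return An object of class `gi_config` (a validated list).
#' @export
gi_config <- function(n_focal = 98L, n_tester = 10L, n_blocks = 2L,
                      n_markers = 1000L, causal_maf = 0.18,
                      mu_v = 1.0, sigma_v = 0.15,
                      s0 = 0.5, gamma_a = 0.3, sigma_s = 0.1,
                      theta_self = 0.2, theta_neigh = 0.4,
                      sigma_e = 0.05, block_effect = -0.05, b_max = 2.0,
                      pot_area = 64, area_halfsat = 3, mortality = 0.1,
                      rts_base = 0.25, rts_allele_effect = 0.19, rts_cv = 0.1,
                      include_singles = TRUE,
                      nil_backgrounds = c("33RV085", "33RV113",
                                          "33RV142", "33RV192"),
                      nil_v = c("33RV085" = 1.1, "33RV113" = 0.9,
                                "33RV142" = 1.0, "33RV192" = 1.2),
                      nil_penalty = c("33RV113" = 0.4, "33RV142" = 0.15),
                      nil_n_single = 16L, nil_n_mono = 16L, nil_n_mix = 32L,
                      score_allele_shift = 1.5,
                      score_bg_shift = c("33RV085" = 0, "33RV113" = 2,
                                         "33RV142" = 1, "33RV192" = 0),
                      score_community_shift = 0.5,
                      score_cutpoints = c(1.0, 2.5),
                      seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_focal = n_focal, n_tester = n_tester, n_blocks = n_blocks,
              n_markers = n_markers, nil_n_single = nil_n_single,
              nil_n_mono = nil_n_mono, nil_n_mix = nil_n_mix)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers: ",
         paste(names(counts)[counts < 1 | counts != round(counts)],
               collapse = ", "))
  if (!is.finite(causal_maf) || causal_maf <= 0 || causal_maf >= 0.5)
    stop("'causal_maf' must lie strictly between 0 and 0.5")
  vars <- c(sigma_v = sigma_v, sigma_s = sigma_s, sigma_e = sigma_e,
            rts_cv = rts_cv)
  if (any(vars < 0))
    stop("variance parameters must be >= 0: ",
         paste(names(vars)[vars < 0], collapse = ", "))
  if (!(theta_neigh > theta_self && theta_self > 0))
    stop("need theta_neigh > theta_self > 0 (otherwise there is no ",
         "group-versus-individual trade-off to recover)")
  if (mu_v <= 0 || b_max <= 0 || pot_area <= 0 || area_halfsat <= 0)
    stop("'mu_v', 'b_max', 'pot_area' and 'area_halfsat' must be positive")
  if (mortality < 0 || mortality >= 1)
    stop("'mortality' must be in [0, 1)")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "gi_config")
}

as_gi_config <- function(config) {
  if (inherits(config, "gi_config")) return(config)
  if (is.list(config)) return(do.call(gi_config, config))
  stop("'config' must be a gi_config or a list of gi_config arguments")
}

#' @export
print.gi_config <- function(x, ...) {
  cat("Synthetic competition-experiment configuration\n")
  cat(sprintf("  panel: %d focal + %d tester genotypes, %d block(s), %d markers\n",
              x$n_focal, x$n_tester, x$n_blocks, x$n_markers))
  cat(sprintf("  causal allele: freq %.2f, competitiveness shift -%.2f\n",
              x$causal_maf, x$gamma_a))
  cat(sprintf("  interaction: theta_self %.2f < theta_neigh %.2f (social dilemma)\n",
              x$theta_self, x$theta_neigh))
  cat(sprintf("  noise: sigma_v %.3g, sigma_s %.3g, sigma_e %.3g; seed %d\n",
              x$sigma_v, x$sigma_s, x$sigma_e, x$seed))
  invisible(x)
}
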