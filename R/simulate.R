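# Synthetic experiment generators. All tables are deterministic functions of
# (config, seed); each generator runs on its own seed offset so any one table
# can be regenerated without the others.

seed_offset <- c(panel = 0L, competition = 1L, density = 2L, nil = 3L)

with_table_seed <- function(config, table, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + seed_offset[[table]])
  expr
}

# Concave saturating biomass response; space becomes limiting as the linear
# predictor u grows. Non-positive predictors map to a small positive floor.
saturate <- function(u, b_max) {
  ifelse(u > 0, b_max * u / (b_max + u), 0.001)
}

#' Simulate a genotype panel with latent strategies and marker dosages
#'
#' Draws, for `n_tester + n_focal` genotypes, a baseline vigor
#' `v ~ Normal(mu_v, sigma_v^2)` truncated below at `0.1 * mu_v`, a causal
#' cooperation allele `a ~ Bernoulli(causal_maf)`, a competitiveness
#' `s = s0 - gamma_a * a + Normal(0, sigma_s^2)`, and a binary marker matrix
#' in which one marker is the causal locus (placed at coordinate
#' `3:15294955`) and all others are independent of the phenotype, with
#' per-marker allele frequencies drawn from Uniform(0.05, 0.5). Genotypes
#' are inbred lines, so dosages are binary.
#'
#' @param config a [gi_config()].
#' @return An object of class `gi_panel`: a list with `truth` (data frame of
#'   genotype, role, vigor, competitiveness, allele), `markers` (genotype x
#'   marker 0/1 matrix with `chr:pos` column names) and `causal_marker` (the
#'   causal marker's id).
#' @export
simulate_panel <- function(config = gi_config()) {
  config <- as_gi_config(config)
  with_table_seed(config, "panel", {
    n <- config$n_tester + config$n_focal
    ids <- c(sprintf("T%02d", seq_len(config$n_tester)),
             sprintf("G%03d", seq_len(config$n_focal)))
    v <- stats::rnorm(n, config$mu_v, config$sigma_v)
    floor_v <- 0.1 * config$mu_v
    while (any(bad <- v < floor_v))
      v[bad] <- stats::rnorm(sum(bad), config$mu_v, config$sigma_v)
    a <- stats::rbinom(n, 1L, config$causal_maf)
    s <- config$s0 - config$gamma_a * a + stats::rnorm(n, 0, config$sigma_s)
    truth <- data.frame(
      genotype = ids,
      role = rep(c("tester", "focal"), c(config$n_tester, config$n_focal)),
      vigor = v, competitiveness = s, allele = a,
      stringsAsFactors = FALSE)

    n_null <- config$n_markers - 1L
    freqs <- stats::runif(n_null, 0.05, 0.5)
    markers <- matrix(stats::rbinom(n * n_null, 1L, rep(freqs, each = n)),
                      nrow = n)
    chr <- sample(c(1:2, 4:5), n_null, replace = TRUE)
    pos <- sample.int(3e7L, n_null)
    ids_null <- sprintf("%d:%d", chr, pos)
    causal_id <- "3:15294955"
    markers <- cbind(markers[, seq_len(n_null %/% 2), drop = FALSE], a,
                     markers[, seq_len(n_null) > n_null %/% 2, drop = FALSE])
    colnames(markers) <- c(ids_null[seq_len(n_null %/% 2)], causal_id,
                           ids_null[seq_len(n_null) > n_null %/% 2])
    rownames(markers) <- ids
    structure(list(truth = truth, markers = markers,
                   causal_marker = causal_id, config = config),
              class = "gi_panel")
  })
}

#' @export
print.gi_panel <- function(x, ...) {
  cat(sprintf("Synthetic panel: %d genotypes (%d testers), %d markers\n",
              nrow(x$truth), sum(x$truth$role == "tester"), ncol(x$markers)))
  cat(sprintf("  causal marker %s, realized cooperative-allele frequency %.3f\n",
              x$causal_marker, mean(x$truth$allele)))
  invisible(x)
}

# linear predictor of one plant's shoot biomass before saturation
plant_predictor <- function(v, s_self, s_neigh, block, config) {
  v + config$theta_self * s_self - config$theta_neigh * s_neigh +
    config$block_effect * (block - 1)
}

#' Simulate the pairwise focal-by-tester competition experiment
#'
#' For every block, each focal genotype is grown once in monoculture (two
#' plants of its own genotype per pot) and once with each tester genotype
#' (one focal plus one tester plant per pot). A plant's shoot biomass is
#' `sat(v + theta_self*s - theta_neigh*s_neighbour + block_effect + e)`,
#' `e ~ Normal(0, sigma_e^2)`, with the concave saturating transform
#' capturing the progressive space limitation of large plants. Root biomass
#' is shoot biomass times a root-to-shoot ratio that is
#' `rts_allele_effect` lower (proportionally) in cooperative-allele carriers.
#' If `config$include_singles` each tester is additionally grown once per
#' block as a single plant (these pots are excluded by [filter_records()]
#' from the performance analysis, as in the original design).
#'
#' @param panel a [simulate_panel()] result.
#' @param config a [gi_config()]; defaults to the panel's own.
#' @return A data frame of plant-level records: `block`, `pot`, `position`,
#'   `genotype`, `neighbour_genotype`, `composition`, `shoot_mass_g`,
#'   `root_mass_g`.
#' @export
simulate_competition <- function(panel, config = panel$config) {
  config <- as_gi_config(config)
  stopifnot(inherits(panel, "gi_panel"))
  truth <- panel$truth
  testers <- truth$genotype[truth$role == "tester"]
  focals <- truth$genotype[truth$role == "focal"]
  if (length(testers) != config$n_tester)
    stop("panel and config disagree on the number of testers")

  # enumerate pots: per block, per focal, monoculture + one pot per tester
  blocks <- rep(seq_len(config$n_blocks),
                each = length(focals) * (length(testers) + 1L))
  foc <- rep(rep(focals, each = length(testers) + 1L), config$n_blocks)
  nb <- rep(c(NA_character_, testers), length(focals) * config$n_blocks)
  comp <- ifelse(is.na(nb), "monoculture", "mixture")
  nb[is.na(nb)] <- foc[is.na(nb)]
  pot <- sprintf("B%d_P%04d", blocks,
                 stats::ave(blocks, blocks, FUN = seq_along))

  # two plants per pot: plant 1 the focal, plant 2 the neighbour
  g1 <- foc; g2 <- nb
  rec <- data.frame(
    block = rep(blocks, 2L),
    pot = rep(pot, 2L),
    position = rep(1:2, each = length(pot)),
    genotype = c(g1, g2),
    neighbour_genotype = c(g2, g1),
    composition = rep(comp, 2L),
    stringsAsFactors = FALSE)

  if (isTRUE(config$include_singles)) {
    sb <- rep(seq_len(config$n_blocks), each = length(testers))
    singles <- data.frame(
      block = sb,
      pot = sprintf("B%d_S%02d", sb, rep(seq_along(testers), config$n_blocks)),
      position = 1L,
      genotype = rep(testers, config$n_blocks),
      neighbour_genotype = NA_character_,
      composition = "single",
      stringsAsFactors = FALSE)
    rec <- rbind(rec, singles)
  }

  idx <- match(rec$genotype, truth$genotype)
  nidx <- match(rec$neighbour_genotype, truth$genotype)
  s_neigh <- ifelse(is.na(nidx), 0, truth$competitiveness[nidx])

  with_table_seed(config, "competition", {
    u <- plant_predictor(truth$vigor[idx], truth$competitiveness[idx],
                         s_neigh, rec$block, config) +
      stats::rnorm(nrow(rec), 0, config$sigma_e)
    rec$shoot_mass_g <- saturate(u, config$b_max)
    rts <- config$rts_base * (1 - config$rts_allele_effect * truth$allele[idx]) *
      exp(stats::rnorm(nrow(rec), 0, config$rts_cv))
    rec$root_mass_g <- rec$shoot_mass_g * rts
  })
  rownames(rec) <- NULL
  rec
}

#' Simulate a monoculture density-gradient experiment
#'
#' Emulates monoculture stands sown at several target densities in pots of
#' fixed area, with early seedling mortality so that realized density falls
#' short of the sown density. Per-plant biomass follows a space-limited
#' response `(v + (theta_self - theta_neigh) * s) * A / (A + A0)` where `A`
#' is the realized ground area per individual; pot biomass is the realized
#' plant count times the per-plant value plus noise. Genotypes are a
#' stratified sample: cooperative-allele carriers matched by vigor with
#' alternative-allele carriers.
#'
#' @param panel a [simulate_panel()] result.
#' @param densities sown plants per pot (default the 3x3, 4x4, 5x5 grids).
#' @param config a [gi_config()].
#' @param n_carrier,n_noncarrier genotypes sampled per allele class.
#' @param reps replicate pots per genotype and density.
#' @return Data frame: `pot`, `genotype`, `allele` ("C" cooperative, "A"
#'   alternative), `sown_n`, `realized_n`, `area_per_individual_cm2`,
#'   `shoot_mass_g`, `mixture_covariate` (the genotype's expected individual
#'   mixture performance, used for stratified sampling in the design).
#' @export
simulate_density <- function(panel, densities = c(9L, 16L, 25L),
                             config = panel$config,
                             n_carrier = 6L, n_noncarrier = 7L, reps = 4L) {
  config <- as_gi_config(config)
  stopifnot(inherits(panel, "gi_panel"))
  if (length(densities) == 0) stop("'densities' must be nonempty")
  if (any(densities < 1 | densities != round(densities)))
    stop("'densities' must be positive integers")
  truth <- panel$truth
  testers <- truth$role == "tester"
  mean_s_test <- mean(truth$competitiveness[testers])

  with_table_seed(config, "density", {
    carriers <- truth[truth$allele == 1 & !testers, ]
    others <- truth[truth$allele == 0 & !testers, ]
    if (nrow(carriers) < n_carrier || nrow(others) < n_noncarrier)
      stop("panel too small for the requested stratified sample")
    carriers <- carriers[sample.int(nrow(carriers), n_carrier), ]
    # match non-carriers to carriers by vigor (stratified sampling by size)
    others <- others[order(abs(others$vigor - mean(carriers$vigor)))[
      seq_len(n_noncarrier)], ]
    sel <- rbind(carriers, others)

    grid <- expand.grid(genotype = sel$genotype, sown_n = densities,
                        rep = seq_len(reps), stringsAsFactors = FALSE)
    i <- match(grid$genotype, sel$genotype)
    died <- stats::rbinom(nrow(grid), grid$sown_n, config$mortality)
    realized <- pmax(grid$sown_n - died, 1L)
    A <- config$pot_area / realized
    per_plant <- (sel$vigor[i] +
                    (config$theta_self - config$theta_neigh) *
                      sel$competitiveness[i]) * A / (A + config$area_halfsat)
    pot_mass <- pmax(realized * per_plant +
                       stats::rnorm(nrow(grid), 0, config$sigma_e), 0.001)
    data.frame(
      pot = sprintf("D%04d", seq_len(nrow(grid))),
      genotype = grid$genotype,
      allele = ifelse(sel$allele[i] == 1, "C", "A"),
      sown_n = grid$sown_n,
      realized_n = realized,
      area_per_individual_cm2 = A,
      shoot_mass_g = pot_mass,
      mixture_covariate = sel$vigor[i] +
        config$theta_self * sel$competitiveness[i] -
        config$theta_neigh * mean_s_test,
      stringsAsFactors = FALSE)
  })
}

#' Simulate the near-isogenic-line payoff experiment
#'
#' For each genetic background, two near-isogenic lines — one carrying the
#' competitive (Sha) allele, one the cooperative (Bay) allele — are grown as
#' single plants, in monoculture pairs, and in mixture pairs. Single-plant
#' biomass is `Normal(v_bg, sigma_e^2)`; biomass under competition is the
#' single-plant expectation minus `theta_neigh` times the neighbour's
#' competitiveness, minus a disease penalty incurred only by Sha-allele
#' plants in susceptible backgrounds (`config$nil_penalty`), plus noise.
#' An ordinal root browning score in 0/1/2 is drawn from a cumulative-logit
#' model with allele, background and community effects.
#'
#' @param config a [gi_config()].
#' @return Data frame: `background`, `allele` (Bay/Sha), `neighbour_allele`
#'   (Bay/Sha/none), `community` (single/monoculture/mixture),
#'   `shoot_mass_g`, `root_score`, `blotching`.
#' @export
simulate_nil <- function(config = gi_config()) {
  config <- as_gi_config(config)
  bgs <- config$nil_backgrounds
  s_allele <- c(Bay = config$s0 - config$gamma_a, Sha = config$s0)

  rows <- list()
  for (bg in bgs) {
    for (al in c("Bay", "Sha")) {
      rows[[length(rows) + 1L]] <- data.frame(
        background = bg, allele = al, neighbour_allele = "none",
        community = "single", n = config$nil_n_single)
      rows[[length(rows) + 1L]] <- data.frame(
        background = bg, allele = al, neighbour_allele = al,
        community = "monoculture", n = 2L * config$nil_n_mono)
      rows[[length(rows) + 1L]] <- data.frame(
        background = bg, allele = al,
        neighbour_allele = setdiff(c("Bay", "Sha"), al),
        community = "mixture", n = config$nil_n_mix)
    }
  }
  cells <- do.call(rbind, rows)
  rec <- cells[rep(seq_len(nrow(cells)), cells$n),
               c("background", "allele", "neighbour_allele", "community")]
  rownames(rec) <- NULL

  penalty <- function(bg, al) {
    p <- config$nil_penalty[bg]
    p[is.na(p)] <- 0
    unname(p) * (al == "Sha")
  }

  with_table_seed(config, "nil", {
    mu <- unname(config$nil_v[rec$background])
    comp <- rec$community != "single"
    mu[comp] <- mu[comp] -
      config$theta_neigh * s_allele[rec$neighbour_allele[comp]] -
      penalty(rec$background[comp], rec$allele[comp])
    rec$shoot_mass_g <- pmax(mu + stats::rnorm(nrow(rec), 0, config$sigma_e),
                             0.001)

    eta <- config$score_allele_shift * (rec$allele == "Sha") +
      unname(config$score_bg_shift[rec$background]) +
      config$score_community_shift * comp
    p_le0 <- stats::plogis(config$score_cutpoints[1] - eta)
    p_le1 <- stats::plogis(config$score_cutpoints[2] - eta)
    u <- stats::runif(nrow(rec))
    rec$root_score <- ifelse(u <= p_le0, 0L, ifelse(u <= p_le1, 1L, 2L))
    rec$blotching <- stats::runif(nrow(rec)) < stats::plogis(eta - 3)
  })
  rec
}
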