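# End-to-end orchestration: simulate -> performance -> trade-off -> scan ->
# density -> payoff, with table validation, per-stage CSV outputs and a run
# manifest. CSV (RFC 4180, UTF-8, "." decimal) is the interchange dialect.

table_schemas <- list(
  competition = list(
    required = c("block", "pot", "genotype", "composition", "shoot_mass_g"),
    numeric = c("shoot_mass_g"),
    nonneg = c("shoot_mass_g", "root_mass_g"),
    levels = list(composition = c("monoculture", "mixture", "single"))),
  density = list(
    required = c("pot", "genotype", "allele", "sown_n", "realized_n",
                 "area_per_individual_cm2", "shoot_mass_g"),
    numeric = c("sown_n", "realized_n", "area_per_individual_cm2",
                "shoot_mass_g"),
    nonneg = c("sown_n", "realized_n", "area_per_individual_cm2",
               "shoot_mass_g"),
    levels = list(allele = c("A", "C"))),
  nil = list(
    required = c("background", "allele", "neighbour_allele", "community",
                 "shoot_mass_g"),
    numeric = c("shoot_mass_g"),
    nonneg = c("shoot_mass_g"),
    levels = list(community = c("single", "monoculture", "mixture"))),
  markers = list(required = character(), numeric = character(),
                 nonneg = character(), levels = list()),
  traits = list(required = c("genotype"), numeric = character(),
                nonneg = character(), levels = list()))

#' Validate a pipeline table against its schema
#'
#' Checks column presence, numeric typing, nonnegativity, and categorical
#' levels; for competition tables additionally that no pot holds more than
#' two plants and that mixture pots pair two distinct genotypes.
#'
#' @param x a data frame, or the path of a CSV file to read.
#' @param schema one of `"competition"`, `"density"`, `"nil"`, `"markers"`,
#'   `"traits"`.
#' @return List with `ok` (logical) and `violations` (data frame with
#'   columns `row`, `column`, `problem`; zero rows when valid).
#' @export
validate_table <- function(x, schema) {
  if (!schema %in% names(table_schemas))
    stop("unknown schema '", schema, "'; expected one of: ",
         paste(names(table_schemas), collapse = ", "))
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  sc <- table_schemas[[schema]]
  v <- list()
  add <- function(row, column, problem)
    v[[length(v) + 1L]] <<- data.frame(row = row, column = column,
                                       problem = problem,
                                       stringsAsFactors = FALSE)
  miss <- setdiff(sc$required, names(x))
  for (m in miss) add(NA_integer_, m, "missing column")
  for (col in intersect(sc$numeric, names(x))) {
    bad <- which(!is.na(x[[col]]) & !is.numeric(x[[col]]))
    if (!is.numeric(x[[col]])) add(NA_integer_, col, "not numeric")
    nas <- which(is.na(x[[col]]))
    for (i in nas) add(i, col, "missing value")
  }
  for (col in intersect(sc$nonneg, names(x))) {
    if (is.numeric(x[[col]]))
      for (i in which(!is.na(x[[col]]) & x[[col]] < 0))
        add(i, col, "negative value")
  }
  for (col in names(sc$levels)) {
    if (col %in% names(x))
      for (i in which(!x[[col]] %in% sc$levels[[col]]))
        add(i, col, paste0("invalid level '", x[[col]][i], "'"))
  }
  if (schema == "competition" && all(c("pot", "genotype") %in% names(x))) {
    n_per_pot <- table(x$pot)
    for (p in names(n_per_pot)[n_per_pot > 2])
      add(NA_integer_, "pot", paste0("pot '", p, "' has >2 plants"))
    if ("composition" %in% names(x)) {
      mix <- x[x$composition == "mixture", , drop = FALSE]
      same <- tapply(mix$genotype, mix$pot,
                     function(g) length(g) == 2 && g[1] == g[2])
      for (p in names(same)[which(same)])
        add(NA_integer_, "pot",
            paste0("mixture pot '", p, "' has identical genotypes"))
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(), column = character(), problem = character(),
               stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0, violations = violations)
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' `simulate` (panel + tables), `estimate` (performance points),
#' `tradeoff` (vigor curve and G-I values), `scan` (marker association),
#' `density` (mixed model along the density gradient) and `payoff`
#' (NIL payoff matrices, game classification, root-score model).
#' Per-stage CSVs, a log, and a manifest with file checksums are written to
#' `out_dir`. Runs are deterministic for a fixed config seed.
#'
#' @param config a [gi_config()] (its `seed` drives all stages).
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @param stages character subset of
#'   `c("simulate", "estimate", "tradeoff", "scan", "density", "payoff")`;
#'   later stages pull in the earlier ones they need.
#' @param maf_min minor-allele-frequency filter for the scan.
#' @return Invisibly, a list with the stage results and the `manifest`.
#' @export
run_pipeline <- function(config = gi_config(), out_dir = NULL,
                         stages = c("simulate", "estimate", "tradeoff",
                                    "scan", "density", "payoff"),
                         maf_min = 0.05) {
  config <- as_gi_config(config)
  all_stages <- c("simulate", "estimate", "tradeoff", "scan", "density",
                  "payoff")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # close over dependencies
  need <- function(s) s %in% stages
  if (need("payoff") || need("density") || need("scan") || need("tradeoff") ||
      need("estimate")) stages <- union(stages, "simulate")
  if (need("scan") || need("tradeoff")) stages <- union(stages, "estimate")
  if (need("scan")) stages <- union(stages, "tradeoff")
  stages <- all_stages[all_stages %in% stages]

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  files <- character()
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  out <- list(config = config)

  panel <- simulate_panel(config)
  note("panel: %d genotypes, %d markers", nrow(panel$truth),
       ncol(panel$markers))
  out$panel <- panel

  if (need("simulate")) {
    comp <- simulate_competition(panel, config)
    stopifnot(validate_table(comp, "competition")$ok)
    note("competition: %d plant records in %d pots", nrow(comp),
         length(unique(comp$pot)))
    out$competition <- comp
    if (!is.null(out_dir)) {
      files <- c(files, write_stage_csv(comp, out_dir, "competition"))
      mk <- data.frame(genotype = rownames(panel$markers),
                       panel$markers, check.names = FALSE)
      files <- c(files, write_stage_csv(mk, out_dir, "markers"))
    }
  }
  if (need("estimate")) {
    flt <- filter_records(out$competition)
    note("filter: %d records kept, %d pots excluded", nrow(flt$records),
         nrow(flt$log))
    testers <- panel$truth$genotype[panel$truth$role == "tester"]
    perf <- genotype_performance(flt$records, testers)
    tet <- tester_effect_test(flt$records, testers)
    note("tester effect: F(%d,%d) = %.2f, slope %.3f", tet$df[1], tet$df[2],
         tet$F, tet$slope)
    out$performance <- perf; out$tester_effect <- tet
    out$exclusions <- flt$log
    if (!is.null(out_dir)) {
      files <- c(files, write_stage_csv(perf, out_dir, "performance"))
      files <- c(files, write_stage_csv(flt$log, out_dir, "exclusions"))
    }
  }
  if (need("tradeoff")) {
    fit <- gi_tradeoff(out$performance)
    note("vigor curve: quadratic F(%d,%d) = %.2f", fit$quad_df[1],
         fit$quad_df[2], fit$quad_F)
    out$tradeoff <- fit
    if (!is.null(out_dir))
      files <- c(files, write_stage_csv(fit$values, out_dir, "gi_values"))
  }
  if (need("scan")) {
    trait <- stats::setNames(out$tradeoff$values$gi_value,
                             out$tradeoff$values$genotype)
    sc <- gi_scan(trait, panel$markers, maf_min = maf_min)
    top <- sc[which.min(sc$p), ]
    note("scan: %d markers tested, top %s (p = %.3g, r2 = %.3f)",
         sum(sc$testable), top$marker, top$p, top$r2)
    out$scan <- sc
    if (!is.null(out_dir))
      files <- c(files, write_stage_csv(sc, out_dir, "scan"))
  }
  if (need("density")) {
    dens <- simulate_density(panel, config = config)
    excl <- exclude_overdense(dens)
    mod <- fit_density_model(excl$records)
    out$density <- excl$records
    out$density_model <- mod
    note("density: %d pots, %s fit", nrow(excl$records),
         if (mod$fallback) "fixed-effects fallback" else "mixed-model")
    if (!is.null(out_dir))
      files <- c(files, write_stage_csv(excl$records, out_dir, "density"))
  }
  if (need("payoff")) {
    nil <- simulate_nil(config)
    stopifnot(validate_table(nil, "nil")$ok)
    mats <- lapply(config$nil_backgrounds, function(bg)
      payoff_matrix(nil, bg))
    names(mats) <- config$nil_backgrounds
    games <- lapply(mats, classify_game)
    rs <- root_score_model(nil)
    note("payoff: %d backgrounds, allele score coef %.2f (p = %.3g)",
         length(mats), rs$allele_coef, rs$allele_p)
    out$nil <- nil; out$payoff <- mats; out$games <- games
    out$root_score <- rs
    if (!is.null(out_dir)) {
      files <- c(files, write_stage_csv(nil, out_dir, "nil"))
      pm <- do.call(rbind, lapply(mats, function(m)
        data.frame(background = m$background,
                   focal = rep(m$alleles, 2),
                   neighbour = rep(m$alleles, each = 2),
                   reduction = as.vector(m$reduction),
                   sem = as.vector(m$sem), n = as.vector(m$n))))
      files <- c(files, write_stage_csv(pm, out_dir, "payoff_matrices"))
    }
  }

  manifest <- list(seed = config$seed, stages = stages,
                   files = if (length(files))
                     data.frame(file = basename(files),
                                md5 = unname(tools::md5sum(files)),
                                stringsAsFactors = FALSE)
                   else NULL)
  out$manifest <- manifest
  out$log <- log
  if (!is.null(out_dir)) {
    writeLines(log, file.path(out_dir, "run.log"))
    mf <- c(sprintf("seed: %d", manifest$seed),
            sprintf("stages: %s", paste(stages, collapse = ", ")),
            if (!is.null(manifest$files))
              sprintf("%s  %s", manifest$files$md5, manifest$files$file))
    writeLines(mf, file.path(out_dir, "manifest.txt"))
  }
  invisible(out)
}
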