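mk_rec <- function(pot, genotype, mass, composition, block = 1,
                   neighbour = NA_character_) {
  data.frame(block = block, pot = pot, position = 1L, genotype = genotype,
             neighbour_genotype = neighbour, composition = composition,
             shoot_mass_g = mass, stringsAsFactors = FALSE)
}

test_that("exclusion rules drop singles and dead-plant pots", {
  rec <- rbind(
    mk_rec(c("p1", "p1"), c("A", "T1"), c(1.0, 1.2), "mixture",
           neighbour = c("T1", "A")),
    mk_rec("p2", "T1", 0.8, "single"),
    mk_rec(c("p3", "p3"), c("B", "T1"), c(NA, 1.1), "mixture",
           neighbour = c("T1", "B")))
  out <- filter_records(rec)
  expect_equal(unique(out$records$pot), "p1")
  expect_equal(nrow(out$log), 2)
  expect_setequal(out$log$pot, c("p2", "p3"))
  expect_equal(sort(out$log$reason), sort(c("single plant", "dead plant")))

  # empty input round-trips
  empty <- filter_records(rec[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$log), 0)

  # >2 plants in a pot is a data-integrity error
  bad <- rbind(rec, mk_rec("p1", "C", 0.5, "mixture", neighbour = "T1"))
  expect_error(filter_records(bad), "more than two")
})

test_that("randomly marked dead pots are excluded exactly", {
  cfg <- gi_config(n_focal = 30, n_tester = 3, n_markers = 5, seed = 6)
  p <- simulate_panel(cfg)
  rec <- simulate_competition(p, cfg)
  rec <- rec[rec$composition != "single", ]
  pots <- unique(rec$pot)
  set.seed(42)
  dead <- sample(pots, round(0.05 * length(pots)))
  # kill one plant in each chosen pot
  kill <- which(rec$pot %in% dead & rec$position == 1L)
  rec$shoot_mass_g[kill] <- NA
  out <- filter_records(rec)
  expect_equal(length(unique(out$records$pot)), length(pots) - length(dead))
  expect_setequal(out$log$pot, dead)
})

test_that("LS means: single block reduces to arithmetic means", {
  rec <- rbind(
    mk_rec(c("p1", "p1"), c("A", "T1"), c(2, 9), "mixture", 1, c("T1", "A")),
    mk_rec(c("p2", "p2"), c("A", "T2"), c(4, 9), "mixture", 1, c("T2", "A")),
    mk_rec(c("p3", "p3"), c("B", "T1"), c(5, 9), "mixture", 1, c("T1", "B")))
  x <- mixture_ls_means(rec, c("T1", "T2"))
  expect_equal(unname(x["A"]), 3)
  expect_equal(unname(x["B"]), 5)
})

test_that("LS means: balanced blocks recover additive offsets", {
  rec <- rbind(
    mk_rec(c("p1", "p1"), c("A", "T1"), c(2, 1), "mixture", 1, c("T1", "A")),
    mk_rec(c("p2", "p2"), c("A", "T1"), c(3, 1), "mixture", 2, c("T1", "A")),
    mk_rec(c("p3", "p3"), c("B", "T1"), c(4, 1), "mixture", 1, c("T1", "B")),
    mk_rec(c("p4", "p4"), c("B", "T1"), c(5, 1), "mixture", 2, c("T1", "B")))
  x <- mixture_ls_means(rec, "T1")
  expect_equal(unname(x["A"]), 2.5)
  expect_equal(unname(x["B"]), 4.5)
})

test_that("LS means match the normal-equations oracle on an unbalanced design", {
  rec <- rbind(
    mk_rec(c("p1", "p1"), c("A", "T1"), c(2.0, 1), "mixture", 1, c("T1", "A")),
    mk_rec(c("p2", "p2"), c("A", "T1"), c(2.4, 1), "mixture", 1, c("T1", "A")),
    mk_rec(c("p3", "p3"), c("A", "T1"), c(3.1, 1), "mixture", 2, c("T1", "A")),
    mk_rec(c("p4", "p4"), c("B", "T1"), c(4.2, 1), "mixture", 2, c("T1", "B")),
    mk_rec(c("p5", "p5"), c("B", "T1"), c(3.9, 1), "mixture", 1, c("T1", "B")),
    mk_rec(c("p6", "p6"), c("B", "T1"), c(4.4, 1), "mixture", 2, c("T1", "B")))
  x <- mixture_ls_means(rec, "T1")
  focal <- rec[rec$genotype %in% c("A", "B"), ]
  oracle <- lsmeans_oracle(focal$shoot_mass_g, focal$block, focal$genotype)
  expect_equal(unname(x[c("A", "B")]), unname(oracle[c("A", "B")]),
               tolerance = 1e-10)
})

test_that("monoculture means halve the pot total and average over pots", {
  rec <- rbind(
    mk_rec(c("m1", "m1"), "A", c(0.8, 1.2), "monoculture", 1, "A"),
    mk_rec(c("m2", "m2"), "A", c(1.0, 1.0), "monoculture", 1, "A"))
  expect_equal(unname(monoculture_means(rec)["A"]), 1.0)
  expect_equal(unname(monoculture_means(rec[1:2, ])["A"]), 1.0)
})

test_that("noise-free generator monocultures match the saturating closed form", {
  cfg <- gi_config(n_focal = 6, n_tester = 2, n_blocks = 1, n_markers = 5,
                   sigma_e = 0, sigma_v = 0, sigma_s = 0, seed = 8,
                   include_singles = FALSE)
  p <- simulate_panel(cfg)
  rec <- simulate_competition(p, cfg)
  y <- monoculture_means(rec)
  u <- cfg$mu_v + (cfg$theta_self - cfg$theta_neigh) * cfg$s0
  expected <- cfg$b_max * u / (cfg$b_max + u)
  g0 <- p$truth$genotype[p$truth$allele == 0 & p$truth$role == "focal"]
  expect_equal(unname(y[g0]), rep(expected, length(g0)), tolerance = 1e-12)
})

test_that("performance points are location-equivariant and order-invariant", {
  cfg <- gi_config(n_focal = 15, n_tester = 3, n_markers = 5, seed = 10)
  p <- simulate_panel(cfg)
  testers <- p$truth$genotype[p$truth$role == "tester"]
  rec <- filter_records(simulate_competition(p, cfg))$records
  perf <- genotype_performance(rec, testers)

  shifted <- rec
  shifted$shoot_mass_g <- shifted$shoot_mass_g + 0.7
  perf_s <- genotype_performance(shifted, testers)
  expect_equal(perf_s$x, perf$x + 0.7, tolerance = 1e-10)
  expect_equal(perf_s$y, perf$y + 0.7, tolerance = 1e-10)

  set.seed(1)
  perm <- rec[sample.int(nrow(rec)), ]
  perf_p <- genotype_performance(perm, testers)
  expect_equal(perf_p[order(perf_p$genotype), ],
               perf[order(perf$genotype), ], ignore_attr = TRUE)
})

test_that("tester effect: perfect signal gives a negative slope", {
  testers <- c("T1", "T2")
  rec <- rbind(
    mk_rec(c("p1", "p1"), c("A", "T1"), c(2.0, 1.0), "mixture", 1, c("T1", "A")),
    mk_rec(c("p2", "p2"), c("B", "T1"), c(2.1, 1.0), "mixture", 1, c("T1", "B")),
    mk_rec(c("p3", "p3"), c("C", "T1"), c(1.9, 1.0), "mixture", 1, c("T1", "C")),
    mk_rec(c("p4", "p4"), c("A", "T2"), c(1.0, 2.0), "mixture", 1, c("T2", "A")),
    mk_rec(c("p5", "p5"), c("B", "T2"), c(1.1, 2.0), "mixture", 1, c("T2", "B")),
    mk_rec(c("p6", "p6"), c("C", "T2"), c(0.9, 2.0), "mixture", 1, c("T2", "C")))
  out <- tester_effect_test(rec, testers)
  expect_lt(out$slope, 0)
  expect_lt(out$p, 0.01)
  expect_error(tester_effect_test(rec, "T1"), "two testers")
})

test_that("tester effect F matches the two-model RSS oracle", {
  cfg <- gi_config(n_focal = 10, n_tester = 2, n_markers = 5, seed = 12)
  p <- simulate_panel(cfg)
  testers <- p$truth$genotype[p$truth$role == "tester"]
  rec <- filter_records(simulate_competition(p, cfg))$records
  out <- tester_effect_test(rec, testers)

  t_rows <- rec$genotype %in% testers
  t_mean <- tapply(rec$shoot_mass_g[t_rows], rec$genotype[t_rows], mean)
  rows <- rec[rec$composition == "mixture" & !(rec$genotype %in% testers), ]
  tm <- unname(t_mean[rows$neighbour_genotype])
  Xf <- cbind(1, rows$block == 2, tm)
  Xr <- cbind(1, rows$block == 2)
  expect_equal(out$F, rss_F_oracle(rows$shoot_mass_g, Xf, Xr),
               tolerance = 1e-10)
})
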