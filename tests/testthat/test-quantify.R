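test_that("counts, densities and proportions follow the definitions", {
  g <- make_gated(c(T_cell = 91, Cytotoxic_T = 80,
                    Exhausted_cytotoxic_T = 29, Macrophage = 30,
                    Other = 20))
  s <- summarize_samples(g, make_meta(area = 1))
  expect_equal(s$n_cd3, 200)
  expect_equal(s$n_cd8, 109)
  expect_equal(s$p_cd8_cd3, 0.545)
  expect_equal(s$density_cd68, 30)            # 30 macrophages on 1 mm^2
  expect_equal(s$p_pd1cd8_cd8, 29 / 109)
  expect_equal(s$n_total, 250)
  # partition conservation: phenotype counts sum to all DAPI+ cells
  expect_equal(sum(table(g$phenotype)), s$n_total)
  # sanity ordering of nested proportions
  expect_lte(s$p_pd1cd8_all, s$p_pd1cd8_cd8)
})

test_that("zero-denominator proportions are undefined, not zero", {
  g <- make_gated(c(T_cell = 10, Other = 5))
  s <- summarize_samples(g, make_meta(area = 1))
  expect_true(is.na(s$p_pdl1cd68_cd68))
  expect_true(is.na(s$p_cd8_cd3) == FALSE)    # defined: 0 of 10
  expect_equal(s$p_cd8_cd3, 0)
  expect_true(is.na(s$ratio_foxp3_cd8))       # no CD8 denominator
})

test_that("proportions are scale-free and densities follow the area", {
  core <- simulate_core(light_comp(), intensity_model(), seed = 23)
  nc <- simulate_negative_control(intensity_model(), 500, seed = 24)
  thr <- estimate_thresholds(nc, 0.99)
  g <- gate_cells(core$table, thr)
  meta <- core$table$meta
  s1 <- summarize_samples(g, meta)
  g2 <- g
  g2$x_um <- g2$x_um * 2
  g2$y_um <- g2$y_um * 2
  meta2 <- meta
  meta2$tissue_area_mm2 <- meta2$tissue_area_mm2 * 4
  s2 <- summarize_samples(g2, meta2)
  props <- grep("^p_", names(s1), value = TRUE)
  expect_equal(s2[, props], s1[, props])
  dens <- grep("^density_", names(s1), value = TRUE)
  expect_equal(as.numeric(s2[, dens]), as.numeric(s1[, dens]) / 4)
})

test_that("convex-hull area is used when metadata area is missing", {
  g <- make_gated(c(Other = 4))
  g$x_um <- c(0, 1000, 1000, 0)
  g$y_um <- c(0, 0, 1000, 1000)       # 1 mm^2 square
  meta <- make_meta(area = NA_real_)
  s <- summarize_samples(g, meta)
  expect_equal(s$tissue_area_mm2, 1)
  expect_error(summarize_samples(g[1:2, ], meta), "area")
})

test_that("group comparison reproduces the closed-form Student t", {
  r <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(1, 2, 3); b <- a + 10
  r <- compare_groups(a, b)
  sp <- sqrt((var(a) + var(b)) / 2)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(r$t, t_manual)
  expect_lt(r$p, 0.001)
  expect_equal(r$sem_a, sd(a) / sqrt(3))

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("planted tumor CD3 deficit is detected across replicate cohorts", {
  # the generator's density layer at preset effect size and cohort shape:
  # CD3 pool 255/mm^2 in tumor vs 320/mm^2 in adjacent normal, per-patient
  # log-normal jitter sd 0.3, Poisson counts on a 1.5 mm core
  p <- tma_preset()
  area <- pi * 0.75^2
  d_tum <- sum(p$tumor_comp$densities[c("t_helper", "t_cytotoxic", "treg")])
  d_nor <- sum(p$normal_comp$densities[c("t_helper", "t_cytotoxic", "treg")])
  expect_lt(d_tum, d_nor)
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    tum <- rpois(84, d_tum * area * rlnorm(84, 0, 0.3)) / area
    nor <- rpois(73, d_nor * area * rlnorm(73, 0, 0.3)) / area
    cmp <- compare_groups(tum, nor)
    cmp$p < 0.05 && cmp$mean_a < cmp$mean_b
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("cross-method correlation recovers exact linear relations", {
  a <- c(1, 3, 5, 7, 11)
  # exact relations make lm warn about a perfect fit; that is the point here
  r <- suppressWarnings(cross_method_correlation(a, 2 * a))
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_true(r$slope_ci[1] <= 2 && 2 <= r$slope_ci[2])
  expect_equal(suppressWarnings(cross_method_correlation(a, -a))$r, -1)
  expect_warning(rz <- cross_method_correlation(a, rep(1, 5)), "variance")
  expect_true(is.na(rz$r))
  expect_error(cross_method_correlation(1:2, 1:2), "3 complete pairs")
})

test_that("gated densities track ground-truth densities across cores", {
  nc <- simulate_negative_control(intensity_model(), 1000, seed = 40)
  thr <- estimate_thresholds(nc, 0.99)
  gated_d <- truth_d <- numeric(12)
  for (i in 1:12) {
    set.seed(200 + i)
    comp <- composition_params(
      densities = c(tumor = 0, t_helper = 50 * rlnorm(1, 0, 0.5),
                    t_cytotoxic = 100, treg = 20,
                    macrophage = 150, other = 200) * rlnorm(6, 0, 0.4),
      p_pd1_given_cd8 = 0.35, p_pdl1_given_cd68 = 0.3)
    core <- simulate_core(comp, intensity_model(), seed = 300 + i)
    g <- gate_cells(core$table, thr)
    s <- summarize_samples(g, core$table$meta)
    gated_d[i] <- s$density_cd3
    truth_d[i] <- sum(core$truth$cd3) / core$table$meta$tissue_area_mm2
  }
  r <- cross_method_correlation(gated_d, truth_d)
  expect_gt(r$r, 0.95)
})
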