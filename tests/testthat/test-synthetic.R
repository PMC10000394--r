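test_that("cell counts are Poisson with mean density x core area", {
  # total density 500/mm^2 on a 1.5 mm disc: mean count 500 * pi * 0.75^2
  comp <- composition_params(
    densities = c(tumor = 0, t_helper = 0, t_cytotoxic = 0, treg = 0,
                  macrophage = 0, other = 500))
  counts <- vapply(1:100, function(s) {
    nrow(simulate_core(comp, intensity_model(), seed = s)$table$cells)
  }, numeric(1L))
  expected <- 500 * pi * 0.75^2
  se <- sqrt(expected / 100)          # Poisson mean over 100 seeds
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("all generated coordinates lie on the core disc", {
  for (s in c(1, 2)) {
    core <- simulate_core(light_comp(), intensity_model(),
                          attraction_params(10, 15), seed = s)
    r <- 750
    expect_true(all((core$table$cells$x_um - r)^2 +
                      (core$table$cells$y_um - r)^2 <= r^2 + 1e-9))
  }
})

test_that("attraction pulls PD-1+CD8+ cells toward PD-L1+CD68+ macrophages", {
  closer <- vapply(1:100, function(s) {
    mean_nn <- function(kappa) {
      core <- simulate_core(light_comp(), intensity_model(),
                            attraction_params(kappa, 15), seed = s)
      tr <- core$truth
      q <- as.matrix(core$table$cells[tr$cd3 & tr$cd8 & tr$pd1,
                                      c("x_um", "y_um")])
      r <- as.matrix(core$table$cells[tr$cd68 & tr$pdl1,
                                      c("x_um", "y_um")])
      if (nrow(q) == 0L || nrow(r) == 0L) return(NA_real_)
      mean(brute_nn(q, r))
    }
    mean_nn(10) < mean_nn(0)
  }, logical(1L))
  expect_gte(sum(closer, na.rm = TRUE), 95)
})

test_that("with no attraction the PD-1+CD8+ pattern is consistent with CSR", {
  # Clark-Evans index of the generated pattern vs the same index for
  # directly simulated uniform points (shared edge-effect bias), averaged
  # over seeds
  ce <- function(xy, area) {
    d <- vapply(seq_len(nrow(xy)), function(i) {
      min(sqrt((xy[-i, 1L] - xy[i, 1L])^2 + (xy[-i, 2L] - xy[i, 2L])^2))
    }, numeric(1L))
    mean(d) / (0.5 / sqrt(nrow(xy) / area))
  }
  area <- pi * 750^2
  gen <- oracle <- numeric(30)
  for (s in 1:30) {
    core <- simulate_core(light_comp(), intensity_model(),
                          attraction_params(0), seed = s)
    tr <- core$truth
    xy <- as.matrix(core$table$cells[tr$cd3 & tr$cd8 & tr$pd1,
                                     c("x_um", "y_um")])
    gen[s] <- ce(xy, area)
    set.seed(10000 + s)
    rr <- 750 * sqrt(runif(nrow(xy)))
    th <- runif(nrow(xy), 0, 2 * pi)
    oracle[s] <- ce(cbind(750 + rr * cos(th), 750 + rr * sin(th)), area)
  }
  se <- sqrt(var(gen) / 30 + var(oracle) / 30)
  expect_lt(abs(mean(gen) - mean(oracle)), 3 * se)
})

test_that("negative control matches the log-normal negative model", {
  im <- intensity_model()
  nc <- simulate_negative_control(im, 100, seed = 3)
  expect_equal(nrow(nc$cells), 100L)
  expect_equal(nc$meta$tissue_class, "negative_control")

  big <- simulate_negative_control(im, 20000, seed = 4)
  q99 <- quantile(big$cells$cd8, 0.99, type = 7, names = FALSE)
  expected <- exp(im$neg_log_mean + 2.326 * im$neg_log_sd)
  expect_lt(abs(q99 - expected) / expected, 0.05)

  expect_error(simulate_negative_control(im, 0), "positive")
})

test_that("fixed seeds make cores and cohorts fully reproducible", {
  a <- simulate_negative_control(intensity_model(), 500, seed = 11)
  b <- simulate_negative_control(intensity_model(), 500, seed = 11)
  expect_identical(a$cells, b$cells)

  p <- tma_preset()
  p$n_patients <- 3L; p$n_normal <- 2L; p$nc_cells <- 200L
  p$tumor_comp <- light_comp()
  p$normal_comp <- light_comp(0.15, 0.10)
  s1 <- simulate_cohort(p, seed = 9)
  s2 <- simulate_cohort(p, seed = 9)
  expect_identical(s1$tables$cells, s2$tables$cells)
  expect_identical(s1$patients, s2$patients)
  # distinct per-patient samples, paired normals, one negative control
  expect_setequal(unique(s1$tables$meta$tissue_class),
                  c("tumor", "adjacent_normal", "negative_control"))
  expect_equal(sum(s1$tables$meta$tissue_class == "tumor"), 3L)
  expect_equal(sum(s1$tables$meta$tissue_class == "adjacent_normal"), 2L)
})

test_that("patient simulator enforces parameters and plants correlation", {
  expect_error(simulate_patients(1), ">= 2")
  expect_error(simulate_patients(10, rho = 1), "rho")
  pat <- simulate_patients(2000, rho = 0.8, seed = 2)
  expect_gt(cor(pat$p_pd1_cd8_true, pat$p_pdl1_cd68_true), 0.6)
  expect_true(all(pat$survival_months > 0))
  # planted cluster covariate shifts the hazard
  patc <- simulate_patients(2000, cluster_log_hr = log(2), seed = 3)
  expect_true("cluster" %in% names(patc))
  rate <- function(k) sum(patc$event[patc$cluster == k]) /
    sum(patc$survival_months[patc$cluster == k])
  expect_gt(rate(1) / rate(0), 1.5)
})

test_that("attraction without a reference population is a parameter error", {
  comp <- composition_params(
    densities = c(tumor = 0, t_helper = 0, t_cytotoxic = 100, treg = 0,
                  macrophage = 0, other = 0),
    p_pd1_given_cd8 = 0.5)
  expect_error(simulate_core(comp, intensity_model(),
                             attraction_params(5, 15), seed = 1),
               "reference")
  expect_error(simulate_core(light_comp(), intensity_model(),
                             diameter_mm = 0, seed = 1), "diameter")
})
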