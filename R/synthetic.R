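#' Parameter objects for the synthetic TMA generator
#'
#' The generator draws per-cell fluorescence intensities from a two-component
#' log-normal mixture: cells truly negative for a marker draw from the
#' negative component, truly positive cells from a brighter positive
#' component. `separation` is the fold change between positive and negative
#' geometric means (positive meanlog = negative meanlog + log(separation)).
#'
#' @param neg_log_mean,neg_log_sd meanlog/sdlog of the negative component
#'   (log arbitrary-units scale).
#' @param separation positive/negative geometric-mean ratio (> 1).
#' @param pos_log_sd sdlog of the positive component.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(neg_log_mean = log(100), neg_log_sd = 0.5,
                            separation = 20, pos_log_sd = 0.5) {
  stopifnot(separation > 1, neg_log_sd > 0, pos_log_sd > 0)
  structure(list(neg_log_mean = neg_log_mean, neg_log_sd = neg_log_sd,
                 pos_log_mean = neg_log_mean + log(separation),
                 pos_log_sd = pos_log_sd),
            class = "intensity_model")
}

#' @description `composition_params()` fixes the expected density of each
#' base phenotype on a core (cells/mm^2) and the functional fractions:
#' the probability that a CD8+ T cell is PD-1+, that a CD68+ macrophage is
#' PD-L1+, and that a tumor cell is PD-L1+.
#'
#' @param densities named numeric vector of expected densities (cells/mm^2)
#'   with names `tumor`, `t_helper` (CD3+CD8-FOXP3-), `t_cytotoxic`
#'   (CD3+CD8+), `treg` (CD3+FOXP3+), `macrophage` (CD68+), `other`.
#' @param p_pd1_given_cd8 probability a CD8+ T cell expresses PD-1.
#' @param p_pdl1_given_cd68 probability a CD68+ macrophage expresses PD-L1.
#' @param p_pdl1_given_tumor probability a tumor cell expresses PD-L1.
#' @rdname intensity_model
#' @export
composition_params <- function(densities, p_pd1_given_cd8 = 0,
                               p_pdl1_given_cd68 = 0,
                               p_pdl1_given_tumor = 0) {
  need <- c("tumor", "t_helper", "t_cytotoxic", "treg", "macrophage",
            "other")
  stopifnot(all(need %in% names(densities)), all(densities >= 0),
            p_pd1_given_cd8 >= 0, p_pd1_given_cd8 <= 1,
            p_pdl1_given_cd68 >= 0, p_pdl1_given_cd68 <= 1,
            p_pdl1_given_tumor >= 0, p_pdl1_given_tumor <= 1)
  structure(list(densities = densities[need],
                 p_pd1_given_cd8 = p_pd1_given_cd8,
                 p_pdl1_given_cd68 = p_pdl1_given_cd68,
                 p_pdl1_given_tumor = p_pdl1_given_tumor),
            class = "composition_params")
}

#' @description `attraction_params()` controls the Thomas-like spatial
#' attraction of PD-1+CD8+ T cells toward PD-L1+CD68+ macrophages: a
#' fraction `strength / (1 + strength)` of the PD-1+CD8+ cells is placed at
#' Gaussian offsets (sd `scale_um`) from randomly chosen PD-L1+CD68+ cells;
#' `strength = 0` leaves the subset completely spatially random.
#'
#' @param strength dimensionless attraction strength (kappa >= 0).
#' @param scale_um dispersion (micrometres) of attracted placements.
#' @rdname intensity_model
#' @export
attraction_params <- function(strength = 0, scale_um = 15) {
  stopifnot(strength >= 0, scale_um > 0)
  structure(list(strength = strength, scale_um = scale_um),
            class = "attraction_params")
}

#' @description `survival_model()` parameterizes the exponential
#' proportional-hazards model used to draw overall-survival times: hazard
#' `baseline_rate * exp(beta %*% (z - z_ref))` with covariates z = (true
#' p(PD-1+|CD8+), true p(PD-L1+|CD68+), age in years, male indicator,
#' stage 1-4) centred at the reference patient z_ref = (0.35, 0.30, 65,
#' female, stage 2), so `baseline_rate` is the hazard of that reference
#' patient. Censoring is exponential and truncated at `max_followup`.
#'
#' @param baseline_rate reference-patient event rate (events/month).
#' @param beta named log-hazard coefficients, names `p_pd1_cd8`,
#'   `p_pdl1_cd68`, `age`, `sexM`, `stage`.
#' @param censoring_rate censoring rate (events/month; 0 = administrative
#'   censoring at `max_followup` only).
#' @param max_followup maximum follow-up (months).
#' @rdname intensity_model
#' @export
survival_model <- function(baseline_rate = 0.035,
                           beta = c(p_pd1_cd8 = 2, p_pdl1_cd68 = 2,
                                    age = 0.02, sexM = 0, stage = 0.3),
                           censoring_rate = 0.035, max_followup = 60) {
  need <- c("p_pd1_cd8", "p_pdl1_cd68", "age", "sexM", "stage")
  stopifnot(baseline_rate > 0, censoring_rate >= 0, max_followup > 0,
            all(need %in% names(beta)))
  structure(list(baseline_rate = baseline_rate, beta = beta[need],
                 censoring_rate = censoring_rate,
                 max_followup = max_followup),
            class = "survival_model")
}

.substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629 + 1)
}

.disc_uniform <- function(n, radius_um) {
  r <- radius_um * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = radius_um + r * cos(th), y = radius_um + r * sin(th))
}

.draw_intensities <- function(truth, im) {
  n <- nrow(truth)
  out <- matrix(0, n, length(marker_names()),
                dimnames = list(NULL, marker_names()))
  for (m in marker_names()) {
    pos <- truth[, m]
    v <- numeric(n)
    v[pos] <- rlnorm(sum(pos), im$pos_log_mean, im$pos_log_sd)
    v[!pos] <- rlnorm(sum(!pos), im$neg_log_mean, im$neg_log_sd)
    out[, m] <- v
  }
  out
}

#' Simulate one tissue-microarray core
#'
#' Draws a synthetic 1.5 mm TMA core: phenotype counts are Poisson with mean
#' density x core area, cells are uniform on the core disc, and — when
#' `attr$strength > 0` — a fraction `strength/(1+strength)` of the PD-1+CD8+
#' T cells is re-placed at Gaussian offsets (sd `attr$scale_um`) from
#' randomly chosen PD-L1+CD68+ macrophages (offsets rejected-resampled to
#' stay on the disc). Intensities come from the log-normal mixture in `im`;
#' every cell is DAPI-positive.
#'
#' @param comp a [composition_params()].
#' @param im an [intensity_model()].
#' @param attr an [attraction_params()].
#' @param diameter_mm core diameter in millimetres (default 1.5).
#' @param seed integer RNG seed (fully determines the core).
#' @param sample_id,patient_id,tissue_class metadata for the generated core.
#' @return A list with elements `table` (a [cell_table()]) and `truth`
#'   (data.frame of per-cell true marker positivity and true phenotype
#'   label).
#' @export
simulate_core <- function(comp, im, attr = attraction_params(0),
                          diameter_mm = 1.5, seed = 1, sample_id = "S1",
                          patient_id = NA, tissue_class = "tumor") {
  stopifnot(inherits(comp, "composition_params"),
            inherits(im, "intensity_model"),
            inherits(attr, "attraction_params"))
  if (diameter_mm <= 0) stop("core diameter must be positive", call. = FALSE)
  wants_pd1cd8 <- comp$densities[["t_cytotoxic"]] > 0 &&
    comp$p_pd1_given_cd8 > 0
  has_ref <- comp$densities[["macrophage"]] > 0 && comp$p_pdl1_given_cd68 > 0
  if (attr$strength > 0 && wants_pd1cd8 && !has_ref) {
    stop("attraction requested but no PD-L1+CD68+ reference population ",
         "(macrophage density or p_pdl1_given_cd68 is zero)", call. = FALSE)
  }
  set.seed(seed)
  radius_um <- diameter_mm * 1000 / 2
  area_mm2 <- pi * (diameter_mm / 2)^2
  counts <- vapply(comp$densities, function(d) rpois(1L, d * area_mm2),
                   integer(1L))
  base <- rep(names(counts), counts)
  n <- length(base)

  mk <- marker_names()
  truth <- matrix(FALSE, n, length(mk), dimnames = list(NULL, mk))
  truth[, "dapi"] <- TRUE
  truth[, "cd3"] <- base %in% c("t_helper", "t_cytotoxic", "treg")
  truth[, "cd8"] <- base == "t_cytotoxic"
  truth[, "foxp3"] <- base == "treg"
  truth[, "cd68"] <- base == "macrophage"
  truth[, "tumor_marker"] <- base == "tumor"
  truth[base == "t_cytotoxic", "pd1"] <-
    runif(sum(base == "t_cytotoxic")) < comp$p_pd1_given_cd8
  truth[base == "macrophage", "pdl1"] <-
    runif(sum(base == "macrophage")) < comp$p_pdl1_given_cd68
  truth[base == "tumor", "pdl1"] <-
    runif(sum(base == "tumor")) < comp$p_pdl1_given_tumor

  xy <- .disc_uniform(n, radius_um)
  if (attr$strength > 0 && n > 0) {
    refs <- which(truth[, "cd68"] & truth[, "pdl1"])
    qry <- which(truth[, "cd8"] & truth[, "pd1"])
    if (length(refs) > 0L && length(qry) > 0L) {
      p_att <- attr$strength / (1 + attr$strength)
      att <- qry[runif(length(qry)) < p_att]
      if (length(att) > 0L) {
        parent <- refs[sample.int(length(refs), length(att), replace = TRUE)]
        px <- xy[parent, 1L]
        py <- xy[parent, 2L]
        nx <- px + rnorm(length(att), 0, attr$scale_um)
        ny <- py + rnorm(length(att), 0, attr$scale_um)
        out <- (nx - radius_um)^2 + (ny - radius_um)^2 > radius_um^2
        iter <- 0L
        while (any(out) && iter < 1000L) {
          k <- which(out)
          nx[k] <- px[k] + rnorm(length(k), 0, attr$scale_um)
          ny[k] <- py[k] + rnorm(length(k), 0, attr$scale_um)
          out <- (nx - radius_um)^2 + (ny - radius_um)^2 > radius_um^2
          iter <- iter + 1L
        }
        # parents are interior points, so resampling terminates in practice;
        # any stragglers fall back to their uniform position
        keep <- !out
        xy[att[keep], 1L] <- nx[keep]
        xy[att[keep], 2L] <- ny[keep]
      }
    }
  }

  inten <- .draw_intensities(truth, im)
  cells <- data.frame(sample_id = rep(sample_id, n),
                      cell_id = sprintf("c%05d", seq_len(max(n, 0L))[seq_len(n)]),
                      x_um = xy[, 1L], y_um = xy[, 2L],
                      stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(inten))
  meta <- data.frame(sample_id = sample_id, patient_id = patient_id,
                     tissue_class = tissue_class,
                     core_diameter_mm = diameter_mm,
                     tissue_area_mm2 = area_mm2, survival_months = NA_real_,
                     event = NA, age = NA_real_, sex = NA_character_,
                     stage = NA_integer_, stringsAsFactors = FALSE)
  truth_df <- data.frame(sample_id = rep(sample_id, n),
                         cell_id = cells$cell_id,
                         true_phenotype = .truth_label(truth),
                         stringsAsFactors = FALSE)
  truth_df <- cbind(truth_df, as.data.frame(truth))
  list(table = cell_table(cells, meta), truth = truth_df)
}

# true phenotype label implied by a true positivity matrix (same hierarchy
# as assign_phenotypes, applied to noise-free truth)
.truth_label <- function(truth) {
  lab <- rep("Other", nrow(truth))
  lab[truth[, "cd68"]] <- ifelse(truth[truth[, "cd68"], "pdl1"],
                                 "PD-L1_Macrophage", "Macrophage")
  cd3 <- truth[, "cd3"]
  lab[cd3] <- "T_cell"
  lab[cd3 & truth[, "foxp3"]] <- "Treg"
  lab[cd3 & truth[, "cd8"]] <- ifelse(truth[cd3 & truth[, "cd8"], "pd1"],
                                      "Exhausted_cytotoxic_T", "Cytotoxic_T")
  tum <- truth[, "tumor_marker"]
  lab[tum] <- ifelse(truth[tum, "pdl1"], "PD-L1_Tumor", "Tumor")
  factor(lab, levels = phenotype_levels())
}

#' Simulate a negative-control core
#'
#' All markers except the DAPI counterstain draw from the negative intensity
#' component, emulating the unstained negative-control slide used to set
#' positivity thresholds.
#'
#' @inheritParams simulate_core
#' @param n_cells number of control cells (> 0).
#' @return A [cell_table()] with `tissue_class = "negative_control"`.
#' @export
simulate_negative_control <- function(im, n_cells, seed = 1,
                                      sample_id = "NC1", diameter_mm = 1.5) {
  stopifnot(inherits(im, "intensity_model"))
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  set.seed(seed)
  radius_um <- diameter_mm * 1000 / 2
  mk <- marker_names()
  truth <- matrix(FALSE, n_cells, length(mk), dimnames = list(NULL, mk))
  truth[, "dapi"] <- TRUE
  xy <- .disc_uniform(n_cells, radius_um)
  inten <- .draw_intensities(truth, im)
  cells <- data.frame(sample_id = rep(sample_id, n_cells),
                      cell_id = sprintf("c%05d", seq_len(n_cells)),
                      x_um = xy[, 1L], y_um = xy[, 2L],
                      stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(inten))
  meta <- data.frame(sample_id = sample_id, patient_id = NA,
                     tissue_class = "negative_control",
                     core_diameter_mm = diameter_mm,
                     tissue_area_mm2 = pi * (diameter_mm / 2)^2,
                     survival_months = NA_real_, event = NA, age = NA_real_,
                     sex = NA_character_, stage = NA_integer_,
                     stringsAsFactors = FALSE)
  cell_table(cells, meta)
}

#' Simulate patient-level covariates, subset proportions and survival
#'
#' Per-patient true subset proportions p(PD-1+|CD8+) and p(PD-L1+|CD68+) are
#' drawn from a bivariate normal on the logit scale (means
#' `logit(prop_means)`, sd `prop_sd`, correlation `rho`), so the two
#' proportions covary across patients. Overall-survival times are
#' exponential with hazard `baseline_rate * exp(beta %*% z)` using the TRUE
#' proportions, age (centred at 65), sex and stage as z; censoring is
#' exponential truncated at `max_followup`.
#'
#' @param n_patients number of patients (>= 2).
#' @param surv a [survival_model()].
#' @param prop_means length-2 vector: mean p(PD-1+|CD8+) and p(PD-L1+|CD68+).
#' @param prop_sd per-patient sd on the logit scale.
#' @param rho logit-scale correlation between the two proportions, in (-1, 1).
#' @param cluster_log_hr if non-`NULL`, adds a balanced binary `cluster`
#'   covariate with this planted log hazard ratio (for parameter-recovery
#'   studies).
#' @param seed integer RNG seed.
#' @return data.frame, one row per patient: `patient_id`, `age`, `sex`,
#'   `stage`, true proportions `p_pd1_cd8_true` / `p_pdl1_cd68_true`,
#'   optional `cluster`, linear predictor `lp`, `survival_months`, `event`.
#' @export
simulate_patients <- function(n_patients, surv = survival_model(),
                              prop_means = c(0.35, 0.30), prop_sd = 0.5,
                              rho = 0.8, cluster_log_hr = NULL, seed = 1) {
  stopifnot(inherits(surv, "survival_model"))
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (!is.finite(rho) || rho <= -1 || rho >= 1) {
    stop("rho must lie in (-1, 1)", call. = FALSE)
  }
  set.seed(seed)
  n <- n_patients
  logit <- function(p) log(p / (1 - p))
  u1 <- rnorm(n)
  u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(n)
  p1 <- stats::plogis(logit(prop_means[1L]) + prop_sd * u1)
  p2 <- stats::plogis(logit(prop_means[2L]) + prop_sd * u2)
  age <- pmin(pmax(round(rnorm(n, 65, 10)), 40), 85)
  sex <- ifelse(runif(n) < 0.55, "M", "F")
  stage <- sample.int(4L, n, replace = TRUE,
                      prob = c(0.15, 0.35, 0.30, 0.20))
  b <- surv$beta
  lp <- b[["p_pd1_cd8"]] * (p1 - 0.35) + b[["p_pdl1_cd68"]] * (p2 - 0.30) +
    b[["age"]] * (age - 65) + b[["sexM"]] * (sex == "M") +
    b[["stage"]] * (stage - 2)
  cluster <- NULL
  if (!is.null(cluster_log_hr)) {
    cluster <- rbinom(n, 1L, 0.5)
    lp <- lp + cluster_log_hr * cluster
  }
  t_event <- rexp(n, surv$baseline_rate * exp(lp))
  t_cens <- if (surv$censoring_rate > 0) rexp(n, surv$censoring_rate) else Inf
  t_cens <- pmin(t_cens, surv$max_followup)
  time <- pmin(t_event, t_cens)
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), age = age,
                    sex = sex, stage = stage, p_pd1_cd8_true = p1,
                    p_pdl1_cd68_true = p2, lp = lp,
                    survival_months = pmax(time, 1e-6),
                    event = t_event <= t_cens, stringsAsFactors = FALSE)
  if (!is.null(cluster)) out$cluster <- cluster
  out
}

#' Cohort presets
#'
#' `tma_preset("pdac-like")` is the default study condition emulated by the
#' generator: 84 tumor cores with adjacent-normal cores for 73 of the
#' patients plus one 2,000-cell negative-control core; tumor composition
#' giving a CD8-of-CD3 proportion near 39% (near 55% in adjacent normal);
#' correlated per-patient functional proportions (logit-scale rho = 0.8);
#' spatial attraction of PD-1+CD8+ cells to PD-L1+CD68+ macrophages
#' (strength 10, scale 15 um); and proportional-hazards survival driven by
#' the two functional proportions. `"null"` is identical except that all
#' survival coefficients and the spatial attraction are zero.
#'
#' @param name `"pdac-like"` or `"null"`.
#' @return A list of generator parameters (class `tma_preset`).
#' @export
tma_preset <- function(name = c("pdac-like", "null")) {
  name <- match.arg(name)
  tumor_comp <- composition_params(
    densities = c(tumor = 1200, t_helper = 120, t_cytotoxic = 100,
                  treg = 35, macrophage = 150, other = 800),
    p_pd1_given_cd8 = 0.35, p_pdl1_given_cd68 = 0.30,
    p_pdl1_given_tumor = 0.15)
  normal_comp <- composition_params(
    densities = c(tumor = 800, t_helper = 115, t_cytotoxic = 175,
                  treg = 30, macrophage = 140, other = 900),
    p_pd1_given_cd8 = 0.15, p_pdl1_given_cd68 = 0.10,
    p_pdl1_given_tumor = 0.05)
  p <- list(name = name, n_patients = 84L, n_normal = 73L,
            tumor_comp = tumor_comp, normal_comp = normal_comp,
            im = intensity_model(),
            attr = attraction_params(strength = 10, scale_um = 15),
            surv = survival_model(),
            prop_sd = 0.5, rho = 0.8, normal_prop_sd = 0.5,
            density_jitter_sdlog = 0.3, nc_cells = 2000L,
            diameter_mm = 1.5)
  if (name == "null") {
    p$surv$beta[] <- 0
    p$attr <- attraction_params(strength = 0, scale_um = 15)
  }
  class(p) <- "tma_preset"
  p
}

.jitter_comp <- function(comp, sdlog, p1 = NULL, p2 = NULL) {
  d <- comp$densities * rlnorm(length(comp$densities), 0, sdlog)
  composition_params(d,
                     p_pd1_given_cd8 = if (is.null(p1)) comp$p_pd1_given_cd8 else p1,
                     p_pdl1_given_cd68 = if (is.null(p2)) comp$p_pdl1_given_cd68 else p2,
                     p_pdl1_given_tumor = comp$p_pdl1_given_tumor)
}

#' Simulate a full TMA cohort
#'
#' Draws patients (covariates, correlated true functional proportions,
#' survival), then one tumor core per patient and one adjacent-normal core
#' for the first `n_normal` patients, plus a negative-control core.
#' Per-patient tumor cores use the patient's TRUE p(PD-1+|CD8+) and
#' p(PD-L1+|CD68+) as the functional fractions, and phenotype densities get
#' a per-patient log-normal jitter (`density_jitter_sdlog`), so estimated
#' proportions and densities vary realistically across the cohort. Each
#' sample is generated on its own RNG substream derived from `seed`, so
#' cohorts are fully reproducible and adding a sample does not perturb the
#' others.
#'
#' @param preset a [tma_preset()] (or a list with the same fields).
#' @param seed integer RNG seed.
#' @param cells if `FALSE`, skip cell-level simulation and return only the
#'   patient table (fast path for survival-only studies).
#' @return A list: `patients` (see [simulate_patients()]), `tables`
#'   (combined [cell_table()] of all cores incl. the negative control),
#'   `truth` (per-cell ground-truth data.frame), `preset`, `seed`.
#' @export
simulate_cohort <- function(preset = tma_preset(), seed = 1, cells = TRUE) {
  patients <- simulate_patients(
    preset$n_patients, surv = preset$surv,
    prop_means = c(preset$tumor_comp$p_pd1_given_cd8,
                   preset$tumor_comp$p_pdl1_given_cd68),
    prop_sd = preset$prop_sd, rho = preset$rho,
    seed = .substream_seed(seed, 0L))
  if (!cells) {
    return(list(patients = patients, tables = NULL, truth = NULL,
                preset = preset, seed = seed))
  }
  tabs <- vector("list", preset$n_patients + preset$n_normal + 1L)
  truths <- vector("list", preset$n_patients + preset$n_normal)
  k <- 0L
  for (i in seq_len(preset$n_patients)) {
    k <- k + 1L
    s <- .substream_seed(seed, k)
    set.seed(s)
    comp_i <- .jitter_comp(preset$tumor_comp, preset$density_jitter_sdlog,
                           p1 = patients$p_pd1_cd8_true[i],
                           p2 = patients$p_pdl1_cd68_true[i])
    core <- simulate_core(comp_i, preset$im, preset$attr,
                          diameter_mm = preset$diameter_mm,
                          seed = .substream_seed(s, 1L),
                          sample_id = sprintf("T%03d", i),
                          patient_id = patients$patient_id[i],
                          tissue_class = "tumor")
    tabs[[k]] <- core$table
    truths[[k]] <- core$truth
  }
  for (i in seq_len(preset$n_normal)) {
    k <- k + 1L
    s <- .substream_seed(seed, k)
    set.seed(s)
    logit <- function(p) log(p / (1 - p))
    p1n <- stats::plogis(logit(preset$normal_comp$p_pd1_given_cd8) +
                           preset$normal_prop_sd * rnorm(1))
    p2n <- stats::plogis(logit(preset$normal_comp$p_pdl1_given_cd68) +
                           preset$normal_prop_sd * rnorm(1))
    comp_i <- .jitter_comp(preset$normal_comp, preset$density_jitter_sdlog,
                           p1 = p1n, p2 = p2n)
    core <- simulate_core(comp_i, preset$im, attraction_params(0),
                          diameter_mm = preset$diameter_mm,
                          seed = .substream_seed(s, 1L),
                          sample_id = sprintf("N%03d", i),
                          patient_id = patients$patient_id[i],
                          tissue_class = "adjacent_normal")
    tabs[[k]] <- core$table
    truths[[k]] <- core$truth
  }
  nc <- simulate_negative_control(preset$im, preset$nc_cells,
                                  seed = .substream_seed(seed, k + 1L),
                                  sample_id = "NC001",
                                  diameter_mm = preset$diameter_mm)
  tabs[[k + 1L]] <- nc
  combined <- bind_cell_tables(tabs)
  pm <- match(combined$meta$patient_id, patients$patient_id)
  keep <- !is.na(pm)
  combined$meta$survival_months[keep] <- patients$survival_months[pm[keep]]
  combined$meta$event[keep] <- patients$event[pm[keep]]
  combined$meta$age[keep] <- patients$age[pm[keep]]
  combined$meta$sex[keep] <- patients$sex[pm[keep]]
  combined$meta$stage[keep] <- patients$stage[pm[keep]]
  list(patients = patients, tables = combined,
       truth = .rbind_fast(truths), preset = preset, seed = seed)
}
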