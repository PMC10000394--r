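# Independent brute-force oracles used to verify the package's accelerated
# or library-backed implementations.

# O(n^2) nearest-reference distances
brute_nn <- function(query, reference) {
  if (nrow(reference) == 0L) return(rep(NA_real_, nrow(query)))
  vapply(seq_len(nrow(query)), function(i) {
    min(sqrt((reference[, 1L] - query[i, 1L])^2 +
               (reference[, 2L] - query[i, 2L])^2))
  }, numeric(1L))
}

# explicit half-open binning [lo, hi)
brute_band_counts <- function(d, edges) {
  d <- d[!is.na(d)]
  vapply(seq_len(length(edges) - 1L), function(b) {
    sum(d >= edges[b] & d < edges[b + 1L])
  }, integer(1L))
}

# textbook two-group log-rank: observed minus expected under the
# hypergeometric model at each distinct event time
logrank_oe <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# AUC as the Mann-Whitney rank statistic U / (n1 * n0), ties counting 1/2
auc_rank <- function(score, outcome) {
  r <- rank(score)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# type-7 empirical quantile by explicit sort-and-interpolate
order_stat_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1L] - x[lo])
}

# tiny gated data.frame builder for quantification tests: one sample with
# the given phenotype counts at arbitrary positions
make_gated <- function(counts, sample_id = "S1", area = 1) {
  n <- sum(counts)
  ph <- rep(names(counts), counts)
  g <- data.frame(sample_id = sample_id,
                  cell_id = sprintf("c%04d", seq_len(n)),
                  x_um = seq_len(n), y_um = rev(seq_len(n)),
                  stringsAsFactors = FALSE)
  for (m in marker_names()) g[[m]] <- FALSE
  g$dapi <- TRUE
  g$phenotype <- factor(ph, levels = phenotype_levels())
  g
}

make_meta <- function(sample_id = "S1", tissue_class = "tumor", area = 1) {
  data.frame(sample_id = sample_id, patient_id = "P1",
             tissue_class = tissue_class, core_diameter_mm = 1.5,
             tissue_area_mm2 = area, survival_months = NA_real_,
             event = NA, age = NA_real_, sex = NA_character_,
             stage = NA_integer_, stringsAsFactors = FALSE)
}

# light composition for fast spatial tests
light_comp <- function(p1 = 0.35, p2 = 0.30) {
  composition_params(
    densities = c(tumor = 0, t_helper = 50, t_cytotoxic = 100, treg = 20,
                  macrophage = 150, other = 200),
    p_pd1_given_cd8 = p1, p_pdl1_given_cd68 = p2, p_pdl1_given_tumor = 0)
}
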