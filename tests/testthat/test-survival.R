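test_that("median split follows the strict-above rule with ties to low", {
  g <- median_split(1:10)
  expect_equal(attr(g, "cutoff"), 5.5)
  expect_equal(as.vector(table(g)), c(5, 5))

  g <- median_split(c(1, 2, 2, 3))
  expect_equal(attr(g, "cutoff"), 2)
  expect_equal(sum(g == "high"), 1)       # only the 3
  expect_equal(sum(g == "low"), 3)        # ties at the median go low

  g <- median_split(c(10, 20, 30, 40, 50, 60, 70))
  expect_equal(sum(g == "high"), 3)       # odd n, unique values: (n-1)/2

  expect_error(median_split(rep(4, 10)), "degenerate")
  expect_error(median_split(c(1, 2, NA, NA, NA)), "at least 4")
  expect_message(median_split(c(1, 2, 3, 4, NA)), "excluding 1")
})

test_that("four-group cluster crosses two median splits", {
  g <- four_group_split(c(1, 1, 9, 9), c(2, 8, 2, 8))
  expect_equal(as.character(g),
               c("low/low", "low/high", "high/low", "high/high"))
  expect_equal(cluster_indicator(g), c(0L, 0L, 0L, 1L))
})

test_that("Kaplan-Meier matches hand-computed product-limit fixtures", {
  # 4 deaths, no censoring
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  # everyone censored
  km <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_equal(km_surv_at(km, c(0, 4, 100)), c(1, 1, 1))

  # mixed fixture, computed by hand:
  # t=1 censored; t=2 death (4 of 5 at risk survive) -> 0.8
  # t=3 censored; t=4 death (2 of 3) -> 0.8*2/3; t=5 death (1 of 2) ->
  # 0.8*2/3*1/2; t=6 censored
  km <- km_estimate(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 1, 0))
  expect_equal(km_surv_at(km, c(2, 4, 5)),
               c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))
  # survival curve is non-increasing and starts at 1
  expect_true(all(diff(km$surv) <= 0))
  expect_equal(km_surv_at(km, 0.5), 1)
})

test_that("log-rank equals the independent observed-minus-expected oracle", {
  # identical groups: statistic 0, p 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 0, 1, 1)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # small two-group fixtures against the textbook O-E computation
  for (s in 1:5) {
    set.seed(s)
    n <- 16
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.7)
    grp <- rep(c("A", "B"), each = n / 2)
    lr <- logrank_test(time, event, grp)
    oe <- logrank_oe(time, event, grp)
    expect_equal(lr$chisq, oe$chisq, tolerance = 1e-9)
    expect_equal(lr$p, oe$p, tolerance = 1e-9)
  }

  # invariance under group relabeling
  set.seed(6)
  time <- rexp(20, 0.1); event <- rbinom(20, 1, 0.6)
  grp <- rep(c("A", "B"), 10)
  expect_equal(logrank_test(time, event, grp)$chisq,
               logrank_test(time, event, ifelse(grp == "A", "B", "A"))$chisq)

  expect_error(logrank_test(time, event, rep("A", 20)), "2 non-empty")
})

test_that("Cox fit recovers the exponential two-group rate ratio", {
  set.seed(31)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(log(2) * z))
  d <- data.frame(time = time, event = rep(TRUE, n), z = z)
  fit <- cox_fit(d, "z")
  rate_ratio <- (sum(d$event[z == 1]) / sum(time[z == 1])) /
    (sum(d$event[z == 0]) / sum(time[z == 0]))
  expect_lt(abs(log(fit$table$hr) - log(rate_ratio)), 0.15)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_true(fit$table$hr_lo < fit$table$hr &&
                fit$table$hr < fit$table$hr_hi)

  expect_error(cox_fit(data.frame(time = 1:20, event = rep(TRUE, 20),
                                  z = rep(1, 20)), "z"), "constant")
  expect_warning(cox_fit(data.frame(time = 1:6,
                                    event = c(TRUE, TRUE, rep(FALSE, 4)),
                                    z = c(0, 1, 0, 1, 0, 1)), "z"),
                 "fewer than 10 events")
})

test_that("a permuted covariate has near-nominal CI coverage of HR 1", {
  covered <- vapply(1:120, function(s) {
    set.seed(400 + s)
    n <- 60
    d <- data.frame(time = rexp(n, 0.05), event = rbinom(n, 1, 0.7) == 1,
                    z = rnorm(n))
    tab <- cox_fit(d, "z")$table
    tab$hr_lo <= 1 && 1 <= tab$hr_hi
  }, logical(1L))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.00)
})

test_that("1-year AUC equals the Mann-Whitney rank statistic", {
  # perfectly separating score
  r <- roc_1yr(score = c(1, 2, 3, 10, 11, 12),
               time = c(20, 30, 25, 3, 5, 8),
               event = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)

  # constant score is uninformative
  r <- roc_1yr(rep(5, 6), c(20, 30, 25, 3, 5, 8),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 0.5)

  # 10-patient fixture vs the rank-statistic oracle (with ties)
  score <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  time <- c(5, 40, 8, 30, 2, 50, 11, 3, 20, 60)
  event <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
             FALSE)
  r <- roc_1yr(score, time, event)
  outcome <- as.integer(event & time <= 12)
  expect_equal(r$auc, auc_rank(score, outcome))

  # censored before the horizon are excluded with a message
  expect_message(
    r <- roc_1yr(c(1, 2, 3, 4, 5), c(6, 20, 30, 40, 2),
                 c(TRUE, FALSE, FALSE, TRUE, FALSE)), "excluding 1")
  expect_equal(r$n_excluded, 1)
  # one-class degenerate outcome: AUC undefined
  expect_warning(r <- roc_1yr(1:4, c(20, 30, 40, 50), rep(FALSE, 4)),
                 "undefined")
  expect_true(is.na(r$auc))
})
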