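test_that("Kaplan-Meier matches the hand product-limit on the 3-subject example", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(as.numeric(survival_at(km, 1)), 2 / 3)          # (1 - 1/3)
  expect_equal(as.numeric(survival_at(km, 2.5)), 2 / 3)        # censoring does not drop S
  expect_equal(as.numeric(survival_at(km, 3)), 0)              # (1 - 1/3)(1 - 1/1)
  expect_equal(as.numeric(survival_at(km, 0)), 1)
  expect_equal(as.numeric(survival_at(km, 0.999)), 1)
  expect_error(survival_at(km, -1), "negative")
  ex <- survival_at(km, 10)
  expect_true(attr(ex, "extrapolated"))
})

test_that("KM with all-censored data stays at 1 and errors are raised", {
  km <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km$survival == 1))
  expect_error(km_estimate(numeric(0), integer(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM equals the ECDF complement under no censoring (exact)", {
  set.seed(11)
  for (r in 1:5) {
    t <- round(rexp(40, 0.2) + 0.1, 1)             # includes ties
    km <- km_estimate(t, rep(1, 40))
    hand <- km_hand(t, rep(1, 40))
    at <- as.numeric(survival_at(km, hand$time))
    expect_equal(at, hand$survival)
    ecdf_c <- 1 - ecdf(t)(hand$time)
    expect_equal(at, ecdf_c)
  }
})

test_that("log-rank is zero for identical groups and matches hand enumeration", {
  t <- c(2, 4, 5, 7, 9, 12); e <- c(1, 0, 1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(1:2, each = 6))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 6-subject two-group toy vs hand O-E/V computation
  g <- c(1, 1, 1, 2, 2, 2)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi2, logrank_hand(t, e, g), tolerance = 1e-10)
  expect_identical(lr$df, 1L)

  # label-swap invariance
  lr_sw <- logrank_test(t, e, 3 - g)
  expect_equal(lr_sw$chi2, lr$chi2)

  expect_error(logrank_test(t, e, rep(1, 6)), "2 nonempty")
  expect_error(logrank_test(t, rep(0, 6), g), "no events")
})

test_that("log-rank keeps nominal type-I error under the null", {
  set.seed(1234)
  reject <- replicate(400, {
    t_ev <- rexp(100, 0.1)
    t_cn <- rexp(100, 0.025)                       # ~20% censoring
    tm <- pmin(t_ev, t_cn); ev <- as.integer(t_ev <= t_cn)
    logrank_test(tm, ev, rep(1:2, each = 50))$p < 0.05
  })
  expect_gt(mean(reject), 0.025)
  expect_lt(mean(reject), 0.075)
})

test_that("concordance index equals exhaustive pair enumeration", {
  set.seed(42)
  for (r in 1:30) {
    o <- random_surv(15, tie_levels = if (r %% 2) NULL else 1:6)
    risk <- sample(1:5, 15, replace = TRUE)
    expect_equal(concordance_index(risk, o$time, o$event),
                 harrell_brute(risk, o$time, o$event))
  }
})

test_that("concordance index has the expected boundary and invariance behavior", {
  t <- c(5, 4, 3, 2, 1); e <- rep(1, 5)
  expect_equal(concordance_index(-t, t, e), 1)     # risk = negated times
  expect_equal(concordance_index(t, t, e), 0)
  r <- c(0.1, 0.7, 0.2, 0.9, 0.4)
  expect_equal(concordance_index(r, t, e),
               concordance_index(exp(3 * r), t, e))  # monotone-invariant
  expect_error(concordance_index(r, t, rep(0, 5)), "no events")
})

test_that("Cox fit matches 1-D brute-force Efron partial likelihood", {
  set.seed(77)
  for (r in 1:8) {
    n <- 8 + r
    o <- random_surv(n, tie_levels = if (r %% 2) NULL else 1:4)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0L, 1L)
    fit <- tryCatch(fit_cox(data.frame(x = x), o$time, o$event),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next       # separation on tiny data
    expect_equal(fit$table$coef, cox_brute_1d(x, o$time, o$event),
                 tolerance = 1e-4)
  }
})

test_that("Cox fit reports HR = exp(coef), bracketing CIs and a valid C-index", {
  co <- generate_cohort(cohort_params(n = 400, seed = 9))
  b <- dichotomize(co$features)
  fit <- fit_cox(b[c("pmtv_cm3_high", "dmax_cm_high")],
                 co$outcomes$time_months, co$outcomes$event)
  expect_true(fit$converged)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_true(all(fit$table$hr_lo < fit$table$hr))
  expect_true(all(fit$table$hr_hi > fit$table$hr))
  expect_true(fit$c_index >= 0 && fit$c_index <= 1)
  # likelihood at the optimum is no worse than at zero
  expect_gte(fit$loglik[2], fit$loglik[1])
  expect_error(fit_cox(data.frame(x = rep(1, 400)),
                       co$outcomes$time_months, co$outcomes$event),
               "constant")
  expect_error(fit_cox(b[1:5, 1, drop = FALSE], co$outcomes$time_months[1:5],
                       co$outcomes$event[1:5]), "n >= 10")
})

test_that("correlation helpers match their definitions and oracles", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_corr(x, 2 * x + 1), 1)
  expect_equal(kendall_tau(x, 2 * x + 1), 1)
  expect_equal(pearson_corr(x, -x), -1)
  set.seed(8)
  for (r in 1:5) {
    a <- sample(1:5, 12, replace = TRUE)            # heavy ties
    b <- sample(1:4, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(kendall_tau(a, b), kendall_brute(a, b))
  }
  expect_error(pearson_corr(rep(1, 5), 1:5), "zero-variance")
  expect_error(kendall_tau(1:2, 1:2), "n >= 3")

  z <- rnorm(50)
  ks <- ks_normality(z)
  expect_true(ks$D >= 0 && ks$D <= 1)
  expect_true(ks$p > 0 && ks$p <= 1)
  expect_match(ks$note, "anti-conservative")
  expect_error(ks_normality(rep(2, 10)), "zero-variance")
})

test_that("cutpoint search equals an exhaustive scan and recovers planted splits", {
  set.seed(15)
  v <- round(runif(25, 0, 10), 2)
  t_ev <- rexp(25, 0.1 * ifelse(v > 5, 3, 1))
  tm <- pmin(t_ev, 30); ev <- as.integer(t_ev <= 30)
  if (sum(ev) < 10) ev[1:10] <- 1L
  cs <- cutpoint_search(v, tm, ev)
  # independent exhaustive scan over every admissible observed value
  qr <- quantile(v, c(0.1, 0.9), names = FALSE)
  cand <- sort(unique(v)); cand <- cand[cand >= qr[1] & cand <= qr[2] & cand < max(v)]
  ps <- vapply(cand, function(cut)
    logrank_test(tm, ev, v > cut)$p, numeric(1))
  expect_equal(cs$cutoff, cand[which.min(ps)])
  expect_equal(cs$p, min(ps))
  expect_match(cs$flag, "exploratory")

  # planted two-group structure: gap between supports at value 10
  set.seed(16)
  n <- 200
  grp <- rbinom(n, 1, 0.5)
  v2 <- ifelse(grp == 1, runif(n, 11, 20), runif(n, 0, 9))
  t2 <- rexp(n, 0.05 * ifelse(grp == 1, 3, 1))
  tm2 <- pmin(t2, 40); ev2 <- as.integer(t2 <= 40)
  cs2 <- cutpoint_search(v2, tm2, ev2)
  expect_gt(cs2$cutoff, 8.9)
  expect_lt(cs2$cutoff, 11.1)

  expect_error(cutpoint_search(rep(1, 25), tm, ev), "degenerate")
  expect_error(cutpoint_search(v[1:10], tm[1:10], ev[1:10]), ">= 20")
})

test_that("permutation correction calibrates the selected p on pure noise", {
  set.seed(17)
  n <- 60
  v <- runif(n)
  t_ev <- rexp(n, 0.08)
  tm <- pmin(t_ev, 25); ev <- as.integer(t_ev <= 25)
  cs <- cutpoint_search(v, tm, ev, permutations = 99)
  expect_gt(cs$p_adjusted, cs$p)   # min-p correction can only be larger
  expect_match(cs$flag, "permutations")
})

test_that("logistic companion reports odds ratios consistent with glm", {
  co <- generate_cohort(cohort_params(n = 300, seed = 19))
  b <- dichotomize(co$features)
  tab <- fit_logistic(b["pmtv_cm3_high"], co$outcomes$event)
  ref <- glm(co$outcomes$event ~ b$pmtv_cm3_high, family = binomial())
  expect_equal(tab$coef, unname(coef(ref)[2]))
  expect_equal(tab$or_, exp(unname(coef(ref)[2])))
})
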