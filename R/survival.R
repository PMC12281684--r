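validate_outcomes <- function(time, event) {
  time <- as.numeric(time)
  if (length(time) == 0L) stop("empty outcome list", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all follow-up times must be positive", call. = FALSE)
  ev <- as.integer(event)
  if (length(ev) != length(time) || any(!ev %in% c(0L, 1L)))
    stop("`event` must be 0/1 of the same length as `time`", call. = FALSE)
  list(time = time, event = ev)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous product-limit estimator
#' `S(t) = prod[t_i <= t] (1 - d_i / n_i)`. Censored subjects leave the risk
#' set after their time; at tied event/censoring times, events are counted
#' first (the standard convention). With no censoring the curve equals the
#' complement of the empirical CDF at every event time.
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators (1 = biochemical recurrence).
#' @return object of class `km_curve`: list with `time` (distinct observed
#'   times, ascending), `n_risk`, `n_event`, `n_censor`, `survival`, and
#'   Greenwood standard errors `std_err`.
#' @export
km_estimate <- function(time, event) {
  o <- validate_outcomes(time, event)
  sf <- survival::survfit(survival::Surv(o$time, o$event) ~ 1,
                          conf.type = "none")
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 n_censor = sf$n.censor, survival = sf$surv,
                 std_err = sf$surv * sf$std.err),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function value; `t` earlier than the first observed
#' time gives 1. Times beyond the last observed time return the last value
#' with attribute `extrapolated = TRUE`.
#'
#' @param curve a [km_estimate()] result.
#' @param t non-negative time(s), months.
#' @return survival probabilities, with an `extrapolated` logical attribute.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) stop("negative evaluation time", call. = FALSE)
  idx <- findInterval(t, curve$time)   # 0 before first time
  out <- ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
  attr(out, "extrapolated") <- t > max(curve$time)
  out
}

#' @export
print.km_curve <- function(x, ...) {
  n <- x$n_risk[1]
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, final S = %.3f at t = %.3g\n",
              n, sum(x$n_event), x$survival[length(x$survival)],
              max(x$time)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (months)",
                          ylab = "BCR-free survival", ...) {
  graphics::plot(c(0, x$time), c(1, x$survival), type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  cens <- x$time[x$n_censor > 0]
  if (length(cens) > 0)
    graphics::points(cens, survival_at(x, cens), pch = 3, cex = 0.7)
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard log-rank test: at each distinct event time, observed minus
#' expected events per group under the hypergeometric model; chi-square
#' statistic with G - 1 degrees of freedom.
#'
#' @param time,event follow-up times and 0/1 indicators.
#' @param group group membership (factor/character/integer), at least two
#'   nonempty groups.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  o <- validate_outcomes(time, event)
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 nonempty groups", call. = FALSE)
  if (sum(o$event) == 0L) stop("no events: log-rank undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(o$time, o$event) ~ g)
  df <- nlevels(g) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Probability that, among admissible pairs (the member with the shorter
#' time experienced the event; pairs with tied event times, or where the
#' shorter time is censored, are inadmissible), the subject with the higher
#' risk score fails first. Ties in risk score count 1/2.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time,event follow-up times and 0/1 indicators.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(risk, time, event) {
  o <- validate_outcomes(time, event)
  if (length(risk) != length(o$time) || length(risk) < 2L)
    stop("`risk` must match the outcomes and have length >= 2", call. = FALSE)
  if (sum(o$event) == 0L) stop("no events: no admissible pairs", call. = FALSE)
  cf <- survival::concordance(survival::Surv(o$time, o$event) ~ risk,
                              reverse = TRUE)
  cnt <- as.numeric(cf$count)
  if (sum(cnt[1:3]) == 0) stop("no admissible pairs", call. = FALSE)
  unname(cf$concordance)
}

#' Cox proportional-hazards regression
#'
#' Fits the Cox partial likelihood (Efron tie handling by default) and
#' reports, per covariate, the log-hazard coefficient, hazard ratio,
#' Wald 95% confidence interval `exp(coef +- 1.96 SE)`, and Wald p-value,
#' plus Harrell's C computed on the fitted linear predictor. Apparent
#' complete separation (|coef| > 20) and failed convergence are flagged via
#' `converged`.
#'
#' @param covariates data frame or matrix (n x p) of covariates; column
#'   names become coefficient names.
#' @param time,event follow-up times and 0/1 indicators (n >= 10 and at
#'   least p + 1 events required).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: list with `table` (term, coef, se,
#'   hr, hr_lo, hr_hi, p), `c_index`, `loglik`, `n`, `n_event`, `converged`.
#' @export
fit_cox <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  o <- validate_outcomes(time, event)
  X <- as.data.frame(covariates)
  if (ncol(X) < 1L) stop("need at least one covariate", call. = FALSE)
  if (nrow(X) != length(o$time)) stop("covariate/outcome length mismatch",
                                      call. = FALSE)
  if (nrow(X) < 10L) stop("need n >= 10 subjects", call. = FALSE)
  if (sum(o$event) < ncol(X) + 1L)
    stop("too few events for ", ncol(X), " covariate(s)", call. = FALSE)
  const <- vapply(X, function(x) length(unique(x)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(X)[const], collapse = ", "),
         call. = FALSE)
  dat <- cbind(.time = o$time, .event = o$event, X)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(X)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(cf)) || any(abs(cf) > 20)) converged <- FALSE
  tab <- data.frame(term = names(X), coef = unname(cf), se = unname(se),
                    hr = exp(unname(cf)),
                    hr_lo = exp(unname(cf - 1.96 * se)),
                    hr_hi = exp(unname(cf + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(unname(cf / se))),
                    stringsAsFactors = FALSE)
  lp <- unname(as.matrix(X) %*% cf)[, 1]
  structure(list(table = tab,
                 c_index = concordance_index(lp, o$time, o$event),
                 loglik = fit$loglik, n = nrow(X), n_event = sum(o$event),
                 converged = converged, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, C-index = %.3f%s\n",
              x$ties, x$n, x$n_event, x$c_index,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- x$table
  tab$`HR [95% CI]` <- sprintf("%.2f [%.2f, %.2f]", tab$hr, tab$hr_lo, tab$hr_hi)
  print(data.frame(term = tab$term, coef = signif(tab$coef, digits),
                   `HR [95% CI]` = tab$`HR [95% CI]`,
                   p = signif(tab$p, 2), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' Logistic regression on the event indicator
#'
#' Companion to [fit_cox()] that ignores follow-up time and models the
#' binary recurrence indicator, reporting odds ratios with Wald 95% CIs.
#' Provided for completeness; the hazard-ratio analysis via [fit_cox()] is
#' the default throughout the package.
#'
#' @inheritParams fit_cox
#' @return data frame: term, coef, se, or_, or_lo, or_hi, p.
#' @export
fit_logistic <- function(covariates, event) {
  X <- as.data.frame(covariates)
  ev <- as.integer(event)
  fit <- stats::glm(ev ~ ., data = X, family = stats::binomial())
  cf <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  data.frame(term = names(X), coef = unname(cf), se = unname(se),
             or_ = exp(unname(cf)), or_lo = exp(unname(cf - 1.96 * se)),
             or_hi = exp(unname(cf + 1.96 * se)),
             p = 2 * stats::pnorm(-abs(unname(cf / se))),
             stringsAsFactors = FALSE)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, n >= 3, finite, non-constant.
#' @return correlation coefficient r.
#' @export
pearson_corr <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' Kendall rank correlation (tau-b, tie-corrected)
#'
#' @inheritParams pearson_corr
#' @return tau-b.
#' @export
kendall_tau <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "kendall")
}

check_corr_input <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("correlation inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input", call. = FALSE)
  invisible(TRUE)
}

#' Kolmogorov-Smirnov check against a fitted normal
#'
#' KS statistic of `x` against a normal with the sample mean and SD.
#' Because the parameters are estimated from the same data, the returned
#' p-value is anti-conservative (the Lilliefors correction is not applied);
#' it is reported as a descriptive normality check only.
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @return list with `D`, `p`, and a `note` restating the caveat.
#' @export
ks_normality <- function(x) {
  if (length(x) < 3L || any(!is.finite(x)))
    stop("need >= 3 finite values", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance input", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(D = unname(kt$statistic), p = kt$p.value,
       note = "parameters estimated from the sample; p is anti-conservative")
}

#' Optimal dichotomization cutpoint by log-rank scan
#'
#' Scans candidate cutoffs at the observed values inside the given quantile
#' range and returns the one minimizing the log-rank p-value for the split
#' `value > cutoff`. Because the minimum is taken over many tests, the
#' selected p-value is exploratory and not adjusted unless `permutations`
#' is positive, in which case a permutation-of-outcomes correction of the
#' minimal p is reported (`p_adjusted`).
#'
#' @param values numeric feature values (n >= 20).
#' @param time,event outcomes (>= 10 events required).
#' @param quantile_range inner quantile range scanned (default 10-90%).
#' @param permutations number of outcome-label permutations for the
#'   multiplicity correction (0 = none; 999 recommended when used).
#' @return list with `cutoff`, `p` (unadjusted minimal p), `chi2`, `flag`
#'   (`"exploratory -- p not adjusted"` unless permutations were run), and
#'   `p_adjusted` when requested.
#' @export
cutpoint_search <- function(values, time, event, quantile_range = c(0.10, 0.90),
                            permutations = 0L) {
  o <- validate_outcomes(time, event)
  if (length(values) != length(o$time)) stop("length mismatch", call. = FALSE)
  if (length(values) < 20L) stop("need >= 20 subjects", call. = FALSE)
  if (sum(o$event) < 10L) stop("need >= 10 events", call. = FALSE)
  if (length(unique(values)) < 2L) stop("degenerate values (all equal)",
                                        call. = FALSE)
  scan <- function(tm, ev) {
    best <- list(p = Inf)
    for (cut in candidate_cuts(values, quantile_range)) {
      g <- values > cut
      lr <- tryCatch(logrank_test(tm, ev, g), error = function(e) NULL)
      if (!is.null(lr) && lr$p < best$p)
        best <- list(cutoff = cut, p = lr$p, chi2 = lr$chi2)
    }
    best
  }
  best <- scan(o$time, o$event)
  if (!is.finite(best$p)) stop("no admissible cutpoint found", call. = FALSE)
  out <- list(cutoff = best$cutoff, p = best$p, chi2 = best$chi2,
              flag = "exploratory -- p not adjusted")
  if (permutations > 0L) {
    null_p <- vapply(seq_len(permutations), function(b) {
      idx <- sample.int(length(o$time))
      scan(o$time[idx], o$event[idx])$p
    }, numeric(1))
    out$p_adjusted <- (1 + sum(null_p <= best$p)) / (permutations + 1)
    out$flag <- sprintf("min-p corrected by %d outcome permutations",
                        permutations)
  }
  out
}

candidate_cuts <- function(values, quantile_range) {
  qr <- stats::quantile(values, quantile_range, names = FALSE)
  cand <- sort(unique(values))
  cand <- cand[cand >= qr[1] & cand <= qr[2]]
  cand[cand < max(values)]          # "value > cut" must leave both groups nonempty
}
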