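# Independent brute-force oracles used to check the analysis code.
# These deliberately use naive enumeration / closed forms, not the package's
# own code paths.

# Harrell's C by explicit pair enumeration: admissible pairs are those where
# the shorter time had the event (a censored-vs-event time tie counts the
# event as shorter); tied event times are inadmissible; tied risks score 1/2.
harrell_brute <- function(risk, time, event) {
  n <- length(time); num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]; ei <- event[i]; ej <- event[j]
    if (ti == tj && ei == 1 && ej == 1) next
    if (ti < tj && ei == 1) { s <- i; l <- j }
    else if (tj < ti && ej == 1) { s <- j; l <- i }
    else if (ti == tj && ei != ej) { if (ei == 1) { s <- i; l <- j } else { s <- j; l <- i } }
    else next
    den <- den + 1
    if (risk[s] > risk[l]) num <- num + 1
    else if (risk[s] == risk[l]) num <- num + 0.5
  }
  num / den
}

# Kendall tau-b by exhaustive pair counting with tie corrections.
kendall_brute <- function(x, y) {
  n <- length(x); nc <- 0; nd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}

# Product-limit estimator by hand at each distinct observed time.
km_hand <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1; out <- numeric(0); kept <- numeric(0)
  for (t in ts) {
    d <- sum(time == t & event == 1)
    n_at <- sum(time >= t)
    if (d > 0) s <- s * (1 - d / n_at)
    kept <- c(kept, t); out <- c(out, s)
  }
  list(time = kept, survival = out)
}

# Two-group log-rank chi-square by hand: sum over distinct event times of
# hypergeometric O-E for group 1, squared over the summed variance.
logrank_hand <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Efron-approximation Cox partial log-likelihood for a single covariate.
efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(x[R] * beta)); sD <- sum(exp(x[D] * beta))
    ll <- ll + sum(x[D] * beta)
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# 1-D brute-force maximizer of the Efron partial likelihood.
cox_brute_1d <- function(x, time, event, interval = c(-8, 8)) {
  stats::optimize(function(b) efron_loglik(b, x, time, event),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# random survival toy data with ties and censoring
random_surv <- function(n, tie_levels = NULL) {
  time <- if (is.null(tie_levels)) round(rexp(n, 0.1) + 0.5, 1)
          else sample(tie_levels, n, replace = TRUE)
  event <- rbinom(n, 1, 0.65)
  if (sum(event) == 0) event[sample(n, 2)] <- 1L
  list(time = time, event = event)
}
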