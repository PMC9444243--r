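# Population survival statistics on a replicative-age axis: Kaplan-Meier
# with Greenwood confidence bands, the discrete hazard with a bootstrap SD,
# and the two comparison tests used for benchmarking (log-rank on survival,
# Wilcoxon rank-sum on duration distributions).

records_to_surv <- function(records) {
  records <- Filter(function(r) !r$excluded, records)
  if (!length(records)) stop("empty-input: all records excluded")
  list(time = vapply(records, function(r) as.numeric(r$rls), numeric(1)),
       event = vapply(records, function(r) !r$censored, logical(1)))
}

km_core <- function(time, event) {
  g <- sort(unique(time))
  n <- vapply(g, function(t) sum(time >= t), numeric(1))
  d <- vapply(g, function(t) sum(time == t & event), numeric(1))
  cn <- vapply(g, function(t) sum(time == t & !event), numeric(1))
  S <- cumprod(1 - d / n)
  gw <- S^2 * cumsum(ifelse(n - d > 0, d / (n * (n - d)), 0))
  list(g = g, n = n, d = d, cens = cn, S = S, var = gw)
}

#' Kaplan-Meier survival estimate over replicative age
#'
#' Survival is `S(g) = P(RLS > g)`: the product over death generations
#' `g_i <= g` of `(1 - d_i / n_i)`.  The variance is Greenwood's
#' `S^2 * sum d_i / (n_i (n_i - d_i))` and the 95% band is
#' `S +/- 1.96 sqrt(var)` clipped to \[0, 1\] (`conf_type = "loglog"` gives
#' the log(-log) transformed band instead).  End-of-movie records are
#' treated as right-censored at their observed generation count; clog/empty
#' records are dropped.
#'
#' @param records list of [lifespan_record()]s.
#' @param conf_type `"plain"` (default) or `"loglog"`.
#' @return a `survival_table` data.frame with columns `g`, `n_at_risk`,
#'   `deaths`, `censored`, `S`, `greenwood_var`, `ci_low`, `ci_high`;
#'   attribute `median_rls` is the smallest `g` with `S(g) <= 0.5`
#'   (no interpolation), `NA` if survival never falls that far.
#' @export
km_estimate <- function(records, conf_type = c("plain", "loglog")) {
  conf_type <- match.arg(conf_type)
  sv <- records_to_surv(records)
  k <- km_core(sv$time, sv$event)
  z <- stats::qnorm(0.975)
  if (conf_type == "plain") {
    lo <- pmax(0, k$S - z * sqrt(k$var))
    hi <- pmin(1, k$S + z * sqrt(k$var))
  } else {
    ok <- k$S > 0 & k$S < 1
    se_ll <- sqrt(k$var) / (k$S * abs(log(k$S)))
    lo <- hi <- k$S
    lo[ok] <- k$S[ok]^exp(z * se_ll[ok])
    hi[ok] <- k$S[ok]^exp(-z * se_ll[ok])
  }
  tab <- data.frame(g = k$g, n_at_risk = k$n, deaths = k$d,
                    censored = k$cens, S = k$S, greenwood_var = k$var,
                    ci_low = lo, ci_high = hi)
  med <- tab$g[tab$deaths > 0 & tab$S <= 0.5]
  attr(tab, "median_rls") <- if (length(med)) med[1] else NA_real_
  attr(tab, "axis") <- "generation"
  class(tab) <- c("survival_table", "data.frame")
  tab
}

#' Discrete hazard rate with bootstrap standard deviation
#'
#' The hazard at replicative age `g` is `h(g) = d(g) / n(g)`, the fraction
#' of cells alive at age `g` that die at that age.  Its SD is estimated by
#' resampling the records with replacement `n_boot` times and recomputing
#' the hazard on the original generation grid.
#'
#' @param records list of [lifespan_record()]s.
#' @param n_boot bootstrap replicates (>= 2; default 100).
#' @param seed integer seed.
#' @return data.frame with `g`, `hazard`, `hazard_sd`, `n_at_risk`,
#'   `deaths`; attributes `n_boot` and `seed`.
#' @export
hazard_rate <- function(records, n_boot = 100L, seed = 1L) {
  if (n_boot < 2L) stop("invalid-parameter: n_boot must be >= 2")
  sv <- records_to_surv(records)
  k <- km_core(sv$time, sv$event)
  grid <- k$g
  h <- k$d / k$n
  hb <- with_seed(seed, {
    nrec <- length(sv$time)
    vapply(seq_len(n_boot), function(b) {
      ii <- sample.int(nrec, nrec, replace = TRUE)
      tt <- sv$time[ii]; ee <- sv$event[ii]
      n <- vapply(grid, function(t) sum(tt >= t), numeric(1))
      d <- vapply(grid, function(t) sum(tt == t & ee), numeric(1))
      ifelse(n > 0, d / n, NA_real_)
    }, numeric(length(grid)))
  })
  sdv <- apply(matrix(hb, nrow = length(grid)), 1L, stats::sd, na.rm = TRUE)
  out <- data.frame(g = grid, hazard = h, hazard_sd = sdv,
                    n_at_risk = k$n, deaths = k$d)
  attr(out, "n_boot") <- as.integer(n_boot)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Two-group log-rank test
#'
#' Standard censoring-aware two-sample log-rank chi-square with 1 degree of
#' freedom, symmetric in group order.
#'
#' @param records_a,records_b lists of [lifespan_record()]s.
#' @return list with `statistic`, `p`, `n` (per-group sizes used).
#' @export
logrank_test <- function(records_a, records_b) {
  a <- records_to_surv(records_a)
  b <- records_to_surv(records_b)
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(1:2, c(length(a$time), length(b$time)))
  dt <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in dt) {
    n1 <- sum(time >= t & grp == 1L)
    n <- sum(time >= t)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       n = c(length(a$time), length(b$time)))
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Midrank tie handling; the exact null distribution is used for small
#' tie-free samples and the normal approximation (with continuity
#' correction) above `exact_cutoff` or in the presence of ties, as
#' implemented by [stats::wilcox.test()].
#'
#' @param durations_a,durations_b numeric samples (e.g. cell-cycle
#'   durations in minutes).
#' @param exact_cutoff largest per-group size for which the exact
#'   distribution is used (ties permitting).
#' @return list with `statistic` (Mann-Whitney U of the first sample),
#'   `p`, `n`.
#' @export
ranksum_test <- function(durations_a, durations_b, exact_cutoff = 50L) {
  if (!length(durations_a) || !length(durations_b))
    stop("invalid-input: both samples must be non-empty")
  exact <- length(durations_a) <= exact_cutoff &&
    length(durations_b) <= exact_cutoff &&
    !anyDuplicated(c(durations_a, durations_b))
  wt <- stats::wilcox.test(durations_a, durations_b, exact = exact,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(durations_a), length(durations_b)))
}
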