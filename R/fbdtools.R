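# Fossil-record completeness and sampling-rate tooling.
#
# Under a birth-death process with extinction rate mu and fossil
# sampling/recovery rate psi (both per lineage per Myr), the probability
# that an extinct taxon is sampled at least once is
#     Phi = psi / (mu + psi),
# and the probability of sampling both members of an ancestor-descendant
# pair is Phi^2.  The three-timer estimator recovers per-interval sampling
# probabilities from occurrence tables, which convert to rates under
# Poisson sampling and moment-match a Beta prior.

#' Fossil-record completeness
#'
#' `Phi = psi / (mu + psi)`: the probability that an extinct taxon is
#' sampled at least once, from the competition between exponential
#' extinction (rate `mu`) and Poisson fossil sampling (rate `psi`).
#'
#' @param psi Fossil sampling rate (per lineage per Myr, `>= 0`).
#' @param mu Extinction rate (per lineage per Myr, `>= 0`).
#' @return Phi in `[0, 1]`.  Vectorized over both arguments.
#' @export
#' @examples
#' completeness(1, 1)    # 0.5
#' completeness(3, 1)    # 0.75
completeness <- function(psi, mu) {
  if (any(psi < 0) || any(mu < 0)) stop("rates must be non-negative")
  if (any(psi == 0 & mu == 0))
    stop("completeness is undefined at psi = mu = 0")
  psi / (mu + psi)
}

#' Probability of sampling an ancestor-descendant pair
#'
#' Both members of the pair must be sampled independently, so
#' `Pr[AD] = Phi^2`.
#'
#' @param phi Completeness in `[0, 1]`.
#' @return `phi^2`.  Vectorized.
#' @export
ad_pair_prob <- function(phi) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  phi^2
}

#' Per-stage completeness summaries from FBD posterior draws
#'
#' Applies [completeness()] and [ad_pair_prob()] elementwise to every
#' posterior draw and summarizes per stage.  Quantiles use R's default
#' midpoint interpolation (type 7), so the median of two draws is their
#' mean.
#'
#' @param posterior Data frame of draws with columns `stage`, `mu`, `psi`
#'   (a `lambda` column is accepted and ignored here), e.g. from
#'   [read_fbd_posterior()].
#' @param probs Quantile probabilities (default median and central 95%).
#' @return Data frame, one row per stage (input order of first appearance):
#'   `n_draws`, then `phi_*` and `ad_*` quantile columns.
#' @export
per_stage_completeness <- function(posterior,
                                   probs = c(0.025, 0.5, 0.975)) {
  stopifnot(all(c("stage", "mu", "psi") %in% names(posterior)))
  stages <- unique(posterior$stage)
  rows <- lapply(stages, function(s) {
    d <- posterior[posterior$stage == s, , drop = FALSE]
    if (nrow(d) == 0L) {
      warning("stage '", s, "' has no draws; skipped")
      return(NULL)
    }
    phi <- completeness(d$psi, d$mu)
    adp <- ad_pair_prob(phi)
    qs <- stats::quantile(phi, probs, names = FALSE, type = 7)
    qa <- stats::quantile(adp, probs, names = FALSE, type = 7)
    out <- data.frame(stage = s, n_draws = nrow(d))
    for (j in seq_along(probs)) {
      out[[paste0("phi_q", probs[j])]] <- qs[j]
      out[[paste0("ad_q", probs[j])]] <- qa[j]
    }
    out
  })
  do.call(rbind, rows)
}

#' Three-timer per-interval sampling probability
#'
#' For each interior interval i, `3T_i` counts taxa present in intervals
#' i-1, i and i+1, and `PT_i` (part-timers) counts taxa present in i-1 and
#' i+1 but absent from i; the estimated sampling probability is
#' `3T_i / (3T_i + PT_i)`.  The first and last intervals, and interiors
#' with `3T + PT = 0`, get `NA`.  This is the basic uncorrected estimator;
#' no cross-interval correction factor is applied.
#'
#' @param occ An `"occurrence_table"` (see [occurrence_table()]).
#' @return Data frame (interval, start_ma, end_ma, three_timer,
#'   part_timer, p_sample), intervals oldest to youngest.
#' @export
three_timer <- function(occ) {
  stopifnot(inherits(occ, "occurrence_table"))
  P <- occ$presence
  ni <- ncol(P)
  if (ni < 3L) stop("three-timer estimation needs at least 3 intervals")
  tt <- pt <- rep(NA_integer_, ni)
  p <- rep(NA_real_, ni)
  for (i in 2:(ni - 1L)) {
    prev <- P[, i - 1L] == 1L
    here <- P[, i] == 1L
    nxt <- P[, i + 1L] == 1L
    tt[i] <- sum(prev & here & nxt)
    pt[i] <- sum(prev & !here & nxt)
    denom <- tt[i] + pt[i]
    p[i] <- if (denom > 0L) tt[i] / denom else NA_real_
  }
  data.frame(interval = occ$intervals$name,
             start_ma = occ$intervals$start_ma,
             end_ma = occ$intervals$end_ma,
             three_timer = tt, part_timer = pt, p_sample = p,
             stringsAsFactors = FALSE)
}

#' Convert a per-interval sampling probability to a rate
#'
#' Under Poisson sampling, `p = 1 - exp(-psi * dt)`, hence
#' `psi = -log(1 - p) / dt`.
#'
#' @param p Probability of at least one sample in the interval (`0 <= p < 1`).
#' @param dt Interval duration in Myr (> 0).
#' @return Sampling rate psi (per lineage per Myr).  Vectorized.
#' @export
prob_to_rate <- function(p, dt) {
  if (any(p < 0 | p >= 1, na.rm = TRUE))
    stop("p must lie in [0, 1); p = 1 implies an infinite rate")
  if (any(dt <= 0)) stop("interval duration must be positive")
  -log(1 - p) / dt
}

#' Moment-match a Beta prior
#'
#' Returns the Beta(alpha, beta) distribution with the given mean and
#' variance: with `nu = mean (1 - mean) / variance - 1`,
#' `alpha = mean * nu` and `beta = (1 - mean) * nu`.  Feasibility requires
#' `variance < mean (1 - mean)`.
#'
#' @param mean Target mean in (0, 1).
#' @param variance Target variance (> 0).
#' @return Object of class `"beta_prior"` with fields `alpha`, `beta`.
#' @export
#' @examples
#' beta_moment_match(0.5, 1 / 12)   # Beta(1, 1), the uniform
beta_moment_match <- function(mean, variance) {
  stopifnot(length(mean) == 1L, length(variance) == 1L)
  if (!(mean > 0 && mean < 1)) stop("mean must lie strictly in (0, 1)")
  if (!(variance > 0)) stop("variance must be positive")
  if (variance >= mean * (1 - mean))
    stop("infeasible moments: variance must be < mean * (1 - mean) = ",
         signif(mean * (1 - mean), 6))
  nu <- mean * (1 - mean) / variance - 1
  structure(list(alpha = mean * nu, beta = (1 - mean) * nu),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat("Beta prior: alpha =", signif(x$alpha, 6),
      ", beta =", signif(x$beta, 6), "\n")
  invisible(x)
}

#' Empirically informed sampling-rate prior from an occurrence table
#'
#' Chains the three-timer estimator, probability-to-rate conversion (each
#' interval using its own duration from the stage table) and Beta moment
#' matching on the unweighted mean and variance of the per-interval rates.
#'
#' @param occ An `"occurrence_table"`.
#' @return List with the per-interval table (`intervals`, with `rate`
#'   column added) and the fitted `prior`.
#' @export
sampling_rate_prior <- function(occ) {
  tt <- three_timer(occ)
  dt <- tt$start_ma - tt$end_ma
  tt$rate <- ifelse(is.na(tt$p_sample), NA_real_,
                    prob_to_rate(ifelse(is.na(tt$p_sample), 0, tt$p_sample), dt))
  r <- tt$rate[!is.na(tt$rate)]
  if (length(r) < 2L)
    stop("need at least two intervals with defined sampling rates")
  m <- mean(r)
  v <- stats::var(r)
  list(intervals = tt, rate_mean = m, rate_var = v,
       prior = beta_moment_match(m, v))
}
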