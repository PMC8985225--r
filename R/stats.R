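#' Gaussian ensemble summary of a measurement distribution
#'
#' Moment statistics (mean, SD with n-1 denominator, SEM), the one-sided
#' 95% positional envelope (mean + 1.96 SD), a 0.5-nm-bin histogram, and
#' a least-squares Gaussian fit to that histogram — the same summary
#' drawn on single-particle measurement histograms. Moment estimates are
#' authoritative for downstream numbers; the histogram fit mirrors the
#' plotted curve.
#'
#' @param values numeric measurements (nm), n >= 2.
#' @param bin_width histogram bin width (nm).
#' @return An `ensemble_summary` list: `n`, `mean`, `sd`, `sem`,
#'   `envelope95`, `histogram` (data.frame mid/count), `fit` (list
#'   `amplitude`, `mean`, `sd`, `converged`) and `degenerate` flag.
#' @export
#' @examples
#' s <- gaussian_summary(rnorm(500, 16.8, 3.3))
#' s$envelope95
gaussian_summary <- function(values, bin_width = 0.5) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  breaks <- seq(floor(min(values) / bin_width) * bin_width,
                ceiling(max(values) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(mid = h$mids, count = h$counts)
  fit <- list(amplitude = NA_real_, mean = NA_real_, sd = NA_real_,
              converged = FALSE)
  if (!degenerate && sum(hist_df$count > 0) >= 3) {
    fit_try <- tryCatch(
      stats::nls(count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
                 data = hist_df,
                 start = list(A = max(hist_df$count), mu = m, sigma = s),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit_try)) {
      cf <- stats::coef(fit_try)
      fit <- list(amplitude = unname(cf["A"]), mean = unname(cf["mu"]),
                  sd = abs(unname(cf["sigma"])), converged = TRUE)
    }
  }
  structure(list(
    n = n, mean = m, sd = s, sem = s / sqrt(n),
    envelope95 = envelope95(m, s),
    histogram = hist_df, fit = fit, degenerate = degenerate
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> n = %d: mean %.1f nm, SD %.1f nm (SEM %.2f), 95%% envelope %.0f nm\n",
              x$n, x$mean, x$sd, x$sem, x$envelope95))
  if (x$degenerate) cat("  (degenerate: zero variance)\n")
  invisible(x)
}

#' Convert between SD and SEM
#'
#' `sd = sem * sqrt(n)`; reconciles reports quoting the same
#' distribution by standard error (e.g. +/- 0.05 SEM at n = 1020) and by
#' standard deviation (+/- 1.6 nm SD).
#'
#' @param sem,sd the known quantity.
#' @param n sample size (>= 2).
#' @return The converted quantity.
#' @export
#' @examples
#' sem_to_sd(0.05, 1020)  # 1.597 -> "1.6 nm SD"
sem_to_sd <- function(sem, n) {
  if (any(n < 2)) stop("n must be >= 2")
  sem * sqrt(n)
}

#' @rdname sem_to_sd
#' @export
sd_to_sem <- function(sd, n) {
  if (any(n < 2)) stop("n must be >= 2")
  sd / sqrt(n)
}

#' One-sided 95% positional envelope
#'
#' `mean + 1.96 * sd`: the radius up to which 95% of kinase-domain
#' positions are expected ("up to" — a one-sided bound, which is what
#' reproduces the ~16 nm (alpha) and ~23 nm (beta) envelopes).
#'
#' @param mean,sd distribution moments (nm); `sd >= 0`.
#' @return Envelope (nm).
#' @export
envelope95 <- function(mean, sd) {
  if (any(sd < 0)) stop("sd must be nonnegative")
  mean + 1.96 * sd
}

#' Two-sample comparison: variance-ratio F test then Welch t test
#'
#' The standard two-stage comparison for particle-measurement
#' distributions: a two-sided F test for equality of variances, followed
#' by the unequal-variance (Welch) t test with Welch-Satterthwaite
#' degrees of freedom. Delegates to [stats::var.test()] and
#' [stats::t.test()].
#'
#' @param sample_a,sample_b numeric samples, each n >= 2.
#' @return List: `f_statistic`, `df_f`, `p_f`, `t_statistic`, `df_t`,
#'   `p_t` (all two-sided).
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("both samples need n >= 2")
  }
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      return(list(f_statistic = NA_real_, df_f = c(NA, NA), p_f = NA_real_,
                  t_statistic = 0, df_t = NA_real_, p_t = 1))
    }
    stop("degenerate zero-variance samples with different means")
  }
  ft <- stats::var.test(sample_a, sample_b)
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(f_statistic = unname(ft$statistic), df_f = unname(ft$parameter),
       p_f = ft$p.value,
       t_statistic = unname(tt$statistic), df_t = unname(tt$parameter),
       p_t = tt$p.value)
}

#' Monte-Carlo test for excess short neighbor separations
#'
#' Tests whether a separation distribution is skewed toward short
#' distances relative to the random-tether null: null ensembles are
#' simulated from `null_config` (which must have `dimer_fraction = 0`),
#' and the p-value is the Monte-Carlo tail probability that a null
#' ensemble's fraction of separations below the cutoff reaches the
#' observed fraction. The (1+k)/(1+n_sims) convention keeps p in (0, 1].
#'
#' @param observed_separations observed neighbor separations (nm).
#' @param null_config a [simulation_config()] with `dimer_fraction = 0`.
#' @param n_particles particles per null ensemble; match the number of
#'   particles behind the observations.
#' @param n_sims number of null simulations (values below 100 warn).
#' @param seed integer seed.
#' @param cutoff short-separation cutoff (nm); default 5.0, the upper
#'   edge of the most populated short-distance bin (4.5-5.0 nm).
#' @return List: `p_value`, `observed_fraction`, `null_fractions`,
#'   `cutoff`, `n_sims`, `seed`.
#' @export
null_deviation_test <- function(observed_separations, null_config, n_particles,
                                n_sims = 1000, seed = NULL, cutoff = 5.0) {
  stopifnot(inherits(null_config, "sim_config"))
  if (null_config$dimer_fraction != 0) {
    stop("null_config must have dimer_fraction = 0")
  }
  if (length(observed_separations) == 0) stop("empty observations")
  if (n_sims < 100) warning("n_sims < 100: p-value resolution is coarse")
  obs_frac <- mean(observed_separations < cutoff)
  if (!is.null(seed)) set.seed(seed)
  null_fracs <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    seps <- unlist(lapply(seq_len(n_particles), function(i) {
      neighbor_separation(simulate_particle(null_config))
    }))
    null_fracs[s] <- mean(seps < cutoff)
  }
  p <- (1 + sum(null_fracs >= obs_frac)) / (1 + n_sims)
  list(p_value = p, observed_fraction = obs_frac,
       null_fractions = null_fracs, cutoff = cutoff,
       n_sims = n_sims, seed = seed)
}
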