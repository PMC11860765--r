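# Rate of HAC (human artificial chromosome) loss from flow cytometry.
# The HAC carries a GFP reporter, so the GFP+ fraction of live cells tracks
# HAC retention; comparing it before and after a treatment over n divisions
# gives the per-division loss rate R = 2 - 2 * (P_si / P0)^(1/n). The number
# of divisions n (division index, DI) is estimated from a dye-dilution
# experiment by a constrained halving-peak mixture fit.

gate_valley_threshold <- function(x) {
  # valley between a two-component normal mixture fitted to log-intensities
  lx <- log(pmax(x, .Machine$double.eps))
  if (sd(lx) == 0) return(exp(lx[1]))
  mu <- quantile(lx, c(0.25, 0.75), names = FALSE)
  s2 <- rep(stats::var(lx) / 4, 2)
  pi1 <- 0.5
  for (i in 1:200) {
    d1 <- pi1 * dnorm(lx, mu[1], sqrt(s2[1]))
    d2 <- (1 - pi1) * dnorm(lx, mu[2], sqrt(s2[2]))
    r <- d1 / pmax(d1 + d2, .Machine$double.xmin)
    pi_new <- mean(r)
    mu_new <- c(sum(r * lx) / sum(r), sum((1 - r) * lx) / sum(1 - r))
    s2_new <- c(sum(r * (lx - mu_new[1])^2) / sum(r),
                sum((1 - r) * (lx - mu_new[2])^2) / sum(1 - r))
    s2_new <- pmax(s2_new, 1e-6)
    if (max(abs(mu_new - mu)) < 1e-8) { mu <- mu_new; s2 <- s2_new; pi1 <- pi_new; break }
    mu <- mu_new; s2 <- s2_new; pi1 <- pi_new
  }
  lo <- min(mu); hi <- max(mu)
  if (hi - lo < 1e-6) return(exp(mean(mu)))
  grid <- seq(lo, hi, length.out = 512)
  dens <- pi1 * dnorm(grid, mu[1], sqrt(s2[1])) + (1 - pi1) * dnorm(grid, mu[2], sqrt(s2[2]))
  exp(grid[which.min(dens)])
}

check_channel <- function(events, channel) {
  if (!is.data.frame(events)) abort("`events` must be a data frame")
  if (!channel %in% names(events)) {
    abort(paste0("channel `", channel, "` not found in the event table"))
  }
}

#' Gate live events on the viability dye
#'
#' Keeps events whose viability-dye intensity is below the threshold (dead
#' cells take up the dye). Counts are conserved: the numbers of live and dead
#' events, attached as attribute `"gate_counts"`, always sum to the input.
#'
#' @param events Event table (one row per event, one column per channel).
#' @param viability_threshold Gate in intensity units; if `NULL`, the valley
#'   between a two-component log-normal mixture fit is used.
#' @param channel Viability channel name.
#' @return The live subset of `events`, with attribute `gate_counts`
#'   (`total`, `live`, `dead`, `threshold`).
#' @export
gate_live <- function(events, viability_threshold = NULL, channel = "viability_dye") {
  check_channel(events, channel)
  x <- events[[channel]]
  if (any(!is.finite(x) | x < 0)) abort("viability intensities must be finite and >= 0")
  thr <- viability_threshold %||% gate_valley_threshold(x)
  live <- dplyr::filter(events, .data[[channel]] < thr)
  attr(live, "gate_counts") <- c(total = nrow(events), live = nrow(live),
                                 dead = nrow(events) - nrow(live), threshold = thr)
  live
}

#' Fraction of GFP-positive events
#'
#' The proportion of events at or above the GFP gate, among the (live)
#' events supplied.
#'
#' @param live_events Event table, typically the output of [gate_live()].
#' @param gfp_threshold Gate in intensity units; if `NULL`, the valley of a
#'   two-component log-normal mixture fit is used.
#' @param channel GFP channel name.
#' @return Fraction in \[0, 1\].
#' @export
gfp_positive_fraction <- function(live_events, gfp_threshold = NULL, channel = "gfp") {
  check_channel(live_events, channel)
  if (nrow(live_events) == 0) {
    abort("no live events: cannot compute a GFP+ fraction from an empty table")
  }
  thr <- gfp_threshold %||% gate_valley_threshold(live_events[[channel]])
  mean(live_events[[channel]] >= thr)
}

#' Fit a constrained halving-peak mixture to dye-dilution data
#'
#' Re-implements the standard proliferation-curve fit: log-fluorescence is a
#' Gaussian mixture whose component means are constrained to
#' `mu0 + g * log(ratio)` for generations g = 0..(n_peaks - 1), with a common
#' SD fixed from the undivided reference population. Only the generation
#' weights are free (maximum likelihood via EM on the weight simplex); the
#' anchor `mu0` is refined within +/- 0.5 SD of the reference mean.
#'
#' @param events Event table of the proliferating population.
#' @param undivided_reference Event table of the undivided population (sets
#'   the peak anchor and CV).
#' @param n_peaks Number of peaks (generations 0..n_peaks-1); conventionally
#'   6-8, default 7.
#' @param ratio Successive-peak fluorescence ratio, default 0.5 (halving).
#' @param channel Proliferation-dye channel name.
#' @return An object of class `proliferation_fit`: `mu0`, `sigma`, `ratio`,
#'   `weights` (named by generation), `loglik`, `n_events`. Methods:
#'   [tidy()], [glance()], [autoplot()], `print()`.
#' @export
fit_dye_dilution <- function(events, undivided_reference, n_peaks = 7,
                             ratio = 0.5, channel = "proliferation_dye") {
  check_channel(events, channel)
  check_channel(undivided_reference, channel)
  if (nrow(events) == 0 || nrow(undivided_reference) == 0) {
    abort("event tables must be nonempty")
  }
  if (n_peaks < 2) abort("`n_peaks` must be at least 2")
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must be in (0, 1)")
  lref <- log(undivided_reference[[channel]])
  sigma <- sd(lref)
  if (!is.finite(sigma) || sigma <= 0) {
    abort("degenerate undivided reference: zero variance")
  }
  mu0_init <- mean(lref)
  lx <- log(events[[channel]])
  gens <- 0:(n_peaks - 1L)

  em_weights <- function(mu0) {
    dens <- vapply(gens, function(g) dnorm(lx, mu0 + g * log(ratio), sigma),
                   numeric(length(lx)))
    w <- rep(1 / n_peaks, n_peaks)
    ll <- -Inf
    for (i in 1:500) {
      num <- sweep(dens, 2, w, "*")
      tot <- rowSums(num)
      tot[tot <= 0] <- .Machine$double.xmin
      w_new <- colMeans(num / tot)
      ll_new <- sum(log(tot))
      if (abs(ll_new - ll) < 1e-10 * abs(ll_new) + 1e-12) { w <- w_new; ll <- ll_new; break }
      w <- w_new; ll <- ll_new
    }
    list(weights = w, loglik = ll)
  }

  prof <- function(mu0) em_weights(mu0)$loglik
  opt <- optimize(prof, interval = mu0_init + c(-0.5, 0.5) * sigma, maximum = TRUE)
  # keep the anchor if refinement did not improve on it
  mu0 <- if (opt$objective >= prof(mu0_init)) opt$maximum else mu0_init
  fit <- em_weights(mu0)
  structure(
    list(mu0 = mu0, sigma = sigma, ratio = ratio,
         weights = setNames(fit$weights, paste0("g", gens)),
         loglik = fit$loglik, n_events = length(lx), n_peaks = n_peaks),
    class = "proliferation_fit"
  )
}

#' @export
print.proliferation_fit <- function(x, ...) {
  cat("Constrained halving-peak mixture fit\n")
  cat(sprintf("  %d events, %d peaks, ratio %.3g, sigma %.4g (log a.u.)\n",
              x$n_events, x$n_peaks, x$ratio, x$sigma))
  cat(sprintf("  anchor mu0 = %.4g (undivided peak at %.4g a.u.)\n", x$mu0, exp(x$mu0)))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat(sprintf("  division index: %.3f (precursor-weighted), %.3f (event-weighted)\n",
              division_index(x, "precursor_weighted"),
              division_index(x, "event_weighted")))
  invisible(x)
}

#' @export
tidy.proliferation_fit <- function(x, ...) {
  gens <- 0:(x$n_peaks - 1L)
  tibble::tibble(
    generation = gens,
    weight = unname(x$weights),
    peak_mean = exp(x$mu0 + gens * log(x$ratio))
  )
}

#' @export
glance.proliferation_fit <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events, n_peaks = x$n_peaks,
    mu0 = x$mu0, sigma = x$sigma, ratio = x$ratio, loglik = x$loglik,
    di_precursor = division_index(x, "precursor_weighted"),
    di_event = division_index(x, "event_weighted")
  )
}

#' Division index from a proliferation fit
#'
#' The division index (DI) is the mean number of divisions. Two conventions
#' are supported: `"precursor_weighted"` (default) averages over founder
#' cells, down-weighting each generation's event count by 2^g,
#' DI = sum(g * w_g / 2^g) / sum(w_g / 2^g); `"event_weighted"` averages over
#' measured events, DI = sum(g * w_g).
#'
#' @param fit A `proliferation_fit` object, or a bare numeric vector of
#'   generation weights over generations 0, 1, 2, ...
#' @param definition Weighting convention (see above).
#' @return Scalar division index (>= 0).
#' @export
division_index <- function(fit, definition = c("precursor_weighted", "event_weighted")) {
  definition <- match.arg(definition)
  w <- if (inherits(fit, "proliferation_fit")) unname(fit$weights) else as.numeric(fit)
  if (any(w < 0) || sum(w) <= 0) abort("weights must be non-negative and sum to a positive value")
  w <- w / sum(w)
  g <- seq_along(w) - 1
  if (definition == "event_weighted") {
    sum(g * w)
  } else {
    pw <- w / 2^g
    sum(g * pw) / sum(pw)
  }
}

#' Per-division rate of HAC loss
#'
#' `R = 2 - 2 * (p_si / p0)^(1/n)`, the probability-scale loss rate per
#' division comparing the GFP+ fraction after treatment (`p_si`) with the
#' baseline (`p0`) over `n` divisions. `R = 0` when `p_si = p0` and tends to
#' 2 as `p_si` tends to 0. Fractions and percentages are both accepted (the
#' ratio is scale-invariant), but the two arguments must use the same scale.
#'
#' @param p_si GFP+ fraction after treatment.
#' @param p0 GFP+ fraction at baseline (> 0).
#' @param n Number of divisions (> 0), typically a division index from
#'   [division_index()].
#' @return Rate(s) of HAC loss. Values for `p_si > p0` are negative and
#'   flagged with a warning (apparent HAC gain).
#' @examples
#' hac_loss_rate(0.2, 0.8, 2) # exactly 1: the GFP+ pool halves each division
#' @export
hac_loss_rate <- function(p_si, p0, n) {
  if (any(p0 <= 0)) abort("`p0` must be > 0")
  if (any(n <= 0)) abort("`n` must be > 0")
  if (any(p_si < 0)) abort("`p_si` must be >= 0")
  if (any(p_si > p0)) {
    warn("`p_si` exceeds `p0` for some inputs: negative loss rate (apparent gain)")
  }
  2 - 2 * (p_si / p0)^(1 / n)
}

#' Full HAC-loss estimate from raw event tables
#'
#' Convenience wrapper chaining the stages: live gating and GFP+ fractions
#' for the baseline and treated tables, the dye-dilution mixture fit for the
#' division index, and the loss-rate formula.
#'
#' @param baseline,treated GFP/viability event tables before and after
#'   treatment.
#' @param dye_events,undivided_reference Proliferation-dye event tables for
#'   the treated population and the undivided reference.
#' @param gfp_threshold,viability_threshold Optional manual gates (auto
#'   valley gates when `NULL`).
#' @param n_peaks,ratio Mixture-fit settings (see [fit_dye_dilution()]).
#' @param definition Division-index convention (see [division_index()]).
#' @return One-row tibble: `p0`, `p_si`, `n`, `rate`, `flagged` (TRUE when
#'   `p_si > p0`).
#' @export
estimate_hac_loss <- function(baseline, treated, dye_events, undivided_reference,
                              gfp_threshold = NULL, viability_threshold = NULL,
                              n_peaks = 7, ratio = 0.5,
                              definition = c("precursor_weighted", "event_weighted")) {
  definition <- match.arg(definition)
  p0 <- gfp_positive_fraction(gate_live(baseline, viability_threshold), gfp_threshold)
  p_si <- gfp_positive_fraction(gate_live(treated, viability_threshold), gfp_threshold)
  fit <- fit_dye_dilution(dye_events, undivided_reference, n_peaks = n_peaks, ratio = ratio)
  n <- division_index(fit, definition)
  rate <- if (p_si > p0) {
    withCallingHandlers(hac_loss_rate(p_si, p0, n),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else {
    hac_loss_rate(p_si, p0, n)
  }
  tibble::tibble(p0 = p0, p_si = p_si, n = n, rate = rate, flagged = p_si > p0)
}
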