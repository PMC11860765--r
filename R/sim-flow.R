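# Simulators for flow-cytometry-like event tables: dye-dilution proliferation
# profiles with halving peaks, and GFP/viability mixtures for the HAC
# stability readout. Every generator is a pure function of its arguments and
# `seed`, and returns the full ground truth alongside the events.

#' Generation weights realizing a target division index
#'
#' Maps a target division index (DI) to a vector of per-generation event
#' weights for [sim_dye_dilution()]. Divisions per founder cell are modeled
#' as Binomial(`n_generations`, DI / `n_generations`), the simplest
#' asynchronous-division model; its mean equals DI exactly under the chosen
#' definition.
#'
#' @param di Target division index (mean divisions), in
#'   \[0, `n_generations`\].
#' @param n_generations Maximum number of divisions G; events fall in
#'   generations 0..G (G + 1 peaks; 6 gives the conventional 7 peaks).
#' @param definition `"precursor_weighted"` (DI averaged over founder cells;
#'   default) or `"event_weighted"` (averaged over measured events).
#' @return Numeric vector of event weights over generations 0..G, summing
#'   to 1.
#' @seealso [division_index()] for the matching estimator-side definitions.
#' @export
generation_weights_from_di <- function(di, n_generations = 6,
                                       definition = c("precursor_weighted", "event_weighted")) {
  definition <- match.arg(definition)
  if (di < 0 || di > n_generations) {
    abort("`di` must lie in [0, n_generations]")
  }
  g <- 0:n_generations
  w <- dbinom(g, n_generations, di / n_generations)
  if (definition == "precursor_weighted") {
    # binomial over founders; each founder in generation g contributes 2^g cells
    w <- w * 2^g
  }
  w / sum(w)
}

#' Simulate a dye-dilution proliferation experiment
#'
#' Events are assigned to generations 0..G with probabilities
#' `generation_weights`; an event in generation g has log-fluorescence drawn
#' from Normal(log(`undivided_mean`) + g * log(`peak_ratio`), `cv`), i.e.
#' successive peaks at a fixed fluorescence ratio (0.5 = halving per
#' division) with a common log-domain width.
#'
#' @param n_events Number of events.
#' @param generation_weights Non-negative event weights over generations
#'   0..G (normalized internally).
#' @param undivided_mean Fluorescence of the undivided peak (a.u.).
#' @param cv Coefficient of variation of a peak; used as the log-domain SD
#'   (exact to first order for small `cv`).
#' @param peak_ratio Successive-peak fluorescence ratio in (0, 1);
#'   default 0.5.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A list with `events` (tibble: `proliferation_dye`, `generation`)
#'   and `truth` (list: the normalized `weights`, realized per-generation
#'   counts, and the true division index under both definitions,
#'   `di_precursor` and `di_event`).
#' @export
sim_dye_dilution <- function(n_events, generation_weights,
                             undivided_mean = 1e4, cv = 0.10,
                             peak_ratio = 0.5, seed = 1) {
  if (length(generation_weights) < 1 || any(generation_weights < 0) ||
      sum(generation_weights) <= 0) {
    abort("`generation_weights` must be non-negative and sum to a positive value")
  }
  if (peak_ratio <= 0 || peak_ratio >= 1) abort("`peak_ratio` must be in (0, 1)")
  w <- generation_weights / sum(generation_weights)
  g_max <- length(w) - 1L
  gens <- 0:g_max
  events <- withr::with_seed(seed, {
    g <- sample(gens, n_events, replace = TRUE, prob = w)
    lf <- log(undivided_mean) + g * log(peak_ratio) + rnorm(n_events, sd = cv)
    tibble::tibble(proliferation_dye = exp(lf), generation = g)
  })
  pw <- w / 2^gens
  truth <- list(
    weights = w,
    counts = tabulate(events$generation + 1L, g_max + 1L),
    di_event = sum(gens * w),
    di_precursor = sum(gens * pw) / sum(pw)
  )
  list(events = events, truth = truth)
}

#' Simulate a GFP/viability flow table for the HAC stability assay
#'
#' Events are a mixture of live and dead cells; live cells are GFP-positive
#' with probability `gfp_positive_fraction`. Dead cells take up the viability
#' dye (high intensity); GFP status is encoded as a low/high log-normal
#' mixture on the `gfp` channel. Dead cells are GFP-negative (the reporter
#' decays on death).
#'
#' @param n_events Number of events.
#' @param gfp_positive_fraction Probability that a live cell is GFP+.
#' @param dead_fraction Probability that an event is a dead cell.
#' @param gfp_levels Named vector `c(neg=, pos=)` of GFP channel medians.
#' @param viability_levels Named vector `c(live=, dead=)` of viability-dye
#'   medians.
#' @param cv Log-domain SD of every intensity population.
#' @param seed Integer seed.
#' @return List with `events` (tibble: `gfp`, `viability_dye`) and `truth`
#'   (realized `gfp_positive_fraction` among live events, realized
#'   `dead_fraction`, and the per-event labels).
#' @export
sim_hac_flow <- function(n_events, gfp_positive_fraction, dead_fraction = 0,
                         gfp_levels = c(neg = 150, pos = 5000),
                         viability_levels = c(live = 120, dead = 6000),
                         cv = 0.25, seed = 1) {
  for (f in c(gfp_positive_fraction, dead_fraction)) {
    if (f < 0 || f > 1) abort("fractions must lie in [0, 1]")
  }
  out <- withr::with_seed(seed, {
    dead <- runif(n_events) < dead_fraction
    gfp_pos <- !dead & (runif(n_events) < gfp_positive_fraction)
    gfp_mu <- ifelse(gfp_pos, gfp_levels[["pos"]], gfp_levels[["neg"]])
    via_mu <- ifelse(dead, viability_levels[["dead"]], viability_levels[["live"]])
    tibble::tibble(
      gfp = exp(log(gfp_mu) + rnorm(n_events, sd = cv)),
      viability_dye = exp(log(via_mu) + rnorm(n_events, sd = cv)),
      dead = dead, gfp_positive = gfp_pos
    )
  })
  n_live <- sum(!out$dead)
  truth <- list(
    gfp_positive_fraction = if (n_live > 0) sum(out$gfp_positive) / n_live else NA_real_,
    dead_fraction = mean(out$dead),
    labels = out[c("dead", "gfp_positive")]
  )
  list(events = out[c("gfp", "viability_dye")], truth = truth)
}
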