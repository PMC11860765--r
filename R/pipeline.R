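# Reproducible multi-stage runs: a flat configuration drives simulation and
# analysis stages, every stage writes CSV artifacts plus a line-oriented
# key=value log, and condition tables aggregate per-cell readouts into
# per-replicate and per-condition means.

signif6 <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
}

write_csv6 <- function(df, path) {
  readr::write_csv(signif6(df), path, progress = FALSE)
}

log_line <- function(con, stage, ...) {
  kv <- c(...)
  writeLines(paste0("stage=", stage, " ",
                    paste(names(kv), unname(kv), sep = "=", collapse = " ")), con)
}

#' Aggregate per-cell readouts into a condition table
#'
#' Computes per-condition means with dispersion from pooled per-cell (or
#' per-nucleus) values, and per-replicate means separately so that
#' replicate-level statistics can be applied downstream. With a control
#' condition, every mean is also normalized to the control mean (control
#' maps to 1).
#'
#' @param data Data frame of per-cell values.
#' @param value,condition Columns (tidy-eval) holding the readout and
#'   condition label.
#' @param replicate Optional replicate column (tidy-eval).
#' @param control Optional control condition label for normalization.
#' @return Object of class `condition_table`: list with `conditions`
#'   (tibble: `condition`, `n`, `mean`, `sd`, `se`, and `normalized_mean`
#'   when a control is given) and `replicates` (tibble of per-replicate
#'   means, or `NULL`).
#' @export
condition_table <- function(data, value, condition, replicate = NULL,
                            control = NULL) {
  if (!nrow(data)) abort("`data` is empty")
  cond <- dplyr::pull(data, {{ condition }})
  if (!is.null(control) && !control %in% cond) {
    abort(paste0("control condition `", control, "` not present in the data"))
  }
  conds <- data |>
    dplyr::group_by(condition = {{ condition }}) |>
    dplyr::summarise(n = dplyr::n(), mean = mean({{ value }}),
                     sd = sd({{ value }}), .groups = "drop") |>
    dplyr::mutate(se = .data$sd / sqrt(.data$n))
  reps <- NULL
  if (!rlang::quo_is_null(rlang::enquo(replicate))) {
    reps <- data |>
      dplyr::group_by(condition = {{ condition }}, replicate = {{ replicate }}) |>
      dplyr::summarise(n = dplyr::n(), mean = mean({{ value }}), .groups = "drop")
  }
  if (!is.null(control)) {
    m0 <- conds$mean[conds$condition == control]
    if (m0 == 0) abort("control mean is zero; cannot normalize")
    conds$normalized_mean <- conds$mean / m0
    if (!is.null(reps)) reps$normalized_mean <- reps$mean / m0
  }
  structure(list(conditions = conds, replicates = reps, control = control),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat("Condition summary", if (!is.null(x$control))
    sprintf("(normalized to %s)", x$control), "\n")
  print(x$conditions)
  if (!is.null(x$replicates)) {
    cat("Replicate means:\n"); print(x$replicates)
  }
  invisible(x)
}

#' @export
tidy.condition_table <- function(x, ...) x$conditions

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  if (is.null(config$out_dir)) abort("config must set `out_dir`")
  if (is.null(config$stages) || !length(config$stages)) abort("config must list `stages`")
  bad <- setdiff(config$stages, c("hacloss", "exofish", "coloc", "colonies"))
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  ex <- config$exofish
  if ("exofish" %in% config$stages && isTRUE(ex$normalize) &&
      is.null(ex$control_condition)) {
    abort("exofish stage requests normalization but sets no `control_condition`")
  }
  config$seed <- config$seed %||% 1L
  config
}

stage_hacloss <- function(cfg, seed, out_dir, logcon) {
  p <- cfg$hacloss
  if (!is.null(p$baseline_csv)) {
    baseline <- readr::read_csv(p$baseline_csv, show_col_types = FALSE)
    treated <- readr::read_csv(p$treated_csv, show_col_types = FALSE)
    dye <- readr::read_csv(p$dye_csv, show_col_types = FALSE)
    undiv <- readr::read_csv(p$undivided_csv, show_col_types = FALSE)
  } else {
    n <- p$n_events %||% 20000
    w <- generation_weights_from_di(p$di %||% 3.33, p$n_generations %||% 6)
    baseline <- sim_hac_flow(n, p$p0 %||% 0.9, p$dead_fraction %||% 0.05,
                             seed = seed)$events
    treated <- sim_hac_flow(n, p$p_si %||% 0.6, p$dead_fraction %||% 0.05,
                            seed = seed + 1L)$events
    dye <- sim_dye_dilution(n, w, cv = p$cv %||% 0.10, seed = seed + 2L)$events
    undiv <- sim_dye_dilution(n, c(1), cv = p$cv %||% 0.10, seed = seed + 3L)$events
  }
  res <- estimate_hac_loss(baseline, treated, dye, undiv,
                           n_peaks = p$n_peaks %||% 7, ratio = p$ratio %||% 0.5)
  write_csv6(res, file.path(out_dir, "hac_loss.csv"))
  log_line(logcon, "hacloss", n_baseline = nrow(baseline), n_treated = nrow(treated),
           p0 = signif(res$p0, 6), p_si = signif(res$p_si, 6),
           n = signif(res$n, 6), rate = signif(res$rate, 6))
  res
}

stage_exofish <- function(cfg, seed, out_dir, logcon) {
  p <- cfg$exofish
  conditions <- p$conditions %||% list(control = 1.0)
  base_amp <- p$focus_amplitude %||% 800
  cells <- list()
  for (i in seq_along(conditions)) {
    f <- sim_exofish_field(
      n_cells = p$n_cells %||% 25, foci_per_cell = p$foci_per_cell %||% 6,
      focus_amplitude = base_amp * conditions[[i]],
      noise_sd = p$noise_sd %||% 15, seed = seed + i)
    q <- quantify_foci(f$image, f$labels, threshold = p$threshold %||% 400,
                       min_area = p$min_area %||% 2,
                       box_size = p$box_size %||% 10)
    q$condition <- names(conditions)[i]
    cells[[i]] <- q
    log_line(logcon, "exofish", condition = names(conditions)[i],
             cells_in = max(f$labels), cells_kept = nrow(q),
             cells_excluded = max(f$labels) - nrow(q))
  }
  per_cell <- dplyr::bind_rows(cells)
  if (isTRUE(p$normalize)) {
    per_cell <- normalize_to_control(per_cell, .data$signal_sum,
                                     .data$condition, p$control_condition)
  }
  write_csv6(per_cell, file.path(out_dir, "exofish_per_cell.csv"))
  ct <- condition_table(per_cell, .data$signal_sum, .data$condition,
                        control = p$control_condition)
  write_csv6(ct$conditions, file.path(out_dir, "exofish_conditions.csv"))
  per_cell
}

stage_coloc <- function(cfg, seed, out_dir, logcon) {
  p <- cfg$coloc
  amp <- p$amplitude %||% 3000
  stack <- sim_stack(
    dims = unlist(p$dims %||% c(160, 160, 15)),
    n_nuclei = p$n_nuclei %||% 4, nucleus_radius = p$nucleus_radius %||% 1.8,
    channels = list(ref = list(n_spots = 0, spot_radius = 0.25, amplitude = amp),
                    partner = list(n_spots = p$extra_spots %||% 0,
                                   spot_radius = 0.25, amplitude = amp)),
    engineered_overlaps = tibble::tibble(
      ref_channel = "ref", partner_channel = "partner",
      fraction = unlist(p$fractions %||% c(0.5, 0.5, 0, 0))),
    seed = seed)
  # little z smoothing: the 0.71 um slice spacing already undersamples foci
  spot_params <- list(smooth_sigma = c(1, 1, 0.3),
                      seed_threshold = p$seed_threshold %||% amp / 2,
                      include_threshold = p$include_threshold %||% amp / 4)
  res <- withCallingHandlers(
    analyze_stack(stack, "ref", "partner", spot_params,
                  min_fraction = p$min_overlap %||% 0.10,
                  n_select = p$n_select %||% 100, seed = seed,
                  area_limit_um2 = p$area_limit %||% 300),
    warning = function(w) invokeRestart("muffleWarning"))
  write_csv6(res$events, file.path(out_dir, "coloc_events.csv"))
  write_csv6(tidy(res$summary), file.path(out_dir, "coloc_per_nucleus.csv"))
  write_csv6(glance(res$summary), file.path(out_dir, "coloc_summary.csv"))
  write_csv6(res$excluded, file.path(out_dir, "coloc_excluded.csv"))
  log_line(logcon, "coloc", nuclei_in = res$n_segmented,
           nuclei_kept = res$summary$n_nuclei,
           nuclei_excluded = res$n_segmented - res$summary$n_nuclei,
           events = nrow(res$events))
  res
}

stage_colonies <- function(cfg, seed, out_dir, logcon) {
  p <- cfg$colonies
  plate <- sim_colony_plate(n_disks = p$n_disks %||% 12,
                            disk_radius = p$disk_radius %||% 6,
                            streak_length = p$streak_length,
                            seed = seed)
  cc <- count_colonies(plate$image, threshold = p$threshold %||% 100)
  write_csv6(cc$objects, file.path(out_dir, "colonies.csv"))
  log_line(logcon, "colonies", objects_in = nrow(cc$objects), kept = cc$count,
           excluded = nrow(cc$objects) - cc$count)
  cc
}

#' Run a configured multi-stage analysis
#'
#' Executes the requested stages (`hacloss`, `exofish`, `coloc`,
#' `colonies`), each either simulating its inputs or reading the CSVs named
#' in the config, and writes every stage's tables under `out_dir` together
#' with a `run.log` of parameters and in/kept/excluded counts for every
#' filter. Identical config + seed yields byte-identical outputs.
#'
#' @param config Named list or path to a YAML file. Must set `out_dir` and
#'   `stages`; each stage reads its own sub-list of parameters (see the
#'   package vignette for the schema).
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return Invisible named list of per-stage results.
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- validate_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon), add = TRUE)
  log_line(logcon, "run", seed = seed,
           stages = paste(cfg$stages, collapse = ","),
           package_version = as.character(utils::packageVersion("censtab")))
  results <- list()
  for (st in cfg$stages) {
    results[[st]] <- tryCatch(
      switch(st,
             hacloss = stage_hacloss(cfg, seed, out_dir, logcon),
             exofish = stage_exofish(cfg, seed, out_dir, logcon),
             coloc = stage_coloc(cfg, seed, out_dir, logcon),
             colonies = stage_colonies(cfg, seed, out_dir, logcon)),
      error = function(e) {
        abort(paste0("stage `", st, "` failed: ", conditionMessage(e)),
              parent = e)
      })
  }
  invisible(results)
}
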