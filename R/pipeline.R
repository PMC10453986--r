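#' Analysis run configuration
#'
#' Bundles every tunable of the distributional pipeline; the defaults are
#' the analysis' standard choices (100 ms outlier cutoff, quantile levels
#' .1-.9, the speed/accuracy overlap quantile subsets).
#'
#' @param input Optional path to a delimited trial file (see
#'   [read_trials()]); `NULL` when trials are passed directly or simulated.
#' @param design [lca_design()] used by [simulate_and_analyze()].
#' @param params [lca_params()] used by [simulate_and_analyze()].
#' @param probs Quantile levels.
#' @param min_rt Outlier cutoff in ms.
#' @param subsets Overlap quantile subsets per instruction.
#' @param seed Integer seed (single source of randomness).
#' @param participant_cv Between-participant jitter for simulation.
#' @param out_dir Optional directory: result tables are written there as
#'   CSV files.
#' @param stages Named logical toggles: `distributional`, `error_bins`,
#'   `inference`. Disabled stages are skipped independently.
#' @param col_map Optional column mapping for [read_trials()].
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, design = lca_design(),
                       params = lca_params(),
                       probs = c(.1, .3, .5, .7, .9), min_rt = 100,
                       subsets = overlap_subsets(), seed = 1,
                       participant_cv = 0.1, out_dir = NULL,
                       stages = list(distributional = TRUE, error_bins = TRUE,
                                     inference = TRUE),
                       col_map = NULL) {
  stopifnot(is.null(input) || is.character(input))
  defaults <- list(distributional = TRUE, error_bins = TRUE, inference = TRUE)
  defaults[names(stages)] <- stages
  structure(list(input = input, design = design, params = params,
                 probs = probs, min_rt = min_rt, subsets = subsets,
                 seed = seed, participant_cv = participant_cv,
                 out_dir = out_dir, stages = defaults, col_map = col_map),
            class = "run_config")
}

write_stage_csv <- function(tbl, name, out_dir) {
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(tbl, file.path(out_dir, paste0(name, ".csv")))
  }
  invisible(tbl)
}

#' Run the full distributional analysis
#'
#' Executes outlier filtering, cell summaries, delta plots, overlap-range
#' slopes, overlap centres, cubic level matching, binned error congruency
#' effects, and the inferential battery (three-way rm-ANOVA on mean RTs,
#' instruction x soa ANOVA on slopes, one-way ANOVA on level differences,
#' Friedman tests of the error-rate congruency effect across asynchronies
#' per instruction, Wilcoxon tests of that effect against zero per
#' instruction and asynchrony, group slope means with 95% confidence
#' intervals).
#'
#' @param trials A validated trial table (from [read_trials()] or
#'   [simulate_experiment()]), or `NULL` to read `config$input`.
#' @param config A [run_config()].
#' @return A `simon_analysis` list of tibbles: `outliers`, `summaries`,
#'   `delta`, `slopes`, `slope_means`, `slope_anova`, `centers`, `levels`,
#'   `level_diffs`, `level_diff_anova`, `error_bins`, `rt_anova`,
#'   `rt_cell_means`, `descriptives`, `error_friedman`, `error_wilcoxon`.
#'   Stages that are toggled off (or not computable) are `NULL`.
#' @export
run_analysis <- function(trials = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(trials)) {
    if (is.null(config$input)) stop("no trials and no input path in config",
                                    call. = FALSE)
    trials <- read_trials(config$input, col_map = config$col_map)
  }
  out_dir <- config$out_dir
  res <- list(config = config)

  filtered <- filter_outliers(trials, min_rt = config$min_rt)
  res$outliers <- write_stage_csv(outlier_report(filtered), "outliers", out_dir)
  res$summaries <- write_stage_csv(cell_summaries(filtered, config$probs),
                                   "cell_summaries", out_dir)

  if (isTRUE(config$stages$distributional)) {
    res$delta <- write_stage_csv(delta_plots(res$summaries), "delta_plots", out_dir)
    res$slopes <- write_stage_csv(overlap_slopes(res$delta, config$subsets),
                                  "slopes", out_dir)
    # per-soa group mean slope: participants' speed/accuracy slopes averaged
    # first so each participant contributes one value
    subj_slope <- res$slopes |>
      dplyr::group_by(.data$participant, .data$soa) |>
      dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
    res$slope_means <- write_stage_csv(
      subj_slope |>
        dplyr::group_by(.data$soa) |>
        dplyr::group_modify(~ ci_mean(.x$slope)) |>
        dplyr::ungroup(),
      "slope_means", out_dir)
    res$centers <- write_stage_csv(overlap_centers(res$delta), "overlap_centers",
                                   out_dir)
    res$levels <- write_stage_csv(
      suppressWarnings(cubic_levels(res$delta, res$centers)), "cubic_levels",
      out_dir)
    lvl <- res$levels |>
      tidyr::pivot_wider(id_cols = c("participant", "soa"),
                         names_from = "instruction", values_from = "ce_at_rt") |>
      dplyr::mutate(diff = .data$speed - .data$accuracy)
    res$level_diffs <- write_stage_csv(
      lvl |>
        dplyr::group_by(.data$soa) |>
        dplyr::group_modify(~ ci_mean(.x$diff)) |>
        dplyr::ungroup(),
      "level_diffs", out_dir)
  }

  if (isTRUE(config$stages$error_bins)) {
    res$error_bins <- write_stage_csv(
      suppressWarnings(error_bin_ce(filtered, config$probs)), "error_bins",
      out_dir)
  }

  if (isTRUE(config$stages$inference)) {
    two_instr <- length(unique(res$summaries$instruction)) == 2
    multi_soa <- length(unique(res$summaries$soa)) >= 2
    res$rt_cell_means <- res$summaries |>
      dplyr::select("participant", "instruction", "soa", "congruency",
                    "mean_rt")
    if (two_instr && multi_soa) {
      res$rt_anova <- rm_anova(res$rt_cell_means, "mean_rt", "participant",
                               c("instruction", "soa", "congruency"))
      write_stage_csv(tidy(res$rt_anova), "rt_anova", out_dir)
      if (!is.null(res$slopes)) {
        res$slope_anova <- rm_anova(res$slopes, "slope", "participant",
                                    c("instruction", "soa"))
        write_stage_csv(tidy(res$slope_anova), "slope_anova", out_dir)
        lvl_long <- res$levels |>
          tidyr::pivot_wider(id_cols = c("participant", "soa"),
                             names_from = "instruction",
                             values_from = "ce_at_rt") |>
          dplyr::mutate(diff = .data$speed - .data$accuracy)
        res$level_diff_anova <- rm_anova(lvl_long, "diff", "participant", "soa")
        write_stage_csv(tidy(res$level_diff_anova), "level_diff_anova", out_dir)
      }
    }
    # congruency effect for error rates, per participant x instruction x soa
    err_ce <- res$summaries |>
      tidyr::pivot_wider(id_cols = c("participant", "instruction", "soa"),
                         names_from = "congruency", values_from = "error_pct") |>
      dplyr::mutate(ce_err = .data$incongruent - .data$congruent)
    res$error_ce <- err_ce
    if (multi_soa && length(unique(err_ce$soa)) >= 3) {
      res$error_friedman <- err_ce |>
        dplyr::group_by(.data$instruction) |>
        dplyr::group_modify(~ friedman_test(.x, "ce_err", "participant", "soa")) |>
        dplyr::ungroup()
      write_stage_csv(res$error_friedman, "error_friedman", out_dir)
    }
    res$error_wilcoxon <- err_ce |>
      dplyr::group_by(.data$instruction, .data$soa) |>
      dplyr::group_modify(function(d, key) {
        # a condition without any nonzero difference has no evidence either
        # way; report NA rather than aborting the whole pipeline
        tryCatch(wilcoxon_signed_rank(d$ce_err),
                 error = function(e) tibble::tibble(
                   statistic = NA_real_, n = nrow(d), n_nonzero = 0L,
                   p = NA_real_))
      }) |>
      dplyr::ungroup()
    write_stage_csv(res$error_wilcoxon, "error_wilcoxon", out_dir)

    # headline descriptives
    resp <- res$rt_cell_means
    ce_soa <- resp |>
      tidyr::pivot_wider(id_cols = c("participant", "instruction", "soa"),
                         names_from = "congruency", values_from = "mean_rt") |>
      dplyr::mutate(ce = .data$incongruent - .data$congruent)
    res$descriptives <- write_stage_csv(
      list(
        mean_rt_by_instruction = resp |>
          dplyr::group_by(.data$instruction) |>
          dplyr::summarise(mean_rt = mean(.data$mean_rt), .groups = "drop"),
        mean_rt_by_soa = resp |>
          dplyr::group_by(.data$soa) |>
          dplyr::summarise(mean_rt = mean(.data$mean_rt), .groups = "drop"),
        ce_by_soa = ce_soa |>
          dplyr::group_by(.data$soa) |>
          dplyr::summarise(ce = mean(.data$ce), .groups = "drop"),
        ce_by_instruction_soa = ce_soa |>
          dplyr::group_by(.data$instruction, .data$soa) |>
          dplyr::summarise(ce = mean(.data$ce), .groups = "drop"),
        error_pct_by_instruction = res$summaries |>
          dplyr::group_by(.data$instruction) |>
          dplyr::summarise(error_pct = mean(.data$error_pct), .groups = "drop"),
        error_pct_by_soa = res$summaries |>
          dplyr::group_by(.data$soa) |>
          dplyr::summarise(error_pct = mean(.data$error_pct), .groups = "drop")
      ) |>
        purrr::imap(~ dplyr::mutate(.x, table = .y)) |>
        purrr::map(~ tidyr::pivot_longer(.x, cols = -dplyr::any_of(
          c("table", "instruction", "soa")), names_to = "quantity")) |>
        dplyr::bind_rows() |>
        dplyr::select("table", dplyr::any_of(c("instruction", "soa")),
                      "quantity", "value"),
      "descriptives", out_dir)
  }

  class(res) <- "simon_analysis"
  res
}

#' Simulate an experiment and analyse it in one call
#'
#' Chains [simulate_experiment()] into [run_analysis()]; all randomness
#' flows from `config$seed`.
#'
#' @param config A [run_config()].
#' @return A `simon_analysis` bundle (see [run_analysis()]); the simulated
#'   trials are included as element `trials`.
#' @export
simulate_and_analyze <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  trials <- simulate_experiment(config$design, config$params,
                                seed = config$seed,
                                participant_cv = config$participant_cv)
  res <- run_analysis(trials, config)
  res$trials <- trials
  res
}

#' @export
print.simon_analysis <- function(x, ...) {
  cat("Simon-task distributional analysis\n")
  cat(sprintf("  trials kept: %d of %d (%.2f%% removed)\n",
              x$outliers$n_kept, x$outliers$n_total, x$outliers$pct_removed))
  if (!is.null(x$slope_means)) {
    cat("  group delta-plot slopes (mean [95% CI]) by soa:\n")
    for (i in seq_len(nrow(x$slope_means))) {
      r <- x$slope_means[i, ]
      cat(sprintf("    soa %+5d: %+.3f [%+.3f, %+.3f]\n",
                  r$soa, r$mean, r$lo, r$hi))
    }
  }
  if (!is.null(x$rt_anova)) {
    cat("  mean-RT ANOVA:\n")
    print(x$rt_anova)
  }
  invisible(x)
}
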