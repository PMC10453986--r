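#' Delta plots from cell summaries
#'
#' For each participant x instruction x soa, pairs the congruent and
#' incongruent quantiles: the congruency effect `y = q_incongruent -
#' q_congruent` is plotted against the mean quantile
#' `x = (q_incongruent + q_congruent) / 2` at each quantile level. A
#' decreasing delta plot means the congruency effect shrinks at longer
#' reaction times.
#'
#' @param summaries Output of [cell_summaries()] (must contain both
#'   congruency cells for every participant/instruction/soa).
#' @return A tibble in long form: `participant`, `instruction`, `soa`,
#'   `prob` (quantile level), `x` (ms), `y` (ms).
#' @export
delta_plots <- function(summaries) {
  probs <- attr(summaries, "probs")
  if (is.null(probs)) {
    qcols <- grep("^q\\d+$", names(summaries), value = TRUE)
    probs <- as.numeric(sub("^q", "", qcols)) / 100
  }
  qcols <- quantile_col(probs)
  long <- summaries |>
    dplyr::select(dplyr::all_of(c("participant", "instruction", "soa",
                                  "congruency", qcols))) |>
    tidyr::pivot_longer(dplyr::all_of(qcols), names_to = "qname",
                        values_to = "q") |>
    dplyr::mutate(prob = as.numeric(sub("^q", "", .data$qname)) / 100) |>
    dplyr::select(-"qname") |>
    tidyr::pivot_wider(names_from = "congruency", values_from = "q")
  if (!all(c("congruent", "incongruent") %in% names(long)) ||
      anyNA(long$congruent) || anyNA(long$incongruent)) {
    stop("both congruency cells are required for every participant/instruction/soa",
         call. = FALSE)
  }
  long |>
    dplyr::mutate(x = (.data$incongruent + .data$congruent) / 2,
                  y = .data$incongruent - .data$congruent) |>
    dplyr::select("participant", "instruction", "soa", "prob", "x", "y") |>
    dplyr::arrange(.data$participant, .data$instruction, .data$soa, .data$prob)
}

#' Default overlap quantile subsets
#'
#' Speed and accuracy delta plots span different reaction-time ranges;
#' slopes are compared over the roughly overlapping parts: the four upper
#' quantile levels (.3-.9) under speed instructions and the four lower
#' levels (.1-.7) under accuracy instructions.
#' @return Named list of quantile-level vectors.
#' @export
overlap_subsets <- function() {
  list(speed = c(.3, .5, .7, .9), accuracy = c(.1, .3, .5, .7))
}

ols_fit <- function(x, y) {
  if (length(unique(x)) < 2L) stop("degenerate delta plot: all x equal", call. = FALSE)
  fit <- lm(y ~ x)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' Overlap-range slopes of delta plots
#'
#' Ordinary least-squares slope of the congruency effect on the mean
#' quantile, restricted per instruction to the overlap quantile subset
#' (see [overlap_subsets()]), for each participant x instruction x soa.
#'
#' @param dps Delta plots from [delta_plots()].
#' @param subsets Named list (`speed`, `accuracy`) of quantile levels to
#'   use per instruction.
#' @return A tibble: `participant`, `instruction`, `soa`, `slope`
#'   (ms per ms), `intercept` (ms), `n_points`.
#' @export
overlap_slopes <- function(dps, subsets = overlap_subsets()) {
  stopifnot(all(INSTRUCTIONS %in% names(subsets)))
  dps |>
    dplyr::group_by(.data$participant, .data$instruction, .data$soa) |>
    dplyr::group_modify(function(d, key) {
      use <- subsets[[as.character(key$instruction)]]
      d <- d[d$prob %in% use, , drop = FALSE]
      if (nrow(d) < 2L) stop("fewer than 2 points in the overlap subset", call. = FALSE)
      f <- ols_fit(d$x, d$y)
      tibble::tibble(slope = unname(f["slope"]),
                     intercept = unname(f["intercept"]),
                     n_points = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Centres of the speed/accuracy reaction-time overlap
#'
#' The overlap of the reaction-time ranges covered by the two instructions
#' runs from the group-mean lowest delta-plot abscissa under accuracy
#' instructions (.1 quantile level) to the group-mean highest abscissa
#' under speed instructions (.9 level); the centre is the midpoint of that
#' interval, one per asynchrony. At these matched reaction times the levels
#' of the speed and accuracy delta plots are compared.
#'
#' @param dps Delta plots from [delta_plots()].
#' @return A tibble: `soa`, `overlap_lo`, `overlap_hi`, `rt_eval` (ms).
#' @export
overlap_centers <- function(dps) {
  out <- dps |>
    dplyr::group_by(.data$soa) |>
    dplyr::summarise(
      overlap_lo = mean(.data$x[.data$instruction == "accuracy" &
                                  .data$prob == min(.data$prob)]),
      overlap_hi = mean(.data$x[.data$instruction == "speed" &
                                  .data$prob == max(.data$prob)]),
      .groups = "drop") |>
    dplyr::mutate(rt_eval = (.data$overlap_lo + .data$overlap_hi) / 2)
  bad <- out$overlap_lo > out$overlap_hi
  if (any(bad)) {
    stop(sprintf("empty reaction-time overlap at soa %s (interval [%0.1f, %0.1f])",
                 out$soa[bad][1], out$overlap_lo[bad][1], out$overlap_hi[bad][1]),
         call. = FALSE)
  }
  out
}

#' Delta-plot levels at matched reaction times via cubic fits
#'
#' Fits a third-order polynomial to each participant's five delta-plot
#' points and evaluates it at the shared reaction time `rt_eval` of that
#' asynchrony (typically the overlap centre from [overlap_centers()]),
#' yielding the congruency effect both instructions would show at an
#' identical reaction time. Five points determine a least-squares cubic
#' with one residual degree of freedom; evaluation outside the observed
#' abscissa range is permitted but flagged.
#'
#' @param dps Delta plots from [delta_plots()].
#' @param centers Either the tibble from [overlap_centers()] or a named
#'   numeric vector / tibble with columns `soa`, `rt_eval`.
#' @return A tibble: `participant`, `instruction`, `soa`, `rt_eval`,
#'   `ce_at_rt` (ms), coefficients `b0`-`b3`, and `extrapolated` (logical,
#'   `TRUE` when `rt_eval` fell outside the fitted range; a warning
#'   summarises how many fits extrapolated).
#' @export
cubic_levels <- function(dps, centers) {
  centers <- tibble::as_tibble(centers)
  stopifnot(all(c("soa", "rt_eval") %in% names(centers)))
  out <- dps |>
    dplyr::group_by(.data$participant, .data$instruction, .data$soa) |>
    dplyr::group_modify(function(d, key) {
      rt_eval <- centers$rt_eval[match(key$soa, centers$soa)]
      if (is.na(rt_eval)) stop("no rt_eval supplied for soa ", key$soa, call. = FALSE)
      if (length(unique(d$x)) < 4L)
        stop("degenerate delta plot: need at least 4 distinct x for a cubic",
             call. = FALSE)
      fit <- lm(y ~ x + I(x^2) + I(x^3), data = d)
      b <- unname(coef(fit))
      tibble::tibble(
        rt_eval = rt_eval,
        ce_at_rt = b[1] + b[2] * rt_eval + b[3] * rt_eval^2 + b[4] * rt_eval^3,
        b0 = b[1], b1 = b[2], b2 = b[3], b3 = b[4],
        extrapolated = rt_eval < min(d$x) | rt_eval > max(d$x))
    }) |>
    dplyr::ungroup()
  n_ex <- sum(out$extrapolated)
  if (n_ex > 0) {
    warning(sprintf("%d cubic fit(s) evaluated outside the observed RT range", n_ex),
            call. = FALSE)
  }
  out
}

# right-closed bin assignment: rt <= q1 -> 1, q1 < rt <= q2 -> 2, ..., rt > q5 -> 6
assign_bin <- function(rt, boundaries) {
  1L + rowSums(outer(rt, boundaries, FUN = ">"))
}

#' Binned error-rate congruency effects (conditional accuracy)
#'
#' Within each participant x instruction x soa cell and each congruency,
#' responded trials are assigned to six reaction-time bins bounded by that
#' congruency cell's correct-RT quantiles (levels `probs`; intervals
#' right-closed, so a trial at a boundary falls in the lower bin). The
#' error percentage per bin is computed over all responded trials in the
#' bin, and the congruency effect is the bin-wise difference incongruent
#' minus congruent.
#'
#' @param trials A filtered trial table.
#' @param probs Quantile levels bounding the bins (default
#'   `c(.1, .3, .5, .7, .9)`, giving 6 bins).
#' @return A tibble: `participant`, `instruction`, `soa`, `bin`,
#'   `err_congruent`, `err_incongruent`, `ce_error_pct` (percentage
#'   points). Empty bins yield `NA` with a warning.
#' @export
error_bin_ce <- function(trials, probs = c(.1, .3, .5, .7, .9)) {
  trials <- validate_trials(trials)
  responded <- trials[!is.na(trials$correct), , drop = FALSE]
  n_bins <- length(probs) + 1L
  any_empty <- FALSE
  out <- responded |>
    dplyr::group_by(.data$participant, .data$instruction, .data$soa,
                    .data$congruency) |>
    dplyr::group_modify(function(d, key) {
      rts_correct <- d$rt[d$correct]
      if (length(rts_correct) == 0L) {
        stop(sprintf("cell %s/%s/soa %d/%s has no correct trials",
                     key$participant, key$instruction, key$soa, key$congruency),
             call. = FALSE)
      }
      bnd <- rt_quantile(rts_correct, probs)
      bin <- assign_bin(d$rt, bnd)
      n_in <- tabulate(bin, nbins = n_bins)
      errs <- vapply(seq_len(n_bins),
                     function(b) sum(!d$correct[bin == b]), integer(1))
      err_pct <- ifelse(n_in > 0, 100 * errs / n_in, NA_real_)
      if (any(n_in == 0)) any_empty <<- TRUE
      tibble::tibble(bin = seq_len(n_bins), err_pct = err_pct, n_in_bin = n_in)
    }) |>
    dplyr::ungroup()
  if (any_empty) warning("empty RT bin(s): error percentage undefined there",
                         call. = FALSE)
  out |>
    tidyr::pivot_wider(id_cols = c("participant", "instruction", "soa", "bin"),
                       names_from = "congruency",
                       values_from = c("err_pct", "n_in_bin")) |>
    dplyr::mutate(ce_error_pct = .data$err_pct_incongruent - .data$err_pct_congruent) |>
    dplyr::rename(err_congruent = "err_pct_congruent",
                  err_incongruent = "err_pct_incongruent")
}
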