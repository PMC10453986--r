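#' Quantile-bin fitting targets from trial data
#'
#' Summarises each instruction x soa x congruency cell (pooled over
#' participants) into defective bin probabilities: the correct-response
#' mass in the six reaction-time bins bounded by the cell's own correct-RT
#' quantiles, plus the error mass as a single category. Probabilities are
#' relative to all responded trials in the cell, so correct bin masses and
#' the error proportion sum to one. The cell's quantile boundaries are kept
#' alongside so simulated data can be binned by the *observed* boundaries.
#'
#' @param trials A filtered trial table.
#' @param probs Quantile levels (default `c(.1, .3, .5, .7, .9)`).
#' @param min_n Cells with fewer responded trials are dropped with a
#'   warning (default 10).
#' @return A tibble with one row per cell: `instruction`, `soa`,
#'   `congruency`, `n`, `error_prop`, boundaries `qXX`, and correct bin
#'   masses `p1`-`p6`.
#' @export
quantile_targets <- function(trials, probs = c(.1, .3, .5, .7, .9), min_n = 10) {
  trials <- validate_trials(trials)
  responded <- trials[!is.na(trials$correct), , drop = FALSE]
  qnames <- quantile_col(probs)
  n_bins <- length(probs) + 1L
  out <- responded |>
    dplyr::group_by(.data$instruction, .data$soa, .data$congruency) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      rts_correct <- d$rt[d$correct]
      if (n < min_n || length(rts_correct) == 0L) {
        return(tibble::tibble(n = n, .drop_cell = TRUE))
      }
      bnd <- rt_quantile(rts_correct, probs)
      bins <- assign_bin(rts_correct, bnd)
      mass <- tabulate(bins, nbins = n_bins) / n
      res <- tibble::tibble(n = n, error_prop = sum(!d$correct) / n,
                            .drop_cell = FALSE)
      res[qnames] <- as.list(bnd)
      res[paste0("p", seq_len(n_bins))] <- as.list(mass)
      res
    }) |>
    dplyr::ungroup()
  if (any(out$.drop_cell)) {
    warning(sum(out$.drop_cell), " cell(s) below min_n dropped from the targets",
            call. = FALSE)
    out <- out[!out$.drop_cell, , drop = FALSE]
  }
  out$.drop_cell <- NULL
  attr(out, "probs") <- probs
  out
}

# defective bin proportions of one simulated cell, binned by the observed
# boundaries of the target row
sim_cell_props <- function(sim, boundaries, n_bins) {
  responded <- !is.na(sim$correct)
  n_resp <- sum(responded)
  if (n_resp == 0L) return(NULL)
  rts_correct <- sim$rt[responded & sim$correct]
  bins <- assign_bin(rts_correct, boundaries)
  c(tabulate(bins, nbins = n_bins), sum(responded & !sim$correct)) / n_resp
}

#' Quantile-bin chi-square objective for the LCA
#'
#' Simulates `n_sim` trials for every target cell under the candidate
#' parameters and measures the Pearson chi-square discrepancy between
#' observed and simulated defective bin counts (six correct-RT bins, bounded
#' by the observed quantiles, plus the error category), summed over cells.
#' The RNG is re-seeded identically on every call (common random numbers),
#' so the objective is a deterministic function of `(params, seed)` and
#' smooth enough for simplex search.
#'
#' @param params An [lca_params()] object.
#' @param targets Output of [quantile_targets()].
#' @param n_sim Simulated trials per cell (>= 1000 recommended).
#' @param seed Integer seed used for every evaluation.
#' @return Non-negative scalar discrepancy. A simulated cell with no
#'   responses contributes a large penalty rather than an error.
#' @export
lca_objective <- function(params, targets, n_sim = 1000, seed = 1) {
  stopifnot(inherits(params, "lca_params"), n_sim >= 1)
  probs <- attr(targets, "probs")
  if (is.null(probs)) probs <- c(.1, .3, .5, .7, .9)
  qnames <- quantile_col(probs)
  n_bins <- length(probs) + 1L
  pnames <- paste0("p", seq_len(n_bins))
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(targets))) {
    row <- targets[i, ]
    sim <- simulate_trials(n_sim, params, as.character(row$instruction),
                           as.character(row$congruency), row$soa)
    props <- sim_cell_props(sim, unlist(row[qnames]), n_bins)
    if (is.null(props)) {
      total <- total + 1e6
      next
    }
    obs <- unlist(row[c(pnames)])
    obs <- c(obs, row$error_prop) * row$n
    expd <- pmax(props * row$n, 0.5)   # floor guards empty simulated bins
    total <- total + sum((obs - expd)^2 / expd)
  }
  total
}

default_fit_bounds <- function() {
  list(theta_speed = c(2, 10), theta_accuracy = c(2, 12),
       A = c(0.02, 1), tau = c(5, 200),
       drift = c(0.02, 0.3), k = c(0.001, 0.08),
       beta = c(0.0005, 0.05), sigma = c(0.05, 1),
       t_nd = c(80, 400), d_rel = c(10, 200), d_irr = c(2, 120))
}

# box-constrained reparameterisation for the simplex search
to_unconstrained <- function(x, lo, hi) stats::qlogis((x - lo) / (hi - lo))
to_constrained <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

# maximum of the irrelevant-drive activation A * convolution of exp(-t/tau)
# input with exp(-k t) leak; (A, tau) pairs with equal peak height form the
# weakly identified ridge of the quantile-bin objective
pulse_peak <- function(A, tau, k) {
  r <- 1 / tau - k
  if (abs(r) < 1e-9) return(A * exp(-1) / k)   # tau -> 1/k limit
  tstar <- log(1 / (tau * k)) / r
  A * (exp(-k * tstar) - exp(-tstar / tau)) / r
}

#' Fit the extended LCA to quantile targets
#'
#' Derivative-free minimisation (Nelder-Mead with restarts on a bounded
#' logistic reparameterisation) of the common-random-numbers chi-square
#' objective. Only the parameters named in `free` are searched; the rest
#' stay at their values in `init`. By default the thresholds and the
#' irrelevant-drive amplitude and decay constant are free, while leak,
#' inhibition, relevant drift and the noise scale are fixed to avoid ridge
#' degeneracy (sigma sets the activation scale).
#'
#' @param targets Output of [quantile_targets()].
#' @param init An [lca_params()] object: starting point and values of the
#'   fixed parameters.
#' @param free Character vector of free parameter names.
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults supplied for all standard parameters.
#' @param n_sim Simulated trials per cell per evaluation.
#' @param seed Seed for the common random numbers.
#' @param budget Maximum objective evaluations.
#' @param restarts Number of Nelder-Mead restarts from the incumbent.
#' @param n_scan Seeded uniform random scan of the box before the simplex
#'   search (counts toward `budget`); the best scanned point (or `init`, if
#'   better) seeds the search. Guards against a poor starting point.
#' @return An object of class `lca_fit` with elements `params` (fitted
#'   [lca_params()]), `objective`, `n_evaluations`, `convergence`, `seed`,
#'   `free`, `bounds` and `trace` (best-so-far objective values). Has
#'   [tidy()] and [glance()] methods.
#' @export
fit_lca <- function(targets, init = lca_params(),
                    free = c("theta_speed", "theta_accuracy", "A", "tau"),
                    bounds = NULL, n_sim = 1000, seed = 1,
                    budget = 400, restarts = 1, n_scan = 32) {
  stopifnot(inherits(init, "lca_params"), length(free) >= 1)
  all_bounds <- default_fit_bounds()
  if (!is.null(bounds)) all_bounds[names(bounds)] <- bounds
  missing_b <- setdiff(free, names(all_bounds))
  if (length(missing_b)) stop("no bounds for: ", paste(missing_b, collapse = ", "),
                              call. = FALSE)
  lo <- vapply(all_bounds[free], `[`, numeric(1), 1)
  hi <- vapply(all_bounds[free], `[`, numeric(1), 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite with lower < upper", call. = FALSE)

  n_eval <- 0L
  best <- list(value = Inf, par = NULL)
  trace <- numeric(0)
  # keep evaluations in reserve for the ridge-profiling phase when the
  # weakly identified (A, tau) pair is free
  ridge_free <- all(c("A", "tau") %in% free)
  pre_budget <- if (ridge_free) budget - min(100L, budget %/% 5L) else budget
  # chi-square sampling floor of the objective: with n observed and n_sim
  # simulated trials per cell the expected discrepancy at the true
  # parameters is about (1 + n/n_sim) * (categories - 1) per cell; once the
  # search is at the floor, further descent only fits simulation noise
  n_cat <- sum(grepl("^p\\d+$", names(targets))) + 1L
  floor_est <- (1 + mean(targets$n) / n_sim) * (n_cat - 1) * nrow(targets)
  stop_at <- 1.15 * floor_est
  make_params <- function(x) {
    p <- init
    for (j in seq_along(free)) p[[free[j]]] <- x[j]
    if (p$theta_speed > p$theta_accuracy) return(NULL)  # ordering constraint
    p
  }
  obj_z <- function(z) {
    if (n_eval >= budget) return(best$value + 1)  # starve the search
    x <- to_constrained(z, lo, hi)
    p <- make_params(x)
    if (is.null(p)) return(1e8)
    n_eval <<- n_eval + 1L
    v <- lca_objective(p, targets, n_sim = n_sim, seed = seed)
    if (v < best$value) best <<- list(value = v, par = x)
    trace <<- c(trace, best$value)
    v
  }
  x0 <- pmin(pmax(unlist(init[free]), lo + 1e-6 * (hi - lo)),
             hi - 1e-6 * (hi - lo))
  obj_z(to_unconstrained(x0, lo, hi))
  conv <- 1L
  if (n_scan > 0) {
    # geometric (log-space) scan of the box: all parameters are positive
    # scale-like quantities, so log-uniform coverage finds narrow basins at
    # the small end that a linear scan misses
    set.seed(seed + 1L)
    scan_rng <- matrix(stats::runif(n_scan * length(free)), n_scan)
    n_loc <- max(8L, floor(n_scan / 2))
    local_rng <- list(matrix(stats::rnorm(n_loc * length(free), sd = 0.6), n_loc),
                      matrix(stats::rnorm(n_loc * length(free), sd = 0.3), n_loc))
    for (s in seq_len(n_scan)) {
      u <- 0.02 + 0.96 * scan_rng[s, ]
      xs <- lo * (hi / lo)^u
      obj_z(to_unconstrained(xs, lo, hi))
    }
    # alternate local scans around the incumbent with simplex descents; the
    # local jumps step across the flat plateaus of the binned objective
    for (phase in 1:2) {
      if (best$value <= stop_at) break
      zb <- to_unconstrained(best$par, lo, hi)
      for (s in seq_len(n_loc)) obj_z(zb + local_rng[[phase]][s, ])
      if (n_eval >= pre_budget || best$value <= stop_at) break
      res <- stats::optim(to_unconstrained(best$par, lo, hi), obj_z,
                          method = "Nelder-Mead",
                          control = list(maxit = max(0, pre_budget - n_eval),
                                         reltol = 1e-5))
      conv <- res$convergence
    }
  }
  if (n_scan > 0 && best$value > 2.5 * floor_est && n_eval < pre_budget) {
    # stuck far above the floor: one fresh scan round from a shifted seed
    set.seed(seed + 2L)
    scan_rng <- matrix(stats::runif(n_scan * length(free)), n_scan)
    for (s in seq_len(n_scan)) {
      if (n_eval >= pre_budget) break
      u <- 0.02 + 0.96 * scan_rng[s, ]
      obj_z(to_unconstrained(lo * (hi / lo)^u, lo, hi))
    }
    zb <- to_unconstrained(best$par, lo, hi)
    set.seed(seed + 3L)
    for (s in seq_len(n_loc)) {
      if (n_eval >= pre_budget) break
      obj_z(zb + stats::rnorm(length(free), sd = 0.4))
    }
    if (n_eval < pre_budget) {
      res <- stats::optim(to_unconstrained(best$par, lo, hi), obj_z,
                          method = "Nelder-Mead",
                          control = list(maxit = pre_budget - n_eval,
                                         reltol = 1e-5))
      conv <- res$convergence
    }
  }
  for (r in seq_len(restarts)) {
    if (n_eval >= pre_budget || best$value <= stop_at) break
    res <- stats::optim(to_unconstrained(best$par, lo, hi), obj_z,
                        method = "Nelder-Mead",
                        control = list(maxit = max(0, pre_budget - n_eval),
                                       reltol = 1e-5))
    conv <- res$convergence
  }
  if (ridge_free) {
    # profile the weakly identified direction: step along the iso-peak
    # (A, tau) ridge, adjusting A so the pulse height stays fixed, then let
    # the simplex re-polish from the best ridge point
    iA <- match("A", free); itau <- match("tau", free)
    for (pass in 1:2) {
      if (n_eval >= budget || best$value <= stop_at) break
      x <- best$par
      pk <- pulse_peak(x[iA], x[itau], init$k)
      for (fac in c(0.72, 0.84, 0.93, 1.08, 1.2, 1.4)) {
        if (n_eval >= budget) break
        x2 <- x
        x2[itau] <- min(max(x[itau] * fac, lo[itau] * 1.001), hi[itau] * 0.999)
        a2 <- pk / pulse_peak(1, x2[itau], init$k)
        x2[iA] <- min(max(a2, lo[iA] * 1.001), hi[iA] * 0.999)
        obj_z(to_unconstrained(x2, lo, hi))
      }
      if (n_eval >= budget) break
      res <- stats::optim(to_unconstrained(best$par, lo, hi), obj_z,
                          method = "Nelder-Mead",
                          control = list(maxit = max(0, budget - n_eval),
                                         reltol = 1e-5))
      conv <- res$convergence
    }
  }
  params <- make_params(best$par)
  structure(list(params = params, objective = best$value,
                 n_evaluations = n_eval,
                 convergence = conv == 0 && n_eval < budget,
                 seed = seed, free = free,
                 bounds = all_bounds[free], n_sim = n_sim,
                 trace = trace),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("LCA fit: objective %.2f after %d evaluations (converged: %s)\n",
              x$objective, x$n_evaluations, x$convergence))
  est <- vapply(x$free, function(f) x$params[[f]], numeric(1))
  print(round(est, 4))
  invisible(x)
}

#' @rdname fit_lca
#' @param x An `lca_fit` object.
#' @param ... Unused.
#' @export
tidy.lca_fit <- function(x, ...) {
  tibble::tibble(
    term = x$free,
    estimate = vapply(x$free, function(f) x$params[[f]], numeric(1)),
    lower = vapply(x$bounds, `[`, numeric(1), 1),
    upper = vapply(x$bounds, `[`, numeric(1), 2))
}

#' @rdname fit_lca
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_evaluations = x$n_evaluations,
                 convergence = x$convergence, seed = x$seed, n_sim = x$n_sim)
}

#' Parameter-recovery experiment
#'
#' Simulates experiments at known parameters, fits the free parameters to
#' the quantile targets of each synthetic data set, and reports the
#' relative recovery error per parameter and replicate. Recovery uses the
#' cells at the asynchronies in `soa_subset`: the zero asynchrony carries
#' the threshold and amplitude information while the positive one, where
#' the irrelevant drive arrives mid-decision, pins down the decay constant.
#'
#' @param n_reps Number of seeded replicates.
#' @param truth Generating [lca_params()].
#' @param design [lca_design()] (defaults to the standard 24 x 40 design).
#' @param free Free parameter names.
#' @param init Starting/fixed parameter set for the fits; fixed parameters
#'   are held at the true values, as in a standard recovery study.
#' @param soa_subset Asynchronies whose cells enter the fitting targets.
#' @param seed Base seed; replicate r uses `seed + r` for the data and
#'   `seed + 1000 + r` for the fit's common random numbers.
#' @param n_sim,budget Passed to [fit_lca()].
#' @return A tibble with one row per replicate x parameter: `rep`, `term`,
#'   `truth`, `estimate`, `rel_error`, plus fit diagnostics.
#' @export
parameter_recovery <- function(n_reps = 10, truth = lca_params(),
                               design = lca_design(),
                               free = c("theta_speed", "theta_accuracy",
                                        "A", "tau"),
                               init = NULL, soa_subset = c(0L, 100L),
                               seed = 1, n_sim = 1000, budget = 700) {
  if (is.null(init)) {
    init <- truth
    init$theta_speed <- 6
    init$theta_accuracy <- 7
    init$A <- 0.1
    init$tau <- 60
  }
  rows <- lapply(seq_len(n_reps), function(r) {
    trials <- simulate_experiment(design, truth, seed = seed + r,
                                  participant_cv = 0)
    targets <- quantile_targets(trials[trials$soa %in% soa_subset, ,
                                       drop = FALSE])
    fit <- fit_lca(targets, init, free = free, n_sim = n_sim,
                   seed = seed + 1000L + r, budget = budget)
    est <- vapply(free, function(f) fit$params[[f]], numeric(1))
    tru <- vapply(free, function(f) truth[[f]], numeric(1))
    tibble::tibble(rep = r, term = free, truth = tru, estimate = est,
                   rel_error = abs(est - tru) / tru,
                   objective = fit$objective,
                   n_evaluations = fit$n_evaluations,
                   convergence = fit$convergence)
  })
  dplyr::bind_rows(rows)
}

#' Effect of averaging stimulus-processing parameters across instructions
#'
#' Given separate fits (or parameter sets) for the speed and accuracy
#' sessions, simulates congruency effects per instruction twice: once with
#' each session's own parameters, and once with the stimulus-processing
#' parameters (`drift`, `A`, `tau`) averaged across sessions while the
#' response thresholds stay session-specific. If the instruction difference
#' in congruency effects is carried by stimulus processing rather than by
#' the thresholds, averaging shrinks that difference.
#'
#' @param fit_speed,fit_accuracy `lca_fit` objects or [lca_params()]
#'   objects for the two sessions.
#' @param soa Asynchrony at which congruency effects are simulated
#'   (default 0).
#' @param n_sim Simulated trials per cell.
#' @param seed Integer seed.
#' @return A tibble with one row per instruction: mean-RT congruency
#'   effects `ce_own` (session parameters) and `ce_averaged`, and the
#'   attribute-free columns `instr_diff_own` / `instr_diff_averaged`
#'   (difference between instructions, repeated on both rows).
#' @export
parameter_averaging_check <- function(fit_speed, fit_accuracy, soa = 0,
                                      n_sim = 4000, seed = 1) {
  pick <- function(f) if (inherits(f, "lca_fit")) f$params else f
  p_s <- pick(fit_speed)
  p_a <- pick(fit_accuracy)
  stopifnot(inherits(p_s, "lca_params"), inherits(p_a, "lca_params"))
  avg <- function(field) (p_s[[field]] + p_a[[field]]) / 2
  p_s_avg <- p_s; p_a_avg <- p_a
  for (f in c("drift", "A", "tau")) {
    p_s_avg[[f]] <- avg(f)
    p_a_avg[[f]] <- avg(f)
  }
  ce_of <- function(p, instruction, seed_offset) {
    set.seed(seed + seed_offset)
    m <- vapply(CONGRUENCIES, function(cg) {
      sim <- simulate_trials(n_sim, p, instruction, cg, soa)
      mean(sim$rt[sim$correct], na.rm = TRUE)
    }, numeric(1))
    unname(m["incongruent"] - m["congruent"])
  }
  ce_own <- c(speed = ce_of(p_s, "speed", 0), accuracy = ce_of(p_a, "accuracy", 1))
  ce_avg <- c(speed = ce_of(p_s_avg, "speed", 0),
              accuracy = ce_of(p_a_avg, "accuracy", 1))
  diff_own <- unname(ce_own["speed"] - ce_own["accuracy"])
  diff_avg <- unname(ce_avg["speed"] - ce_avg["accuracy"])
  tibble::tibble(
    instruction = INSTRUCTIONS,
    ce_own = unname(ce_own[INSTRUCTIONS]),
    ce_averaged = unname(ce_avg[INSTRUCTIONS]),
    instr_diff_own = diff_own,
    instr_diff_averaged = diff_avg)
}
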