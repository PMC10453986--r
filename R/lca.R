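#' Parameters of the extended leaky competing accumulator
#'
#' Constructs and validates the parameter vector of the two-accumulator
#' leaky competing accumulator (LCA) extended with staggered route onsets
#' and an exponentially decaying irrelevant drive. Two response accumulators
#' race to an instruction-dependent threshold; each leaks at rate `k`,
#' inhibits the other at rate `beta`, and is floored at zero activation.
#' The relevant route feeds the correct accumulator with constant drift
#' `drift` from `d_rel` ms after the relevant feature's onset; the
#' irrelevant route feeds the spatially corresponding accumulator (the
#' correct one on congruent trials, the incorrect one on incongruent
#' trials) with amplitude `A * exp(-lag / tau)` from `d_irr` ms after the
#' irrelevant feature's onset.
#'
#' The defaults are the calibrated set shipped with the package: under the
#' standard design they produce mean reaction times of roughly 380-560 ms
#' across asynchronies, error rates of a few percent, congruency effects of
#' about 15-30 ms, decreasing delta plots when the irrelevant feature leads
#' and increasing ones when it lags.
#'
#' @param theta_speed,theta_accuracy Response thresholds (activation units)
#'   under speed and accuracy instructions; `theta_speed <= theta_accuracy`.
#' @param k Leak rate (1/ms).
#' @param beta Lateral inhibition rate (1/ms).
#' @param drift Relevant-route input strength (activation/ms).
#' @param A Initial irrelevant-route input strength (activation/ms).
#' @param tau Decay time constant of the irrelevant drive (ms).
#' @param sigma Diffusion coefficient (activation/sqrt(ms)).
#' @param t_nd Non-decision time (ms): encoding and motor execution outside
#'   the accumulation process.
#' @param d_rel,d_irr Perceptual delays (ms) between a feature's physical
#'   onset and the onset of its drive; location information is typically
#'   available earlier than colour, so `d_irr < d_rel` by default.
#' @param dt Euler integration step (ms); keep at 1 ms or below.
#' @param t_max Response deadline (ms); trials without a threshold crossing
#'   whose reaction time would exceed `t_max` are recorded as missing.
#' @param A_accuracy,tau_accuracy Optional instruction-dependent overrides:
#'   when supplied, accuracy-instruction sessions use these in place of `A`
#'   and `tau`, emulating an irrelevant influence that differs between
#'   instruction sets. By default instruction affects the threshold only.
#'
#' @return An object of class `lca_params` (a named list).
#' @examples
#' p <- lca_params()
#' p$theta_speed
#' @export
lca_params <- function(theta_speed = 4, theta_accuracy = 4.3,
                       k = 0.03, beta = 0.002,
                       drift = 0.132, A = 0.23, tau = 20,
                       sigma = 0.245, t_nd = 190,
                       d_rel = 135, d_irr = 12,
                       dt = 1, t_max = 2000,
                       A_accuracy = NULL, tau_accuracy = NULL) {
  p <- list(theta_speed = theta_speed, theta_accuracy = theta_accuracy,
            k = k, beta = beta, drift = drift, A = A, tau = tau,
            sigma = sigma, t_nd = t_nd, d_rel = d_rel, d_irr = d_irr,
            dt = dt, t_max = t_max,
            A_accuracy = A_accuracy, tau_accuracy = tau_accuracy)
  class(p) <- "lca_params"
  validate_lca_params(p)
  p
}

validate_lca_params <- function(p) {
  pos <- c("theta_speed", "theta_accuracy", "k", "beta", "drift", "A", "tau",
           "t_nd", "d_rel", "d_irr", "dt", "t_max")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("lca_params: '", f, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (!is.numeric(p$sigma) || p$sigma < 0)
    stop("lca_params: 'sigma' must be non-negative", call. = FALSE)
  if (p$theta_speed > p$theta_accuracy)
    stop("lca_params: theta_speed must not exceed theta_accuracy", call. = FALSE)
  if (p$dt > 1)
    warning("integration step dt > 1 ms; results may be inaccurate", call. = FALSE)
  if (p$t_nd >= p$t_max)
    stop("lca_params: t_nd must be below t_max", call. = FALSE)
  for (f in c("A_accuracy", "tau_accuracy")) {
    v <- p[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop("lca_params: '", f, "' must be NULL or strictly positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.lca_params <- function(x, ...) {
  cat("Extended LCA parameters\n")
  flat <- unlist(x[!vapply(x, is.null, logical(1))])
  print(round(flat, 4))
  invisible(x)
}

# threshold / irrelevant-drive parameters for one instruction session
resolve_instruction <- function(params, instruction) {
  instruction <- match.arg(instruction, INSTRUCTIONS)
  list(
    theta = if (instruction == "speed") params$theta_speed else params$theta_accuracy,
    A = if (instruction == "accuracy" && !is.null(params$A_accuracy))
      params$A_accuracy else params$A,
    tau = if (instruction == "accuracy" && !is.null(params$tau_accuracy))
      params$tau_accuracy else params$tau
  )
}

#' Feature onset times for a given asynchrony
#'
#' Time zero is the onset of the *first* stimulus feature. When the
#' asynchrony is zero or negative the irrelevant feature (position) leads:
#' it appears at 0 and the relevant feature (colour) at `-soa`. When the
#' asynchrony is positive the relevant feature appears at 0 and the
#' irrelevant one at `soa`.
#'
#' @param soa Asynchrony in ms (vectorised).
#' @return A tibble with columns `soa`, `t_relevant`, `t_irrelevant` (ms).
#' @examples
#' feature_onsets(c(-200, 0, 100))
#' @export
feature_onsets <- function(soa) {
  stopifnot(is.numeric(soa))
  tibble::tibble(
    soa = soa,
    t_relevant = ifelse(soa <= 0, -soa, 0),
    t_irrelevant = ifelse(soa <= 0, 0, soa)
  )
}

#' Route inputs to the two accumulators at time t
#'
#' Evaluates the deterministic drive of both routes: the relevant route
#' contributes `drift` to the correct accumulator once active, and the
#' irrelevant route contributes `A * exp(-lag / tau)` (lag = time since its
#' drive onset) to the correct accumulator on congruent trials and to the
#' incorrect accumulator on incongruent trials. Both are zero before their
#' onsets (feature onset plus perceptual delay).
#'
#' @param t Time in ms from first-feature onset (vectorised).
#' @param soa Asynchrony in ms (scalar).
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param params An [lca_params()] object.
#' @param instruction Instruction session, used only to resolve
#'   instruction-dependent irrelevant-drive overrides.
#' @return A tibble with columns `t`, `I_correct`, `I_incorrect`
#'   (activation/ms).
#' @export
lca_drive <- function(t, soa, congruency, params, instruction = "speed") {
  stopifnot(inherits(params, "lca_params"), length(soa) == 1L)
  congruency <- match.arg(congruency, CONGRUENCIES)
  ons <- feature_onsets(soa)
  ins <- resolve_instruction(params, instruction)
  rel_on <- ons$t_relevant + params$d_rel
  irr_on <- ons$t_irrelevant + params$d_irr
  I_rel <- ifelse(t >= rel_on, params$drift, 0)
  lag <- t - irr_on
  I_irr <- ifelse(lag >= 0, ins$A * exp(-lag / ins$tau), 0)
  tibble::tibble(
    t = t,
    I_correct = I_rel + if (congruency == "congruent") I_irr else 0,
    I_incorrect = if (congruency == "incongruent") I_irr else rep(0, length(t))
  )
}

#' Simulate LCA trials for one design cell
#'
#' Euler-Maruyama integration of the two accumulators from zero activation:
#' at each step `dx_i = (I_i - k x_i - beta x_j) dt + sigma sqrt(dt) xi`,
#' with activations floored at zero. The response is given by the first
#' accumulator to reach the instruction's threshold; the reaction time is
#' the crossing time plus the non-decision time, measured from
#' first-feature onset. Trials without a crossing by the deadline are
#' recorded as missing (no response).
#'
#' @param n Number of trials.
#' @param params An [lca_params()] object.
#' @param instruction `"speed"` or `"accuracy"`.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param soa Asynchrony in ms.
#' @return A tibble with columns `rt` (ms, `NA` if no response) and
#'   `correct` (logical, `NA` if no response). Uses R's RNG: seed with
#'   [set.seed()] for reproducibility.
#' @examples
#' set.seed(1)
#' simulate_trials(5, lca_params(), "speed", "incongruent", 0)
#' @export
simulate_trials <- function(n, params, instruction, congruency, soa) {
  stopifnot(inherits(params, "lca_params"), n >= 0)
  instruction <- match.arg(instruction, INSTRUCTIONS)
  congruency <- match.arg(congruency, CONGRUENCIES)
  ons <- feature_onsets(soa)
  ins <- resolve_instruction(params, instruction)
  m <- lca_sim_cpp(as.integer(n), ins$theta, params$k, params$beta,
                   params$drift, ins$A, ins$tau, params$sigma,
                   params$t_nd, ons$t_relevant, ons$t_irrelevant,
                   params$d_rel, params$d_irr, params$dt, params$t_max,
                   congruency == "congruent")
  tibble::tibble(rt = m[, 1], correct = as.logical(m[, 2]))
}

#' Experimental design specification
#'
#' The default reproduces the standard design: 24 participants, two
#' instruction sessions, five asynchronies, two congruencies, 40 trials per
#' cell (19200 trials in total).
#'
#' @param n_participants Number of participants.
#' @param n_trials_per_cell Trials per participant x instruction x soa x
#'   congruency cell.
#' @param soa_levels Asynchrony levels (ms).
#' @param instructions Instruction sessions.
#' @param congruencies Congruency levels.
#' @return An object of class `lca_design` (a named list).
#' @export
lca_design <- function(n_participants = 24, n_trials_per_cell = 40,
                       soa_levels = SOA_LEVELS,
                       instructions = INSTRUCTIONS,
                       congruencies = CONGRUENCIES) {
  stopifnot(n_participants >= 1, n_trials_per_cell >= 1,
            length(soa_levels) >= 1, all(soa_levels %in% SOA_LEVELS),
            all(instructions %in% INSTRUCTIONS),
            all(congruencies %in% CONGRUENCIES))
  structure(list(n_participants = as.integer(n_participants),
                 n_trials_per_cell = as.integer(n_trials_per_cell),
                 soa_levels = as.integer(soa_levels),
                 instructions = instructions,
                 congruencies = congruencies),
            class = "lca_design")
}

# multiplicative log-normal jitter with mean 1 and coefficient of variation cv
jitter_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Simulate a full experiment
#'
#' Generates a trial table with the statistical structure the
#' distributional analysis assumes: the crossed within-participant design,
#' faster but more error-prone responding under speed instructions (lower
#' threshold), decreasing delta plots when the irrelevant feature leads and
#' increasing ones when it lags. Between-participant variability is
#' introduced as mild log-normal jitter (coefficient of variation
#' `participant_cv`) on the thresholds (one common factor, preserving their
#' ordering), the two route strengths, the decay constant, and the
#' non-decision time.
#'
#' @param design An [lca_design()] object.
#' @param params An [lca_params()] object (group-level parameters).
#' @param seed Integer seed; the single source of randomness. `NULL` leaves
#'   the RNG state untouched.
#' @param participant_cv Coefficient of variation of the participant-level
#'   parameter jitter (default 0.1; 0 disables it).
#' @return A validated trial tibble (see [read_trials()] for the columns),
#'   with the design, parameters, seed and per-participant parameter sets
#'   recorded in the `"provenance"` attribute.
#' @examples
#' trials <- simulate_experiment(lca_design(n_participants = 2,
#'                                          n_trials_per_cell = 5),
#'                               lca_params(), seed = 1)
#' nrow(trials)
#' @export
simulate_experiment <- function(design = lca_design(), params = lca_params(),
                                seed = NULL, participant_cv = 0.1) {
  stopifnot(inherits(design, "lca_design"), inherits(params, "lca_params"))
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%02d", seq_len(design$n_participants))
  subj_params <- lapply(seq_len(design$n_participants), function(i) {
    f <- jitter_factor(5, participant_cv)
    p <- params
    p$theta_speed <- params$theta_speed * f[1]
    p$theta_accuracy <- params$theta_accuracy * f[1]
    p$drift <- params$drift * f[2]
    p$A <- params$A * f[3]
    if (!is.null(params$A_accuracy)) p$A_accuracy <- params$A_accuracy * f[3]
    p$tau <- params$tau * f[4]
    if (!is.null(params$tau_accuracy)) p$tau_accuracy <- params$tau_accuracy * f[4]
    p$t_nd <- params$t_nd * f[5]
    p
  })
  grid <- expand.grid(congruency = design$congruencies,
                      soa = design$soa_levels,
                      instruction = design$instructions,
                      participant = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(congruency, soa, instruction, participant) {
    p <- subj_params[[match(participant, ids)]]
    out <- simulate_trials(design$n_trials_per_cell, p, instruction, congruency, soa)
    tibble::tibble(participant = participant, instruction = instruction,
                   soa = as.integer(soa), congruency = congruency,
                   rt = out$rt, correct = out$correct)
  })
  trials <- validate_trials(dplyr::bind_rows(rows))
  attr(trials, "provenance") <- list(
    source = "simulate_experiment", design = design, params = params,
    seed = seed, participant_cv = participant_cv,
    participant_params = setNames(subj_params, ids))
  trials
}
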