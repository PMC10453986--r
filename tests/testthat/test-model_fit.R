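test_that("quantile targets carry defective bin masses that sum to one", {
  # 20 distinct correct RTs: interpolated quantile bins hold 2/4/4/4/4/2
  rts <- seq(300, 490, by = 10)
  trials <- make_trials(rts)
  tg <- quantile_targets(trials, min_n = 5)
  expect_equal(unlist(tg[paste0("p", 1:6)]),
               c(.1, .2, .2, .2, .2, .1), ignore_attr = TRUE)
  expect_equal(tg$error_prop, 0)

  # 50% errors: correct masses halve, total mass still one
  trials2 <- dplyr::bind_rows(make_trials(rts),
                              make_trials(rts + 1, correct = FALSE))
  tg2 <- quantile_targets(trials2, min_n = 5)
  expect_equal(unlist(tg2[paste0("p", 1:6)]),
               c(.1, .2, .2, .2, .2, .1) / 2, ignore_attr = TRUE)
  expect_equal(tg2$error_prop, 0.5)
  expect_equal(sum(unlist(tg2[paste0("p", 1:6)])) + tg2$error_prop, 1)

  expect_warning(quantile_targets(make_trials(rts[1:8]), min_n = 10),
                 "below min_n")
})

test_that("quantile targets match direct trial counting on simulated cells", {
  set.seed(17)
  trials <- dplyr::bind_rows(
    make_trials(round(rlnorm(200, log(400), .25)),
                correct = sample(c(TRUE, FALSE), 200, TRUE, c(.9, .1))),
    make_trials(round(rlnorm(180, log(430), .25)),
                congruency = "incongruent",
                correct = sample(c(TRUE, FALSE), 180, TRUE, c(.85, .15))))
  tg <- quantile_targets(trials)
  for (i in seq_len(nrow(tg))) {
    cell <- trials[trials$congruency == tg$congruency[i], ]
    rts_c <- cell$rt[cell$correct]
    bnd <- quantile(rts_c, c(.1, .3, .5, .7, .9), type = 7)
    counts <- vapply(1:6, function(b) {
      lo <- if (b == 1) -Inf else bnd[b - 1]
      hi <- if (b == 6) Inf else bnd[b]
      sum(rts_c > lo & rts_c <= hi)
    }, numeric(1))
    expect_equal(unlist(tg[i, paste0("p", 1:6)]), counts / nrow(cell),
                 ignore_attr = TRUE)
    expect_equal(tg$n[i], nrow(cell))
  }
})

test_that("the chi-square objective is deterministic and penalises misfit", {
  set.seed(23)
  truth <- lca_params()
  trials <- simulate_experiment(lca_design(n_participants = 6,
                                           n_trials_per_cell = 40,
                                           soa_levels = 0L),
                                truth, seed = 23, participant_cv = 0)
  tg <- quantile_targets(trials)
  o1 <- lca_objective(truth, tg, n_sim = 600, seed = 5)
  o2 <- lca_objective(truth, tg, n_sim = 600, seed = 5)
  expect_identical(o1, o2)

  # doubling the thresholds away from truth increases the discrepancy
  off <- truth
  off$theta_speed <- truth$theta_speed * 2
  off$theta_accuracy <- truth$theta_accuracy * 2
  expect_gt(lca_objective(off, tg, n_sim = 600, seed = 5), o1)

  # self-fit sits near the chi-square sampling floor
  n_cells <- nrow(tg)
  floor_est <- (1 + mean(tg$n) / 600) * 6 * n_cells
  expect_lt(o1, 3 * floor_est)
})

test_that("objective at truth beats single-axis 20% perturbations in median", {
  set.seed(29)
  truth <- lca_params()
  trials <- simulate_experiment(lca_design(n_participants = 12,
                                           n_trials_per_cell = 40,
                                           soa_levels = c(0L, 100L)),
                                truth, seed = 29, participant_cv = 0)
  tg <- quantile_targets(trials)
  o_true <- lca_objective(truth, tg, n_sim = 800, seed = 11)
  worse <- 0L; total <- 0L
  for (par in c("theta_speed", "A", "tau", "drift")) {
    for (fac in c(0.8, 1.2)) {
      p <- truth
      p[[par]] <- truth[[par]] * fac
      if (p$theta_speed > p$theta_accuracy) next
      total <- total + 1L
      if (lca_objective(p, tg, n_sim = 800, seed = 11) > o_true)
        worse <- worse + 1L
    }
  }
  expect_gt(worse / total, 0.5)
})

test_that("fitting from the truth does not increase the objective", {
  set.seed(37)
  truth <- lca_params()
  trials <- simulate_experiment(lca_design(n_participants = 6,
                                           n_trials_per_cell = 30,
                                           soa_levels = 0L),
                                truth, seed = 37, participant_cv = 0)
  tg <- quantile_targets(trials)
  o_true <- lca_objective(truth, tg, n_sim = 500, seed = 7)
  fit <- fit_lca(tg, truth, free = c("A", "tau"), n_sim = 500, seed = 7,
                 budget = 60, n_scan = 8)
  expect_lte(fit$objective, o_true)
  expect_lte(fit$n_evaluations, 60)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$seed, 7)
})

test_that("instruction-dependent amplitude is recoverable in direction", {
  # data generated with a stronger irrelevant drive under speed instructions;
  # separate fits per instruction should order the amplitudes accordingly
  set.seed(41)
  gen <- lca_params(A = 0.3, A_accuracy = 0.16)
  trials <- simulate_experiment(lca_design(n_participants = 24,
                                           soa_levels = c(0L, 100L)),
                                gen, seed = 41, participant_cv = 0)
  fits <- lapply(c("speed", "accuracy"), function(ins) {
    tg <- quantile_targets(trials[trials$instruction == ins, , drop = FALSE])
    init <- lca_params()
    fit_lca(tg, init, free = c(if (ins == "speed") "theta_speed" else
      "theta_accuracy", "A", "tau"),
      n_sim = 800, seed = 43, budget = 250, n_scan = 24)
  })
  expect_gt(fits[[1]]$params$A, fits[[2]]$params$A)
})

test_that("averaging stimulus parameters shrinks amplitude-driven differences only", {
  p_s <- lca_params(A = 0.3)
  p_a <- lca_params(A = 0.15)
  chk <- parameter_averaging_check(p_s, p_a, n_sim = 2500, seed = 3)
  # with A averaged, the instruction difference in congruency effects shrinks
  expect_lt(abs(chk$instr_diff_averaged[1]), abs(chk$instr_diff_own[1]))

  # identical parameter sets: averaging changes nothing
  chk0 <- parameter_averaging_check(lca_params(), lca_params(),
                                    n_sim = 1500, seed = 3)
  expect_equal(chk0$ce_own, chk0$ce_averaged)

  # threshold-only differences are untouched (thresholds are not averaged)
  p_hi <- lca_params(theta_speed = 5, theta_accuracy = 5.3)
  chk1 <- parameter_averaging_check(lca_params(), p_hi, n_sim = 1500, seed = 3)
  expect_equal(chk1$ce_own, chk1$ce_averaged)
})
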