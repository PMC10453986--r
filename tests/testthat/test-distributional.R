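summaries_from <- function(rt_cong, rt_incong, ...) {
  cell_summaries(make_cell_pair(rt_cong, rt_incong, ...))
}

test_that("delta plots pair quantiles into effect-by-mean points", {
  base <- c(300, 350, 400, 450, 500)
  s <- summaries_from(base, base + 20)
  dp <- delta_plots(s)
  expect_equal(nrow(dp), 5L)
  expect_equal(dp$y, rep(20, 5))
  # x is the mean of the two cells' interpolated quantiles
  qb <- unname(quantile(base, c(.1, .3, .5, .7, .9), type = 7))
  expect_equal(dp$x, qb + 10)

  # identical distributions give a flat zero delta plot
  dp0 <- delta_plots(summaries_from(base, base))
  expect_equal(dp0$y, rep(0, 5))
})

test_that("delta plots are antisymmetric under congruency swap", {
  set.seed(8)
  for (i in 1:10) {
    a <- sort(round(rlnorm(19, log(400), 0.25)))
    b <- sort(round(rlnorm(23, log(430), 0.25)))
    dp <- delta_plots(summaries_from(a, b))
    dp_swap <- delta_plots(summaries_from(b, a))
    expect_equal(dp_swap$y, -dp$y)
    expect_equal(dp_swap$x, dp$x)
  }
})

test_that("overlap slopes restrict to the instruction's quantile window", {
  # exact delta-plot points with y = 0.2 x - 70 on the speed window
  dp <- tibble::tibble(participant = "P01", instruction = "speed", soa = 0L,
                       prob = c(.1, .3, .5, .7, .9),
                       x = c(380, 400, 420, 440, 460),
                       y = c(99, 10, 14, 18, 22))
  sl <- overlap_slopes(dp)
  # speed window is .3-.9, so the aberrant .1 point is ignored
  expect_equal(sl$slope, 0.2, tolerance = 1e-12)
  expect_equal(sl$intercept, -70, tolerance = 1e-9)
  expect_equal(sl$n_points, 4L)

  dp_acc <- dplyr::mutate(dp, instruction = "accuracy", y = rep(7, 5))
  sl_acc <- overlap_slopes(dp_acc)
  expect_equal(sl_acc$slope, 0)
  expect_error(overlap_slopes(dplyr::mutate(dp, x = 400)), "degenerate")
})

test_that("overlap slope equals a normal-equations oracle on random points", {
  set.seed(13)
  for (i in 1:25) {
    x <- runif(4, 300, 600)
    y <- runif(4, -30, 60)
    dp <- tibble::tibble(participant = "P", instruction = "accuracy", soa = 0L,
                         prob = c(.1, .3, .5, .7), x = x, y = y)
    sl <- overlap_slopes(dp)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(sl$slope, beta[2], tolerance = 1e-9)
    expect_equal(sl$intercept, beta[1], tolerance = 1e-9)
  }
})

test_that("cubic level fits recover generating polynomials exactly", {
  set.seed(3)
  for (i in 1:10) {
    b <- c(runif(1, -20, 20), runif(1, -0.5, 0.5), runif(1, -2e-3, 2e-3),
           runif(1, -5e-6, 5e-6))
    x <- sort(runif(5, 300, 600))
    y <- b[1] + b[2] * x + b[3] * x^2 + b[4] * x^3
    dp <- tibble::tibble(participant = "P", instruction = "speed", soa = 0L,
                         prob = c(.1, .3, .5, .7, .9), x = x, y = y)
    lv <- suppressWarnings(
      cubic_levels(dp, tibble::tibble(soa = 0L, rt_eval = 450)))
    expect_equal(unlist(lv[c("b0", "b1", "b2", "b3")]), b,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(lv$ce_at_rt,
                 b[1] + b[2] * 450 + b[3] * 450^2 + b[4] * 450^3,
                 tolerance = 1e-6)
  }
})

test_that("constant delta plots give constant levels; extrapolation is flagged", {
  dp <- tibble::tibble(participant = "P", instruction = "speed", soa = 0L,
                       prob = c(.1, .3, .5, .7, .9),
                       x = c(300, 350, 400, 450, 500), y = rep(20, 5))
  lv <- cubic_levels(dp, tibble::tibble(soa = 0L, rt_eval = 420))
  expect_equal(lv$ce_at_rt, 20, tolerance = 1e-8)
  expect_false(lv$extrapolated)
  expect_warning(
    lv2 <- cubic_levels(dp, tibble::tibble(soa = 0L, rt_eval = 700)),
    "outside")
  expect_true(lv2$extrapolated)
})

test_that("overlap centres are midpoints of the group overlap interval", {
  dp <- dplyr::bind_rows(
    tibble::tibble(participant = "P1", instruction = "speed", soa = 0L,
                   prob = c(.1, .3, .5, .7, .9),
                   x = c(300, 330, 360, 400, 450), y = 0),
    tibble::tibble(participant = "P1", instruction = "accuracy", soa = 0L,
                   prob = c(.1, .3, .5, .7, .9),
                   x = c(350, 400, 450, 500, 550), y = 0))
  ctr <- overlap_centers(dp)
  expect_equal(ctr$overlap_lo, 350)   # accuracy .1 quantile
  expect_equal(ctr$overlap_hi, 450)   # speed .9 quantile
  expect_equal(ctr$rt_eval, 400)

  # identical distributions: centre is the midpoint of the own .1-.9 span
  dp_same <- dplyr::mutate(dp, x = rep(c(300, 330, 360, 400, 450), 2))
  expect_equal(overlap_centers(dp_same)$rt_eval, (300 + 450) / 2)

  # empty overlap errors with the interval reported
  dp_gap <- dp
  dp_gap$x[dp_gap$instruction == "accuracy"] <- c(500, 520, 540, 560, 580)
  expect_error(overlap_centers(dp_gap), "empty.*overlap")
})

test_that("binned error congruency effects match a direct counting oracle", {
  # congruent: 60 correct trials at distinct RTs; incongruent: same plus two
  # fast errors, so only the first bin picks up a congruency effect
  rt_c <- seq(200, 790, by = 10)
  rt_i <- seq(205, 795, by = 10)
  trials <- dplyr::bind_rows(
    make_trials(rt_c, TRUE, congruency = "congruent"),
    make_trials(rt_i, TRUE, congruency = "incongruent"),
    make_trials(c(150, 160), FALSE, congruency = "incongruent"))
  eb <- error_bin_ce(trials)
  expect_equal(nrow(eb), 6L)
  expect_equal(eb$err_congruent, rep(0, 6))

  # oracle: recount incongruent errors per bin from the quantile boundaries
  bnd <- quantile(rt_i, c(.1, .3, .5, .7, .9), type = 7)
  all_i <- c(rt_i, 150, 160)
  bins <- 1 + rowSums(outer(all_i, bnd, ">"))
  err_bins <- 1 + rowSums(outer(c(150, 160), bnd, ">"))
  oracle <- vapply(1:6, function(b) {
    100 * sum(err_bins == b) / sum(bins == b)
  }, numeric(1))
  expect_equal(eb$ce_error_pct, oracle)
  expect_gt(eb$ce_error_pct[1], 0)
  expect_equal(eb$ce_error_pct[2:6], rep(0, 5))

  # no errors anywhere: all six effects are zero
  eb0 <- error_bin_ce(dplyr::bind_rows(
    make_trials(rt_c, TRUE, congruency = "congruent"),
    make_trials(rt_i, TRUE, congruency = "incongruent")))
  expect_equal(eb0$ce_error_pct, rep(0, 6))
})

test_that("error bins partition all responded trials in a cell", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(25:80, 1)
    trials <- make_trials(round(rlnorm(n, log(400), 0.3)),
                          correct = sample(c(TRUE, FALSE), n, TRUE, c(.85, .15)))
    if (sum(trials$correct) < 5) next
    eb <- error_bin_ce(dplyr::bind_rows(
      trials, make_trials(round(rlnorm(n, log(420), 0.3)),
                          congruency = "incongruent")))
    expect_equal(sum(eb$n_in_bin_congruent), n)
  }
})
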