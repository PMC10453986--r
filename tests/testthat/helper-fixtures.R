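# small in-code fixtures and independent oracles shared across test files

make_trials <- function(rt, correct = TRUE, participant = "P01",
                        instruction = "speed", soa = 0L,
                        congruency = "congruent") {
  tibble::tibble(participant = participant, instruction = instruction,
                 soa = as.integer(soa), congruency = congruency,
                 rt = rt, correct = rep_len(correct, length(rt)))
}

# a balanced two-congruency cell pair for one participant
make_cell_pair <- function(rt_cong, rt_incong, correct_cong = TRUE,
                           correct_incong = TRUE, ...) {
  dplyr::bind_rows(
    make_trials(rt_cong, correct_cong, congruency = "congruent", ...),
    make_trials(rt_incong, correct_incong, congruency = "incongruent", ...))
}

write_trials_csv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

# independent within-subject ANOVA oracle via stats::aov error strata
aov_oracle <- function(data, dv, id, within) {
  data <- as.data.frame(data)
  data[[id]] <- factor(data[[id]])
  for (w in within) data[[w]] <- factor(data[[w]])
  f <- stats::as.formula(paste(
    dv, "~", paste(within, collapse = "*"),
    "+ Error(", id, "/(", paste(within, collapse = "*"), "))"))
  sm <- summary(stats::aov(f, data = data))
  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    for (i in seq_along(rn)) {
      if (rn[i] == "Residuals") next
      out[[rn[i]]] <- list(
        df = tab[i, "Df"],
        ss = tab[i, "Sum Sq"],
        ss_err = tab[rn == "Residuals", "Sum Sq"],
        df_err = tab[rn == "Residuals", "Df"],
        F = tab[i, "F value"])
    }
  }
  out
}

# noise-free Euler integration of the two-accumulator dynamics in plain R;
# independent of the compiled path
ode_oracle <- function(params, instruction, congruency, soa) {
  ons <- feature_onsets(soa)
  theta <- if (instruction == "speed") params$theta_speed else params$theta_accuracy
  rel_on <- ons$t_relevant + params$d_rel
  irr_on <- ons$t_irrelevant + params$d_irr
  dt <- params$dt
  x1 <- 0; x2 <- 0
  steps <- ceiling((params$t_max - params$t_nd) / dt)
  for (s in seq_len(steps)) {
    t <- (s - 1) * dt
    I1 <- if (t >= rel_on) params$drift else 0
    Ii <- if (t >= irr_on) params$A * exp(-(t - irr_on) / params$tau) else 0
    if (congruency == "congruent") I1 <- I1 + Ii
    I2 <- if (congruency == "incongruent") Ii else 0
    nx1 <- max(0, x1 + (I1 - params$k * x1 - params$beta * x2) * dt)
    nx2 <- max(0, x2 + (I2 - params$k * x2 - params$beta * x1) * dt)
    x1 <- nx1; x2 <- nx2
    if (x1 >= theta || x2 >= theta) {
      return(list(rt = s * dt + params$t_nd, correct = x1 >= x2))
    }
  }
  list(rt = NA_real_, correct = NA)
}
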