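#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Full within-subject decomposition of a fully crossed, balanced design
#' with one score per participant per cell. Each effect is tested against
#' its interaction with participants. Per effect the table reports F,
#' degrees of freedom, the mean squared error, the uncorrected p, partial
#' eta squared, the Greenhouse-Geisser epsilon (from the eigenvalues of
#' the effect's contrast-transformed covariance matrix:
#' `(sum lambda)^2 / (d * sum lambda^2)` for `d` orthonormal contrasts)
#' and the epsilon-corrected p.
#'
#' @param data A data frame in long form.
#' @param dv Name of the numeric response column (string).
#' @param id Name of the participant identifier column.
#' @param within Character vector (1-3) of within-participant factor
#'   columns.
#' @return An object of class `rm_anova`; use [tidy()][generics::tidy] for
#'   the effect table and `print()` for a report in the conventional
#'   `F(df1,df2) = ..., MSE = ..., p = ...` format.
#' @examples
#' d <- tidyr::expand_grid(id = factor(1:6), cond = factor(1:3))
#' d$y <- rnorm(nrow(d)) + as.numeric(d$cond)
#' fit <- rm_anova(d, "y", "id", "cond")
#' tidy(fit)
#' @export
rm_anova <- function(data, dv, id, within) {
  stopifnot(is.data.frame(data), length(within) >= 1, length(within) <= 3,
            all(c(dv, id, within) %in% names(data)))
  data <- tibble::as_tibble(data)
  data[[id]] <- factor(data[[id]])
  for (w in within) data[[w]] <- factor(data[[w]])
  if (anyNA(data[[dv]])) stop("missing scores are not supported", call. = FALSE)

  levs <- lapply(within, function(w) levels(data[[w]]))
  names(levs) <- within
  k <- vapply(levs, length, integer(1))
  subjects <- levels(data[[id]])
  n <- length(subjects)
  # cell grid in a fixed order: last factor varies fastest
  grid <- expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(within)), drop = FALSE]
  names(grid) <- within
  K <- nrow(grid)
  key_data <- do.call(paste, c(lapply(within, function(w) as.character(data[[w]])),
                               sep = "\r"))
  key_grid <- do.call(paste, c(lapply(within, function(w) as.character(grid[[w]])),
                               sep = "\r"))
  Y <- matrix(NA_real_, n, K, dimnames = list(subjects, key_grid))
  idx_s <- match(as.character(data[[id]]), subjects)
  idx_c <- match(key_data, key_grid)
  if (anyNA(idx_c)) stop("internal cell indexing failure", call. = FALSE)
  if (anyDuplicated(cbind(idx_s, idx_c)))
    stop("more than one score per participant per cell; aggregate first",
         call. = FALSE)
  Y[cbind(idx_s, idx_c)] <- data[[dv]]
  if (anyNA(Y)) stop("design is not complete: missing participant x cell scores",
                     call. = FALSE)

  # orthonormal contrast rows per factor (t(contr.poly) has orthonormal rows
  # orthogonal to the unit vector); averaging row for factors not in an effect
  contr_of <- function(kf) t(stats::contr.poly(kf))
  avg_of <- function(kf) matrix(1 / sqrt(kf), 1, kf)

  effects <- unlist(lapply(seq_along(within), function(m) {
    utils::combn(within, m, simplify = FALSE)
  }), recursive = FALSE)

  rows <- lapply(effects, function(eff) {
    M <- matrix(1, 1, 1)
    for (w in within) {
      Mw <- if (w %in% eff) contr_of(k[[w]]) else avg_of(k[[w]])
      M <- M %x% Mw
    }
    Z <- Y %*% t(M)                      # n x d transformed scores
    d <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar)^2)
    df1 <- d
    df2 <- (n - 1) * d
    ms_eff <- ss_eff / df1
    mse <- ss_err / df2
    Fv <- ms_eff / mse
    S <- stats::cov(Z)
    eps <- if (d == 1) 1 else {
      tr <- sum(diag(S))
      tr2 <- sum(S * S)   # = sum lambda^2 for symmetric S
      max(min(tr^2 / (d * tr2), 1), 1 / d)
    }
    tibble::tibble(
      effect = paste(eff, collapse = ":"),
      df_effect = df1, df_error = df2,
      ss_effect = ss_eff, ss_error = ss_err, mse = mse,
      F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE),
      pes = ss_eff / (ss_eff + ss_err),
      epsilon_gg = eps,
      p_gg = pf(Fv, eps * df1, eps * df2, lower.tail = FALSE))
  })
  tab <- dplyr::bind_rows(rows)

  subj_means <- rowMeans(Y)
  ss_subject <- K * sum((subj_means - mean(Y))^2)
  ss_total <- sum((Y - mean(Y))^2)

  structure(list(table = tab, n = n, k = k,
                 ss_subject = ss_subject, ss_total = ss_total,
                 dv = dv, id = id, within = within),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Repeated-measures ANOVA on '%s' (%d participants)\n\n",
              x$dv, x$n))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    line <- sprintf("%s: F(%d,%d) = %.*f, MSE = %.*f, p = %.4g, eta_p^2 = %.*f",
                    r$effect, r$df_effect, r$df_error, digits, r$F,
                    digits, r$mse, r$p, digits, r$pes)
    if (r$df_effect > 1) {
      line <- sprintf("%s, epsilon = %.2f, p_GG = %.4g", line, r$epsilon_gg, r$p_gg)
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n = x$n, n_effects = nrow(x$table),
                 ss_total = x$ss_total, ss_subject = x$ss_subject)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor from a covariance matrix of condition
#' scores and an orthonormal contrast basis: with eigenvalues `lambda` of
#' the transformed covariance `C S C'`, `epsilon = (sum lambda)^2 /
#' (d * sum lambda^2)`. Equal to 1 exactly when the transformed covariance
#' is spherical, and bounded below by `1/d`.
#'
#' @param cov Symmetric positive semi-definite k x k covariance matrix.
#' @param contrasts d x k matrix with orthonormal rows orthogonal to the
#'   unit vector; defaults to the polynomial contrast basis.
#' @return Epsilon in `(1/d, 1]`.
#' @examples
#' gg_epsilon(diag(3) + 1)  # compound symmetry -> 1
#' @export
gg_epsilon <- function(cov, contrasts = NULL) {
  cov <- as.matrix(cov)
  kk <- ncol(cov)
  stopifnot(nrow(cov) == kk, kk >= 2)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance matrix must be symmetric", call. = FALSE)
  ev_full <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_full) < -1e-8 * max(abs(ev_full)))
    stop("covariance matrix must be positive semi-definite", call. = FALSE)
  if (is.null(contrasts)) contrasts <- t(stats::contr.poly(kk))
  contrasts <- as.matrix(contrasts)
  stopifnot(ncol(contrasts) == kk)
  d <- nrow(contrasts)
  if (d == 1) return(1)
  S <- contrasts %*% cov %*% t(contrasts)
  tr <- sum(diag(S))
  tr2 <- sum(S * S)
  if (tr2 <= 0) stop("degenerate transformed covariance", call. = FALSE)
  max(min(tr^2 / (d * tr2), 1), 1 / d)
}

#' Friedman rank test across conditions
#'
#' Nonparametric test for differences among `k >= 3` within-participant
#' conditions, based on within-participant ranks (mid-ranks for ties) and
#' the chi-square approximation with `k - 1` degrees of freedom.
#'
#' @param data Long-form data frame.
#' @param dv,id,within Column names: response, participant, condition.
#' @return A tibble: `statistic` (chi-square), `df`, `n`, `p`.
#' @export
friedman_test <- function(data, dv, id, within) {
  stopifnot(all(c(dv, id, within) %in% names(data)))
  m <- tapply(data[[dv]], list(factor(data[[id]]), factor(data[[within]])), mean)
  if (anyNA(m)) stop("friedman_test requires a complete balanced table", call. = FALSE)
  if (ncol(m) < 3) stop("friedman_test requires at least 3 conditions", call. = FALSE)
  if (all(apply(m, 1, function(r) max(r) == min(r)))) {
    # every participant fully tied: the tie-corrected statistic is 0/0,
    # but there is no evidence of condition differences
    return(tibble::tibble(statistic = 0, df = ncol(m) - 1,
                          n = nrow(m), p = 1))
  }
  res <- stats::friedman.test(m)
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 n = nrow(m),
                 p = res$p.value)
}

#' Wilcoxon signed-rank test
#'
#' Tests per-participant differences against zero. Zero differences are
#' dropped (Wilcoxon convention), absolute differences receive mid-ranks
#' under ties, and the reported statistic `T` is the smaller of the
#' positive and negative rank sums. The p-value uses the normal
#' approximation with tie-corrected variance and continuity correction, so
#' printed p's from exact-enumeration software can differ slightly.
#'
#' @param diffs Numeric vector of per-participant differences.
#' @return A tibble: `statistic` (T), `n` (number of participants
#'   supplied), `n_nonzero` (used after dropping zeros), `p` (two-sided).
#' @export
wilcoxon_signed_rank <- function(diffs) {
  stopifnot(is.numeric(diffs))
  diffs <- diffs[!is.na(diffs)]
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(nz))
  t_pos <- sum(r[nz > 0])
  t_neg <- sum(r[nz < 0])
  p <- suppressWarnings(
    stats::wilcox.test(nz, exact = FALSE, correct = TRUE)$p.value)
  tibble::tibble(statistic = min(t_pos, t_neg),
                 n = length(diffs), n_nonzero = length(nz), p = p)
}

#' Cousineau-Morey within-participant standard errors
#'
#' Each score is centred by its participant's mean and re-centred by the
#' grand mean, removing between-participant offsets; the per-condition
#' standard error of the centred scores is then inflated by
#' `sqrt(M / (M - 1))` for `M` conditions (Morey's bias correction).
#'
#' @param data Long-form data frame (balanced; one score per participant
#'   per condition).
#' @param dv,id Column names of the response and participant identifier.
#' @param conditions Character vector of columns that jointly define the
#'   conditions.
#' @return A tibble with the condition columns, `mean`, `se`, `n`.
#' @export
cousineau_morey_se <- function(data, dv, id, conditions) {
  stopifnot(all(c(dv, id, conditions) %in% names(data)))
  data <- tibble::as_tibble(data)
  cond_key <- interaction(data[conditions], drop = TRUE)
  M <- nlevels(cond_key)
  if (M < 2) stop("need at least 2 conditions", call. = FALSE)
  cnt <- table(data[[id]], cond_key)
  if (any(cnt != 1)) stop("need exactly one score per participant per condition",
                          call. = FALSE)
  grand <- mean(data[[dv]])
  subj_mean <- stats::ave(data[[dv]], data[[id]], FUN = mean)
  centred <- data[[dv]] - subj_mean + grand
  data$.centred <- centred
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(conditions))) |>
    dplyr::summarise(mean = mean(.data[[dv]]),
                     se = sqrt(M / (M - 1)) * sd(.data$.centred) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' t-based confidence interval for a mean
#'
#' @param values Numeric vector of per-participant estimates.
#' @param level Confidence level (default .95).
#' @return A tibble: `mean`, `lo`, `hi`, `n`.
#' @export
ci_mean <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n >= 2)
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(values) / sqrt(n)
  tibble::tibble(mean = m, lo = m - half, hi = m + half, n = n)
}
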