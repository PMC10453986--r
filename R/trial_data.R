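#' @useDynLib simonlca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats quantile sd qt pf pchisq var coef lm predict setNames
#' @importFrom utils head
NULL

# The five canonical feature-onset asynchronies (ms); negative = the
# irrelevant feature (position) leads the relevant one (colour).
SOA_LEVELS <- c(-200L, -100L, 0L, 100L, 200L)
INSTRUCTIONS <- c("speed", "accuracy")
CONGRUENCIES <- c("congruent", "incongruent")

# Single quantile estimator used throughout the package: linear
# interpolation at position h = (n - 1) p + 1 on the sorted sample,
# i.e. stats::quantile type 7.
rt_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

quantile_col <- function(probs) sprintf("q%02d", round(probs * 100))

#' Read a trial-level data file
#'
#' Reads a delimited text file (comma or tab separated, one header row) into
#' a validated trial table with one row per trial. Column names in the file
#' are mapped to the canonical names via `col_map`, so files with arbitrary
#' headers need not be renamed.
#'
#' @param path Path to a delimited text file.
#' @param col_map Named character vector mapping canonical column names
#'   (`participant`, `instruction`, `soa`, `congruency`, `rt`, `correct`,
#'   and optionally `block`) to the header names used in the file. Defaults
#'   to the identity mapping.
#' @param delim Field delimiter. `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#'
#' @return A tibble with columns `participant` (character), `instruction`
#'   (factor speed/accuracy), `soa` (integer ms), `congruency` (factor),
#'   `rt` (numeric ms, `NA` when no response was recorded), `correct`
#'   (logical, `NA` iff `rt` is `NA`) and, when present in the file,
#'   `block` (integer). The source path is recorded in the
#'   `"provenance"` attribute.
#'
#' @details Reaction time is measured from the onset of the *first*
#'   stimulus feature (relevant or irrelevant), so mean RTs are longer at
#'   negative asynchronies, where the irrelevant feature leads.
#'   Malformed rows (unknown asynchrony, unparseable RT, invalid factor
#'   levels) abort with a message naming the offending line and value.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "participant,instruction,soa,congruency,rt,correct",
#'   "P01,speed,0,congruent,345,1",
#'   "P01,speed,0,incongruent,402,1"
#' ), tf)
#' read_trials(tf)
#' @export
read_trials <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  header_names <- trimws(strsplit(header, delim, fixed = TRUE)[[1]])
  if (anyDuplicated(header_names)) {
    stop("duplicate header column(s): ",
         paste(unique(header_names[duplicated(header_names)]), collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           trim_ws = TRUE, na = c("", "NA", "na", "NaN"))
  nms <- names(raw)
  canonical <- c("participant", "instruction", "soa", "congruency", "rt", "correct", "block")
  map <- setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) stop("unknown canonical name(s) in col_map: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    map[names(col_map)] <- col_map
  }
  required <- canonical[canonical != "block"]
  missing_cols <- required[!map[required] %in% nms]
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    participant = as.character(raw[[map["participant"]]]),
    instruction = tolower(as.character(raw[[map["instruction"]]])),
    soa = suppressWarnings(as.numeric(raw[[map["soa"]]])),
    congruency = tolower(as.character(raw[[map["congruency"]]])),
    rt = suppressWarnings(as.numeric(raw[[map["rt"]]])),
    correct_raw = tolower(as.character(raw[[map["correct"]]]))
  )
  if (map["block"] %in% nms) out$block <- as.integer(raw[[map["block"]]])
  line_of <- function(i) i + 1L  # header occupies line 1

  bad_rt_txt <- which(is.na(out$rt) & !is.na(raw[[map["rt"]]]))
  if (length(bad_rt_txt)) {
    i <- bad_rt_txt[1]
    stop(sprintf("line %d: unparseable rt value '%s'", line_of(i),
                 raw[[map["rt"]]][i]), call. = FALSE)
  }
  bad_soa <- which(is.na(out$soa) | !(out$soa %in% SOA_LEVELS))
  if (length(bad_soa)) {
    i <- bad_soa[1]
    stop(sprintf("line %d: soa value '%s' is not one of %s", line_of(i),
                 as.character(raw[[map["soa"]]][i]),
                 paste(SOA_LEVELS, collapse = ", ")), call. = FALSE)
  }
  out$correct <- dplyr::case_when(
    out$correct_raw %in% c("1", "true", "t", "yes") ~ TRUE,
    out$correct_raw %in% c("0", "false", "f", "no") ~ FALSE,
    TRUE ~ NA
  )
  bad_corr <- which(is.na(out$correct) & !is.na(out$correct_raw))
  if (length(bad_corr)) {
    i <- bad_corr[1]
    stop(sprintf("line %d: unparseable correct value '%s'", line_of(i),
                 out$correct_raw[i]), call. = FALSE)
  }
  out$correct_raw <- NULL
  out$soa <- as.integer(out$soa)
  trials <- validate_trials(out)
  attr(trials, "provenance") <- list(source = path, n_parsed = nrow(trials))
  trials
}

#' Validate a trial table
#'
#' Checks the trial-table contract: required columns, the five canonical
#' asynchrony levels, valid instruction/congruency levels, non-negative
#' reaction times, and the pairing of missing reaction times with missing
#' correctness (a trial with no recorded response has neither).
#'
#' @param trials A data frame of trials.
#' @return The validated trials as a tibble (factor columns normalised),
#'   invisibly usable in a pipe.
#' @export
validate_trials <- function(trials) {
  required <- c("participant", "instruction", "soa", "congruency", "rt", "correct")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  bad_instr <- setdiff(unique(as.character(trials$instruction)), INSTRUCTIONS)
  if (length(bad_instr)) {
    stop("invalid instruction level(s): ", paste(bad_instr, collapse = ", "),
         call. = FALSE)
  }
  bad_congr <- setdiff(unique(as.character(trials$congruency)), CONGRUENCIES)
  if (length(bad_congr)) {
    stop("invalid congruency level(s): ", paste(bad_congr, collapse = ", "),
         call. = FALSE)
  }
  bad_soa <- setdiff(unique(trials$soa), SOA_LEVELS)
  if (length(bad_soa)) {
    stop("invalid soa level(s): ", paste(bad_soa, collapse = ", "), call. = FALSE)
  }
  if (any(trials$rt < 0, na.rm = TRUE)) stop("negative rt values", call. = FALSE)
  mism <- xor(is.na(trials$rt), is.na(trials$correct))
  if (any(mism)) {
    stop(sprintf("%d row(s) violate rt-missing <=> correct-missing (first at row %d)",
                 sum(mism), which(mism)[1]), call. = FALSE)
  }
  trials$instruction <- factor(as.character(trials$instruction), levels = INSTRUCTIONS)
  trials$congruency <- factor(as.character(trials$congruency), levels = CONGRUENCIES)
  trials$soa <- as.integer(trials$soa)
  trials
}

#' Remove outlier trials
#'
#' Applies the single trial-level exclusion of the analysis: trials with a
#' reaction time strictly below `min_rt` or with no recorded response are
#' removed. The boundary is strict, so a trial at exactly `min_rt` ms is
#' kept. This filter is idempotent.
#'
#' @param trials A validated trial table.
#' @param min_rt Minimum admissible reaction time in ms (default 100).
#' @return The filtered tibble. The removal report (counts and percentage)
#'   is attached as attribute `"outlier_report"`; retrieve it with
#'   [outlier_report()].
#' @examples
#' trials <- tibble::tibble(
#'   participant = "P01", instruction = "speed", soa = 0L,
#'   congruency = "congruent", rt = c(95, 100, 500),
#'   correct = c(TRUE, TRUE, TRUE)
#' )
#' kept <- filter_outliers(trials)
#' outlier_report(kept)
#' @export
filter_outliers <- function(trials, min_rt = 100) {
  trials <- validate_trials(trials)
  n_total <- nrow(trials)
  drop <- is.na(trials$rt) | trials$rt < min_rt
  kept <- trials[!drop, , drop = FALSE]
  report <- tibble::tibble(
    n_total = n_total,
    n_removed = sum(drop),
    n_kept = n_total - sum(drop),
    pct_removed = if (n_total > 0) 100 * sum(drop) / n_total else NA_real_,
    min_rt = min_rt
  )
  if (nrow(kept) == 0L) warning("all trials removed by the outlier filter", call. = FALSE)
  attr(kept, "outlier_report") <- report
  attr(kept, "provenance") <- attr(trials, "provenance")
  kept
}

#' Retrieve the outlier report attached by [filter_outliers()]
#' @param trials A trial table returned by [filter_outliers()].
#' @return A one-row tibble with counts and the removal percentage.
#' @export
outlier_report <- function(trials) {
  rep <- attr(trials, "outlier_report")
  if (is.null(rep)) stop("no outlier report attached; run filter_outliers() first",
                         call. = FALSE)
  rep
}

#' Per-cell summaries: error rate, mean correct RT, RT quantiles
#'
#' For every participant x instruction x soa x congruency cell, computes the
#' error rate over responded trials, the mean reaction time of correct
#' responses, and quantiles of the correct-RT distribution (defaults
#' .1/.3/.5/.7/.9, linear interpolation between order statistics).
#'
#' @param trials A filtered trial table (see [filter_outliers()]); rows with
#'   missing responses should already have been removed.
#' @param probs Quantile levels (default `c(.1, .3, .5, .7, .9)`).
#' @return A tibble with one row per cell: `participant`, `instruction`,
#'   `soa`, `congruency`, `n_correct`, `n_error`, `error_pct`, `mean_rt`,
#'   and one `qXX` column per quantile level.
#' @export
cell_summaries <- function(trials, probs = c(.1, .3, .5, .7, .9)) {
  trials <- validate_trials(trials)
  stopifnot(length(probs) >= 1, all(probs > 0 & probs < 1), !is.unsorted(probs))
  responded <- trials[!is.na(trials$correct), , drop = FALSE]
  qnames <- quantile_col(probs)
  out <- responded |>
    dplyr::group_by(.data$participant, .data$instruction, .data$soa, .data$congruency) |>
    dplyr::group_modify(function(d, key) {
      n_correct <- sum(d$correct)
      n_error <- sum(!d$correct)
      if (n_correct == 0L) {
        stop(sprintf("cell %s/%s/soa %d/%s has no correct trials",
                     key$participant, key$instruction, key$soa, key$congruency),
             call. = FALSE)
      }
      rts <- d$rt[d$correct]
      qs <- rt_quantile(rts, probs)
      res <- tibble::tibble(
        n_correct = n_correct, n_error = n_error,
        error_pct = 100 * n_error / (n_correct + n_error),
        mean_rt = mean(rts)
      )
      res[qnames] <- as.list(qs)
      res
    }) |>
    dplyr::ungroup()
  attr(out, "probs") <- probs
  out
}
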