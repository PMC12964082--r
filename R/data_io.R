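#' Read a familial count table
#'
#' Reads a CSV of per-study offspring counts by parental mating class.
#' Mandatory columns: `study_id`, `rxr_r`, `rxr_l`, `mix_r`, `mix_l`,
#' `lxl_r`, `lxl_l`. Optional columns: `pairs_rxr`, `pairs_mix`, `pairs_lxl`
#' (parental couples per mating class) and `m_p` (externally reported
#' parental incidence of left-handedness).
#'
#' With `incidence_mode = "triplets"` and no pair columns present, parental
#' pair counts are imputed as the row offspring totals divided by three
#' (rounded to the nearest integer), the convention of treating each couple's
#' entry as three offspring.
#'
#' @param path Path to the CSV file (comma-separated, UTF-8, header
#'   required).
#' @param incidence_mode `"reported"` (default; per-study `m_p` comes from
#'   the `m_p` column, with triplet-derived pairs as fallback) or
#'   `"triplets"`.
#' @return A data frame of class `familial_data`, one row per study.
#' @examples
#' path <- system.file("extdata", "synthetic_familial_17studies.csv",
#'                     package = "handtrans")
#' fam <- read_familial_table(path)
#' nrow(fam)
#' @export
read_familial_table <- function(path, incidence_mode = c("reported",
                                                         "triplets")) {
  incidence_mode <- match.arg(incidence_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "rxr_r", "rxr_l", "mix_r", "mix_l", "lxl_r", "lxl_l")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(.as_familial(df[, need], incidence_mode))
  count_cols <- need[-1]
  for (col in count_cols) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 |
                   df[[col]] != round(df[[col]]))
    if (length(bad)) {
      stop(sprintf("invalid count in column %s for study '%s'",
                   col, df$study_id[bad[1]]), call. = FALSE)
    }
  }
  totals <- rowSums(df[, count_cols])
  if (any(totals == 0)) {
    stop(sprintf("study '%s' has zero total offspring",
                 df$study_id[which(totals == 0)[1]]), call. = FALSE)
  }
  pair_cols <- c("pairs_rxr", "pairs_mix", "pairs_lxl")
  if (!all(pair_cols %in% names(df))) {
    # triplets convention: one couple per three offspring in the row
    df$pairs_rxr <- as.integer(round((df$rxr_r + df$rxr_l) / 3))
    df$pairs_mix <- as.integer(round((df$mix_r + df$mix_l) / 3))
    df$pairs_lxl <- as.integer(round((df$lxl_r + df$lxl_l) / 3))
    attr(df, "pairs_imputed") <- TRUE
  } else {
    attr(df, "pairs_imputed") <- FALSE
  }
  if (!"m_p" %in% names(df)) df$m_p <- NA_real_
  if (any(!is.na(df$m_p) & (df$m_p <= 0 | df$m_p >= 1))) {
    stop("reported m_p must lie strictly between 0 and 1", call. = FALSE)
  }
  .as_familial(df, incidence_mode)
}

.as_familial <- function(df, incidence_mode = "reported") {
  structure(df, class = c("familial_data", "data.frame"),
            incidence_mode = incidence_mode)
}

#' Measured parental incidence of one study
#'
#' Either echoes the externally reported frequency of left-handed parents
#' (`mode = "reported"`) or derives it from the parental pair counts:
#' `m_p = (pairs_mix + 2 pairs_lxl) / (2 total pairs)`.
#'
#' @param study One row of a `familial_data` frame (or a list with the same
#'   fields).
#' @param mode `"reported"` or `"triplets"`.
#' @return The measured parental incidence, strictly inside `(0, 1)`.
#' @export
compute_parent_incidence <- function(study, mode = c("reported",
                                                     "triplets")) {
  mode <- match.arg(mode)
  if (mode == "reported") {
    m_p <- study$m_p
    if (is.null(m_p) || is.na(m_p)) {
      stop("mode 'reported' requires a reported m_p for study '",
           study$study_id, "'", call. = FALSE)
    }
  } else {
    pairs <- c(study$pairs_rxr, study$pairs_mix, study$pairs_lxl)
    if (is.null(pairs) || anyNA(pairs)) {
      stop("mode 'triplets' requires parental pair counts for study '",
           study$study_id, "'", call. = FALSE)
    }
    m_p <- (pairs[2] + 2 * pairs[3]) / (2 * sum(pairs))
  }
  if (m_p <= 0 || m_p >= 1) {
    stop(sprintf("parental incidence %.3f of study '%s' is degenerate ",
                 m_p, study$study_id),
         "(must be strictly between 0 and 1)", call. = FALSE)
  }
  m_p
}

#' Measured offspring incidence of one study
#'
#' `m_o` = total left-handed offspring / total offspring.
#'
#' @param study One row of a `familial_data` frame.
#' @return The measured offspring incidence in `[0, 1]`.
#' @export
compute_offspring_incidence <- function(study) {
  l <- study$rxr_l + study$mix_l + study$lxl_l
  n <- l + study$rxr_r + study$mix_r + study$lxl_r
  if (n <= 0) stop("total offspring must be positive", call. = FALSE)
  l / n
}

#' Read a twin-pair count table
#'
#' CSV columns: `study_id`, `zygosity` (`MZ` or `DZ`), `n_rr`, `n_rl`,
#' `n_ll` (right-right, discordant and left-left pair counts; discordant
#' pairs are pooled).
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `twin_data`.
#' @export
read_twin_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "zygosity", "n_rr", "n_rl", "n_ll")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (!all(df$zygosity %in% c("MZ", "DZ"))) {
      stop("zygosity must be 'MZ' or 'DZ'", call. = FALSE)
    }
    for (col in c("n_rr", "n_rl", "n_ll")) {
      bad <- which(is.na(df[[col]]) | df[[col]] < 0)
      if (length(bad)) {
        stop(sprintf("invalid count in column %s for study '%s'",
                     col, df$study_id[bad[1]]), call. = FALSE)
      }
    }
    if (any(rowSums(df[, c("n_rr", "n_rl", "n_ll")]) == 0)) {
      stop("each twin dataset must contain at least one pair", call. = FALSE)
    }
  }
  structure(df, class = c("twin_data", "data.frame"))
}

#' Read a sex-stratified familial count table
#'
#' Long-format CSV columns: `study_id`, `mating` (`rmrf`, `rmlf`, `lmrf`,
#' `lmlf`; mother phenotype then father phenotype), `sex` (`f` or `m`,
#' offspring sex), `n_r`, `n_l`. Optional: `pairs` (couples per mating,
#' constant within mating).
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `sex_data`.
#' @export
read_sex_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "mating", "sex", "n_r", "n_l")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) > 0) {
    if (!all(df$mating %in% c("rmrf", "rmlf", "lmrf", "lmlf"))) {
      stop("mating must be one of rmrf, rmlf, lmrf, lmlf", call. = FALSE)
    }
    if (!all(df$sex %in% c("f", "m"))) {
      stop("sex must be 'f' or 'm'", call. = FALSE)
    }
    for (col in c("n_r", "n_l")) {
      bad <- which(is.na(df[[col]]) | df[[col]] < 0)
      if (length(bad)) {
        stop(sprintf("invalid count in column %s (row %d)", col, bad[1]),
             call. = FALSE)
      }
    }
    if (sum(df$n_r + df$n_l) == 0) {
      stop("sex-stratified table contains no offspring", call. = FALSE)
    }
  }
  structure(df, class = c("sex_data", "data.frame"))
}

#' Write a familial count table
#'
#' Inverse of [read_familial_table()]; writing then reading reproduces the
#' counts exactly.
#'
#' @param fam A `familial_data` frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_familial_table <- function(fam, path) {
  utils::write.csv(as.data.frame(fam), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes a fit, goodness-of-fit, likelihood-ratio or evaluation result
#' to a human-readable text file, together with the inputs, seed and package
#' version recorded on the object.
#'
#' @param result An object produced by [fit_mle()], [gof_familial()],
#'   [gof_twins()], [likelihood_ratio_test()] or [evaluate_estimator()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("handtrans %s report", as.character(utils::packageVersion("handtrans"))),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    ""), con)
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(result)
  invisible(path)
}
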