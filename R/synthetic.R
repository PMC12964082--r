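# Default 17-study offspring totals (divisible by 3: one couple per three
# offspring), spanning the small-to-large range of the historical familial
# literature, ~28,000 offspring in total.
.default_study_sizes <- c(8100, 4800, 3600, 2700, 2100, 1500, 1200, 900,
                          750, 600, 450, 390, 330, 300, 270, 240, 210)

#' Configuration of the synthetic familial-data generator
#'
#' Describes the generating conditions for synthetic familial datasets: the
#' true transmission parameters, the per-study sizes, and the study-level
#' criterion-shift model. Under `per_study_uniform` each study draws, for
#' each generation (parents and offspring) independently, a misclassification
#' flip probability uniform on `[lo, hi]` and a random direction; the flips
#' are applied through the same two-state maps used by the adjustment
#' module.
#'
#' @param true_params Generating [base_params()] (default: rho = 0.277,
#'   alpha = 0.138, beta = 0).
#' @param study_sizes Offspring totals per study (default: 17 studies
#'   between 210 and 8100 offspring).
#' @param offspring_per_pair Offspring per couple (default 3, the triplet
#'   convention).
#' @param shift `"per_study_uniform"` (default) or `"none"`.
#' @param shift_lo,shift_hi Bounds of the flip-probability distribution
#'   (defaults 0 and 0.2).
#' @param n_datasets Number of datasets to generate.
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_params = base_params(0.277, 0.138, 0),
                             study_sizes = .default_study_sizes,
                             offspring_per_pair = 3L,
                             shift = c("per_study_uniform", "none"),
                             shift_lo = 0, shift_hi = 0.2,
                             n_datasets = 1L, seed) {
  shift <- match.arg(shift)
  stopifnot(inherits(true_params, "base_params"),
            length(study_sizes) >= 1, all(study_sizes > 0),
            offspring_per_pair >= 1,
            shift_lo >= 0, shift_hi < 1, shift_lo <= shift_hi,
            n_datasets >= 1, is.numeric(seed), length(seed) == 1)
  structure(list(true_params = true_params, study_sizes = study_sizes,
                 offspring_per_pair = as.integer(offspring_per_pair),
                 shift = shift, shift_lo = shift_lo, shift_hi = shift_hi,
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# simulate one study's measured counts; returns a one-row data frame or NULL
# if the draw produced a degenerate measured incidence
.simulate_study <- function(size, config, T_tab, t) {
  kpp <- config$offspring_per_pair
  n_pairs <- max(1L, round(size / kpp))
  true_pairs <- as.integer(stats::rmultinom(1, n_pairs,
                                            c((1 - t)^2, 2 * t * (1 - t),
                                              t^2)))
  shift <- config$shift == "per_study_uniform"
  flip <- function() {
    if (!shift) return(c(0, 0))  # c(R-to-L, L-to-R) flip probabilities
    s <- stats::runif(1, config$shift_lo, config$shift_hi)
    if (stats::runif(1) < 0.5) c(s, 0) else c(0, s)
  }
  fp <- flip()  # parents
  fo <- flip()  # offspring
  # per-parent true -> measured map
  qR <- c(1 - fp[1], fp[1])  # true R -> (measured R, measured L)
  qL <- c(fp[2], 1 - fp[2])
  class_flow <- rbind(
    c(qR[1]^2, 2 * qR[1] * qR[2], qR[2]^2),
    c(qR[1] * qL[1], qR[1] * qL[2] + qR[2] * qL[1], qR[2] * qL[2]),
    c(qL[1]^2, 2 * qL[1] * qL[2], qL[2]^2)
  )
  measured <- matrix(0, 3, 2)  # measured class x (R, L)
  pair_flow <- matrix(0L, 3, 3)
  for (ci in 1:3) {
    if (true_pairs[ci] == 0) next
    fl <- as.integer(stats::rmultinom(1, true_pairs[ci], class_flow[ci, ]))
    pair_flow[ci, ] <- fl
    for (cj in 1:3) {
      if (fl[cj] == 0) next
      n_off <- fl[cj] * kpp
      true_r <- stats::rbinom(1, n_off, T_tab[ci, "R"])
      true_l <- n_off - true_r
      meas_r <- stats::rbinom(1, true_r, 1 - fo[1]) +
        stats::rbinom(1, true_l, fo[2])
      measured[cj, 1] <- measured[cj, 1] + meas_r
      measured[cj, 2] <- measured[cj, 2] + (n_off - meas_r)
    }
  }
  meas_pairs <- colSums(pair_flow)
  m_p <- (meas_pairs[2] + 2 * meas_pairs[3]) / (2 * n_pairs)
  m_o <- sum(measured[, 2]) / sum(measured)
  if (m_p <= 0 || m_p >= 1 || m_o <= 0 || m_o >= 1) return(NULL)
  data.frame(rxr_r = measured[1, 1], rxr_l = measured[1, 2],
             mix_r = measured[2, 1], mix_l = measured[2, 2],
             lxl_r = measured[3, 1], lxl_l = measured[3, 2],
             pairs_rxr = meas_pairs[1], pairs_mix = meas_pairs[2],
             pairs_lxl = meas_pairs[3], m_p = m_p)
}

#' Simulate familial datasets with criterion shift
#'
#' For each dataset and each study: couples are formed by random mating at
#' the equilibrium phenotype frequencies of the generating parameters; true
#' offspring phenotypes are drawn binomially from the true transmission
#' table; then study-specific misclassification (per the config's shift
#' model) is applied independently to parent classifications and offspring
#' phenotypes, and the measured counts and measured parental incidence are
#' recorded. Studies drawing a degenerate measured incidence (0 or 1 in
#' either generation) are redrawn, up to 50 retries.
#'
#' @param config A [synthetic_config()].
#' @param true_params Optional override of the generating parameters (used
#'   by the uniform-truth evaluation).
#' @return A list of `config$n_datasets` `familial_data` frames, fully
#'   reproducible from `config$seed`.
#' @export
simulate_familial <- function(config, true_params = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(true_params)) true_params <- config$true_params
  set.seed(config$seed)
  T_tab <- transmission_table(true_params)
  t <- equilibrium(true_params)$f_dl
  lapply(seq_len(config$n_datasets), function(d) {
    rows <- lapply(seq_along(config$study_sizes), function(i) {
      for (try in 1:50) {
        row <- .simulate_study(config$study_sizes[i], config, T_tab, t)
        if (!is.null(row)) {
          row$study_id <- sprintf("synth_%02d", i)
          return(row[, c("study_id", setdiff(names(row), "study_id"))]) }
      }
      stop("could not draw a non-degenerate study after 50 retries",
           call. = FALSE)
    })
    .as_familial(do.call(rbind, rows), "reported")
  })
}

#' Simulate twin-pair datasets
#'
#' Draws MZ and DZ pair counts from the model's expected pair distribution
#' ([twin_expectations()]; identical for both zygosities) and applies
#' per-twin misclassification chosen so that the individual-level measured
#' incidence equals `m_o_target` in expectation.
#'
#' @param params Generating [base_params()].
#' @param n_pairs Pairs per zygosity group (length 1 or 2, MZ then DZ).
#' @param m_o_target Target measured individual-level left rate (defaults to
#'   the true incidence: no shift).
#' @param seed Integer seed.
#' @return A `twin_data` frame with one MZ and one DZ row.
#' @export
simulate_twins <- function(params, n_pairs, m_o_target = NULL, seed) {
  stopifnot(inherits(params, "base_params"), all(n_pairs > 0))
  n_pairs <- rep_len(n_pairs, 2)
  set.seed(seed)
  probs <- twin_expectations(params)
  t <- equilibrium(params)$f_dl
  if (is.null(m_o_target)) m_o_target <- t
  probs_m <- if (abs(m_o_target - t) < 1e-12) probs else
    adjust_twin(probs, t, m_o_target)
  draw <- function(n) as.integer(stats::rmultinom(1, n, probs_m))
  mz <- draw(n_pairs[1]); dz <- draw(n_pairs[2])
  structure(data.frame(study_id = c("synth_mz", "synth_dz"),
                       zygosity = c("MZ", "DZ"),
                       n_rr = c(mz[1], dz[1]),
                       n_rl = c(mz[2], dz[2]),
                       n_ll = c(mz[3], dz[3])),
            class = c("twin_data", "data.frame"))
}

#' Practical non-identifiability filters
#'
#' Removes synthetic datasets in which the transmission parameters are
#' practically non-identifiable: (i) the measured frequency of
#' left-handedness is below 1% in either the parent or the offspring
#' generation (pooled across studies), or (ii) the pooled empirical
#' difference `p(R | RxR) - p(R | LxL)` is below 7 percentage points (or
#' undefined because a pooled extreme mating class is empty).
#'
#' @param datasets A list of `familial_data` frames (or a single frame).
#' @return A list with `kept`, `removed` and a character vector `reasons`
#'   (`"low_incidence"`, `"flat_transmission"` or `"ok"`, one per dataset).
#' @export
apply_identifiability_filters <- function(datasets) {
  if (inherits(datasets, "familial_data")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  reasons <- vapply(datasets, function(fam) {
    pairs_tot <- sum(fam$pairs_rxr, fam$pairs_mix, fam$pairs_lxl)
    par_rate <- (sum(fam$pairs_mix) + 2 * sum(fam$pairs_lxl)) /
      (2 * pairs_tot)
    off_l <- sum(fam$rxr_l, fam$mix_l, fam$lxl_l)
    off_rate <- off_l / sum(fam$rxr_r, fam$rxr_l, fam$mix_r, fam$mix_l,
                            fam$lxl_r, fam$lxl_l)
    if (par_rate < 0.01 || off_rate < 0.01) return("low_incidence")
    n_rxr <- sum(fam$rxr_r, fam$rxr_l); n_lxl <- sum(fam$lxl_r, fam$lxl_l)
    if (n_rxr == 0 || n_lxl == 0) return("flat_transmission")
    diff <- sum(fam$rxr_r) / n_rxr - sum(fam$lxl_r) / n_lxl
    if (diff < 0.07) return("flat_transmission")
    "ok"
  }, character(1))
  list(kept = datasets[reasons == "ok"],
       removed = datasets[reasons != "ok"],
       reasons = reasons)
}

# the five fixed Nelder-Mead starting points of the evaluation protocol,
# ordered (rho, alpha)
.eval_starts <- list(c(0.1, 0.1), c(0.01, 0.1), c(0.1, 0.01),
                     c(0.45, 0.01), c(0.01, 0.45))

#' Simulation study of estimator bias, MSE and coverage
#'
#' Generates `config$n_datasets` synthetic familial datasets, fits the
#' two-parameter model to each under the chosen scenario (best of five fixed
#' Nelder-Mead starts), and reports per-parameter bias and mean squared
#' error, the (truth, estimate) scatter, and - when `bootstrap` is supplied -
#' the empirical coverage of percentile bootstrap confidence intervals at
#' the requested nominal levels.
#'
#' @param config A [synthetic_config()].
#' @param scenario `"B"` (fit without adjustment) or `"C"` (fit with
#'   adjustment).
#' @param truth `"fixed"` (all datasets at `config$true_params`) or
#'   `"uniform"` (per dataset, `rho ~ U(0, 0.5)` and
#'   `alpha ~ U(0, 0.5 - rho)`).
#' @param starts Start points per fit (default: the five fixed evaluation
#'   starts).
#' @param n_random_starts Additional uniform random starts per fit. Defaults
#'   to 0 for scenario B and 25 for scenario C: the criterion-shift
#'   adjustment curves the support surface, and the five fixed starts alone
#'   frequently stall on local optima there.
#' @param bootstrap `NULL`, or a list with `n_boot` and `levels` to compute
#'   coverage.
#' @param filters Apply [apply_identifiability_filters()] before fitting?
#' @return An object of class `handtrans_eval`: `estimates` (data frame of
#'   truths and estimates), `bias`, `mse`, `coverage` (or `NULL`),
#'   `filter_diagnostics`, `n_failed` and the configuration.
#' @export
evaluate_estimator <- function(config, scenario = c("B", "C"),
                               truth = c("fixed", "uniform"),
                               starts = .eval_starts,
                               n_random_starts = NULL, bootstrap = NULL,
                               filters = FALSE) {
  scenario <- match.arg(scenario)
  truth <- match.arg(truth)
  if (is.null(n_random_starts)) {
    n_random_starts <- if (scenario == "C") 25L else 0L
  }
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (truth == "fixed") {
    truths <- matrix(c(config$true_params$rho, config$true_params$alpha),
                     config$n_datasets, 2, byrow = TRUE)
  } else {
    rho <- stats::runif(config$n_datasets, 0, 0.5)
    alpha <- stats::runif(config$n_datasets, 0, 0.5 - rho)
    truths <- cbind(rho, alpha)
  }
  seeds <- sample.int(.Machine$integer.max, config$n_datasets)
  one_cfg <- function(d) {
    cfg <- config; cfg$n_datasets <- 1L; cfg$seed <- seeds[d]
    cfg$true_params <- base_params(truths[d, 1], truths[d, 2], 0)
    cfg
  }
  datasets <- lapply(seq_len(config$n_datasets),
                     function(d) simulate_familial(one_cfg(d))[[1]])
  keep <- rep(TRUE, config$n_datasets)
  reasons <- rep("ok", config$n_datasets)
  if (filters) {
    fl <- apply_identifiability_filters(datasets)
    reasons <- fl$reasons
    keep <- reasons == "ok"
  }
  est <- matrix(NA_real_, config$n_datasets, 2,
                dimnames = list(NULL, c("rho", "alpha")))
  covered <- NULL
  if (!is.null(bootstrap)) {
    levels <- bootstrap$levels
    covered <- array(NA, dim = c(config$n_datasets, 2, length(levels)),
                     dimnames = list(NULL, c("rho", "alpha"), levels))
  }
  n_failed <- 0L
  for (d in which(keep)) {
    fit <- tryCatch(
      fit_mle(datasets[[d]], scenario = scenario, model = "two",
              n_starts = length(starts) + n_random_starts,
              starts = starts, seed = seeds[d] %% 10000000L),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    est[d, ] <- c(fit$params$rho, fit$params$alpha)
    if (!is.null(bootstrap)) {
      bt <- tryCatch(
        bootstrap_ci(datasets[[d]], scenario = scenario, model = "two",
                     n_boot = bootstrap$n_boot, levels = bootstrap$levels,
                     seed = seeds[d] %% 1000000L, fit = fit),
        error = function(e) NULL)
      if (!is.null(bt)) {
        for (pi in 1:2) {
          pn <- c("rho", "alpha")[pi]
          iv <- bt$intervals[bt$intervals$parameter == pn, ]
          covered[d, pi, ] <- truths[d, pi] >= iv$lower &
            truths[d, pi] <= iv$upper
        }
      }
    }
  }
  ok <- keep & !is.na(est[, 1])
  err <- est[ok, , drop = FALSE] - truths[ok, , drop = FALSE]
  bias <- colMeans(err)
  mse <- colMeans(err^2)
  names(bias) <- names(mse) <- c("rho", "alpha")
  coverage <- NULL
  if (!is.null(bootstrap)) {
    coverage <- do.call(rbind, lapply(seq_along(bootstrap$levels),
      function(li) data.frame(
        level = bootstrap$levels[li],
        coverage_rho = mean(covered[ok, 1, li], na.rm = TRUE),
        coverage_alpha = mean(covered[ok, 2, li], na.rm = TRUE))))
  }
  structure(list(
    estimates = data.frame(truth_rho = truths[, 1], truth_alpha = truths[, 2],
                           est_rho = est[, 1], est_alpha = est[, 2],
                           kept = keep, reason = reasons),
    bias = bias, mse = mse, coverage = coverage,
    filter_diagnostics = table(reasons),
    n_failed = n_failed, scenario = scenario, truth = truth,
    config = config),
    class = "handtrans_eval")
}

#' @export
print.handtrans_eval <- function(x, ...) {
  cat(sprintf("Estimator evaluation (scenario %s, %s truth, %d datasets, seed %d)\n",
              x$scenario, x$truth, x$config$n_datasets, x$config$seed))
  cat(sprintf("  shift model: %s [%g, %g]\n", x$config$shift,
              x$config$shift_lo, x$config$shift_hi))
  cat(sprintf("  bias:  rho %+.4f  alpha %+.4f\n",
              x$bias["rho"], x$bias["alpha"]))
  cat(sprintf("  MSE:   rho %.5f  alpha %.5f\n",
              x$mse["rho"], x$mse["alpha"]))
  if (!is.null(x$coverage)) {
    cat("  coverage:\n")
    print(x$coverage, row.names = FALSE, digits = 3)
  }
  cat("  filter diagnostics:\n")
  print(x$filter_diagnostics)
  if (x$n_failed > 0) cat(sprintf("  %d fit(s) failed\n", x$n_failed))
  invisible(x)
}

#' Simulate a sex-stratified familial dataset
#'
#' Draws offspring counts for the four ordered mother-by-father matings and
#' both offspring sexes from the extended transmission table. Couples per
#' mating are given by `pairs`; each couple contributes
#' `offspring_per_pair` offspring whose sex is equally likely and whose
#' phenotype is binomial with the table's sex- and mating-specific
#' right-probability. No criterion shift is applied: the design emulates a
#' single-study table with known mating structure.
#'
#' @param params Generating [extended_params()].
#' @param pairs Couples per mating, ordered `(RmRf, RmLf, LmRf, LmLf)`.
#' @param offspring_per_pair Offspring per couple (default 3).
#' @param seed Integer seed.
#' @param study_id Label for the generated study.
#' @return A `sex_data` frame (8 rows: 4 matings x 2 offspring sexes).
#' @export
simulate_sex_stratified <- function(params, pairs,
                                    offspring_per_pair = 3L, seed,
                                    study_id = "synth_sex") {
  stopifnot(inherits(params, "extended_params"), length(pairs) == 4,
            all(pairs >= 0), sum(pairs) > 0)
  set.seed(seed)
  tab <- extended_transmission_table(params)
  mat_lev <- c("rmrf", "rmlf", "lmrf", "lmlf")
  rows <- list()
  for (i in 1:4) {
    n_off <- pairs[i] * offspring_per_pair
    n_f <- stats::rbinom(1, n_off, 0.5)
    for (j in 1:2) {
      n <- if (j == 1) n_f else n_off - n_f
      p_r <- tab[(j - 1) * 4 + i, "R"]
      r <- stats::rbinom(1, n, p_r)
      rows[[length(rows) + 1]] <-
        data.frame(study_id = study_id, mating = mat_lev[i],
                   sex = c("f", "m")[j], n_r = r, n_l = n - r,
                   pairs = pairs[i])
    }
  }
  structure(do.call(rbind, rows), class = c("sex_data", "data.frame"))
}
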