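.base_npar <- c(two = 2L, three = 3L)

# Draw one feasible random start for a base model
.random_start_base <- function(model) {
  rho <- stats::runif(1, 0, 0.5)
  alpha <- stats::runif(1, 0, 0.5 - rho)
  if (model == "two") c(rho, alpha)
  else c(rho, alpha, stats::runif(1, -0.2, min(0.2, 0.5 - rho)))
}

.random_start_ext <- function(model_id) {
  rho <- stats::runif(1, 0, 0.45)
  amax <- 0.5 - rho
  ab <- function() stats::runif(1, -0.15, min(0.15, amax))
  switch(model_id,
    I   = c(rho, stats::runif(1, 0, amax)),
    II  = c(rho, stats::runif(1, 0, amax), ab()),
    III = c(rho, stats::runif(1, 0, amax), ab(), ab()),
    IV  = c(rho, stats::runif(1, 0, amax), stats::runif(1, 0, amax),
            ab(), ab()),
    V   = c(rho, stats::runif(1, 0, amax), stats::runif(1, 0, amax),
            ab(), ab(), ab(), ab()))
}

# clean tiny constraint violations left by the simplex
.snap_base <- function(theta) {
  theta[1:2] <- pmax(theta[1:2], 0)
  if (theta[1] + theta[2] > 0.5) {
    theta[2] <- 0.5 - theta[1]
  }
  theta
}

#' Maximum-likelihood estimation of transmission parameters
#'
#' Multi-start Nelder-Mead maximization of the support function selected by
#' the analysis scenario. Scenarios `A` and `B` maximize the unadjusted
#' support `S_T` (they differ only in how goodness-of-fit is tested later);
#' scenario `C` maximizes the criterion-shift-adjusted support `S_M` (or the
#' adjusted extended support for sex-stratified data). Starts are drawn
#' uniformly from the feasible region under the given seed; infeasible
#' proposals inside the simplex receive a large negative sentinel.
#'
#' @param studies A `familial_data` frame (models `"two"`/`"three"`) or a
#'   `sex_data` frame (models `"I"` to `"V"`).
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param model `"two"` (`beta` fixed at 0), `"three"`, or an extended model
#'   id `"I"`-`"V"`.
#' @param n_starts Number of random starts (default 1000).
#' @param seed Integer seed for the start draws (required when
#'   `n_starts > length(starts)` supplied).
#' @param starts Optional list of explicit start vectors used before any
#'   random starts.
#' @param incidence_mode Optional override of the parental-incidence mode.
#' @param control Passed to [stats::optim()]; defaults to a tight simplex
#'   (`reltol = 1e-10`, `maxit = 5000`).
#' @return An object of class `handtrans_fit`: the fitted parameter object,
#'   `loglik`, `scenario`, `model`, `n_starts`, `best_start_index`,
#'   `converged`, `seed` and the implied true incidence `t`.
#' @export
fit_mle <- function(studies, scenario = c("B", "A", "C"),
                    model = c("two", "three", "I", "II", "III", "IV", "V"),
                    n_starts = 1000L, seed = NULL, starts = NULL,
                    incidence_mode = NULL,
                    control = list(reltol = 1e-10, maxit = 5000L)) {
  scenario <- match.arg(scenario)
  model <- match.arg(model)
  extended <- model %in% c("I", "II", "III", "IV", "V")
  if (extended) {
    stopifnot(inherits(studies, "sex_data"))
    summ <- .sex_summary(studies)
    obj <- function(theta) {
      -.loglik_ext_fast(theta, model, summ, adjusted = scenario == "C")
    }
    rand <- function() .random_start_ext(model)
    npar <- .model_npar[[model]]
  } else {
    stopifnot(inherits(studies, "familial_data"))
    summ <- .familial_summary(studies, incidence_mode)
    agg <- colSums(summ$counts)
    obj <- if (scenario == "C") {
      function(theta) -.loglik_M_fast(theta, summ)
    } else {
      function(theta) -.loglik_T_fast(theta, agg)
    }
    rand <- function() .random_start_base(model)
    npar <- .base_npar[[model]]
  }
  if (!is.null(seed)) set.seed(seed)
  n_explicit <- length(starts)
  n_starts <- max(as.integer(n_starts), n_explicit)
  best <- NULL; best_val <- Inf; best_idx <- NA_integer_; conv <- FALSE
  for (i in seq_len(n_starts)) {
    s0 <- if (i <= n_explicit) starts[[i]] else rand()
    if (length(s0) != npar) {
      stop(sprintf("start %d has length %d, expected %d", i, length(s0),
                   npar), call. = FALSE)
    }
    fit <- stats::optim(s0, obj, method = "Nelder-Mead", control = control)
    if (fit$value < best_val && fit$value < -.LL_SENTINEL / 2) {
      best_val <- fit$value; best <- fit$par; best_idx <- i
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    stop("all starts landed in the infeasible region", call. = FALSE)
  }
  if (extended) {
    pl <- .extended_from_free(best, model)
    pl$rho <- max(pl$rho, 0)
    params <- extended_params(pl$rho, pl$alpha_f, pl$alpha_m, pl$beta_f,
                              pl$beta_m, pl$gamma_f, pl$gamma_m,
                              model_id = model)
    eq <- extended_equilibrium(params)
    t_hat <- eq$f_dl
  } else {
    best <- .snap_base(best)
    params <- base_params(best[1], best[2],
                          if (model == "three") best[3] else 0)
    t_hat <- equilibrium(params)$f_dl
  }
  structure(list(params = params, scenario = scenario, model = model,
                 loglik = -best_val, n_starts = n_starts,
                 best_start_index = best_idx, converged = conv,
                 seed = seed, t = t_hat,
                 incidence_mode = if (extended) NA_character_ else
                   summ$incidence_mode,
                 m_p_fallback = if (extended) character(0) else
                   summ$m_p_fallback,
                 n_studies = if (extended) length(summ) else
                   nrow(summ$counts)),
            class = "handtrans_fit")
}

#' @export
print.handtrans_fit <- function(x, ...) {
  cat(sprintf("Transmission-model fit (scenario %s, model %s)\n",
              x$scenario, x$model))
  print(x$params)
  cat(sprintf("  support = %.3f   true incidence t = %.4f\n",
              x$loglik, x$t))
  cat(sprintf("  %d start(s), best start %d, converged: %s",
              x$n_starts, x$best_start_index, x$converged))
  if (!is.null(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat("\n")
  if (length(x$m_p_fallback)) {
    cat("  m_p triplet fallback used for:",
        paste(x$m_p_fallback, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Grid-search validation of the likelihood surface
#'
#' Exhaustively evaluates the scenario's support function over a regular
#' grid on the feasible box (`rho` and `alpha` in `[0, 0.5]`, `beta` in
#' `[-0.25, 0.25]` for the three-parameter model; points violating
#' `rho + alpha <= 1/2` are infeasible) and returns the best grid point
#' together with the full surface for plotting.
#'
#' @param studies A `familial_data` frame.
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param model `"two"` or `"three"`.
#' @param n_points Grid resolution per parameter (>= 2).
#' @param incidence_mode Optional override of the parental-incidence mode.
#' @return A list with `best` (named parameter vector), `loglik`, and
#'   `surface` (a data frame of grid points and support values; infeasible
#'   points carry `-Inf`).
#' @export
grid_search <- function(studies, scenario = c("B", "A", "C"),
                        model = c("two", "three"), n_points = 200L,
                        incidence_mode = NULL) {
  scenario <- match.arg(scenario)
  model <- match.arg(model)
  stopifnot(n_points >= 2)
  summ <- .familial_summary(studies, incidence_mode)
  agg <- colSums(summ$counts)
  rho <- seq(0, 0.5, length.out = n_points)
  alpha <- seq(0, 0.5, length.out = n_points)
  if (model == "two") {
    grid <- expand.grid(rho = rho, alpha = alpha)
  } else {
    grid <- expand.grid(rho = rho, alpha = alpha,
                        beta = seq(-0.25, 0.25, length.out = n_points))
  }
  if (scenario %in% c("A", "B") && model == "two") {
    # closed-form vectorized evaluation over the whole grid
    p1 <- 0.5 + grid$rho + grid$alpha
    p3 <- 0.5 + grid$rho - grid$alpha
    p2 <- 0.5 + grid$rho
    feas <- p1 <= 1 & p3 >= 0
    ll <- rep(-Inf, nrow(grid))
    safe_log <- function(p) ifelse(p > 0, log(p), -Inf)
    ll[feas] <- agg[1] * safe_log(p1[feas]) + agg[2] * safe_log(1 - p1[feas]) +
      agg[3] * safe_log(p2[feas]) + agg[4] * safe_log(1 - p2[feas]) +
      agg[5] * safe_log(p3[feas]) + agg[6] * safe_log(1 - p3[feas])
    ll[is.nan(ll)] <- -Inf
  } else {
    f <- if (scenario == "C") {
      function(theta) .loglik_M_fast(theta, summ)
    } else {
      function(theta) .loglik_T_fast(theta, agg)
    }
    ll <- vapply(seq_len(nrow(grid)),
                 function(i) f(as.numeric(grid[i, ])), numeric(1))
    ll[ll <= .LL_SENTINEL / 2] <- -Inf
  }
  grid$loglik <- ll
  best_i <- which.max(ll)
  best <- as.numeric(grid[best_i, seq_len(ncol(grid) - 1)])
  names(best) <- names(grid)[seq_len(ncol(grid) - 1)]
  list(best = best, loglik = ll[best_i], surface = grid)
}

#' Non-parametric bootstrap confidence intervals
#'
#' Resamples offspring outcomes with replacement within each study-by-mating
#' cell (cell totals fixed; equivalently, each cell's left count is redrawn
#' binomially at its observed proportion), recomputes the measured offspring
#' incidences (and, when triplet-derived, the parental incidences), refits
#' the model, and returns percentile intervals.
#'
#' Refits start from the original point estimate; under scenario `C` three
#' additional random restarts are used per resample by default, because the
#' criterion-shift adjustment curves the support surface and single-start
#' refits can stall on local optima there.
#'
#' @param studies A `familial_data` frame.
#' @param scenario,model As in [fit_mle()].
#' @param n_boot Number of bootstrap resamples (>= 2; the headline analyses
#'   use 200).
#' @param levels Confidence levels for the percentile intervals.
#' @param seed Integer seed.
#' @param fit Optional previously computed [fit_mle()] result for these
#'   data (avoids refitting the original sample).
#' @param refit_starts Starts per bootstrap refit (default 1 for scenarios
#'   A and B, 4 for scenario C; the first start is always the point
#'   estimate).
#' @param n_starts Starts for the initial fit when `fit` is missing.
#' @param incidence_mode Optional override of the parental-incidence mode.
#' @return An object of class `handtrans_boot` with the point `estimate`,
#'   the bootstrap `samples` matrix, percentile `intervals` (one row per
#'   parameter and level), the failure count, and the seed.
#' @export
bootstrap_ci <- function(studies, scenario = c("B", "A", "C"),
                         model = c("two", "three"), n_boot = 200L,
                         levels = c(0.8, 0.9, 0.95), seed = NULL,
                         fit = NULL, refit_starts = NULL, n_starts = 50L,
                         incidence_mode = NULL) {
  scenario <- match.arg(scenario)
  model <- match.arg(model)
  if (is.null(refit_starts)) {
    refit_starts <- if (scenario == "C") 4L else 1L
  }
  stopifnot(n_boot >= 2, all(levels > 0 & levels < 1))
  if (is.null(fit)) {
    fit <- fit_mle(studies, scenario, model, n_starts = n_starts,
                   seed = if (is.null(seed)) NULL else seed + 1L,
                   incidence_mode = incidence_mode)
  }
  summ <- .familial_summary(studies, incidence_mode)
  est <- c(rho = fit$params$rho, alpha = fit$params$alpha)
  if (model == "three") est <- c(est, beta = fit$params$beta)
  if (!is.null(seed)) set.seed(seed)
  counts <- summ$counts
  n_cell <- counts[, c(1, 3, 5)] + counts[, c(2, 4, 6)]
  phat <- ifelse(n_cell > 0, counts[, c(2, 4, 6)] / n_cell, 0)
  triplet_mp <- summ$incidence_mode == "triplets"
  samples <- matrix(NA_real_, n_boot, length(est),
                    dimnames = list(NULL, names(est)))
  control <- list(reltol = 1e-10, maxit = 5000L)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    l_star <- matrix(stats::rbinom(length(n_cell), as.vector(n_cell),
                                   as.vector(phat)),
                     nrow = nrow(counts))
    boot_counts <- counts
    boot_counts[, c(2, 4, 6)] <- l_star
    boot_counts[, c(1, 3, 5)] <- n_cell - l_star
    bsumm <- summ
    bsumm$counts <- boot_counts
    bsumm$m_o <- rowSums(boot_counts[, c(2, 4, 6), drop = FALSE]) /
      rowSums(boot_counts)
    # triplet-derived m_p depends only on the fixed cell totals, so it is
    # unchanged under within-cell resampling; recomputed for transparency
    if (triplet_mp) bsumm$m_p <- summ$m_p
    agg <- colSums(boot_counts)
    obj <- if (scenario == "C") {
      function(theta) -.loglik_M_fast(theta, bsumm)
    } else {
      function(theta) -.loglik_T_fast(theta, agg)
    }
    best_val <- Inf; best_par <- NULL
    for (r in seq_len(max(1L, refit_starts))) {
      s0 <- if (r == 1L) as.numeric(est) else .random_start_base(model)
      o <- stats::optim(s0, obj, method = "Nelder-Mead", control = control)
      if (o$value < best_val && o$value < -.LL_SENTINEL / 2) {
        best_val <- o$value; best_par <- o$par
      }
    }
    if (is.null(best_par)) n_failed <- n_failed + 1L
    else samples[b, ] <- .snap_base(best_par)[seq_along(est)]
  }
  if (n_failed > n_boot / 2) {
    stop("more than half of the bootstrap refits failed", call. = FALSE)
  }
  ok <- stats::complete.cases(samples)
  intervals <- do.call(rbind, lapply(names(est), function(pn) {
    do.call(rbind, lapply(levels, function(lv) {
      qs <- stats::quantile(samples[ok, pn], c((1 - lv) / 2, 1 - (1 - lv) / 2),
                            names = FALSE)
      data.frame(parameter = pn, level = lv, lower = qs[1], upper = qs[2])
    }))
  }))
  structure(list(estimate = est, samples = samples, intervals = intervals,
                 n_boot = n_boot, n_failed = n_failed, levels = levels,
                 scenario = scenario, model = model, seed = seed),
            class = "handtrans_boot")
}

#' @export
print.handtrans_boot <- function(x, ...) {
  cat(sprintf("Bootstrap CIs (scenario %s, model %s, %d resamples, %d failed",
              x$scenario, x$model, x$n_boot, x$n_failed))
  if (!is.null(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat(")\n")
  cat("Point estimate:\n")
  print(round(x$estimate, 4))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}
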