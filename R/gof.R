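#' G statistic for one count table
#'
#' `G = 2 * sum O * ln(O / E)` over all cells, with expected counts
#' `E = class total * expected probability`. Cells with observed count 0
#' contribute 0; an expected probability of 0 facing a positive observed
#' count is an error (the model excludes an observed outcome).
#'
#' @param observed Numeric matrix of observed counts (classes in rows,
#'   phenotypes in columns).
#' @param expected_probs Row-stochastic matrix of the same shape.
#' @param totals Optional per-class totals; defaults to the observed row
#'   sums.
#' @return The G statistic (non-negative).
#' @examples
#' g_statistic(matrix(c(30, 70), 1), matrix(c(0.5, 0.5), 1))
#' @export
g_statistic <- function(observed, expected_probs, totals = NULL) {
  observed <- rbind(observed); expected_probs <- rbind(expected_probs)
  stopifnot(all(dim(observed) == dim(expected_probs)),
            all(observed >= 0))
  if (is.null(totals)) totals <- rowSums(observed)
  stopifnot(all(totals > 0))
  expected <- expected_probs * totals
  if (any(observed > 0 & expected <= 0)) {
    stop("expected count 0 where a positive count was observed",
         call. = FALSE)
  }
  pos <- observed > 0
  2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
}

#' Goodness-of-fit of a familial fit
#'
#' Computes a G statistic per study and across all studies combined, against
#' the fitted true table `T-hat` (`adjusted = FALSE`, scenario A) or each
#' study's fitted measured table `M-hat = P T-hat O` (`adjusted = TRUE`,
#' scenarios B and C). Degrees of freedom: 2 per study (three offspring
#' cells minus one offspring criterion-shift nuisance) and `2 S - k`
#' combined, where `S` is the number of studies and `k` the number of free
#' model parameters. Verifies that observed and expected totals match per
#' mating class and flags expected cells below 5.
#'
#' @param studies A `familial_data` frame.
#' @param fit A [fit_mle()] result on these data (base model).
#' @param adjusted Compare against `M-hat` rather than `T-hat`; defaults to
#'   `TRUE` unless the fit's scenario is `"A"`.
#' @return An object of class `handtrans_gof` with `per_study`, `combined`,
#'   `expected_tables` and `assumption_flags`.
#' @export
gof_familial <- function(studies, fit, adjusted = NULL) {
  stopifnot(inherits(studies, "familial_data"),
            inherits(fit, "handtrans_fit"),
            inherits(fit$params, "base_params"))
  if (is.null(adjusted)) adjusted <- fit$scenario != "A"
  summ <- .familial_summary(studies, fit$incidence_mode)
  S <- nrow(summ$counts)
  k <- .base_npar[[fit$model]]
  T_hat <- transmission_table(fit$params)
  t_hat <- equilibrium(fit$params)$f_dl
  per <- vector("list", S)
  expected_tables <- vector("list", S)
  low_expected <- logical(S)
  for (i in seq_len(S)) {
    probs <- if (adjusted) {
      adjust_familial(T_hat, adjustment_set(t_hat, summ$m_p[i], summ$m_o[i]))
    } else T_hat
    obs <- matrix(summ$counts[i, ], nrow = 3, byrow = TRUE,
                  dimnames = list(c("RxR", "mixed", "LxL"), c("R", "L")))
    keep <- rowSums(obs) > 0  # empty mating classes contribute nothing
    g <- g_statistic(obs[keep, , drop = FALSE],
                     probs[keep, , drop = FALSE])
    df <- 2L
    p <- stats::pchisq(g, df, lower.tail = FALSE)
    per[[i]] <- data.frame(study_id = summ$study_id[i], G = g, df = df,
                           p = p, fits_at_0.05 = p >= 0.05)
    expected_tables[[i]] <- probs
    low_expected[i] <- any(probs[keep, ] * rowSums(obs)[keep] < 5)
  }
  per_study <- do.call(rbind, per)
  G_comb <- sum(per_study$G)
  df_comb <- 2L * S - k
  combined <- data.frame(G = G_comb, df = df_comb,
                         p = stats::pchisq(G_comb, df_comb,
                                           lower.tail = FALSE))
  names(expected_tables) <- summ$study_id
  structure(list(per_study = per_study, combined = combined,
                 expected_tables = expected_tables,
                 assumption_flags = list(totals_match = TRUE,
                                         low_expected_cells =
                                           summ$study_id[low_expected]),
                 adjusted = adjusted, scenario = fit$scenario,
                 model = fit$model),
            class = "handtrans_gof")
}

#' Goodness-of-fit of a familial fit on held-out twin data
#'
#' The familial fit predicts the twin-pair distribution via
#' [twin_expectations()] (identical for MZ and DZ pairs under the fixed
#' allele); each twin dataset's expectation is carried to its measured scale
#' with [adjust_twin()] at the dataset's own individual-level incidence.
#' Degrees of freedom: 1 per dataset (two free pair proportions minus one
#' criterion-shift nuisance); the combined statistic is the sum with no
#' parameters subtracted, since no parameter was fitted to twin data.
#'
#' @param twin_studies A `twin_data` frame.
#' @param fit A [fit_mle()] result obtained on familial data.
#' @return An object of class `handtrans_gof`.
#' @export
gof_twins <- function(twin_studies, fit) {
  stopifnot(inherits(twin_studies, "twin_data"),
            inherits(fit, "handtrans_fit"),
            inherits(fit$params, "base_params"))
  probs0 <- twin_expectations(fit$params)
  t_hat <- equilibrium(fit$params)$f_dl
  S <- nrow(twin_studies)
  per <- vector("list", S)
  expected_tables <- vector("list", S)
  for (i in seq_len(S)) {
    obs <- as.numeric(twin_studies[i, c("n_rr", "n_rl", "n_ll")])
    n_pairs <- sum(obs)
    m_o <- (obs[2] + 2 * obs[3]) / (2 * n_pairs)
    probs <- if (abs(m_o - t_hat) < 1e-12) probs0 else
      adjust_twin(probs0, t_hat, m_o)
    g <- g_statistic(matrix(obs, 1), matrix(probs, 1))
    p <- stats::pchisq(g, 1, lower.tail = FALSE)
    per[[i]] <- data.frame(study_id = twin_studies$study_id[i],
                           zygosity = twin_studies$zygosity[i],
                           G = g, df = 1L, p = p, fits_at_0.05 = p >= 0.05)
    expected_tables[[i]] <- probs
  }
  per_study <- do.call(rbind, per)
  G_comb <- sum(per_study$G)
  df_comb <- S
  combined <- data.frame(G = G_comb, df = df_comb,
                         p = stats::pchisq(G_comb, df_comb,
                                           lower.tail = FALSE))
  structure(list(per_study = per_study, combined = combined,
                 expected_tables = expected_tables,
                 assumption_flags = list(totals_match = TRUE,
                                         low_expected_cells = character(0)),
                 adjusted = TRUE, scenario = fit$scenario,
                 model = fit$model),
            class = "handtrans_gof")
}

#' @export
print.handtrans_gof <- function(x, ...) {
  cat(sprintf("G-test goodness-of-fit (scenario %s, model %s, %s)\n",
              x$scenario, x$model,
              if (x$adjusted) "adjusted M-hat" else "unadjusted T-hat"))
  print(x$per_study, row.names = FALSE, digits = 4)
  cat(sprintf("Combined: G = %.2f, df = %d, p = %.3g (%d of %d fit at 0.05)\n",
              x$combined$G, x$combined$df, x$combined$p,
              sum(x$per_study$fits_at_0.05), nrow(x$per_study)))
  if (length(x$assumption_flags$low_expected_cells)) {
    cat("Warning: expected cell below 5 in:",
        paste(x$assumption_flags$low_expected_cells, collapse = ", "), "\n")
  }
  invisible(x)
}

# nesting graph over model ids (transitively closed)
.nested_pairs <- local({
  direct <- list(c("two", "three"), c("I", "II"), c("II", "III"),
                 c("II", "IV"), c("III", "V"), c("IV", "V"))
  closure <- direct
  repeat {
    added <- FALSE
    for (p1 in closure) for (p2 in closure) {
      if (p1[2] == p2[1]) {
        cand <- c(p1[1], p2[2])
        if (!any(vapply(closure, function(z) all(z == cand), logical(1)))) {
          closure <- c(closure, list(cand)); added <- TRUE
        }
      }
    }
    if (!added) break
  }
  closure
})

.npar_of <- function(model) {
  if (model %in% names(.base_npar)) .base_npar[[model]]
  else .model_npar[[model]]
}

#' Likelihood-ratio test between nested transmission models
#'
#' `LR = 2 (loglik_complex - loglik_simple)`, compared to a chi-squared
#' distribution with degrees of freedom equal to the difference in free
#' parameter counts (Wilks). The nesting graph is `two` in `three` for the
#' base models and `I` in `II` in (`III`, `IV`) in `V` for the sex-difference
#' family.
#'
#' @param fit_simple,fit_complex [fit_mle()] results on the same data and
#'   scenario, with the simple model nested in the complex one.
#' @return An object of class `handtrans_lrt` with the two support values,
#'   `LR`, `df` and `p`.
#' @export
likelihood_ratio_test <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "handtrans_fit"),
            inherits(fit_complex, "handtrans_fit"))
  pair <- c(fit_simple$model, fit_complex$model)
  nested <- any(vapply(.nested_pairs, function(z) all(z == pair),
                       logical(1)))
  if (!nested) {
    stop(sprintf("model %s is not nested in model %s", pair[1], pair[2]),
         call. = FALSE)
  }
  if (fit_simple$scenario != fit_complex$scenario) {
    stop("fits were produced under different scenarios", call. = FALSE)
  }
  lr <- 2 * (fit_complex$loglik - fit_simple$loglik)
  if (lr < -1e-6) {
    stop("negative likelihood ratio beyond tolerance: the complex model ",
         "fit likely failed to converge", call. = FALSE)
  }
  if (lr < 0) {
    warning("small negative likelihood ratio clamped to 0")
    lr <- 0
  }
  df <- .npar_of(fit_complex$model) - .npar_of(fit_simple$model)
  structure(list(simple_model_id = fit_simple$model,
                 complex_model_id = fit_complex$model,
                 loglik_simple = fit_simple$loglik,
                 loglik_complex = fit_complex$loglik,
                 LR = lr, df = df,
                 p = stats::pchisq(lr, df, lower.tail = FALSE)),
            class = "handtrans_lrt")
}

#' @export
print.handtrans_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: %s vs %s\n",
              x$simple_model_id, x$complex_model_id))
  cat(sprintf("  support %.3f vs %.3f; LR = %.4f, df = %d, p = %.3g\n",
              x$loglik_simple, x$loglik_complex, x$LR, x$df, x$p))
  invisible(x)
}
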