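#' Transmission-model parameters
#'
#' Construct the parameter set of the base gene-culture transmission model
#' under fixation of the right-shift allele. `rho` is the genetic shift in the
#' probability of right-handedness shared by all individuals; `alpha` is the
#' cultural shift contributed by two same-handed parents (added for two
#' right-handers, subtracted for two left-handers); `beta` is the cultural
#' shift contributed by mixed-handed parents and may be negative.
#'
#' All six implied offspring probabilities (`1/2 + rho + alpha`,
#' `1/2 + rho + beta`, `1/2 + rho - alpha` and their complements) must lie in
#' `[0, 1]`; in particular `rho + alpha <= 1/2`.
#'
#' @param rho Genetic probability shift, `>= 0`.
#' @param alpha Same-handed-parents cultural shift, `>= 0`.
#' @param beta Mixed-handed-parents cultural shift (default 0, may be
#'   negative).
#' @return An object of class `base_params`.
#' @examples
#' base_params(0.277, 0.138)
#' @export
base_params <- function(rho, alpha, beta = 0) {
  p <- structure(list(rho = rho, alpha = alpha, beta = beta),
                 class = "base_params")
  msg <- .validate_base(rho, alpha, beta)
  if (!isTRUE(msg)) stop(msg, call. = FALSE)
  p
}

.validate_base <- function(rho, alpha, beta) {
  if (!is.numeric(rho) || !is.numeric(alpha) || !is.numeric(beta) ||
      anyNA(c(rho, alpha, beta))) {
    return("rho, alpha and beta must be finite numbers")
  }
  if (rho < 0) return("rho must be >= 0")
  if (alpha < 0) return("alpha must be >= 0")
  probs <- 0.5 + rho + c(alpha, beta, -alpha)
  if (any(probs < 0) || any(probs > 1)) {
    return(paste0("implied offspring probabilities outside [0, 1]; ",
                  "need rho + alpha <= 1/2 and -1/2 <= rho + beta <= 1/2"))
  }
  TRUE
}

#' Test feasibility of base parameters without erroring
#'
#' @param rho,alpha,beta Numeric parameter values.
#' @return `TRUE` if the implied transmission probabilities are valid.
#' @export
is_feasible_base <- function(rho, alpha, beta = 0) {
  isTRUE(.validate_base(rho, alpha, beta))
}

#' @export
print.base_params <- function(x, ...) {
  cat("Base transmission parameters\n")
  cat(sprintf("  rho = %.4f  alpha = %.4f  beta = %.4f\n",
              x$rho, x$alpha, x$beta))
  invisible(x)
}

#' Sex-difference transmission-model parameters
#'
#' Construct the extended parameter set in which the cultural effects differ
#' by offspring sex and by which parent is the left-hander. For offspring of
#' sex `i` (`F` or `M`): two right-handed parents shift the right-hand
#' probability by `+alpha_i`, a right-handed mother with a left-handed father
#' by `+beta_i`, a left-handed mother with a right-handed father by
#' `+gamma_i`, and two left-handed parents by `-alpha_i`. The genetic shift
#' `rho` is shared by both sexes.
#'
#' `model_id` records the constraint pattern:
#' \describe{
#'   \item{I}{`alpha_f = alpha_m`, all `beta = gamma = 0` (two-parameter
#'     model).}
#'   \item{II}{`alpha_f = alpha_m`, `beta_f = beta_m = gamma_f = gamma_m`
#'     (three-parameter model, no sex differences).}
#'   \item{III}{sex-equal within offspring (`alpha_f = alpha_m`,
#'     `beta_f = beta_m`, `gamma_f = gamma_m`) but `beta != gamma` allowed
#'     (parental sex differences).}
#'   \item{IV}{offspring-sex-specific `alpha_i` with `beta_i = gamma_i` per
#'     sex (offspring sex differences only).}
#'   \item{V}{unconstrained, seven parameters.}
#' }
#'
#' @param rho Genetic probability shift, `>= 0`.
#' @param alpha_f,alpha_m Same-handed-parents effects on daughters / sons.
#' @param beta_f,beta_m Right-mother-left-father effects on daughters / sons.
#' @param gamma_f,gamma_m Left-mother-right-father effects on daughters /
#'   sons.
#' @param model_id One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`; the
#'   constraint pattern must hold exactly.
#' @return An object of class `extended_params`.
#' @examples
#' extended_params(0.2, 0.1, 0.1, 0.02, 0.02, 0.02, 0.02, model_id = "II")
#' @export
extended_params <- function(rho, alpha_f, alpha_m, beta_f, beta_m,
                            gamma_f, gamma_m, model_id = "V") {
  model_id <- match.arg(model_id, c("I", "II", "III", "IV", "V"))
  p <- structure(list(rho = rho, alpha_f = alpha_f, alpha_m = alpha_m,
                      beta_f = beta_f, beta_m = beta_m,
                      gamma_f = gamma_f, gamma_m = gamma_m,
                      model_id = model_id),
                 class = "extended_params")
  msg <- .validate_extended(p)
  if (!isTRUE(msg)) stop(msg, call. = FALSE)
  p
}

.validate_extended <- function(p) {
  vals <- unlist(p[c("rho", "alpha_f", "alpha_m", "beta_f", "beta_m",
                     "gamma_f", "gamma_m")])
  if (!is.numeric(vals) || anyNA(vals)) {
    return("all parameters must be finite numbers")
  }
  if (p$rho < 0) return("rho must be >= 0")
  probs <- 0.5 + p$rho + c(p$alpha_f, p$beta_f, p$gamma_f, -p$alpha_f,
                           p$alpha_m, p$beta_m, p$gamma_m, -p$alpha_m)
  if (any(probs < 0) || any(probs > 1)) {
    return("implied offspring probabilities outside [0, 1]")
  }
  eq <- function(a, b) isTRUE(all.equal(a, b, tolerance = 1e-12))
  ok <- switch(p$model_id,
    I   = eq(p$alpha_f, p$alpha_m) && all(c(p$beta_f, p$beta_m,
                                            p$gamma_f, p$gamma_m) == 0),
    II  = eq(p$alpha_f, p$alpha_m) && eq(p$beta_f, p$beta_m) &&
          eq(p$beta_f, p$gamma_f) && eq(p$gamma_f, p$gamma_m),
    III = eq(p$alpha_f, p$alpha_m) && eq(p$beta_f, p$beta_m) &&
          eq(p$gamma_f, p$gamma_m),
    IV  = eq(p$beta_f, p$gamma_f) && eq(p$beta_m, p$gamma_m),
    V   = TRUE)
  if (!ok) return(sprintf("parameters violate the constraints of model %s",
                          p$model_id))
  TRUE
}

#' @export
print.extended_params <- function(x, ...) {
  cat(sprintf("Extended transmission parameters (model %s)\n", x$model_id))
  cat(sprintf("  rho = %.4f\n", x$rho))
  cat(sprintf("  alpha_f = %.4f  alpha_m = %.4f\n", x$alpha_f, x$alpha_m))
  cat(sprintf("  beta_f  = %.4f  beta_m  = %.4f\n", x$beta_f, x$beta_m))
  cat(sprintf("  gamma_f = %.4f  gamma_m = %.4f\n", x$gamma_f, x$gamma_m))
  invisible(x)
}

# number of free parameters per extended model id
.model_npar <- c(I = 2L, II = 3L, III = 4L, IV = 5L, V = 7L)

# expand a free-parameter vector into an extended_params list (unvalidated,
# for use inside optimizers where infeasible points get a sentinel)
.extended_from_free <- function(theta, model_id) {
  switch(model_id,
    I   = list(rho = theta[1], alpha_f = theta[2], alpha_m = theta[2],
               beta_f = 0, beta_m = 0, gamma_f = 0, gamma_m = 0),
    II  = list(rho = theta[1], alpha_f = theta[2], alpha_m = theta[2],
               beta_f = theta[3], beta_m = theta[3],
               gamma_f = theta[3], gamma_m = theta[3]),
    III = list(rho = theta[1], alpha_f = theta[2], alpha_m = theta[2],
               beta_f = theta[3], beta_m = theta[3],
               gamma_f = theta[4], gamma_m = theta[4]),
    IV  = list(rho = theta[1], alpha_f = theta[2], alpha_m = theta[3],
               beta_f = theta[4], beta_m = theta[5],
               gamma_f = theta[4], gamma_m = theta[5]),
    V   = list(rho = theta[1], alpha_f = theta[2], alpha_m = theta[3],
               beta_f = theta[4], beta_m = theta[5],
               gamma_f = theta[6], gamma_m = theta[7]))
}

.free_from_extended <- function(p) {
  switch(p$model_id,
    I   = c(rho = p$rho, alpha = p$alpha_f),
    II  = c(rho = p$rho, alpha = p$alpha_f, beta = p$beta_f),
    III = c(rho = p$rho, alpha = p$alpha_f, beta = p$beta_f,
            gamma = p$gamma_f),
    IV  = c(rho = p$rho, alpha_f = p$alpha_f, alpha_m = p$alpha_m,
            betagamma_f = p$beta_f, betagamma_m = p$beta_m),
    V   = c(rho = p$rho, alpha_f = p$alpha_f, alpha_m = p$alpha_m,
            beta_f = p$beta_f, beta_m = p$beta_m,
            gamma_f = p$gamma_f, gamma_m = p$gamma_m))
}
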