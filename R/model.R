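#' Transmission probability table of the base model
#'
#' Builds the row-stochastic table `T` of true offspring phenotype
#' probabilities given the parental mating class, under fixation of the
#' right-shift allele:
#' `P(R | RxR) = 1/2 + rho + alpha`, `P(R | mixed) = 1/2 + rho + beta`,
#' `P(R | LxL) = 1/2 + rho - alpha`, with the left column the complement.
#'
#' @param params A [base_params()] object.
#' @return A 3 x 2 matrix with rows `RxR`, `mixed`, `LxL` and columns `R`,
#'   `L`; rows sum to 1.
#' @examples
#' transmission_table(base_params(0.277, 0.138))
#' @export
transmission_table <- function(params) {
  stopifnot(inherits(params, "base_params"))
  pr <- 0.5 + params$rho + c(params$alpha, params$beta, -params$alpha)
  if (any(pr < 0) || any(pr > 1)) {
    stop("implied probability outside [0, 1]", call. = FALSE)
  }
  m <- cbind(R = pr, L = 1 - pr)
  rownames(m) <- c("RxR", "mixed", "LxL")
  m
}

#' One-generation recursion on the right-hander frequency
#'
#' Advances the population frequency of right-handers by one generation under
#' random mating: the three mating classes occur with Hardy-Weinberg-like
#' weights `F^2`, `2F(1-F)`, `(1-F)^2` and contribute offspring
#' right-probabilities `1/2 + rho + alpha`, `1/2 + rho + beta`,
#' `1/2 + rho - alpha`.
#'
#' @param f_dr Current right-hander frequency in `[0, 1]` (vectorized).
#' @param params A [base_params()] object.
#' @return Next-generation right-hander frequency.
#' @export
recursion_step <- function(f_dr, params) {
  stopifnot(inherits(params, "base_params"),
            all(f_dr >= 0 & f_dr <= 1))
  r <- params$rho; a <- params$alpha; b <- params$beta
  f_dr^2 * (0.5 + r + a) +
    2 * f_dr * (1 - f_dr) * (0.5 + r + b) +
    (1 - f_dr)^2 * (0.5 + r - a)
}

#' Equilibrium phenotype frequencies of the base model
#'
#' Solves the fixed point of [recursion_step()]. With `beta = 0` the closed
#' form is `f_dr = (1/2 + rho - alpha) / (1 - 2 alpha)`; with `beta != 0` the
#' fixed point is the root in `[0, 1]` of
#' `-2 beta F^2 + (2 alpha + 2 beta - 1) F + (1/2 + rho - alpha) = 0`,
#' taken as the root continuous in `beta` at 0 (evaluated in a numerically
#' stable form). `method = "fixed_point"` instead iterates the recursion to a
#' residual below `tol`.
#'
#' @param params A [base_params()] object.
#' @param method `"closed_form"` (default) or `"fixed_point"`.
#' @param tol Convergence tolerance for the fixed-point iteration.
#' @param max_iter Iteration cap for the fixed-point iteration.
#' @return A list of class `equilibrium_result` with elements `f_dr`, `f_dl`
#'   (the true incidence of left-handers) and `method`.
#' @examples
#' equilibrium(base_params(0.277, 0.138))$f_dl
#' @export
equilibrium <- function(params, method = c("closed_form", "fixed_point"),
                        tol = 1e-12, max_iter = 100000L) {
  stopifnot(inherits(params, "base_params"))
  method <- match.arg(method)
  if (method == "closed_form") {
    f <- .equilibrium_fdr(params$rho, params$alpha, params$beta)
    if (is.na(f)) {
      stop("no equilibrium in [0, 1] for these parameters", call. = FALSE)
    }
  } else {
    f <- 0.5
    for (i in seq_len(max_iter)) {
      f_new <- recursion_step(f, params)
      if (abs(f_new - f) < tol) { f <- f_new; break }
      f <- f_new
    }
  }
  structure(list(f_dr = f, f_dl = 1 - f, method = method),
            class = "equilibrium_result")
}

# scalar/vectorized equilibrium right-hander frequency; NA when no root in
# [0, 1]. Stable quadratic root: the one continuous in beta at beta = 0.
.equilibrium_fdr <- function(rho, alpha, beta = 0) {
  n <- max(length(rho), length(alpha), length(beta))
  rho <- rep_len(rho, n); alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  c0 <- 0.5 + rho - alpha
  b0 <- 2 * alpha + 2 * beta - 1
  a0 <- -2 * beta
  out <- rep(NA_real_, n)
  zb <- beta == 0
  # beta == 0: linear equation b0 F + c0 = 0
  out[zb] <- c0[zb] / (1 - 2 * alpha[zb])
  if (any(!zb)) {
    disc <- b0^2 - 4 * a0 * c0
    ok <- !zb & disc >= 0
    # root = 2 c0 / (sqrt(disc) - b0): continuous as beta -> 0 since b0 < 0
    out[ok] <- 2 * c0[ok] / (sqrt(disc[ok]) - b0[ok])
  }
  out[!is.na(out) & (out < 0 | out > 1)] <- NA_real_
  out
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium (%s): f_DR = %.6f, f_DL = %.6f\n",
              x$method, x$f_dr, x$f_dl))
  invisible(x)
}

#' Transmission probability table of the sex-difference model
#'
#' Builds the row-stochastic table of true offspring phenotype probabilities
#' for the four ordered parental matings (mother x father) and the two
#' offspring sexes. For offspring of sex `i`:
#' `P(R | RmRf, i) = 1/2 + rho + alpha_i`,
#' `P(R | RmLf, i) = 1/2 + rho + beta_i`,
#' `P(R | LmRf, i) = 1/2 + rho + gamma_i`,
#' `P(R | LmLf, i) = 1/2 + rho - alpha_i`.
#'
#' @param params An [extended_params()] object.
#' @return An 8 x 2 matrix with rows `RmRf.F`, `RmLf.F`, `LmRf.F`, `LmLf.F`,
#'   `RmRf.M`, ..., columns `R`, `L`.
#' @export
extended_transmission_table <- function(params) {
  stopifnot(inherits(params, "extended_params"))
  r <- params$rho
  pr <- 0.5 + r + c(params$alpha_f, params$beta_f, params$gamma_f,
                    -params$alpha_f,
                    params$alpha_m, params$beta_m, params$gamma_m,
                    -params$alpha_m)
  if (any(pr < 0) || any(pr > 1)) {
    stop("implied probability outside [0, 1]", call. = FALSE)
  }
  m <- cbind(R = pr, L = 1 - pr)
  rownames(m) <- paste(rep(c("RmRf", "RmLf", "LmRf", "LmLf"), 2),
                       rep(c("F", "M"), each = 4), sep = ".")
  m
}

#' Equilibrium of the sex-difference model
#'
#' Damped fixed-point iteration on the pair of right-hander frequencies
#' (females, males) assuming a 1:1 sex ratio and random mating between the
#' phenotype distributions of mothers (females) and fathers (males). The true
#' incidence of left-handers `t` is one minus the mean of the two equilibrium
#' right-hander frequencies.
#'
#' @param params An [extended_params()] object.
#' @param tol Residual tolerance (default `1e-12`, well below the `1e-10`
#'   contract).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param damping Step damping in `(0, 1]`.
#' @return A list of class `equilibrium_result` with `f_dr` (mean across
#'   sexes), `f_dl`, `f_dr_f`, `f_dr_m` and `method = "fixed_point"`.
#' @export
extended_equilibrium <- function(params, tol = 1e-12, max_iter = 100000L,
                                 damping = 1) {
  stopifnot(inherits(params, "extended_params"))
  tab <- extended_transmission_table(params)
  pF <- tab[1:4, "R"]; pM <- tab[5:8, "R"]
  ff <- fm <- 0.5
  for (i in seq_len(max_iter)) {
    # mating distribution over (RmRf, RmLf, LmRf, LmLf): mother phenotype
    # from the female frequency, father from the male frequency
    w <- c(ff * fm, ff * (1 - fm), (1 - ff) * fm, (1 - ff) * (1 - fm))
    ff_new <- ff + damping * (sum(w * pF) - ff)
    fm_new <- fm + damping * (sum(w * pM) - fm)
    if (abs(ff_new - ff) < tol && abs(fm_new - fm) < tol) {
      ff <- ff_new; fm <- fm_new
      f <- (ff + fm) / 2
      return(structure(list(f_dr = f, f_dl = 1 - f,
                            f_dr_f = ff, f_dr_m = fm,
                            method = "fixed_point"),
                       class = "equilibrium_result"))
    }
    ff <- ff_new; fm <- fm_new
  }
  stop("extended equilibrium did not converge", call. = FALSE)
}

#' Expected twin-pair phenotype probabilities
#'
#' Under the fixed-allele model the two members of a twin pair are
#' conditionally independent given the parental mating class, so monozygotic
#' and dizygotic pairs have identical expected pair-phenotype distributions.
#' Parents mate at random at the equilibrium phenotype frequency `F`, giving
#' mating weights `(F^2, 2F(1-F), (1-F)^2)`; within a mating with offspring
#' right-probability `p` the unordered pair probabilities are
#' `(p^2, 2p(1-p), (1-p)^2)`, and the totals are the weighted sums.
#'
#' @param params A [base_params()] object.
#' @return Named numeric vector `c(RR, RL, LL)` summing to 1.
#' @examples
#' twin_expectations(base_params(0.277, 0.138))
#' @export
twin_expectations <- function(params) {
  stopifnot(inherits(params, "base_params"))
  eq <- equilibrium(params)
  f <- eq$f_dr
  w <- c(f^2, 2 * f * (1 - f), (1 - f)^2)
  p <- transmission_table(params)[, "R"]
  c(RR = sum(w * p^2),
    RL = sum(w * 2 * p * (1 - p)),
    LL = sum(w * (1 - p)^2))
}
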