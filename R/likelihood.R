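# Large negative sentinel standing in for -Inf so the simplex can recover
# from infeasible proposals (soft constraint handling).
.LL_SENTINEL <- -1e10

# Collapse a familial_data frame into the fixed arrays the likelihoods need:
# a count matrix and the per-study measured incidences. m_p honours the
# frame's incidence mode; in "reported" mode studies without a reported m_p
# fall back to the triplet-derived value (fallback ids are recorded).
.familial_summary <- function(fam, incidence_mode = NULL) {
  stopifnot(inherits(fam, "familial_data"))
  if (is.null(incidence_mode)) {
    incidence_mode <- attr(fam, "incidence_mode")
    if (is.null(incidence_mode)) incidence_mode <- "reported"
  }
  cols <- c("rxr_r", "rxr_l", "mix_r", "mix_l", "lxl_r", "lxl_l")
  counts <- as.matrix(as.data.frame(fam)[, cols])
  storage.mode(counts) <- "double"
  pairs <- as.matrix(as.data.frame(fam)[, c("pairs_rxr", "pairs_mix",
                                            "pairs_lxl")])
  m_p_trip <- (pairs[, 2] + 2 * pairs[, 3]) / (2 * rowSums(pairs))
  fallback <- character(0)
  if (incidence_mode == "reported") {
    m_p <- fam$m_p
    miss <- is.na(m_p)
    if (any(miss)) {
      m_p[miss] <- m_p_trip[miss]
      fallback <- as.character(fam$study_id[miss])
    }
  } else {
    m_p <- m_p_trip
  }
  m_o <- rowSums(counts[, c(2, 4, 6), drop = FALSE]) / rowSums(counts)
  if (any(m_p <= 0 | m_p >= 1)) {
    stop("parental incidence degenerate (0 or 1) in study '",
         fam$study_id[which(m_p <= 0 | m_p >= 1)[1]], "'", call. = FALSE)
  }
  list(counts = counts, m_p = as.numeric(m_p), m_o = as.numeric(m_o),
       incidence_mode = incidence_mode, m_p_fallback = fallback,
       study_id = as.character(fam$study_id))
}

# sum of count * log(prob) with 0 * log(0) = 0; NA if a positive count meets
# a non-positive probability
.xlogp <- function(counts, probs) {
  bad <- counts > 0 & probs <= 0
  if (any(bad)) return(NA_real_)
  pos <- counts > 0
  sum(counts[pos] * log(probs[pos]))
}

# unadjusted support from aggregated counts (theta = c(rho, alpha, beta))
.loglik_T_fast <- function(theta, agg) {
  rho <- theta[1]; alpha <- theta[2]
  beta <- if (length(theta) > 2) theta[3] else 0
  if (rho < 0 || alpha < 0) return(.LL_SENTINEL)
  p <- 0.5 + rho + c(alpha, beta, -alpha)
  if (any(p < 0) || any(p > 1)) return(.LL_SENTINEL)
  probs <- c(p[1], 1 - p[1], p[2], 1 - p[2], p[3], 1 - p[3])
  ll <- .xlogp(agg, probs)
  if (is.na(ll)) .LL_SENTINEL else ll
}

# adjusted support, vectorized over studies; summ from .familial_summary
.loglik_M_fast <- function(theta, summ) {
  rho <- theta[1]; alpha <- theta[2]
  beta <- if (length(theta) > 2) theta[3] else 0
  if (rho < 0 || alpha < 0) return(.LL_SENTINEL)
  p <- 0.5 + rho + c(alpha, beta, -alpha)
  if (any(p < 0) || any(p > 1)) return(.LL_SENTINEL)
  f <- .equilibrium_fdr(rho, alpha, beta)
  if (is.na(f)) return(.LL_SENTINEL)
  t <- 1 - f
  if (t <= 0 || t >= 1) return(.LL_SENTINEL)
  m_p <- summ$m_p; m_o <- summ$m_o
  u <- ifelse(m_p > t, (m_p - t) / m_p, 0)
  v <- ifelse(m_p < t, (t - m_p) / (1 - m_p), 0)
  w <- ifelse(m_o > t, (m_o - t) / (1 - t), 0)
  x <- ifelse(m_o < t, (t - m_o) / t, 0)
  # measured right-probability of each true mating, per study
  q1 <- p[1] * (1 - w) + (1 - p[1]) * x
  q2 <- p[2] * (1 - w) + (1 - p[2]) * x
  q3 <- p[3] * (1 - w) + (1 - p[3]) * x
  # rows of M = P T O, per study (one of u, v is zero per study)
  m1 <- (1 - v)^2 * q1 + 2 * v * (1 - v) * q2 + v^2 * q3
  m2 <- (1 - v) * u * q1 + ((1 - v) * (1 - u) + v * u) * q2 +
    v * (1 - u) * q3
  m3 <- u^2 * q1 + 2 * u * (1 - u) * q2 + (1 - u)^2 * q3
  probs <- cbind(m1, 1 - m1, m2, 1 - m2, m3, 1 - m3)
  ll <- .xlogp(summ$counts, probs)
  if (is.na(ll)) .LL_SENTINEL else ll
}

#' Unadjusted support function (S_T)
#'
#' Sum over studies and mating classes of the binomial log-likelihood of the
#' observed offspring counts under the true transmission table `T`. Binomial
#' coefficients are omitted (support-function convention): they do not
#' affect estimation, G statistics or likelihood ratios. If a cell
#' probability is zero where a positive count is observed, a large negative
#' sentinel is returned.
#'
#' @param params A [base_params()] object.
#' @param studies A `familial_data` frame.
#' @return The support value (natural log scale).
#' @export
loglik_T <- function(params, studies) {
  stopifnot(inherits(params, "base_params"))
  summ <- .familial_summary(studies)
  .loglik_T_fast(c(params$rho, params$alpha, params$beta),
                 colSums(summ$counts))
}

#' Criterion-shift-adjusted support function (S_M)
#'
#' As [loglik_T()] but each study's expected cell probabilities come from its
#' own measured table `M = P T O`: the equilibrium true incidence `t` is
#' recomputed from the parameters at every evaluation, and each study's
#' nuisance proportions are recomputed from `(t, m_p, m_o)`.
#'
#' @param params A [base_params()] object.
#' @param studies A `familial_data` frame.
#' @param incidence_mode Override of the frame's parental-incidence mode
#'   (`"reported"` or `"triplets"`).
#' @return The support value (natural log scale).
#' @export
loglik_M <- function(params, studies, incidence_mode = NULL) {
  stopifnot(inherits(params, "base_params"))
  summ <- .familial_summary(studies, incidence_mode)
  .loglik_M_fast(c(params$rho, params$alpha, params$beta), summ)
}

# Collapse a sex_data frame (possibly several studies) into count arrays and
# measured incidences. Counts: list per study of a 4 x 2 x 2 array
# [mating, sex, phenotype]; pooled parental m_p and per-sex m_o per study.
.sex_summary <- function(sx) {
  stopifnot(inherits(sx, "sex_data"))
  df <- as.data.frame(sx)
  mat_lev <- c("rmrf", "rmlf", "lmrf", "lmlf")
  sex_lev <- c("f", "m")
  ids <- unique(df$study_id)
  out <- lapply(ids, function(id) {
    d <- df[df$study_id == id, ]
    a <- array(0, dim = c(4, 2, 2),
               dimnames = list(mat_lev, sex_lev, c("R", "L")))
    i <- match(d$mating, mat_lev); j <- match(d$sex, sex_lev)
    for (k in seq_len(nrow(d))) {
      a[i[k], j[k], 1] <- a[i[k], j[k], 1] + d$n_r[k]
      a[i[k], j[k], 2] <- a[i[k], j[k], 2] + d$n_l[k]
    }
    if ("pairs" %in% names(d)) {
      pairs <- vapply(mat_lev, function(mm) {
        pp <- d$pairs[d$mating == mm]
        if (length(pp)) pp[1] else 0
      }, numeric(1))
    } else {
      pairs <- round(apply(a, 1, sum) / 3)
    }
    # one left-handed parent in rmlf and lmrf couples, two in lmlf
    m_p <- (pairs[2] + pairs[3] + 2 * pairs[4]) / (2 * sum(pairs))
    m_o <- apply(a[, , 2], 2, sum) / apply(a, 2, sum)
    list(study_id = id, counts = a, pairs = pairs, m_p = m_p, m_o = m_o)
  })
  out
}

# Extended support from free-parameter vector theta for a given model id.
# summ from .sex_summary; adjusted = TRUE applies the criterion-shift maps.
.loglik_ext_fast <- function(theta, model_id, summ, adjusted) {
  pl <- .extended_from_free(theta, model_id)
  if (pl$rho < 0) return(.LL_SENTINEL)
  prF <- 0.5 + pl$rho + c(pl$alpha_f, pl$beta_f, pl$gamma_f, -pl$alpha_f)
  prM <- 0.5 + pl$rho + c(pl$alpha_m, pl$beta_m, pl$gamma_m, -pl$alpha_m)
  if (any(c(prF, prM) < 0) || any(c(prF, prM) > 1)) return(.LL_SENTINEL)
  if (adjusted) {
    eq <- tryCatch(.ext_equilibrium_raw(prF, prM), error = function(e) NULL)
    if (is.null(eq)) return(.LL_SENTINEL)
    t_par <- 1 - (eq[1] + eq[2]) / 2
    t_sex <- 1 - eq
    if (t_par <= 0 || t_par >= 1 || any(t_sex <= 0) || any(t_sex >= 1)) {
      return(.LL_SENTINEL)
    }
  }
  ll <- 0
  for (s in summ) {
    if (adjusted) {
      d <- s$m_p - t_par
      u <- if (d > 0) d / s$m_p else 0
      v <- if (d < 0) -d / (1 - s$m_p) else 0
      P4 <- parent_matrix_ordered(u, v)
      for (j in 1:2) {
        pr <- if (j == 1) prF else prM
        mo <- s$m_o[j]; tt <- t_sex[j]
        w <- if (mo > tt) (mo - tt) / (1 - tt) else 0
        x <- if (mo < tt) (tt - mo) / tt else 0
        q <- pr * (1 - w) + (1 - pr) * x
        mR <- as.numeric(P4 %*% q)
        term <- .xlogp(c(s$counts[, j, 1], s$counts[, j, 2]),
                       c(mR, 1 - mR))
        if (is.na(term)) return(.LL_SENTINEL)
        ll <- ll + term
      }
    } else {
      for (j in 1:2) {
        pr <- if (j == 1) prF else prM
        term <- .xlogp(c(s$counts[, j, 1], s$counts[, j, 2]),
                       c(pr, 1 - pr))
        if (is.na(term)) return(.LL_SENTINEL)
        ll <- ll + term
      }
    }
  }
  ll
}

# coupled fixed point on (female, male) right-hander frequencies given the
# per-mating right-probabilities; returns c(fF, fM)
.ext_equilibrium_raw <- function(prF, prM, tol = 1e-12,
                                 max_iter = 100000L) {
  ff <- fm <- 0.5
  for (i in seq_len(max_iter)) {
    w <- c(ff * fm, ff * (1 - fm), (1 - ff) * fm, (1 - ff) * (1 - fm))
    ff_new <- sum(w * prF); fm_new <- sum(w * prM)
    if (abs(ff_new - ff) < tol && abs(fm_new - fm) < tol) {
      return(c(ff_new, fm_new))
    }
    ff <- ff_new; fm <- fm_new
  }
  stop("extended equilibrium did not converge", call. = FALSE)
}

#' Extended (sex-difference) support function
#'
#' Sum over offspring sexes and the four ordered parental matings of the
#' binomial log-likelihood of the sex-stratified counts, under the extended
#' transmission table; with `adjusted = TRUE` each study's table is first
#' carried to the measured scale using a pooled parental incidence, per-sex
#' offspring incidences, and sex-specific equilibrium true incidences.
#'
#' @param params An [extended_params()] object.
#' @param studies A `sex_data` frame.
#' @param adjusted Apply the criterion-shift adjustment (as in scenario C)?
#' @return The support value (natural log scale).
#' @export
loglik_extended <- function(params, studies, adjusted = FALSE) {
  stopifnot(inherits(params, "extended_params"))
  summ <- .sex_summary(studies)
  .loglik_ext_fast(.free_from_extended(params), params$model_id, summ,
                   adjusted)
}
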