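#' Parent-generation misclassification proportions
#'
#' Given the model's true incidence of left-handers `t` and a study's
#' measured parental incidence `m_p`, returns the two mutually exclusive
#' misclassification proportions. If `m_p > t` some true right-handers were
#' measured left: `u = (m_p - t) / m_p` is the proportion of measured
#' left-handers who are truly right-handed and `v = 0`. If `m_p < t` some
#' true left-handers were measured right: `v = (t - m_p) / (1 - m_p)` and
#' `u = 0`. Both forms are fixed by marginal consistency: the per-parent
#' measured-to-true map must carry measured incidence `m_p` onto true
#' incidence `t`. These are nuisance quantities computed directly from
#' `(t, m_p)`, never fitted.
#'
#' @param t True incidence of left-handers, in `(0, 1)`.
#' @param m_p Measured parental incidence, in `(0, 1)`.
#' @return Named numeric vector `c(u, v)`, at most one nonzero.
#' @examples
#' parent_nuisance(t = 0.1, m_p = 0.2)  # u = 0.5
#' @export
parent_nuisance <- function(t, m_p) {
  .check_unit_open(t, "t"); .check_unit_open(m_p, "m_p")
  d <- m_p - t
  if (abs(d) < 1e-12) return(c(u = 0, v = 0))
  if (d > 0) c(u = d / m_p, v = 0) else c(u = 0, v = -d / (1 - m_p))
}

#' Offspring-generation misclassification proportions
#'
#' As [parent_nuisance()] but for the offspring generation and expressed on
#' the true-phenotype margin: if `m_o > t` the proportion of true
#' right-handers measured left is `w = (m_o - t) / (1 - t)` (`x = 0`); if
#' `m_o < t` the proportion of true left-handers measured right is
#' `x = (t - m_o) / t` (`w = 0`).
#'
#' @param t True incidence of left-handers, in `(0, 1)`.
#' @param m_o Measured offspring incidence, in `(0, 1)`.
#' @return Named numeric vector `c(w, x)`, at most one nonzero.
#' @examples
#' offspring_nuisance(t = 0.1, m_o = 0.2)  # w = 1/9
#' @export
offspring_nuisance <- function(t, m_o) {
  .check_unit_open(t, "t"); .check_unit_open(m_o, "m_o")
  d <- m_o - t
  if (abs(d) < 1e-12) return(c(w = 0, x = 0))
  if (d > 0) c(w = d / (1 - t), x = 0) else c(w = 0, x = -d / t)
}

.check_unit_open <- function(z, name) {
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z <= 0 || z >= 1) {
    stop(sprintf("%s must lie strictly between 0 and 1", name),
         call. = FALSE)
  }
  invisible(z)
}

#' Parental mating-class transition matrix P
#'
#' Expands the per-parent measured-to-true misclassification map to the three
#' unordered mating classes, assuming the map acts independently and
#' identically on the two parents. With `u` active, a parent measured L is
#' truly R with probability `u`; with `v` active, a parent measured R is
#' truly L with probability `v`.
#'
#' @param u,v Misclassification proportions from [parent_nuisance()]; at most
#'   one may be nonzero.
#' @return A 3 x 3 row-stochastic matrix, rows and columns ordered
#'   `(RxR, mixed, LxL)`, mapping measured mating class to true mating class.
#' @examples
#' parent_matrix(u = 0.5, v = 0)
#' @export
parent_matrix <- function(u, v) {
  .check_nuisance_pair(u, v)
  # per-parent map: measured R -> (true R, true L) = (1 - v, v)
  #                 measured L -> (true R, true L) = (u, 1 - u)
  m <- rbind(
    RxR   = c((1 - v)^2, 2 * v * (1 - v), v^2),
    mixed = c((1 - v) * u, (1 - v) * (1 - u) + v * u, v * (1 - u)),
    LxL   = c(u^2, 2 * u * (1 - u), (1 - u)^2)
  )
  colnames(m) <- c("RxR", "mixed", "LxL")
  m
}

#' Offspring phenotype transition matrix O
#'
#' The 2 x 2 map from true to measured offspring phenotype. With `w` active a
#' true right-hander is measured left with probability `w`; with `x` active a
#' true left-hander is measured right with probability `x`.
#'
#' @param w,x Misclassification proportions from [offspring_nuisance()]; at
#'   most one may be nonzero.
#' @return A 2 x 2 row-stochastic matrix, rows true `(R, L)`, columns
#'   measured `(R, L)`.
#' @examples
#' offspring_matrix(w = 0.1, x = 0)
#' @export
offspring_matrix <- function(w, x) {
  .check_nuisance_pair(w, x)
  m <- rbind(R = c(1 - w, w), L = c(x, 1 - x))
  colnames(m) <- c("R", "L")
  m
}

.check_nuisance_pair <- function(a, b) {
  if (anyNA(c(a, b)) || a < 0 || a > 1 || b < 0 || b > 1) {
    stop("misclassification proportions must lie in [0, 1]", call. = FALSE)
  }
  if (a > 0 && b > 0) {
    stop("misclassification errors are mutually exclusive: only one of the ",
         "pair may be nonzero", call. = FALSE)
  }
  invisible(NULL)
}

#' Criterion-shift adjustment set for one dataset
#'
#' Bundles the true incidence, the measured incidences and the derived
#' nuisance proportions and transition matrices used to adjust a true
#' transmission table to the measured scale.
#'
#' @param t True incidence of left-handers (from the model equilibrium).
#' @param m_p Measured parental incidence.
#' @param m_o Measured offspring incidence.
#' @return A list of class `adjustment_set` with elements `t`, `m_p`, `m_o`,
#'   `u`, `v`, `w`, `x`, `P` (3 x 3) and `O` (2 x 2).
#' @export
adjustment_set <- function(t, m_p, m_o) {
  uv <- parent_nuisance(t, m_p)
  wx <- offspring_nuisance(t, m_o)
  structure(list(t = t, m_p = m_p, m_o = m_o,
                 u = uv[["u"]], v = uv[["v"]],
                 w = wx[["w"]], x = wx[["x"]],
                 P = parent_matrix(uv[["u"]], uv[["v"]]),
                 O = offspring_matrix(wx[["w"]], wx[["x"]])),
            class = "adjustment_set")
}

#' @export
print.adjustment_set <- function(x, ...) {
  cat(sprintf("Criterion-shift adjustment: t = %.4f, m_p = %.4f, m_o = %.4f\n",
              x$t, x$m_p, x$m_o))
  cat(sprintf("  u = %.4f  v = %.4f  w = %.4f  x = %.4f\n",
              x$u, x$v, x$w, x$x))
  invisible(x)
}

#' Adjust a true transmission table to the measured scale
#'
#' Computes `M = P T O`: the expected phenotype table indexed by measured
#' mating class and measured offspring phenotype.
#'
#' @param T_tab A 3 x 2 true transmission table from [transmission_table()].
#' @param adj An [adjustment_set()].
#' @return A 3 x 2 row-stochastic matrix on the measured scale.
#' @export
adjust_familial <- function(T_tab, adj) {
  stopifnot(inherits(adj, "adjustment_set"),
            is.matrix(T_tab), nrow(T_tab) == 3, ncol(T_tab) == 2)
  m <- adj$P %*% T_tab %*% adj$O
  dimnames(m) <- dimnames(T_tab)
  m
}

#' Adjust expected twin-pair probabilities to the measured scale
#'
#' Builds the 3 x 3 pair-transition matrix implied by independent per-twin
#' misclassification with the active offspring nuisance (`w` when
#' `m_o > t`, `x` when `m_o < t`) and applies it to the unordered pair
#' distribution `(RR, RL, LL)`. For the `w` case the rows are
#' `RR -> ((1-w)^2, 2w(1-w), w^2)`, `RL -> (0, 1-w, w)`, `LL -> (0, 0, 1)`;
#' the `x` case is the mirror image.
#'
#' @param pair_probs Numeric vector `(RR, RL, LL)` summing to 1.
#' @param t True incidence of left-handers, in `(0, 1)`.
#' @param m_o Measured individual-level incidence in the twin sample.
#' @return Named numeric vector `(RR, RL, LL)` of measured pair
#'   probabilities.
#' @export
adjust_twin <- function(pair_probs, t, m_o) {
  stopifnot(length(pair_probs) == 3, all(pair_probs >= 0),
            abs(sum(pair_probs) - 1) < 1e-8)
  wx <- offspring_nuisance(t, m_o)
  w <- wx[["w"]]; x <- wx[["x"]]
  K <- rbind(
    RR = c((1 - w)^2, 2 * w * (1 - w), w^2),
    RL = c(x * (1 - w), (1 - w) * (1 - x) + w * x, w * (1 - x)),
    LL = c(x^2, 2 * x * (1 - x), (1 - x)^2)
  )
  out <- as.numeric(pair_probs %*% K)
  names(out) <- c("RR", "RL", "LL")
  out
}

#' Ordered 4 x 4 parental transition matrix for the sex-difference model
#'
#' Expands the per-parent measured-to-true map to the four ordered
#' mother-by-father matings `(RmRf, RmLf, LmRf, LmLf)`, with the same map
#' applied independently to mother and father (parental incidences are pooled
#' across sexes).
#'
#' @param u,v Misclassification proportions, at most one nonzero.
#' @return A 4 x 4 row-stochastic matrix mapping measured to true mating.
#' @export
parent_matrix_ordered <- function(u, v) {
  .check_nuisance_pair(u, v)
  # per-parent columns: (true R, true L) given measured R / measured L
  q <- rbind(R = c(1 - v, v), L = c(u, 1 - u))
  lab <- c("RmRf", "RmLf", "LmRf", "LmLf")
  m <- matrix(0, 4, 4, dimnames = list(lab, lab))
  ph <- cbind(mo = c(1, 1, 2, 2), fa = c(1, 2, 1, 2))  # 1 = R, 2 = L
  for (i in 1:4) for (j in 1:4) {
    m[i, j] <- q[ph[i, "mo"], ph[j, "mo"]] * q[ph[i, "fa"], ph[j, "fa"]]
  }
  m
}
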