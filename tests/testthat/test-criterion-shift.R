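# independent oracle: solve the two-state marginal-consistency condition
# numerically for the active flip probability
solve_parent_flip <- function(t, m_p) {
  if (m_p > t) {
    # measured-L -> true-R flip u: true left margin m_p (1 - u) = t
    uniroot(function(u) m_p * (1 - u) - t, c(0, 1), tol = 1e-14)$root
  } else if (m_p < t) {
    uniroot(function(v) m_p + (1 - m_p) * v - t, c(0, 1), tol = 1e-14)$root
  } else 0
}

solve_offspring_flip <- function(t, m_o) {
  if (m_o > t) {
    # true-R -> measured-L flip w: measured left margin t + (1 - t) w = m_o
    uniroot(function(w) t + (1 - t) * w - m_o, c(0, 1), tol = 1e-14)$root
  } else if (m_o < t) {
    uniroot(function(x) t * (1 - x) - m_o, c(0, 1), tol = 1e-14)$root
  } else 0
}

test_that("nuisance formulas satisfy marginal consistency", {
  expect_equal(parent_nuisance(0.1, 0.2), c(u = 0.5, v = 0))
  expect_equal(parent_nuisance(0.1, 0.1), c(u = 0, v = 0))
  expect_equal(parent_nuisance(0.2, 0.1), c(u = 0, v = 0.1 / 0.9))
  expect_equal(offspring_nuisance(0.1, 0.2), c(w = 0.1 / 0.9, x = 0))
  expect_equal(offspring_nuisance(0.2, 0.1), c(w = 0, x = 0.5))
  expect_equal(offspring_nuisance(0.15, 0.15), c(w = 0, x = 0))

  set.seed(11)
  for (i in 1:1000) {
    t <- runif(1, 0.01, 0.99); m <- runif(1, 0.01, 0.99)
    uv <- parent_nuisance(t, m)
    expect_equal(max(uv), max(solve_parent_flip(t, m)), tolerance = 1e-10)
    # pushing the measured margin through the per-parent map returns t
    true_left <- m * (1 - uv[["u"]]) + (1 - m) * uv[["v"]]
    expect_equal(true_left, t, tolerance = 1e-12)
    wx <- offspring_nuisance(t, m)
    expect_equal(max(wx), max(solve_offspring_flip(t, m)),
                 tolerance = 1e-10)
    measured_left <- t * (1 - wx[["x"]]) + (1 - t) * wx[["w"]]
    expect_equal(measured_left, m, tolerance = 1e-12)
  }
  expect_error(parent_nuisance(0, 0.5), "strictly between")
  expect_error(offspring_nuisance(0.5, 1), "strictly between")
})

test_that("parent matrix expands the per-parent map over unordered matings", {
  expect_equal(unname(parent_matrix(0.5, 0)),
               rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.25, 0.5, 0.25)))
  expect_equal(unname(parent_matrix(0, 0.2)),
               rbind(c(0.64, 0.32, 0.04), c(0, 0.8, 0.2), c(0, 0, 1)))
  expect_equal(unname(parent_matrix(0, 0)), diag(3))
  expect_error(parent_matrix(0.2, 0.3), "mutually exclusive")
  # brute-force oracle: enumerate the two parents independently
  set.seed(12)
  for (i in 1:50) {
    u <- if (i %% 2) runif(1) else 0
    v <- if (i %% 2) 0 else runif(1)
    q <- rbind(c(1 - v, v), c(u, 1 - u))  # measured (R, L) -> true (R, L)
    classes <- rbind(c(1, 1), c(1, 2), c(2, 2))
    oracle <- matrix(0, 3, 3)
    for (mi in 1:3) for (p1 in 1:2) for (p2 in 1:2) {
      prob <- q[classes[mi, 1], p1] * q[classes[mi, 2], p2]
      tm <- if (p1 == 1 && p2 == 1) 1 else if (p1 == 2 && p2 == 2) 3 else 2
      oracle[mi, tm] <- oracle[mi, tm] + prob
    }
    # the mixed measured class has one parent of each measured phenotype
    oracle[2, ] <- 0
    for (p1 in 1:2) for (p2 in 1:2) {
      prob <- q[1, p1] * q[2, p2]
      tm <- if (p1 == 1 && p2 == 1) 1 else if (p1 == 2 && p2 == 2) 3 else 2
      oracle[2, tm] <- oracle[2, tm] + prob
    }
    expect_equal(unname(parent_matrix(u, v)), oracle, tolerance = 1e-12)
  }
})

test_that("offspring matrix maps the equilibrium margin onto the measured one", {
  expect_equal(unname(offspring_matrix(0.1, 0)),
               rbind(c(0.9, 0.1), c(0, 1)))
  expect_equal(unname(offspring_matrix(0, 0)), diag(2))
  set.seed(13)
  for (i in 1:200) {
    t <- runif(1, 0.01, 0.99); m <- runif(1, 0.01, 0.99)
    wx <- offspring_nuisance(t, m)
    O <- offspring_matrix(wx[["w"]], wx[["x"]])
    expect_equal(rowSums(O), c(R = 1, L = 1), tolerance = 1e-12)
    measured <- c(1 - t, t) %*% O
    expect_equal(as.numeric(measured), c(1 - m, m), tolerance = 1e-12)
  }
})

test_that("familial adjustment M = P T O is row-stochastic and collapses", {
  p <- base_params(0.277, 0.138, 0)
  T_tab <- transmission_table(p)
  t <- equilibrium(p)$f_dl
  # identity adjustment when the measured incidences equal t
  adj0 <- adjustment_set(t, t, t)
  expect_equal(adjust_familial(T_tab, adj0), T_tab, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:200) {
    adj <- adjustment_set(t, runif(1, 0.02, 0.4), runif(1, 0.02, 0.4))
    M <- adjust_familial(T_tab, adj)
    expect_equal(unname(rowSums(M)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
  }
  # hand-worked triple sum with u = 0.5 (parents), w = 0.1 (offspring)
  adj <- adjustment_set(0.1, 0.2, 0.1 + 0.9 * 0.1)
  expect_equal(adj$u, 0.5)
  expect_equal(adj$w, 0.1)
  M <- adjust_familial(T_tab, adj)
  oracle <- matrix(0, 3, 2)
  for (cm in 1:3) for (ct in 1:3) for (ht in 1:2) for (hm in 1:2) {
    oracle[cm, hm] <- oracle[cm, hm] +
      adj$P[cm, ct] * T_tab[ct, ht] * adj$O[ht, hm]
  }
  expect_equal(unname(M), oracle, tolerance = 1e-12)
})

test_that("twin adjustment preserves mass and hits the measured margin", {
  p <- base_params(0.277, 0.138, 0)
  probs <- twin_expectations(p)
  t <- equilibrium(p)$f_dl
  expect_equal(adjust_twin(probs, t, t), probs, tolerance = 1e-12)
  set.seed(15)
  for (m_o in runif(30, 0.02, 0.5)) {
    out <- adjust_twin(probs, t, m_o)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    # individual-level left margin of the measured pair distribution
    expect_equal(unname((out["RL"] + 2 * out["LL"]) / 2), m_o,
                 tolerance = 1e-12)
  }
  # explicit expansion over the four ordered-pair outcomes, w case
  w <- 0.1
  input <- c(RR = 0.81, RL = 0.18, LL = 0.01)
  t_in <- (0.18 + 0.02) / 2  # individual left margin 0.1
  out <- adjust_twin(input, t_in, t_in + (1 - t_in) * w)
  oracle <- c(0.81 * (1 - w)^2,
              0.81 * 2 * w * (1 - w) + 0.18 * (1 - w),
              0.81 * w^2 + 0.18 * w + 0.01)
  expect_equal(unname(out), oracle, tolerance = 1e-12)
})

test_that("ordered parental matrix reduces to the per-parent products", {
  P4 <- parent_matrix_ordered(0.5, 0)
  # measured LmLf: each parent truly R with probability 0.5
  expect_equal(unname(P4["LmLf", ]), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(unname(rowSums(P4)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(parent_matrix_ordered(0, 0)), diag(4))
})
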