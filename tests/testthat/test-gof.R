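test_that("G statistic matches the closed formula and its edge cases", {
  # O = E exactly
  expect_equal(g_statistic(matrix(c(50, 50), 1), matrix(c(0.5, 0.5), 1)), 0)
  # direct evaluation: 2 * (30 ln(30/50) + 70 ln(70/50))
  expect_equal(g_statistic(matrix(c(30, 70), 1), matrix(c(0.5, 0.5), 1)),
               2 * (30 * log(30 / 50) + 70 * log(70 / 50)))
  expect_equal(g_statistic(matrix(c(30, 70), 1), matrix(c(0.5, 0.5), 1)),
               16.456, tolerance = 1e-4)
  # observed zeros contribute nothing; expected zero with observation errors
  expect_equal(g_statistic(matrix(c(0, 100), 1), matrix(c(0, 1), 1)), 0)
  expect_error(g_statistic(matrix(c(10, 90), 1), matrix(c(0, 1), 1)),
               "expected count 0")
})

test_that("familial goodness-of-fit sums per-study G and books df as 2S - k", {
  fam <- load_familial_fixture()
  fit2 <- fit_mle(fam, "B", "two", n_starts = 30, seed = 41)
  g2 <- gof_familial(fam, fit2)
  expect_equal(g2$combined$G, sum(g2$per_study$G), tolerance = 1e-9)
  expect_equal(g2$combined$df, 2L * 17L - 2L)  # 32 for k = 2
  expect_true(all(g2$per_study$df == 2L))
  fit3 <- fit_mle(fam, "B", "three", n_starts = 60, seed = 42)
  g3 <- gof_familial(fam, fit3)
  expect_equal(g3$combined$df, 2L * 17L - 3L)  # 31 for k = 3
  # the unadjusted test statistic differs from the adjusted one
  gA <- gof_familial(fam, fit2, adjusted = FALSE)
  expect_gt(gA$combined$G, g2$combined$G)
})

test_that("a perfectly fitting expectation gives G = 0 and p = 1", {
  p <- base_params(0.3, 0.1, 0)
  T_tab <- transmission_table(p)
  t <- equilibrium(p)$f_dl
  # counts proportional to T rows, measured incidences equal to t so that
  # the adjustment is the identity
  n <- 10000
  cls <- round(n * c((1 - t)^2, 2 * t * (1 - t), t^2))
  counts <- c(rbind(cls * T_tab[, "R"], cls * T_tab[, "L"]))
  counts <- round(counts, 8)
  m_o <- sum(counts[c(2, 4, 6)]) / sum(counts)
  st <- make_familial(counts, m_p = t)
  fit <- list(params = p, scenario = "C", model = "two",
              incidence_mode = "reported", m_p_fallback = character(0))
  class(fit) <- "handtrans_fit"
  g <- gof_familial(st, fit, adjusted = TRUE)
  # m_o is not exactly t because of rounding; G is tiny, not exactly 0
  expect_lt(g$combined$G, 0.1)
  g0 <- gof_familial(st, fit, adjusted = FALSE)
  expect_lt(g0$combined$G, 0.1)
})

test_that("twin goodness-of-fit books one df per dataset and sums", {
  tw <- load_twin_fixture()
  fam <- load_familial_fixture()
  fit <- fit_mle(fam, "B", "two", n_starts = 30, seed = 43)
  g <- gof_twins(tw, fit)
  expect_equal(nrow(g$per_study), 2L)
  expect_true(all(g$per_study$df == 1L))
  expect_equal(g$combined$df, 2L)
  expect_equal(g$combined$G, sum(g$per_study$G), tolerance = 1e-9)
  # hand-worked single dataset
  probs <- twin_expectations(fit$params)
  t_hat <- 1 - equilibrium(fit$params)$f_dr
  obs <- as.numeric(tw[1, c("n_rr", "n_rl", "n_ll")])
  m_o <- (obs[2] + 2 * obs[3]) / (2 * sum(obs))
  exp_probs <- adjust_twin(probs, t_hat, m_o)
  manual <- 2 * sum(obs * log(obs / (sum(obs) * exp_probs)))
  expect_equal(g$per_study$G[1], manual, tolerance = 1e-9)
})

test_that("model-generated twin counts fit their own model", {
  p <- base_params(0.277, 0.138, 0)
  probs <- twin_expectations(p)
  n <- 20000
  counts <- round(n * probs)
  tw <- structure(data.frame(study_id = "exact", zygosity = "MZ",
                             n_rr = counts[1], n_rl = counts[2],
                             n_ll = counts[3]),
                  class = c("twin_data", "data.frame"))
  fit <- list(params = p, scenario = "B", model = "two")
  class(fit) <- "handtrans_fit"
  g <- gof_twins(tw, fit)
  expect_lt(g$combined$G, 0.01)
  expect_gt(g$combined$p, 0.9)
})

test_that("likelihood-ratio tests respect nesting and Wilks bookkeeping", {
  sx <- load_sex_fixture()
  fits <- lapply(c("I", "II", "III", "IV", "V"), function(m) {
    fit_mle(sx, "C", m, n_starts = 40, seed = 44)
  })
  names(fits) <- c("I", "II", "III", "IV", "V")
  # support never decreases as constraints are released
  expect_gte(fits$II$loglik, fits$I$loglik - 1e-6)
  expect_gte(fits$III$loglik, fits$II$loglik - 1e-6)
  expect_gte(fits$IV$loglik, fits$II$loglik - 1e-6)
  expect_gte(fits$V$loglik, fits$III$loglik - 1e-6)
  expect_gte(fits$V$loglik, fits$IV$loglik - 1e-6)

  lrt <- likelihood_ratio_test(fits$II, fits$IV)
  expect_equal(lrt$df, 2L)
  expect_equal(lrt$LR, 2 * (fits$IV$loglik - fits$II$loglik),
               tolerance = 1e-9)
  expect_error(likelihood_ratio_test(fits$III, fits$IV), "not nested")
  expect_error(likelihood_ratio_test(fits$V, fits$I), "not nested")
  # equal support across a nested pair gives LR = 0, p = 1
  tied <- fits$II
  tied$model <- "IV"
  lr0 <- likelihood_ratio_test(fits$II, tied)
  expect_equal(lr0$LR, 0)
  expect_equal(lr0$p, 1)
})

test_that("testing a model against data it generated is calibrated", {
  # type-I error of the II-vs-I contrast on data generated from model I
  set.seed(45)
  pI <- extended_params(0.28, 0.12, 0.12, 0, 0, 0, 0, model_id = "I")
  n_rep <- 120
  rejects <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sx <- simulate_sex_stratified(pI, pairs = c(600, 60, 60, 10),
                                  seed = 46000 + r)
    fI <- fit_mle(sx, "B", "I", n_starts = 4, seed = r,
                  starts = list(c(0.25, 0.1), c(0.3, 0.15)))
    fII <- fit_mle(sx, "B", "II", n_starts = 4, seed = r,
                   starts = list(c(0.25, 0.1, 0), c(0.3, 0.15, 0.02)))
    lr <- tryCatch(likelihood_ratio_test(fI, fII), error = function(e) NULL)
    rejects[r] <- !is.null(lr) && lr$p < 0.05
  }
  # empirical type-I error near the nominal 5% (binomial noise at n = 120)
  expect_lt(mean(rejects), 0.15)
  expect_gte(mean(rejects), 0)
})
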