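test_that("unadjusted support matches direct binomial arithmetic", {
  # single study, RxR only, 9 right / 1 left at p(R|RxR) = 0.9
  st <- make_familial(c(9, 1, 0, 0, 0, 0), m_p = 0.1)
  p <- base_params(0.262, 0.138, 0)
  expect_equal(loglik_T(p, st), 9 * log(0.9) + log(0.1),
               tolerance = 1e-10)
  # empty mating classes contribute zero; p(R | LxL) = 0.624 here
  st2 <- make_familial(c(9, 1, 0, 0, 5, 5), m_p = 0.1)
  expect_equal(loglik_T(p, st2),
               9 * log(0.9) + log(0.1) + 5 * log(0.624) + 5 * log(0.376),
               tolerance = 1e-10)
})

test_that("the maximized single-class support equals minus n times entropy", {
  # with one mating class the support is maximized at the observed
  # proportion and equals the negative binary cross-entropy
  st <- make_familial(c(80, 20, 0, 0, 0, 0), m_p = 0.2)
  phat <- 0.2
  target <- -(100) * (-(0.8 * log(0.8) + 0.2 * log(0.2)))
  # p(R | RxR) = 0.8 at rho = 0.3, alpha = 0
  expect_equal(loglik_T(base_params(0.3, 0, 0), st), target,
               tolerance = 1e-10)
  # any parameter value with p(R | RxR) != 0.8 does worse
  for (r in c(0.2, 0.25, 0.4)) {
    expect_lt(loglik_T(base_params(r, 0, 0), st), target)
  }
})

test_that("adjusted support equals unadjusted when incidences equal t", {
  set.seed(21)
  for (i in 1:50) {
    p <- random_base_params(beta_free = i %% 2 == 0)
    t <- equilibrium(p)$f_dl
    if (t <= 0.01 || t >= 0.99) next
    st <- make_familial(rbind(c(90, 10, 40, 10, 5, 5),
                              c(45, 5, 20, 5, 3, 2)),
                        m_p = c(t, t))
    # force m_o = t by overriding measured incidence through the counts:
    # use the identity only via m_p = m_o = t, so craft counts with
    # left fraction t is impractical; instead compare against loglik_M
    # evaluated with the study's own m_o replaced by t via adjustment_set
    T_tab <- transmission_table(p)
    M <- adjust_familial(T_tab, adjustment_set(t, t, t))
    expect_equal(M, T_tab, tolerance = 1e-12)
  }
  # direct check on the support values with matching measured incidences:
  # counts with m_o exactly 0.1 and a parameter point whose t is 0.1
  # (rho, alpha) chosen so (1/2 + rho - alpha) / (1 - 2 alpha) = 0.9
  alpha <- 0.1; rho <- 0.9 * (1 - 2 * alpha) - 0.5 + alpha
  p <- base_params(rho, alpha, 0)
  expect_equal(equilibrium(p)$f_dl, 0.1, tolerance = 1e-12)
  st <- make_familial(c(85, 5, 5, 4, 0, 1), m_p = 0.1)  # m_o = 0.1
  expect_equal(loglik_M(p, st), loglik_T(p, st), tolerance = 1e-10)
})

test_that("adjusted support agrees with the matrix-level computation", {
  p <- base_params(0.25, 0.12, 0.01)
  st <- make_familial(c(200, 30, 80, 30, 10, 8), m_p = 0.18)
  t <- equilibrium(p)$f_dl
  m_o <- compute_offspring_incidence(st[1, ])
  M <- adjust_familial(transmission_table(p),
                       adjustment_set(t, 0.18, m_o))
  manual <- 200 * log(M["RxR", "R"]) + 30 * log(M["RxR", "L"]) +
    80 * log(M["mixed", "R"]) + 30 * log(M["mixed", "L"]) +
    10 * log(M["LxL", "R"]) + 8 * log(M["LxL", "L"])
  expect_equal(loglik_M(p, st), manual, tolerance = 1e-10)
})

test_that("extended support reduces to the base support under tied models", {
  sx <- load_sex_fixture()
  # collapse to three unordered classes, both sexes pooled
  df <- as.data.frame(sx)
  agg <- function(m) colSums(df[df$mating %in% m, c("n_r", "n_l")])
  rr <- agg("rmrf"); mx <- agg(c("rmlf", "lmrf")); ll <- agg("lmlf")
  fam <- make_familial(c(rr[1], rr[2], mx[1], mx[2], ll[1], ll[2]),
                       m_p = 0.1)
  p2 <- extended_params(0.25, 0.1, 0.1, 0.02, 0.02, 0.02, 0.02,
                        model_id = "II")
  expect_equal(loglik_extended(p2, sx, adjusted = FALSE),
               loglik_T(base_params(0.25, 0.1, 0.02), fam),
               tolerance = 1e-8)
  # model I at beta = 0 equals model II at the same point
  pI <- extended_params(0.25, 0.1, 0.1, 0, 0, 0, 0, model_id = "I")
  pII <- extended_params(0.25, 0.1, 0.1, 0, 0, 0, 0, model_id = "II")
  expect_equal(loglik_extended(pI, sx), loglik_extended(pII, sx))
})

test_that("scenario A and B give identical estimates; C matches on shift-free data", {
  fam <- load_familial_fixture()
  fa <- fit_mle(fam, "A", "two", n_starts = 30, seed = 5)
  fb <- fit_mle(fam, "B", "two", n_starts = 30, seed = 5)
  expect_equal(fa$params$rho, fb$params$rho, tolerance = 1e-10)
  expect_equal(fa$params$alpha, fb$params$alpha, tolerance = 1e-10)

  # On shift-free data every study has m_p ~ m_o ~ t, and the adjusted
  # support is then constant along a curve through the truth: the point
  # estimate is not identified under adjustment, but the unadjusted
  # optimum is support-equivalent to the adjusted optimum. (With varying
  # per-study shifts the curve differs per study and the fit is
  # identified; that recovery is tested elsewhere.)
  cfg <- synthetic_config(shift = "none", study_sizes = rep(2e5, 17),
                          n_datasets = 1, seed = 31)
  shift_free <- simulate_familial(cfg)[[1]]
  fb2 <- fit_mle(shift_free, "B", "two", n_starts = 30, seed = 6)
  fc2 <- fit_mle(shift_free, "C", "two", n_starts = 30, seed = 6)
  gap <- fc2$loglik - loglik_M(fb2$params, shift_free)
  expect_gte(gap, -1e-6)
  expect_lt(gap / abs(fc2$loglik), 1e-4)
})

test_that("the estimator is consistent on large shift-free data", {
  truth <- base_params(0.277, 0.138, 0)
  cfg <- synthetic_config(true_params = truth, shift = "none",
                          study_sizes = rep(3e5, 6), seed = 32)
  big <- simulate_familial(cfg)[[1]]
  fit <- fit_mle(big, "A", "two", n_starts = 30, seed = 7)
  expect_lt(abs(fit$params$rho - 0.277), 5e-3)
  expect_lt(abs(fit$params$alpha - 0.138), 5e-3)
})

test_that("grid search agrees with the simplex optimum", {
  fam <- load_familial_fixture()
  fit <- fit_mle(fam, "B", "two", n_starts = 50, seed = 8)
  gr <- grid_search(fam, "B", "two", n_points = 501)
  # half a grid step of 0.001 on each axis
  expect_lt(abs(gr$best[["rho"]] - fit$params$rho), 1.5e-3)
  expect_lt(abs(gr$best[["alpha"]] - fit$params$alpha), 1.5e-3)
  expect_lte(gr$loglik, fit$loglik + 1e-6)
  expect_equal(max(gr$surface$loglik), gr$loglik)
  # degenerate two-point grid returns a corner of the box
  gr2 <- grid_search(fam, "B", "two", n_points = 2)
  expect_true(all(gr2$best %in% c(0, 0.5)))
})

test_that("bootstrap intervals are nested across levels and reproducible", {
  fam <- load_familial_fixture()
  fit <- fit_mle(fam, "B", "two", n_starts = 30, seed = 9)
  bt <- bootstrap_ci(fam, "B", "two", n_boot = 60,
                     levels = c(0.9, 0.95, 0.99), seed = 10, fit = fit)
  iv <- bt$intervals
  for (pn in c("rho", "alpha")) {
    sub <- iv[iv$parameter == pn, ]
    sub <- sub[order(sub$level), ]
    expect_true(all(diff(sub$lower) <= 1e-12))
    expect_true(all(diff(sub$upper) >= -1e-12))
  }
  bt2 <- bootstrap_ci(fam, "B", "two", n_boot = 60,
                      levels = c(0.9, 0.95, 0.99), seed = 10, fit = fit)
  expect_equal(bt$samples, bt2$samples)
  expect_equal(bt$n_failed, 0L)
})

test_that("bootstrap coverage is near nominal without criterion shift", {
  # calibration oracle at reduced replicates: scenario A fits on data
  # generated without shift should give ~95% coverage of the truth
  cfg <- synthetic_config(shift = "none", n_datasets = 60, seed = 33)
  ev <- evaluate_estimator(cfg, scenario = "B",
                           bootstrap = list(n_boot = 60, levels = 0.95))
  expect_gt(ev$coverage$coverage_rho, 0.80)
  expect_gt(ev$coverage$coverage_alpha, 0.80)
})
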