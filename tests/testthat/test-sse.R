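test_that("a pure Gompertz schedule is assigned to the senescence component", {
  fx <- gompertz_hump(h = 0, b = 5e-5, theta = 0.09)
  fit <- fit_sse(hump_frame(fx, 1e7), lambdas = REF_LAMBDAS)
  win <- fx$ages >= 20 & fx$ages <= 85
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gamma_S - fx$gS)[win] / fx$gS[win]), 0.03)
  expect_lt(sum(fit$dhat_H) / sum(fit$deaths), 0.01)
})

test_that("noiseless hump and senescence are both recovered", {
  fx <- gompertz_hump()
  fit <- fit_sse(hump_frame(fx, 1e7), lambdas = REF_LAMBDAS)
  for (comp in list(list(est = fit$gamma_H, true = fx$gH),
                    list(est = fit$gamma_S, true = fx$gS))) {
    mask <- comp$true > 0.1 * fx$total
    expect_lt(max(abs(comp$est - comp$true)[mask] / comp$true[mask]), 0.05)
  }
})

test_that("fitted components satisfy their structural identities", {
  fx <- gompertz_hump()
  set.seed(7)
  d <- rpois(length(fx$ages), 1e5 * fx$total)
  fit <- fit_sse(hump_frame(fx, 1e5, deaths = d), lambdas = REF_LAMBDAS)
  expect_identical(fit$mu_hat, fit$gamma_H + fit$gamma_S)
  expect_equal(fit$dhat_H + fit$dhat_S, fit$exposures * fit$mu_hat,
               tolerance = 1e-14)
  # shape invariants on the fitted curves
  expect_gt(min(diff(fit$gamma_S)) / max(fit$gamma_S), -1e-8)
  expect_lt(max(diff(diff(log(fit$gamma_H)))), 1e-8)
})

test_that("the fit is invariant to a common scaling of deaths and exposures", {
  # the likelihood is a pure rate fit, so scaling deaths and exposures
  # together leaves the fitted total unchanged; the component split moves
  # only through the fixed smoothing penalty, whose relative weight falls
  # as the data grow
  fx <- gompertz_hump()
  f1 <- fit_sse(hump_frame(fx, 1e6), lambdas = REF_LAMBDAS)
  f10 <- fit_sse(hump_frame(fx, 1e7), lambdas = REF_LAMBDAS)
  expect_equal(f1$mu_hat, f10$mu_hat, tolerance = 1e-3)
  mask <- fx$gH > 0.1 * fx$total
  expect_lt(max(abs(f1$gamma_H - f10$gamma_H)[mask] / f10$gamma_H[mask]),
            0.05)
  expect_lt(max(abs(f1$gamma_S - f10$gamma_S) / f10$gamma_S), 0.05)
})

test_that("the penalized objective never decreases between accepted iterations", {
  fx <- gompertz_hump()
  set.seed(3)
  d <- rpois(length(fx$ages), 1e5 * fx$total)
  fit <- fit_sse(hump_frame(fx, 1e5, deaths = d), lambdas = REF_LAMBDAS)
  drops <- diff(fit$objective_trace)
  expect_true(all(drops >= -(1e-10 + 1e-13 * abs(fit$objective_trace[-1]))))
})

test_that("negative deaths are rejected", {
  fx <- gompertz_hump()
  df <- hump_frame(fx, 1e5)
  df$deaths[5] <- -2
  expect_error(fit_sse(df, lambdas = REF_LAMBDAS), "negative deaths")
})

test_that("lambda selection returns a single-pair grid unchanged", {
  fx <- gompertz_hump()
  sel <- select_lambdas(hump_frame(fx, 1e6), lambda_grid_H = 100,
                        lambda_grid_S = 1e6)
  expect_equal(sel$lambda_H, 100)
  expect_equal(sel$lambda_S, 1e6)
})

test_that("noiseless input selects smoothing at or above the grid median", {
  fx <- gompertz_hump()
  gh <- 10^(2:6)
  gs <- 10^(4:8)
  sel <- select_lambdas(hump_frame(fx, 1e7), lambda_grid_H = gh,
                        lambda_grid_S = gs)
  expect_gte(sel$lambda_H, median(gh))
  expect_gte(sel$lambda_S, median(gs))
})

test_that("reported BIC equals deviance plus log(m) times effective dimension", {
  fx <- gompertz_hump()
  set.seed(5)
  d <- rpois(length(fx$ages), 1e5 * fx$total)
  fit <- fit_sse(hump_frame(fx, 1e5, deaths = d), lambdas = REF_LAMBDAS)
  expect_equal(fit$bic, fit$deviance + log(81) * fit$ed, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in tabular form", {
  fx <- gompertz_hump()
  fit <- fit_sse(hump_frame(fx, 1e6), lambdas = REF_LAMBDAS)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 81)
  expect_setequal(unique(td$component), c("hump", "senescence", "total"))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(g$hump_share > 0 && g$hump_share < 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
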