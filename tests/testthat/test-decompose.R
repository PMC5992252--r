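toy_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      surf <- sample_deaths(toy_rates(), exposure = 1e7, noiseless = TRUE)
      fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
      cache <<- list(surf = surf, fit = fit)
    }
    cache
  }
})

test_that("the augmented system has the documented block structure", {
  tf <- toy_fit_cache()
  sys <- build_augmented_system(tf$surf, tf$fit, c("A", "B", "C"))
  m <- 81
  expect_equal(length(sys$response), (3 + 2) * m)
  expect_equal(dim(sys$composite), c(5 * m, 6 * m))
  expect_equal(sys$reg_weights[c(1, 3 * m, 3 * m + 1, 5 * m)],
               c(1, 1, 1e5, 1e5))

  # upper block: exposures block-diagonal per cause, once per component
  e <- surface_exposures(tf$surf)
  Cm <- as.matrix(sys$composite)
  expect_equal(Cm[1:m, 1:m], diag(e), ignore_attr = TRUE)
  expect_equal(Cm[1:m, 3 * m + 1:m], diag(e), ignore_attr = TRUE)
  expect_equal(Cm[1:m, m + 1:m], matrix(0, m, m), ignore_attr = TRUE)
  # constraint rows sum the per-cause components
  expect_equal(Cm[3 * m + 1:m, 1:m] + Cm[3 * m + 1:m, m + 1:m] +
                 Cm[3 * m + 1:m, 2 * m + 1:m], 3 * diag(e),
               ignore_attr = TRUE)
})

test_that("constraint responses carry the K - 1 multiplier for K = 2..8", {
  tf <- toy_fit_cache()
  base <- as_tibble(tf$surf)
  m <- 81
  for (K in 2:8) {
    extra <- purrr::map(seq_len(max(0, K - 3)), function(i) {
      dplyr::mutate(dplyr::filter(base, .data$cause == "A"),
                    cause = paste0("X", i), deaths = .data$deaths * 0.5)
    })
    df <- dplyr::bind_rows(c(list(dplyr::filter(base, cause != "total")),
                             extra))
    tot <- dplyr::summarise(dplyr::group_by(df, age, year),
                            deaths = sum(deaths), exposure = exposure[1],
                            .groups = "drop")
    tot$cause <- "total"
    surf <- rate_surface(dplyr::bind_rows(df, tot))
    fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
    causes <- head(setdiff(surf$causes, "total"), K)
    sys <- build_augmented_system(surf, fit, causes)
    expect_equal(sys$response[K * m + 1:m], (K - 1) * fit$dhat_H)
    got_sen <- sys$response[(K + 1) * m + 1:m]
    expect_gte(min(got_sen - (K - 1) * fit$dhat_S), -1e-8)
  }
})

test_that("with no non-hump causes the senescence constraint is (K-1) dhat_S", {
  tf <- toy_fit_cache()
  sys <- build_augmented_system(tf$surf, tf$fit, c("A", "B", "C", "D"))
  m <- 81
  expect_equal(sys$d_nonhump, rep(0, m))
  expect_equal(sys$response[(4 + 1) * m + 1:m], 3 * tf$fit$dhat_S)
})

test_that("a single selected cause requires the documented special path", {
  tf <- toy_fit_cache()
  expect_error(build_augmented_system(tf$surf, tf$fit, "B"), "at least 2")
  dec1 <- decompose_hump(tf$surf, tf$fit, "B")
  expect_s3_class(dec1, "cause_decomposition")
  # deleting the dominant hump cause removes a large share of the hump
  expect_gt(sum(tf$surf$exposures[, 1] * dec1$delta_H[, "B"]) /
              sum(tf$fit$dhat_H), 0.3)
})

test_that("contributions satisfy the sum constraints and recover the truth", {
  params <- clean_toy_params()
  truth <- toy_rates(params)
  surf <- sample_deaths(truth, exposure = 1e7, noiseless = TRUE)
  fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
  dec <- decompose_hump(surf, fit, c("A", "B", "C"))
  expect_true(dec$converged)
  expect_lt(dec$constraint_residual[["hump"]], 1e-3)
  expect_lt(dec$constraint_residual[["senescence"]], 1e-3)

  tw <- tidyr::pivot_wider(dplyr::select(truth, age, cause, hump),
                           names_from = cause, values_from = hump)
  humpT <- rowSums(as.matrix(tw[-1]))
  for (k in c("A", "B", "C")) {
    mask <- tw[[k]] > 0.1 * max(humpT)
    expect_lt(max(abs(dec$delta_H[, k] - tw[[k]])[mask] / tw[[k]][mask]),
              0.1)
  }
})

test_that("a zero-death cause contributes nothing", {
  truth <- toy_rates()
  zero <- dplyr::mutate(dplyr::filter(truth, cause == "A"), cause = "Z",
                        hump = 0, background = 0, rate = 0)
  surf <- sample_deaths(dplyr::bind_rows(truth, zero), exposure = 1e7,
                        noiseless = TRUE)
  fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
  dec <- decompose_hump(surf, fit, c("A", "B", "C", "Z"))
  # limited by the soft sum constraints (weight 1e5) and the smoothing
  # shared across the joint system
  expect_lt(max(abs(dec$delta_H[, "Z"])), 0.01 * max(fit$gamma_H))
})

test_that("a pure Gompertz cause wrongly included gets a negligible share", {
  surf <- sample_deaths(toy_rates(), exposure = 1e7, noiseless = TRUE)
  fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
  dec <- decompose_hump(surf, fit, c("A", "B", "C", "D"))
  shares <- contributions_summary(dec)
  expect_lt(abs(shares$share[shares$cause == "D"]), 0.05)
})

test_that("doubling the constraint weight barely moves the decomposition", {
  tf <- toy_fit_cache()
  d1 <- fit_constrained(build_augmented_system(tf$surf, tf$fit,
                                               c("A", "B", "C"),
                                               constraint_weight = 1e5))
  d2 <- fit_constrained(build_augmented_system(tf$surf, tf$fit,
                                               c("A", "B", "C"),
                                               constraint_weight = 1e6))
  s1 <- rowSums(d1$delta_H)
  s2 <- rowSums(d2$delta_H)
  expect_lt(sqrt(sum((s1 - s2)^2)) / sqrt(sum(s1^2)), 1e-3)
})

test_that("contribution summaries report shares, peaks and quantiles", {
  tf <- toy_fit_cache()
  dec <- decompose_hump(tf$surf, tf$fit, c("A", "B", "C"))
  cs <- contributions_summary(dec)
  expect_equal(sum(cs$share), 1, tolerance = 1e-3)
  # cause A's generating hump is symmetric around age 24
  expect_lte(abs(cs$peak_age[cs$cause == "A"] - 24), 1)
  expect_true(all(diff(unlist(cs[cs$cause == "B",
                                 c("age_q25", "age_q50", "age_q75")])) >= 0))

  # an all-zero contribution yields share 0 and a missing peak
  dec0 <- dec
  dec0$delta_H[, "A"] <- 0
  cs0 <- contributions_summary(dec0)
  expect_true(is.na(cs0$peak_age[cs0$cause == "A"]))
  expect_equal(cs0$hump_deaths[cs0$cause == "A"], 0)
})

test_that("tidy output covers every cause, component and age", {
  tf <- toy_fit_cache()
  dec <- decompose_hump(tf$surf, tf$fit, c("A", "B"))
  td <- tidy(dec)
  expect_equal(nrow(td), 2 * 2 * 81)
  expect_s3_class(autoplot(dec), "ggplot")
  expect_equal(glance(dec)$n_causes, 2)
})
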