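test_that("constant-hazard life expectancy matches survival integration", {
  mu <- 0.05
  lt <- lifetable(rep(mu, 101), 10:110)
  # brute-force oracle: trapezoid integration of exp(-mu t) over the span
  # plus the exponential open-interval tail
  tgrid <- seq(0, 101, by = 0.001)
  e_oracle <- sum(diff(tgrid) *
                    (exp(-mu * tgrid[-1]) + exp(-mu * head(tgrid, -1))) /
                    2) + exp(-mu * 101) / mu
  expect_equal(lt$ex[1], e_oracle, tolerance = 5e-4)
})

test_that("no mortality before closure gives the full age span", {
  lt <- lifetable(rep(0, 81), 10:90)
  expect_equal(lt$ex[1], 80)
  expect_true(all(diff(lt$lx) <= 0))
  expect_equal(lt$qx[81], 1)
})

test_that("doubling rates never increases life expectancy", {
  set.seed(12)
  for (i in 1:5) {
    m <- sort(runif(30, 1e-4, 0.05))
    lt1 <- lifetable(m, 1:30)
    lt2 <- lifetable(2 * m, 1:30)
    expect_true(all(lt2$ex <= lt1$ex + 1e-12))
  }
})

test_that("negative rates are rejected", {
  expect_error(lifetable(c(0.1, -0.1), 1:2), "negative")
})

test_that("life expectancy lost is zero for identical schedules", {
  m <- 1e-4 * exp(0.1 * (0:70))
  expect_equal(life_expectancy_lost(m, m, ages = 10:80), 0)
})

test_that("grid mismatch and rate violations are surfaced", {
  expect_error(
    life_expectancy_lost(tibble::tibble(age = 1:3, rate = 0.1),
                         tibble::tibble(age = 2:4, rate = 0.1)),
    "different age grids")
  expect_warning(
    life_expectancy_lost(rep(0.1, 5), rep(0.2, 5), ages = 1:5),
    "exceed")
})

test_that("Arriaga contributions sum exactly and are antisymmetric", {
  set.seed(31)
  for (i in 1:10) {
    m1 <- sort(runif(40, 1e-4, 0.08))
    m2 <- m1 * runif(40, 0.5, 1.1)
    lt1 <- lifetable(m1, 10:49)
    lt2 <- lifetable(m2, 10:49)
    a12 <- arriaga(lt1, lt2)
    expect_equal(sum(a12$contribution), lt2$ex[1] - lt1$ex[1],
                 tolerance = 1e-10)
    a21 <- arriaga(lt2, lt1)
    expect_equal(a12$contribution, -a21$contribution, tolerance = 1e-12)
  }
  ident <- arriaga(lifetable(rep(0.01, 10), 1:10),
                   lifetable(rep(0.01, 10), 1:10))
  expect_equal(ident$contribution, rep(0, 10))
})

test_that("a localized rate change concentrates its Arriaga contributions", {
  ages <- 10:59
  m1 <- 1e-3 * exp(0.05 * (ages - 10))
  m2 <- m1
  m2[ages >= 20 & ages < 25] <- m2[ages >= 20 & ages < 25] * 0.5
  a <- arriaga(lifetable(m1, ages), lifetable(m2, ages))
  inside <- ages >= 20 & ages < 25
  expect_gt(sum(abs(a$contribution[inside])),
            50 * sum(abs(a$contribution[!inside])))
  expect_equal(sum(a$contribution),
               lifetable(m2, ages)$ex[1] - lifetable(m1, ages)$ex[1],
               tolerance = 1e-10)
})

test_that("hump deletion yields a positive life expectancy gain", {
  surf <- sample_deaths(toy_rates(), exposure = 1e6, seed = 2,
                        noiseless = TRUE)
  fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
  dec <- decompose_hump(surf, fit, c("A", "B", "C"))
  lel <- lel_measures(fit, dec, surf)
  expect_gt(lel$L1, 0)
  expect_lte(lel$L3, lel$L2 + 1e-12)
  # L1 equals the sum of its Arriaga age contributions
  expect_equal(sum(lel$age_contributions$contribution), lel$L1,
               tolerance = 1e-10)
  # shares sum to one within each measure
  shares <- tapply(lel$cause_contributions$share,
                   lel$cause_contributions$measure, sum)
  expect_equal(as.vector(shares), rep(1, 3), tolerance = 1e-6)
})

test_that("a window outside the fitted grid is rejected", {
  surf <- sample_deaths(toy_rates(), exposure = 1e6, seed = 2,
                        noiseless = TRUE)
  fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
  dec <- decompose_hump(surf, fit, c("A", "B"))
  expect_error(lel_measures(fit, dec, surf, window = c(5, 34)), "window")
})
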