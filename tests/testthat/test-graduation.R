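make_gompertz_groups <- function(width = 5, b = 1e-4, theta = 0.1,
                                 exposure = 1e6) {
  ages <- 10:89
  rate <- b * exp(theta * (ages - 10))
  e <- rep(exposure, length(ages))
  lower <- seq(10, 85, by = width)
  bounds <- cbind(lower, lower + width)
  counts <- vapply(seq_len(nrow(bounds)), function(i) {
    sel <- ages >= bounds[i, 1] & ages < bounds[i, 2]
    sum(e[sel] * rate[sel])
  }, numeric(1))
  list(groups = abridged_groups(bounds, counts, e), ages = ages,
       rate = rate)
}

test_that("grouped Gompertz counts graduate back to the generating rates", {
  fx <- make_gompertz_groups()
  out <- graduate_counts(fx$groups)
  win <- fx$ages >= 15 & fx$ages <= 85
  expect_lt(max(abs(out$rate - fx$rate)[win] / fx$rate[win]), 0.02)
})

test_that("graduation preserves the observed group totals", {
  fx <- make_gompertz_groups()
  out <- graduate_counts(fx$groups)
  e <- fx$groups$exposures
  fitted_groups <- vapply(seq_len(nrow(fx$groups$bounds)), function(i) {
    sel <- fx$ages >= fx$groups$bounds[i, 1] &
      fx$ages < fx$groups$bounds[i, 2]
    sum(e[sel] * out$rate[sel])
  }, numeric(1))
  expect_equal(fitted_groups, unname(fx$groups$counts[, 1]),
               tolerance = 0.01)
})

test_that("too few groups are rejected", {
  e <- rep(1e5, 80)
  expect_error(
    graduate_counts(abridged_groups(cbind(10, 90), 1000, e)),
    "insufficient groups")
})

test_that("unit-width groups reproduce a direct penalized fit", {
  ages <- 10:49
  rate <- 2e-4 * exp(0.07 * (ages - 10))
  e <- rep(1e6, 40)
  g <- abridged_groups(cbind(ages, ages + 1L), e * rate, e)
  out <- graduate_counts(g)
  expect_lt(max(abs(out$rate - rate) / rate), 0.02)
})

test_that("an all-zero cause warns and returns floor rates", {
  fx <- make_gompertz_groups()
  g <- fx$groups
  g$counts <- cbind(g$counts, zero = 0)
  expect_warning(out <- graduate_counts(g), "no deaths")
  expect_equal(unique(out$rate[out$cause == "zero"]), 1e-12)
})

test_that("graduation is invariant to a common scaling of counts and exposures", {
  fx1 <- make_gompertz_groups(exposure = 1e5)
  fx2 <- make_gompertz_groups(exposure = 1e6)
  r1 <- graduate_counts(fx1$groups)$rate
  r2 <- graduate_counts(fx2$groups)$rate
  expect_equal(r1, r2, tolerance = 1e-4)
})

test_that("rescaling makes causes sum to the all-cause schedule exactly", {
  ages <- 10:20
  cr <- dplyr::bind_rows(
    tibble::tibble(age = ages, cause = "A", rate = 0.001),
    tibble::tibble(age = ages, cause = "B", rate = 0.001))
  out <- rescale_to_total(cr, rep(0.004, 11))
  expect_equal(out$rate, rep(0.002, 22))

  set.seed(4)
  cr2 <- dplyr::bind_rows(
    tibble::tibble(age = ages, cause = "A", rate = runif(11, 1e-4, 1e-3)),
    tibble::tibble(age = ages, cause = "B", rate = runif(11, 1e-4, 1e-3)))
  tot <- runif(11, 5e-4, 5e-3)
  out2 <- rescale_to_total(cr2, tot)
  sums <- dplyr::summarise(dplyr::group_by(out2, age), s = sum(rate))
  expect_lt(max(abs(sums$s[order(sums$age)] - tot)), 1e-14)

  # identity when already consistent
  out3 <- rescale_to_total(cr, rep(0.002, 11))
  expect_equal(out3$rate, cr$rate)
})

test_that("a zero cause-sum against a positive total is an error", {
  cr <- tibble::tibble(age = c(10, 11), cause = "A", rate = c(0, 1e-3))
  expect_error(rescale_to_total(cr, c(1e-3, 1e-3)), "age\\(s\\): 10")
})
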