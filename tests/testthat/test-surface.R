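test_that("a complete grid round-trips through write and read", {
  df <- cell_grid(10:90, 2000, c("A", "B", "C", "D"),
                  deaths = runif(81 * 4, 0, 50))
  df$exposure <- runif(81, 500, 1500)[match(df$age, 10:90)]
  surf <- rate_surface(df)
  expect_equal(dim(surf$deaths), c(81, 1, 4))

  path <- withr::local_tempfile(fileext = ".csv")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_equal(back$deaths, surf$deaths, tolerance = 1e-11)
  expect_equal(back$exposures, surf$exposures, tolerance = 1e-11)
  expect_identical(back$causes, surf$causes)
})

test_that("missing cells, duplicates and bad values are rejected", {
  df <- cell_grid(10:12, 2000, c("A", "B"))
  expect_error(rate_surface(df[-3, ]), "missing cell")
  expect_error(rate_surface(rbind(df, df[1, ])), "duplicate cell")

  neg <- df
  neg$deaths[4] <- -1
  expect_error(rate_surface(neg), "negative deaths at row 4")

  zero <- df
  zero$exposure[2] <- 0
  expect_error(rate_surface(zero), "nonpositive exposure at row 2")
})

test_that("a total slice must equal the sum of causes", {
  df <- cell_grid(10:12, 2000, c("A", "B"))
  tot <- dplyr::summarise(dplyr::group_by(df, age, year),
                          deaths = sum(deaths), exposure = exposure[1],
                          .groups = "drop")
  tot$cause <- "total"
  ok <- rate_surface(dplyr::bind_rows(df, tot))
  expect_identical(ok$total, "total")

  bad <- tot
  bad$deaths[1] <- bad$deaths[1] + 1
  expect_error(rate_surface(dplyr::bind_rows(df, bad)), "sum to")
})

test_that("as_tibble is the inverse of the constructor", {
  df <- cell_grid(10:15, 2000:2001, c("A", "B"), deaths = rpois(24, 10))
  surf <- rate_surface(df)
  back <- as_tibble(surf)
  merged <- dplyr::left_join(df, back, by = c("age", "year", "cause"))
  expect_equal(merged$deaths.x, merged$deaths.y)
})

test_that("write_results emits the documented tidy layout", {
  surf <- sample_deaths(toy_rates(), exposure = 1e6, seed = 3,
                        noiseless = TRUE)
  fit <- fit_sse(surf, lambdas = REF_LAMBDAS)
  dec <- decompose_hump(surf, fit, c("A", "B", "C"))
  lel <- lel_measures(fit, dec, surf)
  dir <- withr::local_tempdir()
  paths <- write_results(fit, dec, lel, dir)

  contr <- readr::read_csv(paths[["contributions"]], show_col_types = FALSE)
  expect_equal(nrow(contr), 3 * 2 * 81)
  expect_identical(names(contr), c("age", "cause", "component", "delta"))

  lel_df <- readr::read_csv(paths[["lel"]], show_col_types = FALSE)
  shares <- dplyr::summarise(dplyr::group_by(lel_df, measure),
                             s = sum(share))
  expect_true(all(abs(shares$s - 1) < 1e-9))

  empty <- dec
  empty$causes <- character(0)
  expect_error(write_results(fit, empty, lel, dir), "no causes")
})

test_that("HMD-style Mx_1x1 layout is parsed into a tidy rate table", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Toy population, Death rates (period 1x1)", "",
    "  Year          Age             Female            Male           Total",
    "  2000           10             0.000100        0.000200        0.000150",
    "  2000           11             0.000110        0.000210        0.000160",
    "  2000         110+             0.700000        .               0.650000"
  ), path)
  tab <- read_hmd_rates(path)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$rate[tab$age == 10 & tab$sex == "male"], 2e-4)
  expect_equal(unique(tab$age), c(10L, 11L, 110L))
  expect_true(is.na(tab$rate[tab$age == 110 & tab$sex == "male"]))
})
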