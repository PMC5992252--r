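#' Parameters of the four-cause synthetic example
#'
#' Returns the default parameter set of the packaged synthetic example:
#' four causes of death on ages 10-90 whose sum shows a clear young adult
#' hump over a Gompertz background. Causes A, B and C carry a hump; cause D
#' is pure Gompertz. Each cause is built from three nonnegative pieces:
#' a log-Gaussian bump `h * exp(-(x - p)^2 / (2 s^2))`, a plateau that
#' switches on through a logistic ramp
#' `level / (1 + exp(-(x - onset) / ramp))`, and a Gompertz trend
#' `b * exp(theta * (x - 10))`.
#'
#' Qualitatively: cause A has a marked but small hump around age 24 and
#' near-zero mortality elsewhere; cause B has a higher and much wider hump
#' plus a stable plateau after age 40; cause C combines an early, narrow
#' hump (leading cause in the teens) with a Gompertz trend; cause D is the
#' leading cause from the late twenties onward and lies above cause A at
#' every age.
#'
#' @param ... Named overrides; each cause entry is a list with fields
#'   `h`, `p`, `s` (hump), `plateau`, `onset`, `ramp`, `b`, `theta`
#'   (background). Top-level fields: `ages`, `exposure`, `causes`.
#' @return An object of class `toy_params`.
#' @examples
#' p <- toy_params()
#' names(p$causes)
#' @export
toy_params <- function(...) {
  p <- list(
    ages = 10:90,
    exposure = 1e5,
    causes = list(
      A = list(h = 6e-5, p = 24, s = 5, plateau = 0, onset = 40, ramp = 4,
               b = 1.5e-6, theta = 0.045),
      B = list(h = 1.4e-4, p = 23, s = 8, plateau = 6e-5, onset = 35,
               ramp = 4, b = 0, theta = 0),
      C = list(h = 1.1e-4, p = 18, s = 4, plateau = 0, onset = 40,
               ramp = 4, b = 2e-5, theta = 0.07),
      D = list(h = 0, p = 20, s = 5, plateau = 0, onset = 40, ramp = 4,
               b = 3e-5, theta = 0.08)
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "causes") {
      for (cn in names(dots$causes)) {
        p$causes[[cn]] <- utils::modifyList(p$causes[[cn]] %||% list(),
                                            dots$causes[[cn]])
      }
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  bad <- vapply(p$causes, function(cp) {
    any(unlist(cp[c("h", "s", "plateau", "ramp", "b")]) < 0)
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("negative level parameters for cause(s): %s",
                  paste(names(bad)[bad], collapse = ", ")))
  }
  structure(p, class = "toy_params")
}

#' True cause-specific rate schedules of the synthetic example
#'
#' Evaluates the generating rate schedules of [toy_params()] on the age
#' grid, split into the hump piece and the background (plateau + Gompertz)
#' piece, so downstream tests can compare estimated contributions against
#' the construction truth.
#'
#' @param params A [toy_params()] object (defaults used when omitted).
#' @return A tibble with columns `age`, `cause`, `hump`, `background`,
#'   `rate` (`= hump + background`).
#' @examples
#' rates <- toy_rates()
#' head(rates)
#' @export
toy_rates <- function(params = toy_params()) {
  stopifnot(inherits(params, "toy_params"))
  x <- params$ages
  purrr::imap(params$causes, function(cp, nm) {
    hump <- cp$h * exp(-(x - cp$p)^2 / (2 * cp$s^2))
    plateau <- cp$plateau / (1 + exp(-(x - cp$onset) / cp$ramp))
    gompertz <- cp$b * exp(cp$theta * (x - min(x)))
    tibble(age = x, cause = nm, hump = hump,
           background = plateau + gompertz,
           rate = hump + plateau + gompertz)
  }) |>
    dplyr::bind_rows()
}

#' Draw a death-count surface from known rate schedules
#'
#' Samples deaths as independent Poisson counts
#' `deaths ~ Poisson(exposure * rate)` per age and cause, and assembles a
#' [rate_surface()] including an exact `"total"` slice (sum over causes).
#' With `noiseless = TRUE` the expected counts are returned unchanged,
#' which is the fixture used by the exact-recovery tests.
#'
#' @param rates A tibble with columns `age`, `cause`, `rate` (such as
#'   [toy_rates()] output), optionally a `year` column for multi-year
#'   surfaces.
#' @param exposure Person-years of exposure per single age (scalar or
#'   vector over ages). Default `1e5`.
#' @param seed Integer seed for reproducibility; `NULL` leaves the random
#'   number generator state alone.
#' @param noiseless If `TRUE`, deaths are set to their expectations.
#' @param year Calendar year label used when `rates` has no `year` column.
#' @return A `rate_surface` with the sampled (or expected) deaths.
#' @examples
#' surf <- sample_deaths(toy_rates(), seed = 42)
#' surf
#' @export
sample_deaths <- function(rates, exposure = 1e5, seed = NULL,
                          noiseless = FALSE, year = 2000L) {
  stopifnot(all(c("age", "cause", "rate") %in% names(rates)))
  if (any(exposure <= 0)) abort("`exposure` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  if (!"year" %in% names(rates)) rates$year <- year

  df <- rates |>
    dplyr::arrange(.data$year, .data$cause, .data$age) |>
    dplyr::group_by(.data$year, .data$cause) |>
    dplyr::mutate(exposure = rep_len(.env$exposure, dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::mutate(expected = .data$exposure * .data$rate)
  df$deaths <- if (noiseless) df$expected else rpois(nrow(df), df$expected)

  totals <- df |>
    dplyr::group_by(.data$age, .data$year) |>
    dplyr::summarise(deaths = sum(.data$deaths),
                     exposure = .data$exposure[1], .groups = "drop") |>
    dplyr::mutate(cause = "total")
  rate_surface(dplyr::bind_rows(
    dplyr::select(df, "age", "year", "cause", "deaths", "exposure"),
    dplyr::select(totals, "age", "year", "cause", "deaths", "exposure")
  ))
}

#' Multi-year synthetic surface with drifting hump intensities
#'
#' Extends the four-cause example over several calendar years by scaling
#' each cause's hump height with a smooth period trend (a sinusoid with a
#' cause-specific phase, amplitude `trend`), which gives the cause
#' screening step year-to-year variation to summarise.
#'
#' @param params A [toy_params()] object.
#' @param n_years Number of consecutive years (first year 2000).
#' @param trend Relative amplitude of the hump-height trend. Default 0.3.
#' @param seed,exposure,noiseless Passed to [sample_deaths()].
#' @return A `rate_surface` with `n_years` years.
#' @export
simulate_toy_surface <- function(params = toy_params(), n_years = 20,
                                 trend = 0.3, seed = NULL,
                                 exposure = params$exposure,
                                 noiseless = FALSE) {
  stopifnot(n_years >= 1)
  hump_causes <- names(params$causes)[
    vapply(params$causes, function(cp) cp$h > 0, logical(1))]
  years <- seq(2000L, length.out = n_years)
  rates <- purrr::map(seq_along(years), function(t) {
    pt <- params
    phase <- 0
    for (cn in hump_causes) {
      fac <- 1 + trend * sin(2 * pi * (t - 1) / max(n_years - 1, 1) + phase)
      pt$causes[[cn]]$h <- pt$causes[[cn]]$h * max(fac, 0)
      phase <- phase + pi / 2
    }
    dplyr::mutate(toy_rates(pt), year = years[t])
  }) |>
    dplyr::bind_rows()
  sample_deaths(rates, exposure = exposure, seed = seed,
                noiseless = noiseless)
}
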