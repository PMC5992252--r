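# Shared fixtures: closed-form schedules with known components, so every
# fitting test can compare against its generator.

AGES <- 10:90

# reference smoothing for noiseless validation fits: light on the hump,
# heavy on senescence (see the methods vignette)
REF_LAMBDAS <- c(1e3, 1e7)

# marked young adult hump over a Gompertz background (rates per person-year)
gompertz_hump <- function(ages = AGES, b = 1e-4, theta = 0.1,
                          h = 8e-4, p = 22, s = 5) {
  gS <- b * exp(theta * (ages - min(ages)))
  gH <- h * exp(-(ages - p)^2 / (2 * s^2))
  list(ages = ages, gS = gS, gH = gH, total = gS + gH)
}

# single-year data frame for fit_sse
hump_frame <- function(fx, exposure, deaths = NULL) {
  data.frame(age = fx$ages,
             deaths = deaths %||% (exposure * fx$total),
             exposure = rep_len(exposure, length(fx$ages)))
}

# surface tibble builder for io tests
cell_grid <- function(ages, years, causes, deaths = 5, exposure = 1000) {
  df <- tidyr::expand_grid(age = ages, year = years, cause = causes)
  df$deaths <- rep_len(deaths, nrow(df))
  df$exposure <- rep_len(exposure, nrow(df))
  df
}

# clean additive four-cause fixture (no plateau): per-cause truth =
# log-Gaussian hump + Gompertz background
clean_toy_params <- function() {
  toy_params(causes = list(B = list(plateau = 0, b = 1e-5, theta = 0.06)))
}

`%||%` <- rlang::`%||%`
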