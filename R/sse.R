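#' Fit the two-component sum-of-smooth-exponentials model
#'
#' Decomposes the force of mortality on a single-age grid into a log-concave
#' young adult hump and a monotone nondecreasing senescence component. The
#' observed deaths are modelled as Poisson counts with composed mean
#' `E %*% gamma_H + E %*% gamma_S`, where `E = diag(exposures)` and each
#' component is `exp(B %*% beta)` on an equally spaced B-spline basis with a
#' difference penalty. Shape constraints are enforced through iteratively
#' reweighted asymmetric penalties on coefficient differences, which makes
#' the two components identifiable (the hump cannot absorb the monotone
#' rise, nor the senescence curve the bump).
#'
#' @param data A [rate_surface()] (the all-cause slice of `year` is used) or
#'   a data frame with columns `age`, `deaths`, `exposure` for one period.
#' @param year Calendar year to extract when `data` is a surface; defaults
#'   to the first year.
#' @param lambdas Numeric pair `c(hump, senescence)` of smoothing weights.
#'   When `NULL` (default) they are chosen by BIC over the two grids via
#'   [select_lambdas()].
#' @param lambda_grid_H,lambda_grid_S Candidate smoothing weights for the
#'   hump and senescence components. The senescence grid is deliberately
#'   heavier: strong smoothing of the senescence log-curve (which drives it
#'   towards log-linearity unless the data demand otherwise) is what
#'   identifies the split between the components in directions where the
#'   likelihood alone cannot allocate mass.
#' @param hump_mass Weight of the linear tie-break penalty
#'   `hump_mass * sum(e * gamma_H)` that resolves residual allocation
#'   indeterminacy by preferring the decomposition with the smallest hump
#'   mass (the hump as *minimal* excess over the senescent background).
#'   The default `1e-3` is orders of magnitude below the likelihood
#'   curvature wherever the data identify the hump.
#' @param knot_spacing,degree B-spline knot spacing in years and spline
#'   degree. Defaults 2 and 3 (cubic).
#' @param order Difference-penalty order per component, recycled to length
#'   2 as `c(hump, senescence)`. The default `c(3, 2)` shrinks the hump's
#'   log-curve towards a quadratic (a Gaussian-shaped bump) and the
#'   senescence log-curve towards a straight Gompertz line under heavy
#'   smoothing, while leaving both free where the data push back.
#' @param shape_weight Starting weight of the asymmetric shape penalties;
#'   escalated automatically until residual violations are negligible.
#' @param weights Optional per-age regression weights (default 1).
#' @param max_iter,tol IRLS iteration cap and relative coefficient-change
#'   convergence tolerance.
#'
#' @return An object of class `sse_fit` with elements `ages`, `gamma_H`,
#'   `gamma_S` (component rate schedules), `beta_H`, `beta_S`, `mu_hat`
#'   (`= gamma_H + gamma_S`), `dhat_H`, `dhat_S` (expected deaths per
#'   component), `lambdas`, `deviance`, `ed` (effective dimension), `bic`,
#'   `converged`, `iterations`, plus the bases and data used.
#' @examples
#' surf <- sample_deaths(toy_rates(), exposure = 1e5, seed = 1)
#' fit <- fit_sse(surf, lambdas = c(100, 100))
#' glance(fit)
#' @export
fit_sse <- function(data, year = NULL, lambdas = NULL,
                    lambda_grid_H = 10^(2:6), lambda_grid_S = 10^(4:8),
                    knot_spacing = 2, degree = 3,
                    order = c(3, 2), shape_weight = 1e6, hump_mass = 1e-3,
                    weights = NULL, max_iter = 200L, tol = 1e-6) {
  inp <- sse_inputs(data, year)
  if (is.null(lambdas)) {
    sel <- select_lambdas(data, year = year, lambda_grid_H = lambda_grid_H,
                          lambda_grid_S = lambda_grid_S,
                          knot_spacing = knot_spacing, degree = degree,
                          order = order, shape_weight = shape_weight,
                          hump_mass = hump_mass, weights = weights)
    lambdas <- c(sel$lambda_H, sel$lambda_S)
  }
  fit_sse_vec(inp$deaths, inp$exposures, inp$ages, lambdas = lambdas,
              knot_spacing = knot_spacing, degree = degree, order = order,
              shape_weight = shape_weight, hump_mass = hump_mass,
              weights = weights, max_iter = max_iter, tol = tol)
}

# normalize fit_sse inputs to vectors
sse_inputs <- function(data, year = NULL) {
  if (inherits(data, "rate_surface")) {
    year <- year %||% data$years[1]
    list(deaths = surface_total_deaths(data, year),
         exposures = surface_exposures(data, year),
         ages = data$ages)
  } else if (is.data.frame(data)) {
    req <- c("age", "deaths", "exposure")
    if (!all(req %in% names(data))) {
      abort("`data` needs columns age, deaths, exposure.")
    }
    data <- dplyr::arrange(data, .data$age)
    list(deaths = data$deaths, exposures = data$exposure,
         ages = as.integer(data$age))
  } else {
    abort("`data` must be a rate_surface or a data frame.")
  }
}

# vector-interface workhorse behind fit_sse()
fit_sse_vec <- function(deaths, exposures, ages, lambdas,
                        knot_spacing = 2, degree = 3, order = c(3, 2),
                        shape_weight = 1e6, hump_mass = 1e-3,
                        weights = NULL, max_iter = 200L, tol = 1e-6) {
  m <- length(ages)
  stopifnot(length(deaths) == m, length(exposures) == m)
  if (any(deaths < 0)) abort("negative deaths.")
  if (any(exposures <= 0)) abort("nonpositive exposures.")
  if (any(diff(ages) != 1)) abort("ages must be single years of age.")
  lambdas <- rep_len(lambdas, 2)
  order <- rep_len(order, 2)

  basis <- bspline_basis(ages, knot_spacing, degree)
  blocks <- list(
    H = list(X = basis$B,
             penalty = penalty_bundle(lambdas[1], order[1], "log_concave",
                                      shape_weight),
             mass_w = hump_mass * exposures),
    S = list(X = basis$B,
             penalty = penalty_bundle(lambdas[2], order[2],
                                      "monotone_increasing", shape_weight))
  )
  E <- Matrix::Diagonal(x = exposures)
  C <- cbind(E, E)
  beta0 <- sse_init(deaths, exposures, ages, basis, lambdas, order)

  res <- clm_fit(deaths, C, blocks, prior_w = weights %||% 1,
                 beta_init = c(beta0$H, beta0$S),
                 max_iter = max_iter, tol = tol)

  gamma_H <- res$gamma_blocks[[1]]
  gamma_S <- res$gamma_blocks[[2]]
  structure(
    list(ages = ages, deaths = deaths, exposures = exposures,
         gamma_H = gamma_H, gamma_S = gamma_S,
         beta_H = res$beta_blocks[[1]], beta_S = res$beta_blocks[[2]],
         mu_hat = gamma_H + gamma_S,
         dhat_H = exposures * gamma_H, dhat_S = exposures * gamma_S,
         lambdas = setNames(lambdas, c("hump", "senescence")),
         deviance = res$deviance, ed = res$ed,
         bic = res$deviance + log(m) * res$ed,
         converged = res$converged, iterations = res$iterations,
         objective_trace = res$objective_trace,
         basis = basis, order = order, hump_mass = hump_mass,
         shape_weights = res$shape_weights),
    class = "sse_fit"
  )
}

# deterministic initialization: Gompertz tail fit for senescence, smoothed
# log residual for the hump
sse_init <- function(deaths, exposures, ages, basis, lambdas, order) {
  order <- rep_len(order, 2)
  rate <- pmax(deaths, 0.5) / exposures
  tail_from <- max(min(ages), min(55, stats::quantile(ages, 0.6)))
  sel <- ages >= tail_from
  fit <- lm(log(rate[sel]) ~ ages[sel])
  gamma_S0 <- pmin(exp(coef(fit)[1] + coef(fit)[2] * ages), exp(ETA_CAP))
  resid <- pmax(deaths / exposures - gamma_S0, 1e-12)
  pls <- function(y, lambda, ord) {
    D <- difference_matrix(ncol(basis$B), ord)
    drop(solve(crossprod(basis$B) + lambda * crossprod(D) +
                 diag(1e-6, ncol(basis$B)),
               crossprod(basis$B, y)))
  }
  list(H = pls(log(resid), lambdas[1], order[1]),
       S = pls(log(gamma_S0), lambdas[2], order[2]))
}

#' Choose smoothing weights for the two components by BIC
#'
#' Runs [fit_sse()] over a two-dimensional grid of smoothing weights and
#' returns the pair minimising `BIC = deviance + log(m) * ed`, where `ed`
#' is the effective model dimension. Ties are broken deterministically in
#' favour of the heavier smoothing.
#'
#' @inheritParams fit_sse
#' @return A list with `lambda_H`, `lambda_S`, `bic`, and `table`, a tibble
#'   of all grid evaluations.
#' @export
select_lambdas <- function(data, year = NULL, lambda_grid_H = 10^(2:6),
                           lambda_grid_S = 10^(4:8),
                           knot_spacing = 2, degree = 3, order = c(3, 2),
                           shape_weight = 1e6, hump_mass = 1e-3,
                           weights = NULL) {
  if (length(lambda_grid_H) == 0 || length(lambda_grid_S) == 0) {
    abort("empty lambda grid.")
  }
  inp <- sse_inputs(data, year)
  grid <- tidyr::expand_grid(lambda_H = sort(lambda_grid_H),
                             lambda_S = sort(lambda_grid_S))
  evals <- purrr::pmap(grid, function(lambda_H, lambda_S) {
    f <- fit_sse_vec(inp$deaths, inp$exposures, inp$ages,
                     lambdas = c(lambda_H, lambda_S),
                     knot_spacing = knot_spacing, degree = degree,
                     order = order, shape_weight = shape_weight,
                     hump_mass = hump_mass, weights = weights)
    tibble(lambda_H = lambda_H, lambda_S = lambda_S, deviance = f$deviance,
           ed = f$ed, bic = f$bic, converged = f$converged)
  })
  tab <- dplyr::bind_rows(evals)
  ok <- which(is.finite(tab$bic))
  if (!length(ok)) abort("no usable fit on the lambda grid.")
  best <- tab[ok[1], ]
  for (i in ok) {
    if (tab$bic[i] <= best$bic + 1e-9) {
      best <- tab[i, ]
    }
  }
  list(lambda_H = best$lambda_H, lambda_S = best$lambda_S, bic = best$bic,
       table = tab)
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<sse_fit> ages %d-%d, lambda (H, S) = (%g, %g), deviance %.2f,",
           " ed %.1f, %s in %d iterations\n"),
    min(x$ages), max(x$ages), x$lambdas[1], x$lambdas[2], x$deviance, x$ed,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  hump deaths %.1f (%.1f%% of expected deaths)\n",
              sum(x$dhat_H), 100 * sum(x$dhat_H) / sum(x$dhat_H + x$dhat_S)))
  invisible(x)
}

#' Tidy the fitted component schedules
#'
#' @param x An `sse_fit`.
#' @param ... Unused.
#' @return A tibble with one row per age and component (`hump`,
#'   `senescence`, `total`): columns `age`, `component`, `rate`,
#'   `expected_deaths`, plus the observed `rate_observed` for `total`.
#' @export
tidy.sse_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(age = x$ages, component = "hump", rate = x$gamma_H,
           expected_deaths = x$dhat_H, rate_observed = NA_real_),
    tibble(age = x$ages, component = "senescence", rate = x$gamma_S,
           expected_deaths = x$dhat_S, rate_observed = NA_real_),
    tibble(age = x$ages, component = "total", rate = x$mu_hat,
           expected_deaths = x$dhat_H + x$dhat_S,
           rate_observed = x$deaths / x$exposures)
  )
}

#' One-row fit summary
#'
#' @param x An `sse_fit`.
#' @param ... Unused.
#' @return A one-row tibble: smoothing weights, deviance, effective
#'   dimension, BIC, convergence, iteration count, total hump deaths and
#'   the hump share of expected deaths.
#' @export
glance.sse_fit <- function(x, ...) {
  tibble(lambda_H = x$lambdas[[1]], lambda_S = x$lambdas[[2]],
         deviance = x$deviance, ed = x$ed, bic = x$bic,
         converged = x$converged, iterations = x$iterations,
         hump_deaths = sum(x$dhat_H),
         hump_share = sum(x$dhat_H) / sum(x$dhat_H + x$dhat_S))
}

#' Plot an SSE fit on the log-rate scale
#'
#' @param object An `sse_fit`.
#' @param ... Unused.
#' @return A ggplot: observed rates as points, fitted total and the two
#'   components as lines.
#' @export
autoplot.sse_fit <- function(object, ...) {
  td <- tidy(object)
  obs <- dplyr::filter(td, .data$component == "total")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$rate_observed),
                        shape = 1, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate,
                                    colour = .data$component,
                                    linetype = .data$component)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age", y = "force of mortality (log scale)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
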