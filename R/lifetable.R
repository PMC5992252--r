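#' Period life table from single-age death rates
#'
#' Standard single-age period life table with radix 1 and `a_x = 0.5`
#' person-years lived on average by those dying in an interval (adequate
#' for ages 10 and above; no infant correction is attempted). The last age
#' is treated as an open interval: `q = 1` and `L = l / m` (exponential
#' closure), or `L = 0` when the closing rate is zero.
#'
#' @param rates Nonnegative central death rates `m_x`, one per age, or a
#'   data frame with columns `age` and `rate` (or `mx`).
#' @param ages Integer ages matching `rates` (ignored when `rates` is a
#'   data frame carrying its own ages).
#' @param a Average fraction of the interval lived by decedents,
#'   default 0.5.
#' @return A tibble of class `lifetable` with columns `age`, `mx`, `ax`,
#'   `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @examples
#' lt <- lifetable(rep(0.05, 101), 10:110)
#' lt$ex[1] # close to 1 / 0.05 = 20 years
#' @export
lifetable <- function(rates, ages = NULL, a = 0.5) {
  if (is.data.frame(rates)) {
    nm <- intersect(c("rate", "mx"), names(rates))[1]
    if (is.na(nm) || !"age" %in% names(rates)) {
      abort("`rates` data frame needs columns age and rate (or mx).")
    }
    rates <- dplyr::arrange(rates, .data$age)
    ages <- rates$age
    rates <- rates[[nm]]
  }
  if (is.null(ages)) ages <- seq_along(rates)
  n <- length(rates)
  stopifnot(length(ages) == n)
  if (any(rates < 0)) abort("negative death rate.")

  ax <- rep(a, n)
  qx <- pmin(rates / (1 + (1 - ax) * rates), 1)
  qx[n] <- 1
  lx <- cumprod(c(1, 1 - qx[-n]))
  dx <- lx * qx
  Lx <- lx - (1 - ax) * dx
  Lx[n] <- if (rates[n] > 0) lx[n] / rates[n] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  structure(
    tibble(age = ages, mx = rates, ax = ax, qx = qx, lx = lx, dx = dx,
           Lx = Lx, Tx = Tx, ex = ex),
    class = c("lifetable", class(tibble())))
}

#' Life expectancy lost to a set of deaths
#'
#' Gain in life expectancy at the base age under a counterfactual rate
#' schedule: `e(counterfactual) - e(observed)`. A counterfactual that
#' exceeds the observed rates at some age (possible when contributions are
#' slightly negative) triggers a warning, not an error; counterfactual
#' rates below zero are floored at zero with a warning.
#'
#' @param observed,counterfactual Rate vectors on the same age grid, or
#'   data frames with `age` and `rate` columns.
#' @param ages Ages for vector input.
#' @param base_age Age at which life expectancy is evaluated; default the
#'   first age of the grid.
#' @return Years of life expectancy gained (a scalar).
#' @export
life_expectancy_lost <- function(observed, counterfactual, ages = NULL,
                                 base_age = NULL) {
  get_vec <- function(x) {
    if (is.data.frame(x)) {
      x <- dplyr::arrange(x, .data$age)
      list(rate = x$rate, age = x$age)
    } else {
      list(rate = x, age = ages %||% seq_along(x))
    }
  }
  obs <- get_vec(observed)
  cf <- get_vec(counterfactual)
  if (!identical(as.numeric(obs$age), as.numeric(cf$age))) {
    abort("observed and counterfactual are on different age grids.")
  }
  if (any(cf$rate > obs$rate + 1e-12)) {
    warn("counterfactual rates exceed observed rates at some ages.")
  }
  if (any(cf$rate < 0)) {
    warn("negative counterfactual rates floored at zero.")
    cf$rate <- pmax(cf$rate, 0)
  }
  base_age <- base_age %||% obs$age[1]
  bi <- match(base_age, obs$age)
  if (is.na(bi)) abort("`base_age` not on the age grid.")
  lifetable(cf$rate, cf$age)$ex[bi] - lifetable(obs$rate, obs$age)$ex[bi]
}

#' Arriaga decomposition of a life expectancy difference by age
#'
#' Splits `e(counterfactual) - e(observed)` at the base age into additive
#' age contributions combining the direct effect (person-years gained
#' within the age interval) and the indirect/interaction effect (survivors
#' reaching later ages). The symmetrical form -- the average of the
#' decomposition computed in both directions -- is used, so contributions
#' are antisymmetric under swapping the two tables and still sum exactly
#' to the life expectancy difference.
#'
#' @param lt_obs,lt_cf [lifetable()]s on the same age grid with equal
#'   radix.
#' @param symmetric Average the two directions (default `TRUE`); `FALSE`
#'   gives the one-directional classic formula.
#' @return A tibble with columns `age` and `contribution`, summing to the
#'   difference in `ex` at the first age.
#' @export
arriaga <- function(lt_obs, lt_cf, symmetric = TRUE) {
  stopifnot(inherits(lt_obs, "lifetable"), inherits(lt_cf, "lifetable"))
  if (!identical(as.numeric(lt_obs$age), as.numeric(lt_cf$age))) {
    abort("life tables are on different age grids.")
  }
  one_way <- function(l1, l2) {
    n <- nrow(l1)
    safe <- function(num, den) ifelse(den > 0, num / den, 0)
    direct <- l1$lx * (safe(l2$Lx, l2$lx) - safe(l1$Lx, l1$lx))
    indirect <- c(l2$Tx[-1] * (safe(l1$lx, l2$lx)[-n] -
                                 safe(l1$lx[-1], l2$lx[-1])), 0)
    contrib <- direct + indirect
    contrib[n] <- l1$lx[n] * (safe(l2$Tx[n], l2$lx[n]) -
                                safe(l1$Tx[n], l1$lx[n]))
    contrib
  }
  contribution <- if (symmetric) {
    (one_way(lt_obs, lt_cf) - one_way(lt_cf, lt_obs)) / 2
  } else {
    one_way(lt_obs, lt_cf)
  }
  tibble(age = lt_obs$age, contribution = contribution)
}

#' Life expectancy lost to the hump and to young adult deaths
#'
#' Computes the three deletion-based summaries used to size the young
#' adult mortality hump and contrasts them with fixed-age-window measures:
#'
#' * `L1`: delete the hump only -- counterfactual rates
#'   `mu - sum_k delta_H^k` from the cause decomposition;
#' * `L2`: delete all deaths in the age window (rates zeroed on
#'   `window`);
#' * `L3`: delete the selected causes' observed deaths in the window.
#'
#' `L3 <= L2` by construction. Each measure is split into cause
#' contributions: `L1` by applying the Arriaga decomposition to each
#' cause's hump contribution and rescaling so the cause shares sum to one
#' (residual interaction spread proportionally to the main effects); `L2`
#' and `L3` by prorating the Arriaga age contributions across causes in
#' proportion to each cause's share of the deleted rate at that age.
#'
#' @param fit The all-cause [fit_sse()].
#' @param dec The [decompose_hump()] result for the selected causes.
#' @param surface The [rate_surface()] holding observed cause-specific
#'   deaths.
#' @param window Age window for `L2`/`L3`, default `c(10, 34)`.
#' @param year Surface year; defaults to the decomposition's year.
#' @param base_age Age at which life expectancy is evaluated; default the
#'   lower bound of the fitted grid.
#' @return An object of class `lel_result` with fields `L1`, `L2`, `L3`
#'   (years), `age_contributions` (tibble, Arriaga split of `L1`),
#'   `cause_contributions` (tibble `measure`, `cause`, `years`, `share`),
#'   `window`, `base_age`.
#' @export
lel_measures <- function(fit, dec, surface, window = c(10, 34),
                         year = NULL, base_age = NULL) {
  stopifnot(inherits(fit, "sse_fit"), inherits(dec, "cause_decomposition"),
            inherits(surface, "rate_surface"))
  year <- year %||% dec$year %||% surface$years[1]
  ages <- fit$ages
  if (window[1] < min(ages) || window[2] > max(ages)) {
    abort("age window outside the fitted age grid.")
  }
  base_age <- base_age %||% min(ages)
  bi <- match(base_age, ages)
  e <- surface_exposures(surface, year)
  obs <- surface_total_deaths(surface, year) / e
  lt_obs <- lifetable(obs, ages)
  in_win <- ages >= window[1] & ages <= window[2]
  lel_of <- function(cf) {
    unname(lifetable(pmax(cf, 0), ages)$ex[bi] - lt_obs$ex[bi])
  }

  # L1: hump-only deletion
  hump <- rowSums(dec$delta_H)
  if (any(hump < 0)) {
    warn("negative hump contributions at some ages; deleted as computed.")
  }
  cf1 <- pmax(obs - hump, 0)
  L1 <- lel_of(cf1)
  age_contrib <- arriaga(lt_obs, lifetable(cf1, ages))

  # L2 / L3: window deletions
  cf2 <- ifelse(in_win, 0, obs)
  L2 <- lel_of(cf2)
  yi <- match(year, surface$years)
  sel_rate <- rowSums(sapply(dec$causes, function(k)
    surface$deaths[, yi, k])) / e
  cf3 <- ifelse(in_win, pmax(obs - sel_rate, 0), obs)
  L3 <- lel_of(cf3)

  # cause shares of L1: per-cause Arriaga deletions, interaction residual
  # spread proportionally so shares sum to one
  main <- vapply(dec$causes, function(k) {
    sum(arriaga(lt_obs, lifetable(pmax(obs - dec$delta_H[, k], 0),
                                  ages))$contribution)
  }, numeric(1))
  l1_years <- if (sum(abs(main)) > 0) main * (L1 / sum(main)) else main
  cc1 <- tibble(measure = "L1", cause = dec$causes, years = l1_years,
                share = if (abs(L1) > 0) l1_years / L1 else 0)

  # cause shares of L2 and L3: age-wise proration of the Arriaga split
  prorate <- function(measure, cf, rate_by_cause, total_deleted) {
    ag <- arriaga(lt_obs, lifetable(cf, ages))$contribution
    yrs <- vapply(colnames(rate_by_cause), function(k) {
      w <- ifelse(total_deleted > 0, rate_by_cause[, k] / total_deleted, 0)
      sum(ag * w)
    }, numeric(1))
    if (abs(sum(yrs)) > 0) yrs <- yrs * (sum(ag) / sum(yrs))
    tibble(measure = measure, cause = colnames(rate_by_cause), years = yrs,
           share = if (abs(sum(yrs)) > 0) yrs / sum(yrs) else 0)
  }
  all_causes <- surface_causes(surface)
  rate_all <- sapply(all_causes, function(k) {
    ifelse(in_win, surface$deaths[, yi, k] / e, 0)
  })
  cc2 <- prorate("L2", cf2, rate_all, ifelse(in_win, obs, 0))
  rate_sel <- sapply(dec$causes, function(k) {
    ifelse(in_win, surface$deaths[, yi, k] / e, 0)
  })
  cc3 <- prorate("L3", cf3, rate_sel,
                 ifelse(in_win, pmin(sel_rate, obs), 0))

  structure(
    list(L1 = L1, L2 = L2, L3 = L3,
         age_contributions = age_contrib,
         cause_contributions = dplyr::bind_rows(cc1, cc2, cc3),
         window = window, base_age = base_age, year = year),
    class = "lel_result"
  )
}

#' @export
print.lel_result <- function(x, ...) {
  cat(sprintf(
    "<lel_result> at age %s: L1 (hump) %.3f y, L2 (ages %d-%d) %.3f y, L3 (selected causes) %.3f y\n",
    x$base_age, x$L1, x$window[1], x$window[2], x$L2, x$L3))
  invisible(x)
}

#' Tidy life-expectancy-lost measures
#'
#' @param x An `lel_result`.
#' @param ... Unused.
#' @return A tibble with columns `measure`, `cause`, `years`, `share`;
#'   cause shares sum to one within each measure.
#' @export
tidy.lel_result <- function(x, ...) {
  x$cause_contributions
}

#' @export
glance.lel_result <- function(x, ...) {
  tibble(L1 = x$L1, L2 = x$L2, L3 = x$L3, base_age = x$base_age,
         window_lower = x$window[1], window_upper = x$window[2])
}

#' Plot life-expectancy-lost cause shares
#'
#' @param object An `lel_result`.
#' @param ... Unused.
#' @return A ggplot comparing cause shares across the three measures.
#' @export
autoplot.lel_result <- function(object, ...) {
  ggplot2::ggplot(object$cause_contributions,
                  ggplot2::aes(x = .data$measure, y = .data$share,
                               fill = .data$cause)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of life expectancy lost",
                  fill = "cause") +
    ggplot2::theme_minimal()
}
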