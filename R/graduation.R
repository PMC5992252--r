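#' Abridged age-group death counts with single-age exposures
#'
#' Container for grouped (abridged) cause-specific death counts destined
#' for [graduate_counts()]. Groups are half-open `[lower, upper)` integer
#' intervals that tile the target age range without gaps or overlaps;
#' exposures are known at single ages.
#'
#' @param bounds Two-column matrix or data frame of `(lower, upper)` age
#'   bounds, one row per group.
#' @param counts Numeric matrix (groups x causes) or vector of nonnegative
#'   death counts.
#' @param exposures Positive exposures at single ages `lower(1) ..
#'   upper(last) - 1`.
#' @return An object of class `abridged_groups`.
#' @export
abridged_groups <- function(bounds, counts, exposures) {
  bounds <- as.matrix(bounds)
  storage.mode(bounds) <- "integer"
  if (ncol(bounds) != 2) abort("`bounds` needs two columns (lower, upper).")
  o <- order(bounds[, 1])
  bounds <- bounds[o, , drop = FALSE]
  counts <- as.matrix(counts)
  counts <- counts[o, , drop = FALSE]
  if (any(bounds[, 2] <= bounds[, 1])) abort("empty age group.")
  if (nrow(bounds) > 1 &&
      any(bounds[-1, 1] != bounds[-nrow(bounds), 2])) {
    abort("age groups must tile the range with no gaps or overlaps.")
  }
  ages <- seq.int(bounds[1, 1], bounds[nrow(bounds), 2] - 1L)
  if (length(exposures) != length(ages)) {
    abort(sprintf("need %d single-age exposures for ages %d-%d.",
                  length(ages), min(ages), max(ages)))
  }
  if (any(exposures <= 0)) abort("nonpositive exposure.")
  if (any(counts < 0)) abort("negative counts.")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("cause", seq_len(ncol(counts)))
  }
  structure(list(bounds = bounds, counts = counts,
                 exposures = as.numeric(exposures), ages = ages),
            class = "abridged_groups")
}

# tidy CSV layout: age_lower, age_upper, cause, deaths, exposure
# (group exposure is spread uniformly over the single ages of the group)
abridged_from_tidy <- function(df) {
  req <- c("age_lower", "age_upper", "cause", "deaths", "exposure")
  if (!all(req %in% names(df))) {
    abort("abridged input needs columns age_lower, age_upper, cause, deaths, exposure.")
  }
  wide <- tidyr::pivot_wider(df, id_cols = c("age_lower", "age_upper"),
                             names_from = "cause", values_from = "deaths")
  wide <- dplyr::arrange(wide, .data$age_lower)
  expo <- df |>
    dplyr::distinct(.data$age_lower, .data$age_upper, .data$exposure) |>
    dplyr::arrange(.data$age_lower)
  single_e <- unlist(purrr::pmap(expo, function(age_lower, age_upper,
                                               exposure) {
    n <- age_upper - age_lower
    rep(exposure / n, n)
  }))
  abridged_groups(wide[c("age_lower", "age_upper")],
                  as.matrix(wide[setdiff(names(wide),
                                         c("age_lower", "age_upper"))]),
                  single_e)
}

#' @export
print.abridged_groups <- function(x, ...) {
  cat(sprintf("<abridged_groups> %d groups on ages %d-%d, %d cause(s)\n",
              nrow(x$bounds), min(x$ages), max(x$ages), ncol(x$counts)))
  invisible(x)
}

#' Graduate abridged death counts to single ages
#'
#' Estimates smooth single-age death rates from grouped counts with a
#' penalized composite link fit: expected group counts are
#' `G %*% (e * exp(B %*% beta))` where `G` aggregates single ages into the
#' groups, `e` are the single-age exposures and `B` is an equally spaced
#' cubic B-spline basis with a second-order difference penalty. The
#' grouped-likelihood formulation preserves the observed group totals in
#' expectation instead of interpolating them away. The smoothing weight is
#' chosen per cause by BIC over `lambda_grid`.
#'
#' @param groups An [abridged_groups()] object with at least 4 groups.
#' @param lambda_grid Positive candidate smoothing weights.
#' @param knot_spacing,degree,order Basis and penalty settings as in
#'   [bspline_basis()]; defaults 2, 3, 2.
#' @return A tibble with columns `age`, `cause`, `rate` (smooth single-age
#'   death rates) and `lambda` (the selected weight, repeated).
#' @examples
#' b <- cbind(seq(10, 85, by = 5), seq(15, 90, by = 5))
#' rate <- 1e-4 * exp(0.1 * (10:89 - 10))
#' e <- rep(1e5, 80)
#' grouped <- sapply(seq_len(nrow(b)),
#'   function(i) sum((e * rate)[10:89 >= b[i, 1] & 10:89 < b[i, 2]]))
#' g <- abridged_groups(b, grouped, e)
#' head(graduate_counts(g))
#' @export
graduate_counts <- function(groups, lambda_grid = 10^seq(-2, 4),
                            knot_spacing = 2, degree = 3, order = 2) {
  stopifnot(inherits(groups, "abridged_groups"))
  if (nrow(groups$bounds) < 4) abort("insufficient groups (need >= 4).")
  if (any(lambda_grid <= 0)) abort("lambda grid must be positive.")
  ages <- groups$ages
  G <- outer(seq_len(nrow(groups$bounds)), ages,
             function(g, x) as.numeric(x >= groups$bounds[g, 1] &
                                         x < groups$bounds[g, 2]))
  C <- G %*% diag(groups$exposures)
  basis <- bspline_basis(ages, knot_spacing, degree)
  n_g <- nrow(groups$bounds)

  purrr::map(colnames(groups$counts), function(k) {
    d <- groups$counts[, k]
    if (all(d == 0)) {
      warn(sprintf("cause %s has no deaths; returning floor rates", k))
      return(tibble(age = ages, cause = k, rate = 1e-12,
                    lambda = NA_real_))
    }
    fits <- purrr::map(sort(lambda_grid), function(lam) {
      blocks <- list(list(X = basis$B,
                          penalty = penalty_bundle(lam, order, "none")))
      mean_rate <- sum(d) / sum(groups$exposures)
      f <- clm_fit(d, C, blocks,
                   beta_init = rep(log(max(mean_rate, 1e-12)),
                                   ncol(basis$B)))
      list(fit = f, lambda = lam, bic = f$deviance + log(n_g) * f$ed)
    })
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    best <- fits[[max(which(bics <= min(bics, na.rm = TRUE) + 1e-9))]]
    tibble(age = ages, cause = k, rate = best$fit$gamma_blocks[[1]],
           lambda = best$lambda)
  }) |>
    dplyr::bind_rows()
}

#' Constrain cause-specific rates to sum to an all-cause schedule
#'
#' Rescales all causes at each age by the common factor
#' `total(x) / sum_of_causes(x)`, after which the cause-specific rates sum
#' to the supplied all-cause rates exactly.
#'
#' @param cause_rates Tibble with columns `age`, `cause`, `rate` (e.g.
#'   [graduate_counts()] output).
#' @param total_rates Tibble with columns `age`, `rate`, or a numeric
#'   vector over the same ages.
#' @return A tibble like `cause_rates` with rescaled `rate`.
#' @export
rescale_to_total <- function(cause_rates, total_rates) {
  stopifnot(all(c("age", "cause", "rate") %in% names(cause_rates)))
  ages <- sort(unique(cause_rates$age))
  if (is.numeric(total_rates)) {
    total_rates <- tibble(age = ages, rate = total_rates)
  }
  if (!identical(as.numeric(sort(total_rates$age)), as.numeric(ages))) {
    abort("`total_rates` is not on the same age grid.")
  }
  sums <- cause_rates |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(cause_sum = sum(.data$rate), .groups = "drop")
  tot <- dplyr::left_join(
    dplyr::rename(total_rates, total = "rate"), sums, by = "age")
  bad <- tot$cause_sum <= 0 & tot$total > 0
  if (any(bad)) {
    abort(sprintf("zero cause-sum with nonzero total at age(s): %s",
                  paste(tot$age[bad], collapse = ", ")))
  }
  tot$factor <- ifelse(tot$cause_sum > 0, tot$total / tot$cause_sum, 0)
  cause_rates |>
    dplyr::left_join(dplyr::select(tot, "age", "factor"), by = "age") |>
    dplyr::mutate(rate = .data$rate * .data$factor) |>
    dplyr::select(-"factor")
}
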