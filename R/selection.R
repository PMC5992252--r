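#' First-difference shape distance between each cause and all-cause mortality
#'
#' For every year, takes the first difference over age of the all-cause
#' force of mortality and of each cause-specific force of mortality inside
#' the age window, and measures the Euclidean distance between the two
#' difference profiles. First differencing removes level shifts, so the
#' statistic compares the *shape* of the age schedule: causes whose rate of
#' change over the young adult ages resembles the all-cause hump dynamics
#' score low, and causes with flat or purely senescent change score high.
#'
#' Two reference profiles are available. `reference = "total"` (the
#' default) compares each cause with the all-cause difference profile:
#' causes that track the aggregate hump dynamics score low. This works well
#' when the cause typology is wide (each cause a small share of the total).
#' With only a handful of broad causes the all-cause profile is dominated
#' by the largest hump contributors, and a cause with a small hump looks as
#' distant as a humpless one; for such settings `reference = "senescent"`
#' compares each cause with the difference profile of a log-linear
#' (Gompertz) trend fitted to the all-cause schedule, so *any* rise-and-fall
#' profile scores high regardless of its share. `normalize = TRUE` rescales
#' both difference profiles to unit length first, making the comparison a
#' pure shape (direction) comparison, insensitive to the cause's level.
#'
#' @param surface A multi-year [rate_surface()].
#' @param window Age window `c(lower, upper)`, default `c(10, 34)`;
#'   differences are taken at ages `lower .. upper - 1`.
#' @param reference `"total"` (distance to the all-cause profile) or
#'   `"senescent"` (distance to a fitted Gompertz profile).
#' @param normalize Compare unit-length difference profiles instead of raw
#'   ones. Default `FALSE`.
#' @return A tibble with columns `cause`, `year`, `distance`, carrying the
#'   reference in attribute `"reference"`.
#' @export
shape_distance <- function(surface, window = c(10, 34),
                           reference = c("total", "senescent"),
                           normalize = FALSE) {
  stopifnot(inherits(surface, "rate_surface"))
  reference <- match.arg(reference)
  window <- as.integer(window)
  if (window[1] < min(surface$ages) || window[2] > max(surface$ages)) {
    abort("age window outside the surface's age range.")
  }
  if (diff(window) + 1 < 3) abort("age window shorter than 3 ages.")
  idx <- which(surface$ages >= window[1] & surface$ages <= window[2])
  causes <- surface_causes(surface)
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (normalize && n > 0) v / n else v
  }
  res <- purrr::map(surface$years, function(yr) {
    e <- surface_exposures(surface, yr)
    mu_all <- surface_total_deaths(surface, yr) / e
    ref_curve <- if (reference == "total") {
      mu_all
    } else {
      co <- coef(lm(log(pmax(mu_all, 1e-12)) ~ surface$ages))
      exp(co[[1]] + co[[2]] * surface$ages)
    }
    rho_ref <- unit(diff(ref_curve[idx]))
    purrr::map(causes, function(k) {
      mu_k <- surface$deaths[, match(yr, surface$years), k] / e
      rho_k <- unit(diff(mu_k[idx]))
      tibble(cause = k, year = yr,
             distance = sqrt(sum((rho_k - rho_ref)^2)))
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  attr(res, "reference") <- reference
  res
}

#' Summarise shape distances by PCA and flag hump-candidate causes
#'
#' Reduces the cause-by-year matrix of shape distances to two principal
#' components (causes as observations, year columns standardised to zero
#' mean and unit variance) and flags the causes whose distance profiles
#' mark them as hump candidates. Two flagging rules are available:
#'
#' * `"similarity"` (default): split the causes into two groups by 2-means
#'   on the first two PC scores and flag the group on the hump-candidate
#'   side: the *smaller* mean distance when the distances were measured
#'   against the all-cause profile (candidates track the aggregate hump
#'   dynamics), the *larger* mean distance when measured against a
#'   senescent reference (candidates deviate from the Gompertz trend).
#'   The orientation follows the `"reference"` attribute of
#'   [shape_distance()] output, or the `flag` argument. This behaves
#'   sensibly whether the candidates are a small minority (many recorded
#'   causes) or a majority (few broad causes).
#' * `"norm"`: flag causes whose Euclidean norm in the (PC1, PC2) plane
#'   exceeds `k` times the median norm -- a plain outlier rule useful for
#'   wide cause typologies.
#'
#' The flag set is a screening aid, not a canonical selection: the scores
#' are always returned for manual review and the final cause list is the
#' analyst's call.
#'
#' @param distances Output of [shape_distance()] (tibble `cause`, `year`,
#'   `distance`), or a numeric matrix causes x years.
#' @param rule `"similarity"` or `"norm"`.
#' @param k Multiplier of the median norm for `rule = "norm"`. Default 3.
#' @param flag For `rule = "similarity"`: flag the cluster `"near"` to or
#'   `"far"` from the reference profile; `"auto"` (default) chooses from
#'   the distances' `"reference"` attribute (`"total"` flags near,
#'   `"senescent"` flags far).
#' @return An object of class `selection_result`: `scores` (tibble `cause`,
#'   `PC1`, `PC2`, `norm`, `mean_distance`, `flagged`), `explained`
#'   (variance fractions of the first two axes), `flagged` (character
#'   vector), `distances`.
#' @examples
#' surf <- simulate_toy_surface(n_years = 6, seed = 3)
#' sel <- pca_flag(shape_distance(surf))
#' sel$flagged
#' @export
pca_flag <- function(distances, rule = c("similarity", "norm"), k = 3,
                     flag = c("auto", "near", "far")) {
  rule <- match.arg(rule)
  flag <- match.arg(flag)
  if (flag == "auto") {
    flag <- if (identical(attr(distances, "reference"), "senescent")) {
      "far"
    } else {
      "near"
    }
  }
  if (is.matrix(distances)) {
    distances <- tibble(
      cause = rep(rownames(distances) %||%
                    paste0("cause", seq_len(nrow(distances))),
                  ncol(distances)),
      year = rep(seq_len(ncol(distances)), each = nrow(distances)),
      distance = as.vector(distances))
  }
  wide <- tidyr::pivot_wider(distances, names_from = "year",
                             values_from = "distance")
  causes <- wide$cause
  M <- as.matrix(wide[-1])
  if (nrow(M) < 3) abort("need at least 3 causes.")
  if (ncol(M) < 2) abort("need at least 2 years.")

  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant year column(s) before standardization",
                 sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) < 2) abort("fewer than 2 non-constant year columns.")
  }
  Z <- scale(M)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  explained <- explained[1:2]
  scores <- pc$x[, 1:2, drop = FALSE]
  # reproducible sign: loading of the latest year nonnegative on each axis
  for (a in 1:2) {
    if (pc$rotation[nrow(pc$rotation), a] < 0) {
      scores[, a] <- -scores[, a]
    }
  }
  norms <- sqrt(rowSums(scores^2))
  mean_dist <- rowMeans(M)

  flagged_lgl <- if (rule == "norm") {
    norms > k * median(norms)
  } else {
    grp <- two_means(scores)
    means <- tapply(mean_dist, grp, mean)
    pick <- if (flag == "near") which.min(means) else which.max(means)
    grp == names(means)[pick]
  }
  flagged <- sort(causes[flagged_lgl])

  structure(
    list(scores = tibble(cause = causes, PC1 = scores[, 1],
                         PC2 = scores[, 2], norm = norms,
                         mean_distance = mean_dist,
                         flagged = flagged_lgl),
         explained = explained, flagged = flagged, rule = rule,
         distances = distances),
    class = "selection_result"
  )
}

# deterministic 2-means on the PC plane: seeded from the two most
# separated observations, plain Lloyd iterations
two_means <- function(x) {
  d2 <- as.matrix(stats::dist(x))^2
  seed <- arrayInd(which.max(d2), dim(d2))
  centers <- x[as.vector(seed), , drop = FALSE]
  assign_old <- rep(0L, nrow(x))
  for (it in 1:100) {
    da <- rowSums((x - matrix(centers[1, ], nrow(x), 2, byrow = TRUE))^2)
    db <- rowSums((x - matrix(centers[2, ], nrow(x), 2, byrow = TRUE))^2)
    assign_new <- ifelse(da <= db, 1L, 2L)
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (g in 1:2) {
      if (any(assign_new == g)) {
        centers[g, ] <- colMeans(x[assign_new == g, , drop = FALSE])
      }
    }
  }
  as.character(assign_old)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> rule \"%s\"; first two axes explain %.1f%% + %.1f%%\n",
    x$rule, 100 * x$explained[1], 100 * x$explained[2]))
  cat(sprintf("  flagged: %s\n",
              if (length(x$flagged)) paste(x$flagged, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  x$scores
}

#' Plot the PCA screening plane
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot of causes in the (PC1, PC2) plane, flagged causes
#'   highlighted.
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$flagged,
                               label = .data$cause)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(colour = "flagged") +
    ggplot2::theme_minimal()
}
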