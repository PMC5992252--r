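#' Death counts and exposures on an age by year by cause grid
#'
#' `rate_surface` is the universal input container of the package: death
#' counts indexed by single age, calendar year and cause of death, together
#' with person-years of exposure by age and year. Deaths may be real-valued
#' (graduated counts need not be integers). One cause label, by convention
#' `"total"`, may hold the all-cause counts; when present it must equal the
#' sum of the other causes.
#'
#' @param data A data frame with columns `age`, `year`, `cause`, `deaths`,
#'   `exposure`; one row per cell, all cells present.
#' @param total Label of the all-cause slice if one is included.
#'   Default `"total"`; it is only treated specially when actually present.
#' @return An object of class `rate_surface` with fields `ages`, `years`,
#'   `causes`, `deaths` (array `age x year x cause`), `exposures`
#'   (matrix `age x year`) and `total` (label or `NA`).
#' @examples
#' df <- expand.grid(age = 10:15, year = 2000, cause = c("A", "B"))
#' df$deaths <- 5
#' df$exposure <- 1000
#' rate_surface(df)
#' @export
rate_surface <- function(data, total = "total") {
  req <- c("age", "year", "cause", "deaths", "exposure")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  data$cause <- as.character(data$cause)

  dup <- duplicated(data[c("age", "year", "cause")])
  if (any(dup)) {
    first <- data[which(dup)[1], ]
    abort(sprintf("duplicate cell: age %s, year %s, cause %s",
                  first$age, first$year, first$cause))
  }
  bad_d <- which(data$deaths < 0)
  if (length(bad_d)) {
    abort(sprintf("negative deaths at row %d", bad_d[1]))
  }
  bad_e <- which(data$exposure <= 0)
  if (length(bad_e)) {
    abort(sprintf("nonpositive exposure at row %d", bad_e[1]))
  }

  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  causes <- unique(data$cause)
  if (any(diff(ages) != 1)) {
    abort("ages must be contiguous single years of age.")
  }
  if (nrow(data) != length(ages) * length(years) * length(causes)) {
    full <- tidyr::expand_grid(age = ages, year = years, cause = causes)
    miss <- dplyr::anti_join(full, data, by = c("age", "year", "cause"))
    abort(sprintf("missing cell: age %s, year %s, cause %s (and %d more)",
                  miss$age[1], miss$year[1], miss$cause[1], nrow(miss) - 1))
  }

  deaths <- array(NA_real_,
                  dim = c(length(ages), length(years), length(causes)),
                  dimnames = list(age = ages, year = years, cause = causes))
  expo <- matrix(NA_real_, length(ages), length(years),
                 dimnames = list(age = ages, year = years))
  ai <- match(data$age, ages)
  yi <- match(data$year, years)
  ci <- match(data$cause, causes)
  deaths[cbind(ai, yi, ci)] <- data$deaths
  expo[cbind(ai, yi)] <- data$exposure

  # exposures must not vary by cause within a cell
  chk <- tapply(data$exposure, list(ai, yi), function(v) diff(range(v)))
  if (any(unlist(chk) > 1e-9 * max(expo), na.rm = TRUE)) {
    abort("exposure differs across causes within the same age-year cell.")
  }

  total_label <- if (total %in% causes) total else NA_character_
  if (!is.na(total_label)) {
    others <- setdiff(causes, total_label)
    gap <- abs(apply(deaths[, , others, drop = FALSE], c(1, 2), sum) -
                 deaths[, , total_label])
    scale <- pmax(deaths[, , total_label], 1)
    if (any(gap / scale > 1e-9)) {
      abort("cause-specific deaths do not sum to the \"total\" slice.")
    }
  }

  structure(
    list(ages = as.integer(ages), years = as.integer(years), causes = causes,
         deaths = deaths, exposures = expo, total = total_label),
    class = "rate_surface"
  )
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf(
    "<rate_surface> %d ages [%d, %d] x %d year(s) x %d cause(s): %s\n",
    length(x$ages), min(x$ages), max(x$ages), length(x$years),
    length(x$causes), paste(x$causes, collapse = ", ")))
  if (!is.na(x$total)) cat(sprintf("  all-cause slice: \"%s\"\n", x$total))
  invisible(x)
}

#' @export
as_tibble.rate_surface <- function(x, ...) {
  grid <- tidyr::expand_grid(cause = x$causes, year = x$years, age = x$ages)
  grid$deaths <- as.vector(x$deaths[cbind(match(grid$age, x$ages),
                                          match(grid$year, x$years),
                                          match(grid$cause, x$causes))])
  grid$exposure <- as.vector(x$exposures[cbind(match(grid$age, x$ages),
                                               match(grid$year, x$years))])
  dplyr::select(grid, "age", "year", "cause", "deaths", "exposure")
}

# non-total cause labels
surface_causes <- function(surface) {
  setdiff(surface$causes, surface$total)
}

# deaths matrix [age x cause] for one year; causes defaults to non-total
surface_deaths <- function(surface, year = surface$years[1],
                           causes = surface_causes(surface)) {
  yi <- match(year, surface$years)
  if (is.na(yi)) abort(sprintf("year %s not in surface", year))
  surface$deaths[, yi, causes, drop = TRUE]
}

# all-cause deaths for one year (total slice if present, else sum of causes)
surface_total_deaths <- function(surface, year = surface$years[1]) {
  yi <- match(year, surface$years)
  if (is.na(yi)) abort(sprintf("year %s not in surface", year))
  if (!is.na(surface$total)) {
    surface$deaths[, yi, surface$total]
  } else {
    apply(surface$deaths[, yi, , drop = FALSE], 1, sum)
  }
}

surface_exposures <- function(surface, year = surface$years[1]) {
  yi <- match(year, surface$years)
  if (is.na(yi)) abort(sprintf("year %s not in surface", year))
  surface$exposures[, yi]
}

#' Read a mortality surface from a tidy CSV file
#'
#' Expects one row per cell with columns `age`, `year`, `cause`, `deaths`,
#' `exposure` (single ages), or `age_lower`, `age_upper` in place of `age`
#' for abridged age groups. Abridged input is returned as
#' [abridged_groups()] ready for [graduate_counts()]; single-age input is
#' validated into a dense [rate_surface()].
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8).
#' @param total Label of the all-cause slice, if present. Default `"total"`.
#' @return A `rate_surface`, or an `abridged_groups` object for grouped ages.
#' @seealso [write_surface()]
#' @export
read_surface <- function(path, total = "total") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("age_lower", "age_upper") %in% names(df))) {
    return(abridged_from_tidy(df))
  }
  rate_surface(df, total = total)
}

#' Write a mortality surface to a tidy CSV file
#'
#' The inverse of [read_surface()]: one row per age-year-cause cell.
#' Numeric values are written with 12 significant digits, so a write/read
#' round trip reproduces the surface to that precision.
#'
#' @param surface A `rate_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "rate_surface"))
  df <- as_tibble(surface)
  df$deaths <- signif(df$deaths, 12)
  df$exposure <- signif(df$exposure, 12)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Export a fitted decomposition as tidy CSV files
#'
#' Writes three files to `dir`: `components.csv` (columns `age`,
#' `component`, `rate`) with the fitted hump and senescence schedules,
#' `contributions.csv` (`age`, `cause`, `component`, `delta`) with the
#' cause- and age-specific contributions, and `lel.csv` (`measure`,
#' `cause`, `years`, `share`) with the life-expectancy-lost summaries.
#'
#' @param fit An [fit_sse()] result.
#' @param dec A [fit_constrained()] result on the same age grid.
#' @param lel An [lel_measures()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(fit, dec, lel, dir) {
  stopifnot(inherits(fit, "sse_fit"), inherits(dec, "cause_decomposition"),
            inherits(lel, "lel_result"))
  if (length(dec$causes) == 0) abort("no causes in the decomposition.")
  if (!identical(fit$ages, dec$ages)) {
    abort("age grids of the fit and the decomposition differ.")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  fmt <- function(df) {
    df[] <- lapply(df, function(v) if (is.double(v)) signif(v, 12) else v)
    df
  }
  components <- tidyr::pivot_longer(
    tibble(age = fit$ages, hump = fit$gamma_H, senescence = fit$gamma_S),
    -"age", names_to = "component", values_to = "rate")
  contributions <- dplyr::select(
    tidy(dec), "age", "cause", "component", "delta")
  lel_df <- dplyr::select(tidy(lel), "measure", "cause", "years", "share")

  paths <- c(components = file.path(dir, "components.csv"),
             contributions = file.path(dir, "contributions.csv"),
             lel = file.path(dir, "lel.csv"))
  readr::write_csv(fmt(components), paths[["components"]], progress = FALSE)
  readr::write_csv(fmt(contributions), paths[["contributions"]],
                   progress = FALSE)
  readr::write_csv(fmt(lel_df), paths[["lel"]], progress = FALSE)
  invisible(paths)
}

#' Read an HMD-style Mx_1x1 death-rate table
#'
#' Optional convenience reader for the fixed-layout single-age death-rate
#' files distributed by mortality databases: a two-line header followed by
#' whitespace-separated columns `Year`, `Age`, `Female`, `Male`, `Total`.
#' The open age group (`110+`) is read as age 110; missing rates (`.`)
#' become `NA`.
#'
#' @param path Path to the text file.
#' @return A tibble with columns `year`, `age`, `sex` (`"female"`,
#'   `"male"`, `"total"`) and `rate`.
#' @export
read_hmd_rates <- function(path) {
  lines <- readLines(path)
  # drop the title/blank header lines before the column header
  hdr <- grep("^\\s*Year\\s+Age", lines)[1]
  if (is.na(hdr)) abort("no `Year Age ...` header found.")
  body <- lines[(hdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) != 5)
  if (length(bad)) {
    abort(sprintf("malformed row %d: expected 5 fields.", bad[1]))
  }
  M <- do.call(rbind, fields)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  out <- tibble(
    year = as.integer(M[, 1]),
    age = as.integer(sub("\\+$", "", M[, 2])),
    female = num(M[, 3]), male = num(M[, 4]), total = num(M[, 5])
  )
  tidyr::pivot_longer(out, c("female", "male", "total"),
                      names_to = "sex", values_to = "rate")
}
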