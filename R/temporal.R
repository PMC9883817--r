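#' Post-volume weights for a year
#'
#' The weight of company `c` in year `y` is its share of all posts written
#' that year: `w(c, y) = # c's posts in y / total # posts in y`, and 0 for
#' a company with no reviews in `y`. Weights over the companies active in a
#' year sum to 1.
#'
#' @inheritParams compute_company_period_stats
#' @param year A single calendar year.
#' @return A tibble `(company_id, year, n_posts, w)`.
#' @export
yearly_weights <- function(reviews, year) {
  stopifnot(length(year) == 1)
  reviews <- check_reviews(reviews)
  in_year <- filter(reviews, review_year(.data$date) == year)
  if (nrow(in_year) == 0) {
    warn(paste0("No posts in year ", year, "; all weights are zero."))
    return(tibble(company_id = character(), year = integer(),
                  n_posts = integer(), w = double()))
  }
  in_year %>%
    count(.data$company_id, name = "n_posts") %>%
    mutate(year = as.integer(year), w = .data$n_posts / sum(.data$n_posts)) %>%
    select("company_id", "year", "n_posts", "w") %>%
    arrange(.data$company_id)
}

#' Yearly stress-type index
#'
#' For each year `y`, the amount of stress type `s` expressed that year is
#' the volume-weighted sum of company associations:
#' \deqn{m(s, y) = \sum_{c \in s} f(c, s, y) \, w(c, y)}
#' where membership, z-scores and `f` are all recomputed within the year
#' (window `T = {y}`), so a company's stress type may change from year to
#' year, and `w` is the company's share of all posts in `y` (see
#' [yearly_weights()]). All four types are emitted for every year; a type
#' with no member companies in `y` gets `m = 0`. `dispersion` is the
#' population standard deviation, across the type's member companies, of
#' their contributions `f * w` — the spread behind a shaded confidence
#' band.
#'
#' Years in which the cohort is degenerate (fewer than two active
#' companies, or zero dispersion on either axis, e.g. no stress-matching
#' post anywhere) cannot be z-scored; they are emitted with `NA` markers
#' and a warning rather than dropped.
#'
#' @inheritParams compute_company_period_stats
#' @param years Integer vector of calendar years to score.
#' @param min_reviews Per-year minimum review count passed to
#'   [score_quadrants()].
#' @return A tibble of class `yearly_stress_index`:
#'   `(year, stress_type, m, dispersion, n_companies)`.
#' @export
yearly_stress_index <- function(reviews, lexicon, years, min_reviews = 0) {
  reviews <- check_reviews(reviews)
  rows <- purrr::map(years, function(y) {
    na_year <- tibble(
      year = as.integer(y),
      stress_type = factor(stress_type_levels(),
                           levels = stress_type_levels()),
      m = NA_real_, dispersion = NA_real_, n_companies = NA_integer_
    )
    stats <- suppressWarnings(
      compute_company_period_stats(reviews, lexicon, years = y)
    )
    if (nrow(stats) < 2) {
      warn(paste0("Year ", y, ": fewer than two active companies; ",
                  "index not computable."))
      return(na_year)
    }
    quad <- tryCatch(
      score_quadrants(stats, min_reviews = min_reviews),
      error = function(e) {
        warn(paste0("Year ", y, ": ", conditionMessage(e),
                    " Index not computable."))
        NULL
      }
    )
    if (is.null(quad) || nrow(quad$scores) == 0) {
      return(na_year)
    }
    w <- yearly_weights(reviews, y)
    contrib <- quad$scores %>%
      left_join(select(w, "company_id", "w"), by = "company_id") %>%
      mutate(w = dplyr::coalesce(.data$w, 0), fw = .data$f * .data$w)
    contrib %>%
      group_by(.data$stress_type) %>%
      summarise(
        m = sum(.data$fw),
        dispersion = sqrt(mean((.data$fw - mean(.data$fw))^2)),
        n_companies = dplyr::n(),
        .groups = "drop"
      ) %>%
      tidyr::complete(
        stress_type = factor(stress_type_levels(),
                             levels = stress_type_levels()),
        fill = list(m = 0, dispersion = NA_real_, n_companies = 0L)
      ) %>%
      mutate(year = as.integer(y), .before = 1)
  })
  out <- bind_rows(rows)
  class(out) <- c("yearly_stress_index", class(out))
  out
}

#' Correlate the stress index with an external yearly series
#'
#' Reports, per stress type, the Pearson and Spearman correlation between
#' `m(s, y)` and an external yearly series (for instance a national
#' unemployment rate) over the overlapping years. Only the coefficients
#' and the number of overlapping years are reported; no significance or
#' causal claim is attached. A constant series has undefined correlation,
#' reported as `NA`.
#'
#' @param index A [yearly_stress_index()] table.
#' @param external A data frame `(year, value)`.
#' @return A tibble `(stress_type, n_years, pearson, spearman)`.
#' @export
overlay_external_series <- function(index, external) {
  stopifnot(all(c("year", "value") %in% names(external)))
  joined <- index %>%
    filter(!is.na(.data$m)) %>%
    inner_join(as_tibble(external), by = "year")
  n_overlap <- n_distinct(joined$year)
  if (n_overlap < 3) {
    abort(paste0("Only ", n_overlap, " overlapping year(s); ",
                 "need at least 3 to correlate."))
  }
  joined %>%
    group_by(.data$stress_type) %>%
    summarise(
      n_years = dplyr::n(),
      pearson = safe_cor(.data$m, .data$value, "pearson"),
      spearman = safe_cor(.data$m, .data$value, "spearman"),
      .groups = "drop"
    )
}

safe_cor <- function(x, y, method) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(NA_real_)
  }
  suppressWarnings(cor(x, y, method = method))
}
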