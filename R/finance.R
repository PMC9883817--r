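#' Long-term stock growth per company
#'
#' Growth over a window is the ratio of yearly average adjusted closing
#' prices: `growth = stock(end_year) / stock(start_year)`, where `stock(y)`
#' is the average of the daily adjusted closes over calendar year `y`.
#' Input may be yearly (`company_id, year, adj_close_avg`) or daily
#' (`company_id, date, adj_close`), in which case daily prices are averaged
#' per year first. Companies missing either endpoint year are dropped; the
#' count of dropped companies is reported in a message and attached as
#' attribute `"n_dropped"`.
#'
#' @param prices Yearly or daily price table (see Details).
#' @param start_year,end_year Window endpoints (defaults 2009 and 2019, a
#'   decade; a narrower window such as 2014-2019 is a robustness option).
#' @return A tibble `(company_id, growth)`.
#' @examples
#' prices <- tibble::tibble(
#'   company_id = "EQIX", year = c(2009, 2019), adj_close_avg = c(61, 485)
#' )
#' stock_growth(prices) # growth ~ 7.95
#' @export
stock_growth <- function(prices, start_year = 2009, end_year = 2019) {
  prices <- as_tibble(prices)
  if (!"year" %in% names(prices) && "date" %in% names(prices)) {
    price_col <- intersect(c("adj_close", "adj_close_avg"), names(prices))[1]
    if (is.na(price_col)) {
      abort("Daily price table needs an `adj_close` column.")
    }
    prices <- prices %>%
      mutate(year = review_year(.data$date)) %>%
      group_by(.data$company_id, .data$year) %>%
      summarise(adj_close_avg = mean(.data[[price_col]]), .groups = "drop")
  }
  stopifnot(all(c("company_id", "year", "adj_close_avg") %in% names(prices)))
  bad <- filter(prices, .data$adj_close_avg <= 0)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Nonpositive adjusted close for ", bad$company_id[1], " in ",
      bad$year[1], " (", nrow(bad), " offending record(s))."
    ))
  }
  endpoints <- prices %>%
    filter(.data$year %in% c(start_year, end_year)) %>%
    mutate(which = ifelse(.data$year == start_year, "start", "end")) %>%
    select("company_id", "which", "adj_close_avg") %>%
    tidyr::pivot_wider(names_from = "which", values_from = "adj_close_avg")
  n_all <- nrow(endpoints)
  out <- endpoints %>%
    filter(!is.na(.data$start) & !is.na(.data$end)) %>%
    mutate(growth = .data$end / .data$start) %>%
    select("company_id", "growth") %>%
    arrange(.data$company_id)
  n_dropped <- n_all - nrow(out)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " company(ies) missing ", start_year, " or ",
                  end_year, " prices were dropped."))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Geometric mean
#'
#' `exp(mean(log(x)))`, identical to `(prod(x))^(1/n)` but stable for long
#' vectors. Growth ratios are heavy-tailed across companies, which is why
#' they are averaged on the multiplicative scale.
#'
#' @param x Positive numeric vector.
#' @return A single number.
#' @examples
#' geometric_mean(c(2, 8)) # 4
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    abort("geometric_mean() needs a non-empty vector of positive values.")
  }
  exp(mean(log(x)))
}

#' Geometric standard error
#'
#' `GSE = GM(x) / sqrt(N) * sd(log(x))` with natural logarithms and the
#' population standard deviation (divide by N); the multiplicative-scale
#' analogue of the standard error of the mean. Undefined for fewer than
#' two values (`NA` with a warning).
#'
#' @inheritParams geometric_mean
#' @return A single number, `NA` if `length(x) < 2`.
#' @examples
#' geometric_standard_error(c(2, 8)) # 4 / sqrt(2) * log(2)
#' @export
geometric_standard_error <- function(x) {
  if (length(x) < 2) {
    warn("GSE undefined for fewer than two values; returning NA.")
    return(NA_real_)
  }
  lx <- log(x)
  geometric_mean(x) / sqrt(length(x)) * sqrt(mean((lx - mean(lx))^2))
}

#' Growth summaries by stress type and association percentile
#'
#' Joins company growth ratios to their quadrant scores, then, within each
#' stress type, ranks companies on the binning variable and cuts them into
#' `n_bins` equal-count percentile bins (ties broken by company id for a
#' deterministic cut). Each (type, bin) row reports the company count `N`,
#' the geometric mean `gm` and the geometric standard error `gse` of
#' growth. A per-type `overall` row pools all the type's companies — the
#' "average across all percentiles" is the pooled GM, not the mean of bin
#' GMs. The binning variable defaults to the association score `f` (how
#' strongly the company sits in its quadrant); `"stress_score"` ranks on
#' the raw stress-mention rate instead.
#'
#' @param growth Output of [stock_growth()].
#' @param quadrants A `stress_quadrants` object (or its [tidy()] tibble).
#' @param n_bins Number of equal-count bins per type (default 10: deciles).
#' @param bin_on `"f"` (default) or `"stress_score"`.
#' @return A tibble of class `growth_summary`:
#'   `(stress_type, percentile_bin, N, gm, gse)`, with `percentile_bin`
#'   `"1"` (lowest) through `n_bins` plus `"overall"`.
#' @export
growth_by_type_and_percentile <- function(growth, quadrants, n_bins = 10,
                                          bin_on = c("f", "stress_score")) {
  bin_on <- match.arg(bin_on)
  scores <- if (inherits(quadrants, "stress_quadrants")) {
    quadrants$scores
  } else {
    as_tibble(quadrants)
  }
  stopifnot(n_bins >= 1, bin_on %in% names(scores))
  joined <- inner_join(
    as_tibble(growth),
    select(scores, "company_id", "stress_type", all_of(bin_on)),
    by = "company_id"
  )
  binned <- joined %>%
    group_by(.data$stress_type) %>%
    arrange(.data[[bin_on]], .data$company_id, .by_group = TRUE) %>%
    mutate(percentile_bin = as.character(
      ntile(row_number(), min(n_bins, dplyr::n()))
    )) %>%
    ungroup()
  per_bin <- binned %>%
    group_by(.data$stress_type, .data$percentile_bin) %>%
    summarise(
      N = dplyr::n(),
      gm = geometric_mean(.data$growth),
      gse = maybe_gse(.data$growth),
      .groups = "drop"
    )
  overall <- binned %>%
    group_by(.data$stress_type) %>%
    summarise(
      percentile_bin = "overall",
      N = dplyr::n(),
      gm = geometric_mean(.data$growth),
      gse = maybe_gse(.data$growth),
      .groups = "drop"
    )
  out <- bind_rows(per_bin, overall) %>%
    arrange(.data$stress_type,
            suppressWarnings(as.integer(.data$percentile_bin)))
  class(out) <- c("growth_summary", class(out))
  out
}

maybe_gse <- function(x) {
  if (length(x) < 2) NA_real_ else geometric_standard_error(x)
}

#' Stratified growth summaries
#'
#' Repeats [growth_by_type_and_percentile()] within each stratum (industry
#' sector, rating band, ...) as a robustness check that a growth advantage
#' is not an artifact of cohort composition. Companies without a stratum
#' label fall into stratum `"unknown"`.
#'
#' @inheritParams growth_by_type_and_percentile
#' @param strata A data frame `(company_id, stratum)`.
#' @return A `growth_summary` tibble with a leading `stratum` column.
#' @export
stratified_growth <- function(growth, quadrants, strata, n_bins = 10,
                              bin_on = c("f", "stress_score")) {
  bin_on <- match.arg(bin_on)
  stopifnot(all(c("company_id", "stratum") %in% names(strata)))
  growth <- as_tibble(growth) %>%
    left_join(distinct(as_tibble(strata), .data$company_id,
                       .keep_all = TRUE),
              by = "company_id") %>%
    mutate(stratum = dplyr::coalesce(as.character(.data$stratum), "unknown"))
  out <- growth %>%
    group_by(.data$stratum) %>%
    dplyr::group_modify(function(g, key) {
      res <- growth_by_type_and_percentile(
        select(g, "company_id", "growth"), quadrants,
        n_bins = n_bins, bin_on = bin_on
      )
      as_tibble(res)
    }) %>%
    ungroup()
  class(out) <- c("growth_summary", class(out))
  out
}
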