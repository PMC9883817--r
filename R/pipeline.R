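#' Read review and stock tables
#'
#' Reviews are comma-delimited UTF-8 with a header row and columns
#' `company_id`, `date` (ISO-8601), `rating` (integer 1-5), `text` (quoted
#' free text); stocks are `company_id`, `year`, `adj_close_avg` (or daily
#' `company_id`, `date`, `adj_close`). Lines starting with `#` are treated
#' as comments, so files written by [write_pipeline()] round-trip.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_reviews <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           date = readr::col_date(),
                           rating = readr::col_integer(),
                           .default = readr::col_guess()
                         ))
  check_reviews(out)
}

#' @rdname read_reviews
#' @export
read_stocks <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Validate a review table
#'
#' Checks structural requirements row by row: required columns present,
#' rating an integer within 1-5, date parseable as ISO-8601, text
#' non-missing. Invalid rows are counted per reason, never silently
#' coerced.
#'
#' @param reviews A data frame of reviews, or a path to one.
#' @return A list with `n_rows`, `n_valid`, `drops` (a tibble
#'   `(reason, n)`) and `clean` (the valid rows, dates parsed).
#' @export
validate_reviews <- function(reviews) {
  if (is.character(reviews) && length(reviews) == 1) {
    if (!file.exists(reviews)) {
      abort(paste0("Review file not found: ", reviews))
    }
    reviews <- readr::read_csv(reviews, comment = "#",
                               col_types = readr::cols(.default = "c"),
                               show_col_types = FALSE)
  }
  reviews <- check_reviews(reviews)
  parsed_date <- as.Date(
    vapply(as.character(reviews$date), function(d) {
      out <- tryCatch(as.character(as.Date(d, format = "%Y-%m-%d")),
                      error = function(e) NA_character_)
      out %||% NA_character_
    }, character(1), USE.NAMES = FALSE)
  )
  rating_num <- suppressWarnings(as.numeric(as.character(reviews$rating)))
  bad_rating <- is.na(rating_num) | rating_num != round(rating_num) |
    rating_num < 1 | rating_num > 5
  bad_date <- is.na(parsed_date)
  bad_text <- is.na(reviews$text) | !nzchar(as.character(reviews$text))
  reason <- dplyr::case_when(
    bad_rating ~ "rating_range",
    bad_date ~ "date_parse",
    bad_text ~ "empty_text",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)
  clean <- reviews[ok, , drop = FALSE] %>%
    mutate(date = parsed_date[ok], rating = as.integer(rating_num[ok]))
  list(
    n_rows = nrow(reviews),
    n_valid = sum(ok),
    drops = count(tibble(reason = reason[!ok]), .data$reason, name = "n"),
    clean = clean
  )
}

#' Run the whole stress-by-rating pipeline
#'
#' Executes all stages in order on in-memory tables: stress-mention
#' extraction and per-company statistics, quadrant scoring, the yearly
#' stress index, c-TF-IDF keywords with chi-square association verdicts,
#' and (when a stock table is supplied) growth summaries by stress type
#' and percentile bin. Rerunning with identical inputs and settings gives
#' identical output.
#'
#' @inheritParams compute_company_period_stats
#' @param stocks Optional stock price table (see [stock_growth()]).
#' @param years Study window as an integer year vector (default
#'   2009:2019).
#' @param min_reviews Minimum reviews per company for quadrant scoring.
#' @param growth_start,growth_end Stock growth window endpoints; default
#'   to the window bounds.
#' @param n_bins,bin_on Passed to [growth_by_type_and_percentile()].
#' @param top_k Keywords per class (default 3).
#' @param alpha Significance level for association verdicts.
#' @param stopwords,log_idf,correct Passed to the topics stage.
#' @return A `stress_pipeline` list: `stats`, `quadrants`, `index`,
#'   `keywords`, `top_keywords`, `topic_tests`, `growth`,
#'   `growth_summary`, `settings`.
#' @export
run_stress_pipeline <- function(reviews, stocks = NULL,
                                lexicon = default_stress_lexicon(),
                                years = 2009:2019,
                                min_reviews = 0,
                                growth_start = min(years),
                                growth_end = max(years),
                                n_bins = 10,
                                bin_on = c("f", "stress_score"),
                                top_k = 3, alpha = 0.05,
                                stopwords = NULL, log_idf = FALSE,
                                correct = FALSE) {
  bin_on <- match.arg(bin_on)
  reviews <- check_reviews(reviews)
  stats <- compute_company_period_stats(reviews, lexicon, years = years)
  quadrants <- score_quadrants(stats, min_reviews = min_reviews)
  if (nrow(quadrants$scores) == 0) {
    warn("No scorable companies; downstream stages skipped.")
    return(new_stress_pipeline(
      stats = stats, quadrants = quadrants, index = NULL, keywords = NULL,
      top_keywords = NULL, topic_tests = NULL, growth = NULL,
      growth_summary = NULL,
      settings = pipeline_settings(years, min_reviews, growth_start,
                                   growth_end, n_bins, bin_on, top_k,
                                   alpha, log_idf, correct, lexicon)
    ))
  }
  index <- yearly_stress_index(reviews, lexicon, years,
                               min_reviews = min_reviews)
  window_reviews <- filter(reviews, review_year(.data$date) %in% years)
  corpora <- build_class_corpora(window_reviews, quadrants)
  keywords <- ctfidf_scores(corpora, stopwords = stopwords,
                            log_idf = log_idf)
  tops <- top_keywords(keywords, k = top_k)
  topic_tests <- topic_quadrant_chisq(
    keywords %>%
      semi_join(tops, by = "keyword") %>%
      select("class_id", "keyword", n = "k_l"),
    alpha = alpha, correct = correct
  )
  growth <- NULL
  growth_summary <- NULL
  if (!is.null(stocks)) {
    growth <- stock_growth(stocks, start_year = growth_start,
                           end_year = growth_end)
    growth_summary <- growth_by_type_and_percentile(
      growth, quadrants, n_bins = n_bins, bin_on = bin_on
    )
  }
  new_stress_pipeline(
    stats = stats, quadrants = quadrants, index = index,
    keywords = keywords, top_keywords = tops, topic_tests = topic_tests,
    growth = growth, growth_summary = growth_summary,
    settings = pipeline_settings(years, min_reviews, growth_start,
                                 growth_end, n_bins, bin_on, top_k, alpha,
                                 log_idf, correct, lexicon)
  )
}

pipeline_settings <- function(years, min_reviews, growth_start, growth_end,
                              n_bins, bin_on, top_k, alpha, log_idf,
                              correct, lexicon) {
  list(
    years = years, min_reviews = min_reviews,
    growth_start = growth_start, growth_end = growth_end,
    n_bins = n_bins, bin_on = bin_on, top_k = top_k, alpha = alpha,
    log_idf = log_idf, correct = correct,
    lexicon_name = attr(lexicon, "name") %||% "custom",
    lexicon = as.character(lexicon)
  )
}

new_stress_pipeline <- function(...) {
  structure(list(...), class = "stress_pipeline")
}

#' @export
print.stress_pipeline <- function(x, ...) {
  cat("<stress_pipeline>\n")
  cat("  companies scored: ", nrow(x$quadrants$scores), "\n", sep = "")
  if (!is.null(x$index)) {
    cat("  years indexed:    ",
        paste(range(x$index$year), collapse = "-"), "\n", sep = "")
  }
  if (!is.null(x$growth_summary)) {
    ov <- filter(x$growth_summary, .data$percentile_bin == "overall")
    cat("  overall GM by type:\n")
    for (i in seq_len(nrow(ov))) {
      cat(sprintf("    %-16s %.2f (N = %d)\n", ov$stress_type[i],
                  ov$gm[i], ov$N[i]))
    }
  }
  invisible(x)
}

#' Company-level aggregate export
#'
#' One row per scored company with the fields a company-level release of
#' this analysis would carry: review counts, stress-review counts, average
#' rating, stress score, stress type, strength of association, endpoint
#' stock prices and growth, and (optionally) sector.
#'
#' @param pipeline A `stress_pipeline` object.
#' @param sectors Optional data frame `(company_id, sector)`.
#' @return A tibble.
#' @export
company_aggregates <- function(pipeline, sectors = NULL) {
  stopifnot(inherits(pipeline, "stress_pipeline"))
  out <- pipeline$quadrants$scores %>%
    select("company_id", "n_posts", "n_stress_posts", "mean_rating",
           "stress_score", "stress_type", "f")
  if (!is.null(pipeline$growth)) {
    out <- left_join(out, pipeline$growth, by = "company_id")
  }
  if (!is.null(sectors)) {
    out <- left_join(out, distinct(as_tibble(sectors), .data$company_id,
                                   .keep_all = TRUE),
                     by = "company_id")
  }
  out
}

#' Write pipeline artifacts as delimited text
#'
#' Writes every stage table as a comma-delimited UTF-8 file with a `#`
#' header comment carrying a settings hash, so a rerun against the same
#' inputs and settings is diffable file by file.
#'
#' @param pipeline A `stress_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "stress_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(pipeline$settings)
  tables <- list(
    company_stats = pipeline$stats,
    quadrant_scores = pipeline$quadrants$scores,
    yearly_index = pipeline$index,
    keyword_scores = pipeline$keywords,
    top_keywords = pipeline$top_keywords,
    topic_tests = pipeline$topic_tests,
    stock_growth = pipeline$growth,
    growth_summary = pipeline$growth_summary,
    company_aggregates = company_aggregates(pipeline)
  )
  for (name in names(tables)) {
    tab <- tables[[name]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_lines(paste0("# stressquad settings hash ", hash), path)
    readr::write_csv(as_tibble(tab), path, append = TRUE, col_names = TRUE)
  }
  invisible(dir)
}
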