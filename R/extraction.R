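#' Detect stress-related mentions in review text
#'
#' Matches lexicon phrases against free text, case-insensitively and on
#' whole-word boundaries (internal spaces in a phrase match any run of
#' whitespace). Overlapping candidate matches are resolved left-to-right by
#' longest match, so `"extreme stress"` wins over the `"stress"` embedded in
#' it and the embedded phrase is not double-counted. A review "relates to
#' stress" exactly when at least one phrase matches.
#'
#' The matcher is a deliberate surface-form stand-in for neural medical
#' entity extraction: it only finds the phrases it is given (inflected forms
#' such as "overloaded" do not match "overload") and makes no attempt to
#' tell personal from figurative use.
#'
#' @param text A single character string.
#' @param lexicon A [stress_lexicon()].
#' @return A tibble with one row per resolved match: `phrase` (the lowercase
#'   lexicon phrase), `start`, `end` (1-based character offsets into `text`).
#'   Empty text gives zero rows.
#' @examples
#' lex <- default_stress_lexicon()
#' match_stress_mentions("Beware: extreme stress and pressure.", lex)
#' @export
match_stress_mentions <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1)
  hits <- locate_stress_mentions(text, lexicon)
  hits$doc <- NULL
  hits
}

# Vectorised matcher: one row per resolved match across a character vector.
# Returns tibble(doc, phrase, start, end), doc indexing into `texts`.
locate_stress_mentions <- function(texts, lexicon) {
  stopifnot(inherits(lexicon, "stress_lexicon"))
  empty <- tibble(
    doc = integer(), phrase = character(),
    start = integer(), end = integer()
  )
  if (length(texts) == 0) {
    return(empty)
  }
  cand <- purrr::map(as.character(lexicon), function(ph) {
    loc <- stringr::str_locate_all(texts, phrase_regex(ph))
    hit <- lengths(loc) > 0 & vapply(loc, nrow, 1L) > 0
    if (!any(hit)) {
      return(NULL)
    }
    mats <- loc[hit]
    tibble(
      doc = rep(which(hit), vapply(mats, nrow, 1L)),
      phrase = ph,
      start = unname(unlist(lapply(mats, function(m) m[, 1]))),
      end = unname(unlist(lapply(mats, function(m) m[, 2])))
    )
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) {
    return(empty)
  }
  cand <- arrange(cand, .data$doc, .data$start, desc(.data$end - .data$start),
                  .data$phrase)
  cand %>%
    group_by(.data$doc) %>%
    mutate(selected = resolve_longest(.data$start, .data$end)) %>%
    ungroup() %>%
    filter(.data$selected) %>%
    select(-"selected")
}

# Greedy left-to-right scan over candidates already sorted by (start,
# longest-first): keep a candidate unless it overlaps the last kept one.
resolve_longest <- function(start, end) {
  keep <- logical(length(start))
  last_end <- 0L
  for (i in seq_along(start)) {
    if (start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- end[i]
    }
  }
  keep
}

phrase_regex <- function(phrase) {
  esc <- stringr::str_replace_all(phrase, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1")
  esc <- stringr::str_replace_all(esc, " ", "\\\\s+")
  stringr::regex(paste0("\\b", esc, "\\b"), ignore_case = TRUE)
}

# Fast indicator: does each text contain >= 1 lexicon phrase? Equivalent to
# nrow(match_stress_mentions(.)) > 0 because overlap resolution never turns
# a non-empty candidate set into an empty one.
detect_stress <- function(texts, lexicon) {
  stopifnot(inherits(lexicon, "stress_lexicon"))
  hit <- rep(FALSE, length(texts))
  for (ph in as.character(lexicon)) {
    miss <- !hit
    if (!any(miss)) break
    hit[miss] <- stringr::str_detect(texts[miss], phrase_regex(ph))
  }
  hit
}

#' Per-company review statistics over a time window
#'
#' For each company with at least one review in the window `T`, computes the
#' review count, the count of stress-related reviews (reviews matching at
#' least one lexicon phrase — a review counts once no matter how many
#' mentions it contains), the arithmetic mean rating `rating(c, T)`, and the
#' stress score
#' `stress(c, T) = # stress-related reviews in T / # reviews in T`.
#' Companies with no review in the window are absent from the output; they
#' receive a zero association downstream.
#'
#' @param reviews A data frame of reviews with columns `company_id`, `date`
#'   (Date or ISO-8601 string), `rating` (integer 1-5) and `text`.
#' @param lexicon A [stress_lexicon()].
#' @param years Optional integer vector of calendar years defining the
#'   window `T`; `NULL` keeps all reviews.
#' @return A tibble with columns `company_id`, `n_posts`, `n_stress_posts`,
#'   `mean_rating`, `stress_score`, one row per company active in `T`.
#' @examples
#' reviews <- simulate_reviews(cohort_config(n_companies_per_type = 2, seed = 1))
#' compute_company_period_stats(reviews, default_stress_lexicon(), 2009:2019)
#' @export
compute_company_period_stats <- function(reviews, lexicon, years = NULL) {
  reviews <- check_reviews(reviews)
  if (!is.null(years)) {
    reviews <- filter(reviews, review_year(.data$date) %in% years)
  }
  if (nrow(reviews) == 0) {
    warn("No reviews in the requested window; returning an empty table.")
    return(tibble(
      company_id = character(), n_posts = integer(),
      n_stress_posts = integer(), mean_rating = double(),
      stress_score = double()
    ))
  }
  reviews %>%
    mutate(.stress = detect_stress(.data$text, lexicon)) %>%
    group_by(.data$company_id) %>%
    summarise(
      n_posts = dplyr::n(),
      n_stress_posts = sum(.data$.stress),
      mean_rating = mean(.data$rating),
      .groups = "drop"
    ) %>%
    mutate(stress_score = .data$n_stress_posts / .data$n_posts) %>%
    arrange(.data$company_id)
}

#' Corpus-wide mention counts per lexicon condition
#'
#' Counts resolved matches per phrase across all review texts. Counts are
#' mentions, not posts: a review containing "stress" twice contributes two
#' mentions (but would still count once toward a company's stress-post
#' count). Phrases with zero mentions are included with a zero count so the
#' table always has one row per lexicon condition; rows are sorted by
#' descending count.
#'
#' @inheritParams compute_company_period_stats
#' @return A tibble `(phrase, n_mentions)` sorted by descending count.
#' @export
condition_frequency_table <- function(reviews, lexicon) {
  reviews <- check_reviews(reviews)
  hits <- locate_stress_mentions(reviews$text, lexicon)
  tibble(phrase = as.character(lexicon)) %>%
    left_join(count(hits, .data$phrase, name = "n_mentions"), by = "phrase") %>%
    mutate(n_mentions = dplyr::coalesce(.data$n_mentions, 0L)) %>%
    arrange(desc(.data$n_mentions), .data$phrase)
}

review_year <- function(date) {
  as.integer(format(as.Date(date), "%Y"))
}

check_reviews <- function(reviews) {
  needed <- c("company_id", "date", "rating", "text")
  missing <- setdiff(needed, names(reviews))
  if (length(missing) > 0) {
    abort(paste0(
      "Review table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  as_tibble(reviews)
}
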