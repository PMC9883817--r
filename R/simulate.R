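#' Archetype of a synthetic company
#'
#' An archetype bundles the generative parameters for one stress type:
#' the rating law (Normal, rounded and clamped to the 1-5 star scale), the
#' probability that a generated review carries a stress-condition phrase,
#' the mean yearly review volume (Poisson), and the log-normal law of
#' 10-year stock growth.
#'
#' @param stress_type One of `low_stress`, `passive`, `negative_stress`,
#'   `positive_stress`.
#' @param rating_mean Mean of the latent rating Normal, in `[1, 5]`.
#' @param rating_sd Standard deviation of the latent rating Normal (> 0).
#' @param stress_post_prob Probability a review embeds a lexicon phrase,
#'   in `[0, 1]`.
#' @param reviews_per_year_mean Poisson mean of reviews per company-year.
#' @param growth_log_mean Mean of log 10-year stock growth.
#' @param growth_log_sd Standard deviation of log growth (>= 0).
#' @return A one-row tibble.
#' @export
archetype_spec <- function(stress_type, rating_mean, rating_sd,
                           stress_post_prob, reviews_per_year_mean,
                           growth_log_mean, growth_log_sd) {
  stress_type <- match.arg(stress_type, stress_type_levels())
  stopifnot(
    rating_mean >= 1, rating_mean <= 5, rating_sd > 0,
    stress_post_prob >= 0, stress_post_prob <= 1,
    reviews_per_year_mean > 0, growth_log_sd >= 0
  )
  tibble(
    stress_type = stress_type, rating_mean = rating_mean,
    rating_sd = rating_sd, stress_post_prob = stress_post_prob,
    reviews_per_year_mean = reviews_per_year_mean,
    growth_log_mean = growth_log_mean, growth_log_sd = growth_log_sd
  )
}

#' @rdname cohort_config
#' @export
default_archetypes <- function() {
  bind_rows(
    archetype_spec("low_stress", 4.2, 0.8, 0.002, 68, log(3.84), 0.5),
    archetype_spec("passive", 2.8, 0.8, 0.002, 68, log(3.42), 0.5),
    archetype_spec("negative_stress", 2.8, 0.8, 0.030, 68, log(3.84), 0.5),
    archetype_spec("positive_stress", 4.2, 0.8, 0.030, 68, log(5.07), 0.5)
  )
}

default_filler_vocab <- function() {
  c(
    "great benefits and smart coworkers",
    "decent pay for the area",
    "management communicates the roadmap clearly",
    "plenty of growth opportunities",
    "good work life balance most weeks",
    "the cafeteria food is average",
    "remote options depend on the team",
    "onboarding took a few weeks",
    "solid training program for new hires",
    "free coffee and snacks in the office",
    "promotion cycles are slow but fair",
    "interesting projects across departments",
    "the commute can be long",
    "leadership changed recently",
    "quarterly goals are reasonable"
  )
}

#' Configure a synthetic review cohort
#'
#' Defines a cohort of synthetic companies with planted stress-type
#' structure, used to exercise and validate every pipeline stage with known
#' ground truth. Each stress type gets `n_companies_per_type` companies
#' generated from its [archetype_spec()]. Defaults plant well-separated
#' archetypes: satisfied/unsatisfied rating means of 4.2/2.8 stars,
#' stress-mention probabilities of 0.030 for the stressed types against a
#' 0.002 background, review volumes at the scale of large-cap employers
#' (Poisson mean 68 reviews per company-year), and log-normal decade stock
#' growth centred on 5.07x for positive-stress companies, 3.42x for passive
#' ones and 3.84x for the rest.
#'
#' @param n_companies_per_type Companies per stress type.
#' @param years Integer vector of calendar years covered by the review
#'   stream (default 2008:2020).
#' @param seed Integer seed; together with the config it fully determines
#'   the generated tables.
#' @param archetypes A four-row tibble of [archetype_spec()]s, one per
#'   stress type.
#' @param lexicon Character vector of stress phrases to embed.
#' @param filler_vocab Character vector of neutral phrases for
#'   non-stress review text.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_companies_per_type = 50,
                          years = 2008:2020,
                          seed = 42L,
                          archetypes = default_archetypes(),
                          lexicon = as.character(default_stress_lexicon()),
                          filler_vocab = default_filler_vocab()) {
  stopifnot(n_companies_per_type >= 1, length(years) >= 1)
  if (length(lexicon) == 0) {
    abort("cohort_config: `lexicon` must contain at least one phrase.")
  }
  if (length(filler_vocab) == 0) {
    abort("cohort_config: `filler_vocab` must contain at least one phrase.")
  }
  if (!setequal(archetypes$stress_type, stress_type_levels())) {
    abort("cohort_config: need exactly one archetype per stress type.")
  }
  structure(
    list(
      n_companies_per_type = as.integer(n_companies_per_type),
      years = sort(as.integer(years)),
      seed = as.integer(seed),
      archetypes = arrange(as_tibble(archetypes),
                           match(.data$stress_type, stress_type_levels())),
      lexicon = tolower(lexicon),
      filler_vocab = filler_vocab
    ),
    class = "cohort_config"
  )
}

#' Ground-truth company roster of a synthetic cohort
#'
#' Company ids and their planted stress types. This sidecar table is the
#' held-out truth for recovery tests; no pipeline stage consumes it.
#'
#' @param config A [cohort_config()].
#' @return A tibble `(company_id, stress_type)`.
#' @export
company_roster <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  types <- rep(stress_type_levels(), each = config$n_companies_per_type)
  tibble(
    company_id = sprintf("C%04d", seq_along(types)),
    stress_type = factor(types, levels = stress_type_levels())
  )
}

#' Simulate an employee-review stream
#'
#' Per company-year, draws the review count from a Poisson law with the
#' archetype's yearly mean, review dates uniformly within the year, and
#' ratings from the archetype's Normal rounded and clamped to the 1-5
#' scale. With the archetype's `stress_post_prob` a review's text embeds
#' one lexicon phrase verbatim (possibly capitalised) among neutral filler
#' phrases; otherwise the text is filler only. Output is fully determined
#' by the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A tibble of reviews: `review_id`, `company_id`, `date`, `rating`,
#'   `text`, sorted by company and date.
#' @examples
#' head(simulate_reviews(cohort_config(n_companies_per_type = 2, seed = 3)))
#' @export
simulate_reviews <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  roster <- company_roster(config)
  withr::with_seed(config$seed, {
    frame <- tidyr::expand_grid(roster, year = config$years) %>%
      left_join(config$archetypes, by = "stress_type") %>%
      mutate(n_reviews = rpois(dplyr::n(), .data$reviews_per_year_mean)) %>%
      # every company posts at least once over the full period
      group_by(.data$company_id) %>%
      mutate(n_reviews = ifelse(
        sum(.data$n_reviews) == 0 & .data$year == min(.data$year),
        1L, .data$n_reviews
      )) %>%
      ungroup() %>%
      tidyr::uncount(.data$n_reviews)
    n <- nrow(frame)
    days_in_year <- ifelse(is_leap_year(frame$year), 366L, 365L)
    reviews <- frame %>%
      mutate(
        date = as.Date(paste0(.data$year, "-01-01")) +
          floor(runif(n) * days_in_year),
        rating = pmin(5L, pmax(1L, as.integer(round(
          rnorm(n, .data$rating_mean, .data$rating_sd)
        )))),
        has_stress = runif(n) < .data$stress_post_prob,
        text = compose_review_text(
          .data$has_stress, config$lexicon, config$filler_vocab
        )
      ) %>%
      select("company_id", "date", "rating", "text") %>%
      arrange(.data$company_id, .data$date, .data$rating, .data$text) %>%
      mutate(review_id = row_number(), .before = 1)
    reviews
  })
}

is_leap_year <- function(y) {
  (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
}

# Builds review texts: 3-6 filler phrases as sentences; stress reviews get
# one lexicon phrase inserted as its own sentence at a random position,
# capitalised half the time (case inflection only, surface form intact).
compose_review_text <- function(has_stress, lexicon, filler_vocab) {
  n <- length(has_stress)
  n_fill <- sample(3:6, n, replace = TRUE)
  phrase <- sample(lexicon, n, replace = TRUE)
  capitalise <- runif(n) < 0.5
  phrase <- ifelse(
    capitalise,
    paste0(toupper(substr(phrase, 1, 1)), substr(phrase, 2, nchar(phrase))),
    phrase
  )
  purrr::map_chr(seq_len(n), function(i) {
    sentences <- sample(filler_vocab, n_fill[i], replace = TRUE)
    if (has_stress[i]) {
      pos <- sample(n_fill[i] + 1L, 1L)
      sentences <- append(sentences, phrase[i], after = pos - 1L)
    }
    paste0(paste(sentences, collapse = ". "), ".")
  })
}

#' Simulate yearly average stock prices
#'
#' Draws a log-normal start-of-window price per company, multiplies it by a
#' log-normal 10-year growth factor with the archetype's log-mean and
#' log-sd to get the end-of-window price, and interpolates the intervening
#' years geometrically (constant yearly growth rate). Uses a seed derived
#' from the config seed so review and stock streams are independent.
#'
#' @param config A [cohort_config()].
#' @param company_types A tibble `(company_id, stress_type)`; defaults to
#'   [company_roster()] of the config.
#' @param start_year,end_year Window covered by the price series.
#' @return A tibble `(company_id, year, adj_close_avg)` covering every year
#'   from `start_year` to `end_year` for every company.
#' @export
simulate_stocks <- function(config, company_types = company_roster(config),
                            start_year = 2009, end_year = 2019) {
  stopifnot(inherits(config, "cohort_config"), end_year > start_year)
  withr::with_seed(config$seed + 1L, {
    base <- as_tibble(company_types) %>%
      mutate(stress_type = factor(.data$stress_type,
                                  levels = stress_type_levels())) %>%
      left_join(config$archetypes, by = "stress_type") %>%
      mutate(
        start_price = rlnorm(dplyr::n(), meanlog = log(50), sdlog = 0.7),
        log_growth = rnorm(dplyr::n(), .data$growth_log_mean,
                           .data$growth_log_sd)
      )
    tidyr::expand_grid(base, year = start_year:end_year) %>%
      mutate(
        adj_close_avg = .data$start_price * exp(
          .data$log_growth * (.data$year - start_year) /
            (end_year - start_year)
        )
      ) %>%
      select("company_id", "year", "adj_close_avg") %>%
      arrange(.data$company_id, .data$year)
  })
}
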