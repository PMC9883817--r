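#' Z-score companies on rating and stress
#'
#' Standardises `mean_rating` and `stress_score` against the cohort moments
#' for the window: `z_rating = (rating - mu_rating) / sigma_rating` and
#' likewise for stress. By default sigma is the population standard
#' deviation (divide by n), treating the cohort as the full population of
#' scored companies rather than a sample; `sd_type = "sample"` switches to
#' the n-1 convention.
#'
#' @param stats Company period statistics from
#'   [compute_company_period_stats()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The input tibble with `z_rating` and `z_stress` columns added and
#'   the cohort moments attached as attribute `"moments"` (also returned by
#'   [cohort_moments()]).
#' @export
zscore_companies <- function(stats, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(stats) < 2) {
    abort("Need at least two companies to z-score a cohort.")
  }
  mom <- cohort_moments(stats, sd_type = sd_type)
  if (mom$sigma_rating == 0) {
    abort("Zero dispersion on the rating axis: all mean ratings are equal.")
  }
  if (mom$sigma_stress == 0) {
    abort("Zero dispersion on the stress axis: all stress scores are equal.")
  }
  out <- mutate(
    as_tibble(stats),
    z_rating = (.data$mean_rating - mom$mu_rating) / mom$sigma_rating,
    z_stress = (.data$stress_score - mom$mu_stress) / mom$sigma_stress
  )
  attr(out, "moments") <- mom
  out
}

#' @rdname zscore_companies
#' @export
cohort_moments <- function(stats, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  disp <- function(x) {
    if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else sd(x)
  }
  tibble(
    mu_rating = mean(stats$mean_rating),
    sigma_rating = disp(stats$mean_rating),
    mu_stress = mean(stats$stress_score),
    sigma_stress = disp(stats$stress_score),
    n_companies = nrow(stats),
    sd_type = sd_type
  )
}

#' Assign stress types from z-score signs
#'
#' The four stress types are the quadrants of the (z_rating, z_stress)
#' plane: high rating + low stress = low stress; low rating + low stress =
#' passive; low rating + high stress = negative stress; high rating + high
#' stress = positive stress. A z-score of exactly zero counts as the
#' nonnegative side (half-open quadrants), so the origin maps to positive
#' stress; this boundary set has measure zero for continuous scores.
#'
#' @param z_rating,z_stress Numeric vectors of equal length.
#' @return A factor with levels `low_stress`, `passive`, `negative_stress`,
#'   `positive_stress`.
#' @examples
#' assign_stress_type(c(-1, 1, 0), c(1, 1, 0))
#' @export
assign_stress_type <- function(z_rating, z_stress) {
  stopifnot(length(z_rating) == length(z_stress))
  type <- dplyr::case_when(
    z_rating >= 0 & z_stress < 0 ~ "low_stress",
    z_rating < 0 & z_stress < 0 ~ "passive",
    z_rating < 0 & z_stress >= 0 ~ "negative_stress",
    TRUE ~ "positive_stress"
  )
  factor(type, levels = stress_type_levels())
}

#' Geometric association of a company with its stress type
#'
#' Scores how strongly a point (z_rating, z_stress) is associated with its
#' quadrant:
#' \deqn{f = R / (\gamma + \pi)}
#' where \eqn{R = \sqrt{z_{rating}^2 + z_{stress}^2}} is the radius from the
#' origin, \eqn{\alpha = \arccos(|z_{rating}| / R)} and
#' \eqn{\beta = \arccos(|z_{stress}| / R)} are the angles between the radius
#' and the two axes, and \eqn{\gamma = \max(\alpha - \pi/4, \beta - \pi/4)}
#' is the angular distance from the quadrant diagonal. `f` grows with
#' distance from the origin and shrinks with distance from the diagonal,
#' ranging from \eqn{4R/(5\pi)} on an axis to \eqn{R/\pi} on the diagonal.
#' At the origin the angles are undefined and `f = 0` by convention (the
#' point of weakest possible association). Companies with no review in the
#' window also receive `f = 0`; they simply never enter the scored table.
#'
#' @param z_rating,z_stress Numeric vectors of equal length.
#' @return A tibble with columns `z_rating`, `z_stress`, `R`, `alpha`,
#'   `beta`, `gamma` (radians; `NA` at the origin) and `f`.
#' @examples
#' quadrant_association(3, 3)$f # 3 * sqrt(2) / pi
#' quadrant_association(2, 0)$f # 8 / (5 * pi)
#' @export
quadrant_association <- function(z_rating, z_stress) {
  stopifnot(length(z_rating) == length(z_stress))
  R <- sqrt(z_rating^2 + z_stress^2)
  alpha <- ifelse(R > 0, acos(pmin(abs(z_rating) / R, 1)), NA_real_)
  beta <- ifelse(R > 0, acos(pmin(abs(z_stress) / R, 1)), NA_real_)
  gamma <- pmax(alpha - pi / 4, beta - pi / 4)
  f <- ifelse(R > 0, R / (gamma + pi), 0)
  tibble(
    z_rating = z_rating, z_stress = z_stress,
    R = R, alpha = alpha, beta = beta, gamma = gamma, f = f
  )
}

#' Score a cohort on the stress-by-rating quadrant
#'
#' The full quadrant stage: z-scores the cohort ([zscore_companies()]),
#' assigns each company its stress type ([assign_stress_type()]) and
#' computes the geometric association `f` ([quadrant_association()]).
#'
#' @inheritParams zscore_companies
#' @param min_reviews Drop companies with fewer reviews than this before
#'   z-scoring (default 0: no filter).
#' @return A `stress_quadrants` object: a list with `scores` (one row per
#'   scored company: ids, counts, rating/stress, z-scores, `stress_type`,
#'   `R`, `alpha`, `beta`, `gamma`, `f`), `moments` (cohort moments) and
#'   `min_reviews`. Supports [tidy()], [glance()], [autoplot()] and
#'   `print()`.
#' @examples
#' cfg <- cohort_config(n_companies_per_type = 5, seed = 7)
#' stats <- compute_company_period_stats(
#'   simulate_reviews(cfg), default_stress_lexicon(), 2009:2019
#' )
#' score_quadrants(stats)
#' @export
score_quadrants <- function(stats, min_reviews = 0,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stats <- filter(as_tibble(stats), .data$n_posts >= min_reviews)
  if (nrow(stats) == 0) {
    warn("No company passes the minimum-review filter; empty score table.")
    scores <- tibble(
      company_id = character(), n_posts = integer(),
      n_stress_posts = integer(), mean_rating = double(),
      stress_score = double(), z_rating = double(), z_stress = double(),
      stress_type = factor(character(), levels = stress_type_levels()),
      R = double(), alpha = double(), beta = double(), gamma = double(),
      f = double()
    )
    return(new_stress_quadrants(scores, moments = NULL,
                                min_reviews = min_reviews))
  }
  z <- zscore_companies(stats, sd_type = sd_type)
  geom <- quadrant_association(z$z_rating, z$z_stress)
  scores <- z %>%
    mutate(
      stress_type = assign_stress_type(.data$z_rating, .data$z_stress),
      R = geom$R, alpha = geom$alpha, beta = geom$beta,
      gamma = geom$gamma, f = geom$f
    )
  new_stress_quadrants(scores, moments = attr(z, "moments"),
                       min_reviews = min_reviews)
}

new_stress_quadrants <- function(scores, moments, min_reviews) {
  structure(
    list(scores = as_tibble(scores), moments = moments,
         min_reviews = min_reviews),
    class = "stress_quadrants"
  )
}

#' @export
print.stress_quadrants <- function(x, ...) {
  cat("<stress_quadrants: ", nrow(x$scores), " companies>\n", sep = "")
  if (nrow(x$scores) > 0) {
    tab <- table(x$scores$stress_type)
    cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"),
        "\n", sep = "")
  }
  print(x$scores, ...)
  invisible(x)
}

#' @describeIn score_quadrants One row per company with z-scores, stress
#'   type and association `f`.
#' @param x A `stress_quadrants` object.
#' @param ... Unused.
#' @method tidy stress_quadrants
#' @export
tidy.stress_quadrants <- function(x, ...) {
  x$scores
}

#' @describeIn score_quadrants One-row cohort summary: company counts per
#'   type, cohort moments, mean association.
#' @method glance stress_quadrants
#' @export
glance.stress_quadrants <- function(x, ...) {
  counts <- as.list(table(x$scores$stress_type))
  names(counts) <- paste0("n_", names(counts))
  dplyr::bind_cols(
    tibble(n_companies = nrow(x$scores), mean_f = mean(x$scores$f)),
    as_tibble(counts),
    if (!is.null(x$moments)) {
      select(x$moments, -"n_companies")
    } else {
      tibble()
    }
  )
}
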