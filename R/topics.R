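#' Group reviews into document classes
#'
#' Builds the per-class review sets used for keyword scoring. By default a
#' review's class is the stress type of its company (from a scored
#' [score_quadrants()] cohort), giving four classes. Alternatively an
#' external assignment table `(review_id, class_id)` — for example cluster
#' labels produced by an embedding + clustering pipeline — replaces the
#' default classing. Reviews whose company is unscored (or whose id is not
#' assigned) are dropped, with the count reported in a message.
#'
#' @inheritParams compute_company_period_stats
#' @param quadrants A `stress_quadrants` object (default classing).
#' @param assignment Optional data frame `(review_id, class_id)`; when
#'   given it takes precedence over `quadrants`.
#' @return A tibble `(class_id, review_id, text)`, one row per assigned
#'   review.
#' @export
build_class_corpora <- function(reviews, quadrants = NULL, assignment = NULL) {
  reviews <- check_reviews(reviews)
  if (!"review_id" %in% names(reviews)) {
    reviews <- mutate(reviews, review_id = row_number())
  }
  if (!is.null(assignment)) {
    stopifnot(all(c("review_id", "class_id") %in% names(assignment)))
    assignment <- distinct(as_tibble(assignment), .data$review_id,
                           .keep_all = TRUE)
    out <- reviews %>%
      inner_join(select(assignment, "review_id", "class_id"),
                 by = "review_id")
  } else {
    if (is.null(quadrants) || !inherits(quadrants, "stress_quadrants")) {
      abort("Provide either a `stress_quadrants` object or an `assignment`.")
    }
    out <- reviews %>%
      inner_join(
        select(quadrants$scores, "company_id", class_id = "stress_type"),
        by = "company_id"
      )
  }
  n_dropped <- nrow(reviews) - nrow(out)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " review(s) without a class were dropped."))
  }
  out %>%
    mutate(class_id = as.character(.data$class_id)) %>%
    select("class_id", "review_id", "text") %>%
    arrange(.data$class_id, .data$review_id)
}

# Lowercase alphanumeric word tokens; optional stop-word removal and
# adjacent-pair bigrams.
tokenize_texts <- function(texts, stopwords = NULL, bigrams = FALSE) {
  toks <- stringr::str_extract_all(tolower(texts), "[[:alnum:]]+")
  if (!is.null(stopwords)) {
    stopwords <- tolower(stopwords)
    toks <- purrr::map(toks, function(t) t[!t %in% stopwords])
  }
  if (bigrams) {
    toks <- purrr::map(toks, function(t) {
      if (length(t) >= 2) {
        c(t, paste(t[-length(t)], t[-1]))
      } else {
        t
      }
    })
  }
  toks
}

#' Class-based TF-IDF keyword scores
#'
#' Scores how representative each keyword is of each document class:
#' \deqn{\mathrm{cTFIDF}_l(k) = \frac{k_l}{o_l} \times \frac{p}{\sum_j k_j}}
#' where `k_l` is the keyword's frequency in class `l`, `o_l` the total
#' token count of class `l`, `p` the total number of documents across all
#' classes, and the denominator sums the keyword's frequency over all
#' classes. The first factor is a within-class term frequency; the second
#' grows when the keyword is rare outside the class, so class-exclusive
#' keywords outrank equally frequent but widely spread ones. The formula is
#' applied in this plain ratio form by default; `log_idf = TRUE` switches
#' the second factor to `log(1 + p / sum_j k_j)`, the damped variant used
#' by some topic-modeling implementations.
#'
#' @param corpora A tibble `(class_id, text, ...)` from
#'   [build_class_corpora()].
#' @param stopwords Optional character vector of tokens to discard.
#' @param bigrams Also count adjacent word pairs as keywords.
#' @param log_idf Use the logarithmic variant of the second factor.
#' @return A tibble `(class_id, keyword, k_l, o_l, p, q_sum, score)` with
#'   one row per class x keyword-in-vocabulary pair (absent keywords score
#'   0).
#' @examples
#' corp <- tibble::tibble(
#'   class_id = c("a", "b"),
#'   text = c("alpha beta", "beta gamma")
#' )
#' ctfidf_scores(corp)
#' @export
ctfidf_scores <- function(corpora, stopwords = NULL, bigrams = FALSE,
                          log_idf = FALSE) {
  stopifnot(all(c("class_id", "text") %in% names(corpora)))
  if (n_distinct(corpora$class_id) < 2) {
    abort("Need at least two document classes to score keywords.")
  }
  toks <- tokenize_texts(corpora$text, stopwords = stopwords,
                         bigrams = bigrams)
  long <- tibble(
    class_id = rep(corpora$class_id, lengths(toks)),
    keyword = unlist(toks)
  )
  if (nrow(long) == 0) {
    abort("Empty vocabulary after tokenization/filtering.")
  }
  p <- nrow(corpora)
  counts <- count(long, .data$class_id, .data$keyword, name = "k_l")
  class_totals <- count(long, .data$class_id, name = "o_l")
  keyword_totals <- long %>%
    count(.data$keyword, name = "q_sum")
  tidyr::expand_grid(
    class_id = sort(unique(corpora$class_id)),
    keyword = sort(unique(long$keyword))
  ) %>%
    left_join(counts, by = c("class_id", "keyword")) %>%
    mutate(k_l = dplyr::coalesce(.data$k_l, 0L)) %>%
    left_join(class_totals, by = "class_id") %>%
    left_join(keyword_totals, by = "keyword") %>%
    mutate(
      p = p,
      idf = if (log_idf) log1p(p / .data$q_sum) else p / .data$q_sum,
      score = .data$k_l / .data$o_l * .data$idf
    ) %>%
    select("class_id", "keyword", "k_l", "o_l", "p", "q_sum", "score")
}

#' Top-k keywords per class
#'
#' The `k` highest-scoring keywords of each class, ties broken
#' lexicographically (stable under any reordering of the input rows).
#' Classes with fewer than `k` positive-scoring keywords emit what they
#' have, with a warning.
#'
#' @param scores Output of [ctfidf_scores()].
#' @param k Keywords per class (default 3).
#' @return A tibble `(class_id, rank, keyword, score)`.
#' @export
top_keywords <- function(scores, k = 3) {
  stopifnot(k >= 1)
  out <- scores %>%
    filter(.data$score > 0) %>%
    arrange(.data$class_id, desc(.data$score), .data$keyword) %>%
    group_by(.data$class_id) %>%
    slice_head(n = k) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    select("class_id", "rank", "keyword", "score")
  short <- out %>%
    count(.data$class_id) %>%
    filter(.data$n < k)
  if (nrow(short) > 0) {
    warn(paste0("Class(es) with fewer than ", k, " scored keywords: ",
                paste(short$class_id, collapse = ", ")))
  }
  out
}

#' Keyword-quadrant association by chi-square
#'
#' Tests, for each keyword and each class it occurs in, whether the keyword
#' is statistically tied to that class the way a topic is tied to its
#' quadrant: the keyword must (a) occur in the class, (b) be dependent on
#' the class (a 2x2 chi-square of keyword presence against class membership
#' over all token occurrences, significant at `alpha`), and (c) show no
#' significant dependence on any *other* class once the home class is
#' removed from the corpus (per-other-class 2x2 tests on the remaining
#' classes; a keyword absent from the remaining classes is trivially
#' independent of them). Condition (c) is evaluated on the reduced corpus
#' because on the full corpus any class-concentrated keyword is
#' mechanically dependent — by depletion — on every class.
#'
#' Chi-square statistics use no continuity correction by default (so the
#' 2x2 table (10, 0; 0, 10) gives exactly 20); `correct = TRUE` enables the
#' Yates correction. Verdicts whose dependence test has any expected cell
#' count below 1 are flagged `unreliable`. P-values are reported raw;
#' `p_adjust = "BH"` applies Benjamini-Hochberg across the dependence
#' tests.
#'
#' @param keyword_counts A tibble `(class_id, keyword, n)` of nonnegative
#'   integer counts (e.g. `k_l` from [ctfidf_scores()]), or a keyword x
#'   class matrix.
#' @param alpha Significance level (default 0.05).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per (keyword, class) pair:
#'   `n` (count in class), `chisq`, `p_dependence`, `max_other_p`,
#'   `associated` (the three-condition verdict) and `unreliable`.
#' @export
topic_quadrant_chisq <- function(keyword_counts, alpha = 0.05,
                                 correct = FALSE,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.matrix(keyword_counts)) {
    keyword_counts <- as_tibble(keyword_counts, rownames = "keyword") %>%
      tidyr::pivot_longer(-"keyword", names_to = "class_id", values_to = "n")
  }
  stopifnot(all(c("class_id", "keyword", "n") %in% names(keyword_counts)))
  if (any(keyword_counts$n < 0) ||
      any(keyword_counts$n != round(keyword_counts$n))) {
    abort("Counts must be nonnegative integers.")
  }
  wide <- keyword_counts %>%
    group_by(.data$keyword, .data$class_id) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class_id", values_from = "n",
                       values_fill = 0L)
  classes <- setdiff(names(wide), "keyword")
  mat <- as.matrix(wide[classes])
  rownames(mat) <- wide$keyword
  col_totals <- colSums(mat)
  rows <- purrr::map(seq_len(nrow(mat)), function(i) {
    kw <- rownames(mat)[i]
    purrr::map(classes, function(cl) {
      dep <- chisq_2x2(
        k_in = mat[i, cl], k_out = sum(mat[i, ]) - mat[i, cl],
        o_in = col_totals[[cl]] - mat[i, cl],
        o_out = sum(col_totals) - col_totals[[cl]] -
          (sum(mat[i, ]) - mat[i, cl]),
        correct = correct
      )
      others <- setdiff(classes, cl)
      other_p <- vapply(others, function(oc) {
        sub_cols <- setdiff(classes, cl)
        k_in <- mat[i, oc]
        k_out <- sum(mat[i, sub_cols]) - k_in
        o_in <- col_totals[[oc]] - k_in
        o_out <- sum(col_totals[sub_cols]) - col_totals[[oc]] - k_out
        chisq_2x2(k_in, k_out, o_in, o_out, correct = correct)$p
      }, numeric(1))
      tibble(
        keyword = kw, class_id = cl, n = mat[i, cl],
        chisq = dep$stat, p_dependence = dep$p,
        max_other_p = if (all(is.na(other_p))) NA_real_ else
          max(other_p, na.rm = TRUE),
        min_expected = dep$min_expected
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (p_adjust == "BH") {
    rows$p_dependence <- stats::p.adjust(rows$p_dependence, method = "BH")
  }
  rows %>%
    mutate(
      associated = .data$n > 0 &
        !is.na(.data$p_dependence) & .data$p_dependence < alpha &
        (is.na(.data$max_other_p) | .data$max_other_p >= alpha),
      unreliable = !is.na(.data$min_expected) & .data$min_expected < 1
    ) %>%
    select(-"min_expected")
}

# 2x2 chi-square of (keyword, other tokens) x (in class, out of class).
# Degenerate margins (an all-zero row or column) carry no evidence of
# dependence: statistic and p are NA.
chisq_2x2 <- function(k_in, k_out, o_in, o_out, correct = FALSE) {
  tab <- matrix(c(k_in, k_out, o_in, o_out), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(stat = NA_real_, p = NA_real_, min_expected = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(
    stat = unname(ct$statistic),
    p = unname(ct$p.value),
    min_expected = min(ct$expected)
  )
}
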