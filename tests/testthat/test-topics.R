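test_that("class corpora partition assigned reviews", {
  cfg <- tiny_config(n = 3, seed = 19, years = 2009:2010)
  reviews <- simulate_reviews(cfg)
  stats <- compute_company_period_stats(reviews, default_stress_lexicon(),
                                        cfg$years)
  quad <- score_quadrants(stats)
  corp <- build_class_corpora(reviews, quad)
  expect_setequal(unique(corp$class_id), levels(quad$scores$stress_type))
  expect_equal(nrow(corp), nrow(reviews))

  # external assignment takes precedence and keeps only assigned reviews
  assign <- tibble::tibble(
    review_id = reviews$review_id[1:100],
    class_id = rep(c("k1", "k2", "k3"), length.out = 100)
  )
  expect_message(corp2 <- build_class_corpora(reviews, assignment = assign),
                 "dropped")
  expect_setequal(unique(corp2$class_id), c("k1", "k2", "k3"))
  expect_equal(nrow(corp2), 100L)
  expect_error(build_class_corpora(reviews), "assignment")
})

test_that("c-TF-IDF reproduces the hand-computed example", {
  # class A: 10 one-word docs, "zebra" twice; class B: 10 one-word docs.
  # k_A = 2, o_A = 10, p = 20 docs, q_sum = 2 -> (2/10) * (20/2) = 2.
  corp <- tibble::tibble(
    class_id = rep(c("A", "B"), each = 10),
    text = c("zebra", "zebra", paste0("fillA", 1:8), paste0("fillB", 1:10))
  )
  sc <- ctfidf_scores(corp)
  z <- sc[sc$keyword == "zebra", ]
  expect_equal(z$score[z$class_id == "A"], 2.0)
  expect_equal(z$score[z$class_id == "B"], 0)
  expect_equal(z$k_l[z$class_id == "A"], 2L)
  expect_equal(z$o_l[z$class_id == "A"], 10L)
  expect_equal(unique(z$p), 20L)
  expect_equal(unique(z$q_sum), 2L)
})

test_that("c-TF-IDF is invariant under corpus duplication", {
  corp <- tibble::tibble(
    class_id = rep(c("A", "B"), each = 4),
    text = c("alpha beta", "beta gamma", "alpha alpha", "delta",
             "beta beta", "gamma", "delta epsilon", "epsilon")
  )
  sc1 <- ctfidf_scores(corp)
  sc2 <- ctfidf_scores(dplyr::bind_rows(corp, corp))
  joined <- merge(sc1, sc2, by = c("class_id", "keyword"))
  expect_equal(joined$score.x, joined$score.y, tolerance = 1e-12)
})

test_that("class-exclusive keywords outrank spread keywords", {
  # "uniq" and "everywhere" both occur 3x in class A, but "everywhere"
  # also occurs in B and C.
  corp <- tibble::tibble(
    class_id = c("A", "A", "A", "B", "B", "C", "C"),
    text = c("uniq everywhere pad", "uniq everywhere pad",
             "uniq everywhere pad", "everywhere pad other",
             "pad other", "everywhere other", "pad other")
  )
  sc <- ctfidf_scores(corp)
  a <- sc[sc$class_id == "A", ]
  expect_gt(a$score[a$keyword == "uniq"],
            a$score[a$keyword == "everywhere"])
})

test_that("top keywords rank by score with lexicographic ties", {
  sc <- tibble::tibble(
    class_id = "A",
    keyword = c("pear", "apple", "mango", "kiwi"),
    k_l = 1L, o_l = 10L, p = 10L, q_sum = 1L,
    score = c(0.5, 0.5, 0.9, 0.1)
  )
  top <- top_keywords(sc, k = 3)
  expect_equal(top$keyword, c("mango", "apple", "pear"))
  # stable under input reordering
  top2 <- top_keywords(sc[c(3, 1, 4, 2), ], k = 3)
  expect_equal(top2, top)
  expect_warning(top_keywords(sc[1:2, ], k = 3), "fewer than 3")
})

test_that("chi-square statistic matches the textbook formula", {
  tab <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE,
                dimnames = list(c("kw", "other"), c("q1", "q2")))
  got <- topic_quadrant_chisq(
    tibble::tibble(
      keyword = rep(c("kw", "other"), each = 2),
      class_id = rep(c("q1", "q2"), 2),
      n = c(10, 0, 0, 10)
    )
  )
  expect_equal(got$chisq[got$keyword == "kw" & got$class_id == "q1"], 20)
  expect_equal(unname(oracle_chisq_stat(tab)), 20)

  set.seed(33)
  for (i in 1:20) {
    counts <- matrix(rpois(8, 12) + 1, nrow = 2,
                     dimnames = list(c("kw", "other"), paste0("q", 1:4)))
    long <- tidyr::expand_grid(keyword = rownames(counts),
                               class_id = colnames(counts))
    long$n <- as.vector(t(counts))
    got <- topic_quadrant_chisq(long)
    for (q in colnames(counts)) {
      two_by_two <- matrix(c(
        counts["kw", q], sum(counts["kw", ]) - counts["kw", q],
        counts["other", q], sum(counts["other", ]) - counts["other", q]
      ), nrow = 2, byrow = TRUE)
      expect_equal(
        got$chisq[got$keyword == "kw" & got$class_id == q],
        unname(oracle_chisq_stat(two_by_two)),
        tolerance = 1e-9
      )
    }
  }
})

test_that("association verdicts follow the three-condition rule", {
  # keyword concentrated in one quadrant, balanced background
  counts <- tidyr::expand_grid(
    keyword = c("exclusive", "background"),
    class_id = paste0("q", 1:4)
  )
  counts$n <- c(30, 0, 0, 0, 100, 100, 100, 100)
  verdicts <- topic_quadrant_chisq(counts)
  excl <- verdicts[verdicts$keyword == "exclusive", ]
  expect_true(excl$associated[excl$class_id == "q1"])
  expect_false(any(excl$associated[excl$class_id != "q1"]))

  # uniform keyword: associated with nothing
  counts$n <- c(25, 25, 25, 25, 100, 100, 100, 100)
  verdicts <- topic_quadrant_chisq(counts)
  expect_false(any(verdicts$associated[verdicts$keyword == "exclusive"]))

  # tiny expected counts are flagged unreliable
  counts$n <- c(1, 0, 0, 0, 2, 2, 2, 2)
  verdicts <- topic_quadrant_chisq(counts)
  expect_true(any(verdicts$unreliable))
  expect_error(
    topic_quadrant_chisq(dplyr::mutate(counts, n = n - 0.5)),
    "nonnegative integers"
  )
})
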