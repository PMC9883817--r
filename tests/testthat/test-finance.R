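test_that("stock growth is the endpoint price ratio", {
  prices <- tibble::tibble(
    company_id = "EQIX", year = c(2009, 2019), adj_close_avg = c(61, 485)
  )
  g <- stock_growth(prices)
  expect_equal(g$growth, 485 / 61, tolerance = 1e-12)
  expect_gt((g$growth - 1) * 100, 695) # percentage climb

  flat <- tibble::tibble(company_id = "X", year = c(2009, 2019),
                         adj_close_avg = 100)
  expect_equal(stock_growth(flat)$growth, 1)

  # daily input is averaged per year first
  daily <- tibble::tibble(
    company_id = "Y",
    date = c(seq(as.Date("2009-01-01"), as.Date("2009-12-31"), by = "day"),
             seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")),
    adj_close = 100
  )
  daily$adj_close[format(daily$date, "%Y") == "2019"] <- 250
  expect_equal(stock_growth(daily)$growth, 2.5)

  # missing endpoints are dropped and counted
  partial <- tibble::tibble(
    company_id = c("A", "A", "B"), year = c(2009, 2019, 2009),
    adj_close_avg = c(10, 20, 10)
  )
  expect_message(g2 <- stock_growth(partial), "dropped")
  expect_equal(g2$company_id, "A")
  expect_equal(attr(g2, "n_dropped"), 1L)

  bad <- tibble::tibble(company_id = "Z", year = c(2009, 2019),
                        adj_close_avg = c(-1, 5))
  expect_error(stock_growth(bad), "Nonpositive")
})

test_that("geometric mean and standard error match hand values", {
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(7.3), 7.3)
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(numeric()), "positive")

  expect_equal(geometric_standard_error(c(2, 8)), 4 / sqrt(2) * log(2),
               tolerance = 1e-12)
  expect_equal(4 / sqrt(2) * log(2), 1.9605, tolerance = 1e-4)
  expect_equal(geometric_standard_error(rep(3, 5)), 0)
  expect_warning(gse1 <- geometric_standard_error(2), "fewer than two")
  expect_true(is.na(gse1))

  set.seed(9)
  for (i in 1:20) {
    v <- rlnorm(10)
    k <- runif(1, 0.5, 5)
    expect_equal(geometric_mean(k * v), k * geometric_mean(v),
                 tolerance = 1e-12)
    expect_equal(geometric_standard_error(k * v),
                 k * geometric_standard_error(v), tolerance = 1e-12)
    expect_lte(geometric_mean(v), mean(v))
  }
})

make_scored_cohort <- function(seed = 25, n = 10) {
  cfg <- tiny_config(n = n, seed = seed, years = 2009:2011)
  reviews <- simulate_reviews(cfg)
  stats <- compute_company_period_stats(reviews, default_stress_lexicon(),
                                        cfg$years)
  list(
    cfg = cfg,
    quad = score_quadrants(stats),
    growth = stock_growth(simulate_stocks(cfg), 2009, 2019)
  )
}

test_that("percentile summaries pool correctly", {
  sc <- make_scored_cohort()
  one_bin <- growth_by_type_and_percentile(sc$growth, sc$quad, n_bins = 1)
  by_type <- merge(as.data.frame(sc$growth),
                   as.data.frame(tidy(sc$quad))[c("company_id",
                                                  "stress_type")],
                   by = "company_id")
  for (s in unique(by_type$stress_type)) {
    vals <- by_type$growth[by_type$stress_type == s]
    got <- one_bin[one_bin$stress_type == s &
                     one_bin$percentile_bin == "overall", ]
    expect_equal(got$gm, geometric_mean(vals), tolerance = 1e-12)
    expect_equal(got$N, length(vals))
    # with a single bin, bin "1" equals the pooled summary
    bin1 <- one_bin[one_bin$stress_type == s &
                      one_bin$percentile_bin == "1", ]
    expect_equal(bin1$gm, got$gm, tolerance = 1e-12)
  }

  five <- growth_by_type_and_percentile(sc$growth, sc$quad, n_bins = 5)
  for (s in unique(five$stress_type)) {
    sub <- five[five$stress_type == s, ]
    bins <- sub[sub$percentile_bin != "overall", ]
    ov <- sub[sub$percentile_bin == "overall", ]
    expect_equal(sum(bins$N), ov$N)
    # pooled GM is the N-weighted geometric combination of bin GMs
    expect_equal(exp(sum(bins$N * log(bins$gm)) / sum(bins$N)), ov$gm,
                 tolerance = 1e-12)
  }
  # binning on the raw stress score is also accepted
  alt <- growth_by_type_and_percentile(sc$growth, sc$quad, n_bins = 2,
                                       bin_on = "stress_score")
  expect_s3_class(alt, "growth_summary")
})

test_that("planted growth advantages are recovered per type", {
  cfg <- cohort_config(n_companies_per_type = 100, years = 2009:2010,
                       seed = 55)
  growth <- stock_growth(simulate_stocks(cfg), 2009, 2019)
  truth <- company_roster(cfg)
  # score with the ground-truth types (isolates the finance stage)
  quad_tbl <- dplyr::mutate(truth, f = 1, stress_score = 0.5)
  summary <- growth_by_type_and_percentile(growth, quad_tbl, n_bins = 10)
  ov <- summary[summary$percentile_bin == "overall", ]
  for (i in seq_len(nrow(ov))) {
    planted <- exp(cfg$archetypes$growth_log_mean[
      cfg$archetypes$stress_type == as.character(ov$stress_type[i])
    ])
    expect_lt(abs(ov$gm[i] - planted), 3 * ov$gse[i])
  }
  expect_equal(
    as.character(ov$stress_type[which.max(ov$gm)]), "positive_stress"
  )
})

test_that("stratification partitions and localises effects", {
  sc <- make_scored_cohort(seed = 61)
  ids <- sc$growth$company_id
  one <- tibble::tibble(company_id = ids, stratum = "all")
  strat1 <- stratified_growth(sc$growth, sc$quad, one)
  plain <- growth_by_type_and_percentile(sc$growth, sc$quad)
  expect_equal(strat1$gm, plain$gm, tolerance = 1e-12)

  two <- tibble::tibble(
    company_id = ids,
    stratum = rep(c("s1", "s2"), length.out = length(ids))
  )
  strat2 <- stratified_growth(sc$growth, sc$quad, two)
  expect_equal(
    sum(strat2$N[strat2$percentile_bin == "overall"]),
    nrow(sc$growth)
  )
  # unlabeled companies land in "unknown"
  strat3 <- stratified_growth(sc$growth, sc$quad, two[-1, ])
  expect_true("unknown" %in% strat3$stratum)

  # a growth advantage planted in one stratum shows up only there
  boosted <- sc$growth
  s1 <- two$stratum == "s1"
  boosted$growth[s1] <- boosted$growth[s1] * 4
  strat4 <- stratified_growth(boosted, sc$quad, two, n_bins = 1)
  ov <- strat4[strat4$percentile_bin == "overall", ]
  expect_gt(mean(ov$gm[ov$stratum == "s1"]), mean(ov$gm[ov$stratum == "s2"]))
})
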