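Package: stressquad
Title: Stress-by-Rating Quadrant Analysis of Employee Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Places companies on a two-dimensional stress-by-rating space
    built from employee reviews: a lexicon matcher detects workplace-stress
    mentions, companies are z-scored on average rating and stress-mention
    rate and assigned to one of four stress types (low stress, passive,
    negative stress, positive stress), and each company receives a geometric
    association score with its type. The package aggregates volume-weighted
    yearly stress indices, characterises each type by class-based TF-IDF
    keywords with chi-square association tests, and relates stress type to
    long-term stock growth via geometric means and geometric standard
    errors. A seeded synthetic-cohort generator with planted archetypes
    makes every stage testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
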