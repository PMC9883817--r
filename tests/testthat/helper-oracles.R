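# Independent brute-force oracles, deliberately coded along different
# routes than the package internals.

# Character-by-character phrase scan: at every position try each phrase
# (longest first), require non-alphanumeric neighbours, jump past a match.
oracle_match <- function(text, phrases) {
  low <- tolower(text)
  n <- nchar(low)
  phrases <- phrases[order(-nchar(phrases))]
  out <- list()
  i <- 1
  is_word <- function(ch) grepl("[[:alnum:]]", ch)
  while (i <= n) {
    matched <- FALSE
    for (ph in phrases) {
      len <- nchar(ph)
      if (i + len - 1 > n) next
      seg <- substr(low, i, i + len - 1)
      if (gsub("[[:space:]]+", " ", seg) != ph) next
      before <- if (i == 1) "" else substr(low, i - 1, i - 1)
      after <- if (i + len > n) "" else substr(low, i + len, i + len)
      if ((before == "" || !is_word(before)) &&
          (after == "" || !is_word(after))) {
        out[[length(out) + 1]] <- data.frame(
          phrase = ph, start = i, end = i + len - 1
        )
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(phrase = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

# Association score via atan2 (the package uses arccos of the two ratios).
oracle_f <- function(zr, zs) {
  R <- sqrt(zr^2 + zs^2)
  if (R == 0) {
    return(0)
  }
  theta <- atan2(abs(zs), abs(zr)) # angle from the x-axis in [0, pi/2]
  gamma <- abs(theta - pi / 4)
  R / (gamma + pi)
}

# Textbook chi-square statistic on a contingency table.
oracle_chisq_stat <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Simple any-phrase indicator, one grepl per phrase.
oracle_stress_flag <- function(texts, phrases) {
  flag <- rep(FALSE, length(texts))
  for (ph in phrases) {
    flag <- flag | grepl(paste0("\\b", ph, "\\b"), tolower(texts))
  }
  flag
}

# Loop-based reimplementation of the yearly index: per-year company stats,
# population z-scores, sign-based quadrant, radial/angular association,
# volume weights, and the per-type weighted sum.
oracle_yearly_index <- function(reviews, phrases, years) {
  rows <- list()
  for (y in years) {
    rv <- reviews[as.integer(format(as.Date(reviews$date), "%Y")) == y, ]
    comps <- sort(unique(rv$company_id))
    stress_flag <- oracle_stress_flag(rv$text, phrases)
    rating <- stress <- npost <- numeric(length(comps))
    for (k in seq_along(comps)) {
      sel <- rv$company_id == comps[k]
      npost[k] <- sum(sel)
      rating[k] <- mean(rv$rating[sel])
      stress[k] <- mean(stress_flag[sel])
    }
    sd_pop <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
    zr <- (rating - mean(rating)) / sd_pop(rating)
    zs <- (stress - mean(stress)) / sd_pop(stress)
    type <- ifelse(
      zr >= 0 & zs < 0, "low_stress",
      ifelse(zr < 0 & zs < 0, "passive",
             ifelse(zr < 0 & zs >= 0, "negative_stress", "positive_stress"))
    )
    w <- npost / sum(npost)
    fvals <- vapply(seq_along(comps), function(k) oracle_f(zr[k], zs[k]),
                    numeric(1))
    for (s in c("low_stress", "passive", "negative_stress",
                "positive_stress")) {
      rows[[length(rows) + 1]] <- data.frame(
        year = y, stress_type = s,
        m = sum(fvals[type == s] * w[type == s])
      )
    }
  }
  do.call(rbind, rows)
}

tiny_config <- function(n = 5, seed = 101, years = 2009:2011,
                        reviews_per_year = 60, ...) {
  arch <- default_archetypes()
  arch$reviews_per_year_mean <- reviews_per_year
  cohort_config(
    n_companies_per_type = n, years = years, seed = seed,
    archetypes = arch, ...
  )
}
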