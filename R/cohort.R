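#' Reference cohort: 53 subjects, three groups
#'
#' A deterministic synthetic cohort reproducing the study-scale demographic
#' table for temporal-lobe-epilepsy research: 20 healthy controls (HC,
#' 10M/10F, age 27.95 +/- 6.32), 19 left-TLE patients (11M/8F,
#' 32.10 +/- 8.47) and 14 right-TLE patients (10M/4F, 28.28 +/- 6.28).
#' Ages are drawn from group normals under a fixed internal seed and then
#' affinely adjusted so each group's sample mean and SD equal the quoted
#' values exactly; only the first two moments are constrained.
#'
#' @return A tibble with columns `subject`, `group` (factor HC/LTLE/RTLE),
#'   `age` (years), `sex` (`"M"`/`"F"`).
#' @examples
#' cohort <- table1_cohort()
#' dplyr::count(cohort, group, sex)
#' @export
table1_cohort <- function() {
  spec <- tibble::tibble(
    group = c("HC", "LTLE", "RTLE"),
    n = c(20L, 19L, 14L),
    n_male = c(10L, 11L, 10L),
    age_mean = c(27.95, 32.10, 28.28),
    age_sd = c(6.32, 8.47, 6.28)
  )
  withr_seed(20220949L, {
    rows <- purrr::pmap(spec, function(group, n, n_male, age_mean, age_sd) {
      raw <- stats::rnorm(n)
      age <- age_mean + age_sd * (raw - mean(raw)) / stats::sd(raw)
      tibble::tibble(
        group = group,
        age = round(age, 2),
        sex = rep(c("M", "F"), c(n_male, n - n_male))
      )
    })
    out <- dplyr::bind_rows(rows)
    # re-match moments after rounding to 2 decimals
    out <- dplyr::mutate(
      dplyr::group_by(out, group),
      age = round(age_mean_for(group[1]) +
                    age_sd_for(group[1]) * (age - mean(age)) / stats::sd(age), 6)
    )
    out <- dplyr::ungroup(out)
    out$subject <- sprintf("sub%02d", seq_len(nrow(out)))
    out$group <- factor(out$group, levels = c("HC", "LTLE", "RTLE"))
    dplyr::select(out, "subject", "group", "age", "sex")
  })
}

age_mean_for <- function(g) c(HC = 27.95, LTLE = 32.10, RTLE = 28.28)[[g]]
age_sd_for <- function(g) c(HC = 6.32, LTLE = 8.47, RTLE = 6.28)[[g]]

validate_cohort <- function(cohort) {
  need <- c("subject", "group", "age", "sex")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(cohort$subject)) stop("subject ids must be unique")
  if (nrow(cohort) == 0L) stop("cohort is empty")
  invisible(cohort)
}

#' Group age summaries from a cohort table
#'
#' @param cohort A cohort tibble (`subject`, `group`, `age`, `sex`).
#' @return A tibble with one row per group: `group`, `n`, `mean`, `sd`.
#' @export
cohort_age_summary <- function(cohort) {
  validate_cohort(cohort)
  dplyr::summarise(dplyr::group_by(cohort, .data$group),
                   n = dplyr::n(), mean = mean(.data$age),
                   sd = stats::sd(.data$age), .groups = "drop")
}

#' Chi-square test of homogeneity for a contingency table
#'
#' Pearson's chi-square on a groups x categories count table (no continuity
#' correction), as used to compare sex distributions across diagnostic
#' groups.
#'
#' @param counts An integer matrix (or data frame) of counts, at least 2x2,
#'   with positive row and column sums.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chisq_homogeneity(rbind(HC = c(10, 10), LTLE = c(11, 8), RTLE = c(10, 4)))
#' @export
chisq_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must be at least 2 x 2")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the one-way ANOVA F test for equal group means from per-group
#' `(n, mean, sd)` triples alone: between-group sum of squares about the
#' weighted grand mean, within-group sum of squares `sum((n_i - 1) sd_i^2)`.
#' Agrees exactly with `aov()` on raw data realizing the same summaries.
#'
#' @param summaries A data frame with columns `n`, `mean`, `sd` (one row per
#'   group), e.g. from [cohort_age_summary()].
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @examples
#' anova_from_summary(data.frame(n = c(20, 19, 14),
#'                               mean = c(27.95, 32.10, 28.28),
#'                               sd = c(6.32, 8.47, 6.28)))
#' @export
anova_from_summary <- function(summaries) {
  need <- c("n", "mean", "sd")
  if (!all(need %in% names(summaries))) {
    stop("summaries need columns: ", paste(need, collapse = ", "))
  }
  n <- summaries$n; mu <- summaries$mean; s <- summaries$sd
  if (length(n) < 2L) stop("need at least two groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(s < 0)) stop("sd must be >= 0")
  grand <- sum(n * mu) / sum(n)
  ssb <- sum(n * (mu - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- length(n) - 1L
  df2 <- as.integer(sum(n) - length(n))
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pooled moments from group summaries
#'
#' Overall mean and overall (pooled) standard deviation of the combined
#' sample implied by per-group `(n, mean, sd)`: total sum of squares is the
#' within-group part plus the between-group part, divided by `N - 1`.
#'
#' @inheritParams anova_from_summary
#' @return A one-row tibble: `n`, `mean`, `sd`.
#' @export
pooled_moments <- function(summaries) {
  n <- summaries$n; mu <- summaries$mean; s <- summaries$sd
  grand <- sum(n * mu) / sum(n)
  ss <- sum((n - 1) * s^2) + sum(n * (mu - grand)^2)
  tibble::tibble(n = sum(n), mean = grand, sd = sqrt(ss / (sum(n) - 1)))
}
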