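#' Convert stratum rates to meta-analysis inputs
#'
#' For one (outcome, age group, sex) stratum across databases, the pooled
#' quantity is the natural log of the rate on the events-per-person-year
#' scale, `y = log(events / person_years)`, with delta-method standard error
#' `se = 1 / sqrt(events)` (Poisson count). Suppressed cells never enter
#' pooling. Zero-event cells have no finite log rate; by default they are
#' excluded (and flagged in the `zero_excluded` attribute), or retained with
#' a 0.5-event continuity correction.
#'
#' @param rates Tibble with columns `database_id`, `events`, `person_years`
#'   and (if present) `suppressed`; one row per database for a single
#'   stratum.
#' @param zero_policy `"exclude"` (default) or `"continuity"` (adds 0.5 to
#'   zero counts).
#' @return Tibble `database_id`, `y`, `se`, `events`, `person_years`; the
#'   number of zero-event rows dropped is attached as attribute
#'   `zero_excluded`.
#' @export
to_meta_input <- function(rates, zero_policy = c("exclude", "continuity")) {
  zero_policy <- match.arg(zero_policy)
  if ("suppressed" %in% names(rates)) rates <- filter(rates, !.data$suppressed)
  if (nrow(rates) == 0) {
    out <- tibble(database_id = character(), y = double(), se = double(),
                  events = double(), person_years = double())
    attr(out, "zero_excluded") <- 0L
    return(out)
  }
  zero <- rates$events == 0
  n_zero <- 0L
  if (zero_policy == "exclude") {
    n_zero <- sum(zero)
    rates <- rates[!zero, , drop = FALSE]
    ev <- rates$events
  } else {
    ev <- ifelse(zero, rates$events + 0.5, rates$events)
  }
  out <- tibble(
    database_id = rates$database_id,
    y = log(ev / rates$person_years),
    se = 1 / sqrt(ev),
    events = ev,
    person_years = rates$person_years
  )
  attr(out, "zero_excluded") <- n_zero
  out
}

#' DerSimonian-Laird random-effects pooling of log rates
#'
#' Moment-based random-effects meta-analysis. With within-study variances
#' `v_i = se_i^2` and fixed-effect weights `w_i = 1/v_i`, the heterogeneity
#' statistic is `Q = sum w_i (y_i - y_FE)^2`; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / C)` with `C = sum w_i - sum w_i^2 / sum w_i`.
#' Random-effects weights `1/(v_i + tau2)` give the pooled log rate, its
#' standard error, and a normal 95% CI, all back-transformed by
#' exponentiation to the rate-per-100 000-person-years scale.
#'
#' @param input Tibble from [to_meta_input()] with columns `y`, `se` (and
#'   optionally `database_id`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `bg_meta`: a list with `k`, `y_pooled`,
#'   `se_pooled`, `tau2`, `Q`, `i2`, `ci_low_y`, `ci_high_y`, plus the
#'   rate-scale `pooled_rate`, `ci_low`, `ci_high` (per 100 000 PY) and the
#'   normalised random-effects `weights`.
#' @export
dersimonian_laird <- function(input, conf_level = 0.95) {
  k <- nrow(input)
  if (k < 2) {
    abort("at least two databases are required to pool (k >= 2)",
          class = "bgrates_pooling_refused")
  }
  if (any(!is.finite(input$y)) || any(input$se <= 0)) {
    abort("y must be finite and se positive", class = "bgrates_domain_error")
  }
  y <- input$y
  v <- input$se^2
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (v + tau2)
  y_pooled <- sum(ws * y) / sum(ws)
  se_pooled <- 1 / sqrt(sum(ws))
  z <- qnorm(1 - (1 - conf_level) / 2)
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(
    k = k,
    y_pooled = y_pooled,
    se_pooled = se_pooled,
    tau2 = tau2,
    Q = Q,
    i2 = i2,
    ci_low_y = y_pooled - z * se_pooled,
    ci_high_y = y_pooled + z * se_pooled,
    pooled_rate = exp(y_pooled) * 1e5,
    ci_low = exp(y_pooled - z * se_pooled) * 1e5,
    ci_high = exp(y_pooled + z * se_pooled) * 1e5,
    conf_level = conf_level,
    weights = ws / sum(ws),
    database_id = if ("database_id" %in% names(input)) input$database_id
  ), class = "bg_meta")
}

#' 95% prediction interval for the rate in a new database
#'
#' Higgins-type t-interval on the log scale:
#' `y_pooled +/- t(0.975; k-2) * sqrt(tau2 + se_pooled^2)`, back-transformed
#' to the per-100 000-person-years scale. Undefined (returned as `NA`) for
#' fewer than three databases.
#'
#' @param fit A `bg_meta` object from [dersimonian_laird()].
#' @return Named numeric `c(pi_low, pi_high)` per 100 000 PY; both `NA` when
#'   `k < 3`.
#' @export
prediction_interval <- function(fit) {
  stopifnot(inherits(fit, "bg_meta"))
  if (fit$k < 3) return(c(pi_low = NA_real_, pi_high = NA_real_))
  a <- (1 - fit$conf_level) / 2
  tq <- qt(1 - a, df = fit$k - 2)
  half <- tq * sqrt(fit$tau2 + fit$se_pooled^2)
  c(pi_low = exp(fit$y_pooled - half) * 1e5,
    pi_high = exp(fit$y_pooled + half) * 1e5)
}

.cioms_levels <- c("very_rare", "rare", "uncommon", "common", "very_common")

#' Classify a rate into CIOMS adverse-event frequency categories
#'
#' The CIOMS ladder on the per-person-year fraction: very common (>= 1/10),
#' common (< 1/10 to >= 1/100), uncommon (< 1/100 to >= 1/1000), rare
#' (< 1/1000 to >= 1/10 000), very rare (< 1/10 000). Each lower boundary is
#' inclusive, so exactly 1000 per 100 000 PY (1/100) is common.
#'
#' @param rate_100k Non-negative rate(s) per 100 000 person-years.
#' @return Ordered factor with levels very_rare < rare < uncommon < common <
#'   very_common.
#' @export
#' @examples
#' classify_cioms(c(1400, 20, 1000))
classify_cioms <- function(rate_100k) {
  if (any(rate_100k < 0, na.rm = TRUE)) {
    abort("rates must be non-negative", class = "bgrates_domain_error")
  }
  frac <- rate_100k / 1e5
  cut(frac, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 1e-1, Inf),
      labels = .cioms_levels, right = FALSE, ordered_result = TRUE)
}

#' @export
print.bg_meta <- function(x, ...) {
  cat(sprintf(
    "DerSimonian-Laird random-effects pooling of %d databases\n", x$k))
  cat(sprintf("  pooled rate: %.2f per 100 000 PY (%.0f%% CI %.2f to %.2f)\n",
              x$pooled_rate, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  tau^2 = %.4f, Q = %.3f, I^2 = %.1f%%\n",
              x$tau2, x$Q, 100 * x$i2))
  pi <- prediction_interval(x)
  if (!is.na(pi[1])) {
    cat(sprintf("  95%% prediction interval: %.2f to %.2f per 100 000 PY\n",
                pi[1], pi[2]))
  }
  invisible(x)
}

#' Tidy a pooled meta-analysis fit
#'
#' @param x A `bg_meta` object.
#' @param ... Unused.
#' @return One-row tibble with the pooled rate, CI, prediction interval and
#'   CIOMS category.
#' @method tidy bg_meta
#' @export
tidy.bg_meta <- function(x, ...) {
  pi <- prediction_interval(x)
  tibble(
    k = x$k,
    pooled_rate = x$pooled_rate,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    pi_low = unname(pi[1]),
    pi_high = unname(pi[2]),
    cioms_category = classify_cioms(x$pooled_rate)
  )
}

#' Heterogeneity summary of a pooled fit
#'
#' @param x A `bg_meta` object.
#' @param ... Unused.
#' @return One-row tibble `k`, `tau2`, `Q`, `i2`.
#' @method glance bg_meta
#' @export
glance.bg_meta <- function(x, ...) {
  tibble(k = x$k, tau2 = x$tau2, Q = x$Q, i2 = x$i2)
}

#' Pool stratum rates across databases
#'
#' Runs the full meta-analysis for every (outcome, age group, sex) stratum
#' of a multi-database rate table: suppressed and zero-event cells are
#' removed per [to_meta_input()], strata with at least two remaining
#' databases are pooled with [dersimonian_laird()], prediction intervals are
#' added where at least three databases contribute, and the pooled rate is
#' classified on the CIOMS ladder.
#'
#' @param rates Output of [stratum_rates()].
#' @param zero_policy Passed to [to_meta_input()].
#' @param conf_level Confidence level.
#' @return Tibble `outcome_id`, `age_group`, `sex`, `k`, `pooled_rate`,
#'   `ci_low`, `ci_high`, `pi_low`, `pi_high`, `tau2`, `Q`, `i2`,
#'   `cioms_category`, `n_zero_excluded`, `n_suppressed_excluded`. Strata
#'   with fewer than two poolable databases are reported with `NA` results
#'   (pooling refused), so exclusions stay visible.
#' @export
pool_rates <- function(rates, zero_policy = "exclude", conf_level = 0.95) {
  rates |>
    group_by(.data$outcome_id, .data$age_group, .data$sex) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(res = map(.data$data, function(d) {
      n_sup <- if ("suppressed" %in% names(d)) sum(d$suppressed) else 0L
      mi <- to_meta_input(d, zero_policy = zero_policy)
      n_zero <- attr(mi, "zero_excluded")
      if (nrow(mi) < 2) {
        return(tibble(k = nrow(mi), pooled_rate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, pi_low = NA_real_, pi_high = NA_real_,
                      tau2 = NA_real_, Q = NA_real_, i2 = NA_real_,
                      cioms_category = factor(NA, levels = .cioms_levels,
                                              ordered = TRUE),
                      n_zero_excluded = n_zero,
                      n_suppressed_excluded = n_sup))
      }
      fit <- dersimonian_laird(mi, conf_level = conf_level)
      td <- tidy(fit)
      td$tau2 <- fit$tau2
      td$Q <- fit$Q
      td$i2 <- fit$i2
      td$n_zero_excluded <- n_zero
      td$n_suppressed_excluded <- n_sup
      td
    })) |>
    select(-"data") |>
    tidyr::unnest("res") |>
    arrange(.data$outcome_id, .data$age_group, .data$sex)
}
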