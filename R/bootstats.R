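#' Configuration for the bootstrap testing machinery
#'
#' @param B_test Number of bootstrap resamples for hypothesis tests.
#' @param B_ci Number of resamples for percentile confidence intervals.
#' @param ci_level Confidence level for percentile intervals.
#' @param seed Master seed; per-test substreams are derived deterministically
#'   from it together with the endpoint and comparison labels, so serial and
#'   re-ordered execution agree.
#' @param adjust_method Multiplicity correction for test families, `"BH"`
#'   (default) or `"hochberg"`.
#' @param plus_one If `TRUE`, use the `(r + 1)/(B + 1)` p-value estimator
#'   instead of the plain proportion `r/B`.
#' @param pooled If `TRUE` (default), resample from the pooled data under the
#'   null; if `FALSE`, resample each group separately (a location-shift
#'   bootstrap centred by the observed statistic).
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B_test = 10000L, B_ci = 1000L, ci_level = 0.95,
                             seed = 1L, adjust_method = c("BH", "hochberg"),
                             plus_one = FALSE, pooled = TRUE) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(B_test >= 1L, B_ci >= 1L, ci_level > 0, ci_level < 1)
  structure(list(B_test = as.integer(B_test), B_ci = as.integer(B_ci),
                 ci_level = ci_level, seed = as.integer(seed),
                 adjust_method = adjust_method, plus_one = isTRUE(plus_one),
                 pooled = isTRUE(pooled)),
            class = "bootstrap_config")
}

# Deterministic 31-bit substream seed from a master seed and labels.
derive_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (k in utf8ToInt(labs)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Column medians of a matrix via one radix sort over all entries.
col_medians <- function(m) {
  n <- nrow(m)
  s <- matrix(m[order(col(m), m, method = "radix")], nrow = n)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L, ] else (s[n %/% 2L, ] + s[n %/% 2L + 1L, ]) / 2
}

#' Pooled two-sample bootstrap test on the absolute median difference
#'
#' The observed statistic is `|median(A) - median(B)|`. Under the null the two
#' groups are pooled; each of `B_test` resamples draws `n_A + n_B` values with
#' replacement from the pool, assigns the first `n_A` to pseudo-A and the rest
#' to pseudo-B (respecting the observed group sizes), and recomputes the
#' statistic. The two-sided p-value is the proportion of bootstrap statistics
#' that meet or exceed the observed one, so the smallest reportable p is 0
#' (or `1/(B+1)` with `plus_one = TRUE`). Medians of even-sized samples are
#' the mean of the two central order statistics.
#'
#' @param group_a,group_b Numeric vectors with >= 2 non-missing values each;
#'   missing values must be removed upstream.
#' @param config A [bootstrap_config()].
#' @param endpoint,comparison Labels recorded in the result and used to derive
#'   the test's RNG substream.
#' @return A one-row tibble: `endpoint`, `comparison`, `n_a`, `n_b`,
#'   `observed_stat`, `p_raw`, `B`, `seed` (the derived substream seed).
#' @export
bootstrap_median_test <- function(group_a, group_b, config = bootstrap_config(),
                                  endpoint = "", comparison = "") {
  if (anyNA(group_a) || anyNA(group_b)) {
    stop("missing values must be removed before testing", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2L || n_b < 2L) {
    stop("each group needs >= 2 values (got ", n_a, " and ", n_b, ")",
         call. = FALSE)
  }
  t_obs <- abs(stats::median(group_a) - stats::median(group_b))
  B <- config$B_test
  sub_seed <- derive_seed(config$seed, endpoint, comparison)
  n <- n_a + n_b
  # sorted draws make the result invariant to reordering within groups
  group_a <- sort(group_a)
  group_b <- sort(group_b)
  t_star <- withr::with_seed(sub_seed, {
    if (config$pooled) {
      pool <- sort(c(group_a, group_b))
      draws <- matrix(pool[sample.int(n, n * B, replace = TRUE)], nrow = n)
      abs(col_medians(draws[seq_len(n_a), , drop = FALSE]) -
            col_medians(draws[(n_a + 1L):n, , drop = FALSE]))
    } else {
      da <- matrix(group_a[sample.int(n_a, n_a * B, replace = TRUE)], nrow = n_a)
      db <- matrix(group_b[sample.int(n_b, n_b * B, replace = TRUE)], nrow = n_b)
      abs(abs(col_medians(da) - col_medians(db)) - t_obs)
    }
  })
  r <- sum(t_star >= t_obs)
  p <- if (config$plus_one) (r + 1) / (B + 1) else r / B
  tibble::tibble(endpoint = endpoint, comparison = comparison,
                 n_a = n_a, n_b = n_b, observed_stat = t_obs,
                 p_raw = p, B = B, seed = sub_seed)
}

#' Adjust p-values for multiple testing
#'
#' Step-up adjustment within one family: Benjamini-Hochberg for the endpoint
#' test family, Hochberg for pairwise PERMANOVA comparisons. Adjusted values
#' are attached to the original positions and clipped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` or `"hochberg"`.
#' @return Adjusted p-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Percentile bootstrap confidence interval for the median
#'
#' Draws `B_ci` resamples with replacement from the observed values and takes
#' the `(1 - level)/2` and `(1 + level)/2` percentiles of the resampled
#' medians.
#'
#' @param values Numeric vector with >= 2 non-missing values.
#' @param config A [bootstrap_config()]; `B_ci` and `ci_level` are used.
#' @param label Label mixed into the RNG substream derivation.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_median_ci <- function(values, config = bootstrap_config(),
                                label = "") {
  values <- sort(values[!is.na(values)])
  n <- length(values)
  if (n < 2L) stop("need >= 2 non-missing values for a CI", call. = FALSE)
  B <- config$B_ci
  sub_seed <- derive_seed(config$seed, "ci", label)
  meds <- withr::with_seed(sub_seed, {
    draws <- matrix(values[sample.int(n, n * B, replace = TRUE)], nrow = n)
    col_medians(draws)
  })
  alpha <- (1 - config$ci_level) / 2
  q <- stats::quantile(meds, probs = c(alpha, 1 - alpha), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Run the full endpoint x comparison bootstrap test family
#'
#' Tests every non-control group against the designated control for every
#' endpoint, then adjusts p-values across the whole family (all endpoints and
#' comparisons of one assay run form one family by default).
#'
#' @param endpoint_table Output of [build_endpoint_table()] with a group label
#'   column.
#' @param control Label of the control group (for the colonized-versus-exposed
#'   design, the colonized vehicle-control group).
#' @param config A [bootstrap_config()].
#' @param group_col Name of the group label column.
#' @param endpoints Endpoint columns to test; defaults to the 25 standard
#'   endpoints present in the table.
#' @return A tibble with one row per endpoint x comparison: sizes, observed
#'   statistic, raw and adjusted p, `B` and substream seed. Wells with a
#'   missing endpoint value are dropped from that endpoint's tests;
#'   `n_dropped_*` columns record how many.
#' @export
run_endpoint_tests <- function(endpoint_table, control,
                               config = bootstrap_config(),
                               group_col = "group", endpoints = NULL) {
  if (!group_col %in% names(endpoint_table)) {
    stop("group column '", group_col, "' not found", call. = FALSE)
  }
  groups <- unique(endpoint_table[[group_col]])
  if (!control %in% groups) {
    stop("control group '", control, "' not present in the data", call. = FALSE)
  }
  if (is.null(endpoints)) {
    endpoints <- intersect(endpoint_names(), names(endpoint_table))
  }
  others <- setdiff(groups, control)
  res <- list()
  for (ep in endpoints) {
    ctrl_all <- endpoint_table[[ep]][endpoint_table[[group_col]] == control]
    ctrl <- ctrl_all[!is.na(ctrl_all)]
    for (g in others) {
      trt_all <- endpoint_table[[ep]][endpoint_table[[group_col]] == g]
      trt <- trt_all[!is.na(trt_all)]
      row <- bootstrap_median_test(ctrl, trt, config, endpoint = ep,
                                   comparison = paste(g, "vs", control))
      row$n_dropped_control <- length(ctrl_all) - length(ctrl)
      row$n_dropped_treatment <- length(trt_all) - length(trt)
      res[[length(res) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(res)
  out$p_adj <- adjust_pvalues(out$p_raw, config$adjust_method)
  out
}

#' Per-second median and percentile CI series across wells
#'
#' For plotting group traces as median with a bootstrap confidence band: for
#' each 1-s bin, the across-well median and its percentile bootstrap CI.
#'
#' @param activity Long-format activity tibble (`well_id`, `time_s`,
#'   `activity`).
#' @param config A [bootstrap_config()]; `B_ci`/`ci_level` are used.
#' @return Tibble with `time_s`, `median`, `lower`, `upper`, `n_wells`.
#' @export
median_ci_series <- function(activity, config = bootstrap_config()) {
  times <- sort(unique(activity$time_s))
  rows <- lapply(times, function(t) {
    v <- activity$activity[activity$time_s == t]
    v <- v[!is.na(v)]
    ci <- bootstrap_median_ci(v, config, label = as.character(t))
    tibble::tibble(time_s = t, median = stats::median(v),
                   lower = ci["lower"], upper = ci["upper"],
                   n_wells = length(v))
  })
  dplyr::bind_rows(rows)
}
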