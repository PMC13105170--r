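#' Mean acoustic startle response across a stimulus train
#'
#' Startle responses to the repeated stimuli of one block are averaged across
#' trials; masked trials are dropped.
#'
#' @param per_stimulus Numeric vector of >= 1 stimulus-second activities.
#' @return Mean response, or `NA` if every trial is masked.
#' @export
asr_metric <- function(per_stimulus) {
  if (length(per_stimulus) < 1L) return(NA_real_)
  if (all(is.na(per_stimulus))) return(NA_real_)
  mean(per_stimulus, na.rm = TRUE)
}

#' Within-bout habituation score
#'
#' Activity summed over the final 10 stimuli of a habituation bout is scaled
#' by the combined activity of the initial and final sets of 10 stimuli:
#' `last10 / (first10 + last10)`. The scaling absorbs differences in
#' individual baseline startle magnitude: 0.5 means no habituation, values
#' below 0.5 indicate a declining response, 0 complete habituation. A variant
#' that compares the last-10 mean against the mean of the combined first and
#' last sets (differing by a factor of 2 in the denominator contribution) is
#' available for sensitivity analysis.
#'
#' @param bout_vector Ordered per-stimulus responses of one full bout.
#' @param n_compare Number of stimuli in the leading/trailing comparison sets.
#' @param variant `"sum"` (default) uses `last/(first+last)` on sums;
#'   `"mean"` uses `mean(last) / mean(c(first, last))`.
#' @return Score in `[0, 1]` (`"sum"` variant), or `NA` when both sums are 0
#'   or the bout is fully masked.
#' @export
bout_habituation_score <- function(bout_vector, n_compare = 10L,
                                   variant = c("sum", "mean")) {
  variant <- match.arg(variant)
  n <- length(bout_vector)
  if (n < 2L * n_compare) {
    stop("bout vector has ", n, " responses; need at least ", 2L * n_compare,
         call. = FALSE)
  }
  first <- bout_vector[seq_len(n_compare)]
  last <- bout_vector[(n - n_compare + 1L):n]
  if (all(is.na(first)) || all(is.na(last))) return(NA_real_)
  s_first <- sum(first, na.rm = TRUE)
  s_last <- sum(last, na.rm = TRUE)
  if (s_first + s_last == 0) return(NA_real_)
  if (variant == "sum") {
    s_last / (s_first + s_last)
  } else {
    mean(last, na.rm = TRUE) / mean(c(first, last), na.rm = TRUE)
  }
}

#' Potentiation-of-habituation ratio across bouts
#'
#' Ratio of total motor activity during the final habituation bout to the
#' summed activity of the initial and final bouts:
#' `final / (initial + final)`. Uses full bout-window totals (stimulus and
#' intra-bout gap seconds), distinguishing it from the within-bout score,
#' which uses stimulus seconds only.
#'
#' @param initial_total,final_total Non-negative bout-window activity totals.
#' @return Ratio in `[0, 1]`, or `NA` on `0/0` or masked input.
#' @export
potentiation_ratio <- function(initial_total, final_total) {
  if (is.na(initial_total) || is.na(final_total)) return(NA_real_)
  if (initial_total < 0 || final_total < 0) {
    stop("bout totals must be non-negative", call. = FALSE)
  }
  if (initial_total + final_total == 0) return(NA_real_)
  final_total / (initial_total + final_total)
}

#' Total activity across all habituation bouts
#'
#' @param bout_totals Activity summed over the full window of each bout.
#' @return Sum across bouts, or `NA` (with a warning) if any bout is missing.
#' @export
ash_sum <- function(bout_totals) {
  if (any(is.na(bout_totals))) {
    warning("missing bout total; habituation sum set to NA", call. = FALSE)
    return(NA_real_)
  }
  sum(bout_totals)
}

#' Memory-retention ratio across startle blocks
#'
#' Scales the mean post-habituation startle response against the combined
#' pre- and post-habituation high-intensity responses:
#' `post / (pre + post)`. 0.5 means full retention of the pre-habituation
#' response magnitude; lower values indicate a persistently reduced response.
#'
#' @param pre_mean,post_mean Non-negative mean startle responses of the block
#'   before and the block after habituation training.
#' @return Ratio in `[0, 1]`, or `NA` on `0/0` or masked input.
#' @export
retention_ratio <- function(pre_mean, post_mean) {
  if (is.na(pre_mean) || is.na(post_mean)) return(NA_real_)
  if (pre_mean < 0 || post_mean < 0) {
    stop("startle means must be non-negative", call. = FALSE)
  }
  if (pre_mean + post_mean == 0) return(NA_real_)
  post_mean / (pre_mean + post_mean)
}

# 25 endpoint values for one segmented trace
endpoints_from_segments <- function(seg) {
  iv <- seg$intervals
  asr_means <- vapply(seg$asr, asr_metric, numeric(1))
  n_bouts <- nrow(seg$bouts)
  ash1 <- if (n_bouts >= 1L) bout_habituation_score(seg$bouts[1L, ]) else NA_real_
  ash15 <- if (n_bouts >= 2L) {
    potentiation_ratio(unname(seg$bout_totals[1L]),
                       unname(seg$bout_totals[n_bouts]))
  } else NA_real_
  vals <- c(
    iv[paste0("BSL", 1:4)],
    VSR1 = unname(iv["VSR1"]), VMR1 = unname(iv["VMR1"]),
    VSR2 = unname(iv["VSR2"]),
    iv[paste0("VMR", 2:5)],
    ASR1 = unname(asr_means["ASR1"]), ISI1 = unname(iv["ISI1"]),
    IEI1 = unname(iv["IEI1"]),
    ASR2 = unname(asr_means["ASR2"]), ISI2 = unname(iv["ISI2"]),
    IEI2 = unname(iv["IEI2"]),
    ASH1 = ash1, `ASH1/5` = ash15, ASHsum = ash_sum(seg$bout_totals),
    IBI = unname(iv["IBI"]), IEI3 = unname(iv["IEI3"]),
    ASR3 = unname(asr_means["ASR3"]), ISI3 = unname(iv["ISI3"]),
    `ASR2/3` = retention_ratio(unname(asr_means["ASR2"]),
                               unname(asr_means["ASR3"]))
  )
  vals[endpoint_names()]
}

#' Build the wells x endpoints table
#'
#' Segments every well's trace against the schedule, derives the 25 endpoint
#' metrics, and joins plate metadata. Ratio endpoints that are undefined
#' (`0/0`) are recorded as missing, never as 0.
#'
#' @param activity Long-format activity tibble with columns `well_id`,
#'   `time_s` (0-based integer) and `activity`, as read by
#'   [read_activity_table()] or produced by [simulate_traces()].
#' @param metadata Plate metadata tibble keyed by `well_id` (typically with
#'   `colonization`, `treatment`, `concentration`, `flask` and a `group`
#'   label).
#' @param schedule A schedule from [build_schedule()].
#' @return A tibble with one row per well: metadata columns followed by the
#'   25 endpoint columns in the order of [endpoint_names()], plus a
#'   `n_masked_bins` audit column.
#' @export
build_endpoint_table <- function(activity, metadata, schedule) {
  stopifnot(all(c("well_id", "time_s", "activity") %in% names(activity)))
  stopifnot("well_id" %in% names(metadata))
  wells <- unique(activity$well_id)
  orphans <- setdiff(wells, metadata$well_id)
  if (length(orphans) > 0L) {
    stop("wells present in activity data but absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (is.null(attr(schedule, "segment_index"))) {
    attr(schedule, "segment_index") <- build_segment_index(schedule)
  }
  ord <- order(activity$well_id, activity$time_s)
  times <- split(activity$time_s[ord], activity$well_id[ord])
  traces <- split(activity$activity[ord], activity$well_id[ord])
  rows <- lapply(wells, function(w) {
    t <- times[[w]]
    if (t[1] != 0L || any(diff(t) != 1L)) {
      stop("well ", w, " has silent gaps or duplicated time bins; masked ",
           "bins must be explicit NA rows", call. = FALSE)
    }
    seg <- segment_trace(traces[[w]], schedule)
    ep <- endpoints_from_segments(seg)
    tibble::tibble(well_id = w, !!!as.list(ep),
                   n_masked_bins = seg$n_masked)
  })
  ep_tab <- dplyr::bind_rows(rows)
  dplyr::left_join(metadata, ep_tab, by = "well_id")
}

#' Write an endpoint table as TSV with a missing-value audit
#'
#' @param endpoint_table Output of [build_endpoint_table()].
#' @param path Output TSV path; missing values are written as empty fields.
#' @param audit_path Optional JSON path for the per-well missing-endpoint
#'   audit.
#' @return `path`, invisibly.
#' @export
write_endpoint_table <- function(endpoint_table, path, audit_path = NULL) {
  readr::write_tsv(endpoint_table, path, na = "")
  if (!is.null(audit_path)) {
    eps <- intersect(endpoint_names(), names(endpoint_table))
    audit <- lapply(seq_len(nrow(endpoint_table)), function(i) {
      miss <- eps[vapply(eps, function(e) is.na(endpoint_table[[e]][i]),
                         logical(1))]
      list(well_id = endpoint_table$well_id[i], missing_endpoints = miss,
           n_masked_bins = endpoint_table$n_masked_bins[i])
    })
    jsonlite::write_json(audit, audit_path, auto_unbox = TRUE)
  }
  invisible(path)
}
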