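#' Assay protocol for the staged visual/acoustic motor response assay
#'
#' Defines the stimulus timeline of the plate-based larval assay as explicit
#' phase durations, all in whole seconds. The default values describe the
#' standard protocol: a 21-min dark acclimation, 10 min of light, 20 min of
#' dark, two five-stimulus acoustic startle blocks (low then high intensity,
#' 1-min spacing), five 30-stimulus habituation bouts delivered 1 min apart,
#' a 3-min rest, and a final five-stimulus high-intensity block.
#'
#' @param acclimation_duration Dark acclimation length in seconds. Must
#'   accommodate four 5-min baseline intervals (>= 1200).
#' @param light_phase_duration Length of the light phase in seconds.
#' @param post_light_dark_duration Length of the dark phase that follows the
#'   light phase, in seconds (visual startle + ramp + return-to-baseline).
#' @param startle_window Length of the window scored as the startle response
#'   to a single stimulus, in seconds.
#' @param n_stimuli_per_asr Number of stimuli per acoustic startle block.
#' @param inter_stimulus_gap Stimulus onset-to-onset spacing within an
#'   acoustic startle block, in seconds.
#' @param n_habituation_bouts Number of habituation bouts.
#' @param stimuli_per_bout Number of stimuli per habituation bout.
#' @param intra_bout_stimulus_period Onset-to-onset period of stimuli inside a
#'   bout, in seconds (1-s stimulus followed by a 1-s gap by default).
#' @param inter_bout_gap Gap between consecutive habituation bouts, seconds.
#' @param iei1_duration,iei2_duration,iei3_duration Inter-endpoint intervals
#'   after the first startle block, the second startle block, and the
#'   habituation phase, in seconds.
#' @return An object of class `assay_protocol` (a named list).
#' @export
assay_protocol <- function(acclimation_duration = 1260L,
                           light_phase_duration = 600L,
                           post_light_dark_duration = 1200L,
                           startle_window = 1L,
                           n_stimuli_per_asr = 5L,
                           inter_stimulus_gap = 60L,
                           n_habituation_bouts = 5L,
                           stimuli_per_bout = 30L,
                           intra_bout_stimulus_period = 2L,
                           inter_bout_gap = 60L,
                           iei1_duration = 60L,
                           iei2_duration = 60L,
                           iei3_duration = 180L) {
  p <- list(
    acclimation_duration = acclimation_duration,
    light_phase_duration = light_phase_duration,
    post_light_dark_duration = post_light_dark_duration,
    startle_window = startle_window,
    n_stimuli_per_asr = n_stimuli_per_asr,
    inter_stimulus_gap = inter_stimulus_gap,
    n_habituation_bouts = n_habituation_bouts,
    stimuli_per_bout = stimuli_per_bout,
    intra_bout_stimulus_period = intra_bout_stimulus_period,
    inter_bout_gap = inter_bout_gap,
    iei1_duration = iei1_duration,
    iei2_duration = iei2_duration,
    iei3_duration = iei3_duration
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != round(v)) {
      stop("protocol field '", nm, "' must be a strictly positive whole number",
           call. = FALSE)
    }
    p[[nm]] <- as.integer(v)
  }
  if (p$acclimation_duration < 4L * 300L) {
    stop("acclimation_duration must be >= 1200 s to hold four 5-min baseline ",
         "intervals", call. = FALSE)
  }
  if (p$intra_bout_stimulus_period < p$startle_window) {
    stop("intra_bout_stimulus_period must be >= startle_window", call. = FALSE)
  }
  if (p$inter_stimulus_gap < p$startle_window) {
    stop("inter_stimulus_gap must be >= startle_window", call. = FALSE)
  }
  if (p$light_phase_duration <= p$startle_window) {
    stop("light_phase_duration must exceed the startle window", call. = FALSE)
  }
  if (p$post_light_dark_duration <= p$startle_window + 3L * 300L) {
    stop("post_light_dark_duration must exceed startle window + three 5-min ",
         "return-to-baseline intervals", call. = FALSE)
  }
  class(p) <- "assay_protocol"
  p
}

# Length of one acoustic startle block: onsets spaced by inter_stimulus_gap,
# block ends when the last startle window closes.
asr_block_length <- function(p) {
  (p$n_stimuli_per_asr - 1L) * p$inter_stimulus_gap + p$startle_window
}

bout_length <- function(p) p$stimuli_per_bout * p$intra_bout_stimulus_period

#' Total assay length in seconds for a protocol
#' @param protocol An [assay_protocol()].
#' @return Integer number of 1-s bins the assay spans.
#' @export
protocol_length <- function(protocol) {
  stopifnot(inherits(protocol, "assay_protocol"))
  p <- protocol
  hab <- p$n_habituation_bouts * bout_length(p) +
    (p$n_habituation_bouts - 1L) * p$inter_bout_gap
  p$acclimation_duration + p$light_phase_duration + p$post_light_dark_duration +
    asr_block_length(p) + p$iei1_duration +
    asr_block_length(p) + p$iei2_duration +
    hab + p$iei3_duration + asr_block_length(p)
}

#' Build the endpoint window schedule for a protocol
#'
#' Lays the whole assay out as half-open `[start, end)` windows in whole
#' seconds, 0-based from assay start. Each 1-s bin belongs to at most one
#' window; the union of windows plus declared unassigned buffers tiles the
#' full assay. The four 5-min baseline intervals are anchored at assay start
#' (the transfer-related activity peak falls in the first interval); any
#' acclimation time beyond 20 min is a declared unassigned buffer.
#'
#' @param protocol An [assay_protocol()].
#' @return A tibble with columns `window` (unique instance label), `endpoint`
#'   (endpoint family the window contributes to, `NA` for buffers), `role`
#'   (`"interval"`, `"stimulus"`, `"gap"` or `"buffer"`), `stimulus_index`
#'   (position within a stimulus train, `NA` otherwise), `start`, `end`.
#' @export
build_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "assay_protocol"))
  p <- protocol
  rows <- list()
  add <- function(window, endpoint, role, start, len, stim = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      window = window, endpoint = endpoint, role = role,
      stimulus_index = as.integer(stim),
      start = as.integer(start), end = as.integer(start + len)
    )
  }
  t <- 0L

  # dark acclimation: four 5-min baseline intervals, remainder unassigned
  for (b in 1:4) {
    add(paste0("BSL", b), paste0("BSL", b), "interval", t, 300L)
    t <- t + 300L
  }
  buf <- p$acclimation_duration - 1200L
  if (buf > 0L) {
    add("ACCLIM_BUFFER", NA_character_, "buffer", t, buf)
    t <- t + buf
  }

  # light phase: 1-s visual startle, then basal activity
  add("VSR1", "VSR1", "stimulus", t, p$startle_window, 1L)
  t <- t + p$startle_window
  add("VMR1", "VMR1", "interval", t, p$light_phase_duration - p$startle_window)
  t <- t + p$light_phase_duration - p$startle_window

  # dark phase: startle, activity ramp, three return-to-baseline intervals
  add("VSR2", "VSR2", "stimulus", t, p$startle_window, 1L)
  t <- t + p$startle_window
  vmr2_len <- p$post_light_dark_duration - p$startle_window - 3L * 300L
  add("VMR2", "VMR2", "interval", t, vmr2_len)
  t <- t + vmr2_len
  for (v in 3:5) {
    add(paste0("VMR", v), paste0("VMR", v), "interval", t, 300L)
    t <- t + 300L
  }

  # an acoustic startle block: per-stimulus windows + the gaps between them
  asr_block <- function(label, isi_label, t0) {
    for (k in seq_len(p$n_stimuli_per_asr)) {
      s <- t0 + (k - 1L) * p$inter_stimulus_gap
      add(paste0(label, "_stim", k), label, "stimulus", s, p$startle_window, k)
      if (k < p$n_stimuli_per_asr) {
        add(paste0(isi_label, "_gap", k), isi_label, "gap",
            s + p$startle_window, p$inter_stimulus_gap - p$startle_window)
      }
    }
    t0 + asr_block_length(p)
  }

  t <- asr_block("ASR1", "ISI1", t)
  add("IEI1", "IEI1", "interval", t, p$iei1_duration)
  t <- t + p$iei1_duration
  t <- asr_block("ASR2", "ISI2", t)
  add("IEI2", "IEI2", "interval", t, p$iei2_duration)
  t <- t + p$iei2_duration

  # habituation bouts: stimuli at a fixed period, gaps inside the bout count
  # toward the bout window; bouts separated by inter-bout intervals
  for (b in seq_len(p$n_habituation_bouts)) {
    for (i in seq_len(p$stimuli_per_bout)) {
      s <- t + (i - 1L) * p$intra_bout_stimulus_period
      add(paste0("ASH", b, "_stim", i), paste0("ASH", b), "stimulus", s,
          p$startle_window, i)
      gap_len <- p$intra_bout_stimulus_period - p$startle_window
      if (gap_len > 0L) {
        add(paste0("ASH", b, "_gap", i), paste0("ASH", b), "gap",
            s + p$startle_window, gap_len)
      }
    }
    t <- t + bout_length(p)
    if (b < p$n_habituation_bouts) {
      add(paste0("IBI", b), "IBI", "interval", t, p$inter_bout_gap)
      t <- t + p$inter_bout_gap
    }
  }

  add("IEI3", "IEI3", "interval", t, p$iei3_duration)
  t <- t + p$iei3_duration
  t <- asr_block("ASR3", "ISI3", t)

  sched <- dplyr::bind_rows(rows)
  validate_schedule(sched, t)
  attr(sched, "total_length") <- t
  attr(sched, "protocol") <- p
  sched
}

# Tiling check: windows must be non-overlapping and cover [0, total) exactly.
validate_schedule <- function(sched, total) {
  s <- sched[order(sched$start), ]
  if (s$start[1] != 0L) {
    stop("schedule does not start at second 0 (first window '", s$window[1],
         "')", call. = FALSE)
  }
  if (nrow(s) > 1L) {
    gap <- which(s$start[-1] != s$end[-nrow(s)])
    if (length(gap) > 0L) {
      i <- gap[1]
      stop("schedule conflict between windows '", s$window[i], "' and '",
           s$window[i + 1L], "': [", s$start[i], ",", s$end[i], ") then [",
           s$start[i + 1L], ",", s$end[i + 1L], ")", call. = FALSE)
    }
  }
  if (s$end[nrow(s)] != total) {
    stop("schedule does not tile the assay: ends at ", s$end[nrow(s)],
         " instead of ", total, call. = FALSE)
  }
  invisible(TRUE)
}

#' Names of the 25 statistical endpoints, in assay order
#' @return Character vector of length 25.
#' @export
endpoint_names <- function() {
  c("BSL1", "BSL2", "BSL3", "BSL4",
    "VSR1", "VMR1", "VSR2", "VMR2", "VMR3", "VMR4", "VMR5",
    "ASR1", "ISI1", "IEI1", "ASR2", "ISI2", "IEI2",
    "ASH1", "ASH1/5", "ASHsum", "IBI", "IEI3", "ASR3", "ISI3", "ASR2/3")
}

#' Segment one activity trace against a schedule
#'
#' Maps each 1-s activity bin of a single well onto the schedule and returns
#' raw per-window summaries: mean activity per second for interval endpoints
#' (gaps of a startle block pooled into one inter-stimulus interval; all
#' inter-bout gaps pooled), the activity value in each stimulus second for
#' startle endpoints, the ordered per-stimulus response vector and the
#' full-window activity total for each habituation bout.
#'
#' Masked bins (`NA`) are excluded from means and counted; a window whose bins
#' are all masked yields `NA` and is flagged.
#'
#' @param values Numeric vector of non-negative activity values, one per 1-s
#'   bin from assay start; `NA` marks a masked bin.
#' @param schedule A schedule from [build_schedule()].
#' @return A list with elements `intervals` (named numeric), `asr` (list of
#'   per-stimulus response vectors), `bouts` (matrix, bouts x stimuli),
#'   `bout_totals` (numeric, activity summed over each full bout window),
#'   `n_masked` (number of masked bins inside scheduled windows) and
#'   `all_masked_windows` (character).
#' @export
segment_trace <- function(values, schedule) {
  idx <- attr(schedule, "segment_index")
  if (is.null(idx)) idx <- build_segment_index(schedule)
  total <- attr(schedule, "total_length")
  if (length(values) < total) {
    stop("trace shorter than schedule: ", length(values), " bins < ", total,
         call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("activity values must be non-negative", call. = FALSE)
  }
  masked_mean <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)

  intervals <- vapply(idx$interval_idx, function(i) masked_mean(values[i]),
                      numeric(1))
  asr <- lapply(idx$asr_idx, function(stims) {
    vapply(stims, function(i) masked_mean(values[i]), numeric(1))
  })
  n_bouts <- length(idx$bout_stim_idx)
  bouts <- t(vapply(idx$bout_stim_idx, function(stims) {
    vapply(stims, function(i) masked_mean(values[i]), numeric(1))
  }, numeric(length(idx$bout_stim_idx[[1]]))))
  bout_totals <- vapply(idx$bout_full_idx, function(i) {
    v <- values[i]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }, numeric(1))
  list(intervals = intervals, asr = asr, bouts = bouts,
       bout_totals = bout_totals,
       n_masked = sum(is.na(values[idx$sched_idx])),
       all_masked_windows = names(intervals)[is.na(intervals)])
}

# Precompute the bin-index lookup for each endpoint of a schedule so traces
# can be segmented without re-scanning the window table.
build_segment_index <- function(schedule) {
  sched <- schedule[schedule$role != "buffer", ]
  p <- attr(schedule, "protocol")
  win_idx <- function(rows) {
    unlist(Map(function(s, e) (s + 1L):e, rows$start, rows$end),
           use.names = FALSE)
  }
  interval_eps <- intersect(
    c(paste0("BSL", 1:4), "VSR1", "VMR1", "VSR2", paste0("VMR", 2:5),
      paste0("ISI", 1:3), paste0("IEI", 1:3), "IBI"),
    sched$endpoint)
  interval_idx <- lapply(stats::setNames(nm = interval_eps), function(ep) {
    win_idx(sched[sched$endpoint == ep, ])
  })
  stim_list <- function(ep) {
    rows <- sched[sched$endpoint == ep & sched$role == "stimulus", ]
    rows <- rows[order(rows$stimulus_index), ]
    lapply(seq_len(nrow(rows)), function(i) win_idx(rows[i, ]))
  }
  asr_idx <- lapply(stats::setNames(nm = intersect(paste0("ASR", 1:3),
                                                   sched$endpoint)), stim_list)
  bout_eps <- intersect(paste0("ASH", seq_len(p$n_habituation_bouts)),
                        sched$endpoint)
  list(interval_idx = interval_idx,
       asr_idx = asr_idx,
       bout_stim_idx = lapply(stats::setNames(nm = bout_eps), stim_list),
       bout_full_idx = lapply(stats::setNames(nm = bout_eps), function(ep) {
         win_idx(sched[sched$endpoint == ep, ])
       }),
       sched_idx = win_idx(sched))
}

#' Write a schedule as TSV
#' @param schedule A schedule from [build_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  readr::write_tsv(schedule, path)
  invisible(path)
}
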