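# Shared fixtures, built in code at test time.

default_schedule <- function() build_schedule(assay_protocol())

# A trace that is zero everywhere except over the given windows of `endpoint`
# (optionally only stimulus windows), where it takes `level`.
trace_with_endpoint <- function(schedule, endpoint, level = 1,
                                roles = c("interval", "stimulus", "gap")) {
  v <- rep(0, attr(schedule, "total_length"))
  rows <- schedule[!is.na(schedule$endpoint) &
                     schedule$endpoint == endpoint &
                     schedule$role %in% roles, ]
  for (i in seq_len(nrow(rows))) {
    v[(rows$start[i] + 1L):rows$end[i]] <- level
  }
  v
}

# Long-format activity tibble from a named list of trace vectors.
traces_to_activity <- function(traces) {
  total <- length(traces[[1]])
  tibble::tibble(
    well_id = rep(names(traces), each = total),
    time_s = rep(0:(total - 1L), times = length(traces)),
    activity = unlist(traces, use.names = FALSE))
}

toy_metadata <- function(well_ids, group = "g1") {
  tibble::tibble(well_id = well_ids, group = group,
                 colonization = "colonized", treatment = "vehicle",
                 concentration = 0, flask = "f1")
}

# Small protein table: one sample per row-block, explicit intensities.
toy_protein_table <- function(samples) {
  dplyr::bind_rows(lapply(names(samples), function(sid) {
    sp <- samples[[sid]]
    tibble::tibble(sample_id = sid, bioreactor = attr(sp, "bioreactor") %||% "br1",
                   phase = attr(sp, "phase") %||% "stabilization",
                   species = names(sp),
                   protein_group = paste0(sid, "_", names(sp), "_pg"),
                   intensity = as.numeric(sp), ko = NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
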