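#' @keywords internal
#' @importFrom dplyr .data
"_PACKAGE"

#' Read a long-format activity table
#'
#' Reads the per-well activity export (TSV/CSV with columns `well_id`,
#' `time_s`, `activity`). Tracking software that exports one row per
#' integration period is accommodated through `bin_width`: each exported bin
#' is resampled to 1-s bins by spreading its cumulative activity evenly.
#' After resampling every well must cover `0 .. L-1` contiguously; masked
#' bins are explicit `NA` activity values — silent gaps are an error.
#'
#' @param path Delimited text file; tab or comma separated (sniffed).
#' @param bin_width Width in seconds of the exported integration period.
#' @return Tibble `well_id`, `time_s` (integer), `activity` (double).
#' @export
read_activity_table <- function(path, bin_width = 1L) {
  stopifnot(bin_width >= 1L)
  tab <- read_delim_auto(path)
  need <- c("well_id", "time_s", "activity")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tab$time_s) || any(tab$time_s != round(tab$time_s),
                                     na.rm = TRUE)) {
    stop(path, ": time_s must be whole seconds", call. = FALSE)
  }
  if (any(is.na(tab$time_s))) {
    stop(path, ": time_s has missing values", call. = FALSE)
  }
  tab$time_s <- as.integer(tab$time_s)
  if (bin_width > 1L) {
    tab <- tibble::tibble(
      well_id = rep(tab$well_id, each = bin_width),
      time_s = rep(tab$time_s, each = bin_width) +
        rep(0:(bin_width - 1L), times = nrow(tab)),
      activity = rep(tab$activity / bin_width, each = bin_width))
  }
  check_contiguous_bins(tab)
  tab[, need]
}

check_contiguous_bins <- function(tab) {
  for (w in unique(tab$well_id)) {
    t <- sort(tab$time_s[tab$well_id == w])
    if (t[1] != 0L || any(diff(t) != 1L)) {
      stop("well ", w, " has silent time gaps or duplicate bins; masked bins ",
           "must be explicit NA rows", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read plate metadata keyed by well
#' @param path Delimited text file with a `well_id` column.
#' @return Metadata tibble.
#' @export
read_well_metadata <- function(path) {
  tab <- read_delim_auto(path)
  if (!"well_id" %in% names(tab)) {
    stop(path, ": metadata needs a well_id column", call. = FALSE)
  }
  tab
}

#' Read a species-resolved protein intensity table
#'
#' Required columns: `sample_id`, `bioreactor`, `phase`, `species`,
#' `protein_group`, `intensity`; optional `ko`. Negative intensities are
#' rejected with the offending row numbers.
#'
#' @param path Delimited text file.
#' @return Protein abundance tibble.
#' @export
read_protein_table <- function(path) {
  tab <- read_delim_auto(path)
  check_protein_table(tab)
  tab
}

#' Read a pathway membership map
#' @param path Two-column delimited file (`pathway_id`, `ko_id`).
#' @return Validated pathway map tibble.
#' @export
read_pathway_map <- function(path) {
  validate_pathway_map(read_delim_auto(path))
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Run the behavioral analysis pipeline
#'
#' Reads activity and plate metadata, segments every well on the protocol
#' schedule, derives the 25 endpoints, runs the pooled-bootstrap median tests
#' against the control group, and writes the endpoint table (TSV), the
#' missing-value audit (JSON), the test results (TSV + JSON with seeds and
#' resample counts), per-bin median/CI series per group (TSV) and a run
#' manifest.
#'
#' @param activity_path,metadata_path Input files (see
#'   [read_activity_table()], [read_well_metadata()]).
#' @param out_dir Output directory, created if needed.
#' @param control Control group label.
#' @param protocol An [assay_protocol()].
#' @param config A [bootstrap_config()].
#' @param bin_width Integration-period width of the activity export.
#' @param group_col Metadata column holding group labels.
#' @param ci_series Also write per-1-s-bin median + CI series per group
#'   (slower; off by default).
#' @return Invisibly, a list with `endpoints` and `tests` tibbles.
#' @export
run_behavior_pipeline <- function(activity_path, metadata_path, out_dir,
                                  control, protocol = assay_protocol(),
                                  config = bootstrap_config(),
                                  bin_width = 1L, group_col = "group",
                                  ci_series = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  activity <- read_activity_table(activity_path, bin_width = bin_width)
  metadata <- read_well_metadata(metadata_path)
  schedule <- build_schedule(protocol)
  endpoints <- build_endpoint_table(activity, metadata, schedule)
  write_endpoint_table(endpoints, file.path(out_dir, "endpoints.tsv"),
                       audit_path = file.path(out_dir, "endpoint_audit.json"))
  tests <- run_endpoint_tests(endpoints, control = control, config = config,
                              group_col = group_col)
  readr::write_tsv(tests, file.path(out_dir, "endpoint_tests.tsv"), na = "")
  jsonlite::write_json(tests, file.path(out_dir, "endpoint_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  if (ci_series) {
    for (g in unique(metadata[[group_col]])) {
      wells <- metadata$well_id[metadata[[group_col]] == g]
      ser <- median_ci_series(activity[activity$well_id %in% wells, ], config)
      readr::write_tsv(ser, file.path(out_dir, paste0("median_ci_", g, ".tsv")))
    }
  }
  write_manifest(out_dir, list(
    stage = "behavior", control = control, group_col = group_col,
    bin_width = bin_width, seed = config$seed, B_test = config$B_test,
    B_ci = config$B_ci, adjust_method = config$adjust_method,
    n_wells = nrow(endpoints),
    masked_bins_total = sum(endpoints$n_masked_bins)))
  invisible(list(endpoints = endpoints, tests = tests))
}

#' Run the metaproteomic community/function pipeline
#'
#' Computes proteome-weighted community profiles, per-species phase
#' statistics (Kruskal-Wallis + Dunn + BH), and — when a pathway map is
#' supplied — the coverage-filtered pathway matrix, phase log2 fold changes
#' with the KW filter, ordination scores, and global + pairwise PERMANOVA on
#' Bray-Curtis dissimilarities. All tables are written as TSV, statistics
#' additionally as JSON, and excluded pathways are always reported.
#'
#' @param protein_path Protein intensity table (see [read_protein_table()]).
#' @param out_dir Output directory.
#' @param pathway_map_path Optional pathway membership TSV; without it the
#'   pathway stage is skipped with a warning.
#' @param phase_a,phase_b Phases compared by the fold-change filter.
#' @param min_coverage,min_proteins,fc_threshold,alpha Filter thresholds.
#' @param n_perm,seed PERMANOVA permutations and seed.
#' @return Invisibly, a list with the computed objects.
#' @export
run_sihumix_pipeline <- function(protein_path, out_dir,
                                 pathway_map_path = NULL,
                                 phase_a = "stabilization",
                                 phase_b = "exposure",
                                 min_coverage = 0.15, min_proteins = 5L,
                                 fc_threshold = 0.2, alpha = 0.05,
                                 n_perm = 999L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_protein_table(protein_path)
  profiles <- community_profile(table)
  readr::write_tsv(profiles, file.path(out_dir, "community_profile.tsv"))
  stats_sp <- phase_species_stats(profiles)
  readr::write_tsv(stats_sp$kw, file.path(out_dir, "species_kw.tsv"))
  readr::write_tsv(stats_sp$dunn, file.path(out_dir, "species_dunn.tsv"))

  key <- c("sample_id", "bioreactor", "phase")
  share_mat <- as.matrix(profiles[, setdiff(names(profiles), key)])
  rownames(share_mat) <- profiles$sample_id
  bc <- bray_curtis(share_mat)
  global <- permanova(bc, profiles$phase, n_perm = n_perm, seed = seed)
  pairwise <- pairwise_permanova(bc, profiles$phase, n_perm = n_perm,
                                 seed = seed)
  readr::write_tsv(pairwise, file.path(out_dir, "community_permanova_pairwise.tsv"))
  ord <- ordinate(share_mat)
  readr::write_tsv(
    dplyr::bind_cols(profiles[, key], tibble::as_tibble(ord$scores)),
    file.path(out_dir, "community_pca_scores.tsv"))

  out <- list(profiles = profiles, species_stats = stats_sp,
              community_permanova = global,
              community_permanova_pairwise = pairwise,
              community_ordination = ord)

  if (is.null(pathway_map_path)) {
    warning("no pathway map supplied; pathway stage skipped", call. = FALSE)
  } else {
    map <- read_pathway_map(pathway_map_path)
    pw <- pathway_profile(table, map, min_coverage = min_coverage,
                          min_proteins = min_proteins)
    readr::write_tsv(pw$matrix, file.path(out_dir, "pathway_matrix.tsv"))
    readr::write_tsv(pw$coverage, file.path(out_dir, "pathway_coverage.tsv"))
    fc <- phase_log2fc(pw$matrix, phase_a, phase_b,
                       fc_threshold = fc_threshold, alpha = alpha)
    readr::write_tsv(fc, file.path(out_dir, "pathway_log2fc.tsv"), na = "")
    out$pathways <- pw
    out$log2fc <- fc
  }

  jsonlite::write_json(
    list(community_permanova = global,
         species_kw = stats_sp$kw,
         explained_variance = out$community_ordination$explained),
    file.path(out_dir, "sihumix_stats.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, list(
    stage = "sihumix", seed = seed, n_perm = n_perm,
    min_coverage = min_coverage, min_proteins = min_proteins,
    fc_threshold = fc_threshold, alpha = alpha,
    n_samples = nrow(profiles),
    unassigned_fraction = as.list(attr(profiles, "unassigned_fraction")),
    pathway_stage = !is.null(pathway_map_path)))
  invisible(out)
}

#' Write synthetic fixture datasets to disk
#'
#' Emits the exact TSV dialects the pipeline readers consume, alongside the
#' machine-readable ground truth, so the generator doubles as a format
#' fixture factory.
#'
#' @param out_dir Output directory.
#' @param behavior_spec A [behavior_sim_spec()] or `NULL` to skip.
#' @param proteome_spec A [proteome_sim_spec()] or `NULL` to skip.
#' @return Invisibly, the list of written paths.
#' @export
write_simulated_datasets <- function(out_dir, behavior_spec = NULL,
                                     proteome_spec = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(behavior_spec)) {
    sim <- simulate_traces(behavior_spec)
    paths$activity <- file.path(out_dir, "activity.tsv")
    paths$metadata <- file.path(out_dir, "metadata.tsv")
    readr::write_tsv(sim$activity, paths$activity, na = "")
    readr::write_tsv(sim$metadata, paths$metadata)
    paths$behavior_truth <- file.path(out_dir, "behavior_truth.json")
    jsonlite::write_json(
      list(groups = sim$truth$groups, seed = sim$truth$seed,
           well_multipliers = sim$truth$well_multipliers),
      paths$behavior_truth, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(proteome_spec)) {
    sim <- simulate_proteome(proteome_spec)
    paths$proteins <- file.path(out_dir, "proteins.tsv")
    paths$pathway_map <- file.path(out_dir, "pathway_map.tsv")
    readr::write_tsv(sim$table, paths$proteins, na = "")
    readr::write_tsv(sim$pathway_map, paths$pathway_map)
    paths$proteome_truth <- file.path(out_dir, "proteome_truth.json")
    jsonlite::write_json(
      list(baseline_shares = as.list(sim$truth$baseline_shares),
           expected_shares = lapply(sim$truth$expected_shares, as.list),
           seed = sim$truth$seed),
      paths$proteome_truth, auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

write_manifest <- function(out_dir, fields) {
  fields$written_utc <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  fields$package_version <- as.character(utils::packageVersion("vamrbiome"))
  jsonlite::write_json(fields, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
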