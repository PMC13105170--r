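#' Simulation specification for behavioral activity traces
#'
#' Describes the synthetic plate: per-group mean structure aligned to the
#' assay schedule plus two noise layers. Each well receives a lognormal
#' activity multiplier (individual larvae differ widely in overall motility)
#' applied to its whole mean curve, and each 1-s bin receives Gaussian noise
#' rectified at zero (activity is non-negative).
#'
#' The group effect table (`groups`) has one row per experimental group with
#' columns: `group`, `n_wells`, `baseline` (mean activity per second),
#' `noise_sd` (per-bin noise scale), `surge_height` and `surge_tau`
#' (dark-phase ramp: an exponentially decaying surge starting at the
#' light-to-dark transition), `startle_low`/`startle_high` (startle response
#' amplitudes for low/high intensity stimuli), `hab_decay` (geometric
#' per-stimulus decay factor of within-bout responses, in `(0, 1]`),
#' `hyperactivity` (multiplier on the dark-phase surge), `hab_accel`
#' (habituation acceleration: scales the decay exponent, so values > 1 mean
#' faster within-bout response decline), `well_sdlog` (sdlog of the per-well
#' lognormal multiplier).
#'
#' @param protocol An [assay_protocol()].
#' @param groups Group effect tibble (see Details); defaults to the
#'   six-group colonization x exposure design with 45 wells per group.
#' @param seed Master seed.
#' @return An object of class `behavior_sim_spec`.
#' @export
behavior_sim_spec <- function(protocol = assay_protocol(),
                              groups = default_behavior_groups(),
                              seed = 1L) {
  need <- c("group", "n_wells", "baseline", "noise_sd", "surge_height",
            "surge_tau", "startle_low", "startle_high", "hab_decay",
            "hyperactivity", "hab_accel", "well_sdlog")
  missing <- setdiff(need, names(groups))
  if (length(missing) > 0L) {
    stop("group table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(groups$n_wells < 1L)) stop("n_wells must be >= 1", call. = FALSE)
  if (any(groups$noise_sd < 0) || any(groups$well_sdlog < 0)) {
    stop("noise scales must be >= 0", call. = FALSE)
  }
  if (any(groups$hyperactivity <= 0) || any(groups$hab_accel <= 0)) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  if (any(groups$hab_decay <= 0 | groups$hab_decay > 1)) {
    stop("hab_decay must lie in (0, 1]", call. = FALSE)
  }
  structure(list(protocol = protocol, groups = groups,
                 seed = as.integer(seed)),
            class = "behavior_sim_spec")
}

#' Default group effect table for the six-group exposure design
#'
#' Two colonization cohorts x three exposure groups, 45 wells each (the
#' scale of one assay run). All groups share the control parameterization;
#' effects are injected by editing `hyperactivity` or `hab_accel` for
#' selected groups.
#'
#' @param n_wells Wells per group.
#' @return Group effect tibble for [behavior_sim_spec()].
#' @export
default_behavior_groups <- function(n_wells = 45L) {
  cohorts <- c("colonized", "depleted")
  exposures <- c("control", "low", "high")
  tibble::tibble(
    group = paste(rep(cohorts, each = 3), rep(exposures, 2), sep = "_"),
    n_wells = as.integer(n_wells),
    baseline = 2, noise_sd = 1.5,
    surge_height = 20, surge_tau = 120,
    startle_low = 15, startle_high = 40,
    hab_decay = 0.9, hyperactivity = 1, hab_accel = 1,
    well_sdlog = 0.6)
}

# Deterministic per-group mean activity curve aligned to the schedule.
group_mean_curve <- function(g, schedule) {
  total <- attr(schedule, "total_length")
  p <- attr(schedule, "protocol")
  mu <- rep(g$baseline, total)
  at <- function(row) (row$start + 1L):row$end

  # dark-phase surge: exponential ramp-down from the light-to-dark boundary
  dark_rows <- schedule[schedule$endpoint %in% paste0("VMR", 2:5) &
                          !is.na(schedule$endpoint), ]
  t0 <- min(dark_rows$start)
  for (i in seq_len(nrow(dark_rows))) {
    idx <- at(dark_rows[i, ])
    tt <- (idx - 1L) - t0
    mu[idx] <- mu[idx] + g$hyperactivity * g$surge_height * exp(-tt / g$surge_tau)
  }

  # visual startles
  for (w in c("VSR1", "VSR2")) {
    mu[at(schedule[schedule$window == w, ])] <- g$baseline + g$startle_high
  }

  # acoustic startle blocks
  stim <- schedule[schedule$role == "stimulus" & !is.na(schedule$endpoint), ]
  for (blk in c("ASR1", "ASR2", "ASR3")) {
    amp <- if (blk == "ASR1") g$startle_low else g$startle_high
    rows <- stim[stim$endpoint == blk, ]
    for (i in seq_len(nrow(rows))) mu[at(rows[i, ])] <- g$baseline + amp
  }

  # habituation bouts: within-bout geometric decay, accelerated by hab_accel
  bout_eps <- unique(stim$endpoint[grepl("^ASH", stim$endpoint)])
  for (be in bout_eps) {
    rows <- stim[stim$endpoint == be, ]
    rows <- rows[order(rows$stimulus_index), ]
    for (i in seq_len(nrow(rows))) {
      resp <- g$startle_high * g$hab_decay^((i - 1) * g$hab_accel)
      mu[at(rows[i, ])] <- g$baseline + resp
    }
  }
  mu
}

#' Simulate activity traces for a synthetic plate
#'
#' Builds each group's deterministic mean curve on the protocol schedule
#' (baseline, dark-phase surge, startle spikes in exactly the stimulus
#' seconds, within-bout habituation decay), multiplies it by a per-well
#' lognormal factor, adds zero-rectified Gaussian bin noise, and emits the
#' long-format activity table, plate metadata and the ground-truth record.
#'
#' @param spec A [behavior_sim_spec()].
#' @return A list: `activity` (tibble `well_id`, `time_s`, `activity`),
#'   `metadata` (tibble `well_id`, `group`, `colonization`, `treatment`,
#'   `concentration`, `flask`), `truth` (the spec's group table plus per-well
#'   multipliers and the per-group mean curves).
#' @export
simulate_traces <- function(spec) {
  stopifnot(inherits(spec, "behavior_sim_spec"))
  schedule <- build_schedule(spec$protocol)
  total <- attr(schedule, "total_length")
  acts <- list()
  metas <- list()
  curves <- list()
  well_mults <- list()
  for (gi in seq_len(nrow(spec$groups))) {
    g <- spec$groups[gi, ]
    mu <- group_mean_curve(g, schedule)
    curves[[g$group]] <- mu
    wells <- sprintf("%s_w%02d", g$group, seq_len(g$n_wells))
    sim <- withr::with_seed(derive_seed(spec$seed, "behavior", g$group), {
      mult <- if (g$well_sdlog > 0) {
        stats::rlnorm(g$n_wells, meanlog = 0, sdlog = g$well_sdlog)
      } else rep(1, g$n_wells)
      vals <- lapply(seq_len(g$n_wells), function(w) {
        x <- mu * mult[w]
        if (g$noise_sd > 0) x <- x + stats::rnorm(total, 0, g$noise_sd)
        pmax(x, 0)
      })
      list(mult = mult, vals = vals)
    })
    well_mults[[g$group]] <- stats::setNames(sim$mult, wells)
    acts[[gi]] <- tibble::tibble(
      well_id = rep(wells, each = total),
      time_s = rep(0:(total - 1L), times = g$n_wells),
      activity = unlist(sim$vals))
    parts <- strsplit(g$group, "_")[[1]]
    exposure <- if (length(parts) >= 2L) parts[2] else NA_character_
    metas[[gi]] <- tibble::tibble(
      well_id = wells, group = g$group,
      colonization = parts[1],
      treatment = if (identical(exposure, "control")) "vehicle"
                  else if (exposure %in% c("low", "high")) "azoxystrobin"
                  else g$group,
      concentration = unname(c(control = 0, low = 0.6,
                               high = 1.68)[exposure]),
      flask = paste0(g$group, "_f", ((seq_len(g$n_wells) - 1L) %% 10L) + 1L))
  }
  list(activity = dplyr::bind_rows(acts),
       metadata = dplyr::bind_rows(metas),
       truth = list(groups = spec$groups, seed = spec$seed,
                    well_multipliers = well_mults, mean_curves = curves))
}

#' Simulation specification for species-resolved protein intensities
#'
#' Describes synthetic bioreactor metaproteomes across cultivation phases:
#' intensities follow
#' `total x species share x phase effect x bioreactor effect x pathway effect
#' x protein weight x lognormal noise`, with protein groups split per species
#' and KO/pathway annotations attached from a generated membership map.
#'
#' @param species_shares Named baseline share vector (positive, summing
#'   to 1); defaults to eight consortium members with equal shares.
#' @param n_bioreactors Number of bioreactors.
#' @param samples_per_phase Named integer vector: samples per bioreactor per
#'   phase (defaults to daily sampling: 3 stabilization, 7 exposure,
#'   4 recovery).
#' @param phase_effects Tibble `species`, `phase`, `effect` (multiplicative,
#'   > 0); missing combinations default to 1.
#' @param proteins_per_species Protein groups per species.
#' @param n_pathways Number of pathways in the generated map.
#' @param kos_per_pathway KEGG orthologs per pathway.
#' @param ko_detected_fraction Fraction of each pathway's KOs carried by
#'   detected protein groups.
#' @param proteins_per_ko Distinct protein groups annotated with each
#'   detected KO.
#' @param pathway_effects Tibble `pathway_id`, `phase`, `effect`
#'   (multiplicative fold change applied to member proteins in that phase).
#' @param bioreactor_sdlog Scale of the lognormal bioreactor random effect.
#' @param noise_sdlog Scale of the lognormal intensity noise.
#' @param unassigned_fraction Fraction of rows labelled `"unassigned"`
#'   (species-ambiguous intensity), excluded from community shares.
#' @param total_intensity Expected total assigned intensity per sample.
#' @param seed Master seed.
#' @return An object of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(species_shares = default_species_shares(),
                              n_bioreactors = 4L,
                              samples_per_phase = c(stabilization = 3L,
                                                    exposure = 7L,
                                                    recovery = 4L),
                              phase_effects = NULL,
                              proteins_per_species = 30L,
                              n_pathways = 12L,
                              kos_per_pathway = 10L,
                              ko_detected_fraction = 0.3,
                              proteins_per_ko = 2L,
                              pathway_effects = NULL,
                              bioreactor_sdlog = 0.1,
                              noise_sdlog = 0.2,
                              unassigned_fraction = 0.05,
                              total_intensity = 1e9,
                              seed = 1L) {
  if (abs(sum(species_shares) - 1) > 1e-9 || any(species_shares <= 0)) {
    stop("species shares must be positive and sum to 1", call. = FALSE)
  }
  if (!is.null(phase_effects) && any(phase_effects$effect <= 0)) {
    stop("phase effects must be > 0", call. = FALSE)
  }
  if (!is.null(pathway_effects) && any(pathway_effects$effect <= 0)) {
    stop("pathway fold changes must be > 0", call. = FALSE)
  }
  structure(list(species_shares = species_shares,
                 n_bioreactors = as.integer(n_bioreactors),
                 samples_per_phase = samples_per_phase,
                 phase_effects = phase_effects,
                 proteins_per_species = as.integer(proteins_per_species),
                 n_pathways = as.integer(n_pathways),
                 kos_per_pathway = as.integer(kos_per_pathway),
                 ko_detected_fraction = ko_detected_fraction,
                 proteins_per_ko = as.integer(proteins_per_ko),
                 pathway_effects = pathway_effects,
                 bioreactor_sdlog = bioreactor_sdlog,
                 noise_sdlog = noise_sdlog,
                 unassigned_fraction = unassigned_fraction,
                 total_intensity = total_intensity,
                 seed = as.integer(seed)),
            class = "proteome_sim_spec")
}

#' Default baseline shares for the eight-species consortium
#' @return Named numeric vector summing to 1.
#' @export
default_species_shares <- function() {
  sp <- c("A_caccae", "B_thetaiotaomicron", "B_longum", "B_producta",
          "C_butyricum", "T_ramosa", "E_coli", "L_plantarum")
  stats::setNames(c(0.08, 0.30, 0.06, 0.12, 0.10, 0.06, 0.20, 0.08), sp)
}

#' Simulate a species-resolved protein intensity table
#'
#' @param spec A [proteome_sim_spec()].
#' @return A list: `table` (protein abundance tibble with `sample_id`,
#'   `bioreactor`, `phase`, `species`, `protein_group`, `intensity`, `ko`),
#'   `pathway_map` (tibble `pathway_id`, `ko_id`), `truth` (expected shares
#'   per phase, effects, seed).
#' @export
simulate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  species <- names(spec$species_shares)
  phases <- names(spec$samples_per_phase)

  # protein scaffold: fixed weights per protein group within its species
  prot <- expand.grid(species = species,
                      prot_idx = seq_len(spec$proteins_per_species),
                      stringsAsFactors = FALSE)
  prot$protein_group <- sprintf("%s_pg%03d", prot$species, prot$prot_idx)
  w <- seq_len(spec$proteins_per_species)
  w <- w / sum(w)
  prot$weight <- w[prot$prot_idx]

  # pathway map and KO annotations (deterministic layout)
  map <- tibble::tibble(
    pathway_id = rep(sprintf("pw%02d", seq_len(spec$n_pathways)),
                     each = spec$kos_per_pathway),
    ko_id = sprintf("K%05d", seq_len(spec$n_pathways * spec$kos_per_pathway)))
  n_detected <- max(1L, round(spec$ko_detected_fraction * spec$kos_per_pathway))
  detected <- map |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::slice_head(n = n_detected) |>
    dplyr::ungroup()
  prot$ko <- NA_character_
  n_annot <- min(spec$proteins_per_ko * nrow(detected), nrow(prot))
  annot_rows <- unique(round(seq(1L, nrow(prot), length.out = n_annot)))
  prot$ko[annot_rows] <- rep(detected$ko_id,
                             length.out = length(annot_rows))

  effect_of <- function(tab, key_col, key, phase) {
    if (is.null(tab)) return(1)
    hit <- tab$effect[tab[[key_col]] == key & tab$phase == phase]
    if (length(hit) == 0) 1 else prod(hit)
  }

  rows <- list()
  truth_shares <- list()
  br_effects <- withr::with_seed(derive_seed(spec$seed, "proteome", "reactor"), {
    if (spec$bioreactor_sdlog > 0) {
      stats::rlnorm(spec$n_bioreactors, 0, spec$bioreactor_sdlog)
    } else rep(1, spec$n_bioreactors)
  })
  for (ph in phases) {
    sp_eff <- vapply(species, function(s)
      effect_of(spec$phase_effects, "species", s, ph), numeric(1))
    truth_shares[[ph]] <- sp_eff * spec$species_shares /
      sum(sp_eff * spec$species_shares)
    for (b in seq_len(spec$n_bioreactors)) {
      for (d in seq_len(spec$samples_per_phase[[ph]])) {
        sid <- sprintf("br%d_%s_d%02d", b, ph, d)
        base <- spec$total_intensity * spec$species_shares[prot$species] *
          sp_eff[prot$species] * prot$weight * br_effects[b]
        pw_eff <- rep(1, nrow(prot))
        if (!is.null(spec$pathway_effects)) {
          for (j in which(!is.na(prot$ko))) {
            pws <- map$pathway_id[map$ko_id == prot$ko[j]]
            for (pw in pws) {
              pw_eff[j] <- pw_eff[j] *
                effect_of(spec$pathway_effects, "pathway_id", pw, ph)
            }
          }
        }
        noise <- withr::with_seed(derive_seed(spec$seed, "proteome", sid), {
          if (spec$noise_sdlog > 0) {
            stats::rlnorm(nrow(prot), 0, spec$noise_sdlog)
          } else rep(1, nrow(prot))
        })
        rows[[sid]] <- tibble::tibble(
          sample_id = sid, bioreactor = paste0("br", b), phase = ph,
          species = prot$species, protein_group = prot$protein_group,
          intensity = unname(base * pw_eff * noise), ko = prot$ko)
      }
    }
  }
  tab <- dplyr::bind_rows(rows)

  # species-ambiguous mass, excluded from community shares downstream
  if (spec$unassigned_fraction > 0) {
    per_sample <- tapply(tab$intensity, tab$sample_id, sum)
    extra <- tibble::tibble(
      sample_id = names(per_sample),
      bioreactor = sub("^(br\\d+)_.*$", "\\1", names(per_sample)),
      phase = sub("^br\\d+_([a-z]+)_.*$", "\\1", names(per_sample)),
      species = "unassigned", protein_group = "unassigned_pg001",
      intensity = as.numeric(per_sample) * spec$unassigned_fraction /
        (1 - spec$unassigned_fraction),
      ko = NA_character_)
    tab <- dplyr::bind_rows(tab, extra)
  }
  list(table = tab, pathway_map = map,
       truth = list(baseline_shares = spec$species_shares,
                    expected_shares = truth_shares,
                    phase_effects = spec$phase_effects,
                    pathway_effects = spec$pathway_effects,
                    bioreactor_effects = br_effects,
                    seed = spec$seed))
}
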