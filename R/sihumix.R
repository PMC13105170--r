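#' Proteome-weighted community profile
#'
#' Species relative abundances computed from summed species-specific protein
#' intensities rather than sequencing counts: per sample, a species' share is
#' its summed protein-group intensity divided by the sample's total
#' species-assigned intensity. Rows whose species is `"unassigned"` are
#' excluded from the denominator; their intensity fraction is reported.
#'
#' @param table Protein abundance tibble with columns `sample_id`,
#'   `bioreactor`, `phase`, `species`, `protein_group`, `intensity`
#'   (see [read_protein_table()]).
#' @return A tibble with one row per sample (`sample_id`, `bioreactor`,
#'   `phase`, one column per species, shares summing to 1) carrying an
#'   `unassigned_fraction` attribute (named by sample).
#' @export
community_profile <- function(table) {
  check_protein_table(table)
  assigned <- table[table$species != "unassigned", ]
  totals <- tapply(assigned$intensity, assigned$sample_id, sum)
  zero <- names(totals)[is.na(totals) | totals <= 0]
  zero <- union(zero, setdiff(unique(table$sample_id), names(totals)))
  if (length(zero) > 0L) {
    stop("sample(s) with zero species-assigned intensity: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  wide <- assigned |>
    dplyr::group_by(.data$sample_id, .data$bioreactor, .data$phase,
                    .data$species) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(share = .data$intensity / sum(.data$intensity)) |>
    dplyr::ungroup() |>
    dplyr::select(-"intensity") |>
    tidyr_pivot_wider_share()
  grand <- tapply(table$intensity, table$sample_id, sum)
  unass <- 1 - totals[names(grand)] / grand
  attr(wide, "unassigned_fraction") <- stats::setNames(as.numeric(unass),
                                                       names(grand))
  wide
}

# pivot species shares wide without a tidyr dependency
tidyr_pivot_wider_share <- function(long) {
  samples <- unique(long[, c("sample_id", "bioreactor", "phase")])
  species <- sort(unique(long$species))
  m <- matrix(0, nrow = nrow(samples), ncol = length(species),
              dimnames = list(samples$sample_id, species))
  idx <- cbind(match(long$sample_id, samples$sample_id),
               match(long$species, species))
  m[idx] <- long$share
  dplyr::bind_cols(samples, tibble::as_tibble(m))
}

check_protein_table <- function(table) {
  need <- c("sample_id", "bioreactor", "phase", "species", "protein_group",
            "intensity")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    stop("protein table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(table$intensity) | table$intensity < 0)
  if (length(bad) > 0L) {
    stop("negative or missing intensity at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Kruskal-Wallis + Dunn phase statistics per species
#'
#' Following the phase-level analysis design, observations are first averaged
#' to one mean per bioreactor per phase; a tie-corrected Kruskal-Wallis test
#' across phases is then run per species, followed by Dunn's pairwise
#' post-hoc z tests (two-sided normal p) with Benjamini-Hochberg adjustment
#' across the phase pairs within each species.
#'
#' @param profiles Community profile tibble from [community_profile()] (or any
#'   tibble with `sample_id`, `bioreactor`, `phase` and per-species columns).
#' @param species Columns to analyse; defaults to all non-key columns.
#' @return A list with `kw` (per-species H statistic, df, p) and `dunn`
#'   (per species and phase pair: z, raw p, BH-adjusted p).
#' @export
phase_species_stats <- function(profiles, species = NULL) {
  key <- c("sample_id", "bioreactor", "phase")
  if (is.null(species)) species <- setdiff(names(profiles), key)
  phases <- unique(profiles$phase)
  if (length(phases) < 2L) stop("need >= 2 phases", call. = FALSE)
  kw_rows <- list()
  dunn_rows <- list()
  for (sp in species) {
    means <- profiles |>
      dplyr::group_by(.data$bioreactor, .data$phase) |>
      dplyr::summarise(value = mean(.data[[sp]]), .groups = "drop")
    counts <- table(means$phase)
    if (any(counts < 2L)) {
      stop("phase(s) with < 2 bioreactor means for species ", sp, ": ",
           paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
    }
    if (length(unique(means$value)) == 1L) {
      # fully degenerate: every bioreactor mean identical across phases
      kw_rows[[sp]] <- tibble::tibble(species = sp, H = 0,
                                      df = length(unique(means$phase)) - 1L,
                                      p = 1)
    } else {
      kw <- stats::kruskal.test(means$value, factor(means$phase))
      kw_rows[[sp]] <- tibble::tibble(
        species = sp, H = unname(kw$statistic), df = unname(kw$parameter),
        p = kw$p.value)
    }
    d <- dunn_test(means$value, factor(means$phase))
    d$species <- sp
    d$p_adj <- adjust_pvalues(d$p, "BH")
    dunn_rows[[sp]] <- d
  }
  list(kw = dplyr::bind_rows(kw_rows),
       dunn = dplyr::bind_rows(dunn_rows)[, c("species", "group1", "group2",
                                              "z", "p", "p_adj")])
}

#' Dunn's post-hoc test on joint ranks
#'
#' All observations are ranked jointly with midranks for ties; for each group
#' pair the standardized mean-rank difference is
#' `z = (R1 - R2) / sqrt((N(N+1)/12 - T) (1/n1 + 1/n2))` with the tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`. P-values are two-sided
#' normal.
#'
#' @param x Numeric observations.
#' @param g Grouping factor.
#' @return Tibble with `group1`, `group2`, `z`, `p` for every group pair.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2L)
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    # se collapses to 0 only when every observation is tied; then the mean
    # ranks coincide too and the standardized difference is 0
    z <- if (se == 0) 0 else (mean_ranks[pr[1]] - mean_ranks[pr[2]]) / se
    tibble::tibble(group1 = pr[1], group2 = pr[2], z = unname(z),
                   p = 2 * stats::pnorm(-abs(unname(z))))
  })
  dplyr::bind_rows(rows)
}

#' Read or validate a pathway membership map
#'
#' @param pathway_map Tibble with columns `pathway_id` and `ko_id`: full KEGG
#'   ortholog membership of each pathway (the coverage denominator).
#' @return The validated map.
#' @export
validate_pathway_map <- function(pathway_map) {
  stopifnot(all(c("pathway_id", "ko_id") %in% names(pathway_map)))
  counts <- table(pathway_map$pathway_id)
  if (any(counts < 1L) || nrow(pathway_map) == 0L) {
    stop("every pathway must reference >= 1 KEGG ortholog", call. = FALSE)
  }
  pathway_map
}

#' Coverage-filtered pathway intensity profile
#'
#' Aggregates protein-group intensities into KEGG pathways through the KO
#' annotations: a pathway's intensity in a sample is the summed intensity of
#' all protein groups whose KO belongs to the pathway (a KO shared by several
#' pathways counts fully toward each). Pathways are retained only if their
#' functional coverage (detected KOs / pathway KOs) reaches `min_coverage`
#' and at least `min_proteins` distinct protein groups map to them.
#'
#' @param table Protein abundance tibble with a `ko` column (`NA` for
#'   unannotated protein groups).
#' @param pathway_map Pathway membership map (`pathway_id`, `ko_id`).
#' @param min_coverage Minimum fraction of the pathway's KOs detected.
#' @param min_proteins Minimum number of distinct mapped protein groups.
#' @return A list: `matrix` (tibble, samples x retained pathways, plus
#'   `sample_id`, `bioreactor`, `phase` and `total_assigned` columns) and
#'   `coverage` (per-pathway coverage, protein count, retained flag and
#'   exclusion reason).
#' @export
pathway_profile <- function(table, pathway_map, min_coverage = 0.15,
                            min_proteins = 5L) {
  check_protein_table(table)
  if (!"ko" %in% names(table)) {
    stop("protein table has no 'ko' annotation column", call. = FALSE)
  }
  pathway_map <- validate_pathway_map(pathway_map)
  annotated <- table[!is.na(table$ko) & table$ko != "", ]
  if (nrow(annotated) == 0L) {
    stop("no KO-annotated protein groups present", call. = FALSE)
  }
  detected_kos <- unique(annotated$ko)
  pathways <- unique(pathway_map$pathway_id)

  cov_rows <- lapply(pathways, function(pw) {
    kos <- pathway_map$ko_id[pathway_map$pathway_id == pw]
    hit <- annotated[annotated$ko %in% kos, ]
    coverage <- length(intersect(detected_kos, kos)) / length(unique(kos))
    n_prot <- length(unique(hit$protein_group))
    reason <- if (coverage < min_coverage && n_prot < min_proteins) {
      "coverage and protein count below threshold"
    } else if (coverage < min_coverage) {
      "coverage below threshold"
    } else if (n_prot < min_proteins) {
      "protein count below threshold"
    } else NA_character_
    tibble::tibble(pathway_id = pw, coverage = coverage, n_proteins = n_prot,
                   retained = is.na(reason), reason = reason)
  })
  coverage <- dplyr::bind_rows(cov_rows)
  retained <- coverage$pathway_id[coverage$retained]

  samples <- unique(table[, c("sample_id", "bioreactor", "phase")])
  total_assigned <- tapply(annotated$intensity, annotated$sample_id, sum)
  mat <- matrix(0, nrow = nrow(samples), ncol = length(retained),
                dimnames = list(samples$sample_id, retained))
  for (pw in retained) {
    kos <- pathway_map$ko_id[pathway_map$pathway_id == pw]
    hit <- annotated[annotated$ko %in% kos, ]
    sums <- tapply(hit$intensity, hit$sample_id, sum)
    mat[names(sums), pw] <- as.numeric(sums)
  }
  out <- dplyr::bind_cols(
    samples,
    tibble::tibble(total_assigned = as.numeric(
      total_assigned[samples$sample_id])),
    tibble::as_tibble(mat))
  list(matrix = out, coverage = coverage)
}

#' Per-pathway log2 fold change between phases with a Kruskal-Wallis filter
#'
#' Pathway intensities are first converted to relative functional abundances
#' (pathway intensity / total KO-assigned intensity per sample). The fold
#' change is `log2(mean in phase B / mean in phase A)`; a pathway is retained
#' when `|Log2FC| >= fc_threshold` and a Kruskal-Wallis test across the two
#' phases gives `p < alpha`.
#'
#' @param pathway_matrix `matrix` element of [pathway_profile()].
#' @param phase_a,phase_b Phase labels to compare (fold change is B over A).
#' @param fc_threshold Absolute log2 fold-change threshold.
#' @param alpha Kruskal-Wallis significance threshold.
#' @return Tibble with `pathway_id`, `log2fc`, `p_kw`, `retained`,
#'   `direction` (`"up"`/`"down"` relative to phase A, `NA` when not
#'   retained). Pathways with a zero phase mean get a missing fold change and
#'   a `degenerate` flag instead of an infinite value.
#' @export
phase_log2fc <- function(pathway_matrix, phase_a, phase_b,
                         fc_threshold = 0.2, alpha = 0.05) {
  key <- c("sample_id", "bioreactor", "phase", "total_assigned")
  pws <- setdiff(names(pathway_matrix), key)
  in_a <- pathway_matrix$phase == phase_a
  in_b <- pathway_matrix$phase == phase_b
  if (sum(in_a) < 2L || sum(in_b) < 2L) {
    stop("both phases need >= 2 samples", call. = FALSE)
  }
  rows <- lapply(pws, function(pw) {
    rel <- pathway_matrix[[pw]] / pathway_matrix$total_assigned
    ma <- mean(rel[in_a])
    mb <- mean(rel[in_b])
    if (ma == 0 || mb == 0) {
      return(tibble::tibble(pathway_id = pw, log2fc = NA_real_,
                            p_kw = NA_real_, retained = FALSE,
                            direction = NA_character_, degenerate = TRUE))
    }
    l2 <- log2(mb / ma)
    sel <- in_a | in_b
    p_kw <- if (length(unique(rel[sel])) == 1L) 1 else {
      stats::kruskal.test(rel[sel], factor(pathway_matrix$phase[sel]))$p.value
    }
    keep <- abs(l2) >= fc_threshold && p_kw < alpha
    tibble::tibble(pathway_id = pw, log2fc = l2, p_kw = p_kw,
                   retained = keep,
                   direction = if (keep) ifelse(l2 > 0, "up", "down")
                   else NA_character_,
                   degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features, for
#' non-negative sample profiles.
#'
#' @param mat Numeric matrix or data frame, samples in rows, non-negative.
#' @return A symmetric `dist`-derived matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(mat) {
  m <- as.matrix(mat)
  if (any(m < 0)) stop("entries must be non-negative", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[zero] %||% which(zero), collapse = ", "),
         call. = FALSE)
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pseudo-F from a distance matrix and integer group codes.
permanova_f <- function(d2, groups) {
  n <- length(groups)
  k <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) /
      length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a dissimilarity matrix: total and within-group sums
#' of squared dissimilarities give the pseudo-F statistic
#' `F = (SS_between / (g - 1)) / (SS_within / (N - g))`; significance comes
#' from permuting the group labels. The Monte Carlo p-value is
#' `(#{F_perm >= F_obs} + 1) / (n_perm + 1)`; with `exhaustive = TRUE` every
#' distinct label permutation is enumerated and the p-value is the exact
#' proportion of permutations (identity included) whose statistic reaches
#' `F_obs`.
#'
#' @param dist_matrix Square symmetric dissimilarity matrix (or `dist`).
#' @param groups Group labels, one per sample; every group needs >= 2
#'   samples.
#' @param n_perm Number of random permutations.
#' @param seed RNG seed for the permutations.
#' @param exhaustive Enumerate all `N!` label orders instead of sampling
#'   (only sensible for very small N).
#' @return A list: `f` (observed pseudo-F), `p`, `n_perm` (permutations
#'   used), `method`.
#' @export
permanova <- function(dist_matrix, groups, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  groups <- as.integer(factor(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  if (exhaustive) {
    perms <- all_permutations(n)
    f_all <- vapply(seq_len(nrow(perms)),
                    function(i) permanova_f(d2, groups[perms[i, ]]),
                    numeric(1))
    p <- mean(f_all >= f_obs - 1e-12)
    list(f = f_obs, p = p, n_perm = nrow(perms), method = "exhaustive")
  } else {
    f_perm <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm),
             function(i) permanova_f(d2, groups[sample.int(n)]),
             numeric(1))
    })
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    list(f = f_obs, p = p, n_perm = as.integer(n_perm), method = "permutation")
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pairwise PERMANOVA with Hochberg adjustment
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values with
#' the Hochberg step-up method, matching the convention of following a
#' significant global test with adjusted pairwise comparisons.
#'
#' @inheritParams permanova
#' @return Tibble with `group1`, `group2`, `f`, `p`, `p_adj`.
#' @export
pairwise_permanova <- function(dist_matrix, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(dist_matrix)
  groups <- factor(groups)
  pairs <- utils::combn(levels(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    idx <- which(groups %in% pr)
    res <- permanova(d[idx, idx], droplevels(groups[idx]), n_perm = n_perm,
                     seed = derive_seed(seed, pr[1], pr[2]))
    tibble::tibble(group1 = pr[1], group2 = pr[2], f = res$f, p = res$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- adjust_pvalues(out$p, "hochberg")
  out
}

#' Principal-component ordination
#'
#' Column-centred PCA by singular value decomposition. For reproducibility
#' each component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param mat Numeric matrix or data frame, samples in rows.
#' @return A list: `scores` (samples x components), `loadings`,
#'   `explained` (variance fractions, non-increasing, summing to <= 1).
#' @export
ordinate <- function(mat) {
  m <- as.matrix(mat)
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(apply(m, 2, stats::var))
  explained <- if (total_var > 0) pc$sdev^2 / total_var else rep(0, length(pc$sdev))
  flip <- apply(pc$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings, explained = explained)
}

#' Bioreactor dose from an acceptable-daily-intake specification
#'
#' Anchors the bioreactor exposure concentration to a regulatory benchmark:
#' the daily mass is `ADI x fraction x body weight`, delivered into one daily
#' medium-exchange volume, giving a concentration in mg/ml; conversion with
#' the compound's molar mass gives the micromolar equivalent.
#'
#' @param adi Acceptable daily intake in mg per kg body weight per day.
#' @param fraction_of_adi Fraction of the ADI applied, in `(0, 1]`.
#' @param body_weight Reference body weight in kg.
#' @param reactor_volume Bioreactor (daily exchange) volume in ml.
#' @param molar_mass Compound molar mass in g/mol.
#' @return A list: `daily_mass_mg`, `conc_mg_ml`, `conc_um` (micromolar).
#' @export
bioreactor_dose <- function(adi = 0.2, fraction_of_adi = 0.1,
                            body_weight = 70, reactor_volume = 250,
                            molar_mass = 403.4) {
  vals <- c(adi = adi, fraction_of_adi = fraction_of_adi,
            body_weight = body_weight, reactor_volume = reactor_volume,
            molar_mass = molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all dose parameters must be strictly positive", call. = FALSE)
  }
  if (fraction_of_adi > 1) {
    stop("fraction_of_adi must lie in (0, 1]", call. = FALSE)
  }
  daily_mass <- adi * fraction_of_adi * body_weight     # mg/day
  conc <- daily_mass / reactor_volume                   # mg/ml
  conc_um <- conc / molar_mass * 1e6                    # mg/ml = g/l
  list(daily_mass_mg = daily_mass, conc_mg_ml = conc, conc_um = conc_um)
}

#' Design enumerators for the exposure experiment
#'
#' Bookkeeping for the plate/flask design: total flask count across
#' colonization cohorts and exposure groups, and the total inoculum cell
#' count across consortium strains.
#'
#' @param n_cohorts Number of colonization cohorts.
#' @param n_exposure_groups Number of exposure groups (vehicle + compound
#'   concentrations).
#' @param flasks_per_group Replicate flasks per cohort x exposure group.
#' @param n_strains Consortium species count.
#' @param cells_per_strain Inoculum cells per strain per bioreactor.
#' @return A list: `n_flasks`, `inoculum_cells`.
#' @export
exposure_design <- function(n_cohorts = 2L, n_exposure_groups = 3L,
                            flasks_per_group = 10L, n_strains = 8L,
                            cells_per_strain = 1e9) {
  stopifnot(n_cohorts >= 1L, n_exposure_groups >= 1L, flasks_per_group >= 1L,
            n_strains >= 1L, cells_per_strain > 0)
  list(n_flasks = n_cohorts * n_exposure_groups * flasks_per_group,
       inoculum_cells = n_strains * cells_per_strain)
}
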