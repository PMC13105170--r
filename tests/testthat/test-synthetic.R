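zero_noise_groups <- function(n_wells = 2L) {
  g <- default_behavior_groups(n_wells = n_wells)
  g$noise_sd <- 0
  g$well_sdlog <- 0
  g
}

test_that("trace generator is seed-deterministic", {
  g <- default_behavior_groups(n_wells = 3L)[1:2, ]
  s1 <- simulate_traces(behavior_sim_spec(groups = g, seed = 17))
  s2 <- simulate_traces(behavior_sim_spec(groups = g, seed = 17))
  expect_identical(s1$activity, s2$activity)
  s3 <- simulate_traces(behavior_sim_spec(groups = g, seed = 18))
  expect_false(identical(s1$activity, s3$activity))
})

test_that("zero noise and zero effects give a flat baseline trace", {
  g <- zero_noise_groups()[1, ]
  g$surge_height <- 0
  g$startle_low <- 0
  g$startle_high <- 0
  sim <- simulate_traces(behavior_sim_spec(groups = g, seed = 1))
  expect_true(all(sim$activity$activity == g$baseline))
})

test_that("injected startle amplitude is recovered through segmentation", {
  g <- zero_noise_groups()[1, ]
  g$baseline <- 0
  sim <- simulate_traces(behavior_sim_spec(groups = g, seed = 1))
  sched <- default_schedule()
  et <- build_endpoint_table(sim$activity, sim$metadata, sched)
  expect_equal(et$ASR2, rep(g$startle_high, nrow(et)))
  expect_equal(et$ASR1, rep(g$startle_low, nrow(et)))
  # within-bout geometric decay shows up in the habituation score
  d <- g$hab_decay
  expected_ash1 <- sum(d^(20:29)) / (sum(d^(0:9)) + sum(d^(20:29)))
  expect_equal(et$ASH1, rep(expected_ash1, nrow(et)))
})

test_that("habituation acceleration lowers the within-bout score", {
  g <- zero_noise_groups(n_wells = 1L)[1:2, ]
  g$group <- c("ctrl", "accel")
  g$hab_accel <- c(1, 2)
  sim <- simulate_traces(behavior_sim_spec(groups = g, seed = 2))
  et <- build_endpoint_table(sim$activity, sim$metadata,
                             default_schedule())
  expect_lt(et$ASH1[et$group == "accel"], et$ASH1[et$group == "ctrl"])
})

test_that("generator specs validate their invariants", {
  g <- default_behavior_groups()
  g$n_wells[1] <- 0L
  expect_error(behavior_sim_spec(groups = g), "n_wells")
  g2 <- default_behavior_groups()
  g2$hab_decay[2] <- 1.4
  expect_error(behavior_sim_spec(groups = g2), "hab_decay")
  expect_error(proteome_sim_spec(species_shares = c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("zero-noise proteome round-trips the baseline shares exactly", {
  spec <- proteome_sim_spec(noise_sdlog = 0, bioreactor_sdlog = 0,
                            unassigned_fraction = 0, seed = 4,
                            n_bioreactors = 2L,
                            samples_per_phase = c(stabilization = 2L,
                                                  exposure = 2L))
  sim <- simulate_proteome(spec)
  pr <- community_profile(sim$table)
  shares <- as.matrix(pr[, names(default_species_shares())])
  for (i in seq_len(nrow(shares))) {
    expect_equal(unname(shares[i, ]),
                 unname(default_species_shares()[colnames(shares)]),
                 tolerance = 1e-12)
  }
})

test_that("an injected species effect renormalizes shares as the hand oracle", {
  eff <- tibble::tibble(species = "E_coli", phase = "exposure", effect = 2)
  spec <- proteome_sim_spec(noise_sdlog = 0, bioreactor_sdlog = 0,
                            unassigned_fraction = 0, phase_effects = eff,
                            seed = 4, n_bioreactors = 2L,
                            samples_per_phase = c(stabilization = 2L,
                                                  exposure = 2L))
  sim <- simulate_proteome(spec)
  pr <- community_profile(sim$table)
  base <- default_species_shares()
  oracle <- base * c(rep(1, 8))
  oracle["E_coli"] <- base["E_coli"] * 2
  oracle <- oracle / sum(oracle)
  got <- as.matrix(pr[pr$phase == "exposure", names(base)])[1, ]
  expect_equal(unname(got), unname(oracle[names(got)]), tolerance = 1e-12)
  expect_equal(unname(sim$truth$expected_shares$exposure[names(got)]),
               unname(oracle[names(got)]))
})

test_that("proteome generator is seed-deterministic", {
  spec <- proteome_sim_spec(seed = 9, n_bioreactors = 2L,
                            samples_per_phase = c(stabilization = 2L,
                                                  exposure = 2L))
  expect_identical(simulate_proteome(spec)$table,
                   simulate_proteome(spec)$table)
})

test_that("injected hyperactivity yields the smallest raw VMR2 p in most seeds", {
  sched <- default_schedule()
  hits <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    g <- default_behavior_groups(n_wells = 20L)
    g$hyperactivity[g$group == "colonized_high"] <- 2
    sim <- simulate_traces(behavior_sim_spec(groups = g, seed = 100 + s))
    et <- build_endpoint_table(sim$activity, sim$metadata, sched)
    tt <- run_endpoint_tests(et, "colonized_control",
                             bootstrap_config(B_test = 200, seed = s))
    v <- tt[tt$endpoint == "VMR2", ]
    hits <- hits + (v$comparison[which.min(v$p_raw)] ==
                      "colonized_high vs colonized_control")
  }
  expect_gt(hits, n_seeds / 2)
})
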