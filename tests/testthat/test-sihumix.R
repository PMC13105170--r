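test_that("community shares renormalize species-assigned intensity", {
  one <- toy_protein_table(list(s1 = c(E_coli = 12)))
  pr1 <- community_profile(one)
  expect_equal(pr1$E_coli, 1)
  two <- toy_protein_table(list(s1 = c(A = 3, B = 1)))
  pr2 <- community_profile(two)
  expect_equal(pr2$A, 0.75)
  expect_equal(pr2$B, 0.25)
  eq <- toy_protein_table(list(s1 = stats::setNames(rep(5, 8),
                                                    paste0("sp", 1:8))))
  pr3 <- community_profile(eq)
  expect_true(all(abs(as.matrix(pr3[, paste0("sp", 1:8)]) - 0.125) < 1e-12))
  # unassigned mass excluded from the denominator but logged
  un <- toy_protein_table(list(s1 = c(A = 3, B = 1, unassigned = 4)))
  pr4 <- community_profile(un)
  expect_equal(pr4$A, 0.75)
  expect_equal(unname(attr(pr4, "unassigned_fraction")["s1"]), 0.5)
  zero <- toy_protein_table(list(s1 = c(unassigned = 4)))
  expect_error(community_profile(zero), "zero species-assigned.*s1")
})

test_that("phase statistics: degenerate ties and fully separated ranks", {
  prof <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    bioreactor = rep(paste0("br", 1:4), 3),
    phase = rep(c("stabilization", "exposure", "recovery"), each = 4),
    spA = rep(0.5, 12),
    spB = c(1:4, 11:14, 21:24) / 100)   # fully separated across phases
  st <- phase_species_stats(prof)
  a <- st$kw[st$kw$species == "spA", ]
  expect_equal(a$H, 0)
  expect_equal(a$p, 1)
  expect_true(all(st$dunn$p_adj[st$dunn$species == "spA"] == 1))
  # brute-force rank oracle for the separated design (3 groups of 4)
  b <- st$kw[st$kw$species == "spB", ]
  rk <- rank(prof$spB)
  n <- 12
  h_oracle <- 12 / (n * (n + 1)) *
    sum(tapply(rk, prof$phase, function(r) length(r) * mean(r)^2)) -
    3 * (n + 1)
  expect_equal(b$H, h_oracle)
  expect_equal(h_oracle, 9.846153846, tolerance = 1e-9)
})

test_that("Dunn z values match manual rank arithmetic and survive duplication", {
  x <- c(1.2, 3.1, 2.2, 5.5, 4.1, 0.3, 6.6, 2.9, 3.3)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  d <- dunn_test(x, g)
  n <- length(x)
  r <- rank(x)
  z_oracle <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt(n * (n + 1) / 12 * (1 / 3 + 1 / 3))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_oracle)
  # duplicating every observation preserves the ordering of pairwise |z|
  d2 <- dunn_test(c(x, x), factor(rep(g, 2)))
  expect_identical(order(abs(d$z)), order(abs(d2$z)))
})

test_that("pathway filters apply coverage and protein-count thresholds", {
  # toy: pathway of 10 KOs, 2 detected KOs carried by 6 protein groups
  map <- tibble::tibble(pathway_id = "pwA",
                        ko_id = sprintf("K%02d", 1:10))
  tab <- tibble::tibble(
    sample_id = "s1", bioreactor = "br1", phase = "stabilization",
    species = "E_coli", protein_group = paste0("pg", 1:6),
    intensity = c(10, 5, 7, 8, 6, 6),   # sums to 42
    ko = rep(c("K01", "K02"), 3))
  pw <- pathway_profile(tab, map)
  expect_equal(pw$coverage$coverage, 0.2)
  expect_true(pw$coverage$retained)
  expect_equal(pw$matrix$pwA, 42)
  # >= 15% coverage but only 4 proteins: excluded by the count filter
  tab4 <- tab[1:4, ]
  pw4 <- pathway_profile(tab4, map)
  expect_false(pw4$coverage$retained)
  expect_match(pw4$coverage$reason, "protein count")
  # 10% coverage with 20 proteins: excluded by the coverage filter
  tab20 <- tibble::tibble(
    sample_id = "s1", bioreactor = "br1", phase = "stabilization",
    species = "E_coli", protein_group = paste0("pg", 1:20),
    intensity = 1, ko = "K01")
  pw20 <- pathway_profile(tab20, map)
  expect_false(pw20$coverage$retained)
  expect_match(pw20$coverage$reason, "coverage")
  # relaxing a threshold never removes a previously retained pathway
  relaxed <- pathway_profile(tab4, map, min_proteins = 3L)
  expect_true(relaxed$coverage$retained)
  expect_error(pathway_profile(tab, tibble::tibble(pathway_id = character(),
                                                   ko_id = character())),
               ">= 1")
})

test_that("phase log2 fold changes follow the log identity and filters", {
  mk <- function(vals_a, vals_b) {
    tibble::tibble(
      sample_id = paste0("s", seq_len(length(vals_a) + length(vals_b))),
      bioreactor = "br1",
      phase = rep(c("stabilization", "exposure"),
                  c(length(vals_a), length(vals_b))),
      total_assigned = 1,
      pwA = c(vals_a, vals_b))
  }
  same <- phase_log2fc(mk(c(1, 2, 3), c(3, 2, 1)), "stabilization", "exposure")
  expect_equal(same$log2fc, 0)
  expect_false(same$retained)
  dbl <- phase_log2fc(mk(c(1, 1.2, 0.8), 2 * c(1, 1.2, 0.8)),
                      "stabilization", "exposure")
  expect_equal(dbl$log2fc, 1)
  zero <- phase_log2fc(mk(c(0, 0), c(1, 2)), "stabilization", "exposure")
  expect_true(is.na(zero$log2fc))
  expect_true(zero$degenerate)
  expect_error(phase_log2fc(mk(1, 1), "stabilization", "exposure"), ">= 2")
})

test_that("Bray-Curtis matches the direct formula and its invariants", {
  m <- rbind(a = c(1, 0, 3), b = c(2, 1, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 4 / 8)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d, t(d))
  ident <- bray_curtis(rbind(x = c(1, 2), y = c(1, 2)))
  expect_equal(ident["x", "y"], 0)
  disj <- bray_curtis(rbind(x = c(1, 0), y = c(0, 5)))
  expect_equal(disj["x", "y"], 1)
  set.seed(6)
  r <- matrix(rexp(40), nrow = 5)
  perm <- sample.int(8)
  expect_equal(bray_curtis(r), bray_curtis(r[, perm]))
  expect_true(all(bray_curtis(r) >= 0 & bray_curtis(r) <= 1))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 and is label-invariant", {
  set.seed(17)
  m <- matrix(rexp(36), nrow = 6)
  g <- rep(c("x", "y"), each = 3)
  d <- bray_curtis(m)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ grp,
                       data = data.frame(grp = g), permutations = 99)
  expect_equal(res$f, ad$F[1], tolerance = 1e-10)
  relab <- permanova(d, c("B", "B", "B", "A", "A", "A"), n_perm = 99, seed = 1)
  expect_equal(relab$f, res$f)
  # seeded determinism
  expect_identical(permanova(d, g, n_perm = 49, seed = 3)$p,
                   permanova(d, g, n_perm = 49, seed = 3)$p)
})

test_that("PERMANOVA p-values: separated groups and exhaustive oracle", {
  # two groups of 3 separated by enormous between-group distances: only
  # label orders preserving the partition (3! * 3! * 2 of 6! = 1/10) reach
  # the observed F, so the exhaustive p is exactly 0.1
  set.seed(41)
  far <- rbind(matrix(abs(rnorm(9, 1, 0.01)), 3),
               matrix(abs(rnorm(9, 1000, 0.01)), 3))
  d <- bray_curtis(far)
  g <- rep(c("lo", "hi"), each = 3)
  ex6 <- permanova(d, g, exhaustive = TRUE)
  expect_equal(ex6$p, 0.1)
  res <- permanova(d, g, n_perm = 999, seed = 5)
  expect_lt(abs(res$p - 0.1), 3 * sqrt(0.1 * 0.9 / 999) + 1e-3)
  # 2+2: Monte Carlo agrees with full enumeration over label permutations
  set.seed(23)
  m4 <- matrix(rexp(12), nrow = 4)
  d4 <- bray_curtis(m4)
  g4 <- c("a", "a", "b", "b")
  ex <- permanova(d4, g4, exhaustive = TRUE)
  expect_identical(ex$n_perm, 24L)
  mc <- permanova(d4, g4, n_perm = 9999, seed = 11)
  # MC estimator adds one pseudo-permutation; compare at MC precision
  expect_lt(abs(mc$p - ex$p), 3 * sqrt(ex$p * (1 - ex$p) / 9999) + 2e-4)
  expect_error(permanova(d4, c("a", "a", "a", "b")), ">= 2 samples")
})

test_that("pairwise PERMANOVA adjusts with Hochberg across pairs", {
  set.seed(29)
  m <- matrix(rexp(45), nrow = 9)
  g <- rep(c("p1", "p2", "p3"), each = 3)
  pw <- pairwise_permanova(bray_curtis(m), g, n_perm = 99, seed = 2)
  expect_identical(nrow(pw), 3L)
  expect_equal(pw$p_adj, adjust_pvalues(pw$p, "hochberg"))
})

test_that("ordination explains variance in non-increasing fractions", {
  line <- cbind(1:6, 2 * (1:6) + 3, -1 * (1:6))
  o <- ordinate(line)
  expect_equal(o$explained[1], 1)
  set.seed(12)
  m <- matrix(rnorm(12), nrow = 4)
  o2 <- ordinate(m)
  expect_true(all(diff(o2$explained) <= 1e-12))
  expect_lte(sum(o2$explained), 1 + 1e-12)
  # independent eigendecomposition oracle (scores up to sign)
  cent <- scale(m, scale = FALSE)
  ev <- eigen(stats::cov(cent))
  scores_oracle <- cent %*% ev$vectors
  for (k in 1:3) {
    expect_equal(abs(unname(o2$scores[, k])), abs(unname(scores_oracle[, k])),
                 tolerance = 1e-8)
  }
  # fixed sign convention: largest-magnitude loading is positive
  expect_true(all(apply(o2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("dose arithmetic converts ADI to bioreactor concentration", {
  d <- bioreactor_dose(adi = 0.2, fraction_of_adi = 0.1, body_weight = 70,
                       reactor_volume = 250, molar_mass = 403.4)
  expect_equal(d$conc_mg_ml, 0.0056)
  expect_equal(floor(d$conc_um * 10) / 10, 13.8)
  unit <- bioreactor_dose(adi = 1, fraction_of_adi = 1, body_weight = 5,
                          reactor_volume = 5, molar_mass = 100)
  expect_equal(unit$conc_mg_ml, 1)
  expect_error(bioreactor_dose(adi = -0.2), "positive")
  expect_error(bioreactor_dose(fraction_of_adi = 1.5), "0, 1")
})

test_that("design enumerators count flasks and inoculum cells", {
  des <- exposure_design()
  expect_identical(des$n_flasks, 60L)
  expect_equal(des$inoculum_cells, 8e9)
})
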