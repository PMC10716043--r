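cond20 <- thermo_conditions(20, 150, 75)

test_that("duplex thermodynamics match the hand-summed unified NN tables", {
  # frozen by independent hand summation of the published parameter tables
  # (10-mer ACGTACGTAC vs perfect complement, 150 mM Na+, 20 C)
  th <- duplex_thermo("ACGTACGTAC", reverse_complement("ACGTACGTAC"), cond20)
  expect_equal(th$dH, -75.2, tolerance = 1e-12)
  expect_equal(th$dS, -214.083261, tolerance = 1e-6)
  expect_equal(th$dG_at_T, -12.441492, tolerance = 1e-6)
  # independent two-state melting oracle: 45.886 C at 75 uM total
  expect_equal(th$tm, 45.8856, tolerance = 1e-3)
})

test_that("dG identity and strand-swap symmetry hold exactly", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_seq(12)
    b <- reverse_complement(a)
    # occasionally inject an internal mismatch
    if (i %% 2 == 0) substr(a, 6, 6) <- sample(setdiff(.o_bases, substr(a, 6, 6)), 1)
    th <- duplex_thermo(a, b, cond20)
    expect_equal(th$dG_at_T, th$dH - cond20$temperature * th$dS / 1000,
                 tolerance = 1e-12)
    th2 <- duplex_thermo(b, a, cond20)
    expect_equal(th$dG_at_T, th2$dG_at_T, tolerance = 1e-9)
  }
})

test_that("appending a complementary pair strictly stabilizes the duplex", {
  for (core in c("ACGTACGTAC", "GGCCATATCG")) {
    g0 <- duplex_thermo(core, reverse_complement(core), cond20)$dG_at_T
    for (b in .o_bases) {
      ext3 <- paste0(core, b)                 # 3' extension
      ext5 <- paste0(b, core)                 # 5' extension
      expect_lt(duplex_thermo(ext3, reverse_complement(ext3), cond20)$dG_at_T, g0)
      expect_lt(duplex_thermo(ext5, reverse_complement(ext5), cond20)$dG_at_T, g0)
    }
  }
})

test_that("two-state melting temperature matches the numeric root oracle", {
  s <- "GCCACAGTTGCG"  # 12-mer
  th <- duplex_thermo(s, reverse_complement(s), thermo_conditions(20, 150, 37.5))
  tm_oracle <- o_tm_root(th$dH, th$dS, 37.5e-6)
  expect_equal(melting_temperature(th, 37.5e-6), tm_oracle, tolerance = 1e-6)
  # monotone in total concentration
  tms <- vapply(c(1e-6, 1e-5, 1e-4), function(ct) melting_temperature(th, ct),
                numeric(1))
  expect_true(all(diff(tms) > 0))
  # halving the concentration matches the closed form recomputed directly
  expect_equal(melting_temperature(th, 37.5e-6 / 2),
               1000 * th$dH / (th$dS + 1.9872 * log(37.5e-6 / 8)) - 273.15,
               tolerance = 1e-9)
  pos <- th; pos$dH <- 1
  expect_error(melting_temperature(pos, 1e-6), "no two-state")
})

test_that("sub-2-bp duplexes are rejected (no stack defined)", {
  expect_error(duplex_thermo("A", "T", cond20), "stack")
})

test_that("MFE picks the full register for perfect complements and is hurt by mismatches", {
  s <- "GCCACAGTTGCG"
  full <- duplex_thermo(s, reverse_complement(s), cond20)$dG_at_T
  expect_equal(mfe_duplex(s, reverse_complement(s), cond20), full,
               tolerance = 1e-9)
  # every internal single-mismatch variant is less stable than the perfect duplex
  rc <- reverse_complement(s)
  for (pos in 2:(nchar(s) - 1)) {
    for (b in setdiff(.o_bases, substr(s, pos, pos))) {
      mut <- s
      substr(mut, pos, pos) <- b
      expect_gt(mfe_duplex(mut, rc, cond20), mfe_duplex(s, rc, cond20))
    }
  }
})

test_that("MFE equals exhaustive enumeration for short random strands", {
  set.seed(23)
  for (i in 1:200) {
    a <- random_seq(sample(2:8, 1))
    b <- if (i %% 3 == 0) reverse_complement(a) else random_seq(sample(2:8, 1))
    expect_equal(mfe_duplex(a, b, cond20), o_mfe(a, b), tolerance = 1e-9,
                 label = sprintf("mfe(%s, %s)", a, b))
  }
})

test_that("MFE matrices have perfect-match-dominant diagonals", {
  lib1 <- build_library("GCCACAGTTGCGTC", "AACCGCAGTGACACCGGGCC")
  E1 <- mfe_matrix(lib1, cond20)
  expect_identical(dim(E1$mfe), c(1L, 1L))
  lib16 <- build_library("GCNACAGTTGNGTC", "AACCGCAGTGACACCGGGCC")
  E <- mfe_matrix(lib16, cond20)
  for (r in seq_len(16)) {
    expect_equal(which.min(E$mfe[r, ]), r, ignore_attr = TRUE)
  }
  # entries agree with the scalar op
  expect_equal(E$mfe[3, 5],
               mfe_duplex(lib16$pairs$forward[3], lib16$pairs$reverse[5], cond20))
})

test_that("Boltzmann selectivity rows are probability distributions", {
  set.seed(5)
  for (n in c(1, 8, 64, 256)) {
    E <- structure(list(mfe = matrix(-runif(n * n, 0, 30), n, n),
                        temperature = cond20$temperature),
                   class = "energy_matrix")
    S <- boltzmann_selectivity(E, cond20)
    expect_equal(rowSums(S$normalized), rep(1, n), tolerance = 1e-9)
    expect_true(all(S$normalized >= 0 & S$normalized <= 1))
  }
  # 1x1 and symmetric two-column cases
  S1 <- boltzmann_selectivity(structure(list(mfe = matrix(-5, 1, 1)),
                                        class = "energy_matrix"), cond20)
  expect_equal(S1$normalized[1, 1], 1)
  S2 <- boltzmann_selectivity(structure(list(mfe = matrix(c(-5, -2, -5, -2), 2, 2)),
                                        class = "energy_matrix"), cond20)
  expect_equal(unname(S2$normalized[1, ]), c(0.5, 0.5))
})

test_that("a 3 kcal/mol penalty at 293 K splits 0.9943 / 0.0057", {
  E <- structure(list(mfe = matrix(c(-10, -10, -7, -7), 2, 2)),
                 class = "energy_matrix")
  S <- boltzmann_selectivity(E, thermo_conditions(293 - 273.15, 150, 75))
  expect_equal(unname(S$normalized[1, 1]), 0.99425, tolerance = 1e-4)
  expect_equal(unname(S$normalized[1, 2]), 0.00575, tolerance = 2e-3)
})

test_that("selectivity summary reports the intended-pair diagonal", {
  m <- diag(4) * 0.94 + 0.02
  S <- structure(list(normalized = m / rowSums(m)), class = "selectivity_matrix")
  s <- selectivity_summary(S)
  expect_equal(s$diagonal_min, min(diag(S$normalized)))
  expect_lte(s$worst_offdiagonal, 1 - s$diagonal_min + 1e-12)
  bad <- structure(list(normalized = matrix(0.5, 2, 3)), class = "selectivity_matrix")
  expect_error(selectivity_summary(bad), "square")
})

test_that("selectivity degrades as temperature approaches overlap melting", {
  lib <- gen_explicit_library(2)
  mins <- vapply(c(20, 35, 50, 60), function(tc) {
    cc <- thermo_conditions(tc, 150, 75)
    selectivity_summary(boltzmann_selectivity(mfe_matrix(lib, cc), cc))$diagonal_min
  }, numeric(1))
  expect_true(all(diff(mins) <= 1e-12))
})

test_that("matrix melting predictions fall with library complexity", {
  lib <- build_library("GCNACAGTTGNGTC", "AACCGCAGTGACACCGGGCC")
  pm <- predicted_matrix_melting(lib, cond20)
  expect_identical(nrow(pm$per_variant), 16L)
  expect_true(all(diff(pm$trend$tm) < 0))  # strictly decreasing in C
  # C = 1 reduces to the plain melting temperature at full concentration
  lib1 <- build_library(.o_single <- "GCCACAGTTGCGTC", "AACCGCAGTGACACCGGGCC")
  pm1 <- predicted_matrix_melting(lib1, cond20)
  th <- duplex_thermo(lib1$pairs$forward[1], lib1$pairs$reverse[1], cond20)
  expect_equal(pm1$trend$tm[1], melting_temperature(th, 75e-6, FALSE),
               tolerance = 1e-9)
})

test_that("domain hierarchy separates adaptor and overlap melting", {
  h <- domain_hierarchy("AACCGCAGTGACACCGGGCC", "GCNACAGTTGNGTC", cond20)
  expect_true(h$pass)
  expect_gte(h$gap, 10)
  same <- domain_hierarchy("GCCACAGTTGCGTC", "GCCACAGTTGCGTC", cond20)
  expect_equal(same$gap, 0, tolerance = 1e-9)
  expect_false(same$pass)
  # pass is monotone in min_gap
  expect_true(domain_hierarchy("AACCGCAGTGACACCGGGCC", "GCNACAGTTGNGTC",
                               cond20, min_gap = 5)$pass)
})

test_that("blocking occupancy is monotone and activation equals the duplex Tm", {
  ov <- "GCCACAGTTGCGTC"
  blocker <- reverse_complement(substr(ov, 3, 12))  # 10-nt protector
  hac <- hac_design(ov, blocker, blocking_conc = 80e-6, splint_conc = 40e-6)
  occ <- blocking_occupancy(hac, cond20, t_range = c(0, 80))
  expect_true(all(diff(occ$curve$occupancy) <= 1e-9))
  # activation temperature = blocking duplex Tm at c_eff = b0 - s0/2
  th <- duplex_thermo(hac$target, hac$blocking,
                      thermo_conditions(occ$activation_temperature, 150, 75))
  tm_closed <- 1000 * th$dH / (th$dS + 1.9872 * log(80e-6 - 20e-6)) - 273.15
  expect_equal(occ$activation_temperature, tm_closed, tolerance = 0.05)
  expect_error(hac_design(ov, "AAAAAAAA"), "complementary")
})

test_that("a cold-blocked, 37 C-released design is reported heat-activatable", {
  # frozen from a numeric-oracle scan over overlap sub-segments: a 7-nt
  # blocker against positions 2-8 is >99% bound at 4 C and <50% bound at
  # 37 C at the deployed 80/40 uM concentrations
  ov <- "GCCACAGTTGCGTC"
  blocker <- reverse_complement(substr(ov, 2, 8))
  expect_identical(blocker, "ACTGTGG")
  occ <- blocking_occupancy(hac_design(ov, blocker), cond20)
  curve <- occ$curve
  expect_gt(curve$occupancy[which.min(abs(curve$temp_C - 4))], 0.99)
  expect_lt(curve$occupancy[which.min(abs(curve$temp_C - 37))], 0.5)
  expect_true(occ$heat_activatable)
  expect_equal(occ$activation_temperature, 34.5, tolerance = 0.03)
})
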