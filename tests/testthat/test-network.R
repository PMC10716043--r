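test_that("analytic intramolecular fraction matches exhaustive enumeration", {
  expect_equal(intramolecular_fraction_analytic(1, 4), 0)
  # m = 3, C = 1: enumeration over 2^3 splint assignments gives 0.75
  expect_equal(o_intra_enum(3, 1, "any"), 0.75)
  expect_equal(intramolecular_fraction_analytic(3, 1), 0.75)
  # m = 3, C = 4: enumeration over 8^3 assignments gives 15/64
  expect_equal(o_intra_enum(3, 4, "any"), 15 / 64)
  expect_equal(intramolecular_fraction_analytic(3, 4), 15 / 64)
})

test_that("Monte-Carlo agrees with the closed form and with enumeration", {
  for (cfg in list(c(3, 1), c(3, 4), c(2, 2), c(4, 3), c(5, 8), c(10, 16))) {
    m <- cfg[1]; C <- cfg[2]
    sim <- simulate_crosslink_partition(m, C, n_chains = 4e4,
                                        partner_model = "any_partner", seed = 101)
    fa <- intramolecular_fraction_analytic(m, C)
    expect_lt(abs(sim$intramolecular_fraction - fa), 4 * sim$ci95 / 1.96 + 1e-3)
  }
  # matching mode against exhaustive enumeration at tiny size
  simm <- simulate_crosslink_partition(3, 2, n_chains = 4e4,
                                       partner_model = "max_matching", seed = 7)
  expect_lt(abs(simm$intramolecular_fraction - o_intra_enum(3, 2, "mm")), 5e-3)
})

test_that("matching never exceeds the any-partner eligibility count", {
  for (cfg in list(c(3, 2), c(6, 4), c(20, 40))) {
    a <- simulate_crosslink_partition(cfg[1], cfg[2], 2e4, "any_partner", seed = 31)
    m <- simulate_crosslink_partition(cfg[1], cfg[2], 2e4, "max_matching", seed = 31)
    expect_lte(m$intramolecular_fraction,
               a$intramolecular_fraction + 4 * a$ci95 / 1.96)
  }
})

test_that("intramolecular fraction is monotone in C and m, and vanishes as C grows", {
  for (mode in c("any_partner", "max_matching")) {
    fr_C <- vapply(c(1, 2, 8, 32, 256), function(C)
      simulate_crosslink_partition(10, C, 2e4, mode, seed = 3)$intramolecular_fraction,
      numeric(1))
    expect_true(all(diff(fr_C) < 0.02))   # non-increasing up to MC noise
    expect_lt(fr_C[length(fr_C)], 0.05)   # C -> infinity limit
    fr_m <- vapply(c(2, 5, 10, 25), function(m)
      simulate_crosslink_partition(m, 8, 2e4, mode, seed = 4)$intramolecular_fraction,
      numeric(1))
    expect_true(all(diff(fr_m) > -0.02))  # non-decreasing up to MC noise
  }
})

test_that("seeded simulations are bit-reproducible and leave the RNG alone", {
  before <- runif(1)
  a <- simulate_crosslink_partition(20, 40, 5e4, seed = 99)
  b <- simulate_crosslink_partition(20, 40, 5e4, seed = 99)
  expect_identical(a$intramolecular_fraction, b$intramolecular_fraction)
  expect_identical(a$n_engaged, b$n_engaged)
})

test_that("minimal complexity search reports analytic and simulated crossings", {
  res <- min_complexity_for_suppression(3, 0.8, partner_model = "any_partner",
                                        n_chains = 2e4, seed = 5)
  # closed form: smallest C with 1-(1-1/(2C))^2 <= 0.2 is C = 5
  expect_identical(res$C_min_analytic, 5L)
  expect_lte(abs(res$C_min_simulated - 5L), 1L)
  expect_error(min_complexity_for_suppression(50, 0.999, C_max = 4L,
                                              n_chains = 1e3),
               "not reached")
})

test_that("affine network modulus and efficiency inversion are exact", {
  p <- polymer_spec(anchors_per_backbone = 20, mass_conc = 1,
                    anchor_conc = 75e-6)
  g_max <- theoretical_max_modulus(p, 293)
  # nu = N_A * 37.5 uM per m^3; G = nu kB T ~ 91 Pa
  expect_equal(g_max, 37.5e-6 * 1000 * 6.02214076e23 * 1.380649e-23 * 293,
               tolerance = 1e-12)
  expect_equal(g_max, 91.4, tolerance = 0.01)
  expect_equal(theoretical_max_modulus(polymer_spec(anchors_per_backbone = 20,
                                                    anchor_conc = 150e-6), 293),
               2 * g_max, tolerance = 1e-12)
  expect_equal(theoretical_max_modulus(p, 0), 0)
  # inversion round-trip is exact
  for (eff in c(0, 0.28, 0.76, 1)) {
    est <- crosslink_efficiency(eff * g_max, p, 293)
    expect_equal(est$efficiency, eff, tolerance = 1e-12)
  }
  est <- crosslink_efficiency(69.4, p, 293)
  expect_equal(est$efficiency, 0.76, tolerance = 0.01)
  expect_null(est$flag)
  expect_false(is.null(crosslink_efficiency(2 * g_max, p, 293)$flag))
  # phantom normalization halves the tetrafunctional limit
  expect_equal(theoretical_max_modulus(p, 293, model = "phantom"), g_max / 2)
})

test_that("anchor concentration derives from the backbone when not given", {
  p <- polymer_spec(backbone_mass = 3e6, anchors_per_backbone = 20,
                    mass_conc = 1)
  expect_equal(p$anchor_conc, 10 / 3e6 * 20, tolerance = 1e-12)
})

test_that("DNA mass concentration sums strand masses", {
  expect_equal(dna_mass_concentration(data.frame(conc = numeric(0),
                                                 length = numeric(0))), 0)
  # 75 uM of a 20-nt strand at the 325 Da/nt average
  expect_equal(dna_mass_concentration(data.frame(length = 20, conc = 75e-6)),
               75e-6 * 20 * 325, tolerance = 1e-12)
  # sequence-based mass: 20-mer with known composition (free acid, no 5'P)
  s <- "ACGTACGTACGTACGTACGT"
  mass <- 5 * (313.21 + 289.18 + 329.21 + 304.2) - 61.96
  expect_equal(dna_mass_concentration(data.frame(sequence = s, conc = 1e-6)),
               1e-6 * mass, tolerance = 1e-9)
  # mixtures add linearly
  two <- data.frame(length = c(20, 34), conc = c(75e-6, 75e-6))
  expect_equal(dna_mass_concentration(two),
               75e-6 * 325 * 54, tolerance = 1e-12)
})
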