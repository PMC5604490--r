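test_that("parameter construction enforces physical invariants", {
  p <- wt_params()
  expect_s3_class(p, "carrier_params")
  expect_equal(p$kf, 2.5e10)
  expect_equal(p$Kd, 4e-5)
  expect_equal(p$kr, 1e6)
  expect_equal(p$kc, 5.66e6)
  expect_equal(p$temperature, 37)
  expect_equal(p$kr, p$kf * p$Kd, tolerance = 1e-6)

  expect_error(carrier_params(Kd = 0), "Kd")
  expect_error(carrier_params(n_half = 0), "n_half")
  expect_error(carrier_params(widths = c(w_M = -1, w_C = 5, w_S = 4)), "widths")
  expect_error(carrier_params(kr = 2e6), "inconsistent")
  expect_error(carrier_params(substrates = data.frame(
    name = c("a", "a"), cyt_M = c(1e-3, 0), mat_M = c(0, 1e-3))), "duplicate")
  expect_error(carrier_params(substrates = data.frame(
    name = "a", cyt_M = -1e-3, mat_M = 0)), ">= 0")
})

test_that("Gaussian network term peaks at its centre and decays monotonically", {
  expect_equal(network_energy(-10, -550, -10, 5), -550)
  expect_equal(network_energy(0, -550, -10, 5), -550 * exp(-4))
  expect_equal(network_energy(10, -550, -10, 5), -550 * exp(-16))
  expect_error(network_energy(0, -550, -10, 0), "width")
  # strictly decreasing magnitude away from the centre
  v <- abs(network_energy(-10:10, -550, -10, 5))
  expect_true(all(diff(v) < 0))
})

test_that("binding energy follows -kBT ln([S]/Kd)", {
  kBT <- thermal_energy_mv(37)
  expect_equal(binding_energy(4e-5, 4e-5, kBT), 0)
  expect_equal(binding_energy(5e-3, 4e-5, kBT), -kBT * log(125))
  expect_equal(binding_energy(5e-3, 4e-5, 26.7), -128.9, tolerance = 1e-3)
  expect_equal(binding_energy(4e-6, 4e-5, 26.7), 61.5, tolerance = 1e-2)
  expect_identical(binding_energy(0, 4e-5, kBT), Inf)
})

test_that("chemical potential is the additive Gaussian profile", {
  p <- wt_params()
  expect_equal(chemical_potential(0, NULL, p), 2 * -550 * exp(-4))
  expect_equal(chemical_potential(0, NULL, p), -20.15, tolerance = 1e-3)
  p2 <- carrier_params(dE_M = -550, dE_C = 0, dE_S = 0)
  expect_equal(chemical_potential(-10, NULL, p2), -550, tolerance = 1e-9)
  # with a matching cytoplasmic network only the e^-16 tail is added
  expect_equal(chemical_potential(-10, NULL, p), -550 * (1 + exp(-16)))
  # bound state adds the induced-fit Gaussian (dEB excluded)
  expect_equal(chemical_potential(0, 1L, p), 2 * -550 * exp(-4) - 550)
  expect_error(chemical_potential(0, "nosuch", p), "unknown substrate")
  expect_error(chemical_potential(11, NULL, p), "out of range")
  # dEB-inclusive potential shifts bound states by the binding energy
  expect_equal(
    chemical_potential(0, "labelled", p, include_dEB = TRUE, side = "cyt") -
      chemical_potential(0, "labelled", p),
    binding_energy(5e-3, p$Kd, p$kBT))
})

test_that("profile symmetries hold", {
  cs <- -10:10
  # symmetric networks: empty profile symmetric under c <-> -c
  p <- carrier_params(dE_M = -430, dE_C = -430, dE_S = 0)
  expect_equal(chemical_potential(cs, NULL, p),
               rev(chemical_potential(cs, NULL, p)))
  # swapping dE_M and dE_C mirrors the profile exactly
  pa <- carrier_params(dE_M = -620, dE_C = -350, dE_S = 0)
  pb <- carrier_params(dE_M = -350, dE_C = -620, dE_S = 0)
  expect_identical(chemical_potential(cs, NULL, pa),
                   rev(chemical_potential(cs, NULL, pb)))
  # bound-minus-empty offset identical for substrates sharing Kd
  pc <- wt_params()
  d1 <- chemical_potential(cs, 1L, pc) - chemical_potential(cs, NULL, pc)
  d2 <- chemical_potential(cs, 2L, pc) - chemical_potential(cs, NULL, pc)
  expect_identical(d1, d2)
})

test_that("conformational rates satisfy the free-energy identity", {
  p <- wt_params()
  for (s in list(NULL, 1L, 2L)) {
    for (c in c(-10L, -3L, 0L, 9L)) {
      r <- conformational_rates(c, s, p)
      dG <- chemical_potential(c + 1, s, p) - chemical_potential(c, s, p)
      expect_equal(-p$kBT * log(r[["forward"]] / r[["reverse"]]), dG,
                   tolerance = 1e-12)
      expect_equal(r[["forward"]] * r[["reverse"]], p$kc^2, tolerance = 1e-12)
    }
  }
  expect_error(conformational_rates(10, NULL, p), "n_half")
  # flat profile: both rates equal kc
  p0 <- carrier_params(dE_M = 0, dE_C = 0, dE_S = 0)
  expect_equal(unname(conformational_rates(0, NULL, p0)), rep(p0$kc, 2))
  # frozen value from direct profile arithmetic at the wild-type point
  r <- conformational_rates(0, NULL, p)
  dG <- -550 * (exp(-(11 / 5)^2) + exp(-(9 / 5)^2)) - 2 * -550 * exp(-4)
  expect_equal(dG, -5.74182, tolerance = 1e-6)
  expect_equal(r[["forward"]], p$kc * exp(-0.5 * dG / p$kBT))
  expect_equal(r[["forward"]], 6301838, tolerance = 1e-6)
})

test_that("Kolmogorov path independence holds along the ladder", {
  p <- carrier_params(dE_M = -470, dE_C = -510, dE_S = -390)
  for (s in list(NULL, 1L)) {
    mu <- chemical_potential(-10:10, s, p)
    lr <- vapply(-10:9, function(c) {
      r <- conformational_rates(c, s, p)
      log(r[["forward"]] / r[["reverse"]])
    }, numeric(1))
    # product of ratios between any two states = exp(-dmu/kBT)
    expect_equal(cumsum(lr), -(mu[-1] - mu[1]) / p$kBT, tolerance = 1e-12)
  }
})

test_that("binding rates are first order with the published constants", {
  p <- carrier_params(substrates = single_substrate(1e-3, 0))
  b <- binding_rates("cytoplasmic", "substrate", p)
  expect_equal(b[["on"]], 2.5e7)           # mean binding time 40 ns at 1 mM
  expect_equal(1 / b[["on"]], 40e-9)
  expect_equal(b[["off"]], 1e6)
  expect_equal(binding_rates("matrix", "substrate", p)[["on"]], 0)
})

test_that("consistent binding edges fold the induced-fit tail into the edge step", {
  p <- carrier_params(consistent_binding_edges = TRUE,
                      substrates = single_substrate(1e-3, 0))
  b <- binding_rates("cytoplasmic", "substrate", p)
  # implied bound-edge potential now matches the additive profile exactly
  implied <- -p$kBT * log(b[["on"]] / b[["off"]])
  expected <- chemical_potential(-10, 1L, p, include_dEB = TRUE, side = "cyt") -
    chemical_potential(-10, NULL, p)
  expect_equal(implied, expected, tolerance = 1e-12)
  # default literal first-order rates leave the ~1 mV induced-fit tail out
  pl <- carrier_params(substrates = single_substrate(1e-3, 0))
  bl <- binding_rates("cytoplasmic", "substrate", pl)
  off_by <- -pl$kBT * log(bl[["on"]] / bl[["off"]]) - expected
  expect_equal(off_by, -(-550) * exp(-(10 / 4)^2), tolerance = 1e-9)
})

test_that("energy profile table covers both occupancies", {
  prof <- energy_profile(wt_params())
  expect_equal(nrow(prof), 21)
  expect_equal(prof$c, -10:10)
  expect_equal(prof$mu0_bound_mV - prof$mu0_empty_mV,
               -550 * exp(-(prof$c / 4)^2))
})
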