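test_that("state and reaction counts follow 21(N+1) and 20(N+1)+2N", {
  # N = 2 (labelled/unlabelled exchange)
  net <- build_network(wt_params())
  expect_equal(nrow(net$states), 63)
  expect_equal(nrow(net$reactions), 64)
  # N = 1
  net1 <- build_network(carrier_params(substrates = single_substrate(5e-3, 5e-3)))
  expect_equal(nrow(net1$states), 42)
  expect_equal(nrow(net1$reactions), 42)
  # binding reactions touch only the end conformations of the empty ladder
  b <- net$reactions[net$reactions$type != "conformational", ]
  expect_true(all(net$states$c[b$from] %in% c(-10, 10)))
  expect_true(all(net$states$s[b$from] == 0))
  expect_true(all(net$states$s[b$to] > 0))
  # conformational steps connect |dc| = 1 with identical occupancy
  k <- net$reactions[net$reactions$type == "conformational", ]
  expect_true(all(net$states$c[k$to] - net$states$c[k$from] == 1))
  expect_true(all(net$states$s[k$to] == net$states$s[k$from]))
})

test_that("generator columns sum to zero and dimensions match", {
  net <- build_network(wt_params())
  Q <- generator_matrix(net)
  expect_equal(dim(Q), c(63, 63))
  expect_lt(max(abs(colSums(Q))), 1e-12 * max(Q))
  offdiag <- Q - diag(diag(Q))
  expect_true(all(offdiag >= 0))
})

test_that("steady state is a normalised probability with tiny residual", {
  ss <- solve_steady_state(build_network(wt_params()))
  expect_equal(sum(ss$P), 1, tolerance = 1e-12)
  expect_true(all(ss$P >= -1e-12 * max(ss$P)))
  expect_lt(ss$residual, 1e-6)   # absolute, rates are O(1e7)
  expect_lt(max(ss$flux_spread), 1e-6)
})

test_that("no-substrate ladder relaxes to the Boltzmann distribution", {
  p <- carrier_params(dE_M = -550, dE_C = -400, dE_S = -300,
                      substrates = single_substrate(0, 0))
  expect_warning(ss <- solve_steady_state(build_network(p)), "pruning")
  # bound states pruned to exact zeros
  st <- ss$network$states
  expect_true(all(ss$P[st$s > 0] == 0))
  P_empty <- ss$P[st$s == 0]
  pb <- boltzmann_profile(chemical_potential(-10:10, NULL, p), p$kBT)
  expect_equal(unname(P_empty), pb, tolerance = 1e-9)
})

test_that("symmetric exchange has mirror symmetry with labels swapped", {
  ss <- solve_steady_state(build_network(wt_params()))
  st <- ss$network$states
  P <- ss$P
  # P(c, labelled) == P(-c, unlabelled)
  Pl <- P[st$s == 1][order(st$c[st$s == 1])]
  Pu <- P[st$s == 2][order(st$c[st$s == 2])]
  expect_equal(unname(Pl), rev(unname(Pu)), tolerance = 1e-9)
  Pe <- P[st$s == 0][order(st$c[st$s == 0])]
  expect_equal(unname(Pe), rev(unname(Pe)), tolerance = 1e-9)
})

test_that("net flux vanishes without a concentration gradient", {
  p <- carrier_params(substrates = single_substrate(2e-3, 2e-3))
  ss <- solve_steady_state(build_network(p))
  for (b in c(-10, -5, 0, 9)) {
    expect_lt(abs(net_flux(ss, b, "substrate")), 1e-9)
  }
})

test_that("flux is identical across all 20 boundaries", {
  ss <- solve_steady_state(build_network(wt_params()))
  J <- vapply(-10:9, function(b) net_flux(ss, b, "labelled"), numeric(1))
  expect_equal(length(J), 20)
  expect_lt(max(abs(J - mean(J))) / abs(mean(J)), 1e-6)
  expect_equal(net_flux(ss, -5, "labelled"), net_flux(ss, 4, "labelled"),
               tolerance = 1e-6)
  expect_error(net_flux(ss, 10, "labelled"), "invalid boundary")
})

test_that("labelled influx equals unlabelled efflux in exchange", {
  ss <- solve_steady_state(build_network(wt_params()))
  infl <- transport_rate(ss)
  effl <- -net_flux(ss, 0, "unlabelled")
  expect_equal(infl, effl, tolerance = 1e-6)
  expect_equal(infl, 41.29, tolerance = 1e-3)  # ~40 ADP/s wild type
})

test_that("cycle affinities vanish at equal same-species concentrations", {
  # closed cycle: bind cyt -> cross bound ladder -> release mat ->
  # cross empty ladder back; product of rate ratios must be 1
  p <- carrier_params(dE_M = -500, dE_C = -430, dE_S = -380,
                      substrates = single_substrate(1e-3, 1e-3))
  net <- build_network(p)
  r <- net$reactions
  lr <- log(r$fwd / r$rev)
  bound <- r$type == "conformational" & r$substrate == 1
  empty <- r$type == "conformational" & r$substrate == 0
  cyc <- sum(lr[r$type == "bind_cyt"]) + sum(lr[bound]) -
    sum(lr[r$type == "bind_mat"]) - sum(lr[empty])
  expect_lt(abs(cyc), 1e-10)
})

test_that("transport collapses as kc tends to zero and falls with network strength", {
  p <- modify_params(wt_params(), kc = 1)   # transport scales with kc
  expect_lt(abs(solve_steady_state(build_network(p))$transport_rate), 1e-4)
  tr <- vapply(c(-300, -400, -500, -600), function(g) {
    pg <- carrier_params(dE_M = g, dE_C = g, dE_S = 0)
    solve_steady_state(build_network(pg))$transport_rate
  }, numeric(1))
  expect_true(all(diff(tr) < 0))  # stronger networks, less transport
})

test_that("grid refinement leaves transport bounded (convergence)", {
  # doubling the grid with widths scaled to keep the same profile shape
  # changes transport by a bounded factor (roughly the diffusive 1/4 of
  # a random walk with twice the steps); the 21-step default is a
  # modelling choice, not a numerical limit
  tr <- vapply(c(1, 2), function(k) {
    p <- carrier_params(n_half = 10L * k,
                        widths = c(w_M = 5, w_C = 5, w_S = 4) * k)
    solve_steady_state(build_network(p))$transport_rate
  }, numeric(1))
  expect_true(all(is.finite(tr)) && all(tr > 0))
  expect_lt(abs(log(tr[2] / tr[1])), log(10))
})

test_that("steady-state tables are tidy and consistent", {
  ss <- solve_steady_state(build_network(wt_params()))
  tabs <- steady_state_tables(ss)
  expect_equal(nrow(tabs$states), 63)
  expect_equal(sum(tabs$states$P), 1, tolerance = 1e-12)
  expect_equal(nrow(tabs$fluxes), 20 * 2)
  expect_equal(mean(tabs$fluxes$flux_per_s[tabs$fluxes$substrate == "labelled"]),
               transport_rate(ss))
})
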