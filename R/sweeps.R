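#' Conformational base rates normalising peak transport across network
#' strengths
#'
#' For comparisons across symmetric network strengths, the
#' conformational base rate can be renormalised so that the maximum
#' transport rate is the same at every strength. The published values
#' are 0.065, 0.200, 0.721, 2.810, 11.488 and 48.76 per microsecond for
#' network strengths of -200 to -700 mV.
#'
#' @return named numeric vector of kc values in 1/s, names are the
#'   network strengths in mV.
#' @export
kc_renormalised <- function() {
  c(`-200` = 0.065, `-300` = 0.200, `-400` = 0.721,
    `-500` = 2.810, `-600` = 11.488, `-700` = 48.76) * 1e6
}

new_sweep <- function(data, parameter, scenario, fixed) {
  structure(list(data = data, parameter = parameter,
                 scenario = scenario, fixed = fixed),
            class = "carrier_sweep")
}

#' @export
print.carrier_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s (%d points): %s\n",
              x$parameter, nrow(x$data), x$scenario))
  utils::str(x$fixed, give.head = FALSE)
  invisible(x)
}

#' Symmetric network-strength sweep without induced fit
#'
#' Varies the matrix and cytoplasmic network strengths together
#' (\eqn{\Delta E_C = \Delta E_M}) at \eqn{\Delta E_S = 0} under the
#' 5 mM/5 mM labelled/unlabelled exchange scenario. Strong networks
#' suppress conformational change of the (effectively always-bound)
#' carrier, so the residual transport falls roughly exponentially with
#' the network strength. Each point also carries the closed-form
#' forward-flux estimates ([forward_flux_estimate()]).
#'
#' @param grid network strengths \eqn{\Delta E_{M/C}} in mV.
#' @param params base parameter set (energies overridden per point).
#' @return a `carrier_sweep` whose `data` has columns `dE_MC`,
#'   `transport`, `JF_partition`, `JF_two_state`, plus the unlabelled
#'   efflux `efflux_unlabelled` for the mass-balance check.
#' @export
sweep_symmetric_no_binding <- function(grid = seq(-700, 0, by = 10),
                                       params = carrier_params()) {
  stopifnot(all(diff(grid) > 0) || all(diff(grid) < 0))
  rows <- lapply(grid, function(g) {
    p <- modify_params(params, dE_M = g, dE_C = g, dE_S = 0)
    ss <- solve_steady_state(build_network(p))
    ulab <- which(!p$substrates$labelled)
    data.frame(dE_MC = g,
               transport = ss$transport_rate,
               efflux_unlabelled = if (length(ulab)) -mean(ss$J[, ulab[1L]])
                                   else NA_real_,
               JF_partition = forward_flux_estimate(p, "partition"),
               JF_two_state = forward_flux_estimate(p, "two_state"))
  })
  new_sweep(do.call(rbind, rows), "dE_MC", "symmetric networks, no induced fit",
            list(dE_S = 0, substrates = params$substrates, kc = params$kc))
}

#' Induced-fit binding-energy sweep
#'
#' Varies the induced-fit substrate binding energy \eqn{\Delta E_S} at a
#' fixed symmetric network strength under the 5 mM/5 mM exchange
#' scenario. Transport is maximal when the binding energy roughly equals
#' the network strength — i.e. when the chemical potential of the bound
#' intermediate conformation is level with the end conformations and the
#' energy barrier is minimal. Per point the chemical potential of the
#' bound intermediate state \eqn{\mu_I} is reported.
#'
#' @param grid induced-fit strengths \eqn{\Delta E_S} in mV.
#' @param dE_MC symmetric network strength in mV.
#' @param renormalise_kc if `TRUE`, use the published per-strength
#'   conformational base rate ([kc_renormalised()]) when `dE_MC` matches
#'   one of its entries.
#' @param params base parameter set.
#' @return a `carrier_sweep` with columns `dE_S`, `transport`, `mu_I`
#'   (bound, net, mV); the optimum is in `fixed$optimum`.
#' @export
sweep_binding_energy <- function(grid = seq(-900, 0, by = 10),
                                 dE_MC = -550, renormalise_kc = FALSE,
                                 params = carrier_params()) {
  kc <- params$kc
  if (renormalise_kc) {
    tab <- kc_renormalised()
    key <- as.character(dE_MC)
    if (key %in% names(tab)) kc <- tab[[key]]
  }
  rows <- lapply(grid, function(g) {
    p <- modify_params(params, dE_M = dE_MC, dE_C = dE_MC, dE_S = g, kc = kc)
    ss <- solve_steady_state(build_network(p))
    data.frame(dE_S = g,
               transport = ss$transport_rate,
               mu_I = chemical_potential(0, 1L, p))
  })
  data <- do.call(rbind, rows)
  i <- which.max(data$transport)
  new_sweep(data, "dE_S", "induced-fit sweep at symmetric networks",
            list(dE_MC = dE_MC, kc = kc,
                 optimum = data[i, , drop = FALSE]))
}

#' Cytoplasmic network-strength sweep
#'
#' Varies the cytoplasmic network strength at fixed matrix network and
#' induced-fit energies (\eqn{\Delta E_M = \Delta E_S}), 5 mM/5 mM
#' exchange. The optimum is refined on a 1 mV grid around the coarse
#' argmax; maximal transport occurs with the cytoplasmic network a few
#' millivolts weaker than the matrix network.
#'
#' @param grid cytoplasmic network strengths in mV (coarse scan).
#' @param dE_MS common matrix-network / induced-fit strength in mV.
#' @param refine_mV half-width of the 1 mV refinement window around the
#'   coarse argmax (0 skips refinement).
#' @param params base parameter set.
#' @return a `carrier_sweep` with columns `dE_C`, `transport`;
#'   `fixed$optimum` holds the 1 mV-resolution argmax.
#' @export
sweep_cyto_network <- function(grid = seq(-700, -400, by = 10),
                               dE_MS = -550, refine_mV = 15,
                               params = carrier_params()) {
  tr_at <- function(dc) {
    p <- modify_params(params, dE_M = dE_MS, dE_C = dc, dE_S = dE_MS)
    solve_steady_state(build_network(p))$transport_rate
  }
  tr <- vapply(grid, tr_at, numeric(1))
  data <- data.frame(dE_C = grid, transport = tr)
  best <- grid[which.max(tr)]
  if (refine_mV > 0) {
    fine <- seq(best - refine_mV, best + refine_mV, by = 1)
    trf <- vapply(fine, tr_at, numeric(1))
    best <- fine[which.max(trf)]
    best_tr <- max(trf)
  } else {
    best_tr <- max(tr)
  }
  new_sweep(data, "dE_C", "cytoplasmic network sweep",
            list(dE_MS = dE_MS,
                 optimum = data.frame(dE_C = best, transport = best_tr)))
}

#' Michaelis-Menten parameters across cytoplasmic network strengths
#'
#' For each cytoplasmic network strength, fits Michaelis-Menten curves
#' to simulated uptake from both sides (varied substrate 0..100 uM in
#' `conc_step` steps, counter-substrate fixed at 5 mM) and overlays the
#' partition-function approximation ([km_from_partition()]). Fit
#' failures are recorded per point and the sweep continues.
#'
#' @param grid cytoplasmic network strengths in mV.
#' @param dE_M,dE_S fixed matrix-network / induced-fit strengths in mV.
#' @param conc_step concentration grid step in molar (grid is
#'   0..100 uM).
#' @param params base parameter set.
#' @return a `carrier_sweep` with columns `dE_C`, `kcat_cyt`, `KM_cyt`,
#'   `kcat_mat`, `KM_mat`, `KM_cyt_approx`, `KM_mat_approx`,
#'   `converged_cyt`, `converged_mat` (K_M in molar).
#' @export
km_kcat_curves <- function(grid = seq(-700, -300, by = 50),
                           dE_M = -550, dE_S = -550,
                           conc_step = 0.1e-6,
                           params = carrier_params()) {
  conc <- seq(0, 100e-6, by = conc_step)
  rows <- lapply(grid, function(dc) {
    p <- modify_params(params, dE_M = dE_M, dE_C = dc, dE_S = dE_S)
    fc <- fit_michaelis_menten(conc, mm_curve(p, "cytoplasmic", conc)$rate_per_s)
    fm <- fit_michaelis_menten(conc, mm_curve(p, "matrix", conc)$rate_per_s)
    ka <- km_from_partition(partition_decomposition(p), p$Kd)
    data.frame(dE_C = dc,
               kcat_cyt = fc$kcat, KM_cyt = fc$KM,
               kcat_mat = fm$kcat, KM_mat = fm$KM,
               KM_cyt_approx = unname(ka["KM_cyt"]),
               KM_mat_approx = unname(ka["KM_mat"]),
               converged_cyt = fc$converged, converged_mat = fm$converged)
  })
  new_sweep(do.call(rbind, rows), "dE_C",
            "Michaelis-Menten parameters vs cytoplasmic network strength",
            list(dE_M = dE_M, dE_S = dE_S, conc_step = conc_step,
                 counter_mM = 5))
}

#' Exchange and uniport scenarios across cytoplasmic network strengths
#'
#' Net flux under four substrate gradients as the cytoplasmic network
#' strength varies (matrix network and induced fit fixed):
#' \describe{
#'   \item{exchange}{5 mM labelled cytoplasmic vs 5 mM unlabelled
#'     matrix; metric is labelled influx.}
#'   \item{efflux}{substrate only in the matrix (5 mM); metric is net
#'     efflux (positive = matrix-to-cytoplasm).}
#'   \item{influx}{substrate only on the cytoplasmic side (5 mM); metric
#'     is net influx.}
#'   \item{net_influx}{5 mM cytoplasmic vs 0.2 mM matrix of the same
#'     substrate; metric is net influx (the uniport component).}
#' }
#'
#' @param grid cytoplasmic network strengths in mV.
#' @param dE_MS common matrix-network / induced-fit strength in mV.
#' @param params base parameter set (concentrations overridden per
#'   scenario).
#' @return a `carrier_sweep` with columns `dE_C`, `scenario`, `flux`
#'   (1/s); `fixed$summary` reports the influx-scenario argmax, its
#'   salt-bridge equivalent, and the influx-to-exchange ratio at
#'   `dE_C = dE_MS`.
#' @export
uniport_scenarios <- function(grid = seq(-700, -100, by = 10),
                              dE_MS = -550, params = carrier_params()) {
  single <- function(cyt, mat) data.frame(
    name = "substrate", cyt_M = cyt, mat_M = mat, labelled = TRUE,
    stringsAsFactors = FALSE)
  scen <- list(
    exchange = list(substrates = default_substrates(), sign = +1),
    efflux = list(substrates = single(0, 5e-3), sign = -1),
    influx = list(substrates = single(5e-3, 0), sign = +1),
    net_influx = list(substrates = single(5e-3, 0.2e-3), sign = +1))
  rows <- lapply(names(scen), function(nm) {
    sc <- scen[[nm]]
    flux <- vapply(grid, function(dc) {
      p <- modify_params(params, dE_M = dE_MS, dE_C = dc, dE_S = dE_MS,
                         substrates = sc$substrates)
      sc$sign * solve_steady_state(build_network(p))$transport_rate
    }, numeric(1))
    data.frame(dE_C = grid, scenario = nm, flux = flux,
               stringsAsFactors = FALSE)
  })
  data <- do.call(rbind, rows)
  infl <- data[data$scenario == "influx", ]
  exch <- data[data$scenario == "exchange", ]
  best <- infl$dE_C[which.max(infl$flux)]
  at_eq <- exch$flux[which.min(abs(exch$dE_C - dE_MS))]
  new_sweep(data, "dE_C", "exchange and uniport scenarios",
            list(dE_MS = dE_MS,
                 summary = list(
                   influx_argmax_mV = best,
                   influx_argmax_saltbridges = mv_to_saltbridges(best),
                   influx_max = max(infl$flux),
                   exchange_at_equal_networks = at_eq,
                   influx_to_exchange_ratio = max(infl$flux) / at_eq)))
}
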