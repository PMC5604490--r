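#' Gaussian network energy term
#'
#' Conformation-dependent free energy of formation of a salt-bridge
#' network (or of the induced fit), modelled as a Gaussian along the
#' conformational coordinate: `scale * exp(-((c - center)/width)^2)`.
#' The matrix network peaks at the cytoplasmic conformation
#' (center = -n_half, width 5), the cytoplasmic network at the matrix
#' conformation (center = +n_half, width 5) and the induced fit at the
#' intermediate conformation (center = 0, width 4).
#'
#' @param c conformation index (vectorised).
#' @param scale energy scale in mV.
#' @param center conformation at which the term peaks.
#' @param width Gaussian denominator (> 0), conformational units.
#' @return energy in mV.
#' @export
network_energy <- function(c, scale, center, width) {
  if (width <= 0) stop("width must be > 0")
  scale * exp(-((c - center) / width)^2)
}

#' Concentration-dependent substrate binding energy
#'
#' \eqn{\Delta E_B = -k_BT \ln([S]/K_d)} in mV: the free-energy drop on
#' binding at the end conformations, first order in substrate
#' concentration. Negative (stabilising) when the concentration exceeds
#' Kd. A zero concentration returns `Inf` as a sentinel; rate
#' calculations never take this path (the on-rate `kf*[S]` is simply 0).
#'
#' @param concentration substrate concentration in molar (vectorised).
#' @param Kd dissociation constant in molar.
#' @param kBT thermal energy in mV.
#' @return binding energy in mV.
#' @export
binding_energy <- function(concentration, Kd, kBT) {
  if (Kd <= 0) stop("Kd must be > 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  ifelse(concentration == 0, Inf, -kBT * log(concentration / Kd))
}

#' Standard chemical potential of a carrier state
#'
#' Additive free-energy profile: the matrix- and cytoplasmic-network
#' Gaussians for every state, plus — for substrate-bound states — the
#' induced-fit Gaussian and (optionally) the concentration-dependent
#' binding energy \eqn{\Delta E_B}. With `include_dEB = FALSE` the "net"
#' potential used by barrier and partition-function analyses is returned,
#' where the \eqn{K_d/[S]} factors are handled separately.
#'
#' @param c conformation index (vectorised), |c| <= n_half.
#' @param substrate `NULL` or `"empty"` for the unbound carrier, otherwise
#'   a substrate name or index from `params$substrates`.
#' @param params a [carrier_params()] object.
#' @param include_dEB include the binding energy term for bound states?
#' @param side which compartment's concentration feeds \eqn{\Delta E_B}
#'   ("cyt" or "mat"); only relevant when `include_dEB = TRUE`.
#' @return chemical potential in mV.
#' @examples
#' p <- carrier_params(dE_S = 0)
#' chemical_potential(0, NULL, p) # 2 * (-550) * exp(-4)
#' @export
chemical_potential <- function(c, substrate = NULL, params,
                               include_dEB = FALSE, side = "cyt") {
  n <- params$n_half
  if (any(abs(c) > n)) stop("conformation out of range [-n_half, n_half]")
  w <- params$widths
  mu <- network_energy(c, params$dE_M, -n, w[["w_M"]]) +
    network_energy(c, params$dE_C, +n, w[["w_C"]])
  bound <- !is.null(substrate) && !identical(substrate, "empty")
  if (bound) {
    idx <- substrate_index(params, substrate)
    mu <- mu + network_energy(c, params$dE_S, 0, w[["w_S"]])
    if (include_dEB) {
      conc <- switch(side,
                     cyt = params$substrates$cyt_M[idx],
                     mat = params$substrates$mat_M[idx],
                     stop("side must be 'cyt' or 'mat'"))
      mu <- mu + binding_energy(conc, params$Kd, params$kBT)
    }
  }
  unname(mu)
}

substrate_index <- function(params, substrate) {
  if (is.numeric(substrate)) {
    if (substrate < 1 || substrate > nrow(params$substrates)) {
      stop("substrate index out of range: ", substrate)
    }
    return(as.integer(substrate))
  }
  idx <- match(substrate, params$substrates$name)
  if (is.na(idx)) stop("unknown substrate: ", substrate)
  idx
}

#' Full energy profile along the conformational coordinate
#'
#' Net standard chemical potential (binding energy excluded) for the
#' empty and the substrate-bound carrier at every conformation.
#'
#' @param params a [carrier_params()] object.
#' @return data frame with columns `c`, `mu0_empty_mV`, `mu0_bound_mV`.
#' @export
energy_profile <- function(params) {
  cs <- seq(-params$n_half, params$n_half)
  data.frame(
    c = cs,
    mu0_empty_mV = chemical_potential(cs, NULL, params),
    mu0_bound_mV = chemical_potential(cs, 1L, params))
}

#' Conformational step rates
#'
#' Forward and reverse rate constants for the step c -> c+1 with a given
#' occupancy. The standard free-energy change of the step,
#' \eqn{\Delta G^0 = \mu^0_{c+1,s} - \mu^0_{c,s}} (the concentration term
#' cancels), is split symmetrically:
#' forward \eqn{= k_c e^{-\Delta G^0/2k_BT}},
#' reverse \eqn{= k_c e^{+\Delta G^0/2k_BT}}, so the ratio satisfies the
#' thermodynamic identity \eqn{-k_BT\ln(k_+/k_-) = \Delta G^0} exactly.
#'
#' @param c conformation index of the lower state; `-n_half <= c < n_half`.
#' @param substrate `NULL`/"empty" or a substrate name/index.
#' @param params a [carrier_params()] object.
#' @return named numeric vector `c(forward =, reverse =)` in 1/s.
#' @export
conformational_rates <- function(c, substrate = NULL, params) {
  n <- params$n_half
  if (any(c < -n | c >= n)) stop("need -n_half <= c < n_half")
  dG <- chemical_potential(c + 1, substrate, params) -
    chemical_potential(c, substrate, params)
  x <- 0.5 * dG / params$kBT
  c(forward = params$kc * exp(-x), reverse = params$kc * exp(x))
}

#' Substrate binding and release rates at a membrane face
#'
#' Binding is only allowed at the end conformations: from the cytoplasm
#' at c = -n_half and from the matrix at c = +n_half. The on-rate is
#' first order in the compartment concentration, `kf * [S]`; the
#' off-rate is `kr`. With `consistent_binding_edges = TRUE` the residual
#' induced-fit tail at the edge is folded in symmetrically.
#'
#' @param side `"cytoplasmic"` or `"matrix"`.
#' @param substrate substrate name or index.
#' @param params a [carrier_params()] object.
#' @return named numeric vector `c(on =, off =)` in 1/s.
#' @examples
#' p <- carrier_params(substrates = default_substrates(cyt_M = 1e-3))
#' binding_rates("cytoplasmic", "labelled", p) # on = 2.5e7/s (40 ns)
#' @export
binding_rates <- function(side, substrate, params) {
  side <- match.arg(side, c("cytoplasmic", "matrix"))
  idx <- substrate_index(params, substrate)
  conc <- if (side == "cytoplasmic") params$substrates$cyt_M[idx]
          else params$substrates$mat_M[idx]
  on <- params$kf * conc
  off <- params$kr
  if (params$consistent_binding_edges) {
    # residual induced-fit energy at the edge conformation (~ -1 mV at
    # default parameters); split like a conformational step
    tail_mV <- network_energy(params$n_half, params$dE_S, 0,
                              params$widths[["w_S"]])
    x <- 0.5 * tail_mV / params$kBT
    on <- on * exp(-x)
    off <- off * exp(x)
  }
  c(on = on, off = off)
}
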