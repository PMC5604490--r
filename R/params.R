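#' Model parameters for the carrier kinetic model
#'
#' Collects every tunable quantity of the free-energy-profile model: the
#' three Gaussian energy scales, the substrate binding/release kinetics,
#' the conformational base rate, the temperature, the conformational grid
#' and the substrate table. Defaults are the published calibration for the
#' ADP/ATP carrier: a symmetric wild type with
#' \eqn{\Delta E_M = \Delta E_C = \Delta E_S = -550} mV,
#' \eqn{K_d = 40\,\mu M}, \eqn{k_f = 2.5\times 10^{10}} M\eqn{^{-1}}s\eqn{^{-1}}
#' (mean binding time 40 ns at 1 mM), \eqn{k_r = 10^6} s\eqn{^{-1}},
#' \eqn{k_c = 5.66\times 10^6} s\eqn{^{-1}} and T = 37 C, with 5 mM
#' labelled ADP on the cytoplasmic side exchanging against 5 mM unlabelled
#' ADP in the matrix.
#'
#' @param dE_M matrix salt-bridge-network energy scale in mV (negative =
#'   stabilising). The matrix network is engaged in the *cytoplasmic*
#'   conformation, so its Gaussian is centred at c = -n_half.
#' @param dE_C cytoplasmic-network energy scale in mV; Gaussian centred at
#'   c = +n_half.
#' @param dE_S induced-fit substrate-binding energy scale in mV; Gaussian
#'   centred at the intermediate conformation c = 0, acting only on bound
#'   states.
#' @param Kd substrate dissociation constant in molar (no induced fit).
#' @param kf substrate binding rate constant, per molar per second.
#' @param kr substrate release rate constant, per second. Must equal
#'   `kf * Kd` to 1 part in 1e6; supplied explicitly so an inconsistent
#'   trio is caught rather than silently rescaled.
#' @param kc conformational-step base rate at zero free-energy change,
#'   per second.
#' @param temperature temperature in degrees Celsius.
#' @param n_half half-width of the conformational grid; the ladder runs
#'   c = -n_half .. +n_half (default 10, i.e. 21 conformations).
#' @param widths named numeric vector of Gaussian denominators `w_M`,
#'   `w_C`, `w_S` (conformational units).
#' @param substrates data frame with columns `name`, `cyt_M`, `mat_M`
#'   (per-compartment concentrations in molar) and optionally `labelled`
#'   (logical; defaults to labelling the first substrate). All substrates
#'   share `Kd`, `kf`, `kr`.
#' @param consistent_binding_edges logical; if `TRUE`, the residual
#'   induced-fit tail \eqn{\Delta E_S e^{-(n_{half}/w_S)^2}} at the end
#'   conformations is folded symmetrically into the binding/release rates
#'   so the bound-edge potentials implied by the rates agree exactly with
#'   the additive chemical potential. Default `FALSE`: binding is the
#'   literal first-order `kf*[S]` on, `kr` off (a ~1 mV discrepancy at
#'   default parameters).
#' @return an object of class `carrier_params`.
#' @examples
#' p <- carrier_params()
#' p$kBT # thermal energy in mV
#' @export
carrier_params <- function(dE_M = -550, dE_C = -550, dE_S = -550,
                           Kd = 40e-6, kf = 2.5e10, kr = kf * Kd,
                           kc = 5.66e6, temperature = 37,
                           n_half = 10,
                           widths = c(w_M = 5, w_C = 5, w_S = 4),
                           substrates = default_substrates(),
                           consistent_binding_edges = FALSE) {
  stopifnot(is.numeric(dE_M), is.numeric(dE_C), is.numeric(dE_S))
  if (!is.numeric(n_half) || n_half < 1 || n_half != round(n_half)) {
    stop("n_half must be a positive integer (>= 1)")
  }
  widths <- widths[c("w_M", "w_C", "w_S")]
  if (anyNA(widths) || any(widths <= 0)) {
    stop("widths must supply positive w_M, w_C, w_S")
  }
  if (!is.numeric(Kd) || Kd <= 0) stop("Kd must be > 0 (molar)")
  if (any(c(kf, kr, kc) <= 0)) stop("kf, kr, kc must be > 0")
  if (abs(kr - kf * Kd) > 1e-6 * kf * Kd) {
    stop(sprintf(
      "inconsistent binding kinetics: kr = %g but kf*Kd = %g (must agree to 1e-6 relative)",
      kr, kf * Kd))
  }
  substrates <- validate_substrates(substrates)
  kBT <- thermal_energy_mv(temperature)
  structure(
    list(dE_M = dE_M, dE_C = dE_C, dE_S = dE_S,
         Kd = Kd, kf = kf, kr = kr, kc = kc,
         temperature = temperature, kBT = kBT,
         n_half = as.integer(n_half), widths = widths,
         substrates = substrates,
         consistent_binding_edges = isTRUE(consistent_binding_edges)),
    class = "carrier_params")
}

#' Default exchange substrate table
#'
#' Labelled ADP on the cytoplasmic side (5 mM) exchanging against
#' unlabelled ADP in the matrix (5 mM): the radio-labelled exchange assay
#' the model is calibrated to. Both species are chemically identical.
#'
#' @param cyt_M cytoplasmic concentration of the labelled species, molar.
#' @param mat_M matrix concentration of the unlabelled species, molar.
#' @return data frame with columns `name`, `cyt_M`, `mat_M`, `labelled`.
#' @export
default_substrates <- function(cyt_M = 5e-3, mat_M = 5e-3) {
  data.frame(name = c("labelled", "unlabelled"),
             cyt_M = c(cyt_M, 0),
             mat_M = c(0, mat_M),
             labelled = c(TRUE, FALSE),
             stringsAsFactors = FALSE)
}

validate_substrates <- function(substrates) {
  if (!is.data.frame(substrates) ||
      !all(c("name", "cyt_M", "mat_M") %in% names(substrates))) {
    stop("substrates must be a data frame with columns name, cyt_M, mat_M")
  }
  if (nrow(substrates) < 1L) stop("at least one substrate is required")
  if (anyDuplicated(substrates$name)) {
    stop("duplicate substrate names: ",
         paste(unique(substrates$name[duplicated(substrates$name)]),
               collapse = ", "))
  }
  if (any(substrates$cyt_M < 0) || any(substrates$mat_M < 0)) {
    stop("substrate concentrations must be >= 0")
  }
  if (is.null(substrates$labelled)) {
    substrates$labelled <- seq_len(nrow(substrates)) == 1L
  }
  substrates$name <- as.character(substrates$name)
  rownames(substrates) <- NULL
  substrates
}

#' @export
print.carrier_params <- function(x, ...) {
  cat("Carrier model parameters\n")
  cat(sprintf("  dE_M = %g mV, dE_C = %g mV, dE_S = %g mV\n",
              x$dE_M, x$dE_C, x$dE_S))
  cat(sprintf("  Kd = %g M, kf = %g /M/s, kr = %g /s, kc = %g /s\n",
              x$Kd, x$kf, x$kr, x$kc))
  cat(sprintf("  T = %g C (kBT = %.3f mV), grid c = -%d..+%d\n",
              x$temperature, x$kBT, x$n_half, x$n_half))
  cat("  substrates:\n")
  print(x$substrates, row.names = FALSE)
  invisible(x)
}

# Replace fields of a parameter set, revalidating. Internal workhorse for
# sweeps (cheaper to express than repeating the full constructor call).
modify_params <- function(params, ...) {
  upd <- list(...)
  args <- list(dE_M = params$dE_M, dE_C = params$dE_C, dE_S = params$dE_S,
               Kd = params$Kd, kf = params$kf, kr = params$kr,
               kc = params$kc, temperature = params$temperature,
               n_half = params$n_half, widths = params$widths,
               substrates = params$substrates,
               consistent_binding_edges = params$consistent_binding_edges)
  for (nm in names(upd)) {
    if (!nm %in% names(args)) stop("unknown parameter: ", nm)
    args[[nm]] <- upd[[nm]]
  }
  # keep kr consistent when only Kd or kf move
  if (any(c("Kd", "kf") %in% names(upd)) && !"kr" %in% names(upd)) {
    args$kr <- args$kf * args$Kd
  }
  do.call(carrier_params, args)
}

# Set per-compartment concentrations of a named substrate.
set_concentration <- function(params, name, cyt_M = NULL, mat_M = NULL) {
  s <- params$substrates
  i <- match(name, s$name)
  if (is.na(i)) stop("unknown substrate: ", name)
  if (!is.null(cyt_M)) s$cyt_M[i] <- cyt_M
  if (!is.null(mat_M)) s$mat_M[i] <- mat_M
  modify_params(params, substrates = s)
}
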