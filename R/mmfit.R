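#' Fit a Michaelis-Menten curve
#'
#' Unweighted least-squares fit of \eqn{v = k_{cat}[S]/(K_M + [S])} by
#' Levenberg-Marquardt (via [minpack.lm::nlsLM()]), with initial guesses
#' \eqn{k_{cat} =} max rate and \eqn{K_M =} the concentration nearest
#' half-maximal rate. Degenerate inputs (all-zero or non-finite rates)
#' or non-convergence yield a flagged, non-converged fit rather than an
#' error.
#'
#' @param concentrations substrate concentrations in molar (>= 3 points).
#' @param rates transport rates in 1/s, same length.
#' @return object of class `mm_fit`: `kcat` (1/s), `KM` (M),
#'   `residuals`, `rms`, `converged`, and the underlying `nls` object
#'   (or `NULL`).
#' @examples
#' S <- c(1, 2, 5, 10, 20, 50, 100) * 1e-6
#' fit_michaelis_menten(S, 40 * S / (10e-6 + S))
#' @export
fit_michaelis_menten <- function(concentrations, rates) {
  stopifnot(length(concentrations) == length(rates))
  if (length(concentrations) < 3L) stop("need at least 3 points")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  bad <- !all(is.finite(rates)) || max(rates) <= 0
  if (bad) {
    return(structure(list(kcat = NA_real_, KM = NA_real_,
                          residuals = rep(NA_real_, length(rates)),
                          rms = NA_real_, converged = FALSE, fit = NULL),
                     class = "mm_fit"))
  }
  df <- data.frame(S = concentrations, v = rates)
  k0 <- max(rates)
  K0 <- df$S[which.min(abs(df$v - k0 / 2))]
  if (K0 <= 0) K0 <- max(df$S) / 10
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * S / (KM + S), data = df,
                      start = list(kcat = k0, KM = K0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kcat = NA_real_, KM = NA_real_,
                          residuals = rep(NA_real_, length(rates)),
                          rms = NA_real_, converged = FALSE, fit = NULL),
                     class = "mm_fit"))
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(list(kcat = unname(cf["kcat"]), KM = unname(cf["KM"]),
                 residuals = as.numeric(res),
                 rms = sqrt(mean(res^2)),
                 converged = fit$convInfo$isConv && cf["kcat"] > 0 && cf["KM"] > 0,
                 fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Michaelis-Menten fit: NOT converged\n")
  } else {
    cat(sprintf("Michaelis-Menten fit: kcat = %.4g /s, KM = %.4g uM (rms %.3g)\n",
                x$kcat, x$KM * 1e6, x$rms))
  }
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(kcat = object$kcat, KM = object$KM)
}

#' Simulated uptake curve
#'
#' Transport rate as the concentration of the substrate presented on one
#' side of the membrane is varied (one steady-state solve per
#' concentration), the in-silico analogue of an initial-rate uptake
#' experiment: varying the cytoplasmic substrate against 5 mM matrix
#' counter-substrate measures its influx; varying the matrix substrate
#' measures its efflux into the cytoplasm. Rates are reported positive
#' in the transport direction of the varied substrate.
#'
#' @param params a [carrier_params()] object.
#' @param side `"cytoplasmic"` or `"matrix"` — the compartment whose
#'   substrate concentration is varied.
#' @param conc_M concentration grid in molar (may include 0: rate 0).
#' @param substrate name of the varied substrate; defaults to the first
#'   substrate resident on `side` (nonzero concentration there, or the
#'   labelled species as fallback).
#' @return data frame `conc_M`, `rate_per_s`.
#' @export
mm_curve <- function(params, side = c("cytoplasmic", "matrix"),
                     conc_M = seq(0, 100e-6, by = 0.1e-6),
                     substrate = NULL) {
  side <- match.arg(side)
  s <- params$substrates
  if (is.null(substrate)) {
    home <- if (side == "cytoplasmic") s$cyt_M > 0 else s$mat_M > 0
    i <- if (any(home)) which(home)[1L] else which(s$labelled)[1L]
    substrate <- s$name[i]
  }
  idx <- substrate_index(params, substrate)
  rate <- vapply(conc_M, function(x) {
    if (x == 0) return(0)
    p <- if (side == "cytoplasmic") set_concentration(params, substrate, cyt_M = x)
         else set_concentration(params, substrate, mat_M = x)
    ss <- solve_steady_state(build_network(p))
    J <- mean(ss$J[, idx])
    if (side == "matrix") -J else J
  }, numeric(1))
  data.frame(conc_M = conc_M, rate_per_s = rate)
}
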