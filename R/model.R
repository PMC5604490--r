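#' Fit the carrier kinetic model
#'
#' Central constructor: builds the full free-energy-profile Markov model
#' of the carrier (parameters -> reaction network -> steady state) and
#' returns a classed object with the usual modelling methods. The model
#' treats the carrier as a nanomachine performing a thermal random walk
#' over 21 discrete conformations between the cytoplasmic (c = -10) and
#' matrix (c = +10) states, with a single substrate-binding site whose
#' occupancy modulates the energy landscape.
#'
#' @param dE_M,dE_C,dE_S Gaussian energy scales in mV (see
#'   [carrier_params()]).
#' @param substrates substrate table (see [carrier_params()]).
#' @param ... further arguments passed to [carrier_params()].
#' @return an object of class `carrier_model` containing `params`,
#'   `network`, and `steady` (a `carrier_steady`).
#' @examples
#' m <- carrier_model()   # published wild-type calibration
#' coef(m)
#' transport_rate(m$steady) # ~ 40 ADP/s
#' @seealso [solve_steady_state()], [simulate.carrier_model()],
#'   [predict.carrier_model()]
#' @export
carrier_model <- function(dE_M = -550, dE_C = -550, dE_S = -550,
                          substrates = default_substrates(), ...) {
  params <- carrier_params(dE_M = dE_M, dE_C = dE_C, dE_S = dE_S,
                           substrates = substrates, ...)
  network <- build_network(params)
  steady <- solve_steady_state(network)
  structure(list(params = params, network = network, steady = steady),
            class = "carrier_model")
}

#' @export
print.carrier_model <- function(x, ...) {
  p <- x$params
  cat("Free-energy-profile carrier model\n")
  cat(sprintf("  dE_M = %g, dE_C = %g, dE_S = %g mV; kc = %g /s; T = %g C\n",
              p$dE_M, p$dE_C, p$dE_S, p$kc, p$temperature))
  cat(sprintf("  %d states, %d reaction pairs\n",
              nrow(x$network$states), nrow(x$network$reactions)))
  cat(sprintf("  steady-state transport (labelled): %.6g /s\n",
              x$steady$transport_rate))
  invisible(x)
}

#' @export
coef.carrier_model <- function(object, ...) {
  p <- object$params
  c(dE_M = p$dE_M, dE_C = p$dE_C, dE_S = p$dE_S,
    Kd = p$Kd, kf = p$kf, kr = p$kr, kc = p$kc,
    temperature = p$temperature)
}

#' @export
summary.carrier_model <- function(object, ...) {
  prof <- energy_profile(object$params)
  be <- energy_barrier(prof$mu0_bound_mV, conformations = prof$c)
  structure(list(model = object,
                 profile = prof,
                 barrier_bound = be,
                 barrier_empty = energy_barrier(prof$mu0_empty_mV,
                                                conformations = prof$c),
                 tables = steady_state_tables(object$steady)),
            class = "summary.carrier_model")
}

#' @export
print.summary.carrier_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  energy barrier (empty): %.1f mV; (bound, net): %.1f mV\n",
              x$barrier_empty$barrier, x$barrier_bound$barrier))
  cat(sprintf("  balance residual: %.3g\n", x$model$steady$residual))
  occ <- tapply(x$tables$states$P, x$tables$states$s, sum)
  cat("  occupancy by binding-site state (0 = empty):\n")
  print(round(occ, 4))
  invisible(x)
}

#' Residual of the steady-state balance equations
#'
#' Returns `Q %*% P` per state — zero up to solver round-off; a direct
#' check that the reported distribution balances every state.
#'
#' @param object a [carrier_model()] object.
#' @param ... unused.
#' @return named numeric vector, one entry per (unpruned) state.
#' @export
residuals.carrier_model <- function(object, ...) {
  Q <- generator_matrix(object$network)
  keep <- !(object$network$states$label %in% object$steady$pruned)
  r <- as.vector(Q[keep, keep] %*% object$steady$P[keep])
  names(r) <- object$network$states$label[keep]
  r
}

#' Predict transport at new substrate concentrations
#'
#' Re-solves the steady state with the substrate resident on the chosen
#' side set to each concentration in `newdata` (other concentrations
#' unchanged) and returns its transport rate, positive in its direction
#' of transport. A thin wrapper over [mm_curve()]; this is the primitive
#' behind the simulated uptake curves that are fitted to a
#' Michaelis-Menten function.
#'
#' @param object a [carrier_model()] object.
#' @param newdata numeric vector of concentrations in molar, or a data
#'   frame with a `conc_M` column.
#' @param side which compartment's substrate is varied: `"cytoplasmic"`
#'   (influx reported) or `"matrix"` (efflux reported).
#' @param ... passed to [mm_curve()] (e.g. `substrate`).
#' @return numeric vector of transport rates (1/s), one per concentration.
#' @export
predict.carrier_model <- function(object, newdata = NULL,
                                  side = c("cytoplasmic", "matrix"), ...) {
  side <- match.arg(side)
  if (is.null(newdata)) return(object$steady$transport_rate)
  conc <- if (is.data.frame(newdata)) newdata$conc_M else newdata
  stopifnot(is.numeric(conc), all(conc >= 0))
  mm_curve(object$params, side, conc, ...)$rate_per_s
}

#' Plot the free-energy profile of a carrier model
#'
#' Net standard chemical potential along the conformational coordinate
#' for the empty and substrate-bound carrier (concentration term
#' excluded).
#'
#' @param x a [carrier_model()] object.
#' @param ... further arguments to [graphics::matplot()].
#' @return the profile data frame, invisibly.
#' @export
plot.carrier_model <- function(x, ...) {
  prof <- energy_profile(x$params)
  graphics::matplot(prof$c, cbind(prof$mu0_empty_mV, prof$mu0_bound_mV),
                    type = "b", pch = c(1, 16), lty = c(2, 1), col = c(1, 2),
                    xlab = "conformation c (cytoplasmic -10 ... +10 matrix)",
                    ylab = expression(mu^0 ~ "(mV)"), ...)
  graphics::legend("topright", c("empty", "bound (net)"),
                   pch = c(1, 16), lty = c(2, 1), col = c(1, 2), bty = "n")
  invisible(prof)
}
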