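#' Enumerate the carrier reaction network
#'
#' Builds the full state space \eqn{\langle c, s\rangle} (conformation
#' crossed with binding-site occupancy) and every reaction pair: 2*n_half
#' conformational steps per occupancy ladder, plus one binding reaction
#' per substrate at each end conformation. For N substrates on the
#' default grid this gives 21(N+1) states and 20(N+1) + 2N reaction
#' pairs. All rates are drawn from [conformational_rates()] and
#' [binding_rates()].
#'
#' @param params a [carrier_params()] object.
#' @return an object of class `carrier_network`: list with `states`
#'   (data frame `c`, `s`, `label`; `s = 0` is the empty carrier),
#'   `reactions` (data frame `from`, `to`, `fwd`, `rev`, `type`), and
#'   `params`.
#' @examples
#' net <- build_network(carrier_params())
#' nrow(net$states)    # 63 for two substrates
#' nrow(net$reactions) # 64 reaction pairs
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "carrier_params"))
  n <- params$n_half
  nc <- 2L * n + 1L
  N <- nrow(params$substrates)
  cs <- seq(-n, n)

  occ <- c("empty", params$substrates$name)
  states <- data.frame(
    c = rep(cs, N + 1L),
    s = rep(0:N, each = nc),
    label = paste0("c", rep(cs, N + 1L), ":", rep(occ, each = nc)),
    stringsAsFactors = FALSE)
  sidx <- function(c, s) s * nc + (c + n) + 1L

  # conformational steps, one ladder per occupancy
  rx <- vector("list", N + 2L)
  for (s in 0:N) {
    sub <- if (s == 0L) NULL else s
    mu <- chemical_potential(cs, sub, params)
    dG <- diff(mu)
    x <- 0.5 * dG / params$kBT
    rx[[s + 1L]] <- data.frame(
      from = sidx(cs[-nc], s), to = sidx(cs[-1L], s),
      fwd = params$kc * exp(-x), rev = params$kc * exp(x),
      type = "conformational", substrate = s,
      stringsAsFactors = FALSE)
  }
  # binding at the two end conformations
  bind <- lapply(seq_len(N), function(s) {
    bc <- binding_rates("cytoplasmic", s, params)
    bm <- binding_rates("matrix", s, params)
    data.frame(
      from = c(sidx(-n, 0L), sidx(n, 0L)),
      to = c(sidx(-n, s), sidx(n, s)),
      fwd = c(bc[["on"]], bm[["on"]]),
      rev = c(bc[["off"]], bm[["off"]]),
      type = c("bind_cyt", "bind_mat"), substrate = s,
      stringsAsFactors = FALSE)
  })
  rx[[N + 2L]] <- do.call(rbind, bind)
  reactions <- do.call(rbind, rx)
  rownames(reactions) <- NULL

  structure(list(states = states, reactions = reactions, params = params),
            class = "carrier_network")
}

#' @export
print.carrier_network <- function(x, ...) {
  cat(sprintf("Carrier reaction network: %d states, %d reaction pairs (%d substrates)\n",
              nrow(x$states), nrow(x$reactions), nrow(x$params$substrates)))
  invisible(x)
}

#' Master-equation generator matrix
#'
#' Assembles the infinitesimal generator Q of the chemical master
#' equation in the column convention: `Q[j, i]` is the rate from state i
#' to state j, diagonal entries make every column sum to zero, so
#' `dP/dt = Q %*% P`.
#'
#' @param network a [build_network()] object.
#' @return square numeric matrix with state labels as dimnames.
#' @export
generator_matrix <- function(network) {
  ns <- nrow(network$states)
  Q <- matrix(0, ns, ns,
              dimnames = list(network$states$label, network$states$label))
  r <- network$reactions
  Q[cbind(r$to, r$from)] <- Q[cbind(r$to, r$from)] + r$fwd
  Q[cbind(r$from, r$to)] <- Q[cbind(r$from, r$to)] + r$rev
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Steady state of the master equation
#'
#' Solves `Q P = 0` with the normalisation `sum(P) = 1` by replacing one
#' balance row with the normalisation row and solving the dense linear
#' system (partial pivoting); the residual of the replaced row is checked
#' afterwards. Bound ladders of substrates absent from both compartments
#' are unreachable and are pruned (with a warning) before solving; their
#' probabilities are reported as exact zeros.
#'
#' @param network a [build_network()] object.
#' @return an object of class `carrier_steady`: list with `P` (named
#'   probability vector over all states), `J` (net-flux matrix, one row
#'   per conformational boundary c -> c+1, one column per substrate;
#'   positive = cytoplasmic-to-matrix), `transport_rate` (net flux of the
#'   labelled species, 1/s), `flux_spread` (max relative spread of J
#'   across boundaries per substrate), `residual` (max |Q P|), `pruned`
#'   (labels of pruned states), and the `network`.
#' @export
solve_steady_state <- function(network) {
  params <- network$params
  st <- network$states
  ns <- nrow(st)

  absent <- which(params$substrates$cyt_M == 0 & params$substrates$mat_M == 0)
  keep <- rep(TRUE, ns)
  if (length(absent)) {
    warning("substrate(s) absent from both compartments: ",
            paste(params$substrates$name[absent], collapse = ", "),
            "; pruning unreachable bound states")
    keep <- !(st$s %in% absent)
  }

  Q <- generator_matrix(network)
  Qk <- Q[keep, keep, drop = FALSE]
  nk <- nrow(Qk)
  A <- Qk
  A[1L, ] <- 1
  b <- c(1, rep(0, nk - 1L))
  Pk <- solve(A, b)
  residual <- max(abs(Qk %*% Pk))

  P <- numeric(ns)
  P[keep] <- Pk
  names(P) <- st$label
  if (min(P) < -1e-12 * max(P)) {
    warning("steady-state solution has negative probabilities beyond tolerance")
  }

  n <- params$n_half
  nc <- 2L * n + 1L
  N <- nrow(params$substrates)
  cs <- seq(-n, n)
  J <- matrix(NA_real_, 2L * n, N,
              dimnames = list(paste0(cs[-nc], "->", cs[-1L]),
                              params$substrates$name))
  r <- network$reactions
  for (s in seq_len(N)) {
    rs <- r[r$type == "conformational" & r$substrate == s, ]
    J[, s] <- P[rs$from] * rs$fwd - P[rs$to] * rs$rev
  }
  spread <- apply(J, 2L, function(j) {
    m <- mean(j)
    if (abs(m) < 1e-300) 0 else max(abs(j - m)) / abs(m)
  })

  lab <- which(params$substrates$labelled)
  transport <- if (length(lab)) mean(J[, lab[1L]]) else NA_real_

  structure(list(P = P, J = J, transport_rate = transport,
                 flux_spread = spread, residual = residual,
                 pruned = st$label[!keep], network = network),
            class = "carrier_steady")
}

#' @export
print.carrier_steady <- function(x, ...) {
  cat("Carrier steady state\n")
  cat(sprintf("  transport rate (labelled, cyt->mat): %.6g /s\n",
              x$transport_rate))
  cat(sprintf("  balance residual: %.3g; max flux spread: %.3g\n",
              x$residual, max(x$flux_spread)))
  if (length(x$pruned)) {
    cat(sprintf("  pruned %d unreachable states\n", length(x$pruned)))
  }
  invisible(x)
}

#' Net flux across a conformational boundary
#'
#' \eqn{J = P_{c,s} k^{c\to c+1} - P_{c+1,s} k^{c+1\to c}} for the given
#' substrate; positive in the cytoplasmic-to-matrix direction. At steady
#' state the value is independent of the boundary.
#'
#' @param result a [solve_steady_state()] object.
#' @param boundary lower conformation c of the step c -> c+1.
#' @param substrate substrate name or index.
#' @return net flux in 1/s.
#' @export
net_flux <- function(result, boundary, substrate) {
  params <- result$network$params
  n <- params$n_half
  if (boundary < -n || boundary >= n) stop("invalid boundary: ", boundary)
  idx <- substrate_index(params, substrate)
  result$J[boundary + n + 1L, idx]
}

#' Transport rate of the labelled species
#'
#' Net cytoplasmic-to-matrix flux of the species designated `labelled`
#' in the substrate table, the model's metric of transport (per carrier,
#' 1/s). In the symmetric exchange scenario it equals the efflux of the
#' unlabelled species.
#'
#' @param result a [solve_steady_state()] object.
#' @return transport rate in 1/s.
#' @export
transport_rate <- function(result) {
  params <- result$network$params
  if (!any(params$substrates$labelled)) stop("no substrate designated labelled")
  result$transport_rate
}

#' Tidy tables of a steady-state solution
#'
#' @param result a [solve_steady_state()] object.
#' @return list of two data frames: `states` (one row per state with its
#'   probability) and `fluxes` (one row per boundary x substrate).
#' @export
steady_state_tables <- function(result) {
  st <- result$network$states
  states <- data.frame(st, P = unname(result$P), stringsAsFactors = FALSE)
  J <- result$J
  fluxes <- data.frame(
    boundary = rep(rownames(J), ncol(J)),
    substrate = rep(colnames(J), each = nrow(J)),
    flux_per_s = as.vector(J),
    stringsAsFactors = FALSE)
  list(states = states, fluxes = fluxes)
}
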