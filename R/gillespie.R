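#' Gillespie stochastic simulation of the carrier network
#'
#' Exact stochastic simulation algorithm (SSA) on the carrier's Markov
#' jump process: exponential waiting times with the total outgoing rate
#' of the current state, next state chosen proportionally to the
#' individual rates. Because substrate concentrations are clamped, all
#' propensities are state-local constants and are precomputed once.
#'
#' @param network a [build_network()] object.
#' @param n_events number of jump events to simulate (after any burn-in;
#'   see Details). Mutually exclusive with `t_max`.
#' @param t_max simulated time horizon in seconds; events are generated
#'   until the horizon is passed.
#' @param seed integer seed recorded in the log; `NULL` leaves the RNG
#'   state untouched.
#' @param init initial state as `c(conformation, occupancy)`; default is
#'   the empty carrier in the cytoplasmic conformation.
#' @param burn_in fraction (0..0.9) of the trajectory discarded from the
#'   front before computing occupancy fractions and event counters; the
#'   raw event log keeps everything.
#' @return an object of class `carrier_eventlog`: `events` (data frame
#'   `time`, `from`, `to` as state indices), `states` (state table),
#'   `seed`, `t_total`, `t_count` (post-burn-in window length),
#'   `burn_from` (first counted event row), `absorbed` flag, and
#'   `counts` — the 4-way classification from [classify_events()].
#' @examples
#' net <- build_network(carrier_params())
#' log <- simulate_gillespie(net, n_events = 2e4, seed = 1)
#' log$counts
#' @export
simulate_gillespie <- function(network, n_events = 1e5, t_max = NULL,
                               seed = NULL, init = NULL, burn_in = 0.1) {
  stopifnot(inherits(network, "carrier_network"))
  if (!is.null(seed)) set.seed(seed)
  if (burn_in < 0 || burn_in > 0.9) stop("burn_in must be in [0, 0.9]")
  params <- network$params
  n <- params$n_half
  nc <- 2L * n + 1L
  ns <- nrow(network$states)

  # directed edge lists grouped by source state
  r <- network$reactions
  efrom <- c(r$from, r$to)
  eto <- c(r$to, r$from)
  erate <- c(r$fwd, r$rev)
  ord <- order(efrom)
  efrom <- efrom[ord]; eto <- eto[ord]; erate <- erate[ord]
  nout <- tabulate(efrom, nbins = ns)
  ptr <- c(0L, cumsum(nout)) # edges for state i: (ptr[i]+1)..ptr[i+1]
  total <- vapply(seq_len(ns), function(i) {
    if (nout[i] == 0L) 0 else sum(erate[(ptr[i] + 1L):ptr[i + 1L]])
  }, numeric(1))
  cum <- erate
  for (i in seq_len(ns)) {
    if (nout[i] > 1L) {
      idx <- (ptr[i] + 1L):ptr[i + 1L]
      cum[idx] <- cumsum(erate[idx])
    }
  }

  if (is.null(init)) init <- c(-n, 0L)
  state <- as.integer(init[2L]) * nc + (as.integer(init[1L]) + n) + 1L
  if (state < 1L || state > ns) stop("invalid initial state")

  by_time <- !is.null(t_max)
  chunk <- if (by_time) 65536L else as.integer(n_events)
  times_l <- list(); path_l <- list()
  t <- 0; k_total <- 0L; absorbed <- FALSE
  repeat {
    u1 <- stats::runif(chunk); u2 <- stats::runif(chunk)
    tms <- numeric(chunk); pth <- integer(chunk)
    k <- 0L
    while (k < chunk) {
      tot <- total[state]
      if (tot <= 0) { absorbed <- TRUE; break }
      k <- k + 1L
      t <- t + (-log(u1[k]) / tot)
      j <- ptr[state] + 1L
      x <- u2[k] * tot
      while (cum[j] < x) j <- j + 1L
      state <- eto[j]
      tms[k] <- t; pth[k] <- state
      if (by_time && t >= t_max) break
    }
    if (k > 0L) {
      times_l[[length(times_l) + 1L]] <- tms[seq_len(k)]
      path_l[[length(path_l) + 1L]] <- pth[seq_len(k)]
      k_total <- k_total + k
    }
    if (absorbed || (by_time && t >= t_max) ||
        (!by_time && k_total >= n_events)) break
  }
  if (k_total == 0L) stop("no events generated (absorbing initial state)")
  times <- unlist(times_l, use.names = FALSE)
  path <- unlist(path_l, use.names = FALSE)
  init_idx <- as.integer(init[2L]) * nc + (as.integer(init[1L]) + n) + 1L
  from <- c(init_idx, path[-length(path)])

  events <- data.frame(time = times, from = from, to = path)
  burn_from <- max(1L, floor(burn_in * nrow(events)) + 1L)
  t0 <- if (burn_from > 1L) events$time[burn_from - 1L] else 0
  log <- structure(list(events = events, states = network$states,
                        params = params, seed = seed,
                        t_total = times[length(times)],
                        t_count = times[length(times)] - t0,
                        burn_from = burn_from, absorbed = absorbed),
                   class = "carrier_eventlog")
  log$counts <- classify_events(log)
  log
}

#' @export
print.carrier_eventlog <- function(x, ...) {
  cat(sprintf("Gillespie event log: %d events over %.3g s (seed %s)\n",
              nrow(x$events), x$t_total,
              if (is.null(x$seed)) "none" else x$seed))
  if (x$absorbed) cat("  trajectory absorbed before the horizon\n")
  print(x$counts)
  invisible(x)
}

#' Classify completed transport episodes
#'
#' Scans the event log for binding-site transitions and assigns every
#' completed bind-release episode to one of four fates by (binding side,
#' release side): transported cytoplasm-to-matrix, returned to the
#' cytoplasm, returned to the matrix, transported matrix-to-cytoplasm.
#' The episode in progress at the end of the counting window (and any
#' bind pending at its start) is excluded and reported as truncated.
#' Only events after the burn-in window are counted.
#'
#' @param log a [simulate_gillespie()] event log.
#' @return data frame, one row per substrate, with columns
#'   `substrate`, `transport_cyt_to_mat`, `returned_to_cyt`,
#'   `returned_to_mat`, `transport_mat_to_cyt`, `truncated`.
#' @export
classify_events <- function(log) {
  st <- log$states
  params <- log$params
  n <- params$n_half
  N <- nrow(params$substrates)
  ev <- log$events[log$burn_from:nrow(log$events), , drop = FALSE]

  s_from <- st$s[ev$from]; s_to <- st$s[ev$to]
  c_to <- st$c[ev$to]
  counts <- matrix(0L, N, 4L)
  truncated <- integer(N)
  chg <- which(s_from != s_to)
  # side index: 1 = cytoplasmic (c = -n), 2 = matrix (c = +n)
  bind_side <- NA_integer_
  cur <- NA_integer_
  for (i in chg) {
    if (s_from[i] == 0L) {            # binding event
      cur <- s_to[i]
      bind_side <- if (c_to[i] == -n) 1L else 2L
    } else {                          # release event
      rel_side <- if (c_to[i] == -n) 1L else 2L
      if (is.na(bind_side)) {         # bound before counting window
        truncated[s_from[i]] <- truncated[s_from[i]] + 1L
      } else {
        cls <- if (bind_side == 1L && rel_side == 2L) 1L
               else if (bind_side == 1L) 2L
               else if (rel_side == 1L) 4L else 3L
        counts[cur, cls] <- counts[cur, cls] + 1L
      }
      bind_side <- NA_integer_; cur <- NA_integer_
    }
  }
  if (!is.na(bind_side)) truncated[cur] <- truncated[cur] + 1L
  data.frame(substrate = params$substrates$name,
             transport_cyt_to_mat = counts[, 1L],
             returned_to_cyt = counts[, 2L],
             returned_to_mat = counts[, 3L],
             transport_mat_to_cyt = counts[, 4L],
             truncated = truncated,
             stringsAsFactors = FALSE)
}

#' Transport-rate estimate from a stochastic trajectory
#'
#' Net labelled transport estimated from completed episodes:
#' (cyt-to-mat transports minus mat-to-cyt transports) divided by the
#' counting-window time, with a Poisson episode-count standard error
#' `sqrt(n1 + n4)/t`.
#'
#' @param log a [simulate_gillespie()] event log.
#' @param substrate substrate name or index; default the labelled species.
#' @return named numeric vector `c(rate =, se =, episodes =)` (1/s).
#' @export
flux_from_events <- function(log, substrate = NULL) {
  params <- log$params
  if (is.null(substrate)) {
    substrate <- params$substrates$name[which(params$substrates$labelled)[1L]]
  }
  idx <- substrate_index(params, substrate)
  cnt <- log$counts[idx, ]
  n1 <- cnt$transport_cyt_to_mat
  n4 <- cnt$transport_mat_to_cyt
  t <- log$t_count
  if (t <= 0) stop("empty counting window")
  episodes <- n1 + n4
  se <- if (episodes == 0) NA_real_ else sqrt(episodes) / t
  c(rate = (n1 - n4) / t, se = se, episodes = episodes)
}

#' Time-weighted state occupancy of a trajectory
#'
#' Empirical occupancy fraction per state over the post-burn-in window,
#' with batch-means standard errors (the trajectory is autocorrelated,
#' so naive binomial errors would be optimistic).
#'
#' @param log a [simulate_gillespie()] event log.
#' @param batches number of equal-event batches for the SE estimate.
#' @return data frame `label`, `fraction`, `se` (one row per state).
#' @export
occupancy_fractions <- function(log, batches = 100) {
  ev <- log$events[log$burn_from:nrow(log$events), , drop = FALSE]
  ns <- nrow(log$states)
  dt <- diff(c(ev$time[1L], ev$time))
  # state occupied during interval i is ev$from[i]
  occ <- vapply(seq_len(ns), function(i) sum(dt[ev$from == i]), numeric(1))
  frac <- occ / sum(dt)
  nb <- max(2L, min(batches, floor(nrow(ev) / 10)))
  grp <- cut(seq_along(dt), nb, labels = FALSE)
  bf <- matrix(0, nb, ns)
  for (b in seq_len(nb)) {
    sel <- grp == b
    bf[b, ] <- vapply(seq_len(ns), function(i)
      sum(dt[sel][ev$from[sel] == i]), numeric(1)) / sum(dt[sel])
  }
  se <- apply(bf, 2L, stats::sd) / sqrt(nb)
  data.frame(label = log$states$label, fraction = frac, se = se,
             stringsAsFactors = FALSE)
}

#' Simulate method for carrier models
#'
#' Runs [simulate_gillespie()] on the model's network.
#'
#' @param object a [carrier_model()] object.
#' @param nsim number of independent trajectories.
#' @param seed integer seed; trajectory i uses `seed + i - 1`.
#' @param ... passed to [simulate_gillespie()] (`n_events`, `t_max`,
#'   `burn_in`, `init`).
#' @return a `carrier_eventlog`, or a list of them when `nsim > 1`.
#' @export
simulate.carrier_model <- function(object, nsim = 1, seed = NULL, ...) {
  logs <- lapply(seq_len(nsim), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    simulate_gillespie(object$network, seed = s, ...)
  })
  if (nsim == 1L) logs[[1L]] else logs
}
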