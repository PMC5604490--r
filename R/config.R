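# Flat YAML configuration for parameter sets. Recognised keys:
#   dE_M_mV, dE_C_mV, dE_S_mV, Kd_M, kf_perM_perS, kr_perS, kc_perS,
#   temperature_C, n_half, consistent_binding_edges,
#   substrates: list of {name, cyt_M, mat_M, [labelled]}
.config_keys <- c("dE_M_mV", "dE_C_mV", "dE_S_mV", "Kd_M", "kf_perM_perS",
                  "kr_perS", "kc_perS", "temperature_C", "n_half",
                  "consistent_binding_edges", "substrates")

#' Read a parameter configuration file
#'
#' Loads a flat YAML (or JSON, a YAML subset) file into a
#' [carrier_params()] object. Missing keys take the published defaults;
#' an empty file yields the full default calibration. Unknown keys and
#' invalid values are rejected, with all schema violations reported at
#' once.
#'
#' @param path path to the configuration file.
#' @return a [carrier_params()] object.
#' @export
read_carrier_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a key-value mapping")
  problems <- character()
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  num_keys <- setdiff(.config_keys, c("substrates", "consistent_binding_edges"))
  for (k in intersect(names(cfg), num_keys)) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || !is.finite(cfg[[k]])) {
      problems <- c(problems, paste0(k, ": must be a single finite number"))
    }
  }
  for (k in intersect(names(cfg), c("Kd_M", "kf_perM_perS", "kr_perS", "kc_perS"))) {
    if (is.numeric(cfg[[k]]) && length(cfg[[k]]) == 1L && cfg[[k]] <= 0) {
      problems <- c(problems, paste0(k, ": must be > 0"))
    }
  }
  substrates <- NULL
  if (!is.null(cfg$substrates)) {
    s <- cfg$substrates
    ok <- is.list(s) && length(s) > 0 &&
      all(vapply(s, function(x) all(c("name", "cyt_M", "mat_M") %in% names(x)),
                 logical(1)))
    if (!ok) {
      problems <- c(problems,
                    "substrates: must be a list of {name, cyt_M, mat_M}")
    } else {
      substrates <- do.call(rbind, lapply(s, function(x) {
        data.frame(name = as.character(x$name),
                   cyt_M = as.numeric(x$cyt_M),
                   mat_M = as.numeric(x$mat_M),
                   labelled = if (is.null(x$labelled)) NA else
                     isTRUE(x$labelled),
                   stringsAsFactors = FALSE)
      }))
      if (all(is.na(substrates$labelled))) {
        substrates$labelled <- seq_len(nrow(substrates)) == 1L
      } else {
        substrates$labelled[is.na(substrates$labelled)] <- FALSE
      }
      if (any(substrates$cyt_M < 0, na.rm = TRUE) ||
          any(substrates$mat_M < 0, na.rm = TRUE)) {
        problems <- c(problems, "substrates: concentrations must be >= 0")
      }
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  args <- list()
  map <- c(dE_M_mV = "dE_M", dE_C_mV = "dE_C", dE_S_mV = "dE_S",
           Kd_M = "Kd", kf_perM_perS = "kf", kr_perS = "kr",
           kc_perS = "kc", temperature_C = "temperature", n_half = "n_half",
           consistent_binding_edges = "consistent_binding_edges")
  for (k in intersect(names(cfg), names(map))) args[[map[[k]]]] <- cfg[[k]]
  if (!is.null(substrates)) args$substrates <- substrates
  # kr defaults to kf*Kd when the file moves Kd/kf without giving kr
  if (!"kr" %in% names(args) && any(c("Kd", "kf") %in% names(args))) {
    Kd <- if (is.null(args$Kd)) 40e-6 else args$Kd
    kf <- if (is.null(args$kf)) 2.5e10 else args$kf
    args$kr <- kf * Kd
  }
  do.call(carrier_params, args)
}

#' Write a parameter configuration file
#'
#' Serialises a [carrier_params()] object to the flat YAML schema read
#' by [read_carrier_config()]; `read_carrier_config(write_carrier_config(p))`
#' round-trips.
#'
#' @param params a [carrier_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_carrier_config <- function(params, path) {
  stopifnot(inherits(params, "carrier_params"))
  cfg <- list(
    dE_M_mV = params$dE_M, dE_C_mV = params$dE_C, dE_S_mV = params$dE_S,
    Kd_M = params$Kd, kf_perM_perS = params$kf, kr_perS = params$kr,
    kc_perS = params$kc, temperature_C = params$temperature,
    n_half = params$n_half,
    consistent_binding_edges = params$consistent_binding_edges,
    substrates = lapply(seq_len(nrow(params$substrates)), function(i) {
      s <- params$substrates[i, ]
      list(name = s$name, cyt_M = s$cyt_M, mat_M = s$mat_M,
           labelled = s$labelled)
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
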