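#' Geometric dilution series
#'
#' Builds the dose ladders used in checkerboard assays: `count`
#' concentrations in a `factor`-fold dilution, anchored either so that
#' `anchor` sits at the middle position (`"centered"`, the middle is
#' position `floor(count/2) + 1`) or at the top (`"max"`).
#'
#' @param anchor anchor concentration (uM).
#' @param count number of concentrations (>= 1).
#' @param factor dilution factor (> 1).
#' @param anchor_mode `"centered"` or `"max"`.
#' @return increasing numeric vector of length `count`.
#' @examples
#' dilution_series(1, 15, 2, "centered")   # 2^-7 ... 2^7
#' dilution_series(32, 10, 2, "max")       # 0.0625 ... 32
#' @export
dilution_series <- function(anchor, count, factor = 2,
                            anchor_mode = c("centered", "max")) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(count >= 1, factor > 1, anchor > 0)
  expo <- switch(anchor_mode,
    centered = seq_len(count) - (floor(count / 2) + 1),
    max      = seq_len(count) - count
  )
  anchor * factor^expo
}

#' Checkerboard experiment design
#'
#' @param concsA,concsB combination dose ladders (strictly increasing,
#'   positive).
#' @param singleA,singleB single-agent dose ladders (default: the
#'   combination ladders).
#' @param replicates replicates per measured point (>= 1).
#' @return an object of class `checkerboard_design`.
#' @export
checkerboard_design <- function(concsA, concsB = concsA,
                                singleA = concsA, singleB = concsB,
                                replicates = 1) {
  chk <- function(x, nm) {
    if (any(x <= 0) || is.unsorted(x, strictly = TRUE))
      stop("'", nm, "' must be strictly increasing and positive")
  }
  chk(concsA, "concsA"); chk(concsB, "concsB")
  chk(singleA, "singleA"); chk(singleB, "singleB")
  stopifnot(replicates >= 1)
  structure(list(concsA = concsA, concsB = concsB,
                 singleA = singleA, singleB = singleB,
                 replicates = as.integer(replicates)),
            class = "checkerboard_design")
}

#' The simulation design used throughout the bias studies
#'
#' 15-concentration two-fold single-agent series centered on 1 uM, combined
#' in a 10-by-10 two-fold checkerboard with a maximum of 32 uM.
#'
#' @param replicates replicates per point.
#' @return a [checkerboard_design()].
#' @export
standard_bias_design <- function(replicates = 1) {
  checkerboard_design(
    concsA = dilution_series(32, 10, 2, "max"),
    singleA = dilution_series(1, 15, 2, "centered"),
    singleB = dilution_series(1, 15, 2, "centered"),
    replicates = replicates)
}

#' Measurement-noise specification
#'
#' @param response_sd standard deviation of additive Gaussian noise on the
#'   response, in effect units (e.g. 5 on the percent scale).
#' @param conc_log_sd standard deviation of the natural logarithm of the
#'   realized concentration around the nominal target (0 = exact dosing).
#'   The dosing-error condition of the bias studies uses `log(1.1)`, about
#'   0.0953, i.e. a ~10% pipetting error.
#' @param seed optional integer seed applied by the simulators.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(response_sd = 0, conc_log_sd = 0, seed = NULL) {
  stopifnot(response_sd >= 0, conc_log_sd >= 0)
  structure(list(response_sd = response_sd, conc_log_sd = conc_log_sd,
                 seed = seed), class = "noise_spec")
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Simulate a combination checkerboard
#'
#' Evaluates a reference surface over the full dose grid and adds the
#' specified measurement noise.  When `conc_log_sd > 0`, realized doses are
#' drawn log-normally around the nominal targets and the surface is
#' evaluated at the realized doses, but measurements are recorded against
#' the nominal doses, as in a real assay.  Noise is not clipped to the
#' effect range.
#'
#' @param surface a function of `(dA, dB)` returning effects (vectorised),
#'   e.g. `function(a, b) braid_effect(p, a, b)`.
#' @param design a [checkerboard_design()].
#' @param noise a [noise_spec()].
#' @return a data frame (class `checkerboard_data`) with columns `dA`, `dB`,
#'   `response`, `replicate`: one row per grid point and replicate.
#' @export
simulate_checkerboard <- function(surface, design, noise = noise_spec()) {
  maybe_seed(noise$seed)
  grid <- expand.grid(dA = design$concsA, dB = design$concsB,
                      KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(design$replicates), function(r) {
    a <- grid$dA; b <- grid$dB
    if (noise$conc_log_sd > 0) {
      a <- a * exp(stats::rnorm(length(a), 0, noise$conc_log_sd))
      b <- b * exp(stats::rnorm(length(b), 0, noise$conc_log_sd))
    }
    eff <- surface(a, b)
    if (noise$response_sd > 0)
      eff <- eff + stats::rnorm(length(eff), 0, noise$response_sd)
    data.frame(dA = grid$dA, dB = grid$dB, response = eff, replicate = r)
  }))
  class(out) <- c("checkerboard_data", "data.frame")
  out
}

#' Simulate single-agent dose-response series
#'
#' Simulates the two agents of a combination on their single-agent ladders
#' under the same noise model as [simulate_checkerboard()].
#'
#' @param hillA,hillB single-agent [hill_params()].
#' @param design a [checkerboard_design()] (its `singleA`/`singleB` ladders
#'   and `replicates` are used).
#' @param noise a [noise_spec()].
#' @return list with elements `A` and `B`, each a [dose_response_data()].
#' @export
simulate_single_agents <- function(hillA, hillB, design,
                                   noise = noise_spec()) {
  maybe_seed(noise$seed)
  one <- function(p, ladder) {
    dose <- rep(ladder, times = design$replicates)
    repl <- rep(seq_len(design$replicates), each = length(ladder))
    d <- dose
    if (noise$conc_log_sd > 0)
      d <- d * exp(stats::rnorm(length(d), 0, noise$conc_log_sd))
    y <- hill_effect(p, d)
    if (noise$response_sd > 0)
      y <- y + stats::rnorm(length(y), 0, noise$response_sd)
    dose_response_data(dose, y, repl)
  }
  list(A = one(hillA, design$singleA), B = one(hillB, design$singleB))
}

#' Combine checkerboard and single-agent data for surface fitting
#'
#' Stacks a combination checkerboard with the two single-agent series
#' (encoded as rows with the partner dose at 0) into the long format
#' consumed by [fit_braid()].
#'
#' @param checkerboard a `checkerboard_data` data frame.
#' @param singleA,singleB [dose_response_data()] for the two agents.
#' @return data frame with columns `dA`, `dB`, `response`, `replicate`.
#' @export
combine_combination_data <- function(checkerboard, singleA = NULL,
                                     singleB = NULL) {
  parts <- list(checkerboard[c("dA", "dB", "response", "replicate")])
  if (!is.null(singleA))
    parts <- c(parts, list(data.frame(dA = singleA$dose, dB = 0,
                                      response = singleA$response,
                                      replicate = singleA$replicate)))
  if (!is.null(singleB))
    parts <- c(parts, list(data.frame(dA = 0, dB = singleB$dose,
                                      response = singleB$response,
                                      replicate = singleB$replicate)))
  do.call(rbind, parts)
}
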