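#' Bliss volume: mean deviation from Bliss independence
#'
#' Computes the average difference between measured responses on a
#' checkerboard and the Bliss-independent prediction built from the two
#' fitted single-agent curves (evaluated at the nominal doses).  The sign
#' convention is *positive = more effect than independence = synergy* on
#' every input scale; in survival terms the deviation is
#' `predicted survival - measured survival`.  On the percent-effect scale
#' the result is in percentage points.
#'
#' Note that Loewe-additive (sham) combinations do *not* yield zero Bliss
#' volume: the deviation is a deterministic function of the Hill slopes
#' (negative at low slopes, positive at high), which is the source of the
#' slope-dependent bias this package quantifies.
#'
#' @param data a `checkerboard_data` data frame (`dA`, `dB`, `response`).
#' @param hillA,hillB fitted single-agent [hill_params()] on `scale`.
#' @param scale response convention, see [response_to_survival()].
#' @return mean signed deviation (scalar), in percent points for
#'   `scale = "percent"`, in survival fraction otherwise.
#' @export
bliss_volume <- function(data, hillA, hillB, scale = "percent") {
  if (is.null(hillA) || is.null(hillB))
    stop("fitted single-agent curves are required")
  pred <- bliss_survival(hillA, hillB, data$dA, data$dB, scale)
  meas <- response_to_survival(data$response, scale)
  dev <- pred - meas
  if (scale == "percent") dev <- dev * 100
  mean(dev)
}

#' Bliss synergy/antagonism thresholds from self-vs-self calibration
#'
#' Reproduces the common empirical calibration of Bliss volume thresholds:
#' each calibration compound is combined with itself (a sham combination,
#' additive by construction), the resulting Bliss volumes are collected
#' over `reps` repetitions per compound, and the 2.5 / 97.5 percentiles of
#' the pooled values become the antagonism / synergy cutoffs.  With 8
#' compounds and 3 repetitions this yields 24 self-vs-self Bliss volumes.
#'
#' @param compounds list of [hill_params()] (the calibration compounds).
#' @param design a [checkerboard_design()].
#' @param noise a [noise_spec()].
#' @param reps repetitions per compound.
#' @param probs the two percentiles used as thresholds.
#' @return object of class `bliss_thresholds`: list with `lo`, `hi`, the
#'   pooled `values`, and `provenance`.
#' @export
calibrate_bliss_thresholds <- function(compounds, design, noise, reps = 3,
                                       probs = c(0.025, 0.975)) {
  if (length(compounds) < 2)
    stop("need at least two calibration compounds")
  maybe_seed(noise$seed)
  noise_unseeded <- noise_spec(noise$response_sd, noise$conc_log_sd)
  vols <- unlist(lapply(compounds, function(p) {
    vapply(seq_len(reps), function(r) {
      sa <- simulate_single_agents(p, p, design, noise_unseeded)
      fA <- fit_hill_ls(sa$A, fix_bounds = c(p$e0, p$ef))
      fB <- fit_hill_ls(sa$B, fix_bounds = c(p$e0, p$ef))
      surf <- function(a, b) loewe_effect(additive_pair(p, p), a, b)
      chk <- simulate_checkerboard(surf, design, noise_unseeded)
      bliss_volume(chk, fA, fB)
    }, numeric(1))
  }))
  q <- stats::quantile(vols, probs, names = FALSE)
  structure(list(lo = q[1], hi = q[2], values = vols,
                 provenance = sprintf(
                   "%d compounds x %d reps self-vs-self, percentiles %g/%g",
                   length(compounds), reps, probs[1], probs[2])),
            class = "bliss_thresholds")
}

#' @export
print.bliss_thresholds <- function(x, ...) {
  cat(sprintf("Bliss thresholds: antagonism < %.3f, synergy > %.3f\n  (%s)\n",
              x$lo, x$hi, x$provenance))
  invisible(x)
}

#' Classify a Bliss volume against calibrated thresholds
#'
#' @param volume a Bliss volume from [bliss_volume()].
#' @param thresholds a [calibrate_bliss_thresholds()] result, or a length-2
#'   numeric `c(lo, hi)`.
#' @return `"antagonistic"` below `lo`, `"synergistic"` above `hi`,
#'   `"additive"` otherwise (boundary values are additive).
#' @export
classify_bliss <- function(volume, thresholds) {
  if (is.numeric(thresholds)) thresholds <-
      list(lo = thresholds[1], hi = thresholds[2])
  ifelse(volume < thresholds$lo, "antagonistic",
         ifelse(volume > thresholds$hi, "synergistic", "additive"))
}

#' Extract constant-ratio diagonal series from a checkerboard
#'
#' On a square checkerboard whose two ladders share a common dilution
#' factor, each diagonal holds a constant dose ratio A:B.  This extracts
#' the `k` longest diagonals (the main diagonal plus the nearest
#' `(k-1)/2` off-diagonals on each side); on a 10x10 two-fold grid with
#' `k = 7` these are the seven constant-ratio series ranging from 8:1 to
#' 1:8.  Each series is indexed by the total concentration `dA + dB`.
#'
#' @param data a `checkerboard_data` data frame.
#' @param k odd number of diagonals (default 7).
#' @return list of data frames (`dA`, `dB`, `total`, `response`,
#'   `replicate`) with attributes `ratio` (dA:dB) and `offset`.
#' @export
extract_diagonals <- function(data, k = 7) {
  concsA <- sort(unique(data$dA))
  concsB <- sort(unique(data$dB))
  n <- length(concsA)
  if (length(concsB) != n)
    stop("checkerboard must be square to extract constant-ratio diagonals")
  if (k %% 2 != 1 || k < 1) stop("'k' must be a positive odd number")
  if (k > 2 * n - 1) stop("'k' exceeds the number of diagonals")
  half <- (k - 1) / 2
  offsets <- c(0, as.vector(rbind(seq_len(half), -seq_len(half))))
  lapply(offsets, function(o) {
    i <- seq_len(n)
    j <- i + o
    keep <- j >= 1 & j <= n
    i <- i[keep]; j <- j[keep]
    cells <- data.frame(dA = concsA[i], dB = concsB[j])
    rows <- merge(cells, data, by = c("dA", "dB"), sort = FALSE)
    rows$total <- rows$dA + rows$dB
    rows <- rows[order(rows$total, rows$replicate), ]
    ratio <- stats::median(cells$dA / cells$dB)
    structure(rows[c("dA", "dB", "total", "response", "replicate")],
              ratio = ratio, offset = o)
  })
}

#' Combination Index at an effect level
#'
#' The Combination Index of a constant-ratio combination at effect level
#' `x` is \eqn{CI = d_A / IC_{x,A} + d_B / IC_{x,B}}, where `(dA, dB)` is
#' the split, at the fixed ratio, of the total combined dose that the
#' fitted diagonal curve requires to reach the level, and \eqn{IC_{x,X}}
#' are the single-agent doses reaching it.  CI < 1 indicates synergy under
#' Loewe additivity, CI > 1 antagonism; a sham combination has CI = 1 at
#' every level.
#'
#' @param fitA,fitB single-agent [hill_params()].
#' @param diag_fit [hill_params()] fitted to a constant-ratio series
#'   against total concentration.
#' @param level effect level on the fits' scale (e.g. 50 or 99 percent, or
#'   0.5 survival for viability-scale fits).
#' @param ratio the series' dose ratio dA:dB (scalar).
#' @return the CI value, or `NA` when any curve cannot reach the level.
#' @export
combination_index <- function(fitA, fitB, diag_fit, level, ratio) {
  ics <- try({
    ica <- hill_inverse(fitA, level)
    icb <- hill_inverse(fitB, level)
    ict <- hill_inverse(diag_fit, level)
    c(ica, icb, ict)
  }, silent = TRUE)
  if (inherits(ics, "try-error")) return(NA_real_)
  dA <- ics[3] * ratio / (1 + ratio)
  dB <- ics[3] / (1 + ratio)
  dA / ics[1] + dB / ics[2]
}

#' Classify a Combination Index value
#'
#' A combination is judged antagonistic at a level if CI exceeds 2 (a
#' two-fold or greater loss of potency relative to Loewe expectation) and
#' synergistic if CI is below 0.5 (a two-fold or greater gain); boundary
#' values are additive.
#'
#' @param ci CI value(s).
#' @param lo,hi synergy / antagonism cutoffs.
#' @return `"synergistic"`, `"additive"`, `"antagonistic"`, or `NA`.
#' @export
classify_ci <- function(ci, lo = 0.5, hi = 2) {
  ifelse(is.na(ci), NA_character_,
         ifelse(ci < lo, "synergistic",
                ifelse(ci > hi, "antagonistic", "additive")))
}

#' Product of the two single-agent Hill slopes
#'
#' The pairwise slope product is the pharmacological covariate that drives
#' the slope-dependent bias of Bliss and CI.
#'
#' @param fitA,fitB [hill_params()].
#' @return `fitA$n * fitB$n`.
#' @export
hill_product <- function(fitA, fitB) fitA$n * fitB$n

#' Potency index of a single agent
#'
#' The ratio of the highest concentration tested to the concentration
#' producing the reference effect (default: 50% effect, i.e. viability
#' 0.5).  If the level is not reached within the tested range the potency
#' is floored at its minimum value of 1.
#'
#' @param fit a [hill_params()].
#' @param max_conc highest concentration tested.
#' @param level reference effect on the fit's scale (50 for percent-effect
#'   fits, 0.5 for viability-scale fits).
#' @return potency ratio >= 1.
#' @export
potency_index <- function(fit, max_conc, level = 50) {
  ic <- try(hill_inverse(fit, level), silent = TRUE)
  if (inherits(ic, "try-error") || !is.finite(ic) || ic > max_conc) return(1)
  max_conc / ic
}
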