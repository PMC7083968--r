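#' BRAID response-surface parameters
#'
#' The BRAID (Bivariate Response to Additive Interacting Doses) surface is a
#' parametric model of combined action whose interaction parameter `kappa`
#' is 0 for additivity, positive for synergy and negative (but greater than
#' -2) for antagonism.  With \eqn{h = \sqrt{n_a n_b}},
#' \eqn{x_X = (d_X/ID_{M,X})^{n_X}},
#' \eqn{F_X = (E_{f,X}-E_0)/(E_f-E_0)} (where \eqn{E_f} is the maximal
#' effect of larger span) and
#' \deqn{\tilde D_X = \left(\frac{F_X x_X}{1+(1-F_X)x_X}\right)^{1/h},}
#' the surface is
#' \deqn{E(d_A,d_B) = E_0 + (E_f-E_0)
#'   \frac{\tilde D^{\,h}}{1+\tilde D^{\,h}}, \qquad
#'   \tilde D = \tilde D_A + \tilde D_B + \kappa\sqrt{\tilde D_A \tilde D_B}.}
#' Restricted to either axis the surface is exactly the corresponding Hill
#' curve; at `kappa = 0` with equal Hill slopes it coincides with the
#' asymptotically additive Loewe surface.
#'
#' @param idmA,idmB doses of median effect (> 0).
#' @param na,nb Hill slopes (> 0).
#' @param kappa interaction parameter (> -2).
#' @param e0 effect at zero dose.
#' @param efA,efB per-agent maximal effects.
#' @return an object of class `braid_params`.
#' @export
braid_params <- function(idmA, idmB, na, nb, kappa = 0, e0 = 0,
                         efA = 100, efB = 100) {
  if (any(c(idmA, idmB) <= 0)) stop("doses of median effect must be positive")
  if (any(c(na, nb) <= 0)) stop("Hill slopes must be positive")
  if (kappa <= -2) stop("'kappa' must be greater than -2")
  spans <- c(efA, efB) - e0
  if (length(unique(sign(spans[spans != 0]))) > 1)
    stop("'efA' and 'efB' must lie on the same side of 'e0'")
  structure(list(idmA = idmA, idmB = idmB, na = na, nb = nb, kappa = kappa,
                 e0 = e0, efA = efA, efB = efB),
            class = "braid_params")
}

#' @export
print.braid_params <- function(x, ...) {
  cat(sprintf(
    "BRAID surface: IDM = (%g, %g), slopes = (%g, %g), kappa = %g\n",
    x$idmA, x$idmB, x$na, x$nb, x$kappa))
  cat(sprintf("  E0 = %g, Ef = (%g, %g)\n", x$e0, x$efA, x$efB))
  invisible(x)
}

# raw evaluator used in fitting loops: p is a plain list with the 8 fields
braid_effect_raw <- function(p, dA, dB) {
  sA <- p$efA - p$e0
  sB <- p$efB - p$e0
  if (sA == 0 && sB == 0) return(rep(p$e0, max(length(dA), length(dB))))
  ef <- if (abs(sA) >= abs(sB)) p$efA else p$efB
  spanf <- ef - p$e0
  FA <- sA / spanf
  FB <- sB / spanf
  h <- sqrt(p$na * p$nb)
  xA <- (dA / p$idmA)^p$na
  xB <- (dB / p$idmB)^p$nb
  tA <- (FA * xA / (1 + (1 - FA) * xA))^(1 / h)
  tB <- (FB * xB / (1 + (1 - FB) * xB))^(1 / h)
  tA[is.infinite(xA)] <- if (FA < 1) (FA / (1 - FA))^(1 / h) else Inf
  tB[is.infinite(xB)] <- if (FB < 1) (FB / (1 - FB))^(1 / h) else Inf
  D <- tA + tB + p$kappa * sqrt(tA * tB)
  Dh <- D^h
  frac <- ifelse(is.infinite(Dh), 1, Dh / (1 + Dh))
  p$e0 + spanf * frac
}

#' Evaluate a BRAID response surface
#'
#' @param p a [braid_params()] object.
#' @param dA,dB dose vectors (>= 0, recycled to common length).
#' @return effects on the scale of `p$e0`/`p$ef*`.
#' @export
braid_effect <- function(p, dA, dB) {
  k <- max(length(dA), length(dB))
  dA <- rep_len(dA, k); dB <- rep_len(dB, k)
  if (any(dA < 0) || any(dB < 0)) stop("doses must be non-negative")
  braid_effect_raw(p, dA, dB)
}

th_to_params <- function(th) {
  braid_params(idmA = exp(th[1]), idmB = exp(th[2]),
               na = exp(th[3]), nb = exp(th[4]),
               kappa = exp(th[5]) - 2,
               e0 = th[6], efA = th[7], efB = th[8])
}

# axis Hill fit for initialisation, with graceful fallback
axis_init <- function(d, y, e0_guess = NULL) {
  ok <- d > 0
  fit <- try(fit_hill_ls(dose_response_data(d[ok], y[ok])), silent = TRUE)
  if (!inherits(fit, "try-error") && isTRUE(attr(fit, "converged")) &&
      !isTRUE(attr(fit, "flat")))
    return(list(idm = fit$idm, n = fit$n, e0 = fit$e0, ef = fit$ef))
  if (is.null(e0_guess)) e0_guess <- mean(y[d == min(d)])
  ef_guess <- mean(y[d == max(d)])
  if (!is.finite(ef_guess) || ef_guess == e0_guess)
    ef_guess <- e0_guess + max(diff(range(y)), 1e-3)
  list(idm = stats::median(d[ok]), n = 1, e0 = e0_guess, ef = ef_guess)
}

#' Fit the 8-parameter BRAID surface by least squares
#'
#' Estimates all eight BRAID parameters from a combination checkerboard with
#' accompanying single-agent measurements (rows with one dose equal to
#' zero).  Fitting is Levenberg-Marquardt least squares on transformed
#' parameters (log doses/slopes, `log(kappa + 2)`), initialised from Hill
#' fits of the two dose axes with `kappa` starting at 0.  The 95% confidence
#' interval on `kappa` is a wild residual bootstrap (sign-flipped
#' residuals, percentile interval): sign-flipping preserves each
#' measurement's own residual magnitude, so heteroscedastic effective
#' noise — e.g. from log-normal dosing error on steep surfaces — is
#' propagated into the interval instead of being averaged away.  The
#' interaction call follows the interval rule: synergy if the interval
#' lies entirely above 0, antagonism if entirely below.
#'
#' @param data a data frame with columns `dA`, `dB`, `response` (e.g. from
#'   [simulate_checkerboard()] combined with single-agent rows; see
#'   [combine_combination_data()]).
#' @param n_boot bootstrap resamples for the `kappa` interval (0 to skip).
#' @param seed optional integer seed making the bootstrap deterministic.
#' @param conf confidence level of the `kappa` interval.
#' @param fix_e0 optional known zero-dose effect (e.g. 1 for normalised
#'   fractional viability); when supplied the baseline is held fixed and
#'   the remaining seven parameters are estimated.
#' @return an object of class `braid_fit`: a list with elements `params`
#'   ([braid_params()]), `kappa_ci`, `call` (see [classify_braid()]), `rss`,
#'   `r_squared`, `low_information`, `converged`, `residuals`, `fitted`,
#'   `boot_kappa`.
#' @export
fit_braid <- function(data, n_boot = 200, seed = NULL, conf = 0.95,
                      fix_e0 = NULL) {
  dA <- data$dA; dB <- data$dB; y <- data$response
  ok <- is.finite(y) & dA >= 0 & dB >= 0
  dA <- dA[ok]; dB <- dB[ok]; y <- y[ok]
  if (length(unique(paste(dA, dB))) < 12)
    stop("need at least 12 distinct dose pairs (including single-agent data)")

  ctrl <- dA == 0 & dB == 0
  onA <- dB == 0 & dA > 0
  onB <- dA == 0 & dB > 0
  if (!any(onA) || !any(onB))
    stop("single-agent measurements for both drugs are required")
  e0g <- if (any(ctrl)) mean(y[ctrl]) else NA_real_
  iA <- axis_init(dA[onA], y[onA], if (is.na(e0g)) NULL else e0g)
  iB <- axis_init(dB[onB], y[onB], if (is.na(e0g)) NULL else e0g)
  e00 <- if (!is.null(fix_e0)) fix_e0 else
    if (!is.na(e0g)) e0g else mean(c(iA$e0, iB$e0))
  # force initial spans to share a sign (required by the model)
  dir <- sign((iA$ef - e00) + (iB$ef - e00))
  if (dir == 0) dir <- 1
  fix_span <- function(ef) if (sign(ef - e00) == dir) ef else
    e00 + dir * max(abs(ef - e00), 1e-3)
  th0 <- c(log(iA$idm), log(iB$idm), log(iA$n), log(iB$n), log(2),
           e00, fix_span(iA$ef), fix_span(iB$ef))

  yr <- diff(range(y))
  pad <- yr + max(abs(y), 1)
  dpos <- c(dA[dA > 0], dB[dB > 0])
  lower <- c(rep(log(min(dpos)) - log(1e4), 2), rep(log(0.02), 2),
             log(0.01), rep(min(y) - pad, 3))
  upper <- c(rep(log(max(dpos)) + log(1e4), 2), rep(log(50), 2),
             log(102), rep(max(y) + pad, 3))

  free <- if (is.null(fix_e0)) 1:8 else c(1:5, 7:8)
  expand_th <- function(thf) {
    th <- numeric(8); th[free] <- thf
    if (!is.null(fix_e0)) th[6] <- fix_e0
    th
  }
  run_lm <- function(start, yy, maxiter = 150) {
    minpack.lm::nls.lm(
      par = start[free],
      fn = function(thf) braid_resid_cpp(expand_th(thf), dA, dB, yy),
      lower = lower[free], upper = upper[free],
      control = minpack.lm::nls.lm.control(maxiter = maxiter))
  }
  y_obs <- y
  fit <- run_lm(th0, y_obs)
  th <- expand_th(fit$par)
  fitted <- braid_resid_cpp(th, dA, dB, y_obs) + y_obs
  res <- y_obs - fitted
  rss <- sum(res^2)
  tss <- sum((y_obs - mean(y_obs))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0

  boot_kappa <- numeric(0)
  kappa_hat <- exp(th[5]) - 2
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv),
              add = TRUE)
      set.seed(seed)
    }
    n <- length(y_obs)
    boot_kappa <- vapply(seq_len(n_boot), function(b) {
      # wild (sign-flip) residual bootstrap: keeps each well's own
      # residual magnitude, so the heteroscedastic effective noise that
      # dosing error induces on steep surfaces is propagated correctly
      ystar <- fitted + res * sample(c(-1, 1), n, replace = TRUE)
      # refits start at the optimum; stopping at the iteration cap is
      # fine for a percentile interval, so silence the optimizer note
      fb <- try(suppressWarnings(run_lm(th, ystar, maxiter = 60)),
                silent = TRUE)
      if (inherits(fb, "try-error")) return(NA_real_)
      exp(fb$par[5]) - 2
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_kappa, c(alpha, 1 - alpha),
                                 na.rm = TRUE))
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  out <- structure(list(
    params = th_to_params(th),
    kappa_ci = ci,
    kappa_at_bound = min(th[5] - lower[5], upper[5] - th[5]) < 1e-6,
    rss = rss,
    r_squared = r2,
    residuals = res,
    fitted = fitted,
    data = data.frame(dA = dA, dB = dB, response = y_obs),
    low_information = r2 < 0.2 || diff(range(y_obs)) < 10 * stats::sd(res),
    converged = fit$info %in% 1:4,
    boot_kappa = boot_kappa,
    conf = conf,
    n_boot = n_boot
  ), class = "braid_fit")
  out$call_type <- classify_braid(out)
  out
}

#' @export
print.braid_fit <- function(x, ...) {
  print(x$params)
  if (!all(is.na(x$kappa_ci)))
    cat(sprintf("  kappa %.0f%% CI: [%.3f, %.3f]  ->  %s\n",
                100 * x$conf, x$kappa_ci[1], x$kappa_ci[2], x$call_type))
  cat(sprintf("  RSS = %.4g, R^2 = %.3f%s\n", x$rss, x$r_squared,
              if (x$low_information) "  [low information]" else ""))
  invisible(x)
}

#' Classify a BRAID fit as synergistic, additive, or antagonistic
#'
#' A surface is judged synergistic if the confidence interval on `kappa`
#' lies entirely above 0, antagonistic if it lies entirely below 0, and
#' additive otherwise (including when no interval is available).
#'
#' @param fit a [fit_braid()] result.
#' @return one of `"synergistic"`, `"additive"`, `"antagonistic"`.
#' @export
classify_braid <- function(fit) {
  ci <- fit$kappa_ci
  if (any(is.na(ci))) return("additive")
  if (ci[1] > 0) "synergistic" else if (ci[2] < 0) "antagonistic" else "additive"
}

#' Index of achievable efficacy (IAE)
#'
#' Summarises a fitted combination surface as a single combined-efficacy
#' number: the ratio of the total tested dose-space area
#' \eqn{[0, D_A^{max}] \times [0, D_B^{max}]} (in linear dose space) to the
#' area of the sub-threshold region where the surface fails to reach the
#' efficacy threshold, evaluated on a dense grid.  IAE is 1 when no dose
#' pair reaches the threshold and grows as synergy or potency enlarges the
#' achievable region; it is invariant to rescaling both dose axes.
#'
#' @param p a [braid_params()] object (typically `fit$params`).
#' @param limits length-2 positive vector `c(DA_max, DB_max)`, conventionally
#'   the highest concentrations tested in combination.
#' @param threshold the efficacy effect level on the surface's scale (e.g.
#'   50 for 50% effect on the percent scale, or 0.5 survival on the
#'   viability scale).
#' @param n_grid grid resolution per axis.
#' @return an object of class `iae_result`: list with `iae`, `log10_iae`,
#'   `limits`, `threshold`.
#' @export
compute_iae <- function(p, limits, threshold, n_grid = 201) {
  if (length(limits) != 2 || any(!is.finite(limits)) || any(limits <= 0))
    stop("'limits' must be two positive concentrations")
  ef <- if (abs(p$efA - p$e0) >= abs(p$efB - p$e0)) p$efA else p$efB
  dir <- sign(ef - p$e0)
  if (dir == 0) dir <- 1
  # cell-centred grid in linear dose space
  gA <- (seq_len(n_grid) - 0.5) / n_grid * limits[1]
  gB <- (seq_len(n_grid) - 0.5) / n_grid * limits[2]
  E <- braid_effect_raw(p, rep(gA, times = n_grid), rep(gB, each = n_grid))
  achieved <- dir * (E - threshold) >= 0
  a_total <- limits[1] * limits[2]
  cell <- a_total / n_grid^2
  a_fail <- a_total * mean(!achieved)
  iae <- a_total / max(a_fail, cell)
  structure(list(iae = iae, log10_iae = log10(iae), limits = limits,
                 threshold = threshold), class = "iae_result")
}

#' @export
print.iae_result <- function(x, ...) {
  cat(sprintf("IAE = %.4g (log10 = %.3f) at threshold %g within (%g, %g)\n",
              x$iae, x$log10_iae, x$threshold, x$limits[1], x$limits[2]))
  invisible(x)
}

#' Poisson maximum-likelihood BRAID fit for clonogenic assays
#'
#' Colony-forming (clonogenic) assays report counts of surviving colonies.
#' The BRAID equation is used as a model of plating efficiency in log space:
#' the expected colony count at a dose pair is
#' `seeding_density * exp(E(dA, dB))`, where `E` is a BRAID surface on the
#' log-plating-efficiency scale (`e0` near `log` of the control plating
#' efficiency, maximal effects more negative).  Counts are treated as a
#' variable-rate Poisson process and all eight surface parameters are
#' estimated by maximising the Poisson log-likelihood.  The `kappa`
#' interval is a parametric bootstrap: counts are resampled from the fitted
#' Poisson means and refit.
#'
#' @param counts data frame with columns `dA`, `dB`, `colonies`
#'   (non-negative integers); rows with both doses zero are the controls.
#' @param seeding_density cells seeded per well (> 0).
#' @param n_boot parametric bootstrap resamples (0 to skip).
#' @param seed optional integer seed.
#' @param conf confidence level.
#' @return a `braid_fit` (see [fit_braid()]) whose `params` live on the
#'   log-plating-efficiency scale.
#' @export
fit_braid_poisson <- function(counts, seeding_density, n_boot = 100,
                              seed = NULL, conf = 0.95) {
  if (seeding_density <= 0) stop("'seeding_density' must be positive")
  dA <- counts$dA; dB <- counts$dB; yc <- counts$colonies
  if (any(yc < 0) || any(yc != round(yc)))
    stop("'colonies' must be non-negative integers")
  low_info <- all(yc == 0)

  ctrl <- dA == 0 & dB == 0
  pe0 <- if (any(ctrl)) mean(yc[ctrl]) / seeding_density else
    max(yc) / seeding_density
  e00 <- log(max(pe0, 1 / seeding_density))
  floor_eff <- log(0.5 / seeding_density)  # below half a colony expected
  init_ef <- function(on_axis) {
    if (!any(on_axis)) return(e00 - 1)
    mx <- max(dA[on_axis] + dB[on_axis])
    topc <- yc[on_axis][ (dA[on_axis] + dB[on_axis]) == mx ]
    min(log(max(mean(topc), 0.5) / seeding_density), e00 - 1e-3)
  }
  onA <- dB == 0 & dA > 0
  onB <- dA == 0 & dB > 0
  dpos <- c(dA[dA > 0], dB[dB > 0])
  th0 <- c(log(stats::median(dA[dA > 0])), log(stats::median(dB[dB > 0])),
           0, 0, log(2), e00, init_ef(onA), init_ef(onB))

  lower <- c(rep(log(min(dpos)) - log(1e4), 2), rep(log(0.02), 2),
             log(0.01), rep(floor_eff - 5, 3))
  upper <- c(rep(log(max(dpos)) + log(1e4), 2), rep(log(50), 2),
             log(102), rep(e00 + 2, 3))
  run_opt <- function(start, counts_vec) {
    stats::optim(start, braid_poisson_negll_cpp, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 dA = dA, dB = dB, counts = counts_vec,
                 density = seeding_density,
                 control = list(maxit = 500))
  }
  yc_obs <- yc
  fit <- run_opt(th0, yc_obs)
  th <- fit$par
  params <- th_to_params(th)
  eta_hat <- braid_effect_raw(params, dA, dB)
  mu_hat <- seeding_density * exp(eta_hat)

  boot_kappa <- numeric(0)
  if (n_boot > 0 && !low_info) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv),
              add = TRUE)
      set.seed(seed)
    }
    boot_kappa <- vapply(seq_len(n_boot), function(b) {
      ystar <- stats::rpois(length(mu_hat), mu_hat)
      fb <- try(run_opt(th, ystar), silent = TRUE)
      if (inherits(fb, "try-error")) return(NA_real_)
      exp(fb$par[5]) - 2
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_kappa, c(alpha, 1 - alpha),
                                 na.rm = TRUE))
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  dev <- yc_obs - mu_hat
  out <- structure(list(
    params = params,
    kappa_ci = ci,
    rss = sum(dev^2),
    r_squared = if (stats::var(yc_obs) > 0)
      1 - sum(dev^2) / sum((yc_obs - mean(yc_obs))^2) else 0,
    residuals = dev,
    fitted = mu_hat,
    data = counts,
    log_likelihood = -fit$value,
    low_information = low_info,
    converged = fit$convergence == 0,
    boot_kappa = boot_kappa,
    conf = conf,
    n_boot = n_boot
  ), class = "braid_fit")
  out$call_type <- classify_braid(out)
  out
}

#' Serialize / restore a BRAID fit as JSON
#'
#' @param fit a `braid_fit`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
braid_fit_json <- function(fit, path = NULL) {
  x <- list(params = unclass(fit$params), kappa_ci = fit$kappa_ci,
            call = fit$call_type, rss = fit$rss, r_squared = fit$r_squared,
            low_information = fit$low_information, n_boot = fit$n_boot)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a colony-count grid from CSV
#'
#' Expects columns `concA_uM`, `concB_uM`, `colonies`.
#'
#' @param path file path.
#' @return data frame with columns `dA`, `dB`, `colonies`.
#' @export
read_colony_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("concA_uM", "concB_uM", "colonies")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  data.frame(dA = df$concA_uM, dB = df$concB_uM, colonies = df$colonies)
}
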