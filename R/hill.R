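#' Four-parameter log-logistic (Hill) dose-response curve
#'
#' Constructs the parameter set of a single agent's log-logistic
#' dose-response curve
#' \deqn{E(d) = E_0 + (E_f - E_0)\frac{(d/ID_M)^n}{1 + (d/ID_M)^n}}
#' where `idm` is the dose of median effect (the concentration producing an
#' effect halfway between `e0` and `ef`), `n` the Hill slope, `e0` the effect
#' at zero dose and `ef` the asymptotic maximal effect.  The parameterisation
#' is scale-agnostic: `e0`/`ef` may be percent effect (0/100), fractional
#' effect (0/1) or fractional viability (1/0).
#'
#' @param idm dose of median effect, must be positive (concentration units,
#'   conventionally uM).
#' @param n Hill slope, must be positive.
#' @param e0 effect at zero dose.
#' @param ef maximal effect at infinite dose; must differ from `e0`.
#' @return an object of class `hill_params`.
#' @seealso [hill_effect()], [hill_inverse()], [fit_hill_ls()],
#'   [fit_hill_median_effect()]
#' @export
hill_params <- function(idm, n, e0 = 0, ef = 100) {
  if (!is.finite(idm) || idm <= 0) stop("'idm' must be a positive finite dose")
  if (!is.finite(n) || n <= 0) stop("'n' (Hill slope) must be positive")
  if (!is.finite(e0) || !is.finite(ef) || e0 == ef)
    stop("'e0' and 'ef' must be finite and distinct")
  structure(list(idm = idm, n = n, e0 = e0, ef = ef), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill curve: IDM = %g, slope = %g, E0 = %g, Ef = %g\n",
              x$idm, x$n, x$e0, x$ef))
  invisible(x)
}

#' Evaluate a Hill dose-response curve
#'
#' @param p a [hill_params()] object.
#' @param d vector of doses (>= 0).
#' @return effects on the scale of `p$e0`/`p$ef`.
#' @export
hill_effect <- function(p, d) {
  if (any(d < 0)) stop("doses must be non-negative")
  x <- (d / p$idm)^p$n
  # guard d = Inf: x/(1+x) -> 1
  frac <- ifelse(is.infinite(x), 1, x / (1 + x))
  p$e0 + (p$ef - p$e0) * frac
}

#' Invert a Hill dose-response curve
#'
#' Returns the unique dose at which the curve attains effect `e`.  The effect
#' must lie strictly between `e0` and `ef`; effects at or beyond the
#' asymptotes are unreachable.
#'
#' @param p a [hill_params()] object.
#' @param e vector of effects strictly between `p$e0` and `p$ef`.
#' @return doses, same length as `e`.
#' @export
hill_inverse <- function(p, e) {
  r <- (e - p$e0) / (p$ef - p$e0)
  if (any(r <= 0 | r >= 1))
    stop("effect outside the open interval (e0, ef) is unreachable",
         call. = FALSE)
  p$idm * (r / (1 - r))^(1 / p$n)
}

#' Dose-response data container
#'
#' A light validated data frame of single-agent measurements.
#'
#' @param doses concentrations (>= 0, finite).
#' @param responses measured effects, same length.
#' @param replicate optional replicate identifiers (default all 1).
#' @return a `data.frame` with columns `dose`, `response`, `replicate`,
#'   class `dose_response_data`.
#' @export
dose_response_data <- function(doses, responses, replicate = NULL) {
  if (length(doses) != length(responses))
    stop("'doses' and 'responses' must have equal length")
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and non-negative")
  if (is.null(replicate)) replicate <- rep(1L, length(doses))
  structure(
    data.frame(dose = doses, response = responses, replicate = replicate),
    class = c("dose_response_data", "data.frame")
  )
}

#' Read / write dose-response tables
#'
#' Round-trips [dose_response_data()] through a 3-column CSV
#' (`dose_uM`, `response`, `replicate`).
#'
#' @param path file path.
#' @param data a [dose_response_data()] object.
#' @return `read_dose_response_csv` returns [dose_response_data()];
#'   `write_dose_response_csv` returns `path` invisibly.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dose_uM", "response", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  dose_response_data(df$dose_uM, df$response, df$replicate)
}

#' @rdname read_dose_response_csv
#' @export
write_dose_response_csv <- function(data, path) {
  utils::write.csv(
    data.frame(dose_uM = data$dose, response = data$response,
               replicate = data$replicate),
    path, row.names = FALSE)
  invisible(path)
}

#' Median-effect (Chou-Talalay) Hill fit
#'
#' Fits a Hill curve by the median-effect linearisation: fractional effects
#' are clipped into \[0.5%, 99.5%\], logit-transformed, and regressed on log
#' dose by ordinary least squares.  The bounds are fixed at `e0 = 0`,
#' `ef = 100` (percent-effect scale); only doses > 0 enter the regression.
#'
#' @param data a [dose_response_data()] (responses in percent effect).
#' @param clip lower/upper clipping bounds in percent (default `c(0.5, 99.5)`).
#' @return a [hill_params()] with `e0 = 0`, `ef = 100`.
#' @export
fit_hill_median_effect <- function(data, clip = c(0.5, 99.5)) {
  keep <- data$dose > 0
  d <- data$dose[keep]
  y <- pmin(pmax(data$response[keep], clip[1]), clip[2])
  if (length(unique(d)) < 2)
    stop("degenerate fit: need >= 2 distinct positive doses", call. = FALSE)
  if (all(y == clip[1]) || all(y == clip[2]))
    stop("degenerate fit: all responses clipped to the same bound",
         call. = FALSE)
  f <- y / 100
  z <- log(f / (1 - f))
  fit <- stats::lm(z ~ log(d))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate fit: non-positive median-effect slope", call. = FALSE)
  hill_params(idm = exp(-intercept / slope), n = slope, e0 = 0, ef = 100)
}

#' Nonlinear least-squares Hill fit
#'
#' Fits the log-logistic curve directly to the measurements by
#' Levenberg-Marquardt least squares.  Bounds may be left free (4-parameter
#' fit) or fixed, e.g. `fix_bounds = c(0, 100)` for the percent-effect
#' convention or `c(1, 0)` for fractional viability.
#'
#' @param data a [dose_response_data()].
#' @param fix_bounds optional length-2 numeric `c(e0, ef)`; when supplied only
#'   `idm` and `n` are estimated.
#' @param start optional named list overriding the default initial values.
#' @return a [hill_params()] with attributes `converged` (logical), `rss`,
#'   and `flat` (TRUE when the data carry no dose-response signal and the
#'   returned curve is not identifiable).
#' @export
fit_hill_ls <- function(data, fix_bounds = NULL, start = NULL) {
  keep <- data$dose > 0 & is.finite(data$response)
  d <- data$dose[keep]
  y <- data$response[keep]
  free_bounds <- is.null(fix_bounds)
  if (length(unique(d)) < (if (free_bounds) 4 else 2))
    stop("too few distinct positive doses for the requested fit",
         call. = FALSE)

  if (free_bounds) {
    e0 <- y[which.min(d)]
    ef <- y[which.max(d)]
    if (e0 == ef) ef <- e0 + max(diff(range(y)), 1e-6)
  } else {
    e0 <- fix_bounds[1]; ef <- fix_bounds[2]
  }
  # init: idm at the dose whose response is nearest the half-span level
  half <- (e0 + ef) / 2
  idm0 <- d[which.min(abs(y - half))]
  n0 <- 1
  if (!is.null(start)) {
    if (!is.null(start$idm)) idm0 <- start$idm
    if (!is.null(start$n)) n0 <- start$n
    if (free_bounds && !is.null(start$e0)) e0 <- start$e0
    if (free_bounds && !is.null(start$ef)) ef <- start$ef
  }

  flat <- stats::sd(y) < 1e-12
  ld <- log(d)
  resid_fn <- if (free_bounds) {
    function(th) {
      x <- exp(exp(th[2]) * (ld - th[1]))
      th[3] + (th[4] - th[3]) * x / (1 + x) - y
    }
  } else {
    function(th) {
      x <- exp(exp(th[2]) * (ld - th[1]))
      e0 + (ef - e0) * x / (1 + x) - y
    }
  }
  th0 <- c(log(idm0), log(n0))
  lower <- c(min(ld) - log(1e4), log(0.02))
  upper <- c(max(ld) + log(1e4), log(50))
  if (free_bounds) {
    th0 <- c(th0, e0, ef)
    pad <- max(abs(c(e0, ef)), 1) * 2 + diff(range(y))
    lower <- c(lower, min(y) - pad, min(y) - pad)
    upper <- c(upper, max(y) + pad, max(y) + pad)
  }
  fit <- try(minpack.lm::nls.lm(
    par = th0, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    p <- hill_params(idm0, n0, e0, if (ef == e0) e0 + 1 else ef)
    attr(p, "converged") <- FALSE
    attr(p, "flat") <- flat
    attr(p, "rss") <- sum((hill_effect(p, d) - y)^2)
    return(p)
  }
  th <- fit$par
  if (free_bounds) { e0 <- th[3]; ef <- th[4] }
  if (ef == e0) ef <- e0 + 1e-9  # unidentifiable flat curve
  p <- hill_params(idm = exp(th[1]), n = exp(th[2]), e0 = e0, ef = ef)
  attr(p, "converged") <- fit$info %in% 1:4
  attr(p, "flat") <- flat
  attr(p, "rss") <- fit$deviance
  p
}
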