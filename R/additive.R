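#' Two-drug additive surface specification
#'
#' Bundles two Hill curves sharing a baseline effect into the 7-parameter
#' specification (`idmA`, `idmB`, `na`, `nb`, `e0`, `efA`, `efB`) of an
#' additive (non-interacting) reference surface.
#'
#' @param hillA,hillB [hill_params()] for the two agents; their `e0` must be
#'   equal.
#' @return an object of class `additive_pair`.
#' @export
additive_pair <- function(hillA, hillB) {
  stopifnot(inherits(hillA, "hill_params"), inherits(hillB, "hill_params"))
  if (hillA$e0 != hillB$e0)
    stop("the two agents must share the same baseline effect 'e0'")
  structure(list(hillA = hillA, hillB = hillB), class = "additive_pair")
}

#' @export
print.additive_pair <- function(x, ...) {
  cat("Additive pair specification\n  A: "); print(x$hillA)
  cat("  B: "); print(x$hillB)
  invisible(x)
}

span <- function(p) abs(p$ef - p$e0)

#' Loewe-additive (URSA, interaction fixed at zero) response surface
#'
#' Evaluates the classical Loewe additive surface for two agents with equal
#' maximal effects: the effect `E` at dose pair `(dA, dB)` is the unique
#' solution of \eqn{d_A/IC_{E,A} + d_B/IC_{E,B} = 1}, where \eqn{IC_{E,X}}
#' is the dose of drug X alone producing effect E.  For agents with unequal
#' maximal effects use [asymptotic_additive_effect()].
#'
#' When the two Hill slopes are equal the implicit equation has the closed
#' form of a Hill curve in the total normalised dose; otherwise the root is
#' located by Brent's method to a residual below `tol`.
#'
#' @param spec an [additive_pair()] with `hillA$ef == hillB$ef`.
#' @param dA,dB dose vectors (recycled to common length), >= 0.
#' @param tol residual tolerance of the implicit-equation solve.
#' @return effects on the spec's scale.
#' @export
loewe_effect <- function(spec, dA, dB, tol = 1e-9) {
  A <- spec$hillA; B <- spec$hillB
  if (A$ef != B$ef)
    stop("Loewe additivity requires equal maximal effects; ",
         "use asymptotic_additive_effect() for unequal spans")
  k <- max(length(dA), length(dB))
  dA <- rep_len(dA, k); dB <- rep_len(dB, k)
  if (any(dA < 0) || any(dB < 0)) stop("doses must be non-negative")
  e0 <- A$e0; ef <- A$ef

  if (isTRUE(all.equal(A$n, B$n, tolerance = 1e-12))) {
    # equal slopes: IC_{E,X} = idmX * g(E), so dA/idmA + dB/idmB = g(E)
    g <- dA / A$idm + dB / B$idm
    x <- g^A$n
    return(e0 + (ef - e0) * x / (1 + x))
  }

  one <- function(a, b) {
    if (a == 0 && b == 0) return(e0)
    if (b == 0) return(hill_effect(A, a))
    if (a == 0) return(hill_effect(B, b))
    # solve on r = (E-e0)/(ef-e0) in (0,1); f decreasing in r
    f <- function(r) {
      g <- (r / (1 - r))
      a / (A$idm * g^(1 / A$n)) + b / (B$idm * g^(1 / B$n)) - 1
    }
    eps <- 1e-14
    root <- stats::uniroot(f, lower = eps, upper = 1 - eps,
                           f.lower = f(eps), f.upper = f(1 - eps),
                           tol = tol * 1e-3)$root
    e0 + (ef - e0) * root
  }
  vapply(seq_len(k), function(i) one(dA[i], dB[i]), numeric(1))
}

#' Asymptotic effective dose of the weaker agent
#'
#' For a pair in which drug B has the smaller span `|ef - e0|`, maps each
#' dose of B to the dose that would produce the same effect if B shared drug
#' A's maximal effect:
#' \deqn{D'_B = ID_{M,B}\left(\frac{R\,x}{1 + (1-R)\,x}\right)^{1/n_b}}
#' with \eqn{R = (E_{f,B}-E_0)/(E_{f,A}-E_0)} and
#' \eqn{x = (D_B/ID_{M,B})^{n_b}}.  The transform is monotone, satisfies
#' \eqn{D'_B \le D_B}, and saturates as \eqn{D_B \to \infty}.
#'
#' @param spec an [additive_pair()]; drug B must have the smaller (or equal)
#'   span, otherwise swap the roles first.
#' @param dB doses of drug B.
#' @return effective doses on drug B's concentration scale.
#' @export
asymptotic_effective_dose <- function(spec, dB) {
  A <- spec$hillA; B <- spec$hillB
  R <- span(B) / span(A)
  if (R > 1 + 1e-12)
    stop("drug B must be the smaller-span agent; swap the pair first")
  R <- min(R, 1)
  if (any(dB < 0)) stop("doses must be non-negative")
  x <- (dB / B$idm)^B$n
  eff <- (R * x) / (1 + (1 - R) * x)
  out <- B$idm * eff^(1 / B$n)
  out[is.infinite(x)] <- B$idm * (R / (1 - R))^(1 / B$n)
  out[dB == 0] <- 0
  out
}

#' Asymptotically additive response surface
#'
#' Extends Loewe additivity to agents with unequal maximal effects: the
#' smaller-span agent's doses are passed through
#' [asymptotic_effective_dose()] and the pair is then evaluated under plain
#' Loewe additivity with the larger span as the shared maximal effect.  On
#' each axis the surface reproduces the corresponding single-agent curve,
#' and it reduces to [loewe_effect()] when the spans are equal.
#'
#' Role assignment is automatic: the agent with the smaller `|ef - e0|` is
#' transformed (ties: the agent listed second).
#'
#' @inheritParams loewe_effect
#' @return effects on the spec's scale.
#' @export
asymptotic_additive_effect <- function(spec, dA, dB, tol = 1e-9) {
  A <- spec$hillA; B <- spec$hillB
  swap <- span(A) < span(B)
  if (swap) {
    spec <- additive_pair(B, A)
    tmp <- dA; dA <- dB; dB <- tmp
    A <- spec$hillA; B <- spec$hillB
  }
  dBeff <- asymptotic_effective_dose(spec, dB)
  Bstar <- hill_params(B$idm, B$n, B$e0, A$ef)
  loewe_effect(additive_pair(A, Bstar), dA, dBeff, tol = tol)
}

#' Bliss-independent survival surface
#'
#' Under Bliss independence the probability that a cell survives both drugs
#' is the product of the single-agent survival probabilities:
#' \eqn{S(d_A, d_B) = S_A(d_A)\,S_B(d_B)}.
#'
#' @param hillA,hillB single-agent [hill_params()] expressed on `scale`.
#' @param dA,dB dose vectors (recycled).
#' @param scale the convention of the Hill curves' effect values; see
#'   [response_to_survival()].
#' @return survival fractions in \[0, 1\] (up to curve extrapolation).
#' @export
bliss_survival <- function(hillA, hillB, dA, dB, scale = "percent") {
  sA <- response_to_survival(hill_effect(hillA, dA), scale)
  sB <- response_to_survival(hill_effect(hillB, dB), scale)
  sA * sB
}

#' @rdname bliss_survival
#' @return `bliss_effect` returns the Bliss-predicted response on `scale`
#'   rather than as survival.
#' @export
bliss_effect <- function(hillA, hillB, dA, dB, scale = "percent") {
  survival_to_response(bliss_survival(hillA, hillB, dA, dB, scale), scale)
}
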