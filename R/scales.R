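#' Effect-scale conventions and converters
#'
#' Combination data arrive in two common conventions: *percent effect*
#' (0 = untreated, 100 = complete effect, e.g. complete killing) and
#' *fractional viability* (1 = untreated, 0 = complete kill).  Internally the
#' dose-response and surface models are written in terms of an arbitrary
#' baseline `e0` and maximal effect `ef`, so they work on either convention;
#' these helpers convert between the three conventions where an explicit
#' scale is needed (e.g. for Bliss survival probabilities).
#'
#' @param x numeric vector of responses.
#' @return numeric vector on the target scale.
#' @examples
#' percent_to_fraction(50)          # 0.5
#' fraction_to_viability(0.25)      # 0.75
#' viability_to_percent(0.1)        # 90
#' @name effect_scale
NULL

#' @rdname effect_scale
#' @export
percent_to_fraction <- function(x) x / 100

#' @rdname effect_scale
#' @export
fraction_to_percent <- function(x) x * 100

#' @rdname effect_scale
#' @export
fraction_to_viability <- function(x) 1 - x

#' @rdname effect_scale
#' @export
viability_to_fraction <- function(x) 1 - x

#' @rdname effect_scale
#' @export
percent_to_viability <- function(x) 1 - x / 100

#' @rdname effect_scale
#' @export
viability_to_percent <- function(x) (1 - x) * 100

#' Survival fraction implied by a response on a named scale
#'
#' Maps a response value to the probability-of-survival scale on \[0, 1\]
#' used by Bliss independence.
#'
#' @param x numeric responses.
#' @param scale one of `"percent"` (0-100 effect), `"fraction"` (0-1 effect)
#'   or `"viability"` (1-0 survival).
#' @return survival fractions.
#' @export
response_to_survival <- function(x, scale = c("percent", "fraction", "viability")) {
  scale <- match.arg(scale)
  switch(scale,
    percent   = 1 - x / 100,
    fraction  = 1 - x,
    viability = x
  )
}

#' @rdname response_to_survival
#' @export
survival_to_response <- function(x, scale = c("percent", "fraction", "viability")) {
  scale <- match.arg(scale)
  switch(scale,
    percent   = (1 - x) * 100,
    fraction  = 1 - x,
    viability = x
  )
}
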