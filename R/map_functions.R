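#' Map-function conversions between genetic distance and recombination fraction
#'
#' The Kosambi map function converts a per-meiosis recombination fraction
#' `r` to a genetic distance in centiMorgans, d = 25 * log((1 + 2r)/(1 - 2r)),
#' with inverse r = tanh(d/50) / 2. The Haldane function (no interference)
#' is d = -50 * log(1 - 2r) with inverse r = (1 - exp(-d/50)) / 2.
#'
#' @param r Recombination fraction(s) in [0, 0.5).
#' @param d Genetic distance(s) in cM, >= 0.
#' @return `kosambi_d_from_r`/`haldane_d_from_r` return cM distances;
#'   the `*_r_from_d` inverses return recombination fractions.
#' @examples
#' kosambi_d_from_r(0.1)
#' kosambi_r_from_d(kosambi_d_from_r(0.25))
#' @export
kosambi_d_from_r <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)))
  if (any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_d_from_r
#' @export
kosambi_r_from_d <- function(d) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  if (any(d < 0)) stop("genetic distance must be >= 0")
  tanh(d / 50) / 2
}

#' @rdname kosambi_d_from_r
#' @export
haldane_d_from_r <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)))
  if (any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname kosambi_d_from_r
#' @export
haldane_r_from_d <- function(d) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  if (any(d < 0)) stop("genetic distance must be >= 0")
  (1 - exp(-d / 50)) / 2
}

map_d_from_r <- function(r, map_function = c("kosambi", "haldane")) {
  switch(match.arg(map_function),
         kosambi = kosambi_d_from_r(r),
         haldane = haldane_d_from_r(r))
}

map_r_from_d <- function(d, map_function = c("kosambi", "haldane")) {
  switch(match.arg(map_function),
         kosambi = kosambi_r_from_d(d),
         haldane = haldane_r_from_d(d))
}

#' Selfed-RIL recombinant fraction and its inverse
#'
#' In a population of recombinant inbred lines derived by repeated selfing,
#' the observed fraction of (homozygous) recombinant lines between two loci
#' is inflated relative to the per-meiosis recombination fraction r by the
#' Haldane-Waddington relation R = 2r / (1 + 2r). `rf_from_ril_R` inverts
#' it, r = R / (2 (1 - R)); `ril_R_from_r` applies it.
#'
#' Observed fractions at or above 0.5 (possible under sampling noise) are
#' clamped to 0.4999 with a warning rather than rejected.
#'
#' @param R Observed RIL recombinant fraction(s), >= 0.
#' @param r Per-meiosis recombination fraction(s) in [0, 0.5].
#' @return Recombination fraction r, or observed fraction R.
#' @export
rf_from_ril_R <- function(R) {
  stopifnot(is.numeric(R), all(is.finite(R)))
  if (any(R < 0)) stop("observed recombinant fraction must be >= 0")
  clamped <- R >= 0.5
  if (any(clamped)) {
    warning(sum(clamped), " recombinant fraction(s) >= 0.5 clamped to 0.4999")
    R[clamped] <- 0.4999
  }
  R / (2 * (1 - R))
}

#' @rdname rf_from_ril_R
#' @export
ril_R_from_r <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)), all(r >= 0), all(r <= 0.5))
  2 * r / (1 + 2 * r)
}
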