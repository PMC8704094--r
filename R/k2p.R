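#' Kimura two-parameter distance
#'
#' Evolutionary distance correcting observed divergence with separate
#' transition and transversion proportions:
#' \deqn{d = -\tfrac12 \ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)}
#' where `P` and `Q` are the transition and transversion proportions over the
#' compared sites. Returns `NA` (an undefined-distance signal, not an error)
#' when no sites were compared or when a log argument is non-positive
#' (saturation).
#'
#' @param counts A [substitution_counts()] row, or the transition proportion
#'   `P` as a number.
#' @param Q Transversion proportion when `counts` is numeric.
#' @return The K2P distance as a fraction, or `NA_real_` when undefined.
#' @examples
#' k2p_distance(0.10, 0.05)
#' @export
k2p_distance <- function(counts, Q = NULL) {
  pq <- as_pq(counts, Q)
  P <- pq$P
  Q <- pq$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  out <- ifelse(is.na(P) | is.na(Q) | w1 <= 0 | w2 <= 0,
                NA_real_,
                -0.5 * log(w1) - 0.25 * log(w2))
  unname(out)
}

#' Uncorrected p-distance
#'
#' Observed proportion of differing sites, `P + Q`.
#'
#' @inheritParams k2p_distance
#' @return The p-distance as a fraction, or `NA_real_` when undefined.
#' @export
p_distance <- function(counts, Q = NULL) {
  pq <- as_pq(counts, Q)
  unname(pq$P + pq$Q)
}

as_pq <- function(counts, Q) {
  if (is.data.frame(counts)) {
    list(P = counts$P, Q = counts$Q)
  } else if (is.numeric(counts) && !is.null(Q)) {
    list(P = counts, Q = Q)
  } else {
    abort("expected a substitution_counts() row or numeric P and Q")
  }
}

#' Round half-even to a fixed number of decimals
#'
#' Reports print percent distances rounded half-even to one decimal, matching
#' the precision barcode studies publish (e.g. "1.3%", "8.2%"). Base
#' `round()` already implements IEC 60559 half-even rounding; this wrapper
#' exists so the convention is named and testable.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_even <- function(x, digits = 1) round(x, digits)
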