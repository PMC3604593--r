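#' Hand-constructed five-gene geometry fixture
#'
#' A deterministic two-axis layout of five gene positions around one
#' condition direction, used in tests and documentation to pin down the
#' qualitative behavior of the closeness measure: two genes tight against
#' the direction at different distances from the origin (both closeness
#' values above 0.9, only the farther one differing through the norm
#' filter), one gene on the opposite side of the origin (negative
#' closeness), one gene near the origin (small norm, removed by the filter)
#' and one gene exactly orthogonal to the direction (closeness 0).
#'
#' @return A list of class `geometry_fixture` with `points` (5 x 2 matrix,
#'   rows g1..g5), `direction` (length-2 vector) and `expected` (the
#'   qualitative expectations as a named list, asserted verbatim by the test
#'   suite).
#' @examples
#' fx <- figure1_fixture()
#' cd_value(fx$points["g2", ], fx$direction) < 0
#' @export
figure1_fixture <- function() {
  points <- rbind(
    g1 = c(1.60, 0.45),   # near the direction, moderate norm
    g2 = c(-2.20, -0.40), # opposite side of the origin: negative closeness
    g3 = c(4.00, 1.05),   # near the direction, far from the origin
    g4 = c(0.05, -0.10),  # near the origin: filtered out
    g5 = c(-0.50, 2.00)   # exactly orthogonal to the direction
  )
  colnames(points) <- c("axis1", "axis2")
  structure(list(
    points = points,
    direction = c(2, 0.5),
    expected = list(
      positive_high = c("g1", "g3"),  # closeness > 0.9
      negative = "g2",                # sign(closeness) = -1
      near_zero = c("g4", "g5"),      # |closeness| < 0.3
      filtered = "g4"                 # smallest norm, removed by the filter
    )
  ), class = "geometry_fixture")
}
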