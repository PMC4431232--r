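#' Giant magnetoresistance from reduced magnetization
#'
#' For a granular magnetic system the characteristic magnetoresistance
#' follows the total magnetization as
#' \deqn{GMR(M) = A_{GMR}\left[1 - (M/M_s)^2\right]}
#' maximal (equal to the effect amplitude) where the net magnetization
#' crosses zero and vanishing at saturation.
#'
#' @param m_reduced Reduced magnetization M/Ms in \[-1, 1\]. Vectorized.
#' @param amplitude Effect amplitude \eqn{A_{GMR}} in percent; the
#'   default 20 matches the granular Co/agarose experiments this model
#'   was calibrated against.
#' @return GMR in percent, in \[0, amplitude\].
#' @examples
#' gmr_from_m(0)     # 20
#' gmr_from_m(0.5)   # 15
#' gmr_from_m(1)     # 0
#' @export
gmr_from_m <- function(m_reduced, amplitude = 20) {
  if (any(abs(m_reduced) > 1 + 1e-12))
    stop("|m_reduced| must not exceed 1")
  stopifnot(amplitude >= 0)
  m_reduced <- pmin(pmax(m_reduced, -1), 1)
  amplitude * (1 - m_reduced^2)
}

#' GMR characteristic curve from a magnetization curve
#'
#' Applies [gmr_from_m()] elementwise to a field-sweep magnetization
#' curve, preserving the field ordering.
#'
#' @param mag_curve Data frame with columns `B` (T) and `m_reduced`
#'   (e.g. `magnetization_curve(...)$curve`).
#' @param amplitude Effect amplitude in percent.
#' @return A `gmr_curve` data frame `B, m_reduced, gmr_percent` with the
#'   amplitude stored as attribute `amplitude`.
#' @export
gmr_curve <- function(mag_curve, amplitude = 20) {
  stopifnot(all(c("B", "m_reduced") %in% names(mag_curve)))
  out <- data.frame(B = mag_curve$B, m_reduced = mag_curve$m_reduced,
                    gmr_percent = gmr_from_m(mag_curve$m_reduced,
                                             amplitude))
  attr(out, "amplitude") <- amplitude
  class(out) <- c("gmr_curve", class(out))
  out
}
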