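## C-index-weighted consensus of member prediction surfaces (typically the
## GLM-averaged and GAM-averaged surfaces for one response).

#' Weighted-average ensemble of prediction surfaces
#'
#' Per cell `i`, `WA_i = sum_j C_j * m_ji / sum_j C_j`, where `m_ji` is
#' member `j`'s prediction and `C_j` its pre-evaluated concordance index: a
#' convex combination, invariant to rescaling all `C_j` by a constant. A
#' cell is no-data in the ensemble iff it is no-data in any member.
#'
#' @param members List of `sdm_surface` objects on a common grid (or plain
#'   numeric vectors of equal length).
#' @param c_index Numeric vector of member C-indices, in (0, 1].
#' @param response,label Metadata for the returned surface.
#' @return An `sdm_surface` (or plain vector if members were vectors).
#' @examples
#' weighted_average_ensemble(list(c(0.6), c(0.4)), c(0.86, 0.81))
#' @export
weighted_average_ensemble <- function(members, c_index,
                                      response = "ensemble",
                                      label = "summary") {
  if (length(members) < 1) stop("need at least one member", call. = FALSE)
  if (length(members) != length(c_index))
    stop("one C-index per member required", call. = FALSE)
  if (any(!is.finite(c_index)) || any(c_index <= 0))
    stop("C-index weights must be finite and > 0", call. = FALSE)
  is_surface <- vapply(members, inherits, logical(1), "sdm_surface")
  if (any(is_surface)) {
    if (!all(is_surface))
      stop("mix of surfaces and plain vectors", call. = FALSE)
    g <- attr(members[[1]], "grid")
    for (m in members[-1])
      if (!same_grid(g, attr(m, "grid")))
        stop("member surfaces are on different grids", call. = FALSE)
  }
  lens <- vapply(members, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("member surfaces have different lengths", call. = FALSE)
  num <- Reduce(`+`, Map(function(m, c) c * as.numeric(m), members,
                         as.list(c_index)))
  wa <- num / sum(c_index)
  if (any(is_surface))
    sdm_surface(wa, attr(members[[1]], "grid"), response, label)
  else wa
}
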