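# Unit conversions used at the reporting boundary. Geometry is handled in mm,
# the flow solver works in SI (m, s, Pa), and results are reported in the
# CGS-style units conventional in vascular biomechanics (cm/s, dyne/cm^2, ...).

MM_PER_M <- 1000
CM_PER_M <- 100
PA_PER_DYNE_CM2 <- 0.1       # 1 dyne/cm^2 = 0.1 Pa
PA_PER_MMHG <- 133.322387415

mm_to_m <- function(x) x / MM_PER_M
m_to_mm <- function(x) x * MM_PER_M
cm_s_to_m_s <- function(x) x / CM_PER_M
m_s_to_cm_s <- function(x) x * CM_PER_M
pa_to_dyne_cm2 <- function(x) x / PA_PER_DYNE_CM2
pa_m_to_dyne_cm3 <- function(x) x / PA_PER_DYNE_CM2 / CM_PER_M

#' Symmetric relative difference between two scalars
#'
#' The convergence metric used by the mesh- and time-step-independence
#' protocols: `|a - b| / ((|a| + |b|) / 2)`, reported in percent. It is
#' symmetric in its arguments and always non-negative.
#'
#' @param a,b numeric scalars.
#' @return Relative difference in percent.
#' @export
relative_difference <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  denom <- (abs(a) + abs(b)) / 2
  if (denom == 0) return(0)
  100 * abs(a - b) / denom
}

# stop() with a machine-checkable condition class
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "avflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
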