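#' Thresholds of the threshold-based stress metrics
#'
#' Defaults as used in the osteoarthritis literature the metrics come
#' from: supra-threshold area counts stress above 9.5 MPa, the Maxian
#' overdose accumulates stress above 6 MPa, and the supra-threshold
#' elevated (STE) contact area relates cumulative stress above
#' 5.5 MPa*s to area ever stressed above 4 MPa.
#'
#' @param suprathreshold_stress MPa.
#' @param maxian_stress MPa.
#' @param ste_dose MPa*s.
#' @param ste_stress MPa.
#' @return object of class `metric_thresholds`.
#' @export
metric_thresholds <- function(suprathreshold_stress = 9.5,
                              maxian_stress = 6,
                              ste_dose = 5.5,
                              ste_stress = 4) {
  vals <- c(suprathreshold_stress, maxian_stress, ste_dose, ste_stress)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(suprathreshold_stress = suprathreshold_stress,
                 maxian_stress = maxian_stress,
                 ste_dose = ste_dose, ste_stress = ste_stress),
            class = "metric_thresholds")
}

.check_seq <- function(seq) {
  if (!inherits(seq, "gait_stress_sequence"))
    stop("expected a gait_stress_sequence")
  if (length(seq$fields) == 0L) stop("empty stress sequence")
  invisible(seq)
}

# per-instance stress/area matrices (elements x instances)
.seq_matrices <- function(seq) {
  p <- vapply(seq$fields, function(f) f$element_stress,
              numeric(length(seq$fields[[1L]]$element_stress)))
  a <- vapply(seq$fields, function(f) f$element_area,
              numeric(length(seq$fields[[1L]]$element_area)))
  list(p = matrix(p, ncol = seq$t), a = matrix(a, ncol = seq$t))
}

#' Absolute peak stress (MPa)
#'
#' Largest elemental contact stress over all elements and instances.
#' @param seq a `gait_stress_sequence`.
#' @export
absolute_peak_stress <- function(seq) {
  .check_seq(seq)
  max(vapply(seq$fields, function(f) max(f$element_stress), 0))
}

#' Average peak stress (MPa)
#'
#' Mean over instances of the per-instance peak elemental stress.
#' @param seq a `gait_stress_sequence`.
#' @export
average_peak_stress <- function(seq) {
  .check_seq(seq)
  mean(vapply(seq$fields, function(f) max(f$element_stress), 0))
}

#' Peak stress-time dose (MPa*s)
#'
#' Maximum over elements of the element's time-integrated stress
#' sum_j p_ij * dt.
#' @param seq a `gait_stress_sequence`.
#' @export
peak_stress_time_dose <- function(seq) {
  .check_seq(seq)
  m <- .seq_matrices(seq)
  max(rowSums(m$p) * seq$dt)
}

#' Average contact area (% of total acetabular area)
#'
#' 100 / (A t) * sum over instances of the area in contact
#' (stress > 0 MPa).
#' @param seq a `gait_stress_sequence`.
#' @export
average_contact_area <- function(seq) {
  .check_seq(seq)
  m <- .seq_matrices(seq)
  100 * sum(m$a * (m$p > 0)) / (seq$total_area * seq$t)
}

#' Average stress (MPa)
#'
#' Mean over instances of the area-weighted mean stress of the elements
#' in contact (stress > 0 MPa); instances without contact contribute 0.
#' @param seq a `gait_stress_sequence`.
#' @export
average_stress <- function(seq) {
  .check_seq(seq)
  m <- .seq_matrices(seq)
  per <- vapply(seq_len(seq$t), function(j) {
    sel <- m$p[, j] > 0
    if (!any(sel)) return(0)
    sum(m$p[sel, j] * m$a[sel, j]) / sum(m$a[sel, j])
  }, 0)
  mean(per)
}

#' Average supra-threshold area (% of total acetabular area)
#'
#' As [average_contact_area()] but counting only elements whose stress
#' exceeds the supra-threshold stress (default 9.5 MPa).
#' @param seq a `gait_stress_sequence`.
#' @param thr a [metric_thresholds()].
#' @export
average_suprathreshold_area <- function(seq, thr = metric_thresholds()) {
  .check_seq(seq)
  m <- .seq_matrices(seq)
  100 * sum(m$a * (m$p > thr$suprathreshold_stress)) /
    (seq$total_area * seq$t)
}

#' Maxian overdose (MPa*s)
#'
#' Time-accumulated area-weighted mean stress of the elements exceeding
#' the Maxian threshold (default 6 MPa); instances with no such element
#' contribute 0.
#' @param seq a `gait_stress_sequence`.
#' @param thr a [metric_thresholds()].
#' @export
maxian_overdose <- function(seq, thr = metric_thresholds()) {
  .check_seq(seq)
  m <- .seq_matrices(seq)
  per <- vapply(seq_len(seq$t), function(j) {
    sel <- m$p[, j] > thr$maxian_stress
    if (!any(sel)) return(0)
    sum(m$p[sel, j] * m$a[sel, j]) / sum(m$a[sel, j])
  }, 0)
  sum(per) * seq$dt
}

#' Supra-threshold elevated contact area (STE, %)
#'
#' 100 times the area of elements whose cumulative stress-time dose
#' exceeds the dose threshold (default 5.5 MPa*s), relative to the area
#' of elements ever stressed above the stress threshold (default 4 MPa);
#' defined as 0 when the denominator set is empty.
#' @param seq a `gait_stress_sequence`.
#' @param thr a [metric_thresholds()].
#' @export
ste_contact_area <- function(seq, thr = metric_thresholds()) {
  .check_seq(seq)
  m <- .seq_matrices(seq)
  a <- m$a[, 1L]
  dose <- rowSums(m$p) * seq$dt
  ever <- apply(m$p, 1L, max) > thr$ste_stress
  if (!any(ever)) return(0)
  100 * sum(a[dose > thr$ste_dose]) / sum(a[ever])
}

#' All eight stress metrics
#'
#' @param seq a `gait_stress_sequence`.
#' @param thr a [metric_thresholds()].
#' @return named list with the eight metrics: `absolute_peak_stress`,
#'   `average_peak_stress`, `peak_stress_time_dose`,
#'   `average_contact_area`, `average_stress`,
#'   `average_suprathreshold_area`, `maxian_overdose`,
#'   `ste_contact_area`.
#' @export
compute_stress_metrics <- function(seq, thr = metric_thresholds()) {
  .check_seq(seq)
  list(
    absolute_peak_stress = absolute_peak_stress(seq),
    average_peak_stress = average_peak_stress(seq),
    peak_stress_time_dose = peak_stress_time_dose(seq),
    average_contact_area = average_contact_area(seq),
    average_stress = average_stress(seq),
    average_suprathreshold_area = average_suprathreshold_area(seq, thr),
    maxian_overdose = maxian_overdose(seq, thr),
    ste_contact_area = ste_contact_area(seq, thr)
  )
}

#' Names of the eight stress metrics
#' @export
stress_metric_names <- function() {
  c("absolute_peak_stress", "average_peak_stress", "peak_stress_time_dose",
    "average_contact_area", "average_stress", "average_suprathreshold_area",
    "maxian_overdose", "ste_contact_area")
}
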