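# Closed-form assay formulas used alongside sponge experiments. All are
# vectorized over their numeric arguments.

#' Relative expression by the 2^-ddCt method
#'
#' Computes `2^-((ct_target - ct_reference) -
#' (ct_target_calibrator - ct_reference_calibrator))`: the fold change
#' of a target gene relative to reference gene(s), normalized to a
#' calibrator sample. Equals 1 when ddCt = 0; each one-cycle decrease in
#' `ct_target` doubles the result.
#'
#' @param ct_target,ct_reference sample cycle thresholds (cycles).
#' @param ct_target_calibrator,ct_reference_calibrator calibrator
#'   cycle thresholds.
#' @return Fold change (dimensionless), vectorized.
#' @examples
#' relative_expression(25, 20, 24, 21)  # 2^-2 = 0.25
#' @export
relative_expression <- function(ct_target, ct_reference,
                                ct_target_calibrator,
                                ct_reference_calibrator) {
  cts <- cbind(ct_target, ct_reference, ct_target_calibrator,
               ct_reference_calibrator)
  if (!all(is.finite(cts)))
    stop("all Ct values must be finite", call. = FALSE)
  if (any(cts <= 0 | cts >= 45))
    warning("Ct value(s) outside the usual (0, 45) cycle range")
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}

#' Batch 2^-ddCt over a Ct table
#'
#' @param x data.frame (or TSV path) with columns `ct_target`,
#'   `ct_reference`, `ct_target_calibrator`, `ct_reference_calibrator`.
#' @return The input data.frame with a `fold_change` column appended.
#' @export
relative_expression_table <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x)
  need <- c("ct_target", "ct_reference", "ct_target_calibrator",
            "ct_reference_calibrator")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x$fold_change <- relative_expression(
    x$ct_target, x$ct_reference,
    x$ct_target_calibrator, x$ct_reference_calibrator)
  x
}

#' Spheroid volume from two perpendicular diameters
#'
#' `V = a * b^2 * pi / 6`, with `a` the largest diameter and `b` the
#' largest diameter perpendicular to it (both in mm). For a = b = d this
#' is exactly the sphere volume `pi d^3 / 6`.
#'
#' @param a,b diameters in mm; requires `a >= b > 0`.
#' @return Volume in mm^3, vectorized.
#' @examples
#' spheroid_volume(1, 1)  # pi/6
#' @export
spheroid_volume <- function(a, b) {
  if (!all(is.finite(a) & is.finite(b)))
    stop("diameters must be finite", call. = FALSE)
  if (any(b <= 0)) stop("diameters must be positive", call. = FALSE)
  if (any(a < b))
    stop("'a' must be the largest diameter (a >= b)", call. = FALSE)
  a * b^2 * pi / 6
}

#' Batch spheroid volume over a diameter table
#'
#' @param x data.frame (or TSV path) with columns `a` and `b` (mm).
#' @return The input data.frame with a `volume_mm3` column appended.
#' @export
spheroid_volume_table <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x)
  if (!all(c("a", "b") %in% names(x)))
    stop("diameter table needs columns 'a' and 'b'", call. = FALSE)
  x$volume_mm3 <- spheroid_volume(x$a, x$b)
  x
}

#' Relative spheroid volume
#'
#' Growth ratio `volume at day x / volume at day 0`.
#'
#' @param v_day_x,v_day0 volumes (mm^3); `v_day0` must be positive.
#' @return Dimensionless ratio, vectorized.
#' @export
relative_volume <- function(v_day_x, v_day0) {
  if (any(!is.finite(v_day0)) || any(v_day0 <= 0))
    stop("day-0 volume must be positive and finite", call. = FALSE)
  v_day_x / v_day0
}

#' Percent inhibition relative to a baseline
#'
#' `(1 - treated / control) * 100`. The baseline may be either the
#' untreated control or a vehicle/empty-vector control measured at the
#' same timepoint; pass whichever is appropriate as `control`.
#'
#' @param treated measurement under treatment.
#' @param control baseline measurement; must be non-zero.
#' @return Percent inhibition (0 when treated equals control),
#'   vectorized.
#' @examples
#' percent_inhibition(0.532, 1)  # 46.8
#' @export
percent_inhibition <- function(treated, control) {
  if (any(!is.finite(control)) || any(control == 0))
    stop("control must be finite and non-zero", call. = FALSE)
  (1 - treated / control) * 100
}
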