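# Per-tooth rotation, inclination and angulation, and delta movements
# between time points -- the method's core trigonometry.
#
# Sign conventions (all documented in the README because every angle sign
# depends on them):
#   * rotation alpha = atan2(xm - xd, ym - yd) over the frame XY coordinates
#     of the mesial (m) and distal (d) landmarks: the signed angle from the
#     +Y axis to the distal->mesial line, positive towards +X;
#   * before inclination/angulation are read, each tooth is realigned by the
#     Z rotation that brings its distal->mesial line onto +Y ("resetting the
#     rotation"), which in the right-handed convention of rotation_about_z()
#     is a rotation by +alpha;
#   * with v = occlusal - vestibular gingival in realigned coordinates,
#     inclination = atan2(v_x, v_z) (projection on XZ against Z) and
#     angulation = atan2(v_y, v_z) (projection on YZ against Z).

wrap_angle <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  ifelse(out <= -180, out + 360, out)
}

#' Rotation of one tooth in a reference frame
#'
#' The rotation is the signed angle between the tooth's mesiodistal line and
#' the anteroposterior (Y) axis, read in the occlusal (XY) plane of the
#' frame and obtained by the (full-quadrant) arctangent of the coordinate
#' differences.
#'
#' @param tooth a [tooth_landmarks()] object (model coordinates).
#' @param frame a [build_reference_frame()] result.
#' @return rotation in degrees, in (-180, 180].
#' @export
measure_rotation <- function(tooth, frame) {
  f <- to_frame_coords(unclass(tooth), frame)
  dx <- f["mesial", "x"] - f["distal", "x"]
  dy <- f["mesial", "y"] - f["distal", "y"]
  if (sqrt(dx^2 + dy^2) < 1e-9)
    stop("tooth ", attr(tooth, "tooth_id"),
         ": mesial-distal line degenerates in the occlusal plane",
         call. = FALSE)
  wrap_angle(atan2(dx, dy) * 180 / pi)
}

#' Inclination and angulation of one tooth, after rotation reset
#'
#' Reorients the tooth with a rotational matrix so that its mesiodistal line
#' coincides with the Y axis (resetting the rotation -- essential so that
#' tooth rotation does not contaminate the other two angles), then reads,
#' for the line from the vestibular gingival to the occlusal landmark:
#' the angulation as the angle between its projection on the YZ plane and
#' the Z axis, and the inclination as the angle between its projection on
#' the XZ plane and the Z axis, both by the arctangent function.
#'
#' @inheritParams measure_rotation
#' @return list with `rotation_deg`, `inclination_deg`, `angulation_deg`
#'   (degrees) and `rotated_coords` (the five landmarks after the rotation
#'   reset, frame coordinates, mm).
#' @export
measure_inclination_angulation <- function(tooth, frame) {
  alpha <- measure_rotation(tooth, frame)
  f <- to_frame_coords(unclass(tooth), frame)
  rz <- rotation_about_z(alpha)
  rot <- f %*% t(rz$rotation)           # realigned: distal->mesial along +Y
  dimnames(rot) <- dimnames(f)
  v <- rot["occlusal", ] - rot["vestibular_gingival", ]
  if (sqrt(sum(v^2)) < 1e-9)
    stop("tooth ", attr(tooth, "tooth_id"), ": crown line degenerates",
         call. = FALSE)
  if (v["z"] <= 0)
    warning("tooth ", attr(tooth, "tooth_id"),
            ": crown line does not point occlusally (v_z <= 0)",
            call. = FALSE)
  list(rotation_deg = alpha,
       inclination_deg = atan2(v[["x"]], v[["z"]]) * 180 / pi,
       angulation_deg = atan2(v[["y"]], v[["z"]]) * 180 / pi,
       rotated_coords = rot)
}

#' Measure every tooth of an arch model in a reference frame
#'
#' @param model an [arch_model()].
#' @param frame a [build_reference_frame()] result (normally built on the
#'   initial model and shared by both time points).
#' @return a data frame of class `tooth_measures` with one row per tooth:
#'   `tooth_fdi`, `rotation_deg`, `inclination_deg`, `angulation_deg`, and
#'   the 15 post-realignment coordinate columns `rot_<landmark>_<axis>`.
#'   Teeth failing degeneracy checks abort with the tooth id in the message.
#' @export
measure_arch <- function(model, frame) {
  stopifnot(inherits(model, "arch_model"))
  rows <- lapply(names(model$teeth), function(id) {
    m <- measure_inclination_angulation(model$teeth[[id]], frame)
    rc <- m$rotated_coords
    coords <- as.list(as.numeric(t(rc)))
    names(coords) <- paste0("rot_", rep(rownames(rc), each = 3), "_",
                            rep(c("x", "y", "z"), times = 5))
    c(list(tooth_fdi = id, rotation_deg = m$rotation_deg,
           inclination_deg = m$inclination_deg,
           angulation_deg = m$angulation_deg), coords)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out$patient_id <- model$patient_id
  out$arch <- model$arch
  out$timepoint <- model$timepoint
  class(out) <- c("tooth_measures", "data.frame")
  out
}

#' Per-tooth angular change between two sets of measurements
#'
#' Computes delta = final - initial for rotation, inclination and angulation
#' on the teeth present in both tables (inner join on the tooth code; teeth
#' present on one side only are dropped with a warning).  Delta rotation is
#' wrapped to (-180, 180]; inclination and angulation are plain differences
#' (their magnitudes stay below 90 degrees).
#'
#' @param initial,final `tooth_measures` data frames from [measure_arch()].
#' @return data frame with `tooth_fdi`, `d_rotation_deg`,
#'   `d_inclination_deg`, `d_angulation_deg`.
#' @export
compute_deltas <- function(initial, final) {
  only_i <- setdiff(initial$tooth_fdi, final$tooth_fdi)
  only_f <- setdiff(final$tooth_fdi, initial$tooth_fdi)
  if (length(only_i) || length(only_f))
    warning("teeth present at one time point only were dropped: ",
            paste(c(only_i, only_f), collapse = ", "), call. = FALSE)
  ids <- intersect(initial$tooth_fdi, final$tooth_fdi)
  i <- initial[match(ids, initial$tooth_fdi), ]
  f <- final[match(ids, final$tooth_fdi), ]
  data.frame(tooth_fdi = ids,
             d_rotation_deg = wrap_angle(f$rotation_deg - i$rotation_deg),
             d_inclination_deg = f$inclination_deg - i$inclination_deg,
             d_angulation_deg = f$angulation_deg - i$angulation_deg,
             stringsAsFactors = FALSE)
}
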