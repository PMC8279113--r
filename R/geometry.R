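# Reference-frame geometry: total least-squares plane fit, the occlusal
# (Plane 1) / median (Plane 2) construction, and rotation primitives.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Total least-squares plane through a 3D point set
#'
#' Fits the plane minimising the sum of squared orthogonal distances: it
#' passes through the centroid and its normal is the smallest principal
#' direction of the centred point set (smallest right singular vector).
#'
#' @param points numeric n x 3 matrix, n >= 3, not collinear.
#' @param hint orientation hint: the returned normal is flipped, if needed,
#'   to have a positive dot product with `hint`.
#'
#' @return An object of class `plane3`: list with `point` (the centroid) and
#'   unit `normal`.
#' @export
fit_plane_lsq <- function(points, hint = c(0, 0, 1)) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop("plane fitting needs at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  # collinear points leave only one non-vanishing singular value
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("degenerate geometry: points are collinear", call. = FALSE)
  normal <- sv$v[, 3]
  if (sum(normal * hint) < 0) normal <- -normal
  structure(list(point = unname(ctr), normal = unname(unit(normal))),
            class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat("Plane through (", paste(sprintf("%.3f", x$point), collapse = ", "),
      ") with normal (", paste(sprintf("%.4f", x$normal), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

project_onto_plane <- function(p, plane) {
  d <- sum((p - plane$point) * plane$normal)
  p - d * plane$normal
}

#' Frame-construction options
#'
#' @param median how the median plane (Plane 2) is constructed:
#'   `"incisor_midpoint"` (default) places it through the occlusal-plane
#'   projections of the central-incisor mesial midpoint and the lingual
#'   gingival centroid, which is intrinsic to the dentition;
#'   `"native_xz"` takes the median normal proportional to
#'   `normal1 x (0, 1, 0)`, i.e. perpendicular to the occlusal plane and the
#'   scanner's native XZ plane, which inherits the scan orientation.
#' @param exclude_teeth FDI codes excluded from the occlusal-plane fit and
#'   from whole-arch alignment; `NULL` (default) means the second molars.
#' @return list of class `frame_config`.
#' @export
frame_config <- function(median = c("incisor_midpoint", "native_xz"),
                         exclude_teeth = NULL) {
  structure(list(median = match.arg(median), exclude_teeth = exclude_teeth),
            class = "frame_config")
}

#' Build the occlusal/median reference frame of an arch model
#'
#' Plane 1 (occlusal reference) is the total least-squares plane through the
#' lingual gingival landmarks of all teeth except second molars, its normal
#' oriented towards the mean occlusal landmark (occlusal side = +Z).  Plane 2
#' (median reference) is perpendicular to Plane 1 and defines the lateral X
#' axis.  The frame is right-handed: X to the patient's right, Y anterior
#' (towards the incisors), Z occlusal; its origin is the centroid of the
#' lingual gingival points used for Plane 1.
#'
#' @param model an [arch_model()] (normally the initial model).
#' @param config a [frame_config()].
#'
#' @return An object of class `reference_frame`: list with `origin`
#'   (3-vector), `axes` (3 x 3 matrix with unit rows X, Y, Z), `plane1`,
#'   `plane2` and `config`.
#' @export
build_reference_frame <- function(model, config = frame_config()) {
  stopifnot(inherits(model, "arch_model"))
  exclude <- config$exclude_teeth
  if (is.null(exclude)) exclude <- second_molar_ids()
  lg <- arch_landmark_matrix(model, "lingual_gingival", exclude = exclude)
  if (nrow(lg) < 4)
    stop("degenerate geometry: need >= 4 teeth (outside the excluded set) ",
         "with lingual gingival landmarks", call. = FALSE)
  occ <- arch_landmark_matrix(model, "occlusal", exclude = exclude)
  ctr <- colMeans(lg)
  plane1 <- fit_plane_lsq(lg, hint = colMeans(occ) - ctr)
  z <- plane1$normal

  if (config$median == "incisor_midpoint") {
    ci <- central_incisor_ids(model$arch)
    missing <- setdiff(ci, names(model$teeth))
    if (length(missing))
      stop("median = 'incisor_midpoint' needs both central incisors; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    a <- (model$teeth[[ci[1]]]["mesial", ] + model$teeth[[ci[2]]]["mesial", ]) / 2
    y <- project_onto_plane(a, plane1) - project_onto_plane(ctr, plane1)
    y <- unit(y)                       # anteroposterior, towards the incisors
    x <- unit(cross3(y, z))            # lateral; Y = Z x X then holds exactly
  } else {
    x <- unit(cross3(z, c(0, 1, 0)))
    y <- cross3(z, x)
    # orient Y anteriorly when the incisors are available
    ci <- intersect(central_incisor_ids(model$arch), names(model$teeth))
    if (length(ci)) {
      ant <- colMeans(t(vapply(model$teeth[ci], function(t) t["mesial", ],
                               numeric(3)))) - ctr
      if (sum(y * ant) < 0) { x <- -x; y <- -y }
    }
  }
  plane2 <- structure(list(point = unname(ctr), normal = unname(x)),
                      class = "plane3")
  axes <- unname(rbind(x, y, z))
  dimnames(axes) <- list(c("X", "Y", "Z"), NULL)
  structure(list(origin = unname(ctr), axes = axes, plane1 = plane1,
                 plane2 = plane2, config = config),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("Reference frame (median =", x$config$median, ")\n")
  cat("  origin:", paste(sprintf("%.3f", x$origin), collapse = ", "), "\n")
  ax <- round(x$axes, 4)
  for (r in rownames(ax))
    cat("  ", r, ": (", paste(ax[r, ], collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Express points in reference-frame coordinates
#'
#' Applies the change of basis `axes %*% (p - origin)`, so that the XY plane
#' of the result coincides with the occlusal reference plane and the YZ
#' plane with the median plane.
#'
#' @param p a 3-vector or an n x 3 matrix of points.
#' @param frame a [build_reference_frame()] result.
#' @return coordinates in the frame, same shape as `p`.
#' @export
to_frame_coords <- function(p, frame) {
  if (is.matrix(p)) {
    out <- sweep(p, 2, frame$origin) %*% t(frame$axes)
    colnames(out) <- c("x", "y", "z")
    out
  } else {
    unname(drop(frame$axes %*% (p - frame$origin)))
  }
}

#' Map frame coordinates back to model (world) coordinates
#'
#' Inverse of [to_frame_coords()].
#'
#' @inheritParams to_frame_coords
#' @export
from_frame_coords <- function(p, frame) {
  if (is.matrix(p)) {
    out <- sweep(p %*% frame$axes, 2, frame$origin, "+")
    colnames(out) <- c("x", "y", "z")
    out
  } else {
    unname(drop(crossprod(frame$axes, p)) + frame$origin)
  }
}

# ---- rigid transforms -----------------------------------------------------

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0)
    stop("'rotation' must be a proper orthogonal matrix", call. = FALSE)
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("Rigid transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Right-handed rotation about the frame Z axis
#'
#' A positive angle rotates counter-clockwise when looking down the +Z axis:
#' 90 degrees sends +X to +Y and +Y to -X.  Composing `rotation_about_z(a)`
#' with `rotation_about_z(b)` equals `rotation_about_z(a + b)`.
#'
#' @param angle_deg rotation angle in degrees.
#' @return a [rigid_transform()] with zero translation.
#' @export
rotation_about_z <- function(angle_deg) {
  stopifnot(is.finite(angle_deg))
  th <- angle_deg * pi / 180
  r <- rbind(c(cos(th), -sin(th), 0),
             c(sin(th),  cos(th), 0),
             c(0, 0, 1))
  rigid_transform(r, c(0, 0, 0))
}

# Rodrigues rotation about an arbitrary unit axis.
rotation_about_axis <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- angle_deg * pi / 180
  k <- rbind(c(0, -a[3], a[2]),
             c(a[3], 0, -a[1]),
             c(-a[2], a[1], 0))
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Apply a rigid transform to points
#'
#' @param t a [rigid_transform()].
#' @param p 3-vector or n x 3 matrix.
#' @return transformed points, `R p + translation`.
#' @export
transform_points <- function(t, p) {
  if (is.matrix(p)) {
    out <- sweep(p %*% t(t$rotation), 2, t$translation, "+")
    colnames(out) <- colnames(p)
    out
  } else {
    unname(drop(t$rotation %*% p) + t$translation)
  }
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first, then
#' `t2`.
#' @param t2,t1 [rigid_transform()] objects.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  drop(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, -drop(rt %*% t$translation))
}
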