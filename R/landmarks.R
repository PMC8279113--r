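#' The five anatomical landmarks digitised on every tooth
#'
#' Each tooth is represented by five named points: the lingual gingival,
#' mesial, distal, occlusal and vestibular (buccal) gingival landmarks.
#' Their order here is the canonical row order used by every 5 x 3
#' coordinate matrix in the package.
#'
#' @return Character vector of length five, in canonical order.
#' @export
#' @examples
#' landmark_kinds()
landmark_kinds <- function() {
  c("lingual_gingival", "mesial", "distal", "occlusal", "vestibular_gingival")
}

#' Construct the landmark set of a single tooth
#'
#' @param coords numeric 5 x 3 matrix of landmark coordinates in mm.  Rows
#'   must be named with [landmark_kinds()] (any order; they are reordered),
#'   columns are x, y, z.
#' @param tooth_id FDI two-digit tooth code (integer or string), e.g. 15 for
#'   the upper-right second premolar.
#'
#' @return An object of class `tooth_landmarks`: the coordinate matrix in
#'   canonical row order with a `tooth_id` attribute.
#' @export
tooth_landmarks <- function(coords, tooth_id) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || !identical(dim(coords), c(5L, 3L)))
    stop("'coords' must be a numeric 5 x 3 matrix", call. = FALSE)
  kinds <- landmark_kinds()
  if (is.null(rownames(coords)) || !setequal(rownames(coords), kinds))
    stop("rows of 'coords' must be named with the five landmark kinds",
         call. = FALSE)
  coords <- coords[kinds, , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")
  if (!all(is.finite(coords)))
    stop("landmark coordinates must all be finite", call. = FALSE)
  id <- as_fdi(tooth_id)
  if (sum((coords["mesial", ] - coords["distal", ])^2) == 0)
    stop("tooth ", id, ": mesial and distal landmarks coincide", call. = FALSE)
  if (sum((coords["occlusal", ] - coords["vestibular_gingival", ])^2) == 0)
    stop("tooth ", id, ": occlusal and vestibular gingival landmarks coincide",
         call. = FALSE)
  structure(coords, tooth_id = id, class = c("tooth_landmarks", "matrix", "array"))
}

#' Construct an arch model
#'
#' An arch model holds the landmark sets of one dental arch of one patient at
#' one time point.
#'
#' @param teeth list of [tooth_landmarks()] objects (or 5 x 3 matrices with
#'   landmark rownames, in which case the list must be named by FDI code).
#' @param patient_id free-text patient identifier.
#' @param arch `"upper"` or `"lower"`.
#' @param timepoint `"initial"` or `"final_planned"`.
#'
#' @return An object of class `arch_model`: a list with elements
#'   `patient_id`, `arch`, `timepoint` and `teeth` (a list of
#'   `tooth_landmarks`, named by FDI code).
#' @export
arch_model <- function(teeth, patient_id = "P1", arch = c("upper", "lower"),
                       timepoint = c("initial", "final_planned")) {
  arch <- match.arg(arch)
  timepoint <- match.arg(timepoint)
  if (!is.list(teeth) || length(teeth) == 0)
    stop("'teeth' must be a non-empty list", call. = FALSE)
  teeth <- lapply(seq_along(teeth), function(i) {
    t <- teeth[[i]]
    if (inherits(t, "tooth_landmarks")) return(t)
    id <- names(teeth)[i]
    if (is.null(id) || !nzchar(id))
      stop("unnamed plain-matrix tooth entries need list names (FDI codes)",
           call. = FALSE)
    tooth_landmarks(t, id)
  })
  ids <- vapply(teeth, function(t) attr(t, "tooth_id"), character(1))
  if (anyDuplicated(ids))
    stop("duplicate tooth ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  bad <- ids[!fdi_in_arch(ids, arch)]
  if (length(bad))
    stop("tooth ids not valid for the ", arch, " arch: ",
         paste(bad, collapse = ", "), call. = FALSE)
  names(teeth) <- ids
  structure(list(patient_id = as.character(patient_id), arch = arch,
                 timepoint = timepoint, teeth = teeth),
            class = "arch_model")
}

#' @export
print.arch_model <- function(x, ...) {
  cat("Arch model: patient ", x$patient_id, ", ", x$arch, " arch, ",
      x$timepoint, " time point\n", sep = "")
  cat("  ", length(x$teeth), " teeth: ", paste(names(x$teeth), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
format.tooth_landmarks <- function(x, ...) {
  paste0("<tooth ", attr(x, "tooth_id"), ">")
}

# ---- FDI helpers ----------------------------------------------------------

as_fdi <- function(id) {
  id <- suppressWarnings(as.integer(as.character(id)))
  if (any(is.na(id)))
    stop("tooth id is not a two-digit FDI code", call. = FALSE)
  q <- id %/% 10L
  p <- id %% 10L
  if (any(q < 1L | q > 4L | p < 1L | p > 8L))
    stop("tooth id ", paste(id, collapse = ", "),
         " is not a valid FDI code (quadrant 1-4, position 1-8)", call. = FALSE)
  sprintf("%d", id)
}

fdi_quadrant <- function(id) as.integer(as.character(id)) %/% 10L
fdi_position <- function(id) as.integer(as.character(id)) %% 10L

fdi_in_arch <- function(id, arch) {
  q <- fdi_quadrant(id)
  if (arch == "upper") q %in% c(1L, 2L) else q %in% c(3L, 4L)
}

#' Classify FDI codes into clinical tooth groups
#'
#' @param id vector of FDI codes.
#' @return factor with levels incisors, canines, premolars, molars.
#' @export
#' @examples
#' fdi_tooth_group(c(11, 13, 15, 17))
fdi_tooth_group <- function(id) {
  p <- fdi_position(id)
  g <- ifelse(p <= 2, "incisors",
              ifelse(p == 3, "canines",
                     ifelse(p <= 5, "premolars", "molars")))
  factor(g, levels = c("incisors", "canines", "premolars", "molars"))
}

is_second_molar <- function(id) fdi_position(id) == 7L

central_incisor_ids <- function(arch) {
  if (arch == "upper") c("11", "21") else c("31", "41")
}

second_molar_ids <- function(arch = NULL) {
  ids <- c("17", "27", "37", "47")
  if (is.null(arch)) return(ids)
  ids[fdi_in_arch(ids, arch)]
}

# Coordinates of one landmark kind across teeth, as an n x 3 matrix.
arch_landmark_matrix <- function(model, kind, exclude = character(0)) {
  ids <- setdiff(names(model$teeth), as.character(exclude))
  out <- t(vapply(model$teeth[ids], function(t) t[kind, ], numeric(3)))
  rownames(out) <- ids
  out
}
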