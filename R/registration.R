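# Landmark-based rigid best-fit alignment.  The clinical procedure best-fits
# dense mesh surfaces in commercial software; here the same role is played by
# exact-correspondence least-squares fitting (Kabsch) on the digitised
# landmarks.

#' Least-squares rigid fit between corresponding point sets (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' `sum || R s_i + t - t_i ||^2` over corresponding points.  Reflections are
#' excluded: the determinant is forced to +1 by flipping the sign of the
#' smallest singular direction.
#'
#' @param source,target numeric n x 3 matrices of corresponding points,
#'   n >= 3, not collinear.
#' @return a [rigid_transform()] mapping `source` onto `target`, with an
#'   `rmsd` attribute (root-mean-square residual, mm).
#' @export
kabsch_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop("'source' and 'target' must have the same number of points",
         call. = FALSE)
  if (nrow(source) < 3)
    stop("rigid fitting needs at least 3 correspondences", call. = FALSE)
  cs <- colMeans(source); ct <- colMeans(target)
  a <- sweep(source, 2, cs); b <- sweep(target, 2, ct)
  h <- crossprod(a, b)                      # 3x3 cross-covariance
  sv <- svd(h)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: correspondences are (near-)collinear",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - drop(r %*% cs)
  out <- rigid_transform(r, tr)
  attr(out, "rmsd") <- sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  out
}

#' Whole-arch best-fit alignment of a final model onto an initial model
#'
#' Performs the Kabsch fit over the concatenated five landmarks of all teeth
#' shared by the two models and not excluded (by default the second molars,
#' mirroring the occlusal-plane policy).  The returned transform maps
#' final-model coordinates into the initial model's space, so both models
#' can be measured in the single reference frame built on the initial model.
#'
#' @param initial,final [arch_model()] objects for the same arch.
#' @param exclude FDI codes excluded from the fit; `NULL` means second molars.
#' @return a [rigid_transform()] (final -> initial), with `rmsd` attribute.
#' @export
whole_arch_align <- function(initial, final, exclude = NULL) {
  stopifnot(inherits(initial, "arch_model"), inherits(final, "arch_model"))
  if (is.null(exclude)) exclude <- second_molar_ids()
  shared <- setdiff(intersect(names(initial$teeth), names(final$teeth)),
                    as.character(exclude))
  if (length(shared) < 3)
    stop("whole-arch alignment needs >= 3 shared, non-excluded teeth",
         call. = FALSE)
  src <- do.call(rbind, lapply(final$teeth[shared], unclass))
  tgt <- do.call(rbind, lapply(initial$teeth[shared], unclass))
  kabsch_fit(src, tgt)
}

#' Apply a rigid transform to every landmark of an arch model
#'
#' @param t a [rigid_transform()].
#' @param model an [arch_model()].
#' @return the transformed model; tooth and landmark identities preserved.
#' @export
apply_transform <- function(t, model) {
  stopifnot(inherits(t, "rigid_transform"), inherits(model, "arch_model"))
  model$teeth <- lapply(model$teeth, function(tooth) {
    out <- transform_points(t, unclass(tooth))
    attributes(out) <- attributes(tooth)
    out
  })
  model
}
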