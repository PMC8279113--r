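# Synthetic paired arch models with known applied movements and
# digitisation noise.  The generator places upright crown templates on a
# parabolic arch form; movements are applied per tooth, in reference-frame
# coordinates, about the tooth's landmark centroid, using the same sign
# conventions the measurement functions report, so that recovery of a
# single-axis movement is exact in the absence of noise.

default_tooth_ids <- function(arch) {
  pos <- 1:7                              # incisors .. second molar
  if (arch == "upper") {
    c(paste0(1, rev(pos)), paste0(2, pos))
  } else {
    c(paste0(4, rev(pos)), paste0(3, pos))
  }
}

# MD width, crown height, gingival (buccolingual) half-offset, in mm;
# typical adult crown dimensions.
default_crown_templates <- function() {
  data.frame(group = c("incisors", "canines", "premolars", "molars"),
             md_width_mm = c(8, 7.5, 7, 10),
             crown_height_mm = c(10, 10, 8, 7),
             gingival_offset_mm = c(3.5, 4, 4.5, 5.5),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic dental arch
#'
#' @param arch `"upper"` or `"lower"`.
#' @param tooth_ids FDI codes to place, ordered around the arch; default is
#'   the 14 routinely measured teeth (central/lateral incisors, canines,
#'   first/second premolars, first/second molars of both quadrants).
#' @param width_mm,depth_mm intermolar width and arch depth of the
#'   parabolic arch form (defaults 60 and 45 for the upper arch, slightly
#'   smaller for the lower; typical adult dimensions).
#' @param crown_templates data frame with columns `group`, `md_width_mm`,
#'   `crown_height_mm`, `gingival_offset_mm` per tooth group.
#' @param noise_sd_mm SD of isotropic Gaussian digitisation noise added to
#'   every landmark coordinate (0 = noise-free).  Default 0.05 mm, a
#'   realistic point-picking error on scanned models.
#' @param patient_id,timepoint passed to [arch_model()].
#' @param seed integer seed making generation deterministic.
#' @return list of class `arch_spec`.
#' @export
arch_spec <- function(arch = c("upper", "lower"), tooth_ids = NULL,
                      width_mm = NULL, depth_mm = NULL,
                      crown_templates = default_crown_templates(),
                      noise_sd_mm = 0.05, patient_id = "SIM1",
                      timepoint = "initial", seed = 1L) {
  arch <- match.arg(arch)
  if (is.null(tooth_ids)) tooth_ids <- default_tooth_ids(arch)
  tooth_ids <- as_fdi(tooth_ids)
  if (anyDuplicated(tooth_ids))
    stop("duplicate tooth ids in 'tooth_ids'", call. = FALSE)
  if (is.null(width_mm)) width_mm <- if (arch == "upper") 60 else 56
  if (is.null(depth_mm)) depth_mm <- if (arch == "upper") 45 else 42
  stopifnot(width_mm > 0, depth_mm > 0, noise_sd_mm >= 0)
  tpl <- crown_templates
  stopifnot(all(c("group", "md_width_mm", "crown_height_mm",
                  "gingival_offset_mm") %in% names(tpl)),
            all(tpl$md_width_mm > 0), all(tpl$crown_height_mm > 0))
  structure(list(arch = arch, tooth_ids = tooth_ids, width_mm = width_mm,
                 depth_mm = depth_mm, crown_templates = tpl,
                 noise_sd_mm = noise_sd_mm, patient_id = patient_id,
                 timepoint = timepoint, seed = as.integer(seed)),
            class = "arch_spec")
}

# run code with a local RNG state so generation is deterministic without
# clobbering the caller's stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic arch model
#'
#' Teeth are placed at equal parameter steps along the parabola
#' `y = depth (1 - (2x / width)^2)` with the incisors anterior (largest y)
#' and the gingival margin in the z = 0 plane.  Per tooth the five landmarks
#' come from an upright crown template: mesial and distal at half the
#' mesiodistal width along the local arch tangent (at mid-crown height),
#' lingual and vestibular gingival at the gingival offset on the lingual and
#' buccal sides of the arch line, and the occlusal landmark at crown height
#' directly above the vestibular gingival point, so that a noise-free arch
#' measures zero inclination and angulation for every tooth.
#'
#' @param spec an [arch_spec()].
#' @return an [arch_model()]; deterministic given `spec$seed`.
#' @export
generate_arch <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  ids <- spec$tooth_ids
  ntk <- length(ids)
  tpl <- spec$crown_templates
  grp <- as.character(fdi_tooth_group(ids))
  u <- seq(-0.92, 0.92, length.out = ntk)     # arch parameter, left to right
  half <- spec$width_mm / 2
  teeth <- with_local_seed(spec$seed, {
    lapply(seq_len(ntk), function(i) {
      x <- half * u[i]
      y <- spec$depth_mm * (1 - u[i]^2)
      c0 <- c(x, y, 0)
      # tangent of the parabola, oriented towards the anterior midline
      tan_v <- unit(c(1, -2 * spec$depth_mm * u[i] / half, 0))
      if (sum(tan_v * (c(0, spec$depth_mm, 0) - c0)) < 0) tan_v <- -tan_v
      # buccal = in-plane normal pointing away from the arch interior
      buc <- unit(cross3(tan_v, c(0, 0, 1)))
      if (sum(buc * (c0 - c(0, spec$depth_mm / 2, 0))) < 0) buc <- -buc
      p <- tpl[match(grp[i], tpl$group), ]
      vg <- c0 + p$gingival_offset_mm * buc
      coords <- rbind(
        lingual_gingival = c0 - p$gingival_offset_mm * buc,
        mesial = c0 + (p$md_width_mm / 2) * tan_v +
          c(0, 0, p$crown_height_mm / 2),
        distal = c0 - (p$md_width_mm / 2) * tan_v +
          c(0, 0, p$crown_height_mm / 2),
        occlusal = vg + c(0, 0, p$crown_height_mm),
        vestibular_gingival = vg)
      if (spec$noise_sd_mm > 0)
        coords <- coords + matrix(stats::rnorm(15, 0, spec$noise_sd_mm), 5, 3)
      tooth_landmarks(coords, ids[i])
    })
  })
  arch_model(teeth, patient_id = spec$patient_id, arch = spec$arch,
             timepoint = spec$timepoint)
}

#' Apply planned per-tooth movements to an arch model
#'
#' For each tooth listed in `movements`, in reference-frame coordinates and
#' about the tooth's five-landmark centroid, applies in fixed order:
#' rotation about the local distal-to-mesial axis by `inclination_deg`
#' (buccolingual tip), rotation about the local buccolingual axis by
#' `angulation_deg` (mesiodistal tip), rotation about the frame Z axis by
#' `rotation_deg`, then the translation.  The local axes are taken from the
#' tooth's orientation before the movement.  All three angles are specified
#' in the measurement sign convention, so a noise-free single-axis movement
#' is recovered exactly by the measurement pipeline.  Teeth without a
#' movement entry are copied unchanged.
#'
#' @param model an [arch_model()].
#' @param movements data frame with columns `tooth_fdi`, `rotation_deg`,
#'   `inclination_deg`, `angulation_deg` and optionally `tx_mm`, `ty_mm`,
#'   `tz_mm` (frame-coordinate translation).
#' @param frame the [build_reference_frame()] of `model`.
#' @return the moved [arch_model()] (same coordinate space as the input,
#'   `timepoint` set to `"final_planned"`).
#' @export
apply_movements <- function(model, movements, frame) {
  stopifnot(inherits(model, "arch_model"), inherits(frame, "reference_frame"))
  movements$tooth_fdi <- as.character(movements$tooth_fdi)
  unknown <- setdiff(movements$tooth_fdi, names(model$teeth))
  if (length(unknown))
    stop("movements given for unknown teeth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (j in seq_len(nrow(movements))) {
    mv <- movements[j, ]
    id <- mv$tooth_fdi
    f <- to_frame_coords(unclass(model$teeth[[id]]), frame)
    ctr <- colMeans(f)
    md_axis <- unit(f["mesial", ] - f["distal", ])
    bl_axis <- unit(cross3(c(0, 0, 1), md_axis))
    r <- diag(3)
    if (mv$inclination_deg != 0)
      r <- rotation_about_axis(md_axis, mv$inclination_deg) %*% r
    if (mv$angulation_deg != 0)
      r <- rotation_about_axis(bl_axis, mv$angulation_deg) %*% r
    if (mv$rotation_deg != 0)
      r <- rotation_about_axis(c(0, 0, 1), -mv$rotation_deg) %*% r
    moved <- sweep(sweep(f, 2, ctr) %*% t(r), 2, ctr, "+")
    tr <- c(if (!is.null(mv$tx_mm)) mv$tx_mm else 0,
            if (!is.null(mv$ty_mm)) mv$ty_mm else 0,
            if (!is.null(mv$tz_mm)) mv$tz_mm else 0)
    moved <- sweep(moved, 2, tr, "+")
    world <- from_frame_coords(moved, frame)
    rownames(world) <- rownames(f)
    model$teeth[[id]] <- tooth_landmarks(world, id)
  }
  model$timepoint <- "final_planned"
  model
}

#' Draw a random planned-movement table
#'
#' Gaussian per-tooth movements emulating the magnitude of aligner-planned
#' corrections: rotation SD 5 degrees, inclination and angulation SD 3
#' degrees, isotropic translation SD 0.3 mm.
#'
#' @param tooth_ids FDI codes to include.
#' @param rotation_sd,inclination_sd,angulation_sd SDs in degrees.
#' @param translation_sd SD of each translation component, mm.
#' @return movement data frame as consumed by [apply_movements()].
#' @export
random_movements <- function(tooth_ids, rotation_sd = 5, inclination_sd = 3,
                             angulation_sd = 3, translation_sd = 0.3) {
  n <- length(tooth_ids)
  data.frame(tooth_fdi = as.character(tooth_ids),
             rotation_deg = stats::rnorm(n, 0, rotation_sd),
             inclination_deg = stats::rnorm(n, 0, inclination_sd),
             angulation_deg = stats::rnorm(n, 0, angulation_sd),
             tx_mm = stats::rnorm(n, 0, translation_sd),
             ty_mm = stats::rnorm(n, 0, translation_sd),
             tz_mm = stats::rnorm(n, 0, translation_sd),
             stringsAsFactors = FALSE)
}

#' Generate a cohort of paired initial/final arch models with ground truth
#'
#' Emulates a clinical sample of aligner patients: per replicate (patient)
#' and arch, an initial model is generated, the reference frame is built on
#' its noise-free version, planned movements are applied, and independent
#' digitisation noise is added to both time points.  The returned ground
#' truth is the movement table actually applied, in the same schema the
#' agreement analysis consumes.
#'
#' @param spec an [arch_spec()] template (its `arch`, geometry, templates
#'   and `noise_sd_mm` are used; seeds are derived per replicate from
#'   `seed`).
#' @param movements either `NULL` (a fresh [random_movements()] table per
#'   replicate) or a fixed movement data frame applied to every replicate.
#' @param replicates number of patients to simulate (>= 1).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param dir optional directory: when given, landmark CSVs for both time
#'   points and the ground-truth movement table are written there.
#' @return list of class `paired_dataset`: elements `pairs` (list of lists
#'   with `initial`, `final`, `truth`) and `truth` (row-bound ground-truth
#'   table with `patient_id` and `arch` columns).
#' @export
generate_paired_dataset <- function(spec, movements = NULL, replicates = 14,
                                    seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "arch_spec"), replicates >= 1)
  pairs <- vector("list", replicates)
  truths <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- (as.integer(seed) * 1000L + r) %% .Machine$integer.max
    pid <- sprintf("SIM%02d", r)
    clean_spec <- spec
    clean_spec$noise_sd_mm <- 0
    clean_spec$seed <- rep_seed
    clean_spec$patient_id <- pid
    clean <- generate_arch(clean_spec)
    frame <- build_reference_frame(clean)
    mv <- with_local_seed(rep_seed + 1L, {
      if (is.null(movements)) random_movements(names(clean$teeth)) else movements
    })
    final_clean <- apply_movements(clean, mv, frame)
    add_noise <- function(m, s) {
      if (spec$noise_sd_mm <= 0) return(m)
      with_local_seed(s, {
        m$teeth <- lapply(m$teeth, function(t) {
          out <- unclass(t) + matrix(stats::rnorm(15, 0, spec$noise_sd_mm), 5, 3)
          tooth_landmarks(out, attr(t, "tooth_id"))
        })
        m
      })
    }
    initial <- add_noise(clean, rep_seed + 2L)
    final <- add_noise(final_clean, rep_seed + 3L)
    truth <- mv
    truth$patient_id <- pid
    truth$arch <- spec$arch
    pairs[[r]] <- list(initial = initial, final = final, truth = mv)
    truths[[r]] <- truth
  }
  truth_all <- do.call(rbind, truths)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ini <- do.call(rbind, lapply(pairs, function(p) landmarks_to_df(p$initial)))
    fin <- do.call(rbind, lapply(pairs, function(p) landmarks_to_df(p$final)))
    utils::write.csv(ini, file.path(dir, "landmarks_initial.csv"),
                     row.names = FALSE)
    utils::write.csv(fin, file.path(dir, "landmarks_final.csv"),
                     row.names = FALSE)
    utils::write.csv(truth_all, file.path(dir, "planned_movements.csv"),
                     row.names = FALSE)
  }
  structure(list(pairs = pairs, truth = truth_all), class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("Paired synthetic dataset:", length(x$pairs), "replicates,",
      nrow(x$truth), "tooth movements\n")
  invisible(x)
}
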