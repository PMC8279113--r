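#' Pipeline configuration
#'
#' @param median_plane how the median plane is built; see [frame_config()].
#' @param exclude_teeth FDI codes excluded from plane fitting and whole-arch
#'   alignment (`NULL` = second molars).
#' @param align should the final model be rigidly best-fitted onto the
#'   initial model before measuring?  `TRUE` reproduces the clinical
#'   procedure, where the two models arrive in unrelated scanner spaces.
#'   Use `FALSE` when both models are already expressed in one coordinate
#'   system (e.g. synthetic pairs from [apply_movements()]).
#' @param loa_multiplier multiplier of the SD for Bland-Altman limits of
#'   agreement; fixed at 1.96 by convention (overriding it is a deliberate
#'   config change).
#' @param rounding decimals used when formatting report tables; internal
#'   computation is always full precision.
#' @param seed optional integer seed for operations that draw random numbers.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(median_plane = c("incisor_midpoint", "native_xz"),
                            exclude_teeth = NULL, align = TRUE,
                            loa_multiplier = 1.96, rounding = 2, seed = NULL) {
  structure(list(median_plane = match.arg(median_plane),
                 exclude_teeth = exclude_teeth, align = isTRUE(align),
                 loa_multiplier = loa_multiplier, rounding = rounding,
                 seed = seed),
            class = "pipeline_config")
}

#' Measure tooth movement between an initial and a final planned model
#'
#' The full measurement procedure: (1) rigid whole-arch best fit of the
#' final model onto the initial one (all teeth except second molars), so
#' both models live in one space; (2) occlusal and median reference planes
#' built on the initial model and shared by both time points; (3) per-tooth
#' rotation, inclination and angulation at both time points; (4) per-tooth
#' angular changes (delta = final - initial).
#'
#' @param initial,final [arch_model()] objects for the same arch.
#' @param planned optional data frame of externally planned movements with
#'   columns `tooth_fdi`, `rotation_deg`, `inclination_deg`,
#'   `angulation_deg` (e.g. an aligner manufacturer's table of movements);
#'   when supplied, `summary()` and `plot()` report the agreement between
#'   the measured deltas and this table.
#' @param config a [pipeline_config()].
#'
#' @return An object of class `tooth_movement`: list with `frame`,
#'   `alignment` (the rigid transform applied to the final model, or `NULL`),
#'   `initial_measures`, `final_measures` (from [measure_arch()]), `deltas`
#'   (from [compute_deltas()]), `planned`, and `config`.
#' @export
#' @examples
#' spec <- arch_spec(seed = 1)
#' ini <- generate_arch(spec)
#' mov <- data.frame(tooth_fdi = "13", rotation_deg = 10,
#'                   inclination_deg = 0, angulation_deg = 0)
#' fin <- apply_movements(ini, mov, build_reference_frame(ini))
#' fit <- measure_movement(ini, fin, config = pipeline_config(align = FALSE))
#' coef(fit)["13", ]
measure_movement <- function(initial, final, planned = NULL,
                             config = pipeline_config()) {
  stopifnot(inherits(initial, "arch_model"), inherits(final, "arch_model"))
  if (initial$arch != final$arch)
    stop("initial and final models are from different arches", call. = FALSE)
  alignment <- NULL
  if (config$align) {
    alignment <- whole_arch_align(initial, final,
                                  exclude = config$exclude_teeth)
    final <- apply_transform(alignment, final)
  }
  frame <- build_reference_frame(
    initial, frame_config(median = config$median_plane,
                          exclude_teeth = config$exclude_teeth))
  mi <- measure_arch(initial, frame)
  mf <- measure_arch(final, frame)
  deltas <- compute_deltas(mi, mf)
  if (!is.null(planned)) {
    need <- c("tooth_fdi", "rotation_deg", "inclination_deg", "angulation_deg")
    if (!all(need %in% names(planned)))
      stop("'planned' must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    planned$tooth_fdi <- as.character(planned$tooth_fdi)
  }
  structure(list(frame = frame, alignment = alignment,
                 initial_measures = mi, final_measures = mf,
                 deltas = deltas, planned = planned, config = config,
                 call = match.call()),
            class = "tooth_movement")
}

#' @export
print.tooth_movement <- function(x, ...) {
  cat("Tooth movement measurement (", nrow(x$deltas), " teeth, ",
      x$initial_measures$arch[1], " arch, patient ",
      x$initial_measures$patient_id[1], ")\n", sep = "")
  if (!is.null(x$alignment)) {
    cat(sprintf("  whole-arch best fit: RMSD %.4f mm\n",
                attr(x$alignment, "rmsd")))
  }
  d <- round(x$deltas[, -1], x$config$rounding)
  cat("  delta (final - initial), degrees:\n")
  s <- apply(abs(x$deltas[, -1]), 2, function(v)
    sprintf("mean |d| %.2f, max |d| %.2f", mean(v), max(v)))
  for (nm in names(s)) cat("   ", nm, ": ", s[[nm]], "\n", sep = "")
  invisible(x)
}

#' Extract the per-tooth movement deltas
#'
#' @param object a [measure_movement()] fit.
#' @param ... unused.
#' @return numeric matrix (teeth x movements) of deltas in degrees, rows
#'   named by FDI code.
#' @export
coef.tooth_movement <- function(object, ...) {
  m <- as.matrix(object$deltas[, c("d_rotation_deg", "d_inclination_deg",
                                   "d_angulation_deg")])
  rownames(m) <- object$deltas$tooth_fdi
  colnames(m) <- c("rotation", "inclination", "angulation")
  m
}

#' @export
as.data.frame.tooth_movement <- function(x, ...) x$deltas

#' Differences between measured and planned movements
#'
#' Returns planned minus measured deltas per tooth and movement (the
#' systematic-error convention: positive values mean the method
#' underestimates the plan), or `NULL` when no planned table was supplied.
#'
#' @param object a [measure_movement()] fit with a `planned` table.
#' @param ... unused.
#' @export
residuals.tooth_movement <- function(object, ...) {
  if (is.null(object$planned)) return(NULL)
  ids <- intersect(object$deltas$tooth_fdi, object$planned$tooth_fdi)
  d <- object$deltas[match(ids, object$deltas$tooth_fdi), ]
  p <- object$planned[match(ids, object$planned$tooth_fdi), ]
  m <- cbind(rotation = p$rotation_deg - d$d_rotation_deg,
             inclination = p$inclination_deg - d$d_inclination_deg,
             angulation = p$angulation_deg - d$d_angulation_deg)
  rownames(m) <- ids
  m
}

#' Summarise a tooth-movement fit
#'
#' Per tooth-group descriptive statistics of the deltas; when a planned
#' table is attached, Bland-Altman agreement (planned vs measured) per
#' movement.
#'
#' @param object a [measure_movement()] fit.
#' @param ... unused.
#' @export
summary.tooth_movement <- function(object, ...) {
  d <- object$deltas
  grp <- fdi_tooth_group(d$tooth_fdi)
  agg <- do.call(rbind, lapply(split(d, grp), function(s) {
    if (!nrow(s)) return(NULL)
    data.frame(group = fdi_tooth_group(s$tooth_fdi[1]), n = nrow(s),
               mean_d_rotation = mean(s$d_rotation_deg),
               sd_d_rotation = stats::sd(s$d_rotation_deg),
               mean_d_inclination = mean(s$d_inclination_deg),
               sd_d_inclination = stats::sd(s$d_inclination_deg),
               mean_d_angulation = mean(s$d_angulation_deg),
               sd_d_angulation = stats::sd(s$d_angulation_deg))
  }))
  rownames(agg) <- NULL
  agreement <- NULL
  if (!is.null(object$planned)) {
    ids <- intersect(d$tooth_fdi, object$planned$tooth_fdi)
    dd <- d[match(ids, d$tooth_fdi), ]
    p <- object$planned[match(ids, object$planned$tooth_fdi), ]
    agreement <- list(
      rotation = bland_altman(p$rotation_deg, dd$d_rotation_deg, labels = ids,
                              loa_multiplier = object$config$loa_multiplier),
      inclination = bland_altman(p$inclination_deg, dd$d_inclination_deg,
                                 labels = ids,
                                 loa_multiplier = object$config$loa_multiplier),
      angulation = bland_altman(p$angulation_deg, dd$d_angulation_deg,
                                labels = ids,
                                loa_multiplier = object$config$loa_multiplier))
  }
  structure(list(groups = agg, agreement = agreement,
                 rounding = object$config$rounding),
            class = "summary.tooth_movement")
}

#' @export
print.summary.tooth_movement <- function(x, ...) {
  cat("Per-group delta statistics (degrees):\n")
  g <- x$groups
  g[-(1:2)] <- lapply(g[-(1:2)], round, x$rounding)
  print(g, row.names = FALSE)
  if (!is.null(x$agreement)) {
    cat("\nAgreement with the planned movement table (planned - measured):\n")
    for (nm in names(x$agreement)) {
      cat("\n--", nm, "--\n")
      print(x$agreement[[nm]])
    }
  }
  invisible(x)
}

#' Plot a tooth-movement fit
#'
#' With a planned table attached, draws a Bland-Altman plot of planned vs
#' measured deltas for the chosen movement; otherwise a per-tooth dot chart
#' of the measured deltas.
#'
#' @param x a [measure_movement()] fit.
#' @param movement one of `"rotation"`, `"inclination"`, `"angulation"`.
#' @param ... passed to the underlying plotting function.
#' @export
plot.tooth_movement <- function(x, movement = c("rotation", "inclination",
                                                "angulation"), ...) {
  movement <- match.arg(movement)
  col <- paste0("d_", movement, "_deg")
  if (!is.null(x$planned)) {
    ids <- intersect(x$deltas$tooth_fdi, x$planned$tooth_fdi)
    a <- x$planned[[paste0(movement, "_deg")]][match(ids, x$planned$tooth_fdi)]
    b <- x$deltas[[col]][match(ids, x$deltas$tooth_fdi)]
    plot(bland_altman(a, b, labels = ids,
                      loa_multiplier = x$config$loa_multiplier),
         main = paste("Planned vs measured:", movement), ...)
  } else {
    v <- x$deltas[[col]]
    names(v) <- x$deltas$tooth_fdi
    graphics::dotchart(v, xlab = paste("delta", movement, "(degrees)"), ...)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}
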