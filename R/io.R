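# CSV interchange: landmark tables (the canonical format), measurement /
# delta / agreement tables.  Columns and units are fixed and documented so
# files are exchangeable between the applications.

#' Flatten arch models to a landmark data frame
#'
#' @param model an [arch_model()] or a list of them.
#' @return data frame with columns `patient_id`, `arch`, `timepoint`,
#'   `tooth_fdi`, `landmark`, `x_mm`, `y_mm`, `z_mm` (long format, five rows
#'   per tooth).
#' @export
landmarks_to_df <- function(model) {
  if (inherits(model, "arch_model")) model <- list(model)
  do.call(rbind, lapply(model, function(m) {
    do.call(rbind, lapply(names(m$teeth), function(id) {
      co <- unclass(m$teeth[[id]])
      data.frame(patient_id = m$patient_id, arch = m$arch,
                 timepoint = m$timepoint, tooth_fdi = id,
                 landmark = rownames(co),
                 x_mm = co[, 1], y_mm = co[, 2], z_mm = co[, 3],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
}

#' Write arch models to a landmark CSV file
#'
#' @param model an [arch_model()] or list of them.
#' @param file output path.
#' @export
write_landmarks_csv <- function(model, file) {
  utils::write.csv(landmarks_to_df(model), file, row.names = FALSE)
  invisible(file)
}

#' Read arch models from a landmark CSV file
#'
#' The file must have a header with columns `patient_id`, `arch`,
#' `timepoint`, `tooth_fdi`, `landmark`, `x_mm`, `y_mm`, `z_mm`.  Rows are
#' grouped by (patient, arch, timepoint) into arch models; each tooth must
#' have exactly the five landmark kinds.
#'
#' @param file path to the CSV file (or a data frame in the same schema).
#' @return list of [arch_model()] objects.
#' @export
read_landmarks_csv <- function(file) {
  df <- if (is.data.frame(file)) file
        else utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("patient_id", "arch", "timepoint", "tooth_fdi", "landmark",
            "x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("landmark CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$tooth_fdi <- as.character(df$tooth_fdi)
  key <- paste(df$patient_id, df$arch, df$timepoint, df$tooth_fdi,
               df$landmark, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop("duplicate landmark row: patient ", d$patient_id, ", ", d$arch,
         " ", d$timepoint, ", tooth ", d$tooth_fdi, ", ", d$landmark,
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$landmark), landmark_kinds())
  if (length(bad_kind))
    stop("unknown landmark kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  groups <- split(df, paste(df$patient_id, df$arch, df$timepoint, sep = "\r"))
  models <- lapply(groups, function(g) {
    teeth <- lapply(split(g, g$tooth_fdi), function(tg) {
      absent <- setdiff(landmark_kinds(), tg$landmark)
      if (length(absent))
        stop("tooth ", tg$tooth_fdi[1], " (patient ", tg$patient_id[1],
             ", ", tg$arch[1], " ", tg$timepoint[1], ") is missing landmark(s): ",
             paste(toupper(absent), collapse = ", "), call. = FALSE)
      co <- as.matrix(tg[match(landmark_kinds(), tg$landmark),
                         c("x_mm", "y_mm", "z_mm")])
      rownames(co) <- landmark_kinds()
      tooth_landmarks(co, tg$tooth_fdi[1])
    })
    arch_model(teeth, patient_id = g$patient_id[1], arch = g$arch[1],
               timepoint = g$timepoint[1])
  })
  names(models) <- NULL
  models
}

#' Write measurement, delta or agreement tables to CSV
#'
#' Writes the records with a fixed column order and angles at six decimal
#' places.  A `tooth_measures` table (from [measure_arch()]) keeps its 15
#' post-realignment coordinate columns, matching the measurement
#' application's output contract (rotation, rotated coordinates,
#' inclination and angulation per tooth).
#'
#' @param records a data frame: `tooth_measures`, delta, or agreement rows.
#' @param file output path.
#' @export
write_tables <- function(records, file) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "f", digits = 6))
  lead <- intersect(c("patient_id", "arch", "timepoint", "tooth_fdi",
                      "rotation_deg", "inclination_deg", "angulation_deg"),
                    names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
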