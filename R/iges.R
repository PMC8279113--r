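# Minimal IGES 5.x reader for Point entities (Type 116), the entity kind
# produced when picked points are exported from mesh-inspection software.
# Only the fixed 80-column ASCII form is supported: columns 1-72 carry data,
# column 73 the section letter (S/G/D/P/T), columns 74-80 the sequence
# number.  All other entity types are skipped with a warning.

iges_section <- function(lines, code) {
  sel <- substring(lines, 73, 73) == code
  lines[sel]
}

# Split a free-format IGES field list, honouring Hollerith strings (nHxxx)
# which may themselves contain delimiter characters.
iges_split_fields <- function(text, pdelim, rdelim) {
  fields <- character(0)
  buf <- ""
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substring(text, i, i)
    if (grepl("^[0-9]+H", substring(text, i))) {
      m <- regmatches(substring(text, i), regexpr("^[0-9]+H", substring(text, i)))
      len <- as.integer(sub("H$", "", m))
      take <- nchar(m) + len
      buf <- paste0(buf, substring(text, i, i + take - 1L))
      i <- i + take
    } else if (ch == pdelim || ch == rdelim) {
      fields <- c(fields, buf)
      buf <- ""
      if (ch == rdelim) return(fields)
      i <- i + 1L
    } else {
      buf <- paste0(buf, ch)
      i <- i + 1L
    }
  }
  c(fields, buf)
}

#' Read Point entities from an IGES file
#'
#' Parses an IGES 5.x fixed-80-column file and returns one row per entity
#' of Type 116 (Point), with the coordinates read from its parameter-data
#' record using the parameter and record delimiters declared in the Global
#' section (defaults `,` and `;`).  Rows follow directory-entry order; the
#' label comes from the directory-entry label field (blank allowed).
#' Entities of any other type are skipped with a warning.  The Global units
#' flag must be millimetres (2) or left unspecified.
#'
#' @param file path to an IGES file, or a character vector of its lines
#'   (an unsplit single string is also accepted).
#' @return data frame with columns `seq` (directory-entry sequence number),
#'   `label`, `x`, `y`, `z` (mm); zero rows if the file holds no Point
#'   entities.
#' @export
parse_iges_points <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
  lines <- gsub("\r$", "", lines)
  lines <- formatC(lines, width = -80)            # pad to 80 columns
  if (!length(iges_section(lines, "T")))
    stop("malformed IGES file: no Terminate section", call. = FALSE)

  g <- iges_section(lines, "G")
  gtext <- sub("^\\s+", "", paste(substring(g, 1, 72), collapse = ""))
  # the delimiters declare themselves: Global field 1 is the parameter
  # delimiter, field 2 the record delimiter, each a Hollerith string or
  # empty (meaning the defaults ',' and ';')
  pdelim <- ","
  pos <- 1L
  if (startsWith(gtext, ",")) {
    pos <- 2L                                   # empty field 1: default
  } else {
    m <- regexpr("^[0-9]+H", gtext)
    if (m == -1L)
      stop("malformed IGES file: cannot read the Global delimiters",
           call. = FALSE)
    len <- as.integer(sub("H$", "", regmatches(gtext, m)))
    pdelim <- substring(gtext, attr(m, "match.length") + 1L,
                        attr(m, "match.length") + len)
    pos <- attr(m, "match.length") + len + 2L   # skip the delimiter too
  }
  rest <- substring(gtext, pos)
  rdelim <- ";"
  if (!startsWith(rest, pdelim)) {
    m <- regexpr("^[0-9]+H", rest)
    if (m == -1L)
      stop("malformed IGES file: cannot read the Global record delimiter",
           call. = FALSE)
    len <- as.integer(sub("H$", "", regmatches(rest, m)))
    rdelim <- substring(rest, attr(m, "match.length") + 1L,
                        attr(m, "match.length") + len)
  }
  gfields <- iges_split_fields(gtext, pdelim, rdelim)
  if (length(gfields) >= 14) {
    units <- suppressWarnings(as.integer(trimws(gfields[14])))
    if (!is.na(units) && units != 2L)
      stop("IGES Global units flag is ", units,
           "; only millimetres (2) are supported", call. = FALSE)
  }

  d <- iges_section(lines, "D")
  p <- iges_section(lines, "P")
  pseq <- as.integer(substring(p, 74, 80))
  if (length(d) %% 2 != 0)
    stop("malformed IGES file: odd number of directory-entry lines",
         call. = FALSE)
  n_ent <- length(d) / 2
  out <- vector("list", n_ent)
  skipped <- integer(0)
  for (e in seq_len(n_ent)) {
    l1 <- d[2 * e - 1]
    l2 <- d[2 * e]
    etype <- as.integer(substring(l1, 1, 8))
    dseq <- as.integer(substring(l1, 74, 80))
    if (is.na(etype)) next
    if (etype != 116L) {
      skipped <- c(skipped, etype)
      next
    }
    pstart <- as.integer(substring(l1, 9, 16))
    pcount <- as.integer(substring(l2, 25, 32))
    if (is.na(pcount) || pcount < 1) pcount <- 1L
    label <- trimws(substring(l2, 57, 64))
    prows <- match(pstart + seq_len(pcount) - 1L, pseq)
    if (anyNA(prows))
      stop("malformed IGES file: parameter data record ", pstart,
           " not found for directory entry ", dseq, call. = FALSE)
    ptext <- paste(sub("\\s+$", "", substring(p[prows], 1, 64)),
                   collapse = "")
    pf <- iges_split_fields(ptext, pdelim, rdelim)
    pf <- trimws(pf)
    if (length(pf) < 4)
      stop("parse error in directory entry ", dseq,
           ": Point entity needs 4 parameter fields", call. = FALSE)
    vals <- suppressWarnings(as.numeric(pf[2:4]))
    if (anyNA(vals))
      stop("parse error in directory entry ", dseq,
           ": non-numeric coordinate field", call. = FALSE)
    out[[e]] <- data.frame(seq = dseq, label = label,
                           x = vals[1], y = vals[2], z = vals[3],
                           stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " non-Point IGES entit",
            if (length(skipped) == 1) "y" else "ies", " (type ",
            paste(unique(skipped), collapse = ", "), ")", call. = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq = integer(0), label = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert extracted IGES points to a landmark table via a manifest
#'
#' Point identity is not reliably encoded in IGES exports, so a sidecar
#' manifest maps the points, in directory-entry order, to their clinical
#' identity.
#'
#' @param points data frame from [parse_iges_points()].
#' @param manifest data frame (or CSV path) with columns `patient_id`,
#'   `arch`, `timepoint`, `tooth_fdi`, `landmark`, one row per point in the
#'   same order as the IGES directory entries.
#' @return landmark data frame in the [read_landmarks_csv()] schema.
#' @export
iges_points_to_landmarks <- function(points, manifest) {
  if (!is.data.frame(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("patient_id", "arch", "timepoint", "tooth_fdi", "landmark")
  missing <- setdiff(need, names(manifest))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(manifest) != nrow(points))
    stop("manifest has ", nrow(manifest), " rows but the IGES file holds ",
         nrow(points), " points", call. = FALSE)
  cbind(manifest[need],
        data.frame(x_mm = points$x, y_mm = points$y, z_mm = points$z))
}
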