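# Shared fixture builders: all synthetic, constructed in code at test time.

# one upright tooth: crown line vertical, mesiodistal line given
make_tooth <- function(id = "11", center = c(0, 30, 0), md = 8, height = 10,
                       offset = 4, md_dir = c(1, 0, 0), buccal = c(0, 1, 0)) {
  md_dir <- md_dir / sqrt(sum(md_dir^2))
  buccal <- buccal / sqrt(sum(buccal^2))
  vg <- center + offset * buccal
  tooth_landmarks(rbind(
    lingual_gingival = center - offset * buccal,
    mesial = center + (md / 2) * md_dir + c(0, 0, height / 2),
    distal = center - (md / 2) * md_dir + c(0, 0, height / 2),
    occlusal = vg + c(0, 0, height),
    vestibular_gingival = vg), id)
}

# noise-free default upper arch + its frame
make_clean_arch <- function(arch = "upper", seed = 1) {
  generate_arch(arch_spec(arch = arch, noise_sd_mm = 0, seed = seed))
}

random_rigid_transform <- function() {
  # uniform random rotation via QR of a Gaussian matrix, det forced to +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, rnorm(3, 0, 20))
}

rotate_tooth_about_z <- function(tooth, angle_deg, about = NULL) {
  co <- unclass(tooth)
  if (is.null(about)) about <- colMeans(co)
  r <- rotation_about_z(angle_deg)$rotation
  out <- sweep(sweep(co, 2, about) %*% t(r), 2, about, "+")
  rownames(out) <- rownames(co)
  tooth_landmarks(out, attr(tooth, "tooth_id"))
}

# brute-force definitional two-way ANOVA ICC(A,1): sums of squares assembled
# from the definitional formulas, cell by cell
icc_a1_bruteforce <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# minimal IGES writer (fixtures only): point entities with configurable
# delimiters, built field by field in the fixed 80-column layout
make_iges <- function(points = list(), labels = NULL, pdelim = ",",
                      rdelim = ";", units_flag = 2, extra_entity = FALSE,
                      terminate = TRUE, wrap_params = FALSE,
                      declare_delims = TRUE) {
  pad <- function(s, code, n) sprintf("%-72s%s%7d", s, code, n)
  lines <- pad("synthetic point export", "S", 1)
  hol <- function(s) sprintf("%dH%s", nchar(s), s)
  # fields 1 and 2: explicit Hollerith declarations, or empty fields
  # (allowed only for the standard defaults)
  g1 <- if (declare_delims) paste0(hol(pdelim), pdelim) else ","
  g2 <- if (declare_delims) paste0(hol(rdelim), pdelim) else ","
  gbody <- paste0(g1, g2,
                  paste(hol("fixture"), hol("fixture.igs"), hol("none"),
                        hol("none"), "32", "38", "6", "308", "15",
                        hol("fixture"), "1.0", as.character(units_flag),
                        hol("MM"), sep = pdelim),
                  rdelim)
  gchunks <- substring(gbody, seq(1, nchar(gbody), 72),
                       pmin(seq(1, nchar(gbody), 72) + 71, nchar(gbody)))
  glines <- mapply(pad, gchunks, "G", seq_along(gchunks))
  lines <- c(lines, glines)
  n_g <- length(glines)
  dlines <- character(0)
  plines <- character(0)
  dseq <- 0L; pseq <- 0L
  ents <- points
  for (i in seq_along(ents)) {
    pt <- ents[[i]]
    lab <- if (!is.null(labels)) labels[i] else ""
    body <- paste0("116", pdelim,
                   paste(sprintf("%.6g", pt), collapse = pdelim), rdelim)
    if (wrap_params) {
      # wrap after a delimiter, as fixed-format exporters do
      delims <- gregexpr(pdelim, body, fixed = TRUE)[[1]]
      cut <- delims[delims > nchar(body) / 2][1]
      if (is.na(cut)) cut <- delims[length(delims)]
      parts <- c(substring(body, 1, cut), substring(body, cut + 1))
    } else parts <- body
    np <- length(parts)
    d1 <- sprintf("%8d%8d%8d%8d%8d%8s%8s%8s%8s", 116L, pseq + 1L, 0L, 0L, 0L,
                  "0", "0", "0", "00000000")
    d2 <- sprintf("%8d%8d%8d%8d%8d%8s%8s%-8s%8d", 116L, 0L, 0L, np, 0L,
                  " ", " ", lab, 0L)
    dlines <- c(dlines, pad(d1, "D", dseq + 1L), pad(d2, "D", dseq + 2L))
    for (j in seq_len(np)) {
      pseq <- pseq + 1L
      plines <- c(plines,
                  sprintf("%-64s%8d%s%7d", parts[j], dseq + 1L, "P", pseq))
    }
    dseq <- dseq + 2L
  }
  if (extra_entity) {
    body <- paste0("110", pdelim, paste(rep("0.0", 6), collapse = pdelim),
                   rdelim)
    d1 <- sprintf("%8d%8d%8d%8d%8d%8s%8s%8s%8s", 110L, pseq + 1L, 0L, 0L, 0L,
                  "0", "0", "0", "00000000")
    d2 <- sprintf("%8d%8d%8d%8d%8d%8s%8s%-8s%8d", 110L, 0L, 0L, 1L, 0L,
                  " ", " ", "", 0L)
    dlines <- c(dlines, pad(d1, "D", dseq + 1L), pad(d2, "D", dseq + 2L))
    pseq <- pseq + 1L
    plines <- c(plines, sprintf("%-64s%8d%s%7d", body, dseq + 1L, "P", pseq))
    dseq <- dseq + 2L
  }
  lines <- c(lines, dlines, plines)
  if (terminate) {
    t <- sprintf("S%7dG%7dD%7dP%7d%40s", 1L, n_g, dseq, pseq, "")
    lines <- c(lines, sprintf("%-72sT%7d", t, 1L))
  }
  lines
}
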