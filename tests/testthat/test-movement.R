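identity_frame <- function() {
  structure(list(origin = c(0, 0, 0),
                 axes = rbind(X = c(1, 0, 0), Y = c(0, 1, 0), Z = c(0, 0, 1)),
                 plane1 = NULL, plane2 = NULL,
                 config = frame_config()),
            class = "reference_frame")
}

tooth_from_md <- function(mesial, distal, id = "11") {
  tooth_landmarks(rbind(
    lingual_gingival = c(0, 0, 0),
    mesial = c(mesial, 0),
    distal = c(distal, 0),
    occlusal = c(1, 1, 5),
    vestibular_gingival = c(1, 1, 0)), id)
}

test_that("rotation is the signed angle from +Y to the distal-mesial line", {
  f <- identity_frame()
  expect_equal(measure_rotation(tooth_from_md(c(0, 5), c(0, 3)), f), 0,
               tolerance = 1e-12)
  expect_equal(measure_rotation(tooth_from_md(c(1, 4), c(-1, 4)), f), 90,
               tolerance = 1e-12)
  expect_equal(measure_rotation(tooth_from_md(c(-1, 4), c(1, 4)), f), -90,
               tolerance = 1e-12)
  # swapped mesial/distal flips by 180 (wrapped)
  expect_equal(measure_rotation(tooth_from_md(c(0, 3), c(0, 5)), f), 180,
               tolerance = 1e-12)
})

test_that("rotating a tooth about frame Z shifts its rotation by the angle", {
  f <- identity_frame()
  base <- tooth_from_md(c(0, 5), c(0, 3))
  # rotation_about_z is counter-clockwise; the rotation angle is read
  # clockwise from +Y, so rotating the tooth by -theta yields +theta
  for (th in c(-170, -90, -10, 5, 45, 120)) {
    rotated <- rotate_tooth_about_z(base, -th)
    expect_equal(measure_rotation(rotated, f), th, tolerance = 1e-9)
  }
  # vertical mesiodistal line has no occlusal-plane projection
  degen <- tooth_landmarks(rbind(
    lingual_gingival = c(0, 0, 0), mesial = c(0, 3, 1), distal = c(0, 3, 4),
    occlusal = c(1, 1, 5), vestibular_gingival = c(1, 1, 0)), "11")
  expect_error(measure_rotation(degen, f), "degenerate")
})

test_that("inclination and angulation are projection angles of the crown line", {
  f <- identity_frame()
  upright <- make_tooth(center = c(0, 0, 0), md_dir = c(0, 1, 0),
                        buccal = c(1, 0, 0))
  m <- measure_inclination_angulation(upright, f)
  expect_equal(m$inclination_deg, 0, tolerance = 1e-12)
  expect_equal(m$angulation_deg, 0, tolerance = 1e-12)

  # pure buccal tip of 20 degrees: crown vector (2 sin20, 0, 2 cos20)
  vg <- c(1, 0, 0)
  tipped <- tooth_landmarks(rbind(
    lingual_gingival = c(-1, 0, 0),
    mesial = c(0, 4, 0), distal = c(0, -4, 0),
    occlusal = vg + c(2 * sin(20 * pi / 180), 0, 2 * cos(20 * pi / 180)),
    vestibular_gingival = vg), "11")
  m <- measure_inclination_angulation(tipped, f)
  expect_equal(m$inclination_deg, 20, tolerance = 1e-9)
  expect_equal(m$angulation_deg, 0, tolerance = 1e-9)

  # realigned coordinates put the mesiodistal line on the Y axis
  expect_equal(m$rotated_coords["mesial", "x"][[1]], 0, tolerance = 1e-9)
  expect_equal(m$rotated_coords["distal", "x"][[1]], 0, tolerance = 1e-9)
})

test_that("rotation reset makes inclination/angulation invariant to tooth rotation", {
  f <- identity_frame()
  set.seed(41)
  for (i in 1:25) {
    # a tooth in generic position with non-trivial angles
    ctr <- c(runif(1, -20, 20), runif(1, 10, 40), 0)
    md <- c(rnorm(2), 0.2 * rnorm(1))
    tooth <- make_tooth(center = ctr, md_dir = c(1, 0.3, 0),
                        buccal = c(-0.3, 1, 0))
    co <- unclass(tooth)
    co["occlusal", ] <- co["occlusal", ] + c(rnorm(2, 0, 2), 0)
    tooth <- tooth_landmarks(co, "11")
    base <- measure_inclination_angulation(tooth, f)
    th <- runif(1, -180, 180)
    about <- c(runif(2, -30, 30), runif(1, -5, 5))  # any pivot point
    rot <- rotate_tooth_about_z(tooth, th, about = about)
    m <- measure_inclination_angulation(rot, f)
    expect_equal(m$inclination_deg, base$inclination_deg, tolerance = 1e-9)
    expect_equal(m$angulation_deg, base$angulation_deg, tolerance = 1e-9)
  }
})

test_that("a non-occlusal crown vector warns but still returns angles", {
  f <- identity_frame()
  vg <- c(0, 0, 0)
  inverted <- tooth_landmarks(rbind(
    lingual_gingival = c(-1, 0, 0), mesial = c(0, 4, 0), distal = c(0, -4, 0),
    occlusal = vg + c(0.5, 0, -2), vestibular_gingival = vg + c(2, 0, 0)), "11")
  expect_warning(m <- measure_inclination_angulation(inverted, f),
                 "occlusally")
  expect_true(is.finite(m$inclination_deg))
})

test_that("arch measurement covers every tooth and is order-independent", {
  model <- make_clean_arch()
  frame <- build_reference_frame(model)
  m <- measure_arch(model, frame)
  expect_s3_class(m, "tooth_measures")
  expect_equal(nrow(m), 14)
  expect_equal(max(abs(m$inclination_deg)), 0, tolerance = 1e-9)
  expect_equal(max(abs(m$angulation_deg)), 0, tolerance = 1e-9)
  expect_true(all(paste0("rot_", rep(landmark_kinds(), each = 3), "_",
                         c("x", "y", "z")) %in% names(m)))
  perm <- model
  perm$teeth <- perm$teeth[rev(names(perm$teeth))]
  mp <- measure_arch(perm, frame)
  mp <- mp[match(m$tooth_fdi, mp$tooth_fdi), ]
  expect_equal(mp$rotation_deg, m$rotation_deg, tolerance = 1e-12)
  expect_equal(mp$inclination_deg, m$inclination_deg, tolerance = 1e-12)
})

test_that("deltas subtract, wrap, and report one-sided teeth", {
  m <- data.frame(tooth_fdi = c("11", "12"),
                  rotation_deg = c(179, 10), inclination_deg = c(5, 1),
                  angulation_deg = c(-2, 0))
  expect_equal(compute_deltas(m, m)$d_rotation_deg, c(0, 0))
  f <- m
  f$rotation_deg <- c(-179, 20)
  d <- compute_deltas(m, f)
  expect_equal(d$d_rotation_deg, c(2, 10))        # wrap across +/-180
  f2 <- f[1, ]
  expect_warning(d2 <- compute_deltas(m, f2), "12")
  expect_equal(d2$tooth_fdi, "11")
})

test_that("single-axis planned movements are recovered exactly", {
  model <- make_clean_arch(seed = 2)
  frame <- build_reference_frame(model)
  cfg <- pipeline_config(align = FALSE)
  for (mv in c("rotation_deg", "inclination_deg", "angulation_deg")) {
    for (amp in c(-30, -5, 1, 12, 30)) {
      tab <- data.frame(tooth_fdi = c("12", "25"), rotation_deg = 0,
                        inclination_deg = 0, angulation_deg = 0)
      tab[[mv]] <- amp
      fin <- apply_movements(model, tab, frame)
      got <- coef(measure_movement(model, fin, config = cfg))
      want <- c(rotation_deg = 0, inclination_deg = 0, angulation_deg = 0)
      want[mv] <- amp
      for (id in c("12", "25"))
        expect_equal(unname(got[id, ]), unname(want), tolerance = 1e-9)
      moved <- rownames(got)[rowSums(abs(got)) > 1e-9]
      expect_setequal(moved, c("12", "25"))
    }
  }
})

test_that("combined three-axis movements are recovered within 1.5 degrees", {
  model <- make_clean_arch(seed = 6)
  frame <- build_reference_frame(model)
  set.seed(42)
  tab <- data.frame(tooth_fdi = names(model$teeth),
                    rotation_deg = runif(14, -15, 15),
                    inclination_deg = runif(14, -15, 15),
                    angulation_deg = runif(14, -15, 15))
  fin <- apply_movements(model, tab, frame)
  got <- coef(measure_movement(model, fin,
                               config = pipeline_config(align = FALSE)))
  got <- got[tab$tooth_fdi, ]
  expect_lt(max(abs(got[, "rotation"] - tab$rotation_deg)), 1.5)
  expect_lt(max(abs(got[, "inclination"] - tab$inclination_deg)), 1.5)
  expect_lt(max(abs(got[, "angulation"] - tab$angulation_deg)), 1.5)
})

test_that("translation does not change any measured angle", {
  model <- make_clean_arch(seed = 3)
  frame <- build_reference_frame(model)
  tab <- data.frame(tooth_fdi = "14", rotation_deg = 0, inclination_deg = 0,
                    angulation_deg = 0, tx_mm = 1.2, ty_mm = -0.7, tz_mm = 0.4)
  fin <- apply_movements(model, tab, frame)
  got <- coef(measure_movement(model, fin,
                               config = pipeline_config(align = FALSE)))
  expect_equal(max(abs(got)), 0, tolerance = 1e-9)
})

test_that("all deltas are invariant under a common rigid motion of both models", {
  model <- make_clean_arch(seed = 8)
  frame <- build_reference_frame(model)
  set.seed(43)
  tab <- random_movements(names(model$teeth))
  fin <- apply_movements(model, tab, frame)
  base <- coef(measure_movement(model, fin,
                                config = pipeline_config(align = FALSE)))
  for (i in 1:100) {
    tr <- random_rigid_transform()
    got <- coef(measure_movement(apply_transform(tr, model),
                                 apply_transform(tr, fin),
                                 config = pipeline_config(align = FALSE)))
    expect_equal(got, base, tolerance = 1e-9)
  }
})

test_that("the full pipeline with alignment undoes a scanner-space mismatch", {
  model <- make_clean_arch(seed = 12)
  frame <- build_reference_frame(model)
  tab <- data.frame(tooth_fdi = "22", rotation_deg = 8, inclination_deg = 0,
                    angulation_deg = 0)
  fin <- apply_movements(model, tab, frame)
  # export the final model in an unrelated scanner space
  set.seed(44)
  exported <- apply_transform(random_rigid_transform(), fin)
  fit <- measure_movement(model, exported, config = pipeline_config(
    align = TRUE, exclude_teeth = c("22", "17", "27")))
  expect_equal(unname(coef(fit)["22", "rotation"]), 8, tolerance = 1e-9)
})

test_that("the measurement scales to a 14-patient two-arch cohort", {
  n_teeth <- 0
  for (r in 1:14) {
    for (arch in c("upper", "lower")) {
      m <- generate_arch(arch_spec(arch = arch, noise_sd_mm = 0.05,
                                   seed = 100 * r + (arch == "lower")))
      f <- build_reference_frame(m)
      n_teeth <- n_teeth + nrow(measure_arch(m, f))
    }
  }
  expect_equal(n_teeth, 14 * 28)
})
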