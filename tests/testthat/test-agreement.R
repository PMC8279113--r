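test_that("dahlberg index equals its defining formula", {
  expect_equal(dahlberg(c(0, 0, 0)), 0)
  expect_equal(dahlberg(2), sqrt(4 / 2), tolerance = 1e-12)
  expect_equal(dahlberg(c(1, 1, 1, 1)), sqrt(4 / 8), tolerance = 1e-12)
  expect_error(dahlberg(numeric(0)), "non-empty")
  set.seed(51)
  d <- rnorm(200, 0, 3)
  expect_equal(dahlberg(d), sqrt(sum(d^2) / (2 * length(d))), tolerance = 1e-12)
  expect_equal(dahlberg(d)^2, sum(d^2) / (2 * length(d)), tolerance = 1e-12)
})

test_that("bland-altman reproduces a published canine-rotation row", {
  # reported summary: n = 28 pairs, bias 0.98, SD 2.27
  ba <- bland_altman_summary(0.98, 2.27, 28)
  expect_equal(round(ba$loa_low, 2), -3.47)
  expect_equal(round(ba$loa_high, 2), 5.43)
  expect_equal(round(ba$ci_low, 2), 0.10)
  expect_equal(round(ba$ci_high, 2), 1.86)
  expect_equal(round(ba$p_value, 2), 0.03)
  expect_equal(round(ba$dahlberg, 2), 1.72)
})

test_that("bland-altman handles degenerate and raw-vector inputs", {
  z <- bland_altman(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(z$mean_diff, 0)
  expect_equal(z$sd_diff, 0)
  expect_equal(z$loa_low, z$loa_high)
  expect_equal(z$dahlberg, 0)
  expect_true(is.na(z$t_stat) && is.na(z$p_value))
  expect_error(bland_altman(1, numeric(0)), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")

  set.seed(52)
  a <- rnorm(40); b <- rnorm(40)
  ba <- bland_altman(a, b)
  tt <- t.test(a - b)                      # independent check of bias CI/t
  expect_equal(ba$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ba$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(c(ba$ci_low, ba$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(a - b) - 1.96 * sd(a - b), tolerance = 1e-12)
})

test_that("bland-altman is translation-equivariant", {
  set.seed(53)
  a <- rnorm(25); b <- rnorm(25)
  base <- bland_altman(a, b)
  shifted <- bland_altman(a + 3.5, b)
  expect_equal(shifted$mean_diff, base$mean_diff + 3.5, tolerance = 1e-12)
  expect_equal(shifted$ci_low, base$ci_low + 3.5, tolerance = 1e-12)
  expect_equal(shifted$loa_high, base$loa_high + 3.5, tolerance = 1e-12)
  expect_equal(shifted$sd_diff, base$sd_diff, tolerance = 1e-12)
  # centred dahlberg unaffected by the shift
  d0 <- base$diffs - mean(base$diffs)
  d1 <- shifted$diffs - mean(shifted$diffs)
  expect_equal(dahlberg(d1), dahlberg(d0), tolerance = 1e-12)
})

test_that("ICC(A,1) matches the definitional ANOVA on random matrices", {
  set.seed(54)
  for (i in 1:100) {
    n <- sample(4:15, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k), n, k) + rnorm(n)
    expect_equal(icc_single_absolute(x)$icc, icc_a1_bruteforce(x),
                 tolerance = 1e-10)
  }
})

test_that("ICC point estimate and CI match an external reference", {
  # reference values computed independently with a two-way ANOVA ICC
  # implementation on these exact matrices
  x1 <- matrix(c(1.115164, 2.125571, -1.172760, -2.550365, 2.309352, 0.930916,
                 3.199279, 2.220099, -3.647234, -4.194104, -0.942119, -2.369993,
                 0.267052, 0.292443, 0.339523, 0.121855, 0.818829, 0.786115,
                 0.875259, -1.723607), ncol = 2, byrow = TRUE)
  r1 <- icc_single_absolute(x1)
  expect_equal(r1$icc, 0.8299999950, tolerance = 1e-9)
  expect_equal(r1$f_value, 15.1609106114, tolerance = 1e-9)
  expect_equal(r1$p_value, 2.014363e-04, tolerance = 1e-6)
  expect_equal(round(r1$ci_low, 2), 0.36)
  expect_equal(round(r1$ci_high, 2), 0.96)

  x2 <- matrix(c(0.750471,-1.806988,-0.469781, -1.251025,-1.157281,-1.258870,
                 -0.730660,-2.280956,-0.291637, -1.571725,-2.433349,-4.312569,
                 -1.395327,-1.423077,-0.810658, -3.460722,-2.926280,-2.976438,
                 -0.635843,0.715952,-0.701873, 2.700616,3.099586,2.082204,
                 -1.043408,-1.339183,-0.935257, -2.413299,-1.630044,0.103248,
                 -0.514753,1.373833,1.084412, 0.125011,2.248957,1.461408),
               ncol = 3, byrow = TRUE)
  r2 <- icc_single_absolute(x2)
  expect_equal(r2$icc, 0.7398379502, tolerance = 1e-9)
  expect_equal(round(r2$ci_low, 2), 0.46)
  expect_equal(round(r2$ci_high, 2), 0.91)
  # point estimate identical under the mixed model, label differs
  rmix <- icc_single_absolute(x2, model = "two_way_mixed")
  expect_equal(rmix$icc, r2$icc)
  expect_equal(rmix$model, "two_way_mixed")
})

test_that("absolute agreement penalises a constant rater offset", {
  set.seed(55)
  r1 <- rnorm(20, 10, 2)
  x <- cbind(r1, r1 + 5)
  res <- icc_single_absolute(x)
  expect_lt(res$icc, 1)
  expect_equal(cor(x[, 1], x[, 2]), 1, tolerance = 1e-12)
  expect_equal(res$icc, icc_a1_bruteforce(x), tolerance = 1e-10)

  # identical columns of distinct values agree perfectly
  y <- cbind(r1, r1)
  expect_equal(icc_single_absolute(y)$icc, 1, tolerance = 1e-12)

  # invariant under a common shift, reduced by a one-rater shift
  expect_equal(icc_single_absolute(x + 7)$icc, res$icc, tolerance = 1e-10)
  one_shift <- x; one_shift[, 2] <- one_shift[, 2] + 5
  expect_lt(icc_single_absolute(one_shift)$icc, res$icc)
})

test_that("ICC flags constant data and rejects missing cells", {
  expect_true(is.na(icc_single_absolute(matrix(3, 5, 2))$icc))
  bad <- matrix(rnorm(10), 5, 2); bad[2, 1] <- NA
  expect_error(icc_single_absolute(bad), "missing")
  expect_error(icc_single_absolute(matrix(1:2, 1, 2)), ">= 2 subjects")
})

test_that("ICC converges to the noise-attenuation limit for agreeing raters", {
  set.seed(56)
  sigma_s <- 2; sigma_e <- 1
  n <- 4000
  subj <- rnorm(n, 0, sigma_s)
  x <- cbind(subj + rnorm(n, 0, sigma_e), subj + rnorm(n, 0, sigma_e))
  res <- icc_single_absolute(x)
  expect_equal(res$icc, sigma_s^2 / (sigma_s^2 + sigma_e^2), tolerance = 0.05)
})

test_that("the published validation summary table is complete and consistent", {
  v <- validation_summary()
  expect_equal(nrow(v), 30)
  expect_equal(sum(v$analysis == "validity"), 24)
  # the reproduction flags hold: every flagged cell reproduces to 2 decimals
  ba <- Map(bland_altman_summary, v$mean_diff_deg, v$sd_diff_deg, v$n)
  loa_high <- sapply(ba, `[[`, "loa_high")
  expect_true(all(abs(loa_high - v$printed_loa_high)[v$check_loa_high] <= 0.0151))
  # the known misprinted upper limit does not reproduce
  typo <- v$analysis == "validity" & v$arch == "maxillary" &
    v$movement == "rotation" & v$tooth_group == "incisors"
  expect_false(v$check_loa_high[typo])
  expect_gt(abs(loa_high[typo] - v$printed_loa_high[typo]), 0.3)
})
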