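test_that("r50 locates the distal 50% crossing", {
  # linear ramp 100 -> 0 over 0..4 cm: midpoint at 2
  expect_equal(r50(ramp_curve(end = 4)), 2, tolerance = 1e-9)

  # synthetic curve: oracle = bisection on the closed form (continuous max)
  p <- test_params(r50 = 2.3)
  dd <- synth_pdd(p, depths = seq(0, 5.5, by = 0.05))
  oracle <- uniroot(function(z) pdd_model(z, p) - 50,
                    interval = c(p$r50 - 0.5, p$r50 + 0.5), tol = 1e-10)$root
  expect_equal(r50(dd), oracle, tolerance = 0.05)
  expect_lt(abs(r50(dd) - 2.3), 0.05 + 0.02)  # parameter itself, one grid step

  # invariant under uniform rescaling of the dose values
  dd2 <- dd
  dd2$dose <- dd$dose * 7.3
  expect_equal(r50(dd2), r50(dd))

  # no distal crossing -> range error
  z <- seq(0, 3, by = 0.1)
  flat <- depth_dose(z, rep(80, length(z)) + z, check = FALSE)
  expect_error(r50(flat), "range error")
})

test_that("practical range matches the tangent construction", {
  # tangent of a pure ramp with zero tail is the ramp itself
  expect_equal(practical_range(ramp_curve(end = 4)), 4, tolerance = 1e-6)

  # dense-grid independent oracle: steepest tangent of the closed form
  p <- test_params()
  dd <- synth_pdd(p)
  zf <- seq(0, max(dd$depth), by = 1e-3)
  df <- pdd_model(zf, p)
  tail_level <- mean(df[zf >= p$r50 + p$falloff_width + 0.5])
  slope <- diff(df) / diff(zf)
  distal <- which(zf[-1] > p$r50 - p$falloff_width)
  s <- distal[which.min(slope[distal])]
  oracle <- zf[s] + (df[s] - tail_level) / (-slope[s])
  expect_equal(practical_range(dd), oracle, tolerance = 0.05)

  # r50 < practical range whenever there is a descending limb
  for (r in c(1.8, 2.2, 3)) {
    cv <- synth_pdd(test_params(r50 = r), depths = seq(0, r + 3.2, 0.05))
    expect_lt(r50(cv), practical_range(cv))
  }
})

test_that("photon contamination reads the bremsstrahlung tail", {
  expect_equal(photon_contamination(ramp_curve(end = 2, tail = 0)), 0,
               tolerance = 1e-9)
  # the generator's tail parameter is the oracle
  for (tail in c(0.07, 0.49, 2)) {
    dd <- synth_pdd(test_params(tail_level = tail))
    expect_equal(photon_contamination(dd), tail, tolerance = 0.01)
  }
  # insufficient tail sampling -> range error naming the required depth
  p <- test_params()
  full <- synth_pdd(p)
  keep <- full$depth <= p$r50 + 1.2  # ends before Rp + 1
  short <- depth_dose(full$depth[keep], full$dose[keep], energy = 6,
                      field_size = 2, foil = "SFF", ssd = 60)
  expect_error(photon_contamination(short), "range error")
})

test_that("beam metrics are stable under 2x grid refinement", {
  p <- test_params()
  dd <- synth_pdd(p, depths = seq(0, 5.3, by = 0.1))
  fine_z <- seq(0, 5.3, by = 0.05)
  fine <- depth_dose(fine_z, approx(dd$depth, dd$dose, xout = fine_z)$y,
                     energy = 6, field_size = 2, foil = "SFF", ssd = 60)
  expect_equal(r50(fine), r50(dd), tolerance = 0.01)
  expect_equal(practical_range(fine), practical_range(dd), tolerance = 0.01)
  expect_equal(photon_contamination(fine), photon_contamination(dd),
               tolerance = 0.01)
})

test_that("output ratio compares absolute curve maxima", {
  a <- synth_pdd(test_params(output_scale = 5), normalization = "absolute")
  expect_equal(output_ratio(a, a), 1)
  b <- a
  b$dose <- a$dose / 2
  expect_equal(output_ratio(a, b), 2)
  rel <- synth_pdd(test_params())
  expect_error(output_ratio(rel, a), "unit error")
})

test_that("profile FWHM interpolates the half-maximum crossings", {
  expect_equal(profile_fwhm(tophat_profile(width = 2)), 2, tolerance = 0.051)

  # closed-form root oracle for the erf-pair profile
  p <- test_params(field_size = 4)
  depth <- 1.2
  pr <- synth_profile(p, depth = depth)
  oracle_half <- uniroot(
    function(x) profile_model(x, depth, p) - 0.5 * profile_model(0, depth, p),
    interval = c(0.1, 6), tol = 1e-10)$root
  expect_equal(profile_fwhm(pr), 2 * oracle_half, tolerance = 0.01)

  # in the narrow-penumbra regime the FWHM recovers the projected field size
  expect_equal(profile_fwhm(pr), 4 * (60 + depth) / 60, tolerance = 0.05)

  expect_error(profile_fwhm(tophat_profile(width = 20, span = 4)),
               "range error")
})

test_that("dose-difference/DTA agreement behaves like a 2%/1 mm gamma check", {
  p <- test_params()
  dd <- synth_pdd(p)
  same <- curve_agreement(dd, dd)
  expect_equal(same$pass_fraction, 1)
  expect_equal(same$max_index, 0)

  # pure 0.5 mm shift stays within the 1 mm distance tolerance
  shifted <- depth_dose(dd$depth + 0.05, dd$dose, energy = 6, field_size = 2,
                        foil = "SFF", ssd = 60)
  expect_equal(curve_agreement(dd, shifted)$pass_fraction, 1)

  # flat curve offset by 5% of max fails everywhere
  z <- seq(0, 5, 0.1)
  flat <- depth_dose(z, rep(100, length(z)), check = FALSE)
  off <- flat
  off$dose <- flat$dose + 5
  res <- curve_agreement(flat, off)
  expect_equal(res$pass_fraction, 0)
  expect_gte(res$max_index, 2.5 - 1e-6)

  far <- depth_dose(z + 100, flat$dose, check = FALSE)
  expect_error(curve_agreement(flat, far), "range error")
})

test_that("beam_metrics tabulates a curve set with paired output ratio", {
  sff <- synth_pdd(beam_preset("6mev-sff", field_size = 2),
                   normalization = "absolute")
  sf <- synth_pdd(beam_preset("6mev-sf", field_size = 2),
                  normalization = "absolute")
  tab <- beam_metrics(list(sff = sff, sf = sf))
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$foil), c("SF", "SFF"))
  expect_equal(tab$output_ratio[tab$foil == "SFF"], 20.88 / 1,
               tolerance = 1e-3)
  expect_true(all(tab$r50_cm < tab$rp_cm))
})
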