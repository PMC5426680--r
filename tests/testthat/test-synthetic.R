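test_that("beam model parameters enforce their invariants", {
  expect_error(beam_model_params(d_max = 2.5, r50 = 2.2), "d_max")
  expect_error(beam_model_params(tail_level = 60), "tail_level")
  expect_error(beam_model_params(noise_sd = -1), "noise_sd")
  expect_error(beam_model_params(sigma0 = -0.1), "> 0")
})

test_that("presets reproduce the published 2x2 beam characteristics", {
  sff <- beam_preset("6mev-sff", field_size = 2)
  sf <- beam_preset("6mev-sf", field_size = 2)
  expect_equal(sff$r50, 2.2)
  expect_equal(sf$r50, 2.0)
  expect_equal(sff$tail_level, 0.07)
  expect_equal(sf$tail_level, 0.49)
  # small fields are shorter-ranged, large fields approach the broad beam
  expect_lt(beam_preset("6mev-sff", field_size = 1)$r50, 2.2)
  expect_gt(beam_preset("6mev-sff", field_size = 4)$r50, 2.2)
  # explicit override wins
  expect_equal(beam_preset("6mev-sff", field_size = 1, r50 = 2.2)$r50, 2.2)
})

test_that("synth_pdd is deterministic and validates its grid", {
  p <- test_params(noise_sd = 0.3, seed = 42L)
  a <- synth_pdd(p)
  b <- synth_pdd(p)
  expect_identical(a$dose, b$dose)
  p2 <- test_params(noise_sd = 0.3, seed = 43L)
  expect_false(identical(synth_pdd(p2)$dose, a$dose))
  expect_error(synth_pdd(test_params(), depths = seq(0, 3, 0.05)),
               "range error")
  expect_error(synth_pdd(test_params(), depths = c(0, 1, 0.5, 4.5)),
               "ascending")
})

test_that("noise-free parameter recovery and noisy r50 stability", {
  # recovery of r50 / tail / fwhm on noise-free output (one grid step)
  p <- test_params(r50 = 2.3, tail_level = 0.2)
  expect_lt(abs(r50(synth_pdd(p)) - 2.3), 0.06)
  expect_lt(abs(photon_contamination(synth_pdd(p)) - 0.2), 0.01)
  pr <- synth_profile(test_params(field_size = 4), depth = 1)
  expect_lt(abs(profile_fwhm(pr) - 4 * 61 / 60), 0.05)

  # with noise_sd <= 0.5 the recovered r50 stays within 0.05 cm over seeds
  devs <- vapply(1:100, function(s) {
    dd <- synth_pdd(test_params(noise_sd = 0.5, seed = s))
    r50(dd) - r50(synth_pdd(test_params()))
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.05)
})

test_that("lateral profile model narrows to a top-hat and widens with depth", {
  # sigma -> 0 limit: top-hat of the projected field width
  p0 <- test_params(field_size = 2, sigma0 = 1e-4, sigma_growth = 0)
  x <- seq(-3, 3, by = 0.01)
  prof <- profile_model(x, 0, p0)
  expect_true(all(prof[abs(x) < 0.99] > 0.999))
  expect_true(all(prof[abs(x) > 1.01] < 0.001))

  # deeper profiles have monotonically wider 80-20% penumbrae
  p <- test_params(field_size = 4)
  pen <- vapply(c(0.5, 1, 2, 3), function(z) {
    pr <- synth_profile(p, depth = z)
    rel <- pr$dose / max(pr$dose)
    x80 <- approx(rel[pr$position > 0], pr$position[pr$position > 0],
                  xout = 0.8)$y
    x20 <- approx(rel[pr$position > 0], pr$position[pr$position > 0],
                  xout = 0.2)$y
    x20 - x80
  }, numeric(1))
  expect_true(all(diff(pen) > 0))

  expect_error(synth_profile(p, positions = seq(-1, 1, 0.05), depth = 1),
               "range error")
})

test_that("synthetic beam tables round-trip through the reader", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "beams.csv")
  files <- synth_beam_table(beam_preset("6mev-sff", field_size = 2),
                            beam_preset("6mev-sf", field_size = 2),
                            path, output_ratio = 21)
  curves <- read_beam_table(path, files$dialect)
  profs <- read_beam_table(files$profiles, files$dialect)

  gen <- synth_pdd(beam_preset("6mev-sff", field_size = 2))
  expect_equal(curves$sff_rel$dose, gen$dose, tolerance = 1e-8)
  expect_equal(attr(curves$sf_rel, "foil"), "SF")
  expect_equal(output_ratio(curves$sff_abs, curves$sf_abs), 21,
               tolerance = 1e-3)
  expect_equal(r50(curves$sff_rel), r50(gen))

  pr <- profs$sff_profile_d1.2
  expect_s3_class(pr, "lateral_profile")
  expect_equal(attr(pr, "depth"), 1.2)
  gen_pr <- profile_model(pr$position, 1.2,
                          beam_preset("6mev-sff", field_size = 2))
  expect_equal(pr$dose, gen_pr, tolerance = 1e-8)

  # byte-identical on repeated generation
  path2 <- file.path(dir, "beams2.csv")
  synth_beam_table(beam_preset("6mev-sff", field_size = 2),
                   beam_preset("6mev-sf", field_size = 2),
                   path2, output_ratio = 21)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the beam-table reader rejects malformed tables", {
  dir <- withr::local_tempdir()
  dialect <- list(abscissa = list(column = "depth_cm", kind = "depth",
                                  unit = "cm"),
                  series = list(dose = list(curve = "pdd")))
  bad <- file.path(dir, "bad.csv")

  writeLines(c("depth_cm,dose", "0,100", "2,80", "1,60"), bad)
  expect_error(read_beam_table(bad, dialect), "depth_cm")

  writeLines(c("depth_cm,dose", "0,", "1,", "2,"), bad)
  expect_error(read_beam_table(bad, dialect), "empty")

  writeLines(c("z,dose", "0,1", "1,2"), bad)
  expect_error(read_beam_table(bad, dialect), "depth_cm")

  # two-column CSV in mm units converts to a single curve in cm
  ok <- file.path(dir, "ok.csv")
  writeLines(c("depth_mm,dose",
               paste(seq(0, 50, 5), c(80, 90, 100, 95, 85, 60, 30, 10, 2,
                                      1, 1), sep = ",")), ok)
  mm_dialect <- list(abscissa = list(column = "depth_mm", kind = "depth",
                                     unit = "mm"),
                     series = list(dose = list(curve = "pdd")))
  cv <- read_beam_table(ok, mm_dialect)$dose
  expect_s3_class(cv, "depth_dose")
  expect_equal(max(cv$depth), 5)
})
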