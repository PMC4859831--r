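# Synthetic detector and phantom generator: moment contracts.

test_that("unit gain with no offset gives pure Poisson statistics", {
  det <- detector_model(offset_theta = 0, gain_range = c(1, 1),
                        quanta_per_mas = 10, shape = c(512, 512))
  f <- generate_flat(det, 100, seed = 1)  # lambda = 1000
  px <- as.vector(f$pixels)
  expect_equal(mean(px), 1000, tolerance = 0.005)
  expect_equal(var(px), 1000, tolerance = 0.02)
})

test_that("constant gain g makes variance/mean equal g after offset removal", {
  det <- detector_model(offset_theta = 50, gain_range = c(0.25, 0.25),
                        quanta_per_mas = 10, shape = c(512, 512))
  f <- generate_flat(det, 160, seed = 2)
  lin <- as.vector(linearize(f, 50))
  expect_equal(var(lin) / mean(lin), 0.25, tolerance = 0.02)
})

test_that("the gain map spans the configured variance/mean range", {
  det <- detector_model(offset_theta = 50, shape = c(2048, 512))
  f <- generate_flat(det, 160, seed = 3)
  lin <- linearize(f, 50)
  ratio <- local_variance_map(lin, 64) / mean(lin)
  expect_equal(min(ratio), 0.1, tolerance = 0.1)
  expect_equal(max(ratio), 0.3, tolerance = 0.1)
})

test_that("readout noise adds its variance on top of the scaled Poisson term", {
  det <- detector_model(offset_theta = 0, gain_range = c(0.2, 0.2),
                        quanta_per_mas = 10, readout_sigma = 5,
                        shape = c(512, 512))
  f <- generate_flat(det, 160, seed = 4)
  px <- as.vector(f$pixels)
  # var = g^2 lambda + sigma_r^2 = 0.2 * 1600 + 25 (+1/12 quantization)
  expect_equal(var(px), 0.2 * 1600 + 25, tolerance = 0.02)
})

test_that("offset-subtracted flat means are linear in mAs", {
  det <- detector_model(offset_theta = 50, shape = c(512, 512))
  m80 <- mean(linearize(generate_flat(det, 80, seed = 5), 50))
  m160 <- mean(linearize(generate_flat(det, 160, seed = 6), 50))
  expect_equal(m160 / m80, 2, tolerance = 0.005)
  expect_equal(m160, 1600, tolerance = 0.005)
})

test_that("phantom generation reduces to a flat for unit transmission", {
  det <- detector_model(shape = c(256, 256))
  ph <- phantom_model(shape = c(256, 256), seed = 7)
  ph$attenuation <- matrix(1, 256, 256)
  a <- generate_phantom_image(det, ph, 160, seed = 8)
  b <- generate_flat(det, 160, seed = 8)
  expect_identical(a$pixels, b$pixels)
})

test_that("halving mAs halves the offset-subtracted phantom mean", {
  det <- detector_model(shape = c(512, 256))
  ph <- phantom_model(shape = c(512, 256), seed = 9)
  a <- generate_phantom_image(det, ph, 160, seed = 10)
  b <- generate_phantom_image(det, ph, 80, seed = 11)
  expect_equal(mean(linearize(b, 50)) / mean(linearize(a, 50)), 0.5,
               tolerance = 0.005)
})

test_that("generation is deterministic under a fixed seed", {
  det <- detector_model(shape = c(128, 128))
  ph <- phantom_model(shape = c(128, 128), seed = 12)
  expect_identical(generate_phantom_image(det, ph, 160, seed = 13)$pixels,
                   generate_phantom_image(det, ph, 160, seed = 13)$pixels)
  expect_false(identical(generate_phantom_image(det, ph, 160, 13)$pixels,
                         generate_phantom_image(det, ph, 160, 14)$pixels))
})

test_that("calc spots locally reduce transmission inside their diameter", {
  spots <- data.frame(row = 64, col = 64, diameter_px = 10, contrast = 0.5)
  ph0 <- phantom_model(shape = c(128, 128), seed = 15)
  ph1 <- phantom_model(shape = c(128, 128), calc_spots = spots, seed = 15)
  expect_equal(ph1$attenuation[64, 64], ph0$attenuation[64, 64] * 0.5)
  expect_equal(ph1$attenuation[1, 1], ph0$attenuation[1, 1])
  bad <- data.frame(row = 500, col = 64, diameter_px = 10, contrast = 0.5)
  expect_error(phantom_model(shape = c(128, 128), calc_spots = bad),
               "outside")
})

test_that("make_paired_doses produces the full bookkeeping of sets", {
  det <- detector_model(shape = c(128, 128))
  ph <- phantom_model(shape = c(128, 128), seed = 16)
  sets <- make_paired_doses(det, ph, c(160, 80), n_per_dose = 5,
                            n_flats_per_dose = 2, seed = 17)
  expect_named(sets$phantoms, c("160", "80"))
  expect_length(sets$phantoms[["160"]], 5)
  expect_length(sets$flats[["80"]], 2)
  # realizations are independent draws
  expect_false(identical(sets$phantoms[["160"]][[1]]$pixels,
                         sets$phantoms[["160"]][[2]]$pixels))
  # relative variance ordering follows 1/dose
  rv <- function(img) {
    lin <- linearize(img, 50); var(as.vector(lin)) / mean(lin)^2
  }
  expect_gt(rv(sets$flats[["80"]][[1]]), rv(sets$flats[["160"]][[1]]))
})

test_that("ensemble mean of realizations approaches the noiseless signal", {
  det <- detector_model(shape = c(256, 128))
  ph <- phantom_model(shape = c(256, 128), seed = 18)
  imgs <- lapply(1:5, function(i) {
    generate_phantom_image(det, ph, 160, seed = 20 + i)$pixels
  })
  ens <- Reduce(`+`, imgs) / 5
  expected <- 50 + 10 * 160 * ph$attenuation
  # per-pixel SE is ~sqrt(g * 1600 / 5) ~ 8-12; the field mean is tight
  expect_equal(mean(ens), mean(expected), tolerance = 0.002)
  expect_lt(max(abs(ens - expected)) / mean(expected), 0.05)
})
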