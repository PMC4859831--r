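# Shared fixture builders; everything is generated in code under fixed
# seeds so no binary data ships with the package.

# i.i.d. Gaussian matrix under a fixed seed
rmat <- function(nr, nc, sd = 1, mean = 0, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc, mean, sd), nr, nc)
}

# The three-stripe preliminary experiment: a 512 x 512 image whose
# horizontal bands have constant means 60000 / 30000 / 1000.
three_region_image <- function() {
  img <- matrix(0, 512, 512)
  img[1:171, ] <- 60000
  img[172:342, ] <- 30000
  img[343:512, ] <- 1000
  img
}

three_region_bands <- list(I = 1:171, II = 172:342, III = 343:512)

# Small detector + matched flats for pipeline tests
small_detector <- function(theta = 50, shape = c(512, 256)) {
  detector_model(offset_theta = theta, shape = shape)
}
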