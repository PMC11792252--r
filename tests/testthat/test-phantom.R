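test_that("empty phantom settings give an identically zero phase field", {
  sys <- tiny_system(64, pixel_um = 0.5)
  ph <- generate_phantom(sys, n_nuclei = 0, background_sd = 0,
                         n_inclusions = 0, absorption = 0, seed = 5)
  expect_true(all(ph$phase == 0))
  expect_true(all(ph$labels == 0L))
  expect_true(all(ph$absorption == 0))
  expect_equal(ph$meta$regime, "weak")
})

test_that("phantom generation is bit-identical per seed and leaves the RNG alone", {
  sys <- tiny_system(64, pixel_um = 0.5)
  args <- small_phantom_args()
  set.seed(999)
  before <- .Random.seed
  a <- do.call(generate_phantom, c(list(sys = sys, seed = 11), args))
  expect_identical(.Random.seed, before)
  b <- do.call(generate_phantom, c(list(sys = sys, seed = 11), args))
  expect_identical(a$phase, b$phase)
  expect_identical(a$absorption, b$absorption)
  expect_identical(a$labels, b$labels)
  c_ <- do.call(generate_phantom, c(list(sys = sys, seed = 12), args))
  expect_false(identical(a$phase, c_$phase))
})

# Flood-fill connected-component count, 4-connectivity: an independent
# check that the requested nuclei are present and pairwise disjoint.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1) p - 1L, if (i < nr) p + 1L,
                  if (j > 1) p - nr, if (j < ncol(mask)) p + nr))
        if (mask[q] && lab[q] == 0L) { lab[q] <- n; queue <- c(queue, q) }
    }
  }
  n
}

test_that("requested nuclei appear as that many disjoint components", {
  sys <- optical_system(0.72, 0.6, 0.25, c(512, 512))
  ph <- generate_phantom(sys, n_nuclei = 12, nucleus_radius_um = c(3, 6),
                         seed = 21)
  expect_equal(count_components(ph$labels == 1L), 12)
  expect_equal(nrow(ph$meta$nuclei), 12)
})

test_that("infeasible packing errors and reports the achieved count", {
  sys <- tiny_system(64, pixel_um = 0.5)   # 32 um field
  expect_error(
    generate_phantom(sys, n_nuclei = 40, nucleus_radius_um = c(5, 6),
                     seed = 1, max_attempts = 500),
    "placed")
})

test_that("nucleus radii below two pixels are rejected", {
  sys <- tiny_system(64, pixel_um = 0.5)
  expect_error(generate_phantom(sys, nucleus_radius_um = c(0.5, 1)),
               ">= 2 pixels")
})

test_that("acetowhitening transform has the stated limiting behaviors", {
  sys <- tiny_system(64, pixel_um = 0.5)
  ph <- do.call(generate_phantom,
                c(list(sys = sys, seed = 3), small_phantom_args()))
  # identity parameters leave the phase untouched
  id <- apply_aa_transform(ph, aa_params(nuclear_gain = 1,
                                         homogenization = 0))
  expect_equal(id$phase, ph$phase)
  expect_identical(id$labels, ph$labels)
  expect_identical(id$absorption, ph$absorption)
  # nuclear gain doubles the mean phase over the nucleus mask
  g2 <- apply_aa_transform(ph, aa_params(nuclear_gain = 2,
                                         homogenization = 0))
  nuc <- ph$labels == 1L
  expect_equal(mean(g2$phase[nuc]), 2 * mean(ph$phase[nuc]))
  expect_equal(g2$phase[!nuc], ph$phase[!nuc])
  # full homogenization collapses the background to its mean
  h1 <- apply_aa_transform(ph, aa_params(homogenization = 1))
  expect_equal(stats::sd(h1$phase[ph$labels == 0L]), 0)
  expect_equal(mean(h1$phase[ph$labels == 0L]),
               mean(ph$phase[ph$labels == 0L]))
})

test_that("acetowhitening lowers whole-field SD while raising nuclear CNR", {
  sys <- tiny_system(64, pixel_um = 0.5)
  for (seed in 1:8) {
    ph <- do.call(generate_phantom,
                  c(list(sys = sys, seed = seed), small_phantom_args()))
    aa <- apply_aa_transform(ph, aa_params())
    expect_lt(stats::sd(aa$phase), stats::sd(ph$phase))
    expect_gt(nuclear_cnr(aa$phase, aa$labels),
              nuclear_cnr(ph$phase, ph$labels))
  }
})

test_that("nuclear CNR is non-decreasing in nuclear gain", {
  sys <- tiny_system(64, pixel_um = 0.5)
  ph <- do.call(generate_phantom,
                c(list(sys = sys, seed = 4), small_phantom_args()))
  gains <- c(1, 1.25, 1.5, 1.8, 2.2)
  cnr <- vapply(gains, function(g) {
    out <- apply_aa_transform(ph, aa_params(nuclear_gain = g))
    nuclear_cnr(out$phase, out$labels)
  }, numeric(1))
  expect_true(all(diff(cnr) >= 0))
})

test_that("local background homogenization also reduces background SD", {
  sys <- tiny_system(64, pixel_um = 0.5)
  ph <- do.call(generate_phantom,
                c(list(sys = sys, seed = 6), small_phantom_args()))
  loc <- apply_aa_transform(ph, aa_params(background_mode = "local",
                                          local_scale_um = 4))
  bg <- ph$labels == 0L
  expect_lt(stats::sd(loc$phase[bg]), stats::sd(ph$phase[bg]))
  expect_identical(loc$labels, ph$labels)
})
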