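test_that("a flat phantom images to each arm's background level", {
  sys <- tiny_system(32)
  op <- build_optics(sys)
  flat <- matrix(0, 32, 32)
  fr <- simulate_intensities(flat, op$tfs)
  for (arm in names(fr$frames))
    expect_equal(fr$frames[[arm]],
                 matrix(op$tfs[[arm]]$B, 32, 32), tolerance = 1e-12)
})

test_that("a single-frequency phase mode images with |H_ph| and arg H_ph", {
  n <- 64L
  sys <- tiny_system(n)
  op <- build_optics(sys)
  a <- 0.05; ki <- 5L; kj <- 3L
  phi <- lattice_cosine(n, ki, kj, a)
  fr <- simulate_intensities(phi, op$tfs)
  r <- matrix(seq_len(n) - 1, n, n)
  c_ <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  for (arm in c("+x", "-x", "+y", "-y")) {
    tf <- op$tfs[[arm]]
    H0 <- tf$H_ph[ki + 1L, kj + 1L]
    pred <- tf$B + a * Mod(H0) *
      cos(2 * pi * (ki * r / n + kj * c_ / n) + Arg(H0))
    expect_lt(max(abs(fr$frames[[arm]] - pred)), 1e-8 * tf$B)
  }
})

test_that("the weak-object forward model is linear in the phase", {
  sys <- tiny_system(32)
  op <- build_optics(sys)
  set.seed(8)
  phi <- matrix(rnorm(32 * 32, sd = 0.05), 32, 32)
  f1 <- simulate_intensities(phi, op$tfs)
  f3 <- simulate_intensities(3 * phi, op$tfs)
  for (arm in names(f1$frames)) {
    B <- op$tfs[[arm]]$B
    expect_equal(f3$frames[[arm]] - B, 3 * (f1$frames[[arm]] - B),
                 tolerance = 1e-10)
  }
})

test_that("opposing arms split phase into the normalized difference", {
  sys <- tiny_system(64)
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.1, seed = 2)
  fr <- simulate_intensities(bl$phase, op$tfs)
  # for a pure-phase object and an exact mirror pair the frame sum is flat
  S <- fr$frames[["+x"]] + fr$frames[["-x"]]
  B2 <- op$tfs[["+x"]]$B + op$tfs[["-x"]]$B
  expect_equal(S, matrix(B2, 64, 64), tolerance = 1e-10)
  # and the normalized difference is H_dpc acting on the phase spectrum
  D <- compute_dpc(fr, "x")$values
  pred <- Re(stats::fft(op$H_x * stats::fft(bl$phase), inverse = TRUE)) /
    (64 * 64)
  expect_lt(max(abs(D - pred)), 1e-8)
})

test_that("poisson noise is reproducible per seed and changes with it", {
  sys <- tiny_system(32)
  op <- build_optics(sys)
  set.seed(1)
  phi <- matrix(rnorm(32 * 32, sd = 0.05), 32, 32)
  f1 <- simulate_intensities(phi, op$tfs, noise = "poisson",
                             photon_scale = 5000, seed = 77)
  f2 <- simulate_intensities(phi, op$tfs, noise = "poisson",
                             photon_scale = 5000, seed = 77)
  f3 <- simulate_intensities(phi, op$tfs, noise = "poisson",
                             photon_scale = 5000, seed = 78)
  expect_identical(f1$frames, f2$frames)
  expect_false(identical(f1$frames, f3$frames))
  expect_error(simulate_intensities(phi, op$tfs, noise = "poisson"),
               "seed")
  # relative fluctuation on a flat field scales like 1/sqrt(photon_scale)
  ff <- simulate_intensities(matrix(0, 32, 32), op$tfs, noise = "poisson",
                             photon_scale = 5000, seed = 79)
  rel <- stats::sd(ff$frames[["+x"]] / op$tfs[["+x"]]$B)
  expect_lt(abs(rel - sqrt(1 / 5000)) / sqrt(1 / 5000), 0.2)
})

test_that("z stacks simulate slices independently in order", {
  sys <- tiny_system(32)
  op <- build_optics(sys)
  ph <- do.call(generate_phantom, c(list(sys = sys, seed = 1,
                                         nucleus_radius_um = c(1, 2),
                                         n_nuclei = 2L, n_inclusions = 0L)))
  expect_error(simulate_zstack(list(), op$tfs), "empty")
  zs <- simulate_zstack(rep(list(ph), 5), op$tfs)
  expect_length(zs$slices, 5)
  expect_equal(zs$slice_spacing_um, 1.5)
  single <- simulate_intensities(ph, op$tfs)
  for (s in zs$slices) expect_equal(s$frames, single$frames)
  # ten seeded distinct slices keep their order
  stack10 <- lapply(1:10, function(i) do.call(
    generate_phantom, c(list(sys = sys, seed = 100 + i,
                             nucleus_radius_um = c(1, 2),
                             n_nuclei = 2L, n_inclusions = 0L))))
  zs10 <- simulate_zstack(stack10, op$tfs)
  expect_length(zs10$slices, 10)
  f1 <- simulate_intensities(stack10[[7]], op$tfs)
  expect_equal(zs10$slices[[7]]$frames, f1$frames)
})

test_that("weak-object linearization agrees with the Abbe-sum reference", {
  for (n in c(32L, 64L)) {
    sys <- optical_system(0.72, 0.6, 0.5, c(n, n))
    op <- build_optics(sys)
    ph <- do.call(generate_phantom,
                  c(list(sys = sys, seed = 7), small_phantom_args()))
    # evaluate both models with the same truncated source
    src_t <- lapply(op$sources, truncate_source, n_max = 200L)
    tfs_t <- lapply(src_t, function(s)
      compute_wotf(sys, op$grid, op$pupil, s))
    lin <- simulate_intensities(ph, tfs_t)
    abbe <- simulate_intensities_abbe(ph, op$pupil, op$sources,
                                      n_max = 200L)
    for (arm in names(lin$frames)) {
      rel <- sqrt(mean((lin$frames[[arm]] - abbe$frames[[arm]])^2)) /
        sqrt(mean(abbe$frames[[arm]]^2))
      expect_lt(rel, 0.01)
    }
  }
})
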