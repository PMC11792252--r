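make_frames <- function(frames) structure(list(frames = frames,
                                               exposure = list()),
                                          class = "qobm_frames")

test_that("DPC formation is the guarded normalized difference", {
  m <- function(v) matrix(v, 8, 8)
  fr <- make_frames(list("+x" = m(3), "-x" = m(1),
                         "+y" = m(2), "-y" = m(2)))
  expect_equal(compute_dpc(fr, "x")$values, m(0.5))
  expect_equal(compute_dpc(fr, "y")$values, m(0))
  # swapping the arms negates the image
  fr_sw <- make_frames(list("+x" = m(1), "-x" = m(3),
                            "+y" = m(2), "-y" = m(2)))
  expect_equal(compute_dpc(fr_sw, "x")$values, -m(0.5))
  # guarded pixels: near-zero sums are zeroed and counted
  Ia <- m(3); Ib <- m(1)
  Ia[1, 1] <- 1e-9; Ib[1, 1] <- -1e-9 + 1e-16
  frg <- compute_dpc(make_frames(list("+x" = Ia, "-x" = Ib,
                                      "+y" = m(2), "-y" = m(2))), "x")
  expect_equal(frg$values[1, 1], 0)
  expect_equal(frg$n_guarded, 1L)
  fr$frames[["-y"]] <- NULL
  expect_error(compute_dpc(fr, "y"), "'-y'")
})

test_that("one-mode Tikhonov inversion matches its closed form", {
  n <- 32L
  sys <- tiny_system(n)
  op <- build_optics(sys)
  ki <- 4L; kj <- 2L
  d <- 0.01
  Dx <- lattice_cosine(n, ki, kj, d)       # spectrum: (d/2)N^2 at +-u0
  Dy <- matrix(0, n, n)
  alpha <- 1e-4
  dpc_x <- structure(list(values = Dx, axis = "x", arms = c("+x", "-x"),
                          n_guarded = 0L), class = "qobm_dpc")
  dpc_y <- structure(list(values = Dy, axis = "y", arms = c("+y", "-y"),
                          n_guarded = 0L), class = "qobm_dpc")
  rec <- tikhonov_phase(dpc_x, dpc_y, op$H_x, op$H_y, alpha)
  PH <- stats::fft(rec$phase)
  H0 <- op$H_x[ki + 1L, kj + 1L]
  Hy0 <- op$H_y[ki + 1L, kj + 1L]   # joint solve: both axes in the denominator
  expected <- Conj(H0) * (d / 2) * n^2 / (Mod(H0)^2 + Mod(Hy0)^2 + alpha)
  expect_lt(Mod(PH[ki + 1L, kj + 1L] - expected), 1e-10 * Mod(expected))
  # all-zero DPC input reconstructs to exactly zero phase
  zero <- structure(list(values = matrix(0, n, n), axis = "x",
                         arms = c("+x", "-x"), n_guarded = 0L),
                    class = "qobm_dpc")
  zeroy <- zero; zeroy$axis <- "y"
  expect_true(all(tikhonov_phase(zero, zeroy, op$H_x, op$H_y,
                                 alpha)$phase == 0))
  expect_error(tikhonov_phase(zero, zeroy, op$H_x, op$H_y, alpha = 0),
               "alpha")
  expect_error(tikhonov_phase(zero, zeroy, op$H_x * 0, op$H_y * 0, 1e-4),
               "no phase transfer")
})

test_that("noiseless round trip recovers band-limited weak phantoms", {
  sys <- optical_system(0.72, 0.6, 0.25, c(256, 256))
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.3, seed = 42)
  fr <- simulate_intensities(bl$phase, op$tfs)
  rec <- reconstruct_field(fr, op$H_x, op$H_y, alpha = 1e-4)
  expect_lt(band_rmse_frac(rec$phase, bl$phase, bl$band, 0.3), 0.02)
})

test_that("round-trip error is non-decreasing in the regularization", {
  sys <- tiny_system(64)
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.3, seed = 9)
  fr <- simulate_intensities(bl$phase, op$tfs)
  rmse <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1), function(a)
    band_rmse_frac(reconstruct_field(fr, op$H_x, op$H_y, a)$phase,
                   bl$phase, bl$band, 0.3), numeric(1))
  expect_true(all(diff(rmse) >= 0))
})

test_that("constant phase offsets are unobservable (DC neutrality)", {
  sys <- tiny_system(64)
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.2, seed = 5)
  r1 <- reconstruct_field(simulate_intensities(bl$phase, op$tfs),
                          op$H_x, op$H_y, 1e-4)
  r2 <- reconstruct_field(simulate_intensities(bl$phase + 0.4, op$tfs),
                          op$H_x, op$H_y, 1e-4)
  expect_lt(max(abs(r1$phase - r2$phase)), 1e-8)
})

test_that("under shot noise the best regularization grows", {
  # the expected (Monte-Carlo averaged) band RMSE under shot noise is
  # minimized at a strictly larger alpha than the noiseless error
  sys <- tiny_system(64)
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.3, seed = 13)
  alphas <- 10^seq(-6, -1, by = 0.5)
  fr0 <- simulate_intensities(bl$phase, op$tfs)
  rmse0 <- vapply(alphas, function(a)
    band_rmse_frac(reconstruct_field(fr0, op$H_x, op$H_y, a)$phase,
                   bl$phase, bl$band, 0.3), numeric(1))
  rmsen <- rowMeans(vapply(1:8, function(s) {
    frn <- simulate_intensities(bl$phase, op$tfs, noise = "poisson",
                                photon_scale = 1e4, seed = 30 + s)
    vapply(alphas, function(a)
      band_rmse_frac(reconstruct_field(frn, op$H_x, op$H_y, a)$phase,
                     bl$phase, bl$band, 0.3), numeric(1))
  }, numeric(length(alphas))))
  expect_true(all(is.finite(rmsen)))
  expect_gt(alphas[which.min(rmsen)], alphas[which.min(rmse0)])
})

test_that("rotating the field by 90 degrees rotates the reconstruction", {
  sys <- tiny_system(64)
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.2, seed = 17)
  rot90 <- function(m) t(m)[, nrow(m):1]
  r1 <- reconstruct_field(simulate_intensities(bl$phase, op$tfs),
                          op$H_x, op$H_y, 1e-4)
  r2 <- reconstruct_field(simulate_intensities(rot90(bl$phase), op$tfs),
                          op$H_x, op$H_y, 1e-4)
  expect_lt(max(abs(r2$phase - rot90(r1$phase))),
            1e-6 * max(abs(r1$phase)))
})

test_that("stack reconstruction preserves order and reports slice errors", {
  sys <- tiny_system(32)
  op <- build_optics(sys)
  bl <- bandlimited_phase(op$grid, peak = 0.2, seed = 3)
  fr <- simulate_intensities(bl$phase, op$tfs)
  zs <- structure(list(slices = rep(list(fr), 3), slice_spacing_um = 1.5),
                  class = "qobm_zstack")
  recs <- reconstruct_stack(zs, op$H_x, op$H_y, 1e-4)
  expect_length(recs, 3)
  expect_equal(attr(recs, "slice_spacing_um"), 1.5)
  expect_equal(recs[[1]]$phase, recs[[3]]$phase)
  single <- reconstruct_field(fr, op$H_x, op$H_y, 1e-4)
  expect_equal(recs[[1]]$phase, single$phase)
  bad <- zs
  bad$slices[[2]]$frames[["+y"]] <- NULL
  expect_error(reconstruct_stack(bad, op$H_x, op$H_y, 1e-4), "slice 2")
  expect_error(reconstruct_stack(list(), op$H_x, op$H_y), "empty")
})

test_that("per-slice round-trip fidelity holds through a seeded z stack", {
  sys <- tiny_system(64)
  op <- build_optics(sys)
  stack <- lapply(1:10, function(i) bandlimited_phase(op$grid, peak = 0.3,
                                                      seed = 50 + i))
  zs <- simulate_zstack(lapply(stack, `[[`, "phase"), op$tfs)
  recs <- reconstruct_stack(zs, op$H_x, op$H_y, 1e-4)
  for (i in seq_along(stack))
    expect_lt(band_rmse_frac(recs[[i]]$phase, stack[[i]]$phase,
                             stack[[i]]$band, 0.3), 0.02)
})
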