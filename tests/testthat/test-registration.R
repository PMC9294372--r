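test_that("standardize centres to mean 0, unit population SD, idempotently", {
  expect_equal(standardize(matrix(c(1, 1, 3, 3), 2, 2)),
               matrix(c(-1, -1, 1, 1), 2, 2))
  set.seed(7)
  f <- matrix(runif(16 * 16), 16, 16)
  s <- standardize(f)
  expect_lt(abs(mean(s)), 1e-12)
  expect_lt(abs(sqrt(mean((s - mean(s))^2)) - 1), 1e-12)
  expect_equal(standardize(s), s, tolerance = 1e-12)
  expect_error(standardize(matrix(5, 4, 4)), "degenerate")
})

test_that("ssd_objective is zero at perfect alignment and errors on empty overlap", {
  set.seed(1)
  a <- standardize(matrix(runif(64), 8, 8))
  expect_equal(ssd_objective(a, a, 0, 0), 0)
  expect_error(ssd_objective(a, a, 8, 0), "overlap")
  # shifted construction: interior rows of a shifted copy line up
  b <- caimtools:::translate_int(a, 2, 1, fill = "replicate")
  # b[i, j] = a[i - 2, j - 1]; at offset (x, y) = (2, 1): t[i, j] vs b[i+2, j+1] = a[i, j]
  expect_lt(ssd_objective(a, b, 2, 1), 1e-20)
})

test_that("FFT shift estimation equals the brute-force objective argmin", {
  for (n in c(8, 16, 32)) {
    for (ms in c(2, 4)) {
      if (n - 2 * ms < 4) next   # central crop would be smaller than 4 x 4
      for (seed in 1:3) {
        set.seed(seed * 100 + n)
        tpl <- standardize(matrix(runif(n * n), n, n))
        frm <- standardize(matrix(runif(n * n), n, n))
        got <- estimate_shift(tpl, frm, max_shift = ms)
        want <- oracle_shift(tpl, frm, ms)
        expect_identical(unname(got), want,
                         label = sprintf("n=%d ms=%d seed=%d got", n, ms, seed))
      }
    }
  }
})

test_that("true translations are recovered exactly and equivariantly", {
  base <- smooth_texture(64, 64, seed = 11)
  tpl <- standardize(base)
  for (d in list(c(3, -2), c(-5, 5), c(0, 7))) {
    frm <- caimtools:::translate_int(base, d[1], d[2], fill = "replicate")
    got <- estimate_shift(tpl, standardize(frm), max_shift = 8)
    expect_identical(unname(got), as.integer(d))
  }
  # equivariance: shifting the frame by e moves the estimate by e
  frm <- caimtools:::translate_int(base, 1, -1, fill = "replicate")
  frm2 <- caimtools:::translate_int(frm, 2, 3, fill = "replicate")
  s1 <- estimate_shift(tpl, standardize(frm), max_shift = 8)
  s2 <- estimate_shift(tpl, standardize(frm2), max_shift = 8)
  expect_identical(unname(s2 - s1), c(2L, 3L))
})

test_that("exact ties break towards smallest |x|+|y| then row-major", {
  # period-4 stripes: offsets (0, 0), (0, 4), (4, 0), (4, 4) all tie
  tpl <- standardize(matrix(rep(c(0, 1, 2, 1), length.out = 32), 32, 32))
  got <- estimate_shift(tpl, tpl, max_shift = 4)
  expect_identical(unname(got), c(0L, 0L))
  # shifted stripes: (2, 0) and (-2, 0) tie at |x|+|y| = 2; row-major picks -2
  frm <- caimtools:::translate_int(tpl, 2, 0, fill = "replicate")
  frm <- standardize(frm)
  got2 <- estimate_shift(tpl, frm, max_shift = 4)
  want <- oracle_shift(tpl, frm, 4)
  expect_identical(unname(got2), want)
  expect_identical(want[1], -2L)
})

test_that("apply_shift inverts on the interior and fills exposed pixels", {
  f <- matrix(as.numeric(seq_len(16)), 4, 4)
  expect_equal(apply_shift(f, 0, 0), f)
  g <- apply_shift(f, 1, 0, fill = -1)
  # out[i, j] = f[i + 1, j]; last row exposed
  expect_equal(g[1:3, ], f[2:4, ])
  expect_true(all(g[4, ] == -1))
  h <- apply_shift(apply_shift(f, 2, -1), -2, 1)
  # round trip restores where neither shift sampled outside: rows 3:4, cols 1:3
  expect_equal(h[3:4, 1:3], f[3:4, 1:3])
})

test_that("register_stack recovers simulator ground truth; coarse-to-fine agrees", {
  base <- smooth_texture(96, 96, seed = 5)
  truth <- simulate_shifts(20, fps = 15, max_shift_x = 6, max_shift_y = 6,
                           jitter = 2, seed = 9)
  mov <- build_shifted_movie(base, truth)
  # register against the uncorrupted base: recovered shifts are absolute
  reg <- register_stack(mov, registration_params(max_shift = 12,
                                                 template = base))
  expect_identical(reg$shifts$dx, truth$dx)
  expect_identical(reg$shifts$dy, truth$dy)
  expect_equal(unname(registration_error(truth, reg$shifts)), c(0, 0))
  expect_true(all(abs(c(reg$shifts$dx, reg$shifts$dy)) <= 12))
  reg2 <- register_stack(mov, registration_params(max_shift = 12,
                                                  template = base,
                                                  coarse_to_fine = TRUE,
                                                  downsample_factor = 2))
  expect_identical(reg2$shifts, reg$shifts)
  # identical frames stay put
  still <- image_stack(array(rep(base, 3), c(dim(base), 3)))
  reg3 <- register_stack(still, registration_params(max_shift = 8))
  expect_true(all(reg3$shifts$dx == 0 & reg3$shifts$dy == 0))
  expect_equal(reg3$stack$data, still$data)
})

test_that("degenerate frames and oversized Ms raise clear errors", {
  base <- smooth_texture(32, 32, seed = 2)
  stk <- image_stack(array(c(base, matrix(1, 32, 32)), c(32, 32, 2)))
  expect_error(register_stack(stk, registration_params(max_shift = 4)),
               "frame 2")
  expect_error(estimate_shift(standardize(base), standardize(base),
                              max_shift = 15), "Ms too large|max_shift")
})
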