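flat_roi_fixture <- function(baseline = 100, response = 150, h = 16, w = 16) {
  tr <- trial_structure(10, baseline_frames = 1:4)
  d <- array(baseline, c(h, w, 10))
  lab <- matrix(0L, h, w)
  lab[4:8, 4:8] <- 1L
  d[4:8, 4:8, 5:7] <- response
  list(stack = image_stack(d), mask = label_mask(lab), trial = tr)
}

test_that("extract_traces computes F0 and dF/F per ROI", {
  fx <- flat_roi_fixture()
  ts <- extract_traces(fx$stack, fx$mask, fx$trial)
  expect_equal(ts$f0, 100)
  expect_equal(max(ts$dff[, 1]), 0.5)           # (150 - 100)/100
  expect_equal(ts$dff[1:4, 1], rep(0, 4))
  # constant movie: activity identically zero
  const <- flat_roi_fixture(response = 100)
  ts0 <- extract_traces(const$stack, const$mask, const$trial)
  expect_true(all(ts0$dff == 0))
})

test_that("planted transients are recovered within noise tolerance", {
  mv <- generate_cell_movie(cell_movie_spec(seed = 51))
  ts <- extract_traces(mv$stack, mv$mask, mv$spec$trial)
  for (k in seq_len(ncol(ts$dff))) {
    truth <- mv$traces[, ts$roi_ids[k]]
    rmse <- sqrt(mean((ts$dff[, k] - truth)^2))
    area <- mv$mask$rois[[ts$roi_ids[k]]]$area
    # ROI mean of additive noise has SD ~ noise_sd / (F0 sqrt(area))
    expect_lt(rmse, 3 * mv$spec$noise_sd / sqrt(area))
    expect_equal(max(ts$dff[, k]), mv$spec$transient_amplitude,
                 tolerance = 0.02)
  }
  # noise-free single cell: peak equals the planted amplitude to 0.01
  mv0 <- generate_cell_movie(cell_movie_spec(seed = 52, n_cells = 1,
                                             noise_sd = 0,
                                             transient_amplitude = 0.5))
  ts0 <- extract_traces(mv0$stack, mv0$mask, mv0$spec$trial)
  expect_equal(max(ts0$dff[, 1]), 0.5, tolerance = 0.01)
})

test_that("dF/F is scale-invariant and shifts as the closed form under offsets", {
  mv <- generate_cell_movie(cell_movie_spec(seed = 53, n_cells = 3))
  ts <- extract_traces(mv$stack, mv$mask, mv$spec$trial)
  scaled <- image_stack(mv$stack$data * 3.7, fps = mv$stack$fps)
  ts_s <- extract_traces(scaled, mv$mask, mv$spec$trial)
  expect_equal(ts_s$dff, ts$dff, tolerance = 1e-12)
  # additive offset b: F0 -> F0 + b and dff -> (F - F0)/(F0 + b)
  b <- 50
  offset <- image_stack(mv$stack$data + b, fps = mv$stack$fps)
  ts_o <- extract_traces(offset, mv$mask, mv$spec$trial)
  expect_equal(ts_o$f0, ts$f0 + b, tolerance = 1e-9)
  want <- sweep(sweep(ts$dff, 2, ts$f0, "*"), 2, ts$f0 + b, "/")
  expect_equal(ts_o$dff, want, tolerance = 1e-9)
})

test_that("classify_active applies the n-SD criterion monotonically", {
  fx <- flat_roi_fixture()
  # flat trace is inactive
  const <- flat_roi_fixture(response = 100)
  ts0 <- classify_active(extract_traces(const$stack, const$mask, const$trial))
  expect_false(any(ts0$active))
  # constructed: baseline dF/F noise 0.01, peak 0.06 -> active at 5 SD
  set.seed(60)
  tr <- trial_structure(40, baseline_frames = 1:20)
  nse <- rnorm(20, 0, 0.01)
  f <- 100 * (1 + c(nse, rep(0, 19), 0.06))
  d <- array(rep(f, each = 16 * 16), c(16, 16, 40))
  lab <- matrix(1L, 16, 16)
  ts <- extract_traces(image_stack(d), label_mask(lab), tr)
  sd_bl <- sd(ts$dff[1:20, 1])
  mu_bl <- mean(ts$dff[1:20, 1])
  tsc <- classify_active(ts, n_sd = 5)
  expect_equal(unname(tsc$active[1]), ts$peak[1] > mu_bl + 5 * sd_bl)
  expect_true(tsc$active[1])
  # monotone in n_sd: active set shrinks as n_sd grows
  mv <- generate_cell_movie(cell_movie_spec(seed = 54, n_responsive = 4))
  tse <- extract_traces(mv$stack, mv$mask, mv$spec$trial)
  act5 <- classify_active(tse, n_sd = 5)$active
  act6 <- classify_active(tse, n_sd = 6)$active
  act3 <- classify_active(tse, n_sd = 3)$active
  expect_true(all(act6 <= act5))
  expect_true(all(act5 <= act3))
  # the 3-SD variant flags at least the responsive cells
  expect_gte(sum(act3), 4)
})

test_that("sort_export orders active-first by peak and truncates to top_n", {
  tr <- trial_structure(10, baseline_frames = 1:4)
  d <- array(100, c(24, 24, 10))
  lab <- matrix(0L, 24, 24)
  peaks <- c(0.2, 0.9, 0.5)
  boxes <- list(2:6, 10:14, 18:22)
  for (k in 1:3) {
    lab[boxes[[k]], 2:6] <- k
    d[boxes[[k]], 2:6, 6:8] <- 100 * (1 + peaks[k])
  }
  ts <- classify_active(extract_traces(image_stack(d), label_mask(lab), tr))
  out <- sort_export(ts)
  expect_equal(out$summary$roi, c(2L, 3L, 1L))
  expect_equal(out$summary$rank, 1:3)
  out9 <- sort_export(ts, top_n = 2)
  expect_equal(nrow(out9$summary), 2)
  expect_equal(unique(out9$records$roi), c(2L, 3L))
  # ties in peak: stable order by centroid (row, col)
  d[boxes[[1]], 2:6, 6:8] <- 100 * 1.9
  ts2 <- classify_active(extract_traces(image_stack(d), label_mask(lab), tr))
  out2 <- sort_export(ts2)
  expect_equal(out2$summary$roi[1:2], c(1L, 2L))
  # files written when paths given
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  sort_export(ts, csv = csv, summary_json = js)
  expect_true(file.exists(csv) && file.exists(js))
  re <- read.csv(csv)
  expect_equal(sort(unique(re$roi)), 1:3)
})

test_that("degenerate-baseline ROIs are excluded with a message", {
  tr <- trial_structure(6, baseline_frames = 1:3)
  d <- array(100, c(16, 16, 6))
  d[1:5, 1:5, ] <- 0
  lab <- matrix(0L, 16, 16)
  lab[2:4, 2:4] <- 1L    # zero-baseline ROI
  lab[10:13, 10:13] <- 2L
  expect_message(ts <- extract_traces(image_stack(d), label_mask(lab), tr),
                 "degenerate")
  expect_equal(ncol(ts$dff), 1)
  expect_equal(ts$roi_ids, 2L)
})
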