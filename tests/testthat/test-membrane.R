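test_that("polyline validation catches degenerate input", {
  expect_error(polyline_roi(matrix(1, 1, 2)), "m >= 2")
  expect_error(polyline_roi(rbind(c(0, 0), c(0, 0))), "coincide")
  expect_silent(polyline_roi(data.frame(x = c(0, 5), y = c(0, 0))))
})

test_that("a straight trace over a constant row reads that constant", {
  m <- matrix(1, 64, 64); m[11, ] <- 7  # row y = 10
  img <- gray_image(m)
  tr <- suppressWarnings(  # arc < 180 px, upsampling is intended here
    extract_trace(img, polyline_roi(rbind(c(0, 10), c(63, 10)))))
  expect_length(tr$values, 180)
  expect_true(all(tr$values == 7))
})

test_that("bilinear sampling is exact on an intensity ramp", {
  n <- 64
  ramp <- gray_image(matrix(rep(0:(n - 1), each = n), n, n))  # img(x, y) = x
  tr <- suppressWarnings(
    extract_trace(ramp, polyline_roi(rbind(c(2, 5), c(50, 40)))))
  expect_equal(tr$values, seq(2, 50, length.out = 180), tolerance = 1e-9)
})

test_that("out-of-bounds vertices are rejected with their index", {
  img <- gray_image(matrix(1, 32, 32))
  expect_error(extract_trace(img, polyline_roi(rbind(c(0, 0), c(40, 10)))),
               "vertex 2")
})

test_that("diagonal checkerboard sampling stays near a line-integral oracle", {
  n <- 64
  chk <- gray_image(outer(0:(n - 1), 0:(n - 1),
                          function(y, x) (x + y) %% 2))
  roi <- polyline_roi(rbind(c(3.2, 4.7), c(55.4, 49.1)), target_length = 60)
  tr <- extract_trace(chk, roi)
  # oracle: a 10x-oversampled bilinear profile whose every 10th position
  # coincides with a coarse sample; checks arc-length parameterisation is
  # consistent across resampling densities
  fine <- suppressWarnings(  # 591 samples over a ~69 px arc upsamples
    extract_trace(chk, polyline_roi(roi$vertices, target_length = 591)))
  oracle <- fine$values[seq(1, 591, by = 10)]
  expect_lte(mean(abs(tr$values - oracle)), 0.02 * diff(range(chk)))
})

test_that("reversing the polyline reverses the profile and keeps the CV", {
  img <- random_image(64, seed = 2)
  v <- rbind(c(3, 4), c(20, 31), c(55, 12))
  fwd <- suppressWarnings(extract_trace(img, polyline_roi(v)))
  rev_ <- suppressWarnings(extract_trace(img, polyline_roi(v[3:1, ])))
  expect_equal(fwd$values, rev(rev_$values), tolerance = 1e-9)
  expect_equal(trace_cv(fwd)$cv, trace_cv(rev_)$cv, tolerance = 1e-9)
})

test_that("short traces are upsampled with a warning", {
  img <- gray_image(matrix(1:1024 / 100, 32, 32))
  expect_warning(extract_trace(img, polyline_roi(rbind(c(0, 0), c(10, 0)))),
                 "upsampled")
})

test_that("nearest-neighbour sampling is available and differs on subpixels", {
  img <- random_image(32, seed = 4)
  roi <- polyline_roi(rbind(c(0.5, 0.5), c(30.3, 20.7)), target_length = 50)
  bi <- suppressWarnings(extract_trace(img, roi, method = "bilinear"))
  nn <- suppressWarnings(extract_trace(img, roi, method = "nearest"))
  expect_false(isTRUE(all.equal(bi$values, nn$values)))
})

test_that("trace CV follows the population-sd definition", {
  expect_equal(trace_cv(rep(4, 180))$cv, 0)
  alt <- rep(c(1, 3), 90)
  st <- trace_cv(alt)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  expect_equal(st$cv, 0.5)
  expect_equal(trace_cv(alt, "sample")$sd, stats::sd(alt))
  expect_equal(trace_cv(7.3 * alt)$cv, st$cv, tolerance = 1e-12)
  expect_error(trace_cv(rep(0, 10)), "positive")
})

test_that("CV grows with added zero-mean noise on a constant baseline", {
  med_cv <- vapply(c(0.01, 0.05, 0.2), function(amp) {
    median(vapply(1:9, function(s) {
      set.seed(s)
      trace_cv(pmax(1 + stats::rnorm(180, 0, amp), 0))$cv
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_cv) > 0))
})

test_that("cv_batch aggregates per subject and separates phantom groups", {
  tr <- make_membrane_trace(seed = 1)
  tab <- cv_batch(rep(list(tr), 6), subjects = "p1")
  expect_identical(nrow(tab), 7L)
  expect_equal(tab$cv[7], trace_cv(tr)$cv)

  irregular <- lapply(1:8, function(s)
    make_membrane_trace(irregularity = 0.4, seed = s))
  regular <- lapply(1:8, function(s)
    make_membrane_trace(irregularity = 0.05, seed = s))
  tab2 <- cv_batch(c(irregular, regular),
                   subjects = rep(c("mn", "mga"), each = 8))
  roi <- tab2[tab2$level == "trace", ]
  mw <- mann_whitney(roi$cv[roi$subject == "mn"],
                     roi$cv[roi$subject == "mga"], method = "exact")
  expect_lt(mw$p_two_sided, 0.01)
  expect_gt(median(roi$cv[roi$subject == "mn"]),
            median(roi$cv[roi$subject == "mga"]))

  expect_equal(cv_batch(list(c(1, 1, 1.5, 1.5), c(1, 1, 3, 3)),
                        subjects = "s")$cv[3],
               mean(c(trace_cv(c(1, 1, 1.5, 1.5))$cv,
                      trace_cv(c(1, 1, 3, 3))$cv)))
  expect_error(cv_batch(list()), "traces")
})

test_that("polyline ROIs round-trip through CSV and JSON", {
  v <- data.frame(x = c(1.5, 10.25, 30), y = c(2, 8.5, 3))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(v, csv, row.names = FALSE)
  json <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(unname(as.matrix(v))), json)
  from_csv <- read_polyline(csv)
  from_json <- read_polyline(json)
  expect_equal(from_csv$vertices, unname(as.matrix(v)))
  expect_equal(from_json$vertices, unname(as.matrix(v)))
  unlink(c(csv, json))
})
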