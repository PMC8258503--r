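test_that("sector assignment matches the brute-force angle oracle", {
  for (n in c(8, 16, 32)) {
    got <- nephrospec:::sector_index(n)
    want <- oracle_sector_table(n)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("tiny ROIs are rejected", {
  expect_error(sector_means(gray_image(matrix(1, 6, 6))), "at least 8")
})

test_that("opposite sectors are equal for real images", {
  for (seed in 1:5) {
    pr <- sector_means(random_image(32, seed))
    expect_equal(pr$means[1:4], pr$means[5:8], tolerance = 1e-12)
    expect_true(all(pr$n_bins > 0))
  }
})

test_that("an isotropic ring phantom has a flat sector profile", {
  pr <- sector_means(ring_phantom(128))
  expect_lte(max(pr$means) / min(pr$means), 1.05)
})

test_that("vertical stripes put the dominant sector on the u axis", {
  stripes <- make_plane_wave(128, omega_x = 0.4, omega_y = 0)
  pr <- sector_means(stripes)
  expect_true((which.max(pr$means) - 1) %in% c(0, 4))
})

test_that("radar axes read off the orthogonal opposite-sector pairs", {
  prof <- structure(list(means = c(4, 2, 1, 2, 4, 2, 1, 2),
                         n_bins = rep(10L, 8)), class = "sector_profile")
  ax <- radar_axes(prof)
  expect_equal(ax$major_value, 4)
  expect_equal(ax$minor_value, 1)
  expect_equal(ax$major_direction_deg, 0)

  prof$means <- rep(3, 8)
  ax <- radar_axes(prof)
  expect_equal(ax$major_value, ax$minor_value)
  expect_equal(ax$major_direction_deg, 0)  # ties -> smallest label

  prof$means <- c(1, 5, 2, 2, 1, 5, 2, 2)
  ax <- radar_axes(prof)
  expect_equal(ax$major_value, 5)
  expect_equal(ax$minor_value, 2)  # the 135-degree axis, not the minimum
  expect_equal(ax$major_direction_deg, 45)

  prof$means <- rep(0, 8)
  expect_error(radar_axes(prof), "undefined")
})

test_that("damage index is near 1 for isotropic and low for aligned texture", {
  expect_gte(damage_index(ring_phantom(128))$damage_index, 0.95)
  aligned <- vapply(1:10, function(s) {
    damage_index(make_rod_field(orientation_kappa = 100,
                                seed = s))$damage_index
  }, numeric(1))
  fragmented <- vapply(1:10, function(s) {
    damage_index(make_rod_field(orientation_kappa = 0, rod_length_mean = 3,
                                n_rods = 200, seed = s))$damage_index
  }, numeric(1))
  expect_lte(median(aligned), 0.5)
  expect_gte(median(fragmented), 0.8)
  expect_true(all(aligned > 0 & aligned <= 1))
  expect_true(all(fragmented > 0 & fragmented <= 1))
})

test_that("damage index rises as orientation dispersion grows", {
  med_di <- vapply(c(100, 10, 2, 0), function(kap) {
    median(vapply(1:5, function(s) {
      damage_index(make_rod_field(orientation_kappa = kap,
                                  seed = s))$damage_index
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_di) > 0))
})

test_that("90-degree rotation preserves the index and rotates the axis", {
  img <- make_rod_field(orientation_kappa = 50, orientation_mode = 0,
                        seed = 3)
  rot <- gray_image(t(as.matrix(img))[, 128:1])  # 90-degree grid rotation
  a <- damage_index(img); b <- damage_index(rot)
  expect_equal(b$damage_index, a$damage_index, tolerance = 1e-9)
  expect_equal((a$major_axis_direction + 90) %% 180,
               b$major_axis_direction %% 180)
})

test_that("damage index is invariant to global intensity scaling", {
  img <- make_rod_field(orientation_kappa = 5, seed = 9)
  scaled <- gray_image(3.7 * as.matrix(img))
  expect_equal(damage_index(scaled)$damage_index,
               damage_index(img)$damage_index, tolerance = 1e-9)
})

test_that("the ellipse estimator agrees with the axis rule in direction", {
  img <- make_rod_field(orientation_kappa = 100, seed = 4)
  ax <- damage_index(img, method = "axes")
  el <- damage_index(img, method = "ellipse")
  expect_lt(el$damage_index, 0.7)
  expect_gt(el$damage_index, 0)
  expect_lte(el$minor_axis_value, el$major_axis_value)
  expect_gte(damage_index(ring_phantom(128),
                          method = "ellipse")$damage_index, 0.9)
})

test_that("damage batch aggregates per subject and separates groups", {
  img <- make_rod_field(seed = 1)
  tab <- damage_batch(rep(list(img), 3), subjects = "p1")
  expect_equal(tab$damage_index[4], tab$damage_index[1])

  aligned <- lapply(1:8, function(s)
    make_rod_field(orientation_kappa = 100, seed = s))
  fragmented <- lapply(1:8, function(s)
    make_rod_field(orientation_kappa = 0, rod_length_mean = 3, n_rods = 200,
                   seed = s))
  tab2 <- damage_batch(c(aligned, fragmented),
                       subjects = rep(c("mga", "tin"), each = 8))
  roi <- tab2[tab2$level == "roi", ]
  expect_identical(roi$subject, rep(c("mga", "tin"), each = 8))
  mw <- mann_whitney(roi$damage_index[roi$subject == "tin"],
                     roi$damage_index[roi$subject == "mga"])
  expect_lt(mw$p_two_sided, 0.01)
  expect_error(damage_batch(list()), "non-empty")
})
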