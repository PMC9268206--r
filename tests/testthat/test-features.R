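path_skel <- function(yx) {
  prune_to_longest_path(yx)
}

test_that("curve length is exact on axis-aligned and diagonal paths", {
  horiz <- path_skel(cbind(y = rep(10L, 101), x = 0:100))
  expect_equal(fiber_length(horiz), 100)
  diag11 <- path_skel(cbind(y = 0:10, x = 0:10))
  expect_equal(fiber_length(diag11), 10 * sqrt(2))
})

test_that("curve length recovers the analytic arc length of a sinusoid", {
  sp <- fiber_spec("sinusoid", center = c(110, 80), length = 140, width = 5,
                   theta_deg = 10, amplitude = 15, period = 70, peak = 200)
  sc <- render_scene(list(sp), c(220, 160), 20, 8, seed = 3)
  seg <- segment_fibers(sc$plane, fixed_config())
  expect_equal(seg$mask$label_count, 1)
  L <- sp$arc_length
  expect_lt(abs(fiber_length(seg$skeletons[[1]]) - L), 0.05 * L)
})

test_that("thickness equals the mean distance-transform value at the skeleton", {
  rect <- matrix(FALSE, 17, 80)
  rect[6:12, 6:75] <- TRUE  # width 7
  sk <- prune_to_longest_path(skeletonize_component(rect))
  th <- fiber_thickness(sk, rect)
  expect_lt(abs(th - 3.5), 0.55)

  line <- matrix(FALSE, 7, 40)
  line[4, 3:37] <- TRUE
  skl <- prune_to_longest_path(skeletonize_component(line))
  expect_equal(fiber_thickness(skl, line), 1.0)
})

test_that("thickness grows monotonically with rendered stroke width", {
  ths <- vapply(c(3, 5, 7), function(w) {
    sc <- single_fiber_scene(80, w, 40, seed = w)
    seg <- segment_fibers(sc$plane, fixed_config())
    fiber_thickness(seg$skeletons[[1]],
                    seg$mask$labels == seg$skeletons[[1]]$fiber_id)
  }, numeric(1))
  expect_true(all(diff(ths) > 0))
})

test_that("angle follows the declared flipped-y Cartesian convention", {
  expect_equal(fiber_angle(path_skel(cbind(y = rep(50L, 101),
                                           x = 10:110))), 0)
  expect_equal(fiber_angle(path_skel(cbind(y = 10:110,
                                           x = rep(50L, 101)))), 90)
  # raster-descending diagonal maps to 135 degrees with the y flip
  expect_equal(fiber_angle(path_skel(cbind(y = 0:100, x = 0:100))), 135)
  # coincident endpoints are a flagged missing value
  degen <- structure(list(endpoints = cbind(y = c(5, 5), x = c(5, 5))),
                     class = "fiber_skeleton")
  expect_true(is.na(fiber_angle(degen)))
})

test_that("intensity is the mean image value over skeleton pixels", {
  uni <- image_plane(matrix(200, 30, 30))
  sk <- path_skel(cbind(y = rep(15L, 20), x = 5:24))
  expect_equal(fiber_intensity(sk, uni), 200)

  half <- matrix(100, 30, 30)
  half[, 16:30] <- 200
  expect_equal(fiber_intensity(sk, image_plane(half)), 150)

  # skeleton of a Gaussian-profile fiber rides the bright ridge
  sp <- fiber_spec("straight", center = c(60, 40), length = 90, width = 5,
                   theta_deg = 15, peak = 240, profile = "gaussian",
                   profile_sigma = 2)
  sc <- render_scene(list(sp), c(120, 80), 10, 0, seed = 1)
  seg <- segment_fibers(sc$plane, fixed_config(value = 60))
  expect_gte(fiber_intensity(seg$skeletons[[1]], sc$plane), 200)

  out <- fibercell:::new_fiber_skeleton(1L, cbind(y = c(10L, 200L),
                                                  x = c(10L, 200L)))
  expect_error(fiber_intensity(out, uni), "outside")
})

test_that("straightness is 1 for straight paths and 2/pi for a semicircle", {
  straight <- path_skel(cbind(y = rep(3L, 50), x = 0:49))
  expect_equal(fiber_straightness(straight), 1.0)

  sp <- fiber_spec("arc", center = c(100, 60), radius = 60,
                   arc_angle_deg = 180, width = 5, theta_deg = 0, peak = 200)
  sc <- render_scene(list(sp), c(200, 140), 20, 5, seed = 2)
  seg <- segment_fibers(sc$plane, fixed_config())
  expect_equal(seg$mask$label_count, 1)
  expect_lt(abs(fiber_straightness(seg$skeletons[[1]]) - 2 / pi), 0.03)
})

test_that("alignment has the closed-form parallel/perpendicular/isotropic limits", {
  f <- data.frame(x = c(0, 10, 20), y = c(0, 0, 0),
                  angle_deg = c(30, 30, 30))
  a <- fiber_alignment(1, f, 50)
  expect_equal(a$alignment, 1.0)
  expect_equal(a$n, 2)

  fp <- data.frame(x = c(0, 10), y = c(0, 0), angle_deg = c(30, 120))
  expect_equal(fiber_alignment(1, fp, 50)$alignment, 0, tolerance = 1e-12)

  # no neighbors in radius -> missing, not zero
  expect_true(is.na(fiber_alignment(1, fp, 5)$alignment))

  # isotropic field: E[cos alpha] = 2/pi for alpha ~ U[0, 90]
  iso <- fibercell:::isotropic_fiber_field(2500, field_size = 2000, seed = 8)
  al <- alignment_all(iso, radius_px = 100)
  expect_lt(abs(mean(al$alignment, na.rm = TRUE) - 2 / pi), 0.02)
})

test_that("the fiber table is complete, ordered and deterministic", {
  specs <- place_straight_fibers(20, c(512, 512), seed = 21)
  sc <- render_scene(specs, c(512, 512), 20, 12, seed = 21)
  cfg <- fixed_config()
  seg <- segment_fibers(sc$plane, cfg)
  tab <- build_fiber_table(seg, sc$plane, cfg)
  expect_equal(nrow(tab), 20)
  expect_identical(tab$fiber_id, 1:20)
  expect_false(any(is.na(tab$length_px)))
  expect_false(any(is.na(tab$angle_deg)))
  # range invariants
  expect_true(all(tab$straightness >= 0 & tab$straightness <= 1))
  expect_true(all(tab$angle_deg >= 0 & tab$angle_deg < 180))
  expect_true(all(tab$intensity_mean >= 0 & tab$intensity_mean <= 255))
  expect_true(all(is.na(tab$alignment) |
                    (tab$alignment >= 0 & tab$alignment <= 1)))
  expect_true(all(tab$thickness_px > 0))

  tab2 <- build_fiber_table(seg, sc$plane, cfg)
  expect_identical(tab, tab2)

  empty <- segment_fibers(image_plane(matrix(0, 50, 50)), cfg)
  etab <- build_fiber_table(empty, image_plane(matrix(0, 50, 50)), cfg)
  expect_equal(nrow(etab), 0)
  expect_true("straightness" %in% names(etab))

  # micrometer columns appear only with a configured pixel size
  expect_false("length_um" %in% names(tab))
  plum <- image_plane(sc$plane$pixels, pixel_size_um = 0.5)
  tabum <- build_fiber_table(seg, plum, cfg)
  expect_equal(tabum$length_um, tabum$length_px * 0.5)
})

test_that("feature recovery holds on a parameter grid of straight fibers", {
  cfg <- fixed_config()
  for (L in c(50, 100)) {
    for (w in c(3, 7)) {
      for (th in c(0, 30, 90, 150)) {
        sc <- single_fiber_scene(L, w, th, seed = L + w + th)
        seg <- segment_fibers(sc$plane, cfg)
        expect_equal(seg$mask$label_count, 1)
        fs <- seg$skeletons[[1]]
        expect_lt(abs(fiber_length(fs) - L), 0.05 * L + 4)
        dth <- abs(fiber_angle(fs) - th) %% 180
        expect_lt(min(dth, 180 - dth), 3)
        thick <- fiber_thickness(fs, seg$mask$labels == fs$fiber_id)
        expect_lt(abs(thick - w / 2), 1)
        expect_gte(fiber_straightness(fs), 0.97)
      }
    }
  }
})

test_that("rotating the scene by 90 degrees rotates angles and not lengths", {
  sc <- single_fiber_scene(80, 5, 30, seed = 4)
  cfg <- fixed_config()
  seg <- segment_fibers(sc$plane, cfg)
  fs <- seg$skeletons[[1]]
  # rotate the pixel matrix 90 degrees counterclockwise
  rot <- image_plane(t(sc$plane$pixels)[ncol(sc$plane$pixels):1, ])
  segr <- segment_fibers(rot, cfg)
  fsr <- segr$skeletons[[1]]
  d <- (fiber_angle(fsr) - (fiber_angle(fs) + 90)) %% 180
  expect_lt(min(d, 180 - d), 3)
  expect_lt(abs(fiber_length(fsr) - fiber_length(fs)), 3)
  expect_lt(abs(fiber_straightness(fsr) - fiber_straightness(fs)), 0.02)
})
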