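test_that("simple thresholding follows the >= rule and Otsu splits bimodal", {
  uni <- image_plane(matrix(10, 20, 20))
  expect_false(any(threshold_simple(uni, 128)))
  expect_error(threshold_simple(uni, 300), "\\[0, 255\\]")

  # bar of 200 on zero background: mask equals the bar footprint exactly
  px <- matrix(0, 30, 60)
  px[12:16, 10:50] <- 200
  m <- threshold_simple(image_plane(px), 128)
  expect_identical(m, px == 200)

  bi <- matrix(20, 40, 40)
  bi[, 21:40] <- 220
  mo <- threshold_simple(image_plane(bi), "otsu")
  expect_identical(mo, bi == 220)
})

test_that("Frangi thresholding finds ridges and separates parallel fibers", {
  blank <- image_plane(matrix(50, 64, 64))
  expect_false(any(threshold_frangi(blank, c(1, 2, 3), 0.15)))
  expect_error(threshold_frangi(blank, numeric(0)), "sigma")

  sp <- fiber_spec("sinusoid", center = c(100, 75), length = 150, width = 4,
                   theta_deg = 20, amplitude = 12, period = 60, peak = 200,
                   profile = "gaussian", profile_sigma = 1.5)
  sc <- render_scene(list(sp), c(200, 150), background = 20,
                     noise_sigma = 8, seed = 5)
  m <- threshold_frangi(sc$plane, c(1, 2, 3), 0.15)
  truthpx <- sc$truth$footprints[[1]]
  dice <- 2 * length(intersect(truthpx, which(m))) /
    (length(truthpx) + sum(m))
  expect_gte(dice, 0.8)

  s1 <- fiber_spec("straight", center = c(75, 60), length = 80, width = 4)
  s2 <- fiber_spec("straight", center = c(75, 70), length = 80, width = 4)
  sc2 <- render_scene(list(s1, s2), c(150, 130), 20, 8, seed = 2)
  m2 <- threshold_frangi(sc2$plane, c(1, 2, 3), 0.15)
  expect_equal(label_components(m2, 8L, 10L)$label_count, 2)
})

test_that("component labeling counts, filters and renumbers correctly", {
  specs <- place_straight_fibers(3, c(200, 200), seed = 11)
  sc <- render_scene(specs, c(200, 200), 20, 0, seed = 11)
  fg <- sc$plane$pixels >= 110
  fm <- label_components(fg, 8L, 20L)
  expect_equal(fm$label_count, 3)
  expect_setequal(unique(as.vector(fm$labels)), 0:3)

  empty <- label_components(matrix(FALSE, 10, 10), 8L, 0L)
  expect_equal(empty$label_count, 0)

  # two crossing fibers merge into one component (documented behavior)
  a <- fiber_spec("straight", center = c(60, 60), length = 80, theta_deg = 0)
  b <- fiber_spec("straight", center = c(60, 60), length = 80, theta_deg = 90)
  scx <- render_scene(list(a, b), c(120, 120), 20, 0, seed = 1)
  fmx <- label_components(scx$plane$pixels >= 110, 8L, 20L)
  expect_equal(fmx$label_count, 1)

  # diagonal chains hold together under 8- but not 4-connectivity
  diagm <- matrix(FALSE, 10, 10)
  diagm[cbind(1:8, 1:8)] <- TRUE
  expect_equal(label_components(diagm, 8L, 0L)$label_count, 1)
  expect_equal(label_components(diagm, 4L, 0L)$label_count, 8)

  # min_size filter removes speckles and relabels survivors from 1
  fg2 <- matrix(FALSE, 30, 30)
  fg2[2, 2] <- TRUE                # 1-px speckle
  fg2[10:12, 5:25] <- TRUE         # large blob
  fm2 <- label_components(fg2, 8L, 20L)
  expect_equal(fm2$label_count, 1)
  expect_equal(sum(fm2$labels == 1), 3 * 21)
})

test_that("thinning reduces shapes to 1-px skeletons and keeps topology", {
  rect <- matrix(FALSE, 15, 110)
  rect[6:10, 6:105] <- TRUE   # 100 x 5 bar
  sk <- skeletonize_component(rect)
  coords <- mask_coords(sk)
  # near-horizontal medial line of roughly the bar length
  expect_true(nrow(coords) >= 90 && nrow(coords) <= 105)
  expect_true(all(coords[, "y"] >= 5 & coords[, "y"] <= 9))
  expect_true(all(rect[coord_index(coords)]))  # skeleton inside the mask
  # every skeleton pixel has at most 2 neighbors (1-px wide, no thick spots)
  fs <- prune_to_longest_path(sk)
  expect_gte(fs$n_pixels, 90)

  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_identical(skeletonize_component(single), single)

  expect_error(skeletonize_component(matrix(FALSE, 4, 4)), "empty")

  # plus-shaped blob keeps a branch point (motivates pruning)
  plus <- matrix(FALSE, 31, 31)
  plus[14:18, 2:30] <- TRUE
  plus[2:30, 14:18] <- TRUE
  skp <- skeletonize_component(plus)
  cp <- mask_coords(skp)
  nb <- vapply(seq_len(nrow(cp)), function(i) {
    sum(abs(cp[, 1] - cp[i, 1]) <= 1 & abs(cp[, 2] - cp[i, 2]) <= 1) - 1L
  }, integer(1))
  expect_gte(max(nb), 3)
})

test_that("pruning extracts the longest geodesic path deterministically", {
  # Y shape: two arms of 50 plus one of 20; the short arm is removed
  yk <- rbind(cbind(y = rep(50L, 51), x = 0:50),
              cbind(y = 50L - (1:50), x = rep(50L, 50)),
              cbind(y = 50L + (1:20), x = rep(50L, 20)))
  fs <- prune_to_longest_path(yk)
  expect_equal(length(unique(paste(fs$path[, 1], fs$path[, 2]))),
               fs$n_pixels)  # simple path, no repeats
  # geodesic length: both long arms with one diagonal corner cut
  expect_equal(fiber_length(fs, step = 1), 98 + sqrt(2), tolerance = 1e-9)
  expect_false(any(fs$path[, "y"] > 50))  # short arm gone

  # already-simple path is returned unchanged
  path <- cbind(y = rep(5L, 20), x = 0:19)
  fs2 <- prune_to_longest_path(path)
  expect_equal(fs2$path, path, ignore_attr = TRUE)

  # single pixel degenerates gracefully and is flagged
  fs3 <- prune_to_longest_path(cbind(y = 3L, x = 4L))
  expect_true(fs3$degenerate)
  expect_equal(fiber_length(fs3), 0)
})

test_that("pruning matches the brute-force geodesic oracle on random trees", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:60, 1)
    coords <- random_pixel_tree(n)
    fs <- prune_to_longest_path(coords)
    oracle <- oracle_longest_path(coords)
    got <- fiber_length(fs, step = 1)
    expect_equal(got, oracle$length, tolerance = 1e-9)
    expect_equal(unname(fs$path[1, ]), unname(oracle$start))
    expect_equal(unname(fs$path[nrow(fs$path), ]), unname(oracle$end))
    # pruned result always has exactly 2 endpoints and no branch pixels
    p <- fs$path
    nb <- vapply(seq_len(nrow(p)), function(i) {
      sum(abs(p[, 1] - p[i, 1]) <= 1 & abs(p[, 2] - p[i, 2]) <= 1) - 1L
    }, integer(1))
    expect_lte(max(nb), 2)
    expect_equal(sum(nb == 1), if (nrow(p) > 1) 2 else 0)
  }
})

test_that("skeletons with artifact loops prune to a simple path", {
  # a ring with two tails; the path must pass the longer side of the ring
  ring <- rbind(
    cbind(y = 10L, x = 10:14),          # top
    cbind(y = 14L, x = 10:14),          # bottom
    cbind(y = 11:13, x = 10L),          # left
    cbind(y = 11:13, x = 14L),          # right
    cbind(y = 10L, x = 5:9),            # left tail
    cbind(y = 10L, x = 15:19))          # right tail
  fs <- prune_to_longest_path(ring)
  expect_equal(length(unique(paste(fs$path[, 1], fs$path[, 2]))),
               fs$n_pixels)
  expect_equal(fs$endpoints[1, ], c(y = 10, x = 5), ignore_attr = TRUE)
  expect_equal(fs$endpoints[2, ], c(y = 10, x = 19), ignore_attr = TRUE)
  # path must exceed the straight-across length (it has no chord to cut)
  expect_gte(fiber_length(fs, step = 1), 14)
})

test_that("segment_fibers recovers planted scenes and is deterministic", {
  specs <- place_straight_fibers(20, c(512, 512), seed = 7)
  sc <- render_scene(specs, c(512, 512), 20, 15, seed = 7)
  cfg <- fixed_config()
  seg <- segment_fibers(sc$plane, cfg)
  expect_equal(seg$mask$label_count, 20)
  expect_length(seg$skeletons, 20)
  # mask and skeleton list mutually consistent; skeleton inside component
  for (fs in seg$skeletons) {
    labs <- seg$mask$labels[coord_index(fs$path)]
    expect_true(all(labs == fs$fiber_id))
  }

  blank <- image_plane(matrix(20, 64, 64))
  seg0 <- segment_fibers(blank, cfg)
  expect_equal(seg0$mask$label_count, 0)
  expect_length(seg0$skeletons, 0)

  seg2 <- segment_fibers(sc$plane, cfg)
  expect_identical(seg$mask$labels, seg2$mask$labels)  # bitwise determinism
})

test_that("speckle debris is removed by the size and length filters", {
  specs <- place_straight_fibers(10, c(400, 400), seed = 9)
  sc <- render_scene(specs, c(400, 400), 20, 0, seed = 9)
  px <- sc$plane$pixels
  # plant 50 bright 3-px speckles on background pixels
  set.seed(99)
  bg <- which(px < 100)
  for (s in sample(bg, 50)) {
    ij <- arrayInd(s, dim(px))
    if (ij[1] < nrow(px) - 1) px[ij[1] + 0:1, ij[2]] <- 220
  }
  seg <- segment_fibers(image_plane(px), fixed_config())
  expect_equal(seg$mask$label_count, 10)
})
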