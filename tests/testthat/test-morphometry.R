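test_that("component labeling is 8-connected and deterministically ordered", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:3] <- 1L
  m[7:8, 6:9] <- 1L
  parts <- label_components(m)
  expect_length(parts, 2)
  # ordered by first raster-scan pixel: topmost, then leftmost
  expect_equal(unname(parts[[1]][1, ]), c(2, 2))
  expect_equal(unname(parts[[2]][1, ]), c(7, 6))

  # diagonal chain is one component under 8-connectivity
  d <- matrix(0L, 6, 6); d[cbind(1:5, 1:5)] <- 1L
  expect_length(label_components(d), 1)

  expect_length(label_components(matrix(0L, 4, 4)), 0)

  # speckle count matches a flood-fill oracle (well-separated speckles, so
  # the 4-connected library labeling counts the same components)
  set.seed(12)
  sp <- matrix(0L, 80, 80)
  for (i in 1:60) {
    r <- sample(seq(2, 78, by = 4), 1); c <- sample(seq(2, 78, by = 4), 1)
    sp[r, c] <- 1L
  }
  expect_length(label_components(sp), max(EBImage::bwlabel(sp)))
})

test_that("basic measures match hand-computed anchors", {
  img9 <- image2d(matrix(7L, 9, 9))
  single <- basic_measures(rbind(c(5, 5)), img9)
  expect_equal(single$area_px, 1)
  expect_equal(single$perimeter_px, 4)
  expect_equal(unname(single$centroid), c(5, 5))

  sq <- rect_coords(10, 10)
  bs <- basic_measures(sq, image2d(matrix(100L, 20, 20)),
                       perimeter_method = "chain")
  expect_equal(bs$area_px, 100)
  expect_equal(bs$perimeter_px, 36)       # 4 * 9 unit steps around the chain
  expect_equal(unname(bs$centroid), c(7.5, 7.5))

  px <- matrix(0L, 5, 5)
  px[2, 2] <- 5L; px[2, 3] <- 5L; px[2, 4] <- 9L
  bi <- basic_measures(rbind(c(2, 2), c(2, 3), c(2, 4)), image2d(px))
  expect_equal(bi$mean_intensity, 19 / 3)
  expect_equal(bi$mode_intensity, 5)
  expect_equal(bi$min_intensity, 5)
  expect_equal(bi$max_intensity, 9)

  # mode ties break toward the smallest grey level
  px[2, 4] <- 9L; px[3, 2] <- 9L
  bt <- basic_measures(rbind(c(2, 2), c(2, 3), c(2, 4), c(3, 2)), image2d(px))
  expect_equal(bt$mode_intensity, 5)
})

test_that("circularity follows 4 pi A / P^2", {
  expect_equal(circularity(pi * 50^2, 2 * pi * 50), 1)
  expect_equal(circularity(4, 8), pi / 4)
  d <- disk_coords(50)
  bm <- basic_measures(d, flat_image(d))
  circ <- circularity(bm$area_px, bm$perimeter_px)
  expect_gte(circ, 0.94); expect_lte(circ, 1.06)
  expect_error(circularity(10, 0), "perimeter")
  expect_error(circularity(0, 10), "area")
})

test_that("the equivalent ellipse reproduces moment closed forms", {
  d <- disk_coords(40)
  el <- fit_ellipse(d)
  expect_equal(el$major, 80, tolerance = 0.05)
  expect_equal(el$minor, 80, tolerance = 0.05)

  # axis-aligned rectangle: orientation 0, axis ratio w/h
  rc <- rect_coords(10, 30)
  er <- fit_ellipse(rc)
  expect_equal(er$orientation, 0)
  expect_equal(er$major / er$minor, 3, tolerance = 0.05)

  # 45-degree diagonal bar orients at 45 degrees
  bar <- do.call(rbind, lapply(0:29, function(k)
    cbind(10 + k + c(0, 0, 1), 10 + k + c(0, 1, 0))))
  colnames(bar) <- c("row", "col")
  eb <- fit_ellipse(unique(bar))
  expect_equal(abs(eb$orientation), 45, tolerance = 1)

  expect_warning(fit_ellipse(rbind(c(3, 3))), "degenerate")
})

test_that("the minimum bounding rectangle is exact on rectangles", {
  rc <- rect_coords(10, 20)
  mb <- min_bounding_rectangle(rc)
  expect_equal(mb$long, 20)
  expect_equal(mb$short, 10)
  expect_equal(mb$aspect_ratio, 0.5)
  expect_equal(mb$angle %% 180, 0)

  sq <- rect_coords(12, 12)
  expect_equal(min_bounding_rectangle(sq)$aspect_ratio, 1)

  # rotating calipers never beats it: brute-force rotation sweep oracle
  set.seed(19)
  for (i in 1:5) {
    pts <- unique(cbind(sample.int(30, 80, TRUE), sample.int(30, 80, TRUE)))
    colnames(pts) <- c("row", "col")
    mb2 <- min_bounding_rectangle(pts)
    hull <- particlecut:::particle_hull(pts)
    sweep_area <- min(vapply(seq(0, 90, by = 0.1), function(a) {
      th <- a * pi / 180
      u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
      (max(hull %*% u) - min(hull %*% u)) * (max(hull %*% v) - min(hull %*% v))
    }, numeric(1)))
    expect_lte(mb2$long * mb2$short, sweep_area + 1e-6)
    # and the MBR never exceeds the axis-aligned bounding box
    aabb <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
    expect_lte(mb2$long * mb2$short, aabb + 1e-9)
  }
})

test_that("Feret diameters follow the corner convention closed forms", {
  rc <- rect_coords(10, 20)
  f <- feret_diameters(rc)
  expect_equal(f$feret_max, sqrt(20^2 + 10^2))
  expect_equal(f$feret_min, 10)
  expect_equal(f$feret_ratio, 10 / sqrt(500))

  d <- disk_coords(30)
  fd <- feret_diameters(d)
  expect_equal(fd$feret_max, 60, tolerance = 1 / 30)
  expect_equal(fd$feret_min, 60, tolerance = 1 / 30)
})

test_that("geometric ordering and ratio invariants hold across fixtures", {
  set.seed(23)
  fixtures <- list(disk_coords(20), rect_coords(8, 25),
                   unique(cbind(sample.int(40, 150, TRUE),
                                sample.int(40, 150, TRUE))))
  for (pts in fixtures) {
    colnames(pts) <- c("row", "col")
    f <- feret_diameters(pts)
    mb <- min_bounding_rectangle(pts)
    expect_lte(f$feret_min, mb$short + 1e-9)
    expect_lte(mb$long, f$feret_max + 1e-9)
    expect_gte(f$feret_ratio, 0); expect_lte(f$feret_ratio, 1)
    expect_gte(mb$aspect_ratio, 0); expect_lte(mb$aspect_ratio, 1)
  }
})

test_that("measurements are scale-equivariant and rotation-tolerant", {
  d <- disk_coords(25)
  img <- flat_image(d)
  m1 <- measure_particle(d, img, pixel_size_nm = 1)
  m2 <- measure_particle(d, img, pixel_size_nm = 2)
  expect_equal(m2$area_nm2, 4 * m1$area_nm2)
  expect_equal(m2$perimeter_nm, 2 * m1$perimeter_nm)
  expect_equal(m2$feret_max_nm, 2 * m1$feret_max_nm)
  expect_equal(m2$mbr_long_nm, 2 * m1$mbr_long_nm)
  expect_equal(m2$ellipse_major_nm, 2 * m1$ellipse_major_nm)
  expect_equal(m2$circularity, m1$circularity)
  expect_equal(m2$mbr_aspect_ratio, m1$mbr_aspect_ratio)
  expect_equal(m2$feret_ratio, m1$feret_ratio)

  # rotate an elongated blob by 90 degrees: area exact, lengths within 2%
  sc <- generate_particle_image(90, list(
    particle_spec("blob", c(45, 45), c(25, 12), rotation = 20, rng_seed = 6)),
    noise_spec(0, 0, 0), rng_seed = 6)
  p <- label_components(sc$truth)[[1]]
  rot <- cbind(row = p[, 2], col = 90 + 1 - p[, 1])
  ma <- measure_particle(p, sc$image, pixel_size_nm = 1)
  mb <- measure_particle(rot, image2d(matrix(180L, 91, 91)), pixel_size_nm = 1)
  expect_equal(mb$area_px, ma$area_px)
  expect_equal(mb$perimeter_px, ma$perimeter_px, tolerance = 0.02)
  expect_equal(mb$feret_max_nm, ma$feret_max_nm, tolerance = 0.02)
  expect_equal(mb$feret_min_nm, ma$feret_min_nm, tolerance = 0.02)
  expect_equal(mb$mbr_long_nm, ma$mbr_long_nm, tolerance = 0.02)
  expect_equal(mb$mbr_short_nm, ma$mbr_short_nm, tolerance = 0.02)
})

test_that("aggregate records behave on known shapes", {
  d <- disk_coords(30)
  md <- measure_particle(d, flat_image(d))
  expect_gt(md$circularity, 0.94); expect_lt(md$circularity, 1.06)
  expect_equal(md$mbr_aspect_ratio, 1, tolerance = 0.05)
  expect_equal(md$feret_ratio, 1, tolerance = 0.05)

  # 3:1 elongated bar: MBR aspect ~ 1/3
  bar <- rect_coords(10, 30)
  mbar <- measure_particle(bar, image2d(matrix(120L, 45, 45)))
  expect_equal(mbar$mbr_aspect_ratio, 1 / 3, tolerance = 1e-9)

  # mode intensity is a member of the particle's intensity multiset
  set.seed(40)
  img <- image2d(matrix(sample(0:255, 45 * 45, TRUE), 45, 45))
  mi <- measure_particle(bar, img)
  expect_true(mi$mode_intensity %in% img$pixels[bar])
})
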