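test_that("seed statistics are arithmetic means over the seed sets", {
  px <- matrix(0L, 10, 10)
  px[2, 2] <- 200L; px[3, 3] <- 200L
  px[8, 8] <- 100L; px[9, 9] <- 200L
  img <- image2d(px)

  s1 <- seed_set(object = rbind(c(2, 2), c(3, 3)), background = rbind(c(1, 1)))
  st <- seed_statistics(img, s1)
  expect_equal(st$I_object, 200)
  expect_equal(st$I_background, 0)

  s2 <- seed_set(object = rbind(c(8, 8), c(9, 9)), background = rbind(c(1, 1)))
  expect_equal(seed_statistics(img, s2)$I_object, 150)

  # 50 random seeds against an independent sum/count oracle
  set.seed(11)
  img2 <- image2d(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  coords <- unique(cbind(sample.int(20, 60, TRUE), sample.int(20, 60, TRUE)))
  obj <- coords[1:50, , drop = FALSE]
  bg <- coords[51:nrow(coords), , drop = FALSE]
  st2 <- seed_statistics(img2, seed_set(obj, bg))
  oracle <- sum(img2$pixels[obj]) / nrow(obj)
  expect_equal(st2$I_object, oracle)

  expect_error(seed_set(object = matrix(numeric(), 0, 2),
                        background = rbind(c(1, 1))), "nonempty")
  expect_error(seed_set(object = rbind(c(1, 1)), background = rbind(c(1, 1))),
               "disjoint")
})

test_that("regional costs follow M minus absolute intensity difference", {
  expect_equal(regional_costs(200, 200, 40, 255)$R_s, 255)
  expect_equal(regional_costs(0, 255, 40, 255)$R_s, 0)
  rc <- regional_costs(120, 180, 40, 255)
  expect_equal(rc$R_s, 195)
  expect_equal(rc$R_t, 175)
  # bounds and the maximal-at-match property
  set.seed(4)
  I <- sample(0:255, 100, replace = TRUE)
  rc2 <- regional_costs(I, 180, 40, 255)
  expect_true(all(rc2$R_s >= 0 & rc2$R_s <= 255))
  expect_true(all(rc2$R_s <= regional_costs(180, 180, 40, 255)$R_s))
  expect_error(regional_costs(300, 100, 100, 255), "\\[0, M\\]")
  expect_error(regional_costs(-1, 100, 100, 255), "\\[0, M\\]")
})

test_that("n-link capacity is a symmetric, monotone Gaussian similarity", {
  expect_equal(nlink_capacity(100, 100, 10, 1), 1)
  expect_equal(nlink_capacity(100, 100, 10, sqrt(2)), 1 / sqrt(2))
  expect_equal(nlink_capacity(0, 10, 10, 1), exp(-0.5), tolerance = 1e-12)
  set.seed(5)
  a <- sample(0:255, 200, TRUE); b <- sample(0:255, 200, TRUE)
  expect_equal(nlink_capacity(a, b, 12, 1), nlink_capacity(b, a, 12, 1))
  # monotone non-increasing in |I_p - I_q|
  d <- sort(sample(0:255, 50))
  caps <- nlink_capacity(rep(0, 50), d, 12, 1)
  expect_true(all(diff(caps) <= 0))
  expect_error(nlink_capacity(1, 2, 0, 1), "sigma")
  expect_error(nlink_capacity(1, 2, 10, 0), "dist")
})

test_that("K_max exceeds the sum of all non-hard capacities", {
  expect_equal(compute_kmax(c(1, 2, 3)), 7)
  expect_equal(compute_kmax(numeric(0)), 1)
  expect_error(compute_kmax(c(1, Inf)), "finite")
})

test_that("flow network structure matches the grid and seed layout", {
  # 2 x 1 ROI, one object and one background seed
  img <- image2d(matrix(c(200L, 50L), 1, 2))
  sds <- seed_set(object = rbind(c(1, 1)), background = rbind(c(1, 2)))
  net <- build_flow_network(img, full_roi(img), sds, cost_params(sigma = 10))
  expect_equal(net$n_pixels, 2L)
  tl <- net$cap[1:4]                       # s->p1, s->p2, p1->t, p2->t
  expect_equal(sort(tl), sort(c(net$kmax, 0, 0, net$kmax)))
  expect_equal(length(net$from), 4 + 2)    # 4 t-links + 2 directed n-links

  # 3 x 3, 8-neighborhood: 20 undirected n-links (12 axial + 8 diagonal)
  img3 <- image2d(matrix(100L, 3, 3))
  sds3 <- seed_set(object = rbind(c(2, 2)), background = rbind(c(1, 1)))
  net3 <- build_flow_network(img3, seeds = sds3, params = cost_params(sigma = 5))
  expect_equal((length(net3$from) - 2 * 9) / 2, 20)
  net4 <- build_flow_network(img3, seeds = sds3,
                             params = cost_params(sigma = 5, neighborhood = 4))
  expect_equal((length(net4$from) - 2 * 9) / 2, 12)

  # uniform ROI: every n-link capacity equals 1/dist
  ncaps <- net3$cap[-(1:18)]
  expect_true(all(abs(ncaps - 1) < 1e-12 | abs(ncaps - 1 / sqrt(2)) < 1e-12))

  expect_error(build_flow_network(img3, roi(1, 1, 2, 2),
                                  seed_set(rbind(c(3, 3)), rbind(c(1, 1))),
                                  cost_params(sigma = 5)),
               "inside the ROI")
})

test_that("non-seed t-link sums obey the regional-cost identity", {
  set.seed(9)
  img <- image2d(matrix(sample(0:255, 64, TRUE), 8, 8))
  sds <- seed_set(object = rbind(c(4, 4)), background = rbind(c(1, 1)))
  lam <- 1.7
  net <- build_flow_network(img, seeds = sds,
                            params = cost_params(lam = lam, sigma = 15))
  st <- seed_statistics(img, sds)
  npx <- net$n_pixels
  vids <- net$to[1:npx]               # s->p arcs in pixel order
  cs <- net$cap[1:npx]
  ct <- net$cap[npx + (1:npx)]
  # recover each pixel's intensity by vertex id (row-major)
  I <- as.vector(t(img$pixels))
  is_seed <- vids %in% c(net$object_seeds, net$background_seeds)
  expected <- lam * (2 * 255 - abs(st$I_object - I[vids]) -
                       abs(st$I_background - I[vids]))
  expect_equal(cs[!is_seed] + ct[!is_seed], expected[!is_seed],
               tolerance = 1e-12)
  # K_max strictly exceeds the sum of non-hard capacities
  nonhard <- c(cs[!is_seed], ct[!is_seed], net$cap[-(1:(2 * npx))])
  expect_gt(net$kmax, sum(nonhard))
})

test_that("the minimum cut never violates hard seed constraints", {
  # exhaustive cut enumeration on 3 x 3 fixtures
  set.seed(21)
  for (rep in 1:10) {
    img <- image2d(matrix(sample(0:255, 9, TRUE), 3, 3))
    cells <- as.matrix(expand.grid(row = 1:3, col = 1:3))
    picks <- sample(9, 2)
    sds <- seed_set(object = cells[picks[1], , drop = FALSE],
                    background = cells[picks[2], , drop = FALSE])
    net <- build_flow_network(img, seeds = sds, params = cost_params(sigma = 20))
    oracle <- enumerate_pixel_cuts(net)
    mf <- max_flow(net)
    expect_equal(mf$flow, oracle$min_cut, tolerance = 1e-9)
    mask <- particlecut:::cut_to_mask(net, min_cut_partition(mf))
    # hard constraints respected by the computed cut
    expect_true(all(mask[sds$object] == 1))
    expect_true(all(mask[sds$background] == 0))
    # and by the enumerated optimum (any seed-violating cut costs >= K_max)
    lab <- matrix(oracle$labeling[order(c(t(matrix(1:9, 3, 3))))], 3, 3)
    expect_true(all(lab[sds$object]))
    expect_true(all(!lab[sds$background]))
  }
})

test_that("sigma auto-estimation floors at one grey level", {
  flat <- image2d(matrix(100L, 10, 10))
  expect_equal(estimate_sigma(flat), 1.0)
  set.seed(3)
  noisy <- image2d(matrix(pmin(pmax(round(rnorm(10000, 128, 10)), 0), 255), 100, 100))
  s <- estimate_sigma(noisy)
  expect_gt(s, 10)            # neighbour differences have sd ~ sqrt(2) * 10
  expect_lt(s, 18)
})
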