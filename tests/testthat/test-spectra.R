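test_that("spectrum parsing validates, sorts and range-filters", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(energy_keV = c(2, 1, 3), counts = c(5, 4, 6)), tmp,
            row.names = FALSE)
  sp <- read_spectrum(tmp)
  expect_length(sp$energy, 3)
  expect_equal(sp$energy, c(1, 2, 3))
  expect_equal(sp$counts, c(4, 5, 6))

  write.csv(data.frame(energy_keV = c(1, 12), counts = c(5, 9)), tmp,
            row.names = FALSE)
  expect_warning(sp2 <- read_spectrum(tmp), "dropped")
  expect_length(sp2$energy, 1)

  writeLines(c("energy_keV,counts", "a,b"), tmp)
  expect_error(read_spectrum(tmp), "non-numeric")
  expect_error(read_spectrum(tempfile()), "not found")
  expect_error(eds_spectrum(c(1, 1), c(2, 2)), "strictly increasing")
  expect_error(eds_spectrum(1, -3), "nonnegative")
})

test_that("peak detection recovers Gaussian peaks on a flat background", {
  # noiseless single peak: center exact, height equals the amplitude
  sp <- generate_spectrum(data.frame(energy = 6.4, amplitude = 400),
                          poisson_noise = FALSE)
  pk <- detect_peaks(sp, min_prominence = 50)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$energy, 6.4, tolerance = 0.011)
  expect_equal(pk$height, 400, tolerance = 1e-6)

  # flat spectrum: nothing
  flat <- eds_spectrum(seq(0.2, 9, by = 0.01), rep(10, length(seq(0.2, 9, by = 0.01))))
  expect_equal(nrow(detect_peaks(flat, 0)), 0)

  # two peaks with 2:1 amplitudes keep their height ratio within 5%
  sp2 <- generate_spectrum(data.frame(energy = c(6.40, 5.41),
                                      amplitude = c(2000, 1000)), rng_seed = 17)
  pk2 <- detect_peaks(sp2, min_prominence = 100)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$height[1] / pk2$height[2], 2, tolerance = 0.05)
})

test_that("peak centers match an independent findpeaks cross-check", {
  skip_if_not_installed("pracma")
  sp <- generate_spectrum(data.frame(energy = c(2.0, 5.41, 7.47),
                                     amplitude = c(300, 700, 500)),
                          poisson_noise = FALSE)
  ours <- detect_peaks(sp, min_prominence = 100)
  fp <- pracma::findpeaks(sp$counts, minpeakheight = 100 + 20)
  expect_equal(sort(ours$channel), sort(fp[, 2]))
})

test_that("injected peak parameters are recovered across random spectra", {
  set.seed(70)
  worst_de <- 0; worst_rel <- 0
  for (i in 1:100) {
    k <- sample(1:3, 1)
    energies <- sort(runif(k, 1, 9))
    while (k > 1 && min(diff(energies)) < 0.6) energies <- sort(runif(k, 1, 9))
    amps <- runif(k, 100, 1000)
    sp <- generate_spectrum(data.frame(energy = energies, amplitude = amps),
                            rng_seed = i)
    pk <- detect_peaks(sp, min_prominence = 50)
    expect_gte(nrow(pk), k)
    for (j in seq_len(k)) {
      hit <- which.min(abs(pk$energy - energies[j]))
      worst_de <- max(worst_de, abs(pk$energy[hit] - energies[j]))
      worst_rel <- max(worst_rel, abs(pk$height[hit] - amps[j]) / amps[j])
    }
  }
  expect_lte(worst_de, 0.01 + 1e-9)   # within one channel width
  expect_lte(worst_rel, 0.05)         # amplitudes within 5%
})

test_that("element assignment matches nearest lines within tolerance", {
  pk <- data.frame(energy = c(6.38, 3.00), height = c(500, 100),
                   raw_counts = c(520, 120), prominence = c(500, 100),
                   channel = c(1, 2))
  as1 <- assign_elements(pk)
  expect_equal(as1$element[as1$measured_energy == 6.38], "Fe")
  expect_equal(as1$element[as1$measured_energy == 3.00], "unknown")

  # both Ni lines assign to Ni; the taller is primary
  pkni <- data.frame(energy = c(7.47, 0.85), height = c(4500, 4000),
                     raw_counts = c(4520, 4020), prominence = c(4500, 4000),
                     channel = c(1, 2))
  asni <- assign_elements(pkni)
  expect_equal(asni$element, c("Ni", "Ni"))
  expect_true(asni$primary[asni$height == 4500])
  expect_false(asni$primary[asni$height == 4000])

  expect_error(assign_elements(pk, tolerance_keV = 0), "tolerance")
})

test_that("element ratios normalize to the last element and scale freely", {
  a <- data.frame(element = c("Fe", "Zn"), line_energy = c(6.40, 8.64),
                  measured_energy = c(6.40, 8.64), height = c(400, 200),
                  prominence = c(400, 200), primary = c(TRUE, TRUE))
  r <- element_ratio(a, c("Fe", "Zn"))
  expect_equal(unname(r), c(2, 1))
  expect_equal(format_ratio(r), "2.0:1")

  # invariant under uniform scaling of all counts
  a2 <- a; a2$height <- a2$height * 37.5
  expect_equal(element_ratio(a2, c("Fe", "Zn")), r)

  # the three-element worked composition: Fe ~25000, Cr ~10800, Ni ~4200
  a3 <- data.frame(element = c("Fe", "Cr", "Ni"),
                   line_energy = c(6.40, 5.41, 7.47),
                   measured_energy = c(6.40, 5.41, 7.47),
                   height = c(25000, 10800, 4200),
                   prominence = c(25000, 10800, 4200),
                   primary = TRUE)
  r3 <- element_ratio(a3, c("Fe", "Cr", "Ni"))
  expect_equal(unname(r3), c(25000, 10800, 4200) / 4200)
  expect_equal(format_ratio(r3), "6.0:2.6:1")

  # equal heights give 1:1
  ae <- a; ae$height <- c(300, 300)
  expect_equal(unname(element_ratio(ae, c("Fe", "Zn"))), c(1, 1))

  expect_error(element_ratio(a, c("Fe", "Cu")), "Cu")
})

test_that("assignment is deterministic through the full synthetic path", {
  run <- function() {
    sp <- generate_spectrum(data.frame(energy = c(6.40, 5.41, 7.47),
                                       amplitude = c(2500, 1080, 420)),
                            rng_seed = 12)
    assign_elements(detect_peaks(sp, 50))
  }
  expect_identical(run(), run())
})
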