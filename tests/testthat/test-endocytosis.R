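test_that("cytoplasm region is an exact Euclidean-disk erosion", {
  # disk radius 30, erosion 8: area close to the pixel-count of a radius-22 disk
  m <- disk_mask(80, 30)
  reg <- cytoplasm_region(m, 8)
  expect_true(all(m[reg]))                      # region strictly inside mask
  expect_lt(abs(sum(reg) - sum(disk_mask(80, 22))) / sum(disk_mask(80, 22)), 0.05)

  # erosion 1 of a 3x3 square leaves the single center pixel
  sq <- matrix(TRUE, 3, 3)
  reg1 <- cytoplasm_region(sq, 1)
  expect_identical(which(reg1), 5L)

  # brute-force oracle on random blobs
  set.seed(5)
  for (i in 1:5) {
    bw <- disk_mask(40, sample(8:14, 1), ctr = sample(15:25, 1))
    r <- sample(2:4, 1)
    expect_identical(cytoplasm_region(bw, r), brute_erode(bw, r))
  }

  # a cell thinner than 2 x erosion empties: degenerate geometry
  expect_error(cytoplasm_region(disk_mask(30, 7), 8), "degenerate geometry")
  expect_error(cytoplasm_region(m, 0), "erosion_px")
})

test_that("erosion is monotone in the radius", {
  bw <- disk_mask(70, 25)
  prev <- bw
  for (k in 1:6) {
    cur <- cytoplasm_region(bw, k)
    expect_true(all(!cur | prev))   # cur subset of prev
    prev <- cur
  }
})

test_that("the erosion band has the expected physical width", {
  expect_equal(erosion_band_um(8, 0.08), 0.64)
})

test_that("F-cyt averages region means with equal slice weights", {
  ph <- make_cell_stack(size_px = 120, radius_px = 35,
                        cytoplasm_a594_intensity = 30, n_slices = 2)
  cfg <- analysis_config(n_slices_analyzed = 2)
  cm <- build_cell_mask(ph$stack, cfg)
  regions <- lapply(1:2, function(s) cytoplasm_region(cm$masks[s, , ], 8))
  fc <- f_cyt(regions, ph$stack, slices = 1:2)
  expect_equal(as.numeric(fc), 30, tolerance = 1e-6)

  # puncta raise the cytoplasm mean by their analytic share
  ph2 <- make_cell_stack(size_px = 160, radius_px = 50,
                         cytoplasm_a594_intensity = 30,
                         internalized_fraction = 0.3, puncta_count = 10,
                         n_slices = 1, rng_seed = 4)
  meas <- measure_compartments(ph2$stack, analysis_config(n_slices_analyzed = 1))
  expect_equal(meas$f_cyt, ph2$truth$f_cyt, tolerance = 0.05)

  # membrane-only cell: cytoplasm mean is the cytoplasm base, not the rim
  ph3 <- make_cell_stack(size_px = 120, radius_px = 35,
                         cytoplasm_a594_intensity = 0, a594_background = 0,
                         n_slices = 1)
  m3 <- measure_compartments(ph3$stack, analysis_config(n_slices_analyzed = 1))
  expect_lt(m3$f_cyt, 1)
  # empty-region error path
  expect_error(f_cyt(list(matrix(FALSE, 4, 4)), array(0, c(1, 4, 4))),
               "empty cytoplasm region")
})

test_that("compartment fractions sum to one exactly", {
  cf <- compartment_fractions(100, 100)
  expect_equal(cf$memb_fraction, 0.5)
  cf2 <- compartment_fractions(150, 50)
  expect_equal(cf2$memb_fraction, 0.75)
  expect_equal(cf2$cyt_fraction, 0.25)
  set.seed(9)
  for (i in 1:1000) {
    x <- compartment_fractions(runif(1, 0, 1e4), runif(1, 0, 1e4))
    expect_identical(x$memb_fraction + x$cyt_fraction, 1)
  }
  expect_error(compartment_fractions(0, 0), "> 0")
})

test_that("F/F0 ratios detect redistribution and cancel global gain", {
  cfg <- analysis_config(n_slices_analyzed = 2)
  ph0 <- make_cell_stack(size_px = 160, radius_px = 50, n_slices = 2)
  before <- measure_compartments(ph0$stack, cfg)
  # identical before/after: both ratios exactly 1
  r0 <- internalization_ratios(before, measure_compartments(ph0$stack, cfg))
  expect_identical(r0$f_over_f0_cyt, 1)
  expect_identical(r0$f_over_f0_memb, 1)
  # uniform x2 gain on the label channel leaves the ratios at exactly 1
  st2 <- two_channel_stack(ph0$stack$gfp, ph0$stack$a594 * 2)
  r2 <- internalization_ratios(before, measure_compartments(st2, cfg))
  expect_identical(r2$f_over_f0_cyt, 1)
  expect_identical(r2$f_over_f0_memb, 1)
  # 30% of the membrane signal moved into puncta
  ph3 <- make_cell_stack(size_px = 160, radius_px = 50, n_slices = 2,
                         internalized_fraction = 0.3, rng_seed = 2)
  after <- measure_compartments(ph3$stack, cfg)
  r3 <- internalization_ratios(before, after)
  expect_gt(r3$f_over_f0_cyt, 1)
  expect_lt(r3$f_over_f0_memb, 1)
  truth_ratio <- ph3$truth$cyt_fraction / ph0$truth$cyt_fraction
  expect_equal(r3$f_over_f0_cyt, truth_ratio, tolerance = 0.05)
})

test_that("recovered cytoplasmic F/F0 increases with the internalized fraction", {
  cfg <- analysis_config(n_slices_analyzed = 1)
  before <- measure_compartments(
    make_cell_stack(size_px = 160, radius_px = 50, n_slices = 1)$stack, cfg)
  ratios <- vapply(c(0, 0.1, 0.3, 0.5), function(f) {
    ph <- make_cell_stack(size_px = 160, radius_px = 50, n_slices = 1,
                          internalized_fraction = f, rng_seed = 8)
    internalization_ratios(before,
                           measure_compartments(ph$stack, cfg))$f_over_f0_cyt
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
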