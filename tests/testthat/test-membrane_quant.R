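test_that("contour tracing visits each boundary pixel once, in 8-adjacent order", {
  # degenerate ring: a single pixel
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  ct1 <- mask_to_contour(m1)
  expect_identical(ct1$length_px, 1L)
  expect_identical(unname(ct1$path[1, ]), c(3L, 3L))

  # filled 3x3 square: the 8 perimeter pixels, each exactly once
  m2 <- matrix(FALSE, 7, 7); m2[3:5, 3:5] <- TRUE
  ct2 <- mask_to_contour(m2)
  expect_identical(ct2$length_px, 8L)
  expect_identical(nrow(unique(ct2$path)), 8L)
  expect_false(any(ct2$path[, 1] == 4 & ct2$path[, 2] == 4))  # center excluded
  steps <- abs(diff(ct2$path))
  expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))          # 8-neighbors

  # filled disk: path = boundary pixel set, each visited once, ring closed
  m3 <- disk_mask(80, 30)
  ct3 <- mask_to_contour(m3)
  bs <- boundary_set(m3)
  expect_identical(ct3$length_px, nrow(bs))
  expect_identical(nrow(unique(ct3$path)), ct3$length_px)
  got <- ct3$path[order(ct3$path[, 1], ct3$path[, 2]), ]
  want <- bs[order(bs[, 1], bs[, 2]), ]
  expect_true(all(got == want))
  wrap <- abs(ct3$path[1, ] - ct3$path[ct3$length_px, ])
  expect_lte(max(wrap), 1)                                     # closed ring
  # digital-circle perimeter sanity: within 10% of the boundary-count oracle
  expect_lt(abs(ct3$length_px - nrow(bs)) / nrow(bs), 0.1)

  # contract violations
  m4 <- m1; m4[1, 1] <- TRUE
  expect_error(mask_to_contour(m4), "single connected component")
  m5 <- matrix(TRUE, 7, 7); m5[4, 4] <- FALSE
  expect_error(mask_to_contour(m5), "holes")
})

test_that("random break relocates the start without changing membership", {
  m <- disk_mask(40, 12)
  c1 <- mask_to_contour(m, rng_seed = 1)
  c2 <- mask_to_contour(m, rng_seed = 99)
  expect_identical(c1$length_px, c2$length_px)
  expect_identical(unique(c1$path[order(c1$path[, 1], c1$path[, 2]), ]),
                   unique(c2$path[order(c2$path[, 1], c2$path[, 2]), ]))
})

test_that("membrane mean is the unweighted mean along the path, break-invariant", {
  m <- disk_mask(60, 20)
  a <- matrix(17.5, 60, 60)
  expect_equal(membrane_mean(mask_to_contour(m), a), 17.5)
  # two different break seeds give identical means
  set.seed(3)
  a2 <- matrix(runif(3600, 0, 100), 60, 60)
  expect_identical(membrane_mean(mask_to_contour(m, 1), a2),
                   membrane_mean(mask_to_contour(m, 2), a2))
  # ring cell with the contour exactly on the rim
  ph <- make_cell_stack(size_px = 120, radius_px = 35, rim_width_px = 3,
                        membrane_intensity = 200,
                        cytoplasm_a594_intensity = 20, n_slices = 1)
  ct <- mask_to_contour(ph$truth$cell)
  expect_equal(membrane_mean(ct, ph$stack$a594[1, , ]), 200)
})

test_that("F-memb pools slice means with equal weights", {
  # identical slices at a constant membrane value
  ph <- make_cell_stack(size_px = 120, radius_px = 35, membrane_intensity = 120,
                        n_slices = 3)
  cfg <- analysis_config(n_slices_analyzed = 3)
  cm <- build_cell_mask(ph$stack, cfg)
  mm <- pooled_f_memb(ph$stack, cm, cfg)
  expect_equal(mm$f_memb, 120, tolerance = 0.02)
  expect_identical(mm$n_slices, 3L)
  expect_equal(mm$f_memb, mean(mm$per_slice_means))

  # mean-of-means arithmetic on hand-built per-slice membrane values
  base <- make_cell_stack(size_px = 100, radius_px = 30, rim_width_px = 2,
                          n_slices = 3)
  rim <- base$truth$rim
  a <- base$stack$a594
  for (s in 1:3) { pl <- a[s, , ]; pl[rim] <- c(100, 110, 120)[s]; a[s, , ] <- pl }
  st <- two_channel_stack(base$stack$gfp, a)
  cm2 <- build_cell_mask(st, cfg)
  mm2 <- pooled_f_memb(st, cm2, cfg)
  expect_equal(unname(mm2$per_slice_means), c(100, 110, 120), tolerance = 1e-6)
  expect_equal(mm2$f_memb, 110, tolerance = 1e-6)

  # excluding all slices is an error
  expect_error(pooled_f_memb(st, cm2, cfg, exclude_slices = 1:3),
               "all slices excluded")
})

test_that("F-memb recovers generator means and scales linearly", {
  # per-slice membrane values drawn from N(150, 5^2)
  set.seed(21)
  vals <- rnorm(6, 150, 5)
  base <- make_cell_stack(size_px = 100, radius_px = 30, rim_width_px = 2,
                          n_slices = 6)
  a <- base$stack$a594
  for (s in 1:6) { pl <- a[s, , ]; pl[base$truth$rim] <- vals[s]; a[s, , ] <- pl }
  st <- two_channel_stack(base$stack$gfp, a)
  cfg <- analysis_config(n_slices_analyzed = 6)
  cm <- build_cell_mask(st, cfg)
  mm <- pooled_f_memb(st, cm, cfg)
  expect_equal(mm$f_memb, mean(vals), tolerance = 0.02)
  # linearity: scaling the label channel scales F-memb
  st2 <- two_channel_stack(st$gfp, st$a594 * 3)
  mm2 <- pooled_f_memb(st2, cm, cfg)
  expect_equal(mm2$f_memb, 3 * mm$f_memb, tolerance = 1e-12)
})

test_that("percent of control matches the published worked examples", {
  expect_equal(percent_of_control(115.5, 170.7), 68)
  expect_equal(percent_of_control(85.8, 140.9), 61)
  expect_equal(percent_of_control(123.4, 123.4), 100)
  expect_error(percent_of_control(10, 0), "positive")
  expect_error(percent_of_control(10, -5), "positive")
})
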