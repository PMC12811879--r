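test_that("geometry validation names the offending element", {
  expect_s3_class(geometry_spec(), "geometry_spec")
  expect_error(geometry_spec(disk_diameter = -1), "disk_diameter")
  expect_error(geometry_spec(annulus_outer_diameter = 1), "annulus_outer")
  expect_error(geometry_spec(box_side = 1.6), "box_side")
  expect_error(geometry_spec(disk_center_offsets = c(2.5, -1.5)), "disk 1")
  expect_error(geometry_spec(disk_center_offsets = c(0.5, -0.5)), "overlap")
  expect_error(geometry_spec(raster_resolution = 0), "raster_resolution")
})

test_that("condition validation enforces patchwork and background rules", {
  expect_error(condition_spec("exp1", "rivalrous"), "exp2")
  expect_error(condition_spec("exp2", "green"), "exp2")
  bad <- list(L = c(top = "red", bottom = "red"),
              R = c(top = "green", bottom = "red"))
  expect_error(condition_spec("exp1", "gray", disk_assignment = bad),
               "patchwork")
})

test_that("gray background carries no chromatic signal and masked = total", {
  stim <- render_fields(condition_spec("exp1", "gray"))
  s <- channel_sums(stim)
  expect_equal(s$masked_sum, s$total_sum)
  a <- default_areas()
  # one disk per channel per eye, pooled over both eyes
  expect_equal(s$masked_sum[s$channel == "red"], 2 * a$disk)
  expect_equal(s$masked_sum[s$channel == "green"], 2 * a$disk)
})

test_that("green background attenuates only the green pool", {
  s <- channel_sums(render_fields(condition_spec("exp1", "green")))
  red <- s[s$channel == "red", ]
  green <- s[s$channel == "green", ]
  expect_equal(red$masked_sum, red$total_sum) # no red in the background
  expect_lt(green$masked_sum, green$total_sum)
  a <- default_areas()
  # calibrated accounting: full box extent plus both regions' green swap phase
  expect_equal(green$total_sum,
               2 * a$disk + 2 * (a$box + 2 * a$disk))
})

test_that("geometric accountings recover the plain area readings", {
  stim <- render_fields(condition_spec("exp1", "green"))
  a <- default_areas()
  s_ann <- channel_sums(stim, accounting = pool_accounting("annulus_holes"))
  expect_equal(s_ann$total_sum[s_ann$channel == "green"],
               2 * a$disk + 2 * (a$box - 2 * a$hole))
  s_box <- channel_sums(stim, accounting = pool_accounting("full_box"))
  expect_equal(s_box$total_sum[s_box$channel == "green"],
               2 * a$disk + 2 * a$box)
  s_one <- channel_sums(stim, accounting = pool_accounting("annulus_holes",
                                                           eyes = "single"))
  expect_equal(s_one$total_sum[s_one$channel == "green"],
               a$disk + (a$box - 2 * a$hole))
})

test_that("rivalry mask covers exactly the two disk interiors", {
  m <- rivalry_mask(geometry_spec())
  expect_equal(m$area, 2 * pi * 0.75^2)
  expect_identical(mask_at(m, 0, 0), 0)     # fixation lies between disks
  expect_identical(mask_at(m, 0, 1.5), 1)   # top disk centre
  expect_identical(mask_at(m, 0, -1.5), 1)  # bottom disk centre
  expect_identical(mask_at(m, 0, 1.5 + 0.8), 0) # inside the annulus ring
  mr <- rivalry_mask(geometry_spec(), mode = "raster")
  expect_true(all(mr$weights %in% c(0, 1)))
  expect_lt(abs(mr$area - m$area) / m$area, 0.01)
})

test_that("raster areas converge to the analytic areas", {
  a <- default_areas()
  stim40 <- render_fields(
    condition_spec("exp1", "gray",
                   geometry = geometry_spec(raster_resolution = 40)),
    mode = "raster")
  area40 <- sum(stim40$eyes$L$red) / 40^2
  expect_lt(abs(area40 - a$disk) / a$disk, 0.01)

  an <- normalized_drives(condition_spec("exp1", "green"))[["green"]]
  errs <- vapply(c(20, 40, 80), function(res) {
    cond <- condition_spec("exp1", "green",
                           geometry = geometry_spec(raster_resolution = res))
    abs(normalized_drives(cond, mode = "raster")[["green"]] - an)
  }, numeric(1))
  # pixelisation error shrinks with resolution (oscillating within a
  # decreasing envelope, so compare against the coarsest grid)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 1e-3)
})

test_that("channel indicators are exclusive within an eye", {
  for (bg in c("gray", "green")) {
    stim <- render_fields(
      condition_spec("exp1", bg,
                     geometry = geometry_spec(raster_resolution = 20)),
      mode = "raster")
    for (eye in c("L", "R")) {
      total <- Reduce(`+`, stim$eyes[[eye]])
      expect_true(all(total <= 1))
    }
  }
})

test_that("channel sums are invariant under the ISR eye swap", {
  for (cond in list(condition_spec("exp1", "green"),
                    condition_spec("exp1", "gray"),
                    condition_spec("exp2", "rivalrous"))) {
    s1 <- channel_sums(render_fields(cond))
    s2 <- channel_sums(render_fields(swap_eyes(cond)))
    expect_identical(s1, s2)
  }
})

test_that("mismatched raster grids are rejected", {
  stim <- render_fields(
    condition_spec("exp1", "gray",
                   geometry = geometry_spec(raster_resolution = 20)),
    mode = "raster")
  mask <- rivalry_mask(geometry_spec(raster_resolution = 40), mode = "raster")
  expect_error(channel_sums(stim, mask), "grid")
})
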