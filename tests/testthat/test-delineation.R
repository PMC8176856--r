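make_vol <- function(values, spacing = c(10, 10, 10)) {
  scalar_volume(values, spacing = spacing)
}

whole_grid_voi <- function(vol) {
  d <- dim(vol$values)
  ctr <- vol$origin + vol$spacing * (d - 1) / 2
  # circumscribing ellipsoid: covers every voxel centre
  ellipsoid_voi(ctr, vol$spacing * d)
}

test_that("suv_max_in_voi takes the maximum over VOI voxels only", {
  vals <- array(1, c(5, 5, 5))
  vol <- make_vol(vals)
  voi <- ellipsoid_voi(c(20, 20, 20), c(12, 12, 12))
  expect_equal(suv_max_in_voi(vol, voi), 1)

  vals[3, 3, 3] <- 12  # inside the VOI
  expect_equal(suv_max_in_voi(make_vol(vals), voi), 12)

  vals2 <- array(1, c(5, 5, 5))
  vals2[1, 1, 1] <- 50  # outside the VOI: ignored
  vals2[3, 3, 3] <- 12
  vol2 <- make_vol(vals2)
  expect_equal(suv_max_in_voi(vol2, voi), 12)
  mask <- rasterize(vol2, voi)
  expect_equal(suv_max_in_voi(vol2, voi), max(vol2$values[mask]))
})

test_that("roi_mean averages only ROI voxels, disc sees one slice", {
  vol <- make_vol(array(3.5, c(5, 5, 5)))
  expect_equal(roi_mean(vol, box_roi(c(20, 20, 20), 30)), 3.5)

  vals <- array(0, c(5, 5, 5))
  vals[2:4, 2:4, 2:4] <- 1:27
  expect_equal(roi_mean(make_vol(vals), box_roi(c(20, 20, 20), 30)), 14)

  # hot voxels in slices adjacent to the disc do not change its mean
  vals <- array(2, c(5, 5, 5))
  base <- roi_mean(make_vol(vals), disc_roi(c(20, 20, 20), 30))
  vals[, , 2] <- 100
  vals[, , 4] <- 100
  expect_equal(roi_mean(make_vol(vals), disc_roi(c(20, 20, 20), 30)), base)
  expect_equal(base, 2)
})

test_that("fixed-threshold segmentation counts suprathreshold VOI voxels", {
  vals <- array(2, c(3, 3, 3))
  vals[c(1, 5, 9, 14, 22)] <- 6
  vol <- make_vol(vals)  # 10 mm grid: 1 ml per voxel
  voi <- whole_grid_voi(vol)
  r <- segment_fixed(vol, voi, 4.0, "ex")
  expect_equal(r$n_voxels, 5)
  expect_equal(r$volume_ml, 5.0)
  expect_equal(r$threshold_suv, 4.0)
  expect_equal(r$volume_ml, r$n_voxels * voxel_volume_ml(vol))

  # above the maximum: empty but valid
  expect_equal(segment_fixed(vol, voi, 100)$volume_ml, 0)
  # zero threshold: the full VOI
  mask <- rasterize(vol, voi)
  expect_equal(segment_fixed(vol, voi, 0)$n_voxels, sum(mask))
})

test_that("isocontour and background-relative reduce to fixed thresholds", {
  set.seed(31)
  vals <- array(runif(7^3, 0, 10), c(7, 7, 7))
  vol <- make_vol(vals, spacing = c(3, 3, 3))
  voi <- whole_grid_voi(vol)
  mx <- suv_max_in_voi(vol, voi)

  iso <- segment_isocontour(vol, voi, 0.55, "ex")
  fix <- segment_fixed(vol, voi, 0.55 * mx, "ex")
  expect_equal(iso$n_voxels, fix$n_voxels)
  expect_equal(iso$threshold_suv, fix$threshold_suv)
  expect_equal(iso$method, "isocontour")

  rel <- segment_background_relative(vol, voi, 11.3, 0.60, "ex", "liver_rel")
  fix2 <- segment_fixed(vol, voi, 6.78, "ex")
  expect_equal(rel$n_voxels, fix2$n_voxels)
  expect_equal(rel$threshold_suv, 6.78)

  # a background threshold above the lesion max gives an empty segmentation
  vals3 <- array(1, c(5, 5, 5)); vals3[3, 3, 3] <- 12
  vol3 <- make_vol(vals3)
  r3 <- segment_background_relative(vol3, whole_grid_voi(vol3), 20.1, 0.80)
  expect_equal(r3$threshold_suv, 16.08)
  expect_equal(r3$volume_ml, 0)

  # isocontour at fraction 1.0 keeps exactly the voxels equal to the max
  r4 <- segment_isocontour(vol, voi, 1.0)
  expect_gte(r4$n_voxels, 1)
  mask <- rasterize(vol, voi)
  expect_equal(r4$n_voxels, sum(vol$values[mask] >= mx))

  # doubling the fraction can only shrink the volume
  r20 <- segment_isocontour(vol, voi, 0.20)$volume_ml
  r44 <- segment_isocontour(vol, voi, 0.44)$volume_ml
  expect_gte(r20, r44)
  b1 <- segment_background_relative(vol, voi, 5, 0.4)$volume_ml
  b2 <- segment_background_relative(vol, voi, 5, 0.8)$volume_ml
  expect_gte(b1, b2)
})

test_that("backwards threshold solves the inverse problem on a toy grid", {
  # four VOI voxels at 1 ml each with SUVs {2, 3, 5, 8}
  vals <- array(0.01, c(4, 2, 2))
  vals[1:4, 1, 1] <- c(2, 3, 5, 8)
  vol <- make_vol(vals)
  mask <- array(FALSE, dim(vals)); mask[1:4, 1, 1] <- TRUE

  bt <- backwards_threshold(vol, mask, 2.0, "toy")
  expect_equal(bt$threshold_suv, 5)
  expect_equal(bt$achieved_volume_ml, 2.0)

  # target = full VOI volume -> the minimum voxel SUV
  bt_full <- backwards_threshold(vol, mask, 4.0)
  expect_equal(bt_full$threshold_suv, 2)
  expect_equal(bt_full$achieved_volume_ml, 4.0)

  # tie between 2 ml (t=5) and 3 ml (t=3): larger threshold wins
  bt_tie <- backwards_threshold(vol, mask, 2.5)
  expect_equal(bt_tie$threshold_suv, 5)
  expect_equal(bt_tie$achieved_volume_ml, 2.0)

  # re-applying the threshold reproduces the achieved volume exactly
  expect_equal(segment_fixed(vol, mask, bt$threshold_suv)$volume_ml,
               bt$achieved_volume_ml)

  # out-of-range targets violate the contract
  expect_error(backwards_threshold(vol, mask, 0), "target")
  expect_error(backwards_threshold(vol, mask, 4.5), "target")
})

test_that("whole-image thresholding honours exclusion masks", {
  vals <- array(1, c(10, 10, 5))
  vals[2:3, 2:3, 2:3] <- 9   # lesion A: 8 voxels
  vals[7:8, 7:8, 2:3] <- 9   # lesion B: 8 voxels
  vol <- scalar_volume(vals, spacing = c(5, 5, 5))
  vv <- voxel_volume_ml(vol)

  expect_equal(whole_image_fixed(vol, 4.0), 16 * vv)

  exclB <- array(FALSE, dim(vals)); exclB[6:9, 6:9, ] <- TRUE
  expect_equal(whole_image_fixed(vol, 4.0, list(exclB)), 8 * vv)

  expect_equal(whole_image_fixed(vol, 4.0, list(array(TRUE, dim(vals)))), 0)
  expect_equal(whole_image_fixed(scalar_volume(array(1, c(3, 3, 3))), 4.0), 0)
  expect_error(whole_image_fixed(vol, 4.0, list(array(TRUE, c(2, 2, 2)))),
               "mismatch")
})

test_that("connected-component mode keeps only the component at the max", {
  vals <- array(1, c(10, 10, 5))
  vals[2:3, 2:3, 2:3] <- 9
  vals[7:8, 7:8, 2:3] <- 5   # second, dimmer island
  vol <- scalar_volume(vals, spacing = c(5, 5, 5))
  voi <- whole_grid_voi(vol)
  all_vox <- segment_fixed(vol, voi, 4.0)
  main <- segment_fixed(vol, voi, 4.0, connected = TRUE)
  expect_equal(all_vox$n_voxels, 16)
  expect_equal(main$n_voxels, 8)
})

test_that("noise-free blur-free phantoms are recovered exactly by any
           threshold between background and peak", {
  les <- lesion_spec(c(60, 95, 63), c(10, 7, 7), 12)
  cs <- generate_case(les, model = ideal_model(1.0), seed = 17)
  lesion_vox <- sum(rasterize(cs$pet, ellipsoid_voi(les$center, les$semi_axes)))
  for (t in c(1.01, 2, 5, 9, 12))
    expect_equal(segment_fixed(cs$pet, cs$voi, t)$n_voxels, lesion_vox)
})
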