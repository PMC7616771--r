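test_that("detect_nuclei finds nothing on blank fields", {
  seg <- detect_nuclei(matrix(100, 64, 64))
  expect_equal(seg$n_cells, 0)
  seg2 <- detect_nuclei(matrix(rnorm(64^2, 100, 1), 64, 64))
  expect_equal(seg2$n_cells, 0)
  expect_error(detect_nuclei(array(0, c(4, 4, 2))), "2-D")
})

test_that("detect_nuclei counts non-touching nuclei exactly", {
  fp <- gen_fluor_pair(fluor_sim_spec(n_cells = 20, width_px = 384,
                                      height_px = 384, noise_sd = 0,
                                      seed = 41))
  seg <- detect_nuclei(fp$nuclei)
  expect_equal(seg$n_cells, 20)
  expect_equal(nrow(seg$cells), 20)
  # detected centroids sit close to the designed centers
  d <- as.matrix(dist(rbind(fp$centers,
                            cbind(seg$cells$centroid_row,
                                  seg$cells$centroid_col))))
  cross <- d[1:20, 21:40]
  expect_lt(max(apply(cross, 1, min)), 2)
})

test_that("sub-minimum-area specks do not inflate the count", {
  fp <- gen_fluor_pair(fluor_sim_spec(n_cells = 15, width_px = 384,
                                      height_px = 384, noise_sd = 0,
                                      seed = 42))
  img <- fp$nuclei
  set.seed(1)
  for (i in 1:5) {   # bright 2x2 specks, area 4 < min_area_px = 20
    r <- sample(20:360, 1); c <- sample(20:360, 1)
    img[r:(r + 1), c:(c + 1)] <- max(img)
  }
  expect_equal(detect_nuclei(img)$n_cells, 15)
})

test_that("per-cell collagen follows the closed forms and linearity", {
  fp <- gen_fluor_pair(fluor_sim_spec(n_cells = 8, width_px = 256,
                                      height_px = 256,
                                      collagen_intensity = 300,
                                      background = 0, noise_sd = 0,
                                      seed = 7))
  seg <- detect_nuclei(fp$nuclei)
  expect_equal(seg$n_cells, 8)
  q <- per_cell_collagen(fp$collagen, seg)
  expect_equal(q$per_cell_intensity, 256 * 256 * 300 / 8)
  expect_equal(q$per_cell_intensity, fp$true_per_cell_collagen)
  # zero collagen -> zero intensity
  q0 <- per_cell_collagen(matrix(0, 256, 256), seg)
  expect_equal(q0$per_cell_intensity, 0)
  # doubling the image doubles the value in both modes
  q2 <- per_cell_collagen(fp$collagen * 2, seg)
  expect_equal(q2$per_cell_intensity, 2 * q$per_cell_intensity)
  qm <- per_cell_collagen(fp$collagen, seg, mode = "per_mask")
  qm2 <- per_cell_collagen(fp$collagen * 2, seg, mode = "per_mask")
  expect_equal(qm2$per_cell_intensity, 2 * qm$per_cell_intensity)
  # zero cells is an explicit error
  blank <- detect_nuclei(matrix(0, 256, 256))
  expect_error(per_cell_collagen(fp$collagen, blank), "zero cells")
})

test_that("normalization to control gives unit control and cancels gain", {
  fields <- data.frame(
    condition = rep(c("control", "TGFb"), each = 4),
    per_cell_intensity = c(10, 11, 9, 10, 21, 19, 20, 20))
  norm <- normalize_to_control(fields, "control")
  fc <- norm$fold_changes
  expect_equal(fc$fold_change[fc$condition == "control"], 1.0)
  expect_equal(fc$fold_change[fc$condition == "TGFb"], 2.0)
  # a global camera gain rescales every field identically -> same folds
  gained <- fields
  gained$per_cell_intensity <- gained$per_cell_intensity * 3.7
  expect_equal(normalize_to_control(gained, "control")$fold_changes$fold_change,
               fc$fold_change)
  expect_error(normalize_to_control(fields, "DMSO"), "control")
})

test_that("max projection equals the per-pixel brute-force maximum", {
  set.seed(3)
  stack <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  got <- max_intensity_projection(stack)
  want <- apply(stack, c(1, 2), max)
  expect_equal(got, want)
  one <- array(rnorm(16 * 16), c(16, 16, 1))
  expect_equal(max_intensity_projection(one), one[, , 1])
  zeros <- array(0, c(8, 8, 3))
  truth <- matrix(runif(64), 8, 8)
  zeros[, , 2] <- truth
  expect_equal(max_intensity_projection(zeros), truth)
  expect_error(max_intensity_projection(list()), "empty")
})

test_that("rolling ball removes flat background and is bounded", {
  flat <- matrix(7.5, 48, 48)
  rb <- rolling_ball_subtract(flat, 12)
  expect_equal(max(abs(rb$subtracted)), 0)
  set.seed(9)
  img <- matrix(runif(48 * 48, 0, 100), 48, 48)
  rb2 <- rolling_ball_subtract(img, 10)
  expect_true(all(rb2$subtracted >= 0))
  expect_true(all(rb2$subtracted <= img + 1e-9))
  expect_true(all(rb2$background <= img + 1e-9))
  expect_error(rolling_ball_subtract(img, 100), "exceeds")
})

test_that("rolling ball preserves a bright disk and flattens its background", {
  H <- 128; b <- 50
  img <- matrix(b, H, H)
  disk <- (row(img) - 64)^2 + (col(img) - 64)^2 <= 4^2   # diameter 8
  img[disk] <- b + 100
  rb <- rolling_ball_subtract(img, 30)
  expect_gt(max(rb$subtracted), 0.95 * 100)              # peak within 5%
  expect_lt(max(rb$subtracted[!disk]), 0.02 * b)         # background gone
  # idempotence on the flat-background fixture: a second pass removes ~nothing
  rb2 <- rolling_ball_subtract(rb$subtracted, 30)
  expect_lt(max(abs(rb2$subtracted[disk] - rb$subtracted[disk])),
            0.05 * 100)
})

test_that("organoid quantification recovers designed ROI means", {
  zs <- gen_zstack(5, fluor_sim_spec(width_px = 192, height_px = 192,
                                     cell_radius_px = 6, background = 20,
                                     noise_sd = 0.1, seed = 2),
                   roi_count = 3, roi_intensities = c(10, 20, 40))
  proj <- max_intensity_projection(zs$stack)
  oi <- organoid_roi_intensity(proj, zs$roi_masks, radius_px = 60)
  expect_equal(nrow(oi), 3)
  rel <- abs(oi$mean_intensity - zs$true_roi_means) / zs$true_roi_means
  expect_true(all(rel < 0.05))
  # a pure-background ROI reads ~0 after subtraction
  bg_mask <- matrix(0L, 192, 192)
  bg_mask[5:20, 5:20] <- 1L
  bg_mask[zs$roi_masks > 0] <- 0L
  oib <- organoid_roi_intensity(proj, bg_mask, radius_px = 60)
  expect_lt(oib$mean_intensity, 1)
  # relabeling ROIs permutes the records, not the values
  perm <- zs$roi_masks
  perm[zs$roi_masks == 1L] <- 3L
  perm[zs$roi_masks == 3L] <- 1L
  oip <- organoid_roi_intensity(proj, perm, radius_px = 60)
  expect_equal(oip$mean_intensity[c(3, 2, 1)], oi$mean_intensity,
               tolerance = 1e-12)
})

test_that("the FMT pipeline recovers designed condition effects", {
  n_fields <- 6
  quant <- function(gain, cond, seed0) {
    lapply(seq_len(n_fields), function(i) {
      fp <- gen_fluor_pair(fluor_sim_spec(
        n_cells = 12 + 2 * (i %% 3), width_px = 320, height_px = 320,
        collagen_intensity = 2000 * gain, background = 0, noise_sd = 20,
        seed = seed0 + i))
      fmt_quantify_field(fp$nuclei, fp$collagen, condition = cond,
                         field_id = sprintf("%s_%d", cond, i))
    })
  }
  fields <- c(quant(1, "control", 100), quant(2, "TGFb", 200),
              quant(1, "TGFb+inhibitor", 300))
  norm <- normalize_to_control(fields, "control")
  fc <- norm$fold_changes
  expect_lt(abs(fc$fold_change[fc$condition == "TGFb"] - 2), 0.1)
  expect_lt(abs(fc$fold_change[fc$condition == "TGFb+inhibitor"] - 1), 0.05)
  f <- norm$fields
  t <- wilcoxon_rank_sum(
    f$per_cell_intensity[f$condition == "control"],
    f$per_cell_intensity[f$condition == "TGFb"])
  expect_lt(t$p, 0.01)
})
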