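test_that("tissue mask is empty on background and exact on generated slides", {
  white <- rgb_slide(array(255, c(16, 16, 3)), 1)
  expect_false(any(tissue_mask(white)))
  sim <- gen_ihc_slide(ihc_sim_spec(width_px = 64, height_px = 64,
                                    tissue_fraction = 0.6, noise_sd = 0,
                                    seed = 3))
  expect_identical(tissue_mask(sim$slide), sim$tissue_mask)
})

test_that("lowering od_min only grows the tissue mask", {
  sim <- gen_ihc_slide(ihc_sim_spec(width_px = 64, height_px = 64,
                                    tissue_fraction = 0.7, noise_sd = 0.2,
                                    seed = 8))
  loose <- tissue_mask(sim$slide, od_min = 0)
  strict <- tissue_mask(sim$slide, od_min = 0.15)
  expect_true(all(loose[strict]))
})

test_that("otsu_threshold separates a two-level sample at the expected edge", {
  # {1,1,1,7,7,7} over [0,8) with 8 bins: every edge in (1,7] maximizes the
  # between-class variance; the lowest-tie rule fixes the answer at 2
  expect_equal(otsu_threshold(c(1, 1, 1, 7, 7, 7), n_bins = 8,
                              range = c(0, 8)), 2)
  expect_error(otsu_threshold(rep(5, 10)), "distinct")
})

test_that("otsu_threshold matches the exhaustive oracle on random data", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(50:400, 1)
    vals <- switch(1 + i %% 3,
                   runif(n),
                   c(rnorm(n, 0.2, 0.1), rnorm(n, 0.8, 0.15)),
                   rexp(n))
    got <- otsu_threshold(vals, n_bins = 256)
    want <- otsu_brute_force(vals, n_bins = 256)
    expect_identical(got, want)
  }
})

test_that("otsu_threshold lands between the modes of a Gaussian mixture", {
  set.seed(99)
  vals <- c(rnorm(5e4, 0.2, 0.05), rnorm(5e4, 0.8, 0.05))
  thr <- otsu_threshold(vals, n_bins = 256)
  expect_gt(thr, 0.4)
  expect_lt(thr, 0.6)
})

test_that("pooled cutoff equals per-slide Otsu for one slide and is
           order-invariant", {
  model <- hdab_stain_model()
  sims <- lapply(1:3, function(s) {
    gen_ihc_slide(ihc_sim_spec(width_px = 64, height_px = 64,
                               noise_sd = 0.02, seed = s), model)
  })
  slides <- lapply(sims, `[[`, "slide")
  single <- pooled_positive_cutoff(slides[[1]], model)
  conc <- deconvolve(od_transform(sims[[1]]$slide, 255), model)
  manual <- otsu_threshold(conc$chromogen[tissue_mask(sims[[1]]$slide,
                                                      model)])
  expect_equal(single$cutoff, manual)
  fwd <- pooled_positive_cutoff(slides, model)
  rev <- pooled_positive_cutoff(rev(slides), model)
  expect_equal(fwd$cutoff, rev$cutoff)
  expect_equal(fwd$n_pixels_pooled, rev$n_pixels_pooled)
})

test_that("pooled cutoff classifies a designed bimodal cohort correctly", {
  model <- hdab_stain_model()
  sims <- lapply(1:4, function(s) {
    gen_ihc_slide(ihc_sim_spec(width_px = 96, height_px = 96,
                               positive_fraction = 0.4, noise_sd = 0.02,
                               seed = 100 + s), model)
  })
  cut <- pooled_positive_cutoff(lapply(sims, `[[`, "slide"), model)
  expect_gt(cut$cutoff, 0.1)
  expect_lt(cut$cutoff, 1.0)
  correct <- vapply(sims, function(sim) {
    conc <- deconvolve(od_transform(sim$slide, 255), model)
    called <- conc$chromogen > cut$cutoff
    mean((called == sim$positive_mask)[sim$tissue_mask])
  }, numeric(1))
  expect_true(all(correct >= 0.99))
})

test_that("heatmap tiles conserve slide-level counts and saturate at 1", {
  model <- hdab_stain_model()
  sim <- gen_ihc_slide(ihc_sim_spec(width_px = 100, height_px = 80,
                                    tissue_fraction = 0.9, noise_sd = 0.05,
                                    seed = 31), model)
  conc <- deconvolve(od_transform(sim$slide, 255), model)
  msk <- tissue_mask(sim$slide, model)
  hm <- positivity_heatmap(conc, msk, cutoff = 0.5, tile_size_um = 32,
                           microns_per_pixel = 1, sample_id = "t")
  expect_equal(sum(hm$tiles$tissue_px), sum(msk))
  expect_equal(sum(hm$tiles$positive_px), sum(conc$chromogen > 0.5 & msk))
  w <- hm$tiles$tissue_px > 0
  weighted <- sum(hm$tiles$ratio[w] * hm$tiles$tissue_px[w]) /
    sum(hm$tiles$tissue_px)
  expect_equal(weighted, slide_positive_ratio(hm), tolerance = 1e-12)
  # all-positive slide: every tile with tissue has ratio 1
  hm1 <- positivity_heatmap(conc, msk, cutoff = -1, tile_size_um = 32)
  expect_true(all(hm1$tiles$ratio[hm1$tiles$tissue_px > 0] == 1))
  expect_true(all(is.na(hm1$tiles$ratio[hm1$tiles$tissue_px == 0])))
})

test_that("checkerboard positivity yields exactly half-positive tiles", {
  H <- 64; W <- 64
  chrom <- matrix(0, H, W)
  chrom[(row(chrom) + col(chrom)) %% 2 == 0] <- 1
  tissue <- matrix(TRUE, H, W)
  hm <- positivity_heatmap(chrom, tissue, cutoff = 0.5, tile_size_um = 16,
                           microns_per_pixel = 1)
  expect_true(all(hm$tiles$ratio == 0.5))
})

test_that("raising the cutoff never increases any tile ratio", {
  sim <- gen_ihc_slide(ihc_sim_spec(width_px = 64, height_px = 64,
                                    noise_sd = 0.1, seed = 12))
  conc <- deconvolve(od_transform(sim$slide, 255), hdab_stain_model())
  msk <- tissue_mask(sim$slide)
  lo <- positivity_heatmap(conc, msk, cutoff = 0.3, tile_size_um = 16)
  hi <- positivity_heatmap(conc, msk, cutoff = 0.6, tile_size_um = 16)
  both <- !is.na(lo$tiles$ratio)
  expect_true(all(hi$tiles$ratio[both] <= lo$tiles$ratio[both]))
})

test_that("heatmap validates shape mismatches", {
  expect_error(positivity_heatmap(matrix(0, 4, 4), matrix(TRUE, 5, 5), 0.5),
               "shapes")
})

test_that("per-field records degenerate to the slide ratio for one field", {
  sim <- gen_ihc_slide(ihc_sim_spec(width_px = 64, height_px = 64,
                                    noise_sd = 0.05, seed = 14))
  conc <- deconvolve(od_transform(sim$slide, 255), hdab_stain_model())
  msk <- tissue_mask(sim$slide)
  hm <- positivity_heatmap(conc, msk, cutoff = 0.5, tile_size_um = 64)
  f <- per_field_positivity(conc, msk, cutoff = 0.5, field_size_um = 64,
                            microns_per_pixel = 1, group = "HD")
  expect_equal(nrow(f), 1)
  expect_equal(f$positive_ratio, slide_positive_ratio(hm))
  expect_equal(f$group, "HD")
  # zero-tissue fields are dropped
  sim2 <- gen_ihc_slide(ihc_sim_spec(width_px = 64, height_px = 64,
                                     tissue_fraction = 0.4, noise_sd = 0,
                                     seed = 15))
  conc2 <- deconvolve(od_transform(sim2$slide, 255), hdab_stain_model())
  f2 <- per_field_positivity(conc2, sim2$tissue_mask, cutoff = 0.5,
                             field_size_um = 16, microns_per_pixel = 1)
  expect_true(all(f2$tissue_px > 0))
  expect_lt(nrow(f2), 16)   # the empty bottom band contributed no fields
})

test_that("per-field positivity separates low- and high-expression cohorts", {
  model <- hdab_stain_model()
  get_fields <- function(pf, seed, group) {
    sim <- gen_ihc_slide(ihc_sim_spec(width_px = 128, height_px = 128,
                                      positive_fraction = pf,
                                      noise_sd = 0.05, seed = seed), model)
    conc <- deconvolve(od_transform(sim$slide, 255), model)
    per_field_positivity(conc, sim$tissue_mask, cutoff = 0.5,
                         field_size_um = 32, microns_per_pixel = 1,
                         group = group, sample_id = paste0(group, seed))
  }
  hd <- do.call(rbind, lapply(1:2, function(s) get_fields(0.05, s, "HD")))
  mf <- do.call(rbind, lapply(1:2, function(s) get_fields(0.40, 10 + s,
                                                          "MF")))
  t <- wilcoxon_rank_sum(hd$positive_ratio, mf$positive_ratio)
  expect_lt(t$p, 0.001)
  expect_lt(median(hd$positive_ratio), median(mf$positive_ratio))
})

test_that("density correlation hits the identity, reversal and null cases", {
  sim <- gen_ihc_slide(ihc_sim_spec(width_px = 200, height_px = 128,
                                    noise_sd = 0.1, seed = 77))
  conc <- deconvolve(od_transform(sim$slide, 255), hdab_stain_model())
  hm <- positivity_heatmap(conc, sim$tissue_mask, cutoff = 0.45,
                           tile_size_um = 8, microns_per_pixel = 1)
  r <- hm$tiles$ratio
  expect_gte(sum(!is.na(r)), 400)
  ident <- intensity_density_correlation(hm, r)
  expect_equal(ident$rho, 1.0)
  flip <- intensity_density_correlation(hm, max(r, na.rm = TRUE) - r)
  expect_equal(flip$rho, -1.0)
  set.seed(5)
  perm <- r
  perm[!is.na(r)] <- sample(r[!is.na(r)])
  null <- intensity_density_correlation(hm, perm)
  expect_lt(abs(null$rho), 0.15)
  # data-frame keyed input matches the vector path
  df <- data.frame(row = hm$tiles$row, col = hm$tiles$col, density = r)
  expect_equal(intensity_density_correlation(hm, df)$rho, 1.0)
  expect_error(intensity_density_correlation(
    positivity_heatmap(matrix(1, 4, 4), matrix(TRUE, 4, 4), 0.5,
                       tile_size_um = 2),
    c(NA, NA, NA, 1)), "fewer than 3")
})
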