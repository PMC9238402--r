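# Synthetic plate rendering, image IO, kinetic exports.

test_that("noise-free renders place the exact channel amplitudes at colony peaks", {
  lay <- small_layout()
  p <- sensor_params_imager(); ins <- instrument_imager()
  img <- render_uniform(pH = 7.53, layout = lay, noise = FALSE)
  I <- channel_intensities(cell_state(7.53, L = 38000), p, ins)
  # quantization to 16-bit integers bounds the error at half a FLU
  expect_lte(abs(max(img$channel_A) - I[["I_A"]]), 0.5)
  expect_lte(abs(max(img$channel_B) - I[["I_B"]]), 0.5)
  # background everywhere far from colonies
  expect_equal(img$channel_A[1, 1], ins$background)
})

test_that("rendering is deterministic given a seed", {
  lay <- small_layout()
  col <- colony_grid(lay, pH_i = 7.4)
  a <- render_plate(lay, col, sensor_params_imager(), instrument_imager(),
                    seed = 99)
  b <- render_plate(lay, col, sensor_params_imager(), instrument_imager(),
                    seed = 99)
  expect_identical(a$channel_A, b$channel_A)
  expect_identical(a$channel_B, b$channel_B)
  c2 <- render_plate(lay, col, sensor_params_imager(), instrument_imager(),
                     seed = 100)
  expect_false(identical(a$channel_A, c2$channel_A))
})

test_that("duplicate or out-of-layout colony positions are rejected", {
  lay <- small_layout()
  col <- colony_grid(lay, pH_i = 7.4)
  dup <- rbind(col, col[1, ])
  expect_error(render_plate(lay, dup, sensor_params_imager(),
                            instrument_imager(), noise = FALSE),
               "duplicate")
  bad <- col; bad$col[1] <- 99
  expect_error(render_plate(lay, bad, sensor_params_imager(),
                            instrument_imager(), noise = FALSE),
               "outside")
})

test_that("summed above-background signal scales linearly with colony count", {
  lay <- plate_layout(n_rows = 16, n_cols = 24, pitch_mm = 4.5,
                      colony_radius_mm = 1.5, origin_mm = c(10, 10),
                      px_per_mm = 4, edge_margin = 1,
                      width_px = 500, height_px = 330)
  col384 <- colony_grid(lay, pH_i = 7.4)
  expect_equal(nrow(col384), 384)
  img384 <- render_plate(lay, col384, sensor_params_imager(),
                         instrument_imager(), noise = FALSE)
  col96 <- col384[col384$row %% 2 == 1 & col384$col %% 2 == 1, ]
  img96 <- render_plate(lay, col96, sensor_params_imager(),
                        instrument_imager(), noise = FALSE)
  bg <- instrument_imager()$background
  s384 <- sum(img384$channel_A - bg)
  s96 <- sum(img96$channel_A - bg)
  expect_equal(s384 / s96, 4, tolerance = 0.01)
})

test_that("plate images round-trip through 16-bit TIFF + sidecar bit-identically", {
  tmp <- withr::local_tempdir()
  img <- render_uniform(pH = 7.2, noise = TRUE, seed = 5)
  base <- file.path(tmp, "plate")
  write_plate_image(img, base)
  back <- read_plate_image(base)
  expect_identical(back$channel_A, img$channel_A)
  expect_identical(back$channel_B, img$channel_B)
  expect_equal(back$layout, img$layout)
  expect_equal(back$instrument, img$instrument)
})

test_that("image reading refuses missing sidecars and non-16-bit files", {
  tmp <- withr::local_tempdir()
  expect_error(read_plate_image(file.path(tmp, "nothing")),
               "sidecar not found")
  img <- render_uniform(noise = FALSE)
  base <- file.path(tmp, "plate")
  write_plate_image(img, base)
  # overwrite one channel with an 8-bit file
  tiff::writeTIFF(img$channel_A / 65535, paste0(base, "_exA.tif"),
                  bits.per.sample = 8)
  expect_error(read_plate_image(base), "8-bit")
})

test_that("kinetic exports cover both channels at every 5-min point for 1 h", {
  ks <- synthesize_kinetic_export(
    data.frame(well = c("A1", "A2"),
               preset = c("WT_S_K120", "TK2309_S_K120"), pH_ex = 6.0),
    duration = 60, interval = 5, ctab_time = 55, seed = 11)
  expect_equal(nrow(ks), 2 * 13 * 2)  # wells x timepoints x channels
  per <- table(ks$well, ks$ex_nm)
  expect_true(all(per == 13))
  expect_error(synthesize_kinetic_export(
    data.frame(well = "A1", preset = "TP1", pH_ex = 7), interval = 0),
    "interval")
  expect_error(synthesize_kinetic_export(
    data.frame(well = "A1", preset = "TP1", pH_ex = 7), ctab_time = 90),
    "ctab_time")
})

test_that("potassium-replete wild-type wells rise in ratio and drop at CTAB", {
  ks <- synthesize_kinetic_export(
    data.frame(well = "A1", preset = "WT_S_K120", pH_ex = 6.0), seed = 3)
  rt <- ratios_from_series(ks)
  pre <- rt$ratio[rt$time_min < 55]
  post <- rt$ratio[rt$time_min >= 55]
  expect_gt(pre[length(pre)], pre[1])        # homeostasis raises the ratio
  expect_lt(mean(post), min(pre[-1]))        # CTAB step toward ratio(pH 6)
  # seeded reproducibility
  ks2 <- synthesize_kinetic_export(
    data.frame(well = "A1", preset = "WT_S_K120", pH_ex = 6.0), seed = 3)
  expect_identical(ks$intensity_FLU, ks2$intensity_FLU)
})

test_that("kinetic exports round-trip through CSV with annotations", {
  tmp <- withr::local_tempdir()
  ks <- synthesize_kinetic_export(
    data.frame(well = "A1", preset = "TP1", pH_ex = 9.0), seed = 2)
  f <- file.path(tmp, "kin.csv")
  write_kinetic_csv(ks, f)
  expect_identical(readLines(f, n = 1),
                   "well,time_min,ex_nm,em_nm,intensity_FLU")
  back <- read_kinetic_csv(f)
  expect_equal(back$intensity_FLU, ks$intensity_FLU, tolerance = 1e-6)
  expect_equal(attr(back, "ctab_time"), attr(ks, "ctab_time"))
  expect_equal(attr(back, "pH_ex"), attr(ks, "pH_ex"))
})

test_that("raw-ratio planting inverts the full forward model", {
  p <- sensor_params_screen(); ins <- instrument_imager()
  targets <- c(0.44, 0.50, 0.78)
  ph <- ph_for_raw_ratio(targets, p, ins)
  expect_equal(raw_ratio(ph[1], p, ins), 0.44, tolerance = 1e-7)
  expect_equal(raw_ratio(ph[2], p, ins), 0.50, tolerance = 1e-7)
  expect_equal(raw_ratio(ph[3], p, ins), 0.78, tolerance = 1e-7)
  expect_error(ph_for_raw_ratio(0.2, p, ins), "outside the representable")
  expect_error(ph_for_raw_ratio(1.5, p, ins), "outside the representable")
})
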