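test_that("a bone-free section scores zero in every defined region", {
  mg <- generate_micrograph(tiny_micrograph_spec(pore_fill = 0, seed = 4))
  lab <- gate_pixels(mg$image)
  part <- find_scaffold(lab, kernel_px = mg$spec$kernel_px)
  met <- measure_ingrowth(lab, part)
  defined <- !is.na(met$percent)
  expect_true(any(defined))
  expect_true(all(met$percent[defined] == 0))
})

test_that("regional metrics agree with brute-force pixel recounts", {
  mg <- generate_micrograph(tiny_micrograph_spec(
    pore_fill = list(superficial = 0.05, deep = 0.58, circumference = 0.3),
    seed = 9))
  lab <- gate_pixels(mg$image)
  part <- find_scaffold(lab, kernel_px = mg$spec$kernel_px)
  met <- measure_ingrowth(lab, part)
  for (r in c("superficial", "deep", "circumference")) {
    ref <- oracle_region_fraction(mg$image, part$regions ==
                                    match(r, c("superficial", "deep",
                                               "circumference")))
    expect_equal(met$bone_px[[r]], unname(ref[["bone"]]))
    expect_equal(met$denominator_px[[r]], unname(ref[["denominator"]]))
  }
  # the 5% superficial / 58% deep contrast survives the full pipeline
  quantum <- 100 / min(met$denominator_px[c("superficial", "deep")])
  expect_lt(abs(met$percent[["superficial"]] - 5), 1 + quantum)
  expect_lt(abs(met$percent[["deep"]] - 58), 1 + quantum)
})

test_that("adding bone inside the interior never decreases the interior percent", {
  mg <- generate_micrograph(tiny_micrograph_spec(pore_fill = 0.2, seed = 6))
  lab <- gate_pixels(mg$image)
  part <- find_scaffold(lab, kernel_px = mg$spec$kernel_px)
  before <- measure_ingrowth(lab, part)$percent[["interior"]]
  img <- mg$image
  interior <- part$regions == 1L | part$regions == 2L
  cand <- which(interior & lab == 0)    # tissue pixels inside the interior
  bone_rgb <- hsv8_to_rgb(165, 130, 130)
  for (px in cand[seq_len(50)]) {
    ij <- arrayInd(px, dim(lab))
    img[ij[1], ij[2], ] <- bone_rgb
  }
  after <- measure_ingrowth(gate_pixels(img), part)$percent[["interior"]]
  expect_gte(after, before)
})

test_that("zero-denominator regions report undefined, not zero", {
  # solid scaffold block: the interior is pure scaffold
  m <- matrix(FALSE, 80, 80); m[20:60, 20:60] <- TRUE
  rgbv <- hsv8_to_rgb(105, 150, 150)
  img <- array(0, c(80, 80, 3))
  for (ch in 1:3) { pl <- matrix(rgbv[ch], 80, 80)
    pl[m] <- hsv8_to_rgb(20, 30, 40)[ch]; img[, , ch] <- pl }
  lab <- gate_pixels(img)
  part <- find_scaffold(lab, kernel_px = 3L, band_px = 3L)
  met <- measure_ingrowth(lab, part)
  expect_true("interior" %in% met$undefined)
  expect_true(is.na(met$percent[["interior"]]))
})

test_that("the QC overlay is deterministic and preserves raster shape", {
  mg <- generate_micrograph(tiny_micrograph_spec(pore_fill = 0.4, seed = 2))
  ov1 <- render_overlay(mg$image, mg$partition)
  ov2 <- render_overlay(mg$image, mg$partition)
  expect_identical(dim(ov1), dim(mg$image))
  expect_identical(ov1, ov2)
  # pixels outside the hull and away from annotations keep their color
  # up to the side tint
  exterior <- mg$partition$regions == 5L
  cy <- round(mg$partition$centerline_y) + 1L
  cx <- round(mg$partition$centroid[["x"]]) + 1L
  exterior[cy, ] <- FALSE; exterior[, cx] <- FALSE
  expect_identical(ov1[, , 1][exterior], mg$image[, , 1][exterior])
})
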