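# Synthetic micrographs --------------------------------------------------
#
# Emulates resin-embedded, SVG-stained sections: a dark square-lattice
# ceramic scaffold, pores partially filled with bone-colored tissue, blue
# soft tissue elsewhere.  Ground truth is recounted from the emitted
# pixels, never echoed from the request, so color quantization and pixel
# rounding are already folded in.

#' Specify a synthetic micrograph
#'
#' @param width,height Image size in pixels.
#' @param strut_pitch Center-to-center strut spacing in pixels (the analogue
#'   of the 0.9 mm pore spacing of the printed lattice).
#' @param strut_width Strut thickness in pixels; must be `< strut_pitch`.
#' @param pore_fill Bone fill fraction of pore space, either a single number
#'   in `[0, 1]` applied everywhere or a named list with any of `interior`,
#'   `superficial`, `deep`, `circumference` (superficial/deep default to
#'   `interior`; `circumference` defaults to `interior`).
#' @param margin Tissue margin around the scaffold block, pixels.
#' @param scaffold_color,bone_color,tissue_color 8-bit HSV triplets; the
#'   scaffold color must fall inside the scaffold gate, the bone color
#'   inside the bone gate, and the tissue color inside neither.
#' @param noise_sd Gaussian noise SD added per HSV channel (8-bit units).
#' @param kernel_px Closing kernel used to define the generator's own
#'   region partition (kept with the truth so analysis can mirror it).
#' @param seed Integer seed; identical seeds give identical images.
#' @param gates Gates used for validation and truth recounting.
#' @return A `micrograph_spec` list.
#' @export
micrograph_spec <- function(width = 240L, height = 240L, strut_pitch = 24L,
                            strut_width = 6L, pore_fill = 0.5, margin = 30L,
                            scaffold_color = c(20, 30, 40),
                            bone_color = c(165, 130, 130),
                            tissue_color = c(105, 150, 150),
                            noise_sd = 0, kernel_px = 25L, seed = 1L,
                            gates = default_gates()) {
  if (strut_pitch <= strut_width)
    stop("invalid geometry: strut_pitch must exceed strut_width")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fills <- resolve_fills(pore_fill)
  if (any(unlist(fills) < 0 | unlist(fills) > 1))
    stop("pore fill fractions must lie in [0, 1]")
  check_color <- function(col, gate, should) {
    inside <- in_gate(matrix(col, 3), gate)
    if (inside != should)
      stop(sprintf("color (%s) must be %s the %s gate",
                   paste(col, collapse = ","),
                   if (should) "inside" else "outside", gate$label))
  }
  check_color(scaffold_color, gates$scaffold, TRUE)
  check_color(bone_color, gates$bone, TRUE)
  check_color(tissue_color, gates$scaffold, FALSE)
  check_color(tissue_color, gates$bone, FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 strut_pitch = as.integer(strut_pitch),
                 strut_width = as.integer(strut_width),
                 pore_fill = fills, margin = as.integer(margin),
                 scaffold_color = scaffold_color, bone_color = bone_color,
                 tissue_color = tissue_color, noise_sd = noise_sd,
                 kernel_px = as.integer(kernel_px), seed = as.integer(seed),
                 gates = gates),
            class = "micrograph_spec")
}

resolve_fills <- function(pore_fill) {
  if (is.numeric(pore_fill) && length(pore_fill) == 1L)
    pore_fill <- list(interior = pore_fill)
  interior <- pore_fill$interior %||% 0.5
  list(superficial = pore_fill$superficial %||% interior,
       deep = pore_fill$deep %||% interior,
       circumference = pore_fill$circumference %||% interior)
}

#' Generate a synthetic stained-section micrograph
#'
#' Draws an axis-aligned square strut lattice in the scaffold color inside a
#' tissue-colored frame, then colors an exact count of pore pixels per
#' region bone-colored: `round(fill * n_region_pore_pixels)` pixels chosen
#' uniformly under the seed.  Ground-truth regional bone fractions are then
#' recounted from the emitted image by gating it, so they reflect what a
#' pixel-counting analysis can actually see.
#'
#' @param spec A [micrograph_spec()].
#' @return Object of class `micrograph`: list with `image` (RGB array
#'   0..255), `truth` (per-region bone fraction of non-scaffold pixels,
#'   plus counts), `scaffold_mask`, `partition` (the generator's
#'   [find_scaffold()] partition), and `spec`.
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "micrograph_spec"))
  h <- spec$height; w <- spec$width; m <- spec$margin
  ymat <- matrix(seq_len(h) - 1, h, w)
  xmat <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  inside <- xmat >= m & xmat < (w - m) & ymat >= m & ymat < (h - m)
  relx <- (xmat - m) %% spec$strut_pitch
  rely <- (ymat - m) %% spec$strut_pitch
  strut <- inside & (relx < spec$strut_width | rely < spec$strut_width)
  # close the lattice with struts on the far edges of the block
  far_x <- inside & xmat >= (w - m - spec$strut_width)
  far_y <- inside & ymat >= (h - m - spec$strut_width)
  scaffold <- strut | far_x | far_y
  pore <- inside & !scaffold

  partition <- find_scaffold(scaffold, kernel_px = spec$kernel_px)
  bone <- matrix(FALSE, h, w)
  with_seed(spec$seed, {
    for (r in c("superficial", "deep", "circumference")) {
      cand <- which(region_mask(partition, r) & pore)
      k <- round(spec$pore_fill[[r]] * length(cand))
      if (k > 0) bone[cand[sample.int(length(cand), k)]] <- TRUE
    }
    img <- array(0, dim = c(h, w, 3))
    paint <- function(mask, col) {
      rgbv <- hsv8_to_rgb(col[1], col[2], col[3])
      for (ch in 1:3) img[, , ch][mask] <<- rgbv[ch]
    }
    paint(!scaffold & !bone, spec$tissue_color)
    paint(scaffold, spec$scaffold_color)
    paint(bone, spec$bone_color)
    if (spec$noise_sd > 0) {
      hsv <- rgb_to_hsv8(as.vector(img[, , 1]), as.vector(img[, , 2]),
                         as.vector(img[, , 3]))
      hsv <- hsv + matrix(rnorm(length(hsv), 0, spec$noise_sd), 3)
      hsv[1, ] <- pmin(pmax(hsv[1, ], 0), 179)
      hsv[2:3, ] <- pmin(pmax(hsv[2:3, ], 0), 255)
      rgbv <- hsv8_to_rgb(hsv[1, ], hsv[2, ], hsv[3, ])
      for (ch in 1:3) img[, , ch] <- matrix(rgbv[ch, ], h, w)
    }
  })

  labels <- gate_pixels(img, spec$gates)
  truth <- recount_truth(labels, partition)
  structure(list(image = img, truth = truth, scaffold_mask = scaffold,
                 pore_mask = pore, partition = partition, spec = spec),
            class = "micrograph")
}

# truth = bone fraction of non-scaffold pixels per region, recounted from
# the gated emitted image (identical denominator convention to
# measure_ingrowth)
recount_truth <- function(labels, partition) {
  met <- measure_ingrowth(labels, partition)
  list(fraction = met$percent / 100, bone_px = met$bone_px,
       denominator_px = met$denominator_px)
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %dx%d px, pitch %d, strut %d, seed %d>\n",
              x$spec$height, x$spec$width, x$spec$strut_pitch,
              x$spec$strut_width, x$spec$seed))
  fr <- x$truth$fraction
  cat("  truth bone fractions:",
      paste(sprintf("%s=%.3f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}

#' Write a micrograph to PNG with a JSON truth sidecar
#'
#' @param x A `micrograph`.
#' @param path PNG output path; the truth sidecar goes to `<path>.json`.
#' @export
write_micrograph <- function(x, path) {
  png::writePNG(x$image / 255, path)
  truth <- lapply(x$truth, as.list)   # keep names in the JSON objects
  truth$seed <- x$spec$seed
  jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an RGB raster from PNG (or TIFF)
#'
#' @param path Image path; `.png` read via the png package, `.tif`/`.tiff`
#'   via the tiff package if installed.
#' @return RGB array `height x width x 3` with channels in 0..255.
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3, drop = FALSE] * 255)
}
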