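# Section partition and regional ingrowth -------------------------------
#
# The slide-analysis pipeline: from a gated label raster, close the dark
# scaffold lattice with a user-chosen square kernel to obtain the scaffold
# envelope ("hull"), locate its centroid and extreme points, and carve the
# raster into named regions over which percent bony ingrowth is reported.
#
# Region geometry (the named outputs are the program's; their spatial
# bounds are this package's definitions, configurable via band_px):
#   circumference : hull pixels within band_px of the hull boundary
#   interior      : hull minus circumference, split at the horizontal
#                   centerline through the centroid into
#   superficial   : interior above the centerline (y < centroid y)
#   deep          : interior on/below the centerline
#   sides         : exterior pixels within band_px (Chebyshev) of the
#                   left/right extreme points of the hull
#   exterior      : everything else
#   center        : auxiliary disk of radius 0.25 * min(hull w, h) about
#                   the centroid (overlays the labels above)
# Coordinates are 0-based, origin top-left, x rightward, y downward.

REGION_LEVELS <- c("superficial", "deep", "circumference", "sides", "exterior")

#' Locate the scaffold and partition a section into named regions
#'
#' Performs morphological closing of the scaffold mask with a square
#' structuring element of side `kernel_px`, fills interior holes to obtain
#' the scaffold envelope (hull), computes its centroid, extreme points and
#' horizontal centerline, and assigns every pixel to one of the regions
#' `superficial`, `deep`, `circumference`, `sides` or `exterior` (the
#' scaffold interior is `superficial + deep`).
#'
#' @param labels A `gate_labels` raster from [gate_pixels()], or a logical
#'   scaffold mask.
#' @param kernel_px Side of the square closing kernel in pixels; odd,
#'   `>= 1`. Default 25.
#' @param band_px Width in pixels of the circumference band and of the
#'   side neighborhoods; defaults to `kernel_px`.
#' @param orientation `"superficial_up"` (default) treats small y as the
#'   superficial surface; `"superficial_down"` flips the split.
#' @return An object of class `region_partition` with elements
#'   `scaffold_mask`, `hull_mask`, `centroid` (x, y), `extremes` (named
#'   list of (x, y) points), `centerline_y`, `regions` (integer raster with
#'   levels attribute), `center_mask`, `kernel_px`, `band_px`.
#' @export
find_scaffold <- function(labels, kernel_px = 25L, band_px = kernel_px,
                          orientation = c("superficial_up", "superficial_down")) {
  orientation <- match.arg(orientation)
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 1L || kernel_px %% 2L == 0L)
    stop("kernel_px must be an odd integer >= 1")
  scaffold <- if (is.logical(labels)) labels else label_mask(labels, "scaffold")
  if (!any(scaffold)) stop("no scaffold pixels found")
  h <- nrow(scaffold); w <- ncol(scaffold)

  hull <- if (kernel_px > 1L) {
    brush <- EBImage::makeBrush(kernel_px, shape = "box")
    EBImage::closing(scaffold * 1, brush) > 0.5
  } else scaffold
  hull <- EBImage::fillHull(hull * 1) > 0.5

  idx <- which(hull, arr.ind = TRUE)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1        # 0-based
  centroid <- c(x = mean(xs), y = mean(ys))
  pick <- function(sel) {
    cand <- which(sel)
    p <- cand[which.min(ys[cand])]              # deterministic tie-break
    c(x = xs[p], y = ys[p])
  }
  extremes <- list(
    left   = pick(xs == min(xs)), right  = pick(xs == max(xs)),
    top    = pick(ys == min(ys)), bottom = pick(ys == max(ys))
  )
  centerline_y <- if (orientation == "superficial_up") centroid[["y"]]
                  else centroid[["y"]]  # split direction handled below

  # distance of hull pixels to the background: circumference band
  dist_in <- EBImage::distmap(hull * 1)
  circumference <- hull & dist_in <= band_px
  interior <- hull & !circumference
  ymat <- matrix(seq_len(h) - 1, h, w)
  above <- ymat < centerline_y
  if (orientation == "superficial_down") above <- !above
  superficial <- interior & above
  deep <- interior & !above

  xmat <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  near_pt <- function(p) pmax(abs(xmat - p[["x"]]), abs(ymat - p[["y"]])) <= band_px
  sides <- !hull & (near_pt(extremes$left) | near_pt(extremes$right))
  exterior <- !hull & !sides

  regions <- matrix(0L, h, w)
  regions[superficial] <- 1L; regions[deep] <- 2L
  regions[circumference] <- 3L; regions[sides] <- 4L; regions[exterior] <- 5L
  attr(regions, "levels") <- REGION_LEVELS

  hull_w <- max(xs) - min(xs) + 1; hull_h <- max(ys) - min(ys) + 1
  r <- 0.25 * min(hull_w, hull_h)
  center_mask <- (xmat - centroid[["x"]])^2 + (ymat - centroid[["y"]])^2 <= r^2

  structure(list(
    scaffold_mask = scaffold, hull_mask = hull, centroid = centroid,
    extremes = extremes, centerline_y = centerline_y, regions = regions,
    center_mask = center_mask, center_radius = r,
    kernel_px = kernel_px, band_px = band_px, orientation = orientation
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition %dx%d px, kernel %d px>\n",
              nrow(x$hull_mask), ncol(x$hull_mask), x$kernel_px))
  cat(sprintf("  centroid (x, y): (%.1f, %.1f); centerline y = %.1f\n",
              x$centroid[["x"]], x$centroid[["y"]], x$centerline_y))
  tab <- table(factor(attr(x$regions, "levels")[x$regions], REGION_LEVELS))
  cat("  region pixels:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

region_mask <- function(partition, name) {
  if (name == "interior") return(partition$regions == 1L | partition$regions == 2L)
  if (name == "center") return(partition$center_mask)
  i <- match(name, REGION_LEVELS)
  if (is.na(i)) stop(sprintf("unknown region '%s'", name))
  partition$regions == i
}

#' Measure percent bony ingrowth per region
#'
#' For each named region, reports `100 * bone pixels / non-scaffold pixels`
#' within the region.  Regions with zero denominator yield `NA` and are
#' flagged rather than reported as 0.
#'
#' @param labels The `gate_labels` raster the partition was derived from.
#' @param partition A [find_scaffold()] result on the same raster.
#' @return Object of class `histo_metrics`: a list with `percent` (named
#'   numeric), `bone_px` and `denominator_px` (named integer), and
#'   `undefined` (character vector of zero-denominator regions).
#' @export
measure_ingrowth <- function(labels, partition) {
  if (!identical(dim(labels), dim(partition$regions)))
    stop("labels and partition rasters have different dimensions")
  bone <- label_mask(labels, "bone")
  scaffold <- label_mask(labels, "scaffold")
  regions <- c("interior", "superficial", "deep", "circumference", "sides",
               "center")
  pct <- num <- den <- setNames(numeric(length(regions)), regions)
  for (r in regions) {
    m <- region_mask(partition, r)
    den[r] <- sum(m & !scaffold)
    num[r] <- sum(m & bone)
    pct[r] <- if (den[r] > 0) 100 * num[r] / den[r] else NA_real_
  }
  structure(list(percent = pct, bone_px = num, denominator_px = den,
                 undefined = regions[den == 0]),
            class = "histo_metrics")
}

#' @export
print.histo_metrics <- function(x, digits = 1, ...) {
  cat("<histo_metrics> percent bony ingrowth\n")
  for (r in names(x$percent)) {
    cat(sprintf("  %-13s %s  (%d / %d px)\n", r,
                if (is.na(x$percent[r])) "undefined"
                else formatC(x$percent[r], format = "f", digits = digits),
                x$bone_px[r], x$denominator_px[r]))
  }
  invisible(x)
}

#' @export
as.data.frame.histo_metrics <- function(x, ...) {
  data.frame(region = names(x$percent), percent = unname(x$percent),
             bone_px = unname(x$bone_px),
             denominator_px = unname(x$denominator_px))
}

#' Render a check overlay of the partition
#'
#' Produces a copy of the input image with the hull boundary, centroid
#' cross, centerline, and translucent region tints, for visual QC of the
#' partition.  Deterministic for identical inputs.
#'
#' @param image RGB array (`height x width x 3`, 0..255).
#' @param partition A [find_scaffold()] result on the same raster.
#' @param alpha Tint opacity in `[0, 1]`.
#' @return RGB array with the same dimensions as `image`.
#' @export
render_overlay <- function(image, partition, alpha = 0.25) {
  if (!identical(dim(image)[1:2], dim(partition$regions)))
    stop("image and partition have different dimensions")
  out <- image * 1.0
  tint <- list(superficial = c(255, 255, 0), deep = c(0, 255, 255),
               circumference = c(255, 0, 255), sides = c(0, 255, 0))
  for (r in names(tint)) {
    m <- region_mask(partition, r)
    for (ch in 1:3)
      out[, , ch][m] <- (1 - alpha) * out[, , ch][m] + alpha * tint[[r]][ch]
  }
  # hull boundary in red: hull pixels adjacent to background
  er <- EBImage::erode(partition$hull_mask * 1,
                       EBImage::makeBrush(3, "box")) > 0.5
  boundary <- partition$hull_mask & !er
  for (ch in 1:3) out[, , ch][boundary] <- c(255, 0, 0)[ch]
  # centerline and centroid cross in white
  h <- nrow(out); w <- ncol(out)
  cy <- round(partition$centerline_y) + 1L
  if (cy >= 1 && cy <= h) for (ch in 1:3) out[cy, , ch] <- 255
  cx <- round(partition$centroid[["x"]]) + 1L
  if (cx >= 1 && cx <= w) for (ch in 1:3) out[, cx, ch] <- 255
  out
}
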