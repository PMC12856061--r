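# HSV color gates -------------------------------------------------------
#
# All gates live in the 8-bit HSV convention used by mainstream computer
# vision libraries: hue on a halved wheel in [0, 179] (1 unit = 2 degrees),
# saturation and value in [0, 255].  The stock gates for Stevenel's blue /
# van Gieson staining are: scaffold (dark lattice) [0,0,0]..[70,67,90] and
# bone (orange/purple mineralized tissue) [155,57,67]..[179,202,187].

#' Construct an HSV color gate
#'
#' A gate is an inclusive axis-aligned box in 8-bit HSV space (hue in
#' `[0, 179]`, saturation and value in `[0, 255]`).  Pixels whose HSV
#' coordinates fall inside the box, bounds included, belong to the gate's
#' class.
#'
#' @param lower,upper Numeric length-3 vectors `(h, s, v)`; `lower` must be
#'   componentwise `<= upper`.
#' @param label Class label, e.g. `"scaffold"` or `"bone"`.
#' @return An object of class `hsv_gate`.
#' @seealso [default_gates()] for the stock staining gates, [gate_pixels()].
#' @export
#' @examples
#' hsv_gate(c(155, 57, 67), c(179, 202, 187), "bone")
hsv_gate <- function(lower, upper, label) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("gate bounds must be (h, s, v) triplets")
  if (any(lower > upper))
    stop("gate lower bound exceeds upper bound componentwise")
  if (lower[1] < 0 || upper[1] > 179)
    stop("hue must lie in [0, 179] (8-bit halved-degree convention)")
  if (any(lower[2:3] < 0) || any(upper[2:3] > 255))
    stop("saturation and value must lie in [0, 255]")
  structure(list(lower = lower, upper = upper, label = as.character(label)),
            class = "hsv_gate")
}

#' @export
print.hsv_gate <- function(x, ...) {
  cat(sprintf("<hsv_gate '%s': [%s] .. [%s]>\n", x$label,
              paste(x$lower, collapse = ", "),
              paste(x$upper, collapse = ", ")))
  invisible(x)
}

#' Stock color gates for SVG-stained sections
#'
#' Scaffold (dark ceramic lattice) and bone (orange/purple mineralized
#' tissue) gates for sections stained with Stevenel's blue and van Gieson's
#' picro fuchsin.
#'
#' @return A list of two [hsv_gate()] objects named `scaffold` and `bone`.
#' @export
default_gates <- function() {
  list(
    scaffold = hsv_gate(c(0, 0, 0), c(70, 67, 90), "scaffold"),
    bone     = hsv_gate(c(155, 57, 67), c(179, 202, 187), "bone")
  )
}

#' Read color gates from a YAML file
#'
#' The file maps labels to `lower`/`upper` HSV triplets, e.g.
#' `scaffold: {lower: [0,0,0], upper: [70,67,90]}`.
#'
#' @param path Path to the YAML file.
#' @return Named list of [hsv_gate()] objects.
#' @export
read_gates <- function(path) {
  raw <- yaml::read_yaml(path)
  gates <- lapply(names(raw), function(lbl)
    hsv_gate(raw[[lbl]]$lower, raw[[lbl]]$upper, lbl))
  names(gates) <- names(raw)
  gates
}

# -- 8-bit HSV <-> RGB --------------------------------------------------

#' Convert 8-bit RGB channels to 8-bit HSV
#'
#' Maps the full hue circle onto `[0, 179]` (one unit = two degrees) and
#' saturation/value onto `[0, 255]`, the convention the gate magnitudes are
#' quoted in.
#'
#' @param r,g,b Integer vectors in `[0, 255]`.
#' @return A 3-row matrix with rows `h`, `s`, `v`.
#' @export
rgb_to_hsv8 <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  rbind(h = round(hsv[1, ] * 180) %% 180,
        s = round(hsv[2, ] * 255),
        v = round(hsv[3, ] * 255))
}

#' Convert 8-bit HSV to 8-bit RGB channels
#'
#' Inverse of [rgb_to_hsv8()] up to channel quantization.
#'
#' @param h Hue in `[0, 179]`; `s`, `v` in `[0, 255]`.
#' @param s,v Saturation and value in `[0, 255]`.
#' @return A 3-row matrix with rows `r`, `g`, `b` (integers in 0..255).
#' @export
hsv8_to_rgb <- function(h, s, v) {
  cols <- grDevices::hsv(h / 180, s / 255, v / 255)
  out <- grDevices::col2rgb(cols)
  rownames(out) <- c("r", "g", "b")
  out
}

in_gate <- function(hsv, gate) {
  hsv[1, ] >= gate$lower[1] & hsv[1, ] <= gate$upper[1] &
  hsv[2, ] >= gate$lower[2] & hsv[2, ] <= gate$upper[2] &
  hsv[3, ] >= gate$lower[3] & hsv[3, ] <= gate$upper[3]
}

gates_overlap <- function(a, b) {
  all(a$lower <= b$upper & b$lower <= a$upper)
}

#' Classify pixels by HSV color gates
#'
#' Converts an RGB raster to 8-bit HSV and labels each pixel by inclusive
#' box membership: `scaffold`, `bone`, or `other` for pixels inside neither
#' gate.  Gates are validated to be pairwise disjoint boxes.
#'
#' @param image An RGB raster: numeric array `height x width x 3` with
#'   channels in `[0, 255]` (as produced by [generate_micrograph()] or
#'   [read_micrograph()]).
#' @param gates List of [hsv_gate()] objects; defaults to [default_gates()].
#' @return An integer matrix (`height x width`) of class `gate_labels` with
#'   levels attribute `c("other", <gate labels...>)`; `0` codes `other`.
#' @export
gate_pixels <- function(image, gates = default_gates()) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be a height x width x 3 RGB array")
  if (length(gates) >= 2L) {
    for (i in seq_len(length(gates) - 1L))
      for (j in seq(i + 1L, length(gates)))
        if (gates_overlap(gates[[i]], gates[[j]]))
          stop(sprintf("gates '%s' and '%s' overlap", gates[[i]]$label,
                       gates[[j]]$label))
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- rgb_to_hsv8(as.vector(image[, , 1]), as.vector(image[, , 2]),
                     as.vector(image[, , 3]))
  lab <- integer(h * w)
  for (k in seq_along(gates)) {
    hit <- in_gate(hsv, gates[[k]])
    lab[hit] <- k
  }
  out <- matrix(lab, nrow = h, ncol = w)
  attr(out, "levels") <- c("other", unname(vapply(gates, `[[`, "", "label")))
  class(out) <- c("gate_labels", class(out))
  out
}

label_mask <- function(labels, what) {
  lev <- attr(labels, "levels")
  idx <- match(what, lev)
  if (is.na(idx)) stop(sprintf("no gate labeled '%s'", what))
  unclass(labels) == (idx - 1L)
}
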