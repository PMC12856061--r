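# Clock-face bridging scores and inter-rater agreement ------------------

#' Angular implant-bone contact model
#'
#' Represents the bone-implant interface as a binary contact function
#' around the implant perimeter: 1 on bridged arcs, 0 elsewhere.  Angle 0
#' is the anterior anchor and angles proceed clockwise (a convention, not
#' an anatomical fact; rotate with [rotate_interface()] if another anchor
#' is wanted).
#'
#' @param arcs Two-column matrix or list of `c(start, end)` pairs in
#'   degrees, `0 <= start < end <= 360`, pairwise non-overlapping.
#' @param radius Nominal implant radius in mm (25 for a 5-cm implant).
#' @return Object of class `interface_model` with sorted `arcs` and the
#'   total `bridged_fraction`.
#' @export
interface_model <- function(arcs = NULL, radius = 25) {
  if (is.null(arcs) || length(arcs) == 0L) {
    arcs <- matrix(numeric(0), ncol = 2)
  } else {
    if (is.list(arcs)) arcs <- do.call(rbind, arcs)
    arcs <- matrix(as.numeric(arcs), ncol = 2)
  }
  colnames(arcs) <- c("start", "end")
  if (nrow(arcs)) {
    if (any(arcs[, 1] < 0) || any(arcs[, 2] > 360) ||
        any(arcs[, 1] >= arcs[, 2]))
      stop("arcs must satisfy 0 <= start < end <= 360")
    arcs <- arcs[order(arcs[, 1]), , drop = FALSE]
    if (nrow(arcs) > 1L && any(arcs[-1, 1] < arcs[-nrow(arcs), 2]))
      stop("arcs overlap")
  }
  structure(list(arcs = arcs, radius = radius,
                 bridged_fraction = sum(arcs[, 2] - arcs[, 1]) / 360),
            class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  cat(sprintf("<interface_model: %d arc(s), %.1f%% bridged, r = %g mm>\n",
              nrow(x$arcs), 100 * x$bridged_fraction, x$radius))
  invisible(x)
}

#' Rotate the contact function
#'
#' @param model An [interface_model()].
#' @param degrees Clockwise rotation; arcs crossing 0 are split.
#' @return A rotated `interface_model`.
#' @export
rotate_interface <- function(model, degrees) {
  if (!nrow(model$arcs)) return(model)
  a <- (model$arcs + degrees) %% 360
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    if (e == 0) e <- 360
    if (s < e) pieces[[length(pieces) + 1L]] <- c(s, e)
    else { pieces[[length(pieces) + 1L]] <- c(s, 360)
           if (e > 0) pieces[[length(pieces) + 1L]] <- c(0, e) }
  }
  interface_model(pieces, model$radius)
}

#' Score bridging per perimeter segment
#'
#' Divides the perimeter into `n_segments` equal angular segments (segment
#' `k` spans `[k*360/n, (k+1)*360/n)`), and scores each as the percent of
#' its span covered by bridged arcs; the overall score is the unweighted
#' segment mean, which equals the total bridged fraction.
#'
#' @param model An [interface_model()].
#' @param n_segments Number of segments: 12 for the longitudinal clock-face
#'   protocol, 8 for the peripheral micro-CT landmarks.
#' @param rater_id Label recorded with the score.
#' @return Object of class `bridging_score` with `per_segment` (percent),
#'   `n_segments`, `overall`, `rater_id`.
#' @export
score_interface <- function(model, n_segments = 12L, rater_id = "auto") {
  stopifnot(inherits(model, "interface_model"), n_segments >= 1)
  n <- as.integer(n_segments)
  width <- 360 / n
  seg_start <- (seq_len(n) - 1) * width
  per <- vapply(seg_start, function(s) {
    e <- s + width
    if (!nrow(model$arcs)) return(0)
    ov <- pmax(0, pmin(model$arcs[, 2], e) - pmax(model$arcs[, 1], s))
    100 * sum(ov) / width
  }, 0)
  structure(list(per_segment = per, n_segments = n, overall = mean(per),
                 rater_id = rater_id), class = "bridging_score")
}

#' @export
print.bridging_score <- function(x, digits = 1, ...) {
  cat(sprintf("<bridging_score: rater '%s', %d segments, overall %.*f%%>\n",
              x$rater_id, x$n_segments, digits, x$overall))
  cat("  per segment:",
      paste(formatC(x$per_segment, format = "f", digits = digits),
            collapse = " "), "\n")
  invisible(x)
}

#' Average bridging scores across raters
#'
#' @param scores List of [score_interface()] results with identical
#'   segment counts.
#' @return A `bridging_score` with per-segment arithmetic means and
#'   `rater_id = "mean"`.
#' @export
average_raters <- function(scores) {
  stopifnot(length(scores) >= 1L,
            all(vapply(scores, inherits, TRUE, "bridging_score")))
  ns <- vapply(scores, `[[`, 0L, "n_segments")
  if (length(unique(ns)) != 1L)
    stop("raters scored different numbers of segments")
  per <- rowMeans(vapply(scores, `[[`, numeric(ns[1]), "per_segment"))
  structure(list(per_segment = per, n_segments = ns[1], overall = mean(per),
                 rater_id = "mean"), class = "bridging_score")
}

#' Generate a synthetic interface from bridged arcs
#'
#' Thin wrapper kept for symmetry with the other generators: validates the
#' arc list and returns the contact model with its analytic bridged
#' fraction as ground truth.
#'
#' @inheritParams interface_model
#' @return An [interface_model()].
#' @export
generate_interface <- function(arcs = NULL, radius = 25)
  interface_model(arcs, radius)

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation computed from the mean-squares decomposition of the
#' subjects x raters table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with `MSR` the between-subject, `MSC` the between-rater, and `MSE` the
#' residual mean square.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns, no missing cells; >= 2 subjects and >= 2 raters.
#' @return Object of class `icc_result` with `estimate`, the mean squares,
#'   `n` subjects, `k` raters, and `undefined` flag (zero total variance).
#' @export
icc <- function(ratings) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  gm <- mean(x)
  SSR <- k * sum((rowMeans(x) - gm)^2)
  SSC <- n * sum((colMeans(x) - gm)^2)
  SST <- sum((x - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  undefined <- SST <= .Machine$double.eps * max(1, abs(gm))^2
  est <- if (undefined || denom == 0) NA_real_ else (MSR - MSE) / denom
  structure(list(estimate = est, MSR = MSR, MSC = MSC, MSE = MSE,
                 n = n, k = k, undefined = undefined),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined || is.na(x$estimate))
    cat("<icc_result: undefined (no variance)>\n")
  else
    cat(sprintf("<icc_result: ICC(2,1) = %.4f (%d subjects x %d raters)>\n",
                x$estimate, x$n, x$k))
  invisible(x)
}

#' Write / read an interface model as JSON
#'
#' @param model An [interface_model()].
#' @param path JSON path.
#' @export
write_interface <- function(model, path) {
  jsonlite::write_json(list(radius = model$radius,
                            arcs = as.data.frame(model$arcs)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_interface
#' @export
read_interface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arcs <- if (length(obj$arcs)) as.matrix(obj$arcs) else NULL
  interface_model(arcs, obj$radius %||% 25)
}
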