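# Oliver-Pharr nanoindentation analysis ---------------------------------
#
# Working units are uN (load), nm (depth), uN/nm (stiffness), nm^2 (area).
# Moduli and hardness are emitted in GPa via 1 uN/nm^2 = 1000 GPa.

UN_PER_NM2_TO_GPA <- 1000

#' Specify the indenter
#'
#' Defaults describe an ideal Berkovich diamond tip: projected area
#' `A = C0 * hc^2` with `C0 = 24.5`, elastic modulus 1140 GPa, Poisson
#' ratio 0.07, and contact-depth intercept factor `epsilon = 0.75`.
#' A calibrated area function can be supplied instead of the ideal one as
#' polynomial coefficients `A = sum(area_coef[k] * hc^(2^(2-k)))` in the
#' conventional `C0 hc^2 + C1 hc + C2 hc^(1/2) + ...` form.
#'
#' @param Ei Indenter elastic modulus, GPa.
#' @param vi Indenter Poisson ratio.
#' @param C0 Leading (quadratic) area coefficient, dimensionless.
#' @param epsilon Contact-depth intercept factor in `(0, 1]`.
#' @param area_coef Optional numeric vector of calibrated area-function
#'   coefficients `(C0, C1, C2, ...)` for terms `hc^2, hc^1, hc^(1/2),
#'   hc^(1/4), ...`; overrides `C0` when given.
#' @return An `indenter_spec` object.
#' @export
indenter_spec <- function(Ei = 1140, vi = 0.07, C0 = 24.5, epsilon = 0.75,
                          area_coef = NULL) {
  stopifnot(Ei > 0, vi >= 0, vi < 0.5, C0 > 0, epsilon > 0, epsilon <= 1)
  structure(list(Ei = Ei, vi = vi, C0 = C0, epsilon = epsilon,
                 area_coef = area_coef), class = "indenter_spec")
}

#' Projected contact area from contact depth
#'
#' Ideal geometry `A = C0 * hc^2` unless the spec carries a calibrated
#' polynomial area function.
#'
#' @param hc Contact depth, nm; must be positive.
#' @param spec An [indenter_spec()].
#' @return Contact area in nm^2.
#' @export
contact_area <- function(hc, spec = indenter_spec()) {
  if (any(hc <= 0)) stop("contact depth must be positive")
  if (is.null(spec$area_coef)) return(spec$C0 * hc^2)
  expo <- 2 / 2^(seq_along(spec$area_coef) - 1)
  expo[1] <- 2
  rowSums(outer(hc, seq_along(spec$area_coef),
                function(h, k) spec$area_coef[k] * h^expo[k]))
}

#' Reduced modulus from unloading stiffness and contact area
#'
#' `Er = sqrt(pi)/2 * S / sqrt(A)`, converted to GPa
#' (1 uN/nm^2 = 1000 GPa).
#'
#' @param S Unloading stiffness at peak load, uN/nm.
#' @param A Contact area, nm^2.
#' @return Reduced modulus in GPa.
#' @export
reduced_modulus <- function(S, A) {
  stopifnot(all(S > 0), all(A > 0))
  (sqrt(pi) / 2) * S / sqrt(A) * UN_PER_NM2_TO_GPA
}

#' Indentation hardness
#'
#' `H = Pmax / A(hc)` in GPa (1 uN/nm^2 = 1000 GPa).
#'
#' @param Pmax Peak load, uN.
#' @param A Contact area, nm^2.
#' @return Hardness in GPa.
#' @export
hardness <- function(Pmax, A) {
  stopifnot(all(Pmax > 0), all(A > 0))
  Pmax / A * UN_PER_NM2_TO_GPA
}

#' Bone elastic modulus from the reduced modulus
#'
#' Inverts the compliance identity
#' `1/Er = (1 - vb^2)/Eb + (1 - vi^2)/Ei`:
#' `Eb = (1 - vb^2) * Er * Ei / (Ei - (1 - vi^2) * Er)`.
#'
#' @param Er Reduced modulus, GPa; must satisfy `Er < Ei / (1 - vi^2)`.
#' @param vb Poisson ratio of the bone (default 0.3).
#' @param spec An [indenter_spec()].
#' @return Bone elastic modulus in GPa.
#' @export
bone_modulus <- function(Er, vb = 0.3, spec = indenter_spec()) {
  stopifnot(all(Er > 0), vb >= 0, vb < 0.5)
  lim <- spec$Ei / (1 - spec$vi^2)
  if (any(Er >= lim))
    stop(sprintf("nonphysical input: Er must be < Ei/(1-vi^2) = %.1f GPa", lim))
  (1 - vb^2) * Er * spec$Ei / (spec$Ei - (1 - spec$vi^2) * Er)
}

# inverse of bone_modulus: the Er implied by a bone modulus
reduced_from_bone <- function(Eb, vb = 0.3, spec = indenter_spec()) {
  1 / ((1 - vb^2) / Eb + (1 - spec$vi^2) / spec$Ei)
}

# -- curves -------------------------------------------------------------

#' Construct an indentation load-displacement curve
#'
#' @param time Seconds, monotone nondecreasing.
#' @param load uN.
#' @param depth nm, nonnegative.
#' @param segment Optional factor/character of segment labels among
#'   `loading`, `hold`, `unloading`.
#' @return A data frame of class `indent_curve` with columns
#'   `time_s, load_uN, depth_nm, segment`.
#' @export
indent_curve <- function(time, load, depth, segment = NULL) {
  stopifnot(length(time) == length(load), length(load) == length(depth))
  if (is.unsorted(time)) stop("time must be monotone nondecreasing")
  if (any(depth < 0)) stop("depth must be nonnegative")
  df <- data.frame(time_s = time, load_uN = load, depth_nm = depth,
                   segment = if (is.null(segment)) NA_character_
                             else as.character(segment))
  class(df) <- c("indent_curve", "data.frame")
  df
}

#' @export
print.indent_curve <- function(x, ...) {
  cat(sprintf("<indent_curve: %d samples, %.2f s, Pmax = %.1f uN%s>\n",
              nrow(x), max(x$time_s) - min(x$time_s), max(x$load_uN),
              if (all(is.na(x$segment))) ", unsegmented" else ""))
  invisible(x)
}

#' Trapezoidal loading profile
#'
#' The stock profile loads at 60 uN/s for 5 s to a 300 uN peak, holds for
#' 10 s, and unloads in 2 s, sampled at 100 Hz.
#'
#' @param loading_rate uN/s.
#' @param load_duration,hold_duration,unload_duration Seconds, all positive.
#' @param sample_rate Hz.
#' @return A `load_profile` list; `peak_load = loading_rate * load_duration`.
#' @export
load_profile <- function(loading_rate = 60, load_duration = 5,
                         hold_duration = 10, unload_duration = 2,
                         sample_rate = 100) {
  stopifnot(loading_rate > 0, load_duration > 0, hold_duration > 0,
            unload_duration > 0, sample_rate > 0)
  structure(list(loading_rate = loading_rate, load_duration = load_duration,
                 peak_load = loading_rate * load_duration,
                 hold_duration = hold_duration,
                 unload_duration = unload_duration,
                 sample_rate = sample_rate), class = "load_profile")
}

#' Ground-truth material for curve synthesis
#'
#' The residual depth `hf` is not free: given the reduced modulus,
#' hardness, unloading exponent, profile and indenter it is pinned by
#' `hf = hmax - m * Pmax / S`, and the generator reports the realized
#' value.
#'
#' @param Er Reduced modulus, GPa.
#' @param H Hardness, GPa.
#' @param m Unloading power-law exponent in `[1, 2]`.
#' @return A `material_truth` list.
#' @export
material_truth <- function(Er, H, m = 1.5) {
  stopifnot(Er > 0, H > 0, m >= 1, m <= 2)
  structure(list(Er = Er, H = H, m = m), class = "material_truth")
}

#' Generate a synthetic load-displacement curve
#'
#' Builds a curve whose noiseless Oliver-Pharr analysis returns exactly the
#' requested reduced modulus and hardness under the stated indenter:
#' loading follows `P = k h^2` up to the peak, the hold is creep-free, and
#' unloading follows `P = alpha (h - hf)^m` with `alpha, hf` chosen so the
#' unloading stiffness at peak depth matches the target.
#'
#' @param truth A [material_truth()].
#' @param profile A [load_profile()].
#' @param indenter An [indenter_spec()].
#' @param noise_sd Additive Gaussian load noise SD, uN (load only).
#' @param seed Seed for the noise draw.
#' @return An `indent_curve` with segment labels; attributes `truth`
#'   (including the realized `hf`, `S`, `hmax`, `hc`, `alpha`) and
#'   `profile`.
#' @export
generate_indent_curve <- function(truth, profile = load_profile(),
                                  indenter = indenter_spec(),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "material_truth"), inherits(profile, "load_profile"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  Pmax <- profile$peak_load
  A <- Pmax / (truth$H / UN_PER_NM2_TO_GPA)          # nm^2
  hc <- sqrt(A / indenter$C0)                        # ideal-geometry synthesis
  S <- 2 * (truth$Er / UN_PER_NM2_TO_GPA) * sqrt(A) / sqrt(pi)  # uN/nm
  hmax <- hc + indenter$epsilon * Pmax / S
  hf <- hmax - truth$m * Pmax / S
  if (hf < 0) stop("profile/material combination implies negative residual depth")
  alpha <- Pmax / (hmax - hf)^truth$m

  dt <- 1 / profile$sample_rate
  t_load <- seq(0, profile$load_duration, by = dt)
  t_hold <- seq(dt, profile$hold_duration, by = dt) + profile$load_duration
  t_unl <- seq(dt, profile$unload_duration, by = dt) +
    profile$load_duration + profile$hold_duration
  P_load <- profile$loading_rate * t_load
  h_load <- hmax * sqrt(P_load / Pmax)
  P_hold <- rep(Pmax, length(t_hold))
  h_hold <- rep(hmax, length(t_hold))
  P_unl <- Pmax * (1 - (t_unl - max(t_hold)) / profile$unload_duration)
  P_unl[P_unl < 0] <- 0
  h_unl <- hf + (P_unl / alpha)^(1 / truth$m)

  load <- c(P_load, P_hold, P_unl)
  if (noise_sd > 0)
    load <- with_seed(seed, load + rnorm(length(load), 0, noise_sd))
  cv <- indent_curve(c(t_load, t_hold, t_unl), load,
                     c(h_load, h_hold, h_unl),
                     rep(c("loading", "hold", "unloading"),
                         c(length(t_load), length(t_hold), length(t_unl))))
  attr(cv, "truth") <- c(unclass(truth),
                         list(hf = hf, S = S, hmax = hmax, hc = hc,
                              alpha = alpha, A = A))
  attr(cv, "profile") <- profile
  cv
}

#' Label loading / hold / unloading segments of a raw curve
#'
#' The hold is detected as the contiguous run of samples within
#' `plateau_tol * Pmax` of the peak load; everything before is loading,
#' everything after unloading.
#'
#' @param curve An `indent_curve` (segment labels, if present, are
#'   recomputed).
#' @param plateau_tol Relative tolerance defining the plateau (default 2%).
#' @param min_hold Minimum number of plateau samples; fewer raises a
#'   malformed-curve error.
#' @return The curve with `segment` filled in.
#' @export
segment_curve <- function(curve, plateau_tol = 0.02, min_hold = 5L) {
  stopifnot(inherits(curve, "indent_curve"))
  if (nrow(curve) < 50L) stop("curve too short to segment (< 50 samples)")
  P <- curve$load_uN
  Pmax <- max(P)
  near <- P >= Pmax * (1 - plateau_tol)
  i_pk <- which.max(P)
  lo <- i_pk; while (lo > 1L && near[lo - 1L]) lo <- lo - 1L
  hi <- i_pk; while (hi < length(P) && near[hi + 1L]) hi <- hi + 1L
  if ((hi - lo + 1L) < min_hold || hi == length(P))
    stop("malformed curve: no load plateau found")
  curve$segment <- rep(c("loading", "hold", "unloading"),
                       c(lo - 1L, hi - lo + 1L, length(P) - hi))
  curve
}

#' Fit the unloading branch with a power law
#'
#' Fits `P = alpha * (h - hf)^m` by Levenberg-Marquardt least squares on
#' the portion of the unloading branch whose load lies within
#' `fit_range` of the peak unloading load (default top 95% down to 20%),
#' and evaluates the contact stiffness `S = dP/dh` at the maximum depth.
#'
#' @param curve A segmented `indent_curve`.
#' @param fit_range Length-2 fraction pair `(low, high)` of the unloading
#'   load range to fit over.
#' @return List with `S` (uN/nm), `alpha`, `hf` (nm), `m`, `hmax`, `Pmax`,
#'   the `fit` object and the fitted subset size `n`.
#' @export
fit_unloading <- function(curve, fit_range = c(0.20, 0.95)) {
  stopifnot(inherits(curve, "indent_curve"))
  if (all(is.na(curve$segment))) curve <- segment_curve(curve)
  un <- curve[curve$segment == "unloading", ]
  if (nrow(un) < 10L) stop("unloading segment has fewer than 10 samples")
  Ptop <- max(un$load_uN)
  keep <- un$load_uN >= fit_range[1] * Ptop & un$load_uN <= fit_range[2] * Ptop
  d <- un[keep, ]
  if (nrow(d) < 5L) stop("too few unloading samples in the fit window")
  hmax <- max(curve$depth_nm)   # peak depth, attained during the hold
  Pmax <- max(curve$load_uN)
  hf0 <- min(d$depth_nm) - 0.25 * diff(range(d$depth_nm)) - 1e-6
  m0 <- 1.5
  a0 <- max(d$load_uN) / (max(d$depth_nm) - hf0)^m0
  fit <- tryCatch(
    minpack.lm::nlsLM(load_uN ~ alpha * (depth_nm - hf)^m, data = d,
                      start = list(alpha = a0, hf = hf0, m = m0),
                      lower = c(alpha = 1e-12, hf = -Inf, m = 1),
                      upper = c(alpha = Inf, hf = min(d$depth_nm) - 1e-9,
                                m = 4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("unloading fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  S <- cf[["alpha"]] * cf[["m"]] * (hmax - cf[["hf"]])^(cf[["m"]] - 1)
  list(S = S, alpha = cf[["alpha"]], hf = cf[["hf"]], m = cf[["m"]],
       hmax = hmax, Pmax = Pmax, fit = fit, n = nrow(d))
}

#' Analyze one load-displacement curve
#'
#' Full Oliver-Pharr pipeline: segment the curve, fit the unloading power
#' law, form the contact depth `hc = hmax - epsilon * Pmax / S`, the
#' contact area, reduced modulus, hardness, and bone modulus.
#'
#' @param curve An `indent_curve` (raw or segmented).
#' @param indenter An [indenter_spec()].
#' @param vb Bone Poisson ratio used in the compliance identity.
#' @param fit_range Passed to [fit_unloading()].
#' @return Object of class `indent_fit` with the derived quantities
#'   (`S, hc, Pmax, A, Er, H, Eb, vb`), the unloading fit coefficients, and
#'   the configuration used.
#' @export
analyze_curve <- function(curve, indenter = indenter_spec(), vb = 0.3,
                          fit_range = c(0.20, 0.95)) {
  if (all(is.na(curve$segment))) curve <- segment_curve(curve)
  fu <- fit_unloading(curve, fit_range)
  hc <- fu$hmax - indenter$epsilon * fu$Pmax / fu$S
  if (hc <= 0) stop("nonpositive contact depth; curve or indenter invalid")
  A <- contact_area(hc, indenter)
  Er <- reduced_modulus(fu$S, A)
  H <- hardness(fu$Pmax, A)
  Eb <- bone_modulus(Er, vb, indenter)
  if (H > Er)
    warning("hardness exceeds reduced modulus; unusual for bone-like input")
  structure(list(S = fu$S, hc = hc, Pmax = fu$Pmax, A = A, Er = Er, H = H,
                 Eb = Eb, vb = vb, alpha = fu$alpha, hf = fu$hf, m = fu$m,
                 hmax = fu$hmax, indenter = indenter, fit_range = fit_range,
                 fit = fu$fit, curve = curve),
            class = "indent_fit")
}

#' @export
print.indent_fit <- function(x, digits = 4, ...) {
  cat("<indent_fit> Oliver-Pharr analysis\n")
  cat(sprintf("  Pmax = %.1f uN, hmax = %.1f nm, S = %.4g uN/nm\n",
              x$Pmax, x$hmax, x$S))
  cat(sprintf("  hc = %.1f nm, A = %.4g nm^2\n", x$hc, x$A))
  cat(sprintf("  Er = %.*g GPa, H = %.*g GPa, Eb = %.*g GPa (vb = %.2f)\n",
              digits, x$Er, digits, x$H, digits, x$Eb, x$vb))
  invisible(x)
}

#' @export
coef.indent_fit <- function(object, ...) {
  c(S = object$S, hc = object$hc, Pmax = object$Pmax, A = object$A,
    Er = object$Er, H = object$H, Eb = object$Eb,
    alpha = object$alpha, hf = object$hf, m = object$m)
}

#' @export
residuals.indent_fit <- function(object, ...) residuals(object$fit)

#' @export
plot.indent_fit <- function(x, ...) {
  cv <- x$curve
  plot(cv$depth_nm, cv$load_uN, type = "l", xlab = "depth (nm)",
       ylab = "load (uN)", main = "load-displacement", ...)
  un <- cv[cv$segment == "unloading", ]
  hgrid <- seq(x$hf, max(un$depth_nm), length.out = 200)
  graphics::lines(hgrid, x$alpha * pmax(hgrid - x$hf, 0)^x$m, col = 2, lty = 2)
  graphics::abline(v = x$hc, col = 4, lty = 3)
  invisible(x)
}

#' Aggregate indents of one specimen
#'
#' @param results List of [analyze_curve()] results (>= 2), typically the
#'   nine indents of a 3 x 3 grid.
#' @return Object of class `indent_summary`: data frame with `n`, mean and
#'   SD of `Er`, `H`, `Eb`.
#' @export
aggregate_indents <- function(results) {
  stopifnot(length(results) >= 2L,
            all(vapply(results, inherits, TRUE, "indent_fit")))
  grab <- function(f) vapply(results, `[[`, 0, f)
  out <- data.frame(
    quantity = c("Er_GPa", "H_GPa", "Eb_GPa"),
    n = length(results),
    mean = c(mean(grab("Er")), mean(grab("H")), mean(grab("Eb"))),
    sd = c(sd(grab("Er")), sd(grab("H")), sd(grab("Eb")))
  )
  class(out) <- c("indent_summary", "data.frame")
  out
}

#' Write / read indentation curves as CSV
#'
#' CSV dialect: header `time_s,load_uN,depth_nm,segment`.
#'
#' @param curve An `indent_curve`.
#' @param path CSV path.
#' @export
write_indent_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indent_curve
#' @export
read_indent_curve <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "load_uN", "depth_nm")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns time_s, load_uN, depth_nm")
  indent_curve(df$time_s, df$load_uN, df$depth_nm,
               if ("segment" %in% names(df)) df$segment else NULL)
}
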