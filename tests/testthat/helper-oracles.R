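# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations, kept separate from the package's own
# code paths.

# per-pixel recount of bone fraction inside a region mask, straight from
# the RGB image and the gate boxes
oracle_region_fraction <- function(image, region, gates = default_gates()) {
  idx <- which(region)
  hsv <- rgb_to_hsv8(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  inbox <- function(g) hsv[1, ] >= g$lower[1] & hsv[1, ] <= g$upper[1] &
    hsv[2, ] >= g$lower[2] & hsv[2, ] <= g$upper[2] &
    hsv[3, ] >= g$lower[3] & hsv[3, ] <= g$upper[3]
  not_scaffold <- !inbox(gates$scaffold)
  c(bone = sum(inbox(gates$bone) & not_scaffold),
    denominator = sum(not_scaffold))
}

# one-way ANOVA F and p from first-principles sums of squares
oracle_anova <- function(values, groups) {
  keep <- !is.na(values)
  v <- values[keep]; g <- factor(groups[keep])
  k <- nlevels(g); N <- length(v); gm <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  c(F = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# ICC(2,1) from scratch: explicit two-way sums of squares
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x); gm <- mean(x)
  msr <- sum((rowMeans(x) - gm)^2) * k / (n - 1)
  msc <- sum((colMeans(x) - gm)^2) * n / (k - 1)
  sse <- sum((x - outer(rowMeans(x), colMeans(x), `+`) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# exact two-sided Mann-Whitney p for small samples by enumerating all
# assignments of the pooled values to the two groups
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b); n1 <- length(a)
  U_of <- function(aa, bb) sum(outer(aa, bb, `>`)) + 0.5 * sum(outer(aa, bb, `==`))
  u_obs <- U_of(a, b)
  n1n2 <- n1 * (length(pooled) - n1)
  dev_obs <- abs(u_obs - n1n2 / 2)
  combos <- combn(seq_along(pooled), n1, simplify = FALSE)
  hits <- vapply(combos, function(idx) {
    u <- U_of(pooled[idx], pooled[-idx])
    abs(u - n1n2 / 2) >= dev_obs - 1e-12
  }, TRUE)
  mean(hits)
}

# Tukey HSD adjusted p for a balanced pair, straight from ptukey
oracle_tukey_p <- function(values, groups, g1, g2) {
  gs <- split(values, groups)
  k <- length(gs); N <- length(values)
  msw <- sum(vapply(gs, function(z) sum((z - mean(z))^2), 0)) / (N - k)
  n1 <- length(gs[[g1]]); n2 <- length(gs[[g2]])
  se <- sqrt(msw / 2 * (1 / n1 + 1 / n2))
  q <- abs(mean(gs[[g1]]) - mean(gs[[g2]])) / se
  ptukey(q, k, N - k, lower.tail = FALSE)
}

region_mask_for <- function(partition, name)
  osseoquant:::region_mask(partition, name)

tiny_micrograph_spec <- function(...) {
  micrograph_spec(width = 160L, height = 160L, strut_pitch = 20L,
                  strut_width = 5L, margin = 24L, kernel_px = 17L, ...)
}
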