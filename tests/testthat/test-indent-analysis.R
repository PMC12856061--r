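test_that("contact area follows the ideal Berkovich quadratic", {
  expect_equal(contact_area(1, indenter_spec(C0 = 24.5)), 24.5)
  expect_equal(contact_area(200, indenter_spec(C0 = 24.5)), 980000)
  expect_equal(contact_area(4, indenter_spec()), 4 * contact_area(2,
               indenter_spec()))
  expect_error(contact_area(-1), "positive")
  # calibrated polynomial falls back to the conventional term ladder
  sp <- indenter_spec(area_coef = c(24.5, 100, 10))
  expect_equal(contact_area(4, sp), 24.5 * 16 + 100 * 4 + 10 * 2)
})

test_that("reduced modulus and hardness reproduce closed-form values", {
  # 1 uN/nm^2 corresponds to 1000 GPa
  expect_equal(reduced_modulus(1, pi / 4), 1000)
  expect_equal(reduced_modulus(5, 980000), 4.476, tolerance = 1e-4)
  expect_equal(reduced_modulus(10, 980000), 2 * reduced_modulus(5, 980000))
  expect_equal(hardness(300, 652174), 0.46, tolerance = 1e-5)
  expect_equal(hardness(300, 652174 / 2), 2 * hardness(300, 652174))
})

test_that("bone modulus inverts the compliance identity", {
  sp <- indenter_spec(Ei = 1140, vi = 0.07)
  expect_equal(bone_modulus(15, vb = 0.3, sp),
               0.91 / (1 / 15 - (1 - 0.07^2) / 1140), tolerance = 1e-6)
  # rigid-indenter limit
  rigid <- indenter_spec(Ei = 1e9, vi = 0.07)
  expect_equal(bone_modulus(15, vb = 0.3, rigid), (1 - 0.3^2) * 15,
               tolerance = 1e-6)
  # algebraic round trip to machine precision
  for (Eb in c(1, 5.204, 13.384, 20)) {
    Er <- osseoquant:::reduced_from_bone(Eb, 0.3, sp)
    expect_equal(bone_modulus(Er, 0.3, sp), Eb, tolerance = 1e-10)
  }
  # strictly increasing on the physical domain
  ers <- seq(1, 900, length.out = 50)
  ebs <- bone_modulus(ers, 0.3, sp)
  expect_true(all(diff(ebs) > 0))
  expect_error(bone_modulus(1200, 0.3, sp), "nonphysical")
})

test_that("a linear unloading branch is fitted exactly", {
  k <- 5; hf <- 100
  h_un <- seq(300, 120, length.out = 120)
  cv <- indent_curve(
    time = seq_along(c(1:60, 1:40, seq_along(h_un))) / 100,
    load = c(seq(1, 1000, length.out = 60), rep(1000, 40), k * (h_un - hf)),
    depth = c(seq(1, 300, length.out = 60), rep(300, 40), h_un),
    segment = rep(c("loading", "hold", "unloading"), c(60, 40, 120)))
  fu <- fit_unloading(cv)
  expect_equal(fu$S, 5, tolerance = 1e-6)
  expect_equal(fu$m, 1, tolerance = 1e-6)
})

test_that("noiseless power-law unloading recovers hf and m to 4 significant digits", {
  cv <- generate_indent_curve(material_truth(13, 0.46, m = 1.5))
  tr <- attr(cv, "truth")
  fu <- fit_unloading(cv)
  expect_equal(fu$hf, tr$hf, tolerance = 1e-4)
  expect_equal(fu$m, 1.5, tolerance = 1e-4)
  expect_equal(fu$S, tr$S, tolerance = 1e-6)
})

test_that("noisy unloading stiffness stays within a few percent (Monte Carlo)", {
  tru <- material_truth(13, 0.46, m = 1.4)
  S_true <- attr(generate_indent_curve(tru), "truth")$S
  errs <- vapply(1:100, function(s) {
    cv <- generate_indent_curve(tru, noise_sd = 1, seed = s)
    abs(fit_unloading(cv)$S - S_true) / S_true
  }, 0)
  expect_lt(median(errs), 0.02)
})

test_that("full analysis recovers truth on a modulus-hardness grid within 1%", {
  for (Er in c(5, 10, 15)) for (H in c(0.2, 0.5)) {
    cv <- generate_indent_curve(material_truth(Er, H, m = 1.5))
    fit <- analyze_curve(cv)
    expect_lt(abs(fit$Er - Er) / Er, 0.01)
    expect_lt(abs(fit$H - H) / H, 0.01)
  }
})

test_that("nine identical indents aggregate with zero spread; noisy indents with positive spread", {
  cv <- generate_indent_curve(material_truth(13.384, 0.464))
  fits <- replicate(9, analyze_curve(cv), simplify = FALSE)
  agg <- aggregate_indents(fits)
  expect_equal(agg$sd, rep(0, 3), tolerance = 1e-10)
  expect_equal(agg$mean[agg$quantity == "Er_GPa"], 13.384, tolerance = 1e-3)

  noisy <- lapply(1:9, function(s)
    analyze_curve(generate_indent_curve(material_truth(13.384, 0.464),
                                        noise_sd = 1, seed = s)))
  agg_n <- aggregate_indents(noisy)
  expect_true(all(agg_n$sd > 0))
  expect_lt(abs(agg_n$mean[agg_n$quantity == "Er_GPa"] - 13.384) / 13.384,
            0.03)
  expect_error(aggregate_indents(fits[1]), ">= 2")
})
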