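test_that("subunit and space validation rejects malformed definitions", {
  expect_error(moiety_subunit("g", 0, 0), "carbon_count")
  expect_error(moiety_subunit("g", 6, c(0, 7)), "allowed_labels")
  expect_error(moiety_subunit("g", 6, c(0, 6), "g0"), "parameter name")
  expect_error(moiety_space(list()), "at least one subunit")
  expect_error(moiety_space(list(moiety_subunit("a", 2, c(0, 2)),
                                 moiety_subunit("a", 3, c(0, 3)))),
               "distinct")
  # labels are deduplicated and sorted
  su <- moiety_subunit("g", 6, c(6, 0, 6), c("g0", "g6"))
  expect_identical(su$allowed_labels, c(0L, 6L))
})

test_that("default UDP-GlcNAc space has the published structure", {
  sp <- udp_glcnac_space()
  expect_identical(metabolite_carbons(sp), 17L)
  expect_identical(nrow(enumerate_isotopomers(sp)), 32L)
  expect_identical(mass_support(sp), 0:16)
  expect_identical(free_parameter_count(sp), 6L)
  expect_identical(
    vapply(sp$subunits, `[[`, integer(1), "carbon_count"),
    c(6L, 5L, 2L, 4L))
})

test_that("isotopomer enumeration matches hand-derived small cases", {
  one <- moiety_space(list(moiety_subunit("x", 3, 0)))
  iso1 <- enumerate_isotopomers(one)
  expect_identical(nrow(iso1), 1L)
  expect_identical(iso1$mass_shift, 0L)

  two <- moiety_space(list(moiety_subunit("a", 1, c(0, 1)),
                           moiety_subunit("b", 2, c(0, 2))))
  iso2 <- enumerate_isotopomers(two)
  expect_identical(nrow(iso2), 4L)
  expect_setequal(iso2$mass_shift, c(0L, 1L, 2L, 3L))
  expect_setequal(mass_support(two), c(0L, 1L, 2L, 3L))

  gluc_rib <- moiety_space(list(moiety_subunit("glucose", 6, c(0, 6)),
                                moiety_subunit("ribose", 5, c(0, 5))))
  expect_identical(mass_support(gluc_rib), c(0L, 5L, 6L, 11L))

  degenerate <- moiety_space(list(moiety_subunit("a", 2, 0),
                                  moiety_subunit("b", 3, 0)))
  expect_identical(mass_support(degenerate), 0L)
})

test_that("free parameter count follows the closure rule", {
  expect_identical(free_parameter_count(
    moiety_space(list(moiety_subunit("x", 3, 0)))), 0L)
  # acetyl widened to {0,1,2}: one extra free parameter
  sp7 <- moiety_space(list(
    moiety_subunit("glucose", 6, c(0, 6)),
    moiety_subunit("ribose", 5, c(0, 5)),
    moiety_subunit("acetyl", 2, c(0, 1, 2)),
    moiety_subunit("uracil", 4, 0:3)))
  expect_identical(free_parameter_count(sp7), 7L)
})

test_that("parameter sets enforce closure and fill implied complements", {
  sp <- udp_glcnac_space()
  p <- parameter_set(sp, c(g6 = 0.84, r5 = 0.93, a2 = 0.3,
                           u1 = 0.18, u2 = 0.46, u3 = 0.14))
  expect_equal(unname(p["g0"]), 0.16)
  expect_equal(unname(p["u0"]), 0.22)
  expect_error(parameter_set(sp, c(g0 = 0.4, g6 = 0.4, r5 = 1, a2 = 1,
                                   u1 = 0.5, u2 = 0.25, u3 = 0.25)),
               "sum")
  expect_error(parameter_set(sp, c(g6 = 1.5)), "\\[0, 1\\]")
  expect_error(parameter_set(sp, c(gg = 0.5)), "unknown parameter")
  # within-tolerance drift is renormalized
  p2 <- parameter_set(sp, c(g0 = 0.5, g6 = 0.5 + 1e-12, r5 = 1, a2 = 1,
                            u0 = 1, u1 = 0, u2 = 0, u3 = 0))
  expect_equal(sum(p2[c("g0", "g6")]), 1)
})

test_that("predicted profiles match hand convolutions", {
  sp <- udp_glcnac_space()
  allun <- predict_profile(sp, parameter_set(
    sp, c(g0 = 1, r0 = 1, a0 = 1, u0 = 1)))
  expect_equal(unname(allun[1L]), 1)
  expect_equal(sum(allun[-1L]), 0)

  half <- predict_profile(sp, parameter_set(
    sp, c(g0 = 0.5, r0 = 0.5, a0 = 1, u0 = 1)))
  expect_equal(unname(half[c("m0", "m5", "m6", "m11")]),
               rep(0.25, 4))
  expect_equal(sum(half), 1)
  # unsupported masses are exact zeros, not dropped
  expect_identical(unname(half["m1"]), 0)
})

test_that("48 h parameter profile equals the brute-force isotopomer sum", {
  sp <- udp_glcnac_space()
  p <- params_48h(sp)
  expect_equal(as.numeric(predict_profile(sp, p)), oracle_profile(sp, p),
               tolerance = 1e-14)
})

test_that("convolution equals enumeration oracle on random spaces", {
  set.seed(42)
  for (i in 1:25) {
    sp <- random_space()
    p <- random_params(sp)
    pred <- as.numeric(predict_profile(sp, p))
    expect_equal(pred, oracle_profile(sp, p), tolerance = 1e-12)
    expect_equal(sum(pred), 1, tolerance = 1e-12)
  }
})

test_that("profiles are invariant to subunit order", {
  set.seed(7)
  sp <- udp_glcnac_space()
  p <- random_params(sp)
  perm <- c(3, 1, 4, 2)
  sp2 <- moiety_space(sp$subunits[perm], name = sp$name)
  expect_equal(as.numeric(predict_profile(sp, p)),
               as.numeric(predict_profile(sp2, parameter_set(sp2, unclass(p)))),
               tolerance = 1e-15)
})

test_that("raising a labeled fraction raises the mean mass shift", {
  sp <- udp_glcnac_space()
  base <- c(r5 = 0.4, a2 = 0.3, u1 = 0.2, u2 = 0.1, u3 = 0.1)
  g6 <- seq(0, 1, by = 0.2)
  mm <- vapply(g6, function(g) mean_mass_shift(
    predict_profile(sp, parameter_set(sp, c(base, g6 = g)))), numeric(1))
  expect_true(all(diff(mm) > 0))
})
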