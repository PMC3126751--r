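test_that("variant generation expands the grammar combinatorially", {
  sp <- udp_glcnac_space()
  base_only <- generate_variants(sp, grammar = list())
  expect_length(base_only, 1L)
  expect_identical(base_only[[1L]]$k, 6L)

  # one alternative for each of 4 subunits: 2^4 combinations
  g <- list(glucose = list(c(0, 3, 6)), ribose = list(c(0, 4, 5)),
            acetyl = list(c(0, 1, 2)), uracil = list(c(0, 1, 2, 3, 4)))
  expect_length(generate_variants(sp, g), 16L)

  # shipped grammar: 2 x 3 x 3 x 3 = 54 models, exceeding the published 40
  full <- generate_variants(sp)
  expect_length(full, 54L)
  expect_identical(full[[1L]]$k, 6L)  # base model first
  ks <- vapply(full, `[[`, integer(1), "k")
  expect_true(all(ks == vapply(full, function(v)
    free_parameter_count(v$space), integer(1))))

  expect_error(generate_variants(sp, list(acetyl = list(integer(0)))),
               "empty label set")
  expect_error(generate_variants(sp, list(hexose = list(c(0, 6)))),
               "unknown subunits")
})

test_that("least-squares AIC matches the closed form and penalizes k", {
  # independent hand calculation of the closed form
  expect_equal(aic_ls(0.01, 17, 6, corrected = FALSE),
               17 * log(0.01 / 17) + 2 * 6)
  expect_equal(aic_ls(0.01, 17, 6),
               17 * log(0.01 / 17) + 12 + 2 * 6 * 7 / (17 - 6 - 1))
  # penalty monotonicity at fixed rss
  a <- vapply(1:9, function(k) aic_ls(0.01, 17, k), numeric(1))
  expect_true(all(diff(a) > 0))
  expect_error(aic_ls(-1, 17, 6), "non-negative")
  expect_error(aic_ls(0.01, 7, 6), "n_obs")
  expect_warning(perfect <- aic_ls(0, 17, 6), "perfect")
  expect_identical(perfect, -Inf)
})

test_that("a single variant is trivially selected", {
  sp <- udp_glcnac_space()
  obs <- list(as.numeric(predict_profile(sp, params_48h(sp))))
  rep <- select_model(generate_variants(sp, list()), obs,
                      test_settings(seed = 2))
  expect_identical(nrow(as.data.frame(rep)), 1L)
  expect_identical(rep$rank, 1L)
  expect_equal(rep$delta_aic, 0)
})

test_that("the generating model beats the full-acetyl variant on base data", {
  sim <- simulate_timecourse(default_scenario(seed = 21))
  cs <- correction_settings(17, 0.011)
  obs <- lapply(seq_len(nrow(sim$data)), function(i)
    as.numeric(normalize_profile(suppressWarnings(strip_natural_abundance(
      as.numeric(sim$data[i, paste0("m", 0:16)]), cs)))))
  vars <- generate_variants(udp_glcnac_space(),
                            list(acetyl = list(c(0, 1, 2))))
  rep <- select_model(vars, obs, test_settings(seed = 8))
  df <- as.data.frame(rep)
  expect_identical(df$description[df$rank == 1L],
                   vars[[1L]]$description)  # base model wins
  expect_gt(df$aic[grepl("acetyl\\{0,1,2\\}", df$description)],
            df$aic[df$rank == 1L])
})

test_that("failed variants are ranked last with a reason, not fatal", {
  sp <- udp_glcnac_space()
  obs <- list(as.numeric(predict_profile(sp, params_48h(sp))))
  # a variant with more free parameters than observations per timepoint
  # breaks the AICc precondition and must be reported, not thrown
  wide <- moiety_space(list(
    moiety_subunit("glucose", 6, 0:6), moiety_subunit("ribose", 5, 0:5),
    moiety_subunit("acetyl", 2, 0:2), moiety_subunit("uracil", 4, 0:4)))
  rep <- select_model(list(sp, wide), obs, test_settings(seed = 3))
  df <- as.data.frame(rep)
  expect_identical(nrow(df), 2L)
  bad <- df[df$rank == 2L, ]
  expect_true(!is.na(bad$error))
  expect_identical(bad$aic, Inf)
})
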