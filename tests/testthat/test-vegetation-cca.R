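test_that("vegetation filtering applies the three removal criteria", {
  legend <- synthetic_frap_legend()
  expect_equal(nrow(legend), 42)
  retained <- filter_vegetation(legend)
  expect_equal(nrow(retained), 23)
  expect_true(all(retained$tag == "natural"))

  # empty removal config is the identity
  expect_equal(nrow(filter_vegetation(legend, remove_tags = character())), 42)
  # everything tagged for removal is an error (ordination impossible)
  expect_error(
    filter_vegetation(legend, remove_tags = c("natural", "anthropogenic",
                                              "hydrologic", "unknown")),
    "impossible"
  )
  # untagged types are retained with a warning
  legend2 <- legend
  legend2$tag[1] <- NA
  expect_warning(r2 <- filter_vegetation(legend2), "untagged")
  expect_true(legend2$label[1] %in% r2$label)
})

test_that("patch abundance computes percent cover per isobioclimate", {
  g <- grid_geometry(2, 2, 270)
  iso <- iso_from_codes(rep(1252L, 4), g)
  veg <- iso[c("cell", "row", "col", "x", "y")]
  veg$veg_code <- c(1L, 1L, 2L, 2L)
  legend <- tibble::tibble(code = 1:2, label = c("X", "Y"), tag = "natural")
  ab <- patch_abundance(iso, veg, legend)
  expect_equal(ab$X, 50)
  expect_equal(ab$Y, 50)

  # single-type patch
  veg$veg_code <- rep(2L, 4)
  ab2 <- patch_abundance(iso, veg, legend)
  expect_equal(ab2$Y, 100)
  expect_false("X" %in% names(ab2))

  # brute-force double loop on random maps; rows sum to 100 minus excluded share
  set.seed(44)
  g9 <- grid_geometry(9, 9, 270)
  iso9 <- iso_from_codes(sample(c(1252L, 1163L, 853L), 81, TRUE), g9)
  veg9 <- iso9[c("cell", "row", "col", "x", "y")]
  veg9$veg_code <- sample(1:4, 81, TRUE)   # type 4 will be excluded
  legend9 <- tibble::tibble(code = 1:3, label = c("A", "B", "C"), tag = "natural")
  ab9 <- patch_abundance(iso9, veg9, legend9)
  for (code in unique(iso9$code)) {
    in_patch <- iso9$cell[iso9$code == code]
    n_tot <- length(in_patch)
    for (lab in c("A", "B", "C")) {
      tcode <- legend9$code[legend9$label == lab]
      n_type <- sum(veg9$veg_code[veg9$cell %in% in_patch] == tcode)
      expect_equal(ab9[[lab]][ab9$code == code], 100 * n_type / n_tot)
    }
    excluded <- sum(veg9$veg_code[veg9$cell %in% in_patch] == 4)
    expect_equal(sum(unlist(ab9[ab9$code == code, c("A", "B", "C")])),
                 100 - 100 * excluded / n_tot)
  }
})

# small worked table used by several CCA checks
toy_abundance <- function() {
  tibble::tibble(
    code = c(1051L, 1052L, 1151L, 1152L, 1251L, 1252L),
    sp1 = c(40, 35, 20, 10, 2, 0),
    sp2 = c(10, 20, 40, 35, 20, 10),
    sp3 = c(0, 5, 10, 30, 48, 60),
    sp4 = c(50, 40, 30, 25, 30, 30)
  )
}

toy_env <- function() {
  tibble::tibble(
    code = c(1051L, 1052L, 1151L, 1152L, 1251L, 1252L),
    Io = c(2, 2.5, 4, 4.5, 6.5, 7),
    Ic = c(14, 9, 15, 10, 16, 11),
    Itc = c(310, 330, 305, 335, 300, 340)
  )
}

test_that("CCA eigenvalues are bounded, ordered, and below the unconstrained ones", {
  fit <- cca_bioclim(toy_abundance(), toy_env())
  ev <- unname(fit$eigenvalues)
  expect_true(all(ev >= 0 & ev < 1))
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(length(ev), 3)

  # oracle: unconstrained correspondence analysis of the same table
  Y <- as.matrix(toy_abundance()[-1])
  P <- Y / sum(Y)
  r <- rowSums(P); cw <- colSums(P)
  Qbar <- (P - outer(r, cw)) / sqrt(outer(r, cw))
  ca_eig <- svd(Qbar)$d^2
  for (a in seq_along(ev)) expect_lte(ev[a], ca_eig[a] + 1e-12)
  expect_equal(fit$total_inertia, sum(Qbar^2), tolerance = 1e-12)
})

test_that("CCA is invariant to joint row permutation and to variable scaling", {
  ab <- toy_abundance(); env <- toy_env()
  fit <- cca_bioclim(ab, env)
  perm <- c(4, 1, 6, 3, 2, 5)
  fit_p <- cca_bioclim(ab[perm, ], env[perm, ])
  expect_equal(fit$eigenvalues, fit_p$eigenvalues, tolerance = 1e-10)
  expect_equal(fit$species_scores, fit_p$species_scores, tolerance = 1e-8)

  # multiplying a variable by 1000: eigenvalues and species scores unchanged,
  # raw canonical coefficient rescaled by 1/1000
  env2 <- env; env2$Io <- env2$Io * 1000
  fit2 <- cca_bioclim(ab, env2)
  expect_equal(fit$eigenvalues, fit2$eigenvalues, tolerance = 1e-10)
  expect_equal(fit$species_scores, fit2$species_scores, tolerance = 1e-8)
  expect_equal(fit2$coefficients_raw["Io", ], fit$coefficients_raw["Io", ] / 1000,
               tolerance = 1e-8)
  expect_equal(fit2$coefficients["Io", ], fit$coefficients["Io", ],
               tolerance = 1e-8)
})

test_that("two perfectly segregated species recover the 2x2 table's CA axis", {
  ab <- tibble::tibble(code = c(101L, 102L), dry = c(30, 0), wet = c(0, 30))
  env <- tibble::tibble(code = c(101L, 102L), moisture = c(0, 1))
  expect_no_warning(fit <- cca_bioclim(ab, env))
  # brute-force CA eigenvalue of the 2x2 diagonal table is 1 - but CCA
  # eigenvalues are < 1; the constrained axis captures it to numerical limits
  Y <- matrix(c(30, 0, 0, 30), 2, 2)
  P <- Y / sum(Y); r <- rowSums(P); cw <- colSums(P)
  Qbar <- (P - outer(r, cw)) / sqrt(outer(r, cw))
  ca1 <- svd(Qbar)$d[1]^2
  expect_equal(unname(fit$eigenvalues[1]), ca1, tolerance = 1e-9)
})

test_that("an Io-structured synthetic community is recovered on axis 1", {
  g <- grid_geometry(60, 60, 1000)
  tr <- make_terrain(g, 1000, seed = 6)
  clim <- make_climatology(tr, synthetic_climate_params())
  idx <- bioclim_indices(clim)
  iso <- classify_grid(clim)
  niches <- make_niches(idx, n_types = 10, seed = 3)
  veg <- make_vegetation(idx, niches, noise_sd = 0.02, seed = 4)
  ab <- patch_abundance(iso, veg$map, veg$legend)
  env <- idx |>
    dplyr::inner_join(iso[c("cell", "code")], by = "cell") |>
    dplyr::group_by(code) |>
    dplyr::summarise(Io = mean(Io), Ic = mean(Ic), Itc = mean(Itc))
  fit <- cca_bioclim(ab, env)

  # axis-1 site scores align with the moisture gradient
  ord <- match(rownames(fit$site_scores_wa), as.character(env$code))
  r1 <- stats::cor(fit$site_scores_wa[, 1], env$Io[ord])
  expect_gt(abs(r1), 0.95)
  # and the Io canonical coefficient dominates axis 1
  expect_equal(rownames(fit$coefficients)[which.max(abs(fit$coefficients[, 1]))],
               "Io")

  # tidy/glance accessors
  td <- tidy(fit, "eigenvalues")
  expect_equal(nrow(td), length(fit$eigenvalues))
  expect_equal(td$eigenvalue, unname(fit$eigenvalues))
  gl <- glance(fit)
  expect_equal(gl$n_species, ncol(fit$species_scores) * 0 + length(fit$col_weights))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("CCA eigenvalues agree with an independent implementation", {
  skip_if_not_installed("vegan")
  ab <- toy_abundance(); env <- toy_env()
  fit <- cca_bioclim(ab, env)
  vfit <- vegan::cca(as.data.frame(ab[-1]) ~ Io + Ic + Itc,
                     data = as.data.frame(env[-1]))
  expect_equal(unname(fit$eigenvalues),
               unname(vfit$CCA$eig[seq_along(fit$eigenvalues)]),
               tolerance = 1e-8)
  expect_equal(fit$total_inertia, vfit$tot.chi, tolerance = 1e-8)
})

test_that("analog comparison reports shared, lost and expanding types", {
  ab <- tibble::tibble(
    code = c(1252L, 1163L),
    M.WOOD = c(30, 5), D.FIR = c(25, 0), MX.CHP = c(20, 40), RDWD = c(15, 0),
    CR.CHP = c(5, 10), BO.WOOD = c(1, 16), CCP.CYP = c(0, 12)
  )
  rep <- analog_comparison(ab, 1252, 1163)
  # analog support not a subset: CCP.CYP absent from the current patch
  expect_false(rep$no_long_distance_dispersal)
  expect_equal(rep$types$status[rep$types$type == "CCP.CYP"], "analog_only")
  expect_equal(rep$types$status[rep$types$type == "RDWD"], "current_only")
  bo <- rep$types[rep$types$type == "BO.WOOD", ]
  expect_equal(bo$status, "shared")
  expect_equal(bo$cover_current, 1)   # the 1% nucleus expanding to 16%
  expect_equal(bo$cover_analog, 16)

  # drop the analog-only type: local rearrangement suffices
  ab2 <- ab[setdiff(names(ab), "CCP.CYP")]
  expect_true(analog_comparison(ab2, 1252, 1163)$no_long_distance_dispersal)

  # disjoint supports: every analog type needs dispersal
  ab3 <- tibble::tibble(code = c(1L, 2L), a = c(50, 0), b = c(50, 0),
                        c = c(0, 60), d = c(0, 40))
  rep3 <- analog_comparison(ab3, 1, 2)
  expect_false(rep3$no_long_distance_dispersal)
  expect_setequal(rep3$types$type[rep3$types$status == "analog_only"], c("c", "d"))

  expect_error(analog_comparison(ab, 9999, 1163), "not present")
})
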