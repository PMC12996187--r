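test_that("Richards height curve: zero case, published evaluation, limits", {
  expect_identical(predict_mean_height(0, reg), 0)
  expect_equal(predict_mean_height(80, reg), 13.70941, tolerance = 1e-6)
  # approaches the published asymptote
  expect_equal(predict_mean_height(1e5, reg), reg$sci$a0, tolerance = 1e-8)
  # strictly increasing in age
  th <- predict_mean_height(seq(1, 200, by = 1), reg)
  expect_true(all(diff(th) > 0))
  expect_error(predict_mean_height(-1, reg), ">= 0")
})

test_that("site class index standardization and its inverse are consistent", {
  # reference-age identity for arbitrary heights
  for (th in c(0.5, 5, 13.71, 22)) {
    expect_equal(site_class_index(th, 80, reg), th, tolerance = 1e-12)
    expect_equal(height_from_sci(th, 80, reg), th, tolerance = 1e-12)
  }
  expect_equal(height_from_sci(16, 100, reg), 17.21491, tolerance = 1e-6)
  expect_equal(site_class_index(17.215, 100, reg), 16.00008,
               tolerance = 1e-6)
  # round trip over a grid of (SCI, age)
  set.seed(42)
  sci <- runif(50, 6, 20); age <- runif(50, 10, 190)
  back <- site_class_index(height_from_sci(sci, age, reg), age, reg)
  expect_equal(back, sci, tolerance = 1e-9)
  expect_error(site_class_index(10, 0, reg), "age 0")
})

test_that("self-thinning frontier and SDI standardization", {
  expect_equal(max_density(20, reg), 1129.088, tolerance = 1e-5)
  expect_equal(max_density(1, reg), exp(reg$self_thinning$b0))
  expect_true(max_density(10, reg) > max_density(20, reg))
  expect_equal(stand_density_index(777, 20, reg), 777)  # Dg = D0
  expect_equal(stand_density_index(932, 15.3, reg), 669.6955,
               tolerance = 1e-6)
  expect_equal(stand_density_index(1000, 40, reg), 2351.856,
               tolerance = 1e-5)
  expect_error(stand_density_index(-1, 10, reg), "> 0")
  expect_error(max_density(0, reg), "> 0")
})

test_that("SDI dynamics: zero case, published evaluation, asymptote", {
  expect_identical(predict_sdi(16, 0, reg), 0)
  expect_equal(predict_sdi(16, 80, reg), 673.7333, tolerance = 1e-6)
  expect_equal(predict_sdi(16, 1e5, reg), 674.5872, tolerance = 1e-6)
  # negative asymptote rejected
  expect_error(predict_sdi(-10, 50, reg), "positive")
})

test_that("basal-area variants reproduce the published simulation chain", {
  sdi <- predict_sdi(16, 80, reg)
  expect_equal(predict_bas(80, "stand", reg, sci = 16, sdi = sdi),
               17.55656, tolerance = 1e-6)
  expect_equal(predict_bas(80, "climate", reg, sci = 16, sdi = sdi,
                           mai = 60), 17.39793, tolerance = 1e-6)
  expect_equal(predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60,
                           stage = 1), 18.3596, tolerance = 1e-6)
  expect_equal(predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60,
                           stage = 3), 14.67293, tolerance = 1e-6)
  # base variant needs nothing but age
  expect_equal(predict_bas(80, "base", reg),
               reg$bas_base$c * (1 - exp(-reg$bas_base$k * 80)))
})

test_that("basal area is monotone in its drivers", {
  sdi <- predict_sdi(16, 80, reg)
  ages <- seq(5, 200, by = 5)
  for (v in c("base", "stand")) {
    b <- predict_bas(ages, v, reg, sci = 16, sdi = sdi)
    expect_true(all(diff(b) > 0), info = v)
  }
  # climate direction: more humid (larger MAI) means less basal area
  mais <- seq(40, 95, by = 5)
  bc <- predict_bas(80, "climate", reg, sci = 16, sdi = sdi, mai = mais)
  expect_true(all(diff(bc) < 0))
  bs <- predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = mais,
                    stage = 2)
  expect_true(all(diff(bs) < 0))
  # stage ordering at the published driver setting
  b123 <- vapply(1:3, function(s)
    predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60, stage = s),
    numeric(1))
  expect_true(b123[1] > b123[2] && b123[2] > b123[3])
})

test_that("stage dummy coding schemes differ only where they should", {
  sdi <- predict_sdi(16, 80, reg)
  for (s in 1:2)
    expect_equal(
      predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60,
                  stage = s, coding = "cumulative"),
      predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60,
                  stage = s, coding = "non_cumulative"))
  expect_lt(
    predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60,
                stage = 3, coding = "cumulative"),
    predict_bas(80, "stage", reg, sci = 16, sdi = sdi, mai = 60,
                stage = 3, coding = "non_cumulative"))
})

test_that("volume model: unit case and published evaluations", {
  expect_equal(predict_volume(1, 1, reg), reg$volume$d0)
  expect_equal(predict_volume(17.4, 16, reg), 121.7475, tolerance = 1e-6)
  expect_equal(predict_volume(14.674, 16, reg), 102.5059, tolerance = 1e-6)
  v <- predict_volume(seq(1, 30, 0.5), 16, reg)
  expect_true(all(diff(v) > 0))
  expect_error(predict_volume(-1, 16, reg), "> 0")
})

test_that("biomass components: published values, additivity, limits", {
  w <- predict_biomass_components(17.4, 16, reg)
  expect_equal(w$root, 30.04597, tolerance = 1e-6)
  expect_equal(w$stem, 72.25292, tolerance = 1e-6)
  expect_equal(w$branch, 8.473534, tolerance = 1e-6)
  expect_equal(w$leaf, 2.267727, tolerance = 1e-6)
  expect_identical(w$crown, w$branch + w$leaf)
  expect_identical(w$total, w$root + w$stem + w$branch + w$leaf)
  # vanishing basal area drives all components to zero
  w0 <- predict_biomass_components(1e-12, 16, reg)
  expect_true(all(unlist(w0) < 1e-10))
})

test_that("carbon conversion applies the published fractions and re-sums", {
  w <- predict_biomass_components(17.4, 16, reg)
  cc <- carbon_from_biomass(w, reg)
  expect_equal(cc$stem, w$stem * 0.47)
  expect_equal(cc$stem, 33.95887, tolerance = 1e-5)
  expect_equal(cc$total, 55.08349, tolerance = 1e-4)
  expect_equal(cc$total, cc$root + cc$stem + cc$branch + cc$leaf,
               tolerance = 1e-12)
  z <- carbon_from_biomass(
    data.frame(root = 0, stem = 0, branch = 0, leaf = 0), reg)
  expect_true(all(unlist(z) == 0))
})

test_that("Dg and N links reproduce the published chain and close algebraically", {
  expect_equal(dg_from_bas_sdi(17.4, 673.7, reg), 15.48835,
               tolerance = 1e-6)
  expect_equal(dg_from_bas_sdi(14.674, 673.7, reg), 12.40006,
               tolerance = 1e-6)
  expect_equal(n_from_bas_dg(17.4, 15.49), 923.3291, tolerance = 1e-4)
  expect_equal(n_from_bas_dg(18.36, 16.61), 847.3123, tolerance = 1e-4)
  # one tree's basal area gives exactly one stem
  dg <- 17
  expect_equal(n_from_bas_dg(pi / 40000 * dg^2, dg), 1)
  # closure: Dg/N links recover the input SDI across a random grid
  set.seed(7)
  bas <- runif(200, 1, 40); sdi <- runif(200, 100, 1200)
  dgv <- dg_from_bas_sdi(bas, sdi, reg)
  nv <- n_from_bas_dg(bas, dgv)
  expect_equal(stand_density_index(nv, dgv, reg), sdi, tolerance = 1e-9)
  # slope too close to -2 is rejected
  p <- reg$self_thinning; p$b1 <- -2
  expect_error(dg_from_bas_sdi(10, 500, p), "-2")
})

test_that("goodness-of-fit statistics match hand evaluation", {
  gof <- goodness_of_fit(c(10, 20, 30), c(10, 20, 30), k = 1)
  expect_equal(gof$adj_r2, 1)
  expect_equal(gof$mae_pct, 0)
  expect_equal(gof$rmse_pct, 0)
  gof <- goodness_of_fit(c(10, 20, 30), c(12, 18, 33), k = 1)
  expect_equal(gof$mae_pct, 11.66667, tolerance = 1e-6)
  expect_equal(gof$rmse_pct, 20.61553, tolerance = 1e-6)
  expect_equal(gof$adj_r2, 1 - 17 / 200)
  expect_error(goodness_of_fit(1:3, 1:4, k = 1), "equal length")
  expect_error(goodness_of_fit(1:3, c(1, 2, 3), k = 2), "n > k")
  expect_error(goodness_of_fit(c(2, 2, 2, 2), c(1, 2, 3, 4), k = 1),
               "degenerate")
})
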