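test_that("coupling stoichiometry reproduces the reference recipes", {
  # 5 ul x 1.2 mg/ml IgG into 1 ml OD 1 of 20 nm colloid (7.0e11 /ml)
  expect_identical(antibodies_per_particle(conjugate_recipe()), 34)
  expect_identical(
    antibodies_per_particle(conjugate_recipe(antibody_volume_ul = 4.2)), 29)
  expect_identical(
    antibodies_per_particle(conjugate_recipe(antibody_volume_ul = 16)), 110)
  expect_identical(
    antibodies_per_particle(conjugate_recipe(antibody_volume_ul = 0)), 0)
})

test_that("stoichiometry is linear in antibody volume and concentration", {
  base <- antibodies_per_particle(conjugate_recipe(), round = FALSE)
  r2 <- antibodies_per_particle(conjugate_recipe(antibody_volume_ul = 10),
                                round = FALSE)
  r3 <- antibodies_per_particle(
    conjugate_recipe(antibody_concentration_mg_ml = 3.6), round = FALSE)
  expect_equal(r2, 2 * base)
  expect_equal(r3, 3 * base)
})

test_that("monolayer capacity follows the footprint geometry", {
  fp <- antibody_footprint()            # 14.5 x 8.5 nm^2
  expect_equal(fp$area_nm2, 14.5 * 8.5)
  expect_identical(monolayer_capacity(20, fp), 10)
  expect_identical(monolayer_capacity(40, fp), 40)
  # one antibody exactly covering the sphere
  d <- 10
  fp1 <- antibody_footprint(pi * d^2, 1)
  expect_identical(monolayer_capacity(d, fp1), 1)
  # quadratic scaling before flooring (floor may trim up to 3)
  set.seed(5)
  for (d in runif(20, 10, 80)) {
    c1 <- monolayer_capacity(d, fp)
    c2 <- monolayer_capacity(2 * d, fp)
    expect_true(c2 <= 4 * c1 + 3 && c2 >= 4 * c1 - 3)
  }
})

test_that("excess factor relates added antibodies to capacity", {
  expect_equal(excess_factor(conjugate_recipe()), 3.4)     # 34 / 10
  # added equals capacity
  cap <- monolayer_capacity(20)
  vol <- cap / antibodies_per_particle(conjugate_recipe(antibody_volume_ul = 1),
                                       round = FALSE)
  expect_equal(excess_factor(conjugate_recipe(antibody_volume_ul = vol)), 1.0)
  # sub-saturating load: 6 antibodies on a 40 nm particle (capacity 40)
  r40 <- conjugate_recipe(particle_diameter_nm = 40)
  vol6 <- 6 / antibodies_per_particle(
    conjugate_recipe(antibody_volume_ul = 1, particle_diameter_nm = 40),
    round = FALSE)
  expect_equal(excess_factor(conjugate_recipe(antibody_volume_ul = vol6,
                                              particle_diameter_nm = 40)),
               0.15)
})

test_that("lambda_max finds the plasmon peak with lowest-wavelength ties", {
  sp <- synth_spectrum(522, 60, 1.0)
  lm <- lambda_max(sp)
  expect_equal(lm$wavelength_nm, 522)
  expect_equal(lm$absorbance, 1.0)
  # monotone spectrum: endpoint with a warning
  mono <- data.frame(wavelength_nm = 450:700,
                     absorbance = seq(0, 1, length.out = 251))
  expect_warning(lm2 <- lambda_max(mono), "edge")
  expect_equal(lm2$wavelength_nm, 700)
  # two equal maxima: the lower wavelength wins
  two <- data.frame(wavelength_nm = c(495, 500, 510, 520, 525),
                    absorbance = c(0, 1, 0, 1, 0))
  expect_equal(lambda_max(two)$wavelength_nm, 500)
})

test_that("synthesis yield is the ratio of peak optical densities", {
  a <- synth_spectrum(522, 60, 1.0)
  expect_equal(synthesis_yield(a, a), 1.0)
  expect_equal(synthesis_yield(a, synth_spectrum(528, 70, 0.8)), 0.8)
  # simulator pair with an injected 35% particle loss
  expect_equal(synthesis_yield(a, synth_spectrum(526, 60, 0.65)), 0.65)
  expect_error(synthesis_yield(synth_spectrum(522, 60, 0), a),
               "division error")
})

test_that("peak shift and FWHM widening recover generator parameters", {
  bare <- synth_spectrum(522, 60, 1.0)
  conj <- synth_spectrum(528, 60, 0.9)
  res <- peak_shift_and_width(bare, conj)
  expect_equal(res$shift_nm, 6)
  expect_equal(res$widening_nm, 0, tolerance = 0.1)
  expect_equal(peak_shift_and_width(bare, bare)$shift_nm, 0)
  # Lorentzian FWHM equals the width parameter; broadening 60 -> 80
  wide <- synth_spectrum(522, 80, 1.0)
  res2 <- peak_shift_and_width(bare, wide)
  expect_equal(res2$fwhm_bare_nm, 60, tolerance = 0.5)
  expect_equal(res2$widening_nm, 20, tolerance = 0.5)
  # half maximum unreachable inside the window
  flat_top <- data.frame(wavelength_nm = 450:700,
                         absorbance = rep(1, 251) - 1e-4 * abs(450:700 - 575))
  expect_warning(peak_shift_and_width(bare, flat_top), "width undefined")
})

test_that("layer thickness is half the diameter increase", {
  expect_equal(layer_thickness(42, 22), 10)
  expect_equal(layer_thickness(22, 22), 0)
  expect_equal(layer_thickness(52, 22), 15)
  expect_error(layer_thickness(20, 22), "ordering error")
})

test_that("number-mean diameter averages the main peak only", {
  one <- data.frame(diameter_nm = 22, weight = 1)
  expect_equal(number_mean_diameter(one), 22)
  # symmetric distribution about 42
  sym <- data.frame(diameter_nm = seq(32, 52, 2),
                    weight = dnorm(seq(32, 52, 2), 42, 4))
  expect_equal(number_mean_diameter(sym), 42)
  # bimodal fixture with an agglomerate shoulder; oracle = hand-selected
  # main-peak bins
  bim <- data.frame(
    diameter_nm = c(18, 20, 22, 24, 26, 35, 45, 55, 60, 62, 64),
    weight      = c(0.05, 0.25, 0.30, 0.20, 0.05, 0, 0, 0, 0.05, 0.07, 0.03)
  )
  main_idx <- 1:5
  oracle <- sum(bim$diameter_nm[main_idx] * bim$weight[main_idx]) /
    sum(bim$weight[main_idx])
  expect_equal(number_mean_diameter(bim), oracle)
  expect_error(number_mean_diameter(data.frame(diameter_nm = numeric(0),
                                               weight = numeric(0))),
               "empty")
})

test_that("simulated distributions round-trip through the DLS reader", {
  d <- synth_size_distribution(42, 5, n = 2e4, seed = 9)
  expect_equal(number_mean_diameter(d), 42, tolerance = 0.2)
  core <- synth_size_distribution(22, 2, n = 2e4, seed = 9)
  expect_equal(layer_thickness(number_mean_diameter(d),
                               number_mean_diameter(core)),
               10, tolerance = 0.2)
})
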