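test_that("elemental tables interpolate log-log and resolve the iodine K edge", {
  # exact table knot: no interpolation error
  db <- attenuation_db()
  h10 <- db$mu_rho[db$element == "H" & db$energy_keV == 10]
  expect_equal(elemental_mu_rho("H", 10), h10, tolerance = 1e-12)

  # iodine K edge: straddling 33.2 keV jumps by more than a factor 5,
  # and a query exactly at the edge takes the above-edge branch
  below <- elemental_mu_rho("I", 33.2 - 1e-9)
  above <- elemental_mu_rho("I", 33.2 + 1e-9)
  expect_gt(above / below, 5)
  expect_equal(elemental_mu_rho("I", 33.2), above, tolerance = 1e-9)

  # oxygen at 20 keV against an independent standard-table value
  expect_rel_equal(elemental_mu_rho("O", 20), 0.8651, 0.01)

  expect_error(elemental_mu_rho("Xx", 20), "unknown element")
  expect_error(elemental_mu_rho("O", 200), "out of table range")
  expect_error(elemental_mu_rho("O", 1), "out of table range")
})

test_that("within each smooth branch mu/rho decreases with energy", {
  db <- attenuation_db()
  for (el in unique(db$element)) {
    tab <- db[db$element == el, ]
    smooth <- diff(tab$energy_keV) > 0   # exclude duplicated edge rows
    expect_true(all(diff(tab$mu_rho)[smooth] < 0), label = el)
    expect_true(all(tab$mu_rho > 0), label = el)
  }
  expect_true(all(c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K",
                    "Ca", "Fe", "I", "Al", "Be", "Cs", "Si")
                  %in% db$element))
})

test_that("material_mu follows the mixture rule and scales with density", {
  w <- fix_water()
  E <- c(8, 20, 35, 50)
  manual <- 0.1119 * elemental_mu_rho("H", E) +
    0.8881 * elemental_mu_rho("O", E)
  expect_equal(material_mu(w, E), manual, tolerance = 1e-6)

  w2 <- material(w$name, w$composition, 2 * w$density)
  expect_equal(material_mu(w2, E), 2 * material_mu(w, E), tolerance = 1e-12)

  # water against independent standard-table values (NIST, with coherent)
  expect_rel_equal(material_mu(w, 20), 0.8096, 0.02)
  expect_rel_equal(material_mu(w, 35), 0.3137, 0.02)  # log-log of 30/40 rows
  expect_rel_equal(material_mu(w, 50), 0.2269, 0.02)

  expect_error(material(name = "empty", numeric(0), 1), "empty composition")
  expect_error(material("neg", c(H = 1), -2), "density")
})

test_that("a 50/50 mass mixture has the mass-weighted mu/rho", {
  lib <- material_library()
  a <- lib$water; b <- lib$cortical_bone
  comp <- c(a$composition / 2, b$composition / 2)
  comp <- tapply(comp, names(comp), sum)
  mix <- material("mix", comp[comp > 0], 1.0)
  E <- energy_grid()
  manual <- 0.5 * material_mu(a, E) / a$density +
    0.5 * material_mu(b, E) / b$density
  expect_equal(material_mu(mix, E), as.numeric(manual), tolerance = 1e-9)
})

test_that("Kramers spectrum has the bremsstrahlung endpoint and shape", {
  s <- kramers_spectrum(60)
  expect_true(all(s$weights[s$energies > 60] == 0))
  expect_gt(s$weights[s$energies == 10], s$weights[s$energies == 50])
  # mean energy against a direct weighted-sum oracle
  expect_equal(mean_energy(s),
               sum(s$energies * s$weights) / sum(s$weights))
  expect_error(kramers_spectrum(4), "must exceed")
})

test_that("filtration attenuates per-bin and hardens the beam", {
  s <- kramers_spectrum(60)
  lib <- material_library()
  expect_equal(filter_spectrum(s, list()), s)
  expect_equal(filter_spectrum(s, list(list(material = lib$aluminum,
                                            thickness_cm = 0))), s)
  expect_error(filter_spectrum(s, list(list(material = lib$aluminum,
                                            thickness_cm = -1))),
               "negative")

  f <- filter_spectrum(s, list(list(material = lib$beryllium, thickness_cm = 0.08),
                               list(material = lib$aluminum, thickness_cm = 0.1)))
  # direct per-bin oracle
  att <- exp(-material_mu(lib$beryllium, s$energies) * 0.08 -
               material_mu(lib$aluminum, s$energies) * 0.1)
  expect_equal(f$weights, s$weights * att, tolerance = 1e-12)
  expect_true(all(f$weights <= s$weights + 1e-15))
  expect_gt(mean_energy(f), mean_energy(s))
})

test_that("any positive absorber strictly hardens a polyenergetic beam", {
  s <- kramers_spectrum(60)
  lib <- material_library()
  for (t_cm in c(0.01, 0.05, 0.2, 1.0)) {
    f <- filter_spectrum(s, list(list(material = lib$water, thickness_cm = t_cm)))
    expect_gt(mean_energy(f), mean_energy(s))
  }
})

test_that("monoenergetic spectra are single-bin and filter-stable", {
  m <- mono_spectrum(35)
  expect_equal(m$energies, 35)
  expect_equal(m$weights, 1)
  expect_equal(filter_spectrum(m, list()), m)
  expect_error(mono_spectrum(500), "outside table range")
})

test_that("detector response modes match their closed forms", {
  E <- energy_grid()
  expect_equal(detector_response(E, detector_model("ideal")), rep(1, length(E)))
  ei <- detector_response(c(17.5, 35), detector_model("energy-integrating"))
  expect_equal(ei[2] / ei[1], 2)

  # CsI mode against hand-computed Beer-Lambert absorption at spot energies
  lib <- material_library()
  for (e in c(10, 35, 59)) {
    d <- detector_response(e, detector_model("csi", scint_um = 600,
                                             plate_mm = 1))
    manual <- e * exp(-material_mu(lib$carbon, e) * 0.1) *
      (1 - exp(-material_mu(lib$csi, e) * 0.06))
    expect_equal(d, manual, tolerance = 1e-12)
  }
  expect_true(all(detector_response(E, detector_model("csi")) >= 0))
})

test_that("spectrum text round trip preserves the spectrum", {
  s <- sarrp_spectrum()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f)
  expect_equal(s2$energies, s$energies)
  expect_equal(s2$weights, s$weights, tolerance = 1e-12)
})
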