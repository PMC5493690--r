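test_that("kernel-decomposed rates agree with a literal transcription of the formulas", {
  cases <- list(c(1e6, 1e9), c(1e6, 1e6), c(1e9, 1e9), c(1e12, 1e9),
                c(4.2e11, 5.6e12))
  for (cs in cases) {
    for (tr in transition_labels()) {
      req <- default_req(cs[1], cs[2], transition = tr)
      expect_equal(closed_form_rate(req)$gamma,
                   literal_rate(req), tolerance = 1e-8,
                   info = sprintf("%s at (%.2g, %.2g)", tr, cs[1], cs[2]))
      if (tr %in% c("L_to_E2", "R_to_E2")) {
        expect_equal(closed_form_rate(req, "linear")$gamma,
                     literal_rate(req, second_exponent = "linear"),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("elastic rate peaks at resonance and is symmetric in eps - Er", {
  od <- odorant_two_level(1e6, 1e9)
  st <- body_temp()
  a <- st$thermal_frequency * 1e12
  mk <- function(eps) {
    p <- default_electronic_parameters(od)
    p$eps <- eps
    rate_request(od, params = p, spectrum = aqueous(), state = st)
  }
  g_res <- elastic_rate(mk(1e12))$gamma
  expect_equal(g_res, default_electronic_parameters(od)$delta^2 * sqrt(pi / a))
  for (d in c(1e11, 5e11)) {
    expect_equal(elastic_rate(mk(1e12 + d))$gamma,
                 elastic_rate(mk(1e12 - d))$gamma)
    expect_lt(elastic_rate(mk(1e12 + d))$gamma, g_res)
  }
  expect_error(elastic_rate(rate_request(od, spectrum = bath_spectrum(coupling = 0))),
               "reorganization")
})

test_that("inelastic channels collapse onto the elastic one in the degenerate geometry", {
  # omega_x = 0 with vanishing couplings: theta = upsilon = 0, eta_D = eta_A
  od <- odorant_two_level(0, 1e9)
  p <- electronic_parameters(eps = 1e9, delta = 1e7, gamma_D = 0, gamma_A = 0)
  req <- rate_request(od, params = p, spectrum = aqueous(), state = body_temp())
  el <- elastic_rate(req)$gamma
  req$transition <- "L_to_E2"
  expect_equal(closed_form_rate(req)$gamma, el)
  req$transition <- "R_to_E2"
  expect_equal(closed_form_rate(req)$gamma, 0)
  req$transition <- "E1_to_E2"
  expect_equal(closed_form_rate(req)$gamma, 0)
  req$transition <- "R_to_L"
  expect_equal(closed_form_rate(req)$gamma, 0)
})

test_that("R->L rate is the elastic rate scaled by sin^2(upsilon) when shifts cancel", {
  # omega_z = 0 makes both polaron shifts vanish
  od <- odorant_two_level(1e9, 0)
  req <- rate_request(od, spectrum = aqueous(), state = body_temp(),
                      transition = "R_to_L")
  fr <- polaron_frame(od, req$params)
  expect_equal(fr$eta_D + fr$eta_A, 0)
  expect_equal(closed_form_rate(req)$gamma,
               elastic_rate(req)$gamma * sin(fr$upsilon)^2)
})

test_that("closed-form rates scale as the square of the overall frequency scale", {
  # (omega_x, omega_z) -> c*(omega_x, omega_z) far below the cutoff scales
  # rates by c^2 up to the sub-percent drift of the Gaussian factor
  for (tr in c("elastic", "L_to_E2", "R_to_E2")) {
    g1 <- closed_form_rate(default_req(1e3, 1e6, tr))$gamma
    g2 <- closed_form_rate(default_req(1e6, 1e9, tr))$gamma
    expect_equal(g2 / g1, 1e6, tolerance = 2e-3, info = tr)
  }
})

test_that("published reference rows are reproduced within 2 percent", {
  fx <- table1_fixture()
  for (i in seq_len(nrow(fx))) {
    req <- default_req(fx$omega_x_hz[i], fx$omega_z_hz[i])
    expect_equal(elastic_rate(req)$inverse, fx$inv_elastic_s[i],
                 tolerance = 0.02)
    expect_equal(inelastic_rate_L_to_E2(req)$inverse, fx$inv_L_to_E2_s[i],
                 tolerance = 0.02)
    expect_equal(inelastic_rate_R_to_E2(req)$inverse, fx$inv_R_to_E2_s[i],
                 tolerance = 0.02)
  }
})

test_that("inelastic-to-elastic ratio matches the quotient of printed inverse rates", {
  # the global prefactor cancels in the ratio, so agreement is much tighter
  req <- default_req(1e6, 1e9, transition = "R_to_E2")
  expect_equal(inelastic_to_elastic_ratio(req), 0.0150482 / 1.56632,
               tolerance = 5e-3)
  expect_error(inelastic_to_elastic_ratio(default_req(1e6, 1e9)),
               "inelastic")
})

test_that("formula variants differ only through the eta-sum exponential", {
  req <- default_req(1e13, 1e12, transition = "L_to_E2")
  gs <- closed_form_rate(req, "squared")$gamma
  gl <- closed_form_rate(req, "linear")$gamma
  expect_false(isTRUE(all.equal(gs, gl)))
  # channels without an eta-sum variant term are unaffected
  for (tr in c("elastic", "E1_to_E2", "R_to_L")) {
    r <- default_req(1e13, 1e12, transition = tr)
    expect_equal(closed_form_rate(r)$gamma, literal_rate(r), tolerance = 1e-8)
  }
  # variant is immaterial when the shifted Gaussian argument vanishes:
  # omega_z = 0 kills the eta shifts, and eps = Er puts the term at resonance
  r0 <- default_req(1e9, 0, transition = "L_to_E2")
  r0$params$eps <- reorganization_energy(r0$spectrum)
  expect_equal(closed_form_rate(r0, "squared")$gamma,
               closed_form_rate(r0, "linear")$gamma)
})

test_that("negative closed-form values are flagged, never clamped", {
  req <- default_req(4.2e11, 5.6e12, transition = "R_to_E2")
  res <- closed_form_rate(req)
  expect_lt(res$gamma, 0)
  expect_true("negative_rate" %in% res$validity_flags)
  expect_true("weak_coupling_violated" %in% res$validity_flags)
  # weak-coupling flag absent in the perturbative regime
  ok <- closed_form_rate(default_req(1e6, 1e9, transition = "L_to_E2"))
  expect_false("weak_coupling_violated" %in% ok$validity_flags)
  expect_equal(ok$inverse * ok$gamma, 1)
})

test_that("time integrator reproduces the Gaussian closed form exactly", {
  # with the analytic high-temperature correlation the kernel integral is the
  # closed form; checks the integrator independently of the bath quadrature
  for (tr in c("elastic", "L_to_E2", "R_to_E2", "E1_to_E2", "R_to_L")) {
    req <- default_req(1e6, 1e6, transition = tr)
    cf <- closed_form_rate(req)$gamma
    ng <- numeric_rate(req, correlation = "gaussian")$gamma
    expect_equal(ng, cf, tolerance = 1e-3, info = tr)
  }
})

test_that("numeric oracle with the quadrature correlation stays near the closed form", {
  req <- default_req(1e6, 1e9, transition = "L_to_E2")
  expect_equal(numeric_rate(req)$gamma, closed_form_rate(req)$gamma,
               tolerance = 0.05)
  # Delta = 0 kills the rate identically
  r0 <- default_req(1e6, 1e9)
  r0$params$delta <- 0
  expect_identical(numeric_rate(r0)$gamma, 0)
})

test_that("rate request validates transitions", {
  od <- odorant_two_level(1e6, 1e9)
  expect_error(rate_request(od, transition = "L_to_E3"))
  req <- rate_request(od, transition = "L_to_E2")
  expect_s3_class(req, "rate_request")
  expect_output(print(closed_form_rate(req)), "L_to_E2")
})
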