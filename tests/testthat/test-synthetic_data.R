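test_that("identical seeds give identical datasets", {
  a <- generate_buildup_dataset(template_3cmc(), seed = 42)
  b <- generate_buildup_dataset(template_3cmc(), seed = 42)
  expect_identical(a, b)
  c <- generate_buildup_dataset(template_3cmc(), seed = 43)
  expect_false(identical(a, c))

  sys <- default_competition_system()
  ca <- generate_competition_dataset(template_4cmc(), sys, "site_II", seed = 7)
  cb <- generate_competition_dataset(template_4cmc(), sys, "site_II", seed = 7)
  expect_identical(ca, cb)

  da <- generate_dialysis_dataset(default_dialysis_system(), 5, seed = 9)
  db <- generate_dialysis_dataset(default_dialysis_system(), 5, seed = 9)
  expect_identical(da, db)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_buildup_dataset(template_3cmc(), seed = 1))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("noiseless generation inverts exactly through the formula", {
  ds <- generate_buildup_dataset(template_3cmc(), noise = noise_model(0, 0),
                                 seed = 1)
  for (pid in names(ds$series)) {
    s <- ds$series[[pid]]
    tr <- ds$truth[ds$truth$proton_id == pid, ]
    eta <- amplification_factor(s$i0, s$istd, s$epsilon)
    expect_equal(eta, tr$std_max * (1 - exp(-tr$k_sat * s$times)),
                 tolerance = 1e-12)
  }
  expect_equal(ds$truth$std0, ds$truth$std_max * ds$truth$k_sat)
})

test_that("empirical eta scatter matches delta-method propagation", {
  # one proton, cv = 0.02: sd(eta) at each t should be close to
  # eps * (istd/i0) * cv * sqrt(2) (independent multiplicative noise on
  # both intensities)
  tmpl <- ligand_template("L", data.frame(
    proton_id = "p", chemical_shift = 7.9, std_max = 15, k_sat = 0.5,
    w_site_I = 0.5, w_site_II = 0.5))
  cv <- 0.02
  n <- 500
  etas <- matrix(NA_real_, n, 8)
  for (i in seq_len(n)) {
    s <- generate_buildup_dataset(tmpl, noise = noise_model(cv, 0),
                                  seed = 1000 + i)$series[[1]]
    etas[i, ] <- suppressWarnings(
      amplification_factor(s$i0, s$istd, s$epsilon))
  }
  eta_true <- 15 * (1 - exp(-0.5 * default_schedule()))
  r <- 1 - eta_true / 40
  predicted <- 40 * r * cv * sqrt(2)
  empirical <- apply(etas, 2, sd)
  expect_true(all(abs(empirical - predicted) / predicted < 0.20))
})

test_that("estimator scatter grows monotonically with intensity cv", {
  tmpl <- ligand_template("L", data.frame(
    proton_id = "p", chemical_shift = 7.9, std_max = 15, k_sat = 0.5,
    w_site_I = 0.5, w_site_II = 0.5))
  scatter <- vapply(c(0.005, 0.02, 0.06), function(cv) {
    std0 <- vapply(1:80, function(i) {
      s <- generate_buildup_dataset(tmpl, noise = noise_model(cv, 0),
                                    seed = 2000 + i)$series[[1]]
      fit_buildup(s)$std0
    }, numeric(1))
    sd(std0, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(scatter) > 0))
})

test_that("generator rejects invalid inputs", {
  expect_error(generate_buildup_dataset(template_3cmc(), schedule = numeric(0),
                                        seed = 1),
               class = "stdbind_invalid_input")
  expect_error(generate_buildup_dataset(template_3cmc(),
                                        schedule = c(2, 1), seed = 1),
               class = "stdbind_invalid_input")
  expect_error(ligand_template("L", data.frame()),
               class = "stdbind_invalid_input")
  bad <- template_3cmc()$protons
  bad$w_site_I[1] <- 0.9  # weights no longer sum to 1
  expect_error(ligand_template("L", bad), class = "stdbind_invalid_input")
})

test_that("zero probe concentration leaves the with-probe series unchanged", {
  sys <- binding_system(20, 800, c(site_I = 450, site_II = 150),
                        q_total = 0)
  ds <- generate_competition_dataset(template_3cmc(), sys, "site_II",
                                     noise = noise_model(0, 0), seed = 3)
  for (pid in names(ds$reference))
    expect_equal(ds$reference[[pid]]$istd, ds$with_probe[[pid]]$istd,
                 tolerance = 1e-12)
  expect_equal(unname(ds$truth$attenuation_factor), rep(1, 7))
})

test_that("a saturating probe drives its site's protons to the floor", {
  # proton drawing all transfer from the probed site, probe in vast excess
  # with tiny Kd: attenuation ratio collapses toward 0
  tmpl <- ligand_template("L", data.frame(
    proton_id = "p", chemical_shift = 7.9, std_max = 15, k_sat = 0.5,
    w_site_I = 0, w_site_II = 1))
  sys <- binding_system(20, 800, c(site_I = 450, site_II = 150),
                        q_total = 5000, kd_probe = 1e-6,
                        probe_site = "site_II")
  ds <- generate_competition_dataset(tmpl, sys, "site_II",
                                     noise = noise_model(0, 0), seed = 4)
  expect_lt(ds$truth$attenuation_factor[["p"]], 1e-3)
})

test_that("competition ground truth identifies the occupancy-weighted main site", {
  ds <- generate_competition_dataset(template_3cmc(),
                                     default_competition_system(),
                                     "site_II", noise = noise_model(0, 0),
                                     seed = 5)
  expect_identical(ds$truth$main_site, "site_II")
  # site II has the smaller Kd and larger weights -> larger contribution
  expect_gt(ds$truth$site_contribution[["site_II"]],
            ds$truth$site_contribution[["site_I"]])
})

test_that("noiseless dialysis datasets reproduce the model bound fraction", {
  # Kd = p_total/4 with trace ligand gives a bound fraction of 80%
  sys <- binding_system(p_total = 400, l_total = 1e-6, kd_site = 100)
  ds <- generate_dialysis_dataset(sys, 5, noise = noise_model(0, 0), seed = 6)
  deg <- binding_degree(ds$measurements$D_t, ds$measurements$D_f)
  expect_equal(deg, rep(80, 5), tolerance = 1e-6)
  expect_equal(ds$truth$bound_fraction_percent, 80, tolerance = 1e-6)

  # no protein -> nothing bound
  sys0 <- binding_system(0, 50, kd_site = 100)
  ds0 <- generate_dialysis_dataset(sys0, 3, noise = noise_model(0, 0), seed = 7)
  expect_equal(binding_degree(ds0$measurements$D_t, ds0$measurements$D_f),
               rep(0, 3))
})

test_that("replicate scatter of binding degrees is sub-point at cv = 0.01", {
  ds <- generate_dialysis_dataset(default_dialysis_system(), 5,
                                  noise = noise_model(0, 0.01), seed = 8)
  deg <- binding_degree(ds$measurements$D_t, ds$measurements$D_f)
  expect_lt(sd(deg), 1)
  expect_equal(mean(deg), ds$truth$bound_fraction_percent, tolerance = 0.02)
})
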