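test_that("amplification factor matches its defining formula", {
  expect_equal(amplification_factor(1000, 1000, 40), 0)
  expect_equal(amplification_factor(1000, 975, 40), 1.0)

  set.seed(11)
  for (i in 1:50) {
    i0 <- runif(1, 10, 1e5)
    istd <- runif(1, 0, i0)
    eps <- runif(1, 1, 100)
    expect_equal(amplification_factor(i0, istd, eps),
                 eta_oracle(i0, istd, eps))
  }
  expect_error(amplification_factor(0, 10, 40), class = "stdbind_invalid_input")
  expect_error(amplification_factor(1000, 900, -1),
               class = "stdbind_invalid_input")
  expect_warning(amplification_factor(1000, 1010, 40), "negative")
})

test_that("noiseless build-up series are fitted exactly", {
  s <- make_series(std_max = 2.0, k_sat = 0.5)
  f <- fit_buildup(s)
  expect_true(f$converged)
  expect_equal(f$std_max, 2.0, tolerance = 1e-6)
  expect_equal(f$k_sat, 0.5, tolerance = 1e-6)
  expect_equal(f$std0, 1.0, tolerance = 1e-6)
  # product identity holds exactly
  expect_equal(f$std0, f$std_max * f$k_sat, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:25) {
    m <- runif(1, 0.5, 30)
    k <- runif(1, 0.1, 2)
    f <- fit_buildup(make_series(m, k))
    expect_lt(abs(f$std_max - m) / m, 1e-6)
    expect_lt(abs(f$k_sat - k) / k, 1e-6)
    expect_lt(abs(f$std0 - m * k) / (m * k), 1e-6)
  }
})

test_that("fitted curves are monotone nondecreasing in saturation time", {
  set.seed(31)
  grid <- seq(0, 10, length.out = 400)
  for (i in 1:20) {
    f <- fit_buildup(make_series(runif(1, 1, 30), runif(1, 0.05, 3)))
    expect_true(all(diff(predict(f, grid)) >= 0))
  }
})

test_that("degenerate series raise typed errors", {
  t <- default_schedule()
  flat <- saturation_series("lig", "p1", 7.9, t, rep(1000, 8), rep(1000, 8), 40)
  expect_error(fit_buildup(flat), class = "stdbind_no_binding_error")

  s <- make_series(2, 0.5)
  s$overlap_flag <- TRUE
  expect_error(fit_buildup(s), class = "stdbind_overlap_error")

  short <- saturation_series("lig", "p1", 7.9, c(1, 2), c(1000, 1000),
                             c(990, 980), 40)
  expect_error(fit_buildup(short), class = "stdbind_invalid_input")
})

test_that("standard error of STD0 follows delta-method propagation", {
  # with noise present the se must be finite, positive and consistent with
  # the covariance entries it was propagated from
  set.seed(41)
  eta <- 15 * (1 - exp(-0.5 * default_schedule()))
  i0 <- 1000 * (1 + rnorm(8, sd = 0.02))
  istd <- 1000 * (1 - eta / 40) * (1 + rnorm(8, sd = 0.02))
  f <- fit_buildup(saturation_series("lig", "p", 7.9, default_schedule(),
                                     i0, istd, 40))
  expect_true(is.finite(f$se_std0) && f$se_std0 > 0)
  expect_true(is.finite(f$se_std_max) && is.finite(f$se_k_sat))
})

test_that("epitope map normalizes STD0 to the ligand maximum", {
  fits <- list(fake_fit("a", 2.0, shift = 7.9),
               fake_fit("b", 1.0, shift = 7.5),
               fake_fit("c", 0.5, shift = 2.7))
  em <- epitope_map(fits)
  expect_equal(em$entries$normalized_std0_percent, c(100, 50, 25))
  expect_equal(em$entries$proton_id, c("a", "b", "c"))
  expect_identical(em$reference_proton, "a")
  expect_equal(max(em$entries$normalized_std0_percent), 100)

  # single proton -> 100%
  em1 <- epitope_map(list(fake_fit("only", 0.3)))
  expect_equal(em1$entries$normalized_std0_percent, 100)

  # ties at the maximum break to the lowest chemical shift
  em2 <- epitope_map(list(fake_fit("hi", 1.0, shift = 8.0),
                          fake_fit("lo", 1.0, shift = 1.5)))
  expect_identical(em2$reference_proton, "lo")

  # non-converged fits are excluded; none converged is an error
  fits[[2]] <- fake_fit("b", 1.0, converged = FALSE)
  em3 <- epitope_map(fits)
  expect_false("b" %in% em3$entries$proton_id)
  expect_error(epitope_map(list(fake_fit("x", 1, converged = FALSE))),
               class = "stdbind_empty_map_error")
})

test_that("epitope entries are ordered by descending STD0", {
  set.seed(51)
  std0 <- runif(6, 0.1, 5)
  fits <- lapply(seq_along(std0), function(i)
    fake_fit(paste0("p", i), std0[i], shift = i))
  em <- epitope_map(fits)
  expect_true(all(diff(em$entries$normalized_std0_percent) <= 0))
  expect_equal(em$entries$normalized_std0_percent[1], 100)
})

test_that("fits_table flattens a fit set", {
  ds <- generate_buildup_dataset(template_3cmc(), noise = noise_model(0, 0),
                                 seed = 5)
  fs <- fit_buildup_set(ds$series)
  tab <- fits_table(fs$fits)
  expect_equal(nrow(tab), 7)
  expect_true(all(c("std_max", "k_sat_per_s", "std0_per_s", "se_std0") %in%
                    names(tab)))
  expect_true(all(diff(tab$std0_per_s) <= 0))
})

test_that("fixed-rate refits recover a scaled amplitude exactly and stably", {
  # noiseless: amplitude-only refit at the true rate is exact
  s <- make_series(std_max = 6.0, k_sat = 0.5)
  f <- fit_buildup(s, k_fixed = 0.5)
  expect_equal(f$std_max, 6.0, tolerance = 1e-9)
  expect_equal(f$k_sat, 0.5)
  expect_equal(f$std0, 3.0, tolerance = 1e-9)

  # attenuated curve refitted at the reference rate: the STD0 ratio is the
  # planted amplitude ratio
  ref <- fit_buildup(make_series(20, 0.6))
  att <- fit_buildup(make_series(20 * 0.37, 0.6), k_fixed = ref$k_sat)
  expect_equal(100 * att$std0 / ref$std0, 37, tolerance = 1e-6)

  # fit_buildup_set threads the reference rates through by proton id
  ds <- generate_buildup_dataset(template_4cmc(), noise = noise_model(0, 0),
                                 seed = 14)
  refset <- fit_buildup_set(ds$series)
  wpset <- fit_buildup_set(ds$series, reference_fits = refset)
  for (pid in names(wpset$fits)) {
    expect_equal(wpset$fits[[pid]]$k_sat, refset$fits[[pid]]$k_sat)
    expect_equal(wpset$fits[[pid]]$std0, refset$fits[[pid]]$std0,
                 tolerance = 1e-9)
  }
})
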