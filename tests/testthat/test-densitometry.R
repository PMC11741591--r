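# totals for the two study conditions at the best-fit parameters
fit_totals <- function() {
  base <- get_profile("RePlus")
  ctrl <- suppressWarnings(apply_transgene(base, 2.57))
  expt <- apply_knockdown(ctrl, 0.14)
  list(ctrl = steady_state_totals(ctrl$params),
       expt = steady_state_totals(expt$params))
}

test_that("noise-free populations carry the scaled totals exactly", {
  tt <- fit_totals()
  spec <- population_spec(sigma = 0, background_sd = 0, seed = 5)
  cells <- generate_population(spec, tt$ctrl, tt$expt)
  ctrl <- cells[cells$group == "control", ]
  expect_true(all(ctrl$reelin_au == spec$gain * tt$ctrl[["total_reelin"]]))
  expect_true(all(ctrl$abeta_au == spec$gain * tt$ctrl[["total_a_beta"]]))
  expect_false(any(cells$excluded))
  est <- ratio_of_means(cells, n_boot = 50)
  expect_equal(est$reelin_ratio,
               tt$expt[["total_reelin"]] / tt$ctrl[["total_reelin"]],
               tolerance = 1e-12)
  expect_equal(est$abeta_ratio,
               tt$expt[["total_a_beta"]] / tt$ctrl[["total_a_beta"]],
               tolerance = 1e-12)
})

test_that("generation is deterministic given the seed, byte-for-byte in CSV", {
  tt <- fit_totals()
  spec <- population_spec(seed = 17)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  utils::write.csv(generate_population(spec, tt$ctrl, tt$expt), f1,
                   row.names = FALSE)
  utils::write.csv(generate_population(spec, tt$ctrl, tt$expt), f2,
                   row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different population
  spec2 <- population_spec(seed = 18)
  cells2 <- generate_population(spec2, tt$ctrl, tt$expt)
  expect_false(identical(cells2$reelin_au,
                         generate_population(spec, tt$ctrl, tt$expt)$reelin_au))
})

test_that("group sizes and columns match the specification", {
  tt <- fit_totals()
  cells <- generate_population(population_spec(seed = 2), tt$ctrl, tt$expt)
  expect_identical(names(cells),
                   c("cell_id", "group", "reelin_au", "abeta_au", "excluded"))
  expect_identical(sum(cells$group == "control"), 585L)
  expect_identical(sum(cells$group == "experimental"), 820L)
  expect_true(all(cells$excluded ==
                    (cells$reelin_au < 0 | cells$abeta_au < 0)))
})

test_that("ratio of means is invariant to the gain", {
  tt <- fit_totals()
  a <- ratio_of_means(generate_population(population_spec(seed = 9, gain = 1e-5),
                                          tt$ctrl, tt$expt), n_boot = 10)
  b <- ratio_of_means(generate_population(
    population_spec(seed = 9, gain = 2e-5, background_sd = 1.04),
    tt$ctrl, tt$expt), n_boot = 10)
  # doubling gain and background sd rescales every signal by 2: same ratios
  expect_equal(a$reelin_ratio, b$reelin_ratio, tolerance = 1e-10)
  expect_equal(a$abeta_ratio, b$abeta_ratio, tolerance = 1e-10)
})

test_that("exclusion fraction grows with background noise", {
  tt <- fit_totals()
  excl <- vapply(c(0.5, 2, 8), function(sd) {
    cells <- generate_population(population_spec(seed = 4, background_sd = sd),
                                 tt$ctrl, tt$expt)
    mean(cells$excluded)
  }, numeric(1))
  expect_true(all(diff(excl) > 0))
})

test_that("default noise keeps the exclusion rate near 2e-4", {
  tt <- fit_totals()
  # expected rate over many cells; aggregate 40 seeded populations
  excl <- vapply(1:40, function(s) {
    mean(generate_population(population_spec(seed = s),
                             tt$ctrl, tt$expt)$excluded)
  }, numeric(1))
  expect_lt(mean(excl), 1e-3)
  expect_gt(mean(excl), 1e-5)
})

test_that("ratio-of-means estimator is unbiased under default noise", {
  tt <- fit_totals()
  true_r <- tt$expt[["total_reelin"]] / tt$ctrl[["total_reelin"]]
  true_a <- tt$expt[["total_a_beta"]] / tt$ctrl[["total_a_beta"]]
  est <- vapply(1:10, function(s) {
    e <- ratio_of_means(generate_population(population_spec(seed = s),
                                            tt$ctrl, tt$expt), n_boot = 10)
    c(e$reelin_ratio, e$abeta_ratio)
  }, numeric(2))
  expect_equal(mean(est[1, ]), true_r, tolerance = 0.02 / true_r)
  expect_equal(mean(est[2, ]), true_a, tolerance = 0.02 / true_a)
})

test_that("identical groups give unit ratios and a covering bootstrap CI", {
  tt <- fit_totals()
  spec <- population_spec(n_control = 300, n_experimental = 300, seed = 8)
  cells <- generate_population(spec, tt$ctrl, tt$ctrl)
  est <- ratio_of_means(cells, n_boot = 500)
  expect_equal(est$reelin_ratio, 1, tolerance = 0.1)
  expect_true(est$reelin_ci[1] < 1 && 1 < est$reelin_ci[2])
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  tt <- fit_totals()
  width <- function(nc, ne, seed) {
    cells <- generate_population(
      population_spec(n_control = nc, n_experimental = ne, seed = seed),
      tt$ctrl, tt$expt)
    ci <- ratio_of_means(cells, n_boot = 400, seed = seed)$reelin_ci
    diff(ci)
  }
  w1 <- mean(vapply(1:5, function(s) width(585, 820, s), numeric(1)))
  w4 <- mean(vapply(1:5, function(s) width(4 * 585, 4 * 820, s), numeric(1)))
  expect_equal(w4 / w1, 0.5, tolerance = 0.3)
})

test_that("noise-free recovery returns the generating grid point exactly", {
  rec <- recover_parameters(population_spec(sigma = 0, background_sd = 0,
                                            seed = 1),
                            true_fold = 2.57, true_fraction = 0.14,
                            n_boot = 10)
  expect_equal(rec$fit$best_fold, 2.57)
  expect_equal(rec$fit$best_fraction, 0.14)
  expect_equal(unname(rec$error), c(0, 0), tolerance = 1e-9)
})

test_that("no knockdown is recovered as a fraction near one under noise", {
  fracs <- vapply(1:5, function(s) {
    recover_parameters(population_spec(seed = s), true_fold = 3,
                       true_fraction = 1.0, n_boot = 10)$fit$best_fraction
  }, numeric(1))
  expect_gte(stats::median(fracs), 0.95)
  expect_true(all(fracs >= 0.9))
})

test_that("population spec validation rejects impossible settings", {
  expect_error(population_spec(n_control = 0), "positive integers")
  expect_error(population_spec(gain = 0), "gain")
  expect_error(population_spec(sigma = -1), "sigma")
  expect_error(population_spec(background_sd = -0.1), "background sd")
  tt <- fit_totals()
  expect_error(generate_population(population_spec(), c(-1, 5), tt$ctrl),
               "non-negative")
})
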