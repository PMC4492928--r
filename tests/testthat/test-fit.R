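test_that("sum of squared deviations", {
  # a model that interpolates the data exactly has SSD 0
  const <- savings_curve(c(10, 20, 30), rep(0.6, 3))
  expect_equal(retention_ssd(const, "single_exp", c(0.6, 0)), 0)
  # constant offset d on m points gives m * d^2
  expect_equal(retention_ssd(const, "single_exp", c(0.75, 0)), 3 * 0.15^2)
  # reference evaluation near the published optimum
  eb <- load_fixture("table3")$Ebbinghaus
  s <- retention_ssd(eb, "summed_exp", c(0.383, 0.000319, 0.321, 1.79e-7))
  expect_printed(s, "0.00469", slack = 1.5)
})

test_that("uncentered R-squared", {
  cu <- savings_curve(c(1, 2), c(0.3, 0.4))
  expect_equal(r2_uncentered(cu, 0), 1)
  dros <- load_fixture("table3")$Dros
  expect_printed(r2_uncentered(dros, 0.0163), "0.974")
  eb <- load_fixture("table3")$Ebbinghaus
  expect_printed(r2_uncentered(eb, 0.00224), "0.998")
  zero <- savings_curve(c(1, 2), c(0, 0))
  expect_error(r2_uncentered(zero, 0.1), "zero")
})

test_that("Gaussian AIC reproduces every published (SSD, k, AIC) triple", {
  for (tab in list(published_table4, published_table5)) {
    for (m in names(tab)) {
      k <- length(tab[[m]]$pars[[1]])
      for (j in seq_along(published_subjects)) {
        a <- aic_gaussian(as.numeric(tab[[m]]$ssd[j]), n = 7, k = k)
        expect_printed(a, tab[[m]]$aic[j],
                       label = sprintf("%s/%s AIC", m, published_subjects[j]))
      }
    }
  }
  expect_warning(a0 <- aic_gaussian(0, 7, 2), "zero")
  expect_identical(a0, -Inf)
})

test_that("AIC agrees with the generic stats::AIC via logLik", {
  fit <- fit_retention(load_fixture("table3")$Mack, "power", n_starts = 10)
  expect_equal(AIC(fit), fit$aic)
  expect_equal(deviance(fit), fit$ssd)
})

test_that("noiseless data recovers the generating parameters", {
  t <- canonical_intervals()
  cu <- savings_curve(t, q_power(t, 1.2, 0.1), "synthetic")
  # an exact interpolation reaches SSD 0, where AIC degenerates with a
  # warning to its -Inf sentinel
  expect_warning(fit <- fit_retention(cu, "power", n_starts = 20, seed = 4),
                 "zero")
  expect_equal(unname(coef(fit)), c(1.2, 0.1), tolerance = 1e-6)
  expect_lt(fit$ssd, 1e-12)
  expect_identical(fit$aic, -Inf)
})

test_that("stored metrics are internally consistent with the parameters", {
  curves <- load_fixture("table3")
  for (m in c("power", "eb1885", "summed_exp")) {
    fit <- fit_retention(curves$Seitz, m, n_starts = 25, seed = 2)
    ssd <- retention_ssd(curves$Seitz, m, coef(fit))
    expect_equal(ssd, fit$ssd, tolerance = 1e-12)
    expect_equal(r2_uncentered(curves$Seitz, ssd), fit$r2, tolerance = 1e-12)
    expect_equal(aic_gaussian(ssd, fit$n, fit$k), fit$aic, tolerance = 1e-12)
    expect_equal(fit$curve$savings - predict(fit), unname(residuals(fit)))
  }
})

test_that("optimum is invariant to the restart seed at 50 starts", {
  curves <- load_fixture("table3")
  for (s in names(curves)) {
    for (m in c("power", "summed_exp")) {
      f1 <- fit_retention(curves[[s]], m, n_starts = 50, seed = 1)
      f2 <- fit_retention(curves[[s]], m, n_starts = 50, seed = 99)
      expect_equal(f1$ssd, f2$ssd, tolerance = 1e-7)
      expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-3)
    }
  }
})

test_that("under-determined and degenerate fits error out", {
  cu3 <- savings_curve(c(1200, 3600, 86400), c(0.5, 0.4, 0.3))
  expect_error(fit_retention(cu3, "mcm"), "under-determined")
  short <- savings_curve(c(30, 90, 600, 3600), c(0.9, 0.8, 0.6, 0.5))
  expect_error(fit_retention(short, "eb1880"), "2 minutes")
})

test_that("parameter error shrinks with the observation noise", {
  t <- canonical_intervals()
  truth <- list(power = c(1.4, 0.13), eb1885 = c(1.8, 1.21),
                summed_exp = c(0.383, 0.000319, 0.321, 1.79e-7))
  for (m in names(truth)) {
    med_err <- vapply(c(0.003, 0.03), function(sigma) {
      errs <- vapply(1:60, function(i) {
        cu <- simulate_savings_curve(m, truth[[m]], intervals = t,
                                     noise_sd = sigma, seed = 5000 + i)
        fit <- fit_retention(cu, m, n_starts = 15, seed = i)
        max(abs((coef(fit) - truth[[m]]) / truth[[m]]))
      }, 0)
      median(errs)
    }, 0)
    expect_lt(med_err[1], med_err[2])
  }
})

test_that("model comparison assembles per-subject and average metrics", {
  curves <- load_fixture("table3")
  # the memory-chain and summed-exponential forms reach the same optimum
  cmp <- compare_retention(curves["Seitz"], c("summed_exp", "mcm"),
                           n_starts = 40, seed = 0)
  expect_equal(cmp$fits$summed_exp$Seitz$ssd, cmp$fits$mcm$Seitz$ssd,
               tolerance = 1e-9)
  # duplicated curves give identical cells and an average equal to them
  two <- list(a = curves$Mack, b = curves$Mack)
  cmp2 <- compare_retention(two, "power", n_starts = 20, seed = 1)
  expect_equal(cmp2$fits$power$a$ssd, cmp2$fits$power$b$ssd)
  expect_equal(cmp2$averages$aic, cmp2$fits$power$a$aic)
  # averages are the arithmetic means of the per-subject values
  cmp3 <- compare_retention(curves, c("power", "single_exp"),
                            n_starts = 15, seed = 0)
  for (m in c("power", "single_exp")) {
    sub <- cmp3$table[cmp3$table$model == m, ]
    expect_equal(cmp3$averages$aic[cmp3$averages$model == m], mean(sub$aic))
  }
  # the far-worse single exponential is flagged as meaningfully worse
  expect_true(cmp3$averages$meaningful[cmp3$averages$model == "single_exp"])
})

test_that("comparison table writers emit TSV and JSON", {
  curves <- load_fixture("table3")["Mack"]
  cmp <- compare_retention(curves, c("power", "single_exp"),
                           n_starts = 10, seed = 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(cmp, tsv, "tsv")
  back <- read.delim(tsv)
  expect_setequal(unique(back$subject), c("Mack", "Average"))
  expect_equal(nrow(back), 4)
  json <- withr::local_tempfile(fileext = ".json")
  write_comparison(cmp, json, "json")
  obj <- jsonlite::read_json(json)
  expect_named(obj, c("power", "single_exp"))
  expect_equal(obj$power$Mack$ssd, cmp$fits$power$Mack$ssd,
               tolerance = 1e-12)
})

test_that("fit methods: print, summary, predict, plot, simulate", {
  fit <- fit_retention(load_fixture("table3")$Ebbinghaus, "power_boost",
                       n_starts = 20, seed = 0)
  expect_output(print(fit), "power_boost")
  expect_output(print(summary(fit)), "residuals")
  expect_equal(predict(fit), unname(fitted(fit)))
  expect_equal(predict(fit, 86400) - predict(fit, 86399),
               coef(fit)[["boost"]] +
                 q_power(86400, coef(fit)[["mu1"]], coef(fit)[["a1"]]) -
                 q_power(86399, coef(fit)[["mu1"]], coef(fit)[["a1"]]))
  sims <- simulate(fit, nsim = 3, seed = 8)
  expect_equal(dim(sims), c(7L, 4L))
  expect_equal(simulate(fit, nsim = 3, seed = 8), sims)  # seeded determinism
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
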