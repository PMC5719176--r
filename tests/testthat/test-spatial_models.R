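test_that("the hypothesis suite is exactly the ten published predictor sets", {
  suite <- spatial_model_suite()
  expect_length(suite, 10)
  sets <- lapply(suite, sort)
  expected <- list(
    c("AET", "Elev", "HFI", "PET", "Rain", "Temp"),
    c("AET", "HFI", "PET", "Rain", "Temp"),
    c("Elev", "HFI", "PET", "Rain", "Temp"),
    c("Elev", "HFI", "PET", "Rain"),
    c("AET", "PET", "Rain", "Temp"),
    c("HFI", "PET", "Rain"),
    "HFI",
    c("Elev", "PET", "Rain"),
    "Elev",
    c("PET", "Rain")
  )
  for (e in expected) {
    expect_true(any(vapply(sets, identical, TRUE, sort(e))),
                info = paste(e, collapse = "+"))
  }
})

test_that("two-group fit recovers the closed-form logit difference", {
  d <- data.frame(cell_id = sprintf("c%02d", 1:40),
                  Elev = rep(c(0, 1), each = 20))
  d$n_old <- 10
  d$n_lost <- rep(c(2, 8), each = 20)
  d$n_retained <- d$n_old - d$n_lost
  d$p_cell <- d$n_lost / d$n_old
  fit <- binomial_glm_fit(d, "Elev", standardize = FALSE)
  expect_equal(unname(fit$coefficients["Elev"]),
               qlogis(0.8) - qlogis(0.2), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["Elev"]), 2.7726, tolerance = 1e-4)
  # standardized and raw scales agree after back-transformation
  fit_z <- binomial_glm_fit(d, "Elev", standardize = TRUE)
  expect_equal(unname(fit_z$coefficients_raw["Elev"]),
               unname(fit$coefficients["Elev"]), tolerance = 1e-6)
})

test_that("deviance explained is 0 for the null model and under the null", {
  d <- make_cells(60, beta = 1.2, seed = 2)
  null_fit <- binomial_glm_fit(d, character(0))
  expect_equal(null_fit$dev_explained, 0)

  # response independent of every predictor: essentially nothing explained
  d0 <- make_cells(500, beta = 0, seed = 3)
  full <- binomial_glm_fit(d0, spatial_model_suite()$a)
  expect_lt(full$dev_explained, 0.02)
})

test_that("deviance explained grows along nested predictor chains", {
  d <- make_cells(200, beta = 1, seed = 4)
  chain <- list("Elev", c("Elev", "PET"), c("Elev", "PET", "Rain"),
                c("Elev", "PET", "Rain", "HFI"))
  dev <- vapply(chain, function(pr) {
    binomial_glm_fit(d, pr)$dev_explained
  }, 0)
  expect_true(all(diff(dev) >= -1e-12))
  expect_true(all(dev >= 0 & dev <= 1))
})

test_that("fits are invariant to cell ordering", {
  d <- make_cells(120, beta = 0.8, seed = 5)
  f1 <- binomial_glm_fit(d, c("Elev", "HFI"))
  f2 <- binomial_glm_fit(d[sample(nrow(d)), ], c("Elev", "HFI"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
})

test_that("suite ranking finds the generating model among the supported set", {
  d <- make_cells(200, beta = 1.5, predictor = "Elev", seed = 6)
  out <- run_model_suite(d)
  expect_equal(nrow(out$ranking), 10)
  expect_equal(out$ranking$dAICc[1], 0)
  supported <- out$ranking$model[out$ranking$supported]
  with_elev <- names(Filter(function(s) "Elev" %in% s,
                            spatial_model_suite()))
  expect_true(any(supported %in% with_elev))
  # single-model suite trivially has delta = 0
  solo <- run_model_suite(d, suite = list(h = "Elev"))
  expect_equal(solo$ranking$dAICc, 0)
})

test_that("the empirical-logit response mode is available and sane", {
  d <- make_cells(150, beta = 1.2, seed = 7)
  fit <- binomial_glm_fit(d, "Elev", response = "elogit")
  expect_gt(fit$coefficients["Elev"], 0)
  expect_gt(fit$dev_explained, 0.1)
})

test_that("predictor aggregation means rasters onto the grid", {
  border <- list(rect_ring(0, 0, 300, 300))
  g <- make_grid(border, 100)
  const <- list(ncols = 30, nrows = 30, xllcorner = 0, yllcorner = 0,
                cellsize = 10, nodata = -9999, z = matrix(7, 30, 30))
  # linear gradient in x: cell mean = value at the cell-centroid x
  xs <- (seq_len(30) - 0.5) * 10
  grad <- const
  grad$z <- matrix(xs, 30, 30, byrow = TRUE)
  # raster with a hole over the central grid cell
  holed <- const
  holed$z[11:20, 11:20] <- NA
  agg <- aggregate_predictors(list(K = const, G = grad, H = holed), g)
  expect_true(all(agg$K == 7))
  centroids <- g$cells$xmin + 50
  expect_true(all(abs(agg$G - centroids) / centroids < 0.01))
  expect_false(agg$complete[agg$cell_id == "r002_c002"])
  expect_true(all(agg$complete[agg$cell_id != "r002_c002"]))
})

test_that("the modelling table drops incomplete or unanalysed cells", {
  border <- list(rect_ring(0, 0, 200, 100))
  g <- make_grid(border, 100)
  loss <- data.frame(cell_id = c("r001_c001", "r001_c002"),
                     row = 1, col = 1:2, x_min = c(0, 100), y_min = 0,
                     n_old = c(4, 5), n_lost = c(1, 2),
                     p_cell = c(0.25, 0.4), analysed = c(TRUE, FALSE))
  pred <- data.frame(cell_id = c("r001_c001", "r001_c002"),
                     Elev = c(100, 200), complete = TRUE)
  cells <- cell_predictor_table(loss, pred)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$n_retained, 3)
})
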