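test_that("phylogenetic covariance reflects shared path lengths and lambda", {
  expect_equal(unname(phylo_covariance(star_tree(4))), diag(4))

  C <- phylo_covariance(three_taxon_tree())
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))

  C0 <- phylo_covariance(three_taxon_tree(), lambda = 0)
  expect_equal(unname(C0), diag(c(2, 2, 2)))
  C5 <- phylo_covariance(three_taxon_tree(), lambda = 0.5)
  expect_equal(C5["A", "B"], 0.5)
  expect_equal(C5["A", "A"], 2)
})

test_that("PGLS reduces exactly to OLS under an identity-like covariance", {
  set.seed(5)
  n <- 20
  d <- data.frame(species = paste0("t", 1:n),
                  x = rnorm(n), z = rnorm(n))
  d$y <- 1 + 2 * d$x - 0.5 * d$z + rnorm(n)
  tree <- star_tree(n)
  ols <- stats::lm(y ~ x + z, data = d)
  for (lam in list(0, 1)) {  # star tree: any lambda is still diagonal
    fit <- pgls_fit(y ~ x + z, d, tree = tree, lambda = lam)
    expect_equal(unname(fit$coefficients), unname(coef(ols)),
                 tolerance = 1e-8)
  }
  # lambda = 0 on a structured tree also equals OLS
  set.seed(6)
  tree2 <- ape::rphylo(n, 1, 0)
  tree2$tip.label <- d$species
  fit0 <- pgls_fit(y ~ x + z, d, tree = tree2, lambda = 0)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
})

test_that("the three-taxon GLS example matches the matrix-algebra oracle", {
  d <- data.frame(species = c("A", "B", "C"), y = c(0, 1, 1), x = c(0, 1, 2))
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- pgls_fit(y ~ x, d, C = C, lambda = 1)
  X <- cbind(1, d$x)
  oracle <- oracle_gls_beta(d$y, X, unname(C))
  expect_equal(unname(fit$coefficients), as.vector(oracle), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(0, 0.625), tolerance = 1e-10)
})

test_that("constant responses give zero slope and non-positive adjusted r2", {
  d <- data.frame(species = c("A", "B", "C"), y = c(1, 1, 1), x = c(0, 1, 2))
  fit <- pgls_fit(y ~ x, d, tree = three_taxon_tree(), lambda = 1)
  expect_equal(unname(fit$coefficients["x"]), 0, tolerance = 1e-12)
  expect_lte(fit$adj.r.squared, 0)
})

test_that("AICc matches its closed form and guards its domain", {
  # arithmetic check against a published-scale log-likelihood
  LL <- -58.960; k <- 4; n <- 34
  expect_equal(aicc(LL, k, n), -2 * LL + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_equal(round(aicc(LL, k, n), 3), 127.299)
  # large-n limit: AICc -> AIC
  expect_equal(aicc(LL, k, 1e8), -2 * LL + 2 * k, tolerance = 1e-5)
  expect_error(aicc(LL, 4, 5), "undefined")
})

test_that("model ranking flags support at both thresholds", {
  mk <- function(aicc) list(logLik = NA_real_, k = 2, AICc = aicc)
  single <- rank_models(list(only = mk(100)))
  expect_equal(single$dAICc, 0)
  expect_true(single$supported)

  r <- rank_models(list(top = mk(100), close = mk(100.499),
                        far = mk(105.979)))
  expect_equal(r$supported, c(TRUE, TRUE, FALSE))
  expect_equal(r$supported_secondary, c(TRUE, TRUE, TRUE))
  expect_equal(r$dAICc, c(0, 0.499, 5.979), tolerance = 1e-12)
  expect_setequal(r$model, c("top", "close", "far"))
})

test_that("PGLS agrees with the independent nlme/corPagel oracle", {
  skip_if_not_installed("nlme")
  set.seed(17)
  n <- 24
  tree <- ape::rcoal(n)
  tree$tip.label <- paste0("t", 1:n)
  C <- phylo_covariance(tree)
  d <- data.frame(species = tree$tip.label, x = rnorm(n))
  d$y <- 0.5 + 1.5 * d$x + as.vector(t(chol(C)) %*% rnorm(n)) * 0.6
  rownames(d) <- d$species
  for (lam in c(0.3, 1)) {
    fit <- pgls_fit(y ~ x, d, tree = tree, lambda = lam)
    g <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(lam, phy = tree,
                                               form = ~species, fixed = TRUE))
    expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
    expect_equal(fit$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
  }
})

test_that("log-likelihood is monotone under nesting at fixed lambda", {
  set.seed(23)
  n <- 30
  tree <- ape::rphylo(n, 1, 0)
  tree$tip.label <- paste0("t", 1:n)
  d <- data.frame(species = tree$tip.label, x = rnorm(n), z = rnorm(n))
  d$y <- 0.3 * d$x + rnorm(n)
  f1 <- pgls_fit(y ~ x, d, tree = tree, lambda = 1)
  f2 <- pgls_fit(y ~ x + z, d, tree = tree, lambda = 1)
  expect_gte(f2$logLik, f1$logLik - 1e-10)
})

test_that("the trait suite fits exactly the four published formulas", {
  set.seed(31)
  n <- 26
  tree <- ape::rphylo(n, 1, 0)
  tree$tip.label <- sprintf("sp%02d", 1:n)
  traits <- data.frame(
    species = tree$tip.label,
    body_mass_kg = 10^runif(n, -0.5, 3.5),
    trophic = sample(1:3, n, replace = TRUE),
    y_pre1900 = plogis(rnorm(n, -1.5, 1)),
    y_post1900 = NA
  )
  traits$y_post1900 <- (1 - traits$y_pre1900) * plogis(rnorm(n, -2, 0.5))
  out <- fit_trait_models(traits, tree, response = "pre1900", lambda = 1)
  expect_setequal(out$ranking$model,
                  c("body mass", "body mass + trophic level",
                    "body mass + trophic level + interaction",
                    "trophic level"))
  expect_equal(out$ranking$dAICc[1], 0)
  # ranking is a permutation of the fits and the top model is supported
  expect_true(out$ranking$supported[1])
  # ML-lambda path runs and keeps lambda in [0, 1]
  out_ml <- fit_trait_models(traits, tree, response = "post1900")
  lams <- vapply(out_ml$fits, `[[`, 0, "lambda")
  expect_true(all(lams >= 0 & lams <= 1))
})
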