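# Species-level extinction-selectivity models: phylogenetic generalized
# least squares (PGLS) of proportion of range lost on body mass and trophic
# level, with small-sample AICc ranking. The GLS machinery is implemented
# here (profile-ML sigma^2 and optional profile-ML Pagel's lambda); tree
# handling is delegated to ape.

#' Phylogenetic covariance matrix with Pagel's lambda scaling
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j; Pagel's
#' lambda multiplies the off-diagonal entries, interpolating between a star
#' phylogeny (lambda = 0, independent residuals) and plain Brownian motion
#' (lambda = 1).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param lambda scalar in `[0, 1]`.
#' @return symmetric positive-definite matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  C <- ape::vcv.phylo(tree)
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

# GLS fit for a fixed covariance; returns profile-ML quantities.
# X must be full rank; V is used up to a proportionality constant.
gls_engine <- function(y, X, V) {
  n <- length(y)
  L <- tryCatch(chol(V), error = function(e) {
    chol(V + diag(1e-10 * mean(diag(V)), n))
  })
  # whiten: solve L' z = y (V = L'L with R's upper-triangular chol)
  yt <- backsolve(L, y, transpose = TRUE)
  Xt <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xt)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, yt)
  resid <- yt - Xt %*% beta
  rss <- sum(resid^2)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                 drop = FALSE]
  list(beta = beta, rss = rss, sigma2_ml = sigma2_ml, logLik = ll,
       cov_unscaled = XtX_inv, n = n, p = ncol(X))
}

#' Fit a phylogenetic generalized least-squares regression
#'
#' GLS with residual covariance proportional to the lambda-scaled
#' phylogenetic covariance. `sigma^2` is profiled out by maximum likelihood;
#' `lambda` is either fixed or itself profile-ML estimated on `[0, 1]`
#' (the default, consistent with per-model lambda optimization, under which
#' log-likelihoods of nested models need not be monotone). With `lambda = 0`
#' or a star tree the fit reduces exactly to ordinary least squares.
#'
#' The parameter count used for AICc is `k = p + 1` (regression
#' coefficients plus `sigma^2`), plus 1 when lambda is ML-estimated; the
#' convention is exposed via `k_extra` because published tables are not
#' always explicit about it.
#'
#' @param formula model formula.
#' @param data data.frame with rownames (or a `species` column) matching
#'   the tree tips / covariance dimnames.
#' @param tree an `ape::phylo`; alternatively supply `C` directly.
#' @param C optional covariance matrix overriding `tree`.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param k_extra added to the coefficient-plus-sigma parameter count;
#'   default 1 when lambda is ML-estimated, else 0.
#' @return object of class `pgls_fit` with coefficients, standard errors,
#'   `logLik`, `k`, `n`, `AICc`, `r.squared`, `adj.r.squared` and the
#'   lambda used.
#' @export
pgls_fit <- function(formula, data, tree = NULL, C = NULL, lambda = "ML",
                     k_extra = NULL) {
  if (is.null(C)) {
    if (is.null(tree)) stop("supply either a tree or a covariance matrix C")
    C <- ape::vcv.phylo(tree)
  }
  rownames(C) <- colnames(C) <- normalize_species_id(rownames(C))
  ids <- if (!is.null(data$species)) data$species else rownames(data)
  if (is.null(ids)) stop("data needs rownames or a species column")
  ids <- normalize_species_id(ids)
  miss <- setdiff(ids, rownames(C))
  if (length(miss) > 0) {
    stop("species absent from covariance: ", paste(miss, collapse = ", "))
  }
  C <- C[ids, ids]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)

  scale_lambda <- function(lam) {
    Cl <- C * lam
    diag(Cl) <- diag(C)
    Cl
  }
  ml_lambda <- identical(lambda, "ML")
  if (ml_lambda) {
    prof <- function(lam) gls_engine(y, X, scale_lambda(lam))$logLik
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    # the optimum can sit on a boundary; check both ends explicitly
    cand <- c(opt$maximum, 0, 1)
    lls <- vapply(cand, prof, 0)
    lambda_hat <- cand[which.max(lls)]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }
  V <- scale_lambda(lambda_hat)
  fit <- gls_engine(y, X, V)

  # structural fit relative to the GLS intercept-only model under the same V
  null_fit <- gls_engine(y, matrix(1, n, 1), V)
  r2 <- if (null_fit$rss > 1e-12 * n) 1 - fit$rss / null_fit$rss else 0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - fit$p)

  if (is.null(k_extra)) k_extra <- if (ml_lambda) 1L else 0L
  k <- fit$p + 1L + k_extra
  sigma2_unbiased <- fit$rss / (n - fit$p)
  se <- sqrt(diag(fit$cov_unscaled) * sigma2_unbiased)
  structure(
    list(coefficients = stats::setNames(as.vector(fit$beta), colnames(X)),
         se = stats::setNames(se, colnames(X)),
         cov_unscaled = fit$cov_unscaled,
         sigma2 = sigma2_unbiased,
         logLik = fit$logLik, n = n, p = fit$p, k = k,
         AICc = if (n > k + 1) aicc(fit$logLik, k, n) else NA_real_,
         r.squared = r2, adj.r.squared = adj_r2,
         lambda = lambda_hat, lambda_ml = ml_lambda,
         formula = formula, df.residual = n - fit$p),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, lambda = %.3f%s, logLik = %.3f, k = %d, AICc = %.3f\n",
              x$n, x$lambda, if (x$lambda_ml) " (ML)" else "",
              x$logLik, x$k, x$AICc))
  cat(sprintf("  r2 = %.3f (adjusted %.3f)\n", x$r.squared, x$adj.r.squared))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               t = x$coefficients / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Confidence intervals for PGLS coefficients
#'
#' t-intervals on the residual degrees of freedom.
#'
#' @param object a `pgls_fit`.
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.pgls_fit <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  if (is.null(parm)) parm <- names(cf)
  q <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  out <- cbind(lower = cf[parm] - q * object$se[parm],
               upper = cf[parm] + q * object$se[parm])
  rownames(out) <- parm
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2k + 2k(k + 1)/(n - k - 1)`; undefined (an error) when
#' `n <= k + 1`.
#'
#' @param LL maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return numeric.
#' @export
aicc <- function(LL, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined for n <= k + 1")
  -2 * LL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# pull ranking fields out of heterogeneous fit objects
fit_ic_row <- function(fit, ic = "AICc") {
  list(
    LL = if (!is.null(fit$logLik)) as.numeric(fit$logLik) else NA_real_,
    k = fit$k,
    IC = switch(ic, AICc = fit$AICc, AIC = fit$AIC,
                stop("unknown criterion: ", ic)),
    adj_r2 = if (!is.null(fit$adj.r.squared)) fit$adj.r.squared else NA_real_,
    dev_explained = if (!is.null(fit$dev_explained)) fit$dev_explained
                    else NA_real_
  )
}

#' Rank fitted models by information criterion
#'
#' Computes delta-IC relative to the top-ranked (lowest-IC) model and flags
#' support at the conventional threshold of 2 delta-AICc units, with a
#' secondary, more permissive threshold (default 6) also reported.
#'
#' @param fits named list of fitted models (`pgls_fit` or `binomial_glm_fit`
#'   results).
#' @param threshold delta-IC below which a model is "well supported".
#' @param threshold2 secondary reporting threshold.
#' @param ic `"AICc"` or `"AIC"`.
#' @return data.frame sorted by IC: `model`, `LL`, `k`, `IC`, `dAIC`,
#'   `adj_r2` / `dev_explained` where available, `supported`,
#'   `supported_secondary`.
#' @export
rank_models <- function(fits, threshold = 2, threshold2 = 6, ic = "AICc") {
  stopifnot(length(fits) >= 1)
  rows <- lapply(fits, fit_ic_row, ic = ic)
  out <- data.frame(
    model = names(fits),
    LL = vapply(rows, `[[`, 0, "LL"),
    k = vapply(rows, `[[`, 0, "k"),
    IC = vapply(rows, `[[`, 0, "IC"),
    adj_r2 = vapply(rows, `[[`, 0, "adj_r2"),
    dev_explained = vapply(rows, `[[`, 0, "dev_explained"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$IC), ]
  out$dAIC <- out$IC - out$IC[1]
  out$supported <- out$dAIC < threshold
  out$supported_secondary <- out$dAIC < threshold2
  names(out)[names(out) == "IC"] <- ic
  names(out)[names(out) == "dAIC"] <- paste0("d", ic)
  rownames(out) <- NULL
  out
}

#' Fit and rank the four trait models of range loss
#'
#' The model set is {body mass}, {body mass + trophic level},
#' {body mass + trophic level + interaction}, {trophic level}. The response
#' is the proportion of the Holocene range lost before AD 1900
#' (`(A_hol - A_hist)/A_hol`) or further lost after AD 1900
#' (`(A_hist - A_mod)/A_hol`; the Holocene base keeps the two eras additive).
#' Body mass is log10-transformed by default; trophic level enters as an
#' unordered 3-level factor with herbivore as reference (a numeric coding is
#' available for sensitivity).
#'
#' @param traits data.frame with `species`, `body_mass_kg`, `trophic`, and
#'   either `y_pre1900`/`y_post1900` or the three area columns of
#'   [area_table()] from which they are computed.
#' @param tree an `ape::phylo` covering the species.
#' @param response `"pre1900"` or `"post1900"`.
#' @param lambda passed to [pgls_fit()].
#' @param log10_mass log10-transform body mass first?
#' @param trophic_factor treat trophic level as categorical?
#' @param ... further arguments to [pgls_fit()].
#' @return list with `ranking` (the [rank_models()] table) and `fits`.
#' @export
fit_trait_models <- function(traits, tree, response = c("pre1900", "post1900"),
                             lambda = "ML", log10_mass = TRUE,
                             trophic_factor = TRUE, ...) {
  response <- match.arg(response)
  d <- traits
  d$species <- normalize_species_id(d$species)
  if (!all(c("y_pre1900", "y_post1900") %in% names(d))) {
    need <- c("area_hol_km2", "area_hist_km2", "area_mod_km2")
    if (!all(need %in% names(d))) {
      stop("traits must carry y_pre1900/y_post1900 or the area columns")
    }
    d$y_pre1900 <- (d$area_hol_km2 - d$area_hist_km2) / d$area_hol_km2
    d$y_post1900 <- (d$area_hist_km2 - d$area_mod_km2) / d$area_hol_km2
  }
  d$loss <- if (response == "pre1900") d$y_pre1900 else d$y_post1900
  d$mass <- if (log10_mass) log10(d$body_mass_kg) else d$body_mass_kg
  d$troph <- if (trophic_factor) factor(d$trophic, levels = 1:3,
                                        labels = c("herbivore", "omnivore",
                                                   "carnivore"))
             else d$trophic
  rownames(d) <- d$species
  forms <- list(
    "body mass" = loss ~ mass,
    "body mass + trophic level" = loss ~ mass + troph,
    "body mass + trophic level + interaction" = loss ~ mass * troph,
    "trophic level" = loss ~ troph
  )
  fits <- list()
  failures <- list()
  for (nm in names(forms)) {
    res <- tryCatch(
      pgls_fit(forms[[nm]], data = d, tree = tree, lambda = lambda, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) failures[[nm]] <- conditionMessage(res)
    else fits[[nm]] <- res
  }
  if (length(fits) == 0) stop("every trait model failed to fit")
  list(ranking = rank_models(fits), fits = fits, failures = failures,
       response = response)
}
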