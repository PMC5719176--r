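# Regional (cell-level) extinction-selectivity models: binomial GLMs of
# per-cell species loss on six environmental predictors, fitted as a fixed
# ten-model hypothesis suite and ranked by information criterion. Fitting is
# delegated to stats::glm (IRLS); suite logic, predictor aggregation and
# deviance partitioning live here.

SPATIAL_PREDICTORS <- c("Elev", "HFI", "Rain", "Temp", "AET", "PET")

#' The ten-model spatial hypothesis suite
#'
#' Fixed combinations of the six predictors (Elev = elevation, HFI = Human
#' Footprint Index, Rain = annual precipitation, Temp = annual temperature,
#' AET/PET = actual/potential evapotranspiration), each encoding a distinct
#' hypothesis about climatic, anthropogenic and physical drivers of loss:
#' the full model (a); successive removal of the physical factors Elev and
#' HFI (b, c); removal of AET, which tracks PET (d); additionally removing
#' Temp, which tracks Rain (e); human pressure plus reduced climate (f);
#' elevation plus reduced climate (g); elevation only (h); human pressure
#' only (i); non-collinear climate only (j).
#'
#' @return named list of character vectors of predictor names.
#' @export
spatial_model_suite <- function() {
  list(
    a = c("AET", "Elev", "HFI", "PET", "Rain", "Temp"),
    b = c("AET", "HFI", "PET", "Rain", "Temp"),
    c = c("AET", "PET", "Rain", "Temp"),
    d = c("Elev", "HFI", "PET", "Rain", "Temp"),
    e = c("Elev", "HFI", "PET", "Rain"),
    f = c("HFI", "PET", "Rain"),
    g = c("Elev", "PET", "Rain"),
    h = "Elev",
    i = "HFI",
    j = c("PET", "Rain")
  )
}

#' Aggregate predictor rasters to the analysis grid
#'
#' Per grid cell, the mean of the raster cells whose centres fall inside the
#' cell. Cells where less than `min_coverage` of the expected raster cells
#' carry data are flagged incomplete (and normally dropped downstream).
#'
#' @param rasters named list of rasters ([read_esri_ascii()] layout) in the
#'   grid's projected coordinates.
#' @param grid a `grid_spec`.
#' @param min_coverage minimum fraction of a cell's raster cells that must
#'   be non-missing.
#' @return data.frame: `cell_id` plus one column per raster and a logical
#'   `complete`.
#' @export
aggregate_predictors <- function(rasters, grid, min_coverage = 0.5) {
  stopifnot(length(rasters) > 0, !is.null(names(rasters)))
  out <- grid$cells[, "cell_id", drop = FALSE]
  complete <- rep(TRUE, nrow(out))
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    cc <- raster_cell_centers(r)
    idx <- cell_index(grid, cc$x, cc$y)
    ok <- !is.na(idx)
    means <- tapply(cc$value[ok], idx[ok],
                    function(v) mean(v, na.rm = TRUE))
    counts <- tapply(!is.na(cc$value[ok]), idx[ok], sum)
    totals <- tapply(rep(1, sum(ok)), idx[ok], sum)
    out[[nm]] <- as.numeric(means[out$cell_id])
    cov <- as.numeric(counts[out$cell_id]) / as.numeric(totals[out$cell_id])
    cov[is.na(cov)] <- 0
    complete <- complete & cov >= min_coverage & is.finite(out[[nm]])
  }
  out$complete <- complete
  rownames(out) <- NULL
  out
}

#' Assemble the cell-level modelling table
#'
#' Joins a per-cell loss table with aggregated predictors, keeping analysed
#' cells with complete predictor data; dropped cells are reported via
#' attribute `n_dropped`.
#'
#' @param loss a `cell_loss_table` (from [cell_proportion_lost()]).
#' @param predictors output of [aggregate_predictors()].
#' @return data.frame with `cell_id`, `n_old`, `n_lost`, `n_retained`,
#'   `p_cell` and the predictor columns.
#' @export
cell_predictor_table <- function(loss, predictors) {
  keep <- loss$analysed
  d <- merge(loss[keep, c("cell_id", "n_old", "n_lost", "p_cell")],
             predictors, by = "cell_id")
  before <- nrow(d)
  d <- d[d$complete & stats::complete.cases(d), , drop = FALSE]
  d$complete <- NULL
  d$n_retained <- d$n_old - d$n_lost
  rownames(d) <- NULL
  attr(d, "n_dropped") <- before - nrow(d)
  d
}

#' Fit one binomial GLM of per-cell species loss
#'
#' Logit-link binomial fit of the count pair (lost, retained) per cell —
#' cells thereby weigh in proportion to their older-period richness — via
#' iteratively reweighted least squares to convergence 1e-8. Predictors are
#' z-standardized internally (coefficients are reported on both scales).
#' Goodness of fit is the proportion of deviance explained,
#' `1 - residual deviance / null deviance`. An empirical-logit Gaussian
#' response mode is available as a sensitivity alternative.
#'
#' @param cells a [cell_predictor_table()] data.frame.
#' @param predictors character vector of predictor columns.
#' @param standardize z-score predictors before fitting?
#' @param response `"counts"` (binomial, default) or `"elogit"` (Gaussian on
#'   the empirical logit).
#' @param label optional model label.
#' @return list of class `binomial_glm_fit`: `label`, `predictors`,
#'   `coefficients` (standardized scale), `coefficients_raw`, `se`,
#'   `logLik`, `k`, `AIC`, `AICc`, `dev_explained`, `converged`,
#'   `separation`, and the underlying `fit`.
#' @export
binomial_glm_fit <- function(cells, predictors, standardize = TRUE,
                             response = c("counts", "elogit"),
                             label = paste(predictors, collapse = " + ")) {
  response <- match.arg(response)
  miss <- setdiff(predictors, names(cells))
  if (length(miss) > 0) {
    stop("predictor column(s) absent: ", paste(miss, collapse = ", "))
  }
  n <- nrow(cells)
  if (n < length(predictors) + 2) stop("too few cells to fit this model")
  if (length(predictors) > 0) {
    X <- cells[, predictors, drop = FALSE]
    ctr <- vapply(X, mean, 0)
    scl <- vapply(X, stats::sd, 0)
    if (standardize) {
      if (any(scl == 0)) scl[scl == 0] <- 1
      X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    }
    d <- cbind(X, cells[, c("n_lost", "n_retained", "n_old", "p_cell")])
    rhs <- paste(predictors, collapse = " + ")
  } else {
    d <- cells[, c("n_lost", "n_retained", "n_old", "p_cell")]
    rhs <- "1"
  }
  if (response == "counts") {
    f <- stats::as.formula(paste("cbind(n_lost, n_retained) ~", rhs))
    fit <- stats::glm(f, family = stats::binomial(),
                      data = d,
                      control = list(epsilon = 1e-8, maxit = 100))
    if (!fit$converged) stop("IRLS failed to converge for model ", label)
    mu <- stats::fitted(fit)
    separation <- any(mu < 1e-8 | mu > 1 - 1e-8) &&
      any(abs(stats::coef(fit)[-1]) > 15)
    dev_expl <- 1 - fit$deviance / fit$null.deviance
    k <- length(stats::coef(fit))
    ll <- as.numeric(stats::logLik(fit))
  } else {
    d$elogit <- empirical_logit(d$p_cell, d$n_old)
    f <- stats::as.formula(paste("elogit ~", rhs))
    fit <- stats::lm(f, data = d)
    separation <- FALSE
    dev_expl <- summary(fit)$r.squared
    k <- length(stats::coef(fit)) + 1L  # + residual variance
    ll <- as.numeric(stats::logLik(fit))
  }
  cf <- stats::coef(fit)
  cf_raw <- cf
  if (standardize && length(predictors) > 0) {
    cf_raw[predictors] <- cf[predictors] / scl[predictors]
    cf_raw[1] <- cf[1] - sum(cf[predictors] * ctr[predictors] / scl[predictors])
  }
  structure(
    list(label = label, predictors = predictors,
         coefficients = cf, coefficients_raw = cf_raw,
         se = summary(fit)$coefficients[, "Std. Error"],
         logLik = ll, k = k,
         AIC = -2 * ll + 2 * k,
         AICc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
         dev_explained = dev_expl,
         converged = TRUE, separation = separation,
         n = n, fit = fit),
    class = "binomial_glm_fit"
  )
}

#' @export
print.binomial_glm_fit <- function(x, ...) {
  cat(sprintf("binomial GLM [%s]: n = %d, LL = %.3f, k = %d, AICc = %.3f\n",
              x$label, x$n, x$logLik, x$k, x$AICc))
  cat(sprintf("  deviance explained = %.3f%s\n", x$dev_explained,
              if (x$separation) " (separation suspected)" else ""))
  invisible(x)
}

#' Fit and rank the spatial model suite
#'
#' Fits every model of the suite on the same analysed cells and ranks them;
#' a model that fails to fit is recorded and the suite continues.
#'
#' @param cells a [cell_predictor_table()] data.frame.
#' @param suite named list of predictor sets (default
#'   [spatial_model_suite()]).
#' @param ic `"AICc"` (default) or `"AIC"`.
#' @param ... passed to [binomial_glm_fit()].
#' @return list with `ranking` (a [rank_models()] table; `model` holds the
#'   suite letter and `formula` the predictor list), `fits`, `failures`.
#' @export
run_model_suite <- function(cells, suite = spatial_model_suite(),
                            ic = "AICc", ...) {
  fits <- list()
  failures <- list()
  for (nm in names(suite)) {
    res <- tryCatch(
      binomial_glm_fit(cells, suite[[nm]], label = nm, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) failures[[nm]] <- conditionMessage(res)
    else fits[[nm]] <- res
  }
  if (length(fits) == 0) stop("every model in the suite failed")
  ranking <- rank_models(fits, ic = ic)
  ranking$formula <- vapply(ranking$model,
                            function(m) paste(suite[[m]], collapse = " + "),
                            "")
  list(ranking = ranking, fits = fits, failures = failures)
}
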