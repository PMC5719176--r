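# Synthetic study systems with recorded ground truth. The generator
# emulates the structure the analysis assumes: nested true ranges across the
# three time slices, presence-only sampling of the two older periods, body
# mass and trophic effects on contraction with phylogenetically correlated
# residuals, and per-cell loss probabilities driven by known logistic
# coefficients on six correlated environmental surfaces. Everything is
# governed by a single seed; each component draws from a fixed offset of it
# so stages stay independently reproducible.

#' Simulation configuration
#'
#' Defaults describe a fauna of 34 species on an abstract square country of
#' 3000 x 3000 km (tests should not encode real geography): Holocene range
#' sizes 0.3-2.5 million km^2, 30 Holocene and 40 historical localities per
#' species (within the 10-111 and 5-249 spans of real regional archives),
#' pre-1900 contraction increasing with log10 body mass and decreasing with
#' trophic level (herbivores hit harder early), a weaker, trophic-led
#' post-1900 signal, Brownian residuals with full phylogenetic signal, and
#' per-cell loss log-odds with the canonical signs (more loss at low
#' elevation, high human footprint, low rainfall, high temperature, high
#' AET, low PET).
#'
#' @param seed integer master seed.
#' @param n_species number of species.
#' @param border_size_km side of the square study region.
#' @param raster_res_km resolution of the predictor surfaces.
#' @param field_range_km correlation range of the random fields.
#' @param temp_rain_cor,aet_pet_cor imposed cross-field correlations.
#' @param field_sd_scale multiplier on every surface's spatial SD (0 gives
#'   constant rasters).
#' @param n_sites_holocene,n_sites_historical localities per species and
#'   period (scalar or per-species vector).
#' @param area_range_km2 range of true Holocene range areas (uniform draw).
#' @param beta0_pre,beta_mass,beta_trophic logit-scale intercept and trait
#'   effects on pre-1900 contraction (mass in log10 kg centred at 1.2;
#'   trophic centred at 2).
#' @param beta0_post,beta_mass_post,beta_trophic_post same for the post-1900
#'   conditional contraction.
#' @param sigma_phylo SD of the phylogenetic (Brownian) residual on the
#'   logit scale.
#' @param lambda_true Pagel's lambda of the residual correlation.
#' @param glm_intercept,glm_coefs logit-scale coefficients (on z-scored
#'   predictors) of the per-cell loss probability.
#' @param n_old_mean mean older-period richness per simulated cell.
#' @param sampling_bias elevation bias of locality sampling (0 = uniform;
#'   positive values make low-elevation localities more likely, echoing
#'   accessibility bias in real archives).
#' @param proj projection used when emitting lon/lat files.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_species = 34,
                       border_size_km = 3000,
                       raster_res_km = 30,
                       field_range_km = 250,
                       temp_rain_cor = 0.7,
                       aet_pet_cor = 0.8,
                       field_sd_scale = 1,
                       n_sites_holocene = 30,
                       n_sites_historical = 40,
                       area_range_km2 = c(3e5, 2.5e6),
                       beta0_pre = -2.5, beta_mass = 0.9,
                       beta_trophic = -0.6,
                       beta0_post = -2.8, beta_mass_post = 0.1,
                       beta_trophic_post = 0.5,
                       sigma_phylo = 0.8, lambda_true = 1,
                       glm_intercept = -1,
                       glm_coefs = c(Elev = -0.8, HFI = 0.7, Rain = -0.4,
                                     Temp = 0.3, AET = 0.3, PET = -0.4),
                       n_old_mean = 8,
                       sampling_bias = 0,
                       proj = eoo_projection(lon_0 = 0)) {
  cfg <- as.list(environment())
  stopifnot(n_species >= 1, border_size_km > 0, raster_res_km > 0,
            lambda_true >= 0, lambda_true <= 1,
            all(names(glm_coefs) %in% SPATIAL_PREDICTORS))
  class(cfg) <- "sim_config"
  cfg
}

# smooth standardized Gaussian random field on an nr x nc grid
gaussian_field <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells > 0) {
    k <- function(n) {
      K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-") / range_cells)
      K / rowSums(K)
    }
    z <- k(nr) %*% z %*% t(k(nc))
  }
  z
}

#' Simulate the landscape: border and six predictor surfaces
#'
#' Builds the square study-region border and six smooth correlated Gaussian
#' random-field rasters. The latent fields are orthonormalized before
#' mixing, so the configured Temp-Rain and AET-PET correlations are imposed
#' exactly at the cell level; the Human Footprint surface is negatively tied
#' to elevation (people concentrate in lowlands).
#'
#' @param config a [sim_config()].
#' @return list with `border` (projected region), `rasters` (named list in
#'   [read_esri_ascii()] layout) and `fields` (the standardized fields).
#' @export
simulate_landscape <- function(config) {
  set.seed(config$seed + 101L)
  L <- config$border_size_km
  res <- config$raster_res_km
  nr <- nc <- as.integer(round(L / res))
  border <- list(rect_ring(0, 0, L, L))

  range_cells <- config$field_range_km / res
  lat <- sapply(1:6, function(i) as.vector(gaussian_field(nr, nc,
                                                          range_cells)))
  lat <- scale(lat, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(lat))
  Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")  # orthogonal, unit SD

  mix <- function(q1, q2, rho) rho * q1 + sqrt(1 - rho^2) * q2
  f <- list(
    Temp = Q[, 1],
    Rain = mix(Q[, 1], Q[, 2], config$temp_rain_cor),
    AET  = Q[, 3],
    PET  = mix(Q[, 3], Q[, 4], config$aet_pet_cor),
    Elev = Q[, 5],
    HFI  = mix(Q[, 5], Q[, 6], -0.5)
  )
  units <- list(Elev = c(1500, 900), HFI = c(25, 12), Rain = c(800, 350),
                Temp = c(10, 7), AET = c(600, 250), PET = c(900, 300))
  rasters <- lapply(SPATIAL_PREDICTORS, function(nm) {
    u <- units[[nm]]
    list(ncols = nc, nrows = nr, xllcorner = 0, yllcorner = 0,
         cellsize = res, nodata = -9999,
         z = matrix(u[1] + u[2] * config$field_sd_scale * f[[nm]], nr, nc))
  })
  names(rasters) <- SPATIAL_PREDICTORS
  fields <- lapply(f, matrix, nrow = nr, ncol = nc)
  list(border = border, rasters = rasters, fields = fields)
}

#' Simulate species range histories, traits and phylogeny
#'
#' Grows a pure-birth tree, draws body masses (log10-uniform over
#' 0.25-3300 kg) and trophic levels, and converts trait effects plus a
#' lambda-scaled Brownian deviate into per-era contraction fractions via the
#' inverse logit. True ranges are concentric ellipses eroded geometrically,
#' so the nesting A_mod <= A_hist <= A_hol is exact and true areas are the
#' polygon areas themselves.
#'
#' @param config a [sim_config()].
#' @param landscape output of [simulate_landscape()].
#' @return list with `tree`, `traits` (species, body_mass_kg, trophic),
#'   `ranges` (per species: holocene/historical/modern regions, projected),
#'   and `truth` (per-species areas, loss fractions and residuals, plus the
#'   generating coefficients as attributes).
#' @export
simulate_species_histories <- function(config, landscape) {
  set.seed(config$seed + 202L)
  n <- config$n_species
  ids <- sprintf("sp%02d", seq_len(n))
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- ids

  log_mass <- stats::runif(n, log10(0.25), log10(3300))
  trophic <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.26, 0.24))

  C <- ape::vcv.phylo(tree)
  C <- C / max(diag(C))
  Cl <- C * config$lambda_true
  diag(Cl) <- diag(C)
  draw_resid <- function() {
    as.vector(t(chol(Cl)) %*% stats::rnorm(n)) * config$sigma_phylo
  }
  e_pre <- draw_resid()
  e_post <- draw_resid()

  eta_pre <- config$beta0_pre + config$beta_mass * (log_mass - 1.2) +
    config$beta_trophic * (trophic - 2) + e_pre
  eta_post <- config$beta0_post + config$beta_mass_post * (log_mass - 1.2) +
    config$beta_trophic_post * (trophic - 2) + e_post
  loss_pre <- stats::plogis(eta_pre)
  loss_post_cond <- stats::plogis(eta_post)  # fraction of what remained

  L <- config$border_size_km
  area_hol <- stats::runif(n, config$area_range_km2[1],
                           config$area_range_km2[2])
  aspect <- stats::runif(n, 0.55, 0.95)
  theta <- stats::runif(n, 0, pi)
  a <- sqrt(area_hol / (pi * aspect))
  b <- a * aspect
  margin <- 5
  if (any(2 * (a + margin) > L)) {
    stop("area_range_km2 is too large for border_size_km: the largest ",
         "Holocene range (semi-axis ", round(max(a)), " km) does not fit ",
         "inside the study region")
  }
  cx <- stats::runif(n, a + margin, L - a - margin)
  cy <- stats::runif(n, a + margin, L - a - margin)

  ranges <- vector("list", n)
  names(ranges) <- ids
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    hol <- ellipse_ring(cx[i], cy[i], a[i], b[i], theta[i])
    s_hist <- sqrt(1 - loss_pre[i])
    s_mod <- sqrt((1 - loss_pre[i]) * (1 - loss_post_cond[i]))
    hist <- ellipse_ring(cx[i], cy[i], a[i] * s_hist, b[i] * s_hist, theta[i])
    mod <- if (s_mod > 1e-6) {
      ellipse_ring(cx[i], cy[i], a[i] * s_mod, b[i] * s_mod, theta[i])
    } else NULL
    ranges[[i]] <- list(holocene = list(hol), historical = list(hist),
                        modern = as_region(mod))
    A_hol <- region_area(list(hol))
    A_hist <- region_area(list(hist))
    A_mod <- region_area(as_region(mod))
    rows[[i]] <- data.frame(
      species = ids[i], body_mass_kg = 10^log_mass[i], trophic = trophic[i],
      A_hol = A_hol, A_hist = A_hist, A_mod = A_mod,
      y_pre1900 = (A_hol - A_hist) / A_hol,
      y_post1900 = (A_hist - A_mod) / A_hol,
      resid_pre = e_pre[i], resid_post = e_post[i],
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)
  attr(truth, "coefficients") <- list(
    pre = c(intercept = config$beta0_pre, mass = config$beta_mass,
            trophic = config$beta_trophic),
    post = c(intercept = config$beta0_post, mass = config$beta_mass_post,
             trophic = config$beta_trophic_post),
    sigma_phylo = config$sigma_phylo, lambda = config$lambda_true
  )
  traits <- truth[, c("species", "body_mass_kg", "trophic")]
  list(tree = tree, traits = traits, ranges = ranges, truth = truth)
}

# uniform draw inside an ellipse-shaped polygon via the ellipse
# parameterization, rejection-tested against the polygon itself (and
# optionally thinned by an elevation weight)
sample_points_in_region <- function(region, n, elev = NULL, bias = 0) {
  region <- as_region(region)
  if (length(region) == 0 || n == 0) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  bb <- region_bbox(region)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(4 * (n - nrow(out)), 32)
    x <- stats::runif(m, bb["xmin"], bb["xmax"])
    y <- stats::runif(m, bb["ymin"], bb["ymax"])
    ok <- point_in_region(x, y, region)
    if (bias != 0 && !is.null(elev)) {
      z <- (elev(x, y) - 1500) / 900
      w <- exp(-bias * z)
      ok <- ok & (stats::runif(m) < w / exp(3 * abs(bias)))
    }
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Sample presence-only locality records from the true ranges
#'
#' Draws localities uniformly (or with a configurable low-elevation bias)
#' from each species' true range of the corresponding period: Holocene
#' localities from the true Holocene range, historical localities from the
#' true historical range. Every point therefore lies inside the true range
#' polygon by construction. Species whose configured intensity is 0 receive
#' no records and fall to the minimum-site filter downstream.
#'
#' @param histories output of [simulate_species_histories()].
#' @param config a [sim_config()].
#' @param landscape optional [simulate_landscape()] output (needed only for
#'   elevation-biased sampling).
#' @return data.frame of locality records in the input CSV schema
#'   (`species,lon,lat,period,site_id,source`) plus projected `x`, `y`.
#' @export
sample_locality_records <- function(histories, config, landscape = NULL) {
  set.seed(config$seed + 303L)
  ids <- names(histories$ranges)
  n_hol <- rep(config$n_sites_holocene, length.out = length(ids))
  n_hist <- rep(config$n_sites_historical, length.out = length(ids))
  elev_fun <- NULL
  if (config$sampling_bias != 0 && !is.null(landscape)) {
    r <- landscape$rasters$Elev
    elev_fun <- function(x, y) {
      i <- pmin(pmax(r$nrows - floor((y - r$yllcorner) / r$cellsize), 1),
                r$nrows)
      j <- pmin(pmax(floor((x - r$xllcorner) / r$cellsize) + 1, 1), r$ncols)
      r$z[cbind(i, j)]
    }
  }
  out <- list()
  for (i in seq_along(ids)) {
    for (per in c("holocene", "historical")) {
      k <- if (per == "holocene") n_hol[i] else n_hist[i]
      if (k == 0) next
      xy <- sample_points_in_region(histories$ranges[[i]][[per]], k,
                                    elev = elev_fun,
                                    bias = config$sampling_bias)
      ll <- unproject_equal_area(xy[, 1], xy[, 2], config$proj)
      out[[length(out) + 1]] <- data.frame(
        species = ids[i], lon = ll[, 1], lat = ll[, 2], period = per,
        site_id = sprintf("%s_%s_%03d", ids[i], substr(per, 1, 4),
                          seq_len(k)),
        source = "simulated", x = xy[, 1], y = xy[, 2],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate per-cell species loss from known logistic coefficients
#'
#' Independent cell-level generator for auditing the spatial models:
#' predictors are aggregated to the grid and z-scored, each cell receives an
#' older-period richness and a loss probability
#' `plogis(intercept + Z %*% coefs)`, and losses are binomial draws.
#'
#' @param landscape output of [simulate_landscape()].
#' @param config a [sim_config()].
#' @param grid optional `grid_spec` (default: 100-km grid over the border).
#' @return list with `cells` (ready for [run_model_suite()]) and `truth`
#'   (the generating coefficients on the z-scale and per-cell
#'   probabilities).
#' @export
simulate_cell_loss <- function(landscape, config, grid = NULL) {
  set.seed(config$seed + 404L)
  if (is.null(grid)) grid <- make_grid(landscape$border, 100)
  agg <- aggregate_predictors(landscape$rasters, grid)
  agg <- agg[agg$complete, , drop = FALSE]
  Z <- scale(as.matrix(agg[, SPATIAL_PREDICTORS]))
  eta <- config$glm_intercept +
    as.vector(Z[, names(config$glm_coefs), drop = FALSE] %*% config$glm_coefs)
  p <- stats::plogis(eta)
  n_old <- 1L + stats::rpois(nrow(agg), config$n_old_mean - 1)
  n_lost <- stats::rbinom(nrow(agg), n_old, p)
  cells <- data.frame(
    cell_id = agg$cell_id,
    n_old = n_old, n_lost = n_lost, n_retained = n_old - n_lost,
    p_cell = n_lost / n_old,
    agg[, SPATIAL_PREDICTORS],
    stringsAsFactors = FALSE
  )
  list(cells = cells,
       truth = list(intercept = config$glm_intercept,
                    coefficients = config$glm_coefs, p = p))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the whole generator and writes every input the pipeline reads:
#' locality CSV, border and modern-range GeoJSON, trait CSV, Newick tree,
#' six ESRI ASCII predictor rasters, and `truth.json` with the ground
#' truth. Returns the in-memory objects alongside the paths.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths`, `landscape`, `histories`, `records`,
#'   `cell_loss` and `config`, invisibly.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("simdata")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  landscape <- simulate_landscape(config)
  histories <- simulate_species_histories(config, landscape)
  records <- sample_locality_records(histories, config, landscape)
  cell_loss <- simulate_cell_loss(landscape, config)

  p <- list()
  p$locality <- file.path(dir, "localities.csv")
  utils::write.csv(records[, LOCALITY_COLUMNS], p$locality, row.names = FALSE)
  p$border <- file.path(dir, "border.geojson")
  write_geojson_regions(list(border = landscape$border), p$border,
                        proj = config$proj)
  p$modern <- file.path(dir, "modern_ranges.geojson")
  write_geojson_regions(lapply(histories$ranges, `[[`, "modern"), p$modern,
                        proj = config$proj)
  p$traits <- file.path(dir, "traits.csv")
  utils::write.csv(histories$traits, p$traits, row.names = FALSE)
  p$tree <- file.path(dir, "tree.nwk")
  ape::write.tree(histories$tree, p$tree)
  for (nm in names(landscape$rasters)) {
    p[[paste0("raster_", nm)]] <- file.path(dir, paste0(tolower(nm), ".asc"))
    write_esri_ascii(landscape$rasters[[nm]], p[[paste0("raster_", nm)]])
  }
  p$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(species = histories$truth,
         coefficients = attr(histories$truth, "coefficients"),
         cell_glm = cell_loss$truth[c("intercept", "coefficients")],
         seed = config$seed),
    p$truth, auto_unbox = TRUE, digits = 12
  )
  invisible(list(paths = p, landscape = landscape, histories = histories,
                 records = records, cell_loss = cell_loss, config = config))
}
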