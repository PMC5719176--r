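small_cfg <- function(seed = 42, ...) {
  sim_config(seed = seed, n_species = 8, border_size_km = 1500,
             raster_res_km = 50, n_sites_holocene = 12,
             n_sites_historical = 15, area_range_km2 = c(5e4, 3e5), ...)
}

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg()
  l1 <- simulate_landscape(cfg)
  l2 <- simulate_landscape(cfg)
  expect_identical(l1, l2)
  h1 <- simulate_species_histories(cfg, l1)
  h2 <- simulate_species_histories(cfg, l2)
  expect_identical(h1, h2)
  r1 <- sample_locality_records(h1, cfg)
  r2 <- sample_locality_records(h2, cfg)
  expect_identical(r1, r2)
  # a different seed changes the draw
  l3 <- simulate_landscape(small_cfg(seed = 43))
  expect_false(identical(l1$rasters$Elev$z, l3$rasters$Elev$z))
})

test_that("zero-variance field specs give constant rasters", {
  l <- simulate_landscape(small_cfg(field_sd_scale = 0))
  for (r in l$rasters) expect_equal(stats::sd(as.vector(r$z)), 0)
})

test_that("imposed cross-field correlations are hit at the cell level", {
  l <- simulate_landscape(sim_config(seed = 9, border_size_km = 3000,
                                     raster_res_km = 30,
                                     temp_rain_cor = 0.8))
  ct <- cor(as.vector(l$rasters$Temp$z), as.vector(l$rasters$Rain$z))
  expect_lt(abs(ct - 0.8), 0.05)
  ca <- cor(as.vector(l$rasters$AET$z), as.vector(l$rasters$PET$z))
  expect_lt(abs(ca - 0.8), 0.05)
})

test_that("true ranges nest and truth is internally consistent", {
  cfg <- small_cfg()
  h <- simulate_species_histories(cfg, simulate_landscape(cfg))
  tr <- h$truth
  expect_true(all(tr$A_hol >= tr$A_hist & tr$A_hist >= tr$A_mod))
  expect_true(all(tr$y_pre1900 >= 0 & tr$y_pre1900 <= 1))
  expect_true(all(tr$y_pre1900 + tr$y_post1900 <= 1 + 1e-12))
  expect_equal(tr$A_hist / tr$A_hol, 1 - tr$y_pre1900, tolerance = 1e-9)
  expect_equal(ape::Ntip(h$tree), cfg$n_species)
})

test_that("a positive mass effect yields mass-biased simulated losses", {
  cors <- vapply(1:30, function(i) {
    cfg <- sim_config(seed = 1000 + i, n_species = 34,
                      beta_mass = 0.9, sigma_phylo = 0.8)
    h <- simulate_species_histories(cfg, simulate_landscape(small_cfg()))
    loss_total <- 1 - h$truth$A_mod / h$truth$A_hol
    cor(log10(h$truth$body_mass_kg), loss_total, method = "spearman")
  }, 0)
  expect_gt(mean(cors), 0.3)
  expect_gt(mean(cors > 0), 0.9)
})

test_that("without phylogenetic signal residuals ignore the tree", {
  cfg <- sim_config(seed = 77, n_species = 80, lambda_true = 0,
                    sigma_phylo = 1)
  h <- simulate_species_histories(cfg, simulate_landscape(small_cfg()))
  C <- ape::vcv.phylo(h$tree)
  C <- C / max(C)
  off <- upper.tri(C)
  prod <- tcrossprod(h$truth$resid_pre)
  expect_lt(abs(cor(C[off], prod[off])), 0.1)
})

test_that("sampled localities lie inside the matching true range", {
  cfg <- small_cfg()
  h <- simulate_species_histories(cfg, simulate_landscape(cfg))
  rec <- sample_locality_records(h, cfg)
  for (s in unique(rec$species)) {
    for (per in c("holocene", "historical")) {
      r <- rec[rec$species == s & rec$period == per, ]
      expect_true(all(point_in_region(r$x, r$y, h$ranges[[s]][[per]])))
    }
  }
  # emitted lon/lat reprojects to the same plane coordinates
  xy <- project_equal_area(rec$lon, rec$lat, cfg$proj)
  expect_equal(unname(xy[, 1]), rec$x, tolerance = 1e-6)
})

test_that("a zero sampling intensity drops the species at the site filter", {
  cfg <- small_cfg()
  cfg$n_sites_holocene <- c(0, rep(12, cfg$n_species - 1))
  h <- simulate_species_histories(cfg, simulate_landscape(cfg))
  rec <- sample_locality_records(h, cfg)
  cat <- filter_species_by_min_sites(rec, min_sites = 10)
  expect_false("sp01" %in% cat$species_id[cat$included])
  expect_equal(sum(cat$included), cfg$n_species - 1)
})

test_that("reconstruction underestimates shrink as sampling grows", {
  # a strongly contracting fauna, so the Holocene-historical annulus is
  # wide and sampling effort has room to matter
  cfg <- small_cfg(beta0_pre = 0.5, sigma_phylo = 0.3)
  h <- simulate_species_histories(cfg, simulate_landscape(cfg))
  sp <- names(h$ranges)[which.max(h$truth$A_hol - h$truth$A_hist)]
  true_reg <- h$ranges[[sp]]$holocene
  true_area <- region_area(true_reg)
  border <- simulate_landscape(cfg)$border
  baseline <- h$ranges[[sp]]$historical
  mean_rec_area <- function(k) {
    mean(vapply(1:15, function(rep) {
      set.seed(5000 + 37 * k + rep)
      pts <- holorange:::sample_points_in_region(true_reg, k)
      region_area(build_period_range(baseline, pts, border,
                                     point_ids = sprintf("p%03d", 1:k)))
    }, 0))
  }
  a5 <- mean_rec_area(5); a20 <- mean_rec_area(20); a50 <- mean_rec_area(50)
  expect_lte(a50, true_area * (1 + 1e-6))
  expect_lt(a5, a20)
  expect_lt(a20, a50)
})

test_that("cell-loss simulation matches its recorded truth", {
  cfg <- small_cfg()
  l <- simulate_landscape(cfg)
  cl <- simulate_cell_loss(l, cfg)
  expect_true(all(cl$cells$n_lost <= cl$cells$n_old))
  expect_true(all(cl$truth$p >= 0 & cl$truth$p <= 1))
  expect_equal(nrow(cl$cells), length(cl$truth$p))
  # losses track the generating probability
  expect_gt(cor(cl$cells$p_cell, cl$truth$p), 0.5)
})

test_that("simulate_dataset writes every pipeline input plus ground truth", {
  dir <- tempfile("simset")
  out <- simulate_dataset(small_cfg(), dir)
  expect_true(all(file.exists(unlist(out$paths))))
  rec <- read_locality_table(out$paths$locality, proj = out$config$proj)
  expect_equal(rec$n_rejected, 0)
  tr <- jsonlite::read_json(out$paths$truth, simplifyVector = TRUE)
  expect_equal(nrow(tr$species), out$config$n_species)
  tree <- ape::read.tree(out$paths$tree)
  expect_setequal(tree$tip.label, tr$species$species)
})
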