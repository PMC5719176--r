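# Shared fixtures and independent oracles.

unit_square <- function() list(rect_ring(0, 0, 1, 1))
big_border <- function(size = 4) list(rect_ring(0, 0, size, size))

# shoelace on a raw ring, independent of the package's signed-area helper
oracle_ring_area <- function(x, y) {
  abs(0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

# "inside any solid ring" test for raw (possibly overlapping) collections
pip_any <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  for (r in rings) {
    inside <- inside | sp::point.in.polygon(x, y, r$x, r$y) > 0
  }
  inside
}

# Monte-Carlo rejection-sampling union-area oracle over raw rings
mc_union_area <- function(rings, n = 1e6, seed = 42) {
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  bb <- c(min(xs), min(ys), max(xs), max(ys))
  set.seed(seed)
  px <- runif(n, bb[1], bb[3])
  py <- runif(n, bb[2], bb[4])
  mean(pip_any(px, py, rings)) * (bb[3] - bb[1]) * (bb[4] - bb[2])
}

# small locality data.frame in the input schema
make_records <- function(species, lon, lat, period, site_id,
                         source = "test") {
  data.frame(species = species, lon = lon, lat = lat, period = period,
             site_id = site_id, source = source, stringsAsFactors = FALSE)
}

write_locality_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# balanced 3-taxon tree with the hand-computable covariance
#   C = [[2,1,0],[1,2,0],[0,0,2]]
three_taxon_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n = 5, depth = 1) {
  labs <- paste0("t", seq_len(n))
  txt <- paste0("(", paste0(labs, ":", depth, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# independent dense-matrix GLS oracle: beta = (X' C^-1 X)^-1 X' C^-1 y
oracle_gls_beta <- function(y, X, C) {
  Ci <- solve(C)
  solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y
}

# simulated cell table with a single strong predictor for suite tests
make_cells <- function(n, beta, predictor = "Elev", n_old = 10, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  p <- plogis(-0.5 + beta * z)
  n_lost <- rbinom(n, n_old, p)
  d <- data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                  n_old = n_old, n_lost = n_lost,
                  n_retained = n_old - n_lost, p_cell = n_lost / n_old)
  for (nm in holorange::spatial_model_suite()$a) {
    d[[nm]] <- if (nm == predictor) z else rnorm(n)
  }
  d
}
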