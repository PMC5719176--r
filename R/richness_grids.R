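# Gridded richness and per-cell species loss. A 100 x 100 km grid is laid
# over the projected border; per-cell richness is counted from the period
# range layers, and per-cell proportion of species lost is computed only for
# cells that contain at least one locality record of the older period (the
# record-based sampling filter).

#' Lay an equal-area grid over the study region
#'
#' Cells tile the border's projected bounding box from its lower-left
#' corner; partial edge cells are retained, and cells that do not intersect
#' the border are dropped.
#'
#' @param border border region in projected km.
#' @param cell_size cell edge length in km (default 100).
#' @return object of class `grid_spec`: list with `cell_size`, `origin`,
#'   `n_rows`, `n_cols` and `cells`, a data.frame of retained cells
#'   (`cell_id`, `row`, `col`, `xmin`, `ymin`, `xmax`, `ymax`).
#' @export
make_grid <- function(border, cell_size = 100) {
  if (cell_size <= 0) stop("cell_size must be positive")
  border <- as_region(border)
  bb <- region_bbox(border)
  n_cols <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / cell_size - 1e-9))
  n_rows <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / cell_size - 1e-9))
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  grid$xmin <- bb["xmin"] + (grid$col - 1) * cell_size
  grid$ymin <- bb["ymin"] + (grid$row - 1) * cell_size
  grid$xmax <- grid$xmin + cell_size
  grid$ymax <- grid$ymin + cell_size
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    cell <- rect_ring(grid$xmin[i], grid$ymin[i], grid$xmax[i], grid$ymax[i])
    region_area(region_intersect(list(cell), border)) > 0
  }, TRUE)
  cells <- grid[keep, , drop = FALSE]
  cells$cell_id <- sprintf("r%03d_c%03d", cells$row, cells$col)
  rownames(cells) <- NULL
  structure(
    list(cell_size = cell_size,
         origin = c(x = unname(bb["xmin"]), y = unname(bb["ymin"])),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cells = cells[, c("cell_id", "row", "col",
                           "xmin", "ymin", "xmax", "ymax")]),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("grid_spec:", x$n_rows, "x", x$n_cols, "cells of",
      x$cell_size, "km;", nrow(x$cells), "intersect the border\n")
  invisible(x)
}

#' Assign points to grid cells
#'
#' Points on an interior cell edge belong to the cell above/right of the
#' edge; points on the grid's outer maximum edges are clamped into the last
#' cell so the whole closed bounding box is covered.
#'
#' @param grid a `grid_spec`.
#' @param x,y projected point coordinates (km).
#' @return character vector of cell ids (`NA` for points outside the grid's
#'   bounding box or in dropped cells).
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin["x"]) / grid$cell_size) + 1
  row <- floor((y - grid$origin["y"]) / grid$cell_size) + 1
  col[col == grid$n_cols + 1 &
      x <= grid$origin["x"] + grid$n_cols * grid$cell_size + 1e-9] <- grid$n_cols
  row[row == grid$n_rows + 1 &
      y <= grid$origin["y"] + grid$n_rows * grid$cell_size + 1e-9] <- grid$n_rows
  id <- sprintf("r%03d_c%03d", row, col)
  id[col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows] <- NA
  id[!id %in% grid$cells$cell_id] <- NA
  id
}

#' Species-by-cell presence matrix for one period
#'
#' A species is present in a cell iff its period range intersects the cell
#' with positive area (any positive overlap, not a centroid rule — the
#' least-surprising reading, and monotone under the nested period layers).
#'
#' @param ranges named list of species regions (projected km) for one
#'   period.
#' @param grid a `grid_spec` in the same projection.
#' @return object of class `presence_matrix`: list with `m` (binary
#'   species x cell matrix, dimnames set) and `richness` (per-cell column
#'   sums).
#' @export
presence_matrix <- function(ranges, grid) {
  if (is.null(names(ranges)) || any(names(ranges) == "")) {
    stop("ranges must be a named list (one region per species)")
  }
  cells <- grid$cells
  m <- matrix(0L, nrow = length(ranges), ncol = nrow(cells),
              dimnames = list(names(ranges), cells$cell_id))
  for (s in names(ranges)) {
    reg <- as_region(ranges[[s]])
    if (length(reg) == 0) next
    bb <- region_bbox(reg)
    cand <- which(cells$xmin < bb["xmax"] & cells$xmax > bb["xmin"] &
                  cells$ymin < bb["ymax"] & cells$ymax > bb["ymin"])
    for (i in cand) {
      cell <- rect_ring(cells$xmin[i], cells$ymin[i],
                        cells$xmax[i], cells$ymax[i])
      if (region_area(region_intersect(reg, list(cell))) > 0) {
        m[s, i] <- 1L
      }
    }
  }
  structure(list(m = m, richness = colSums(m)), class = "presence_matrix")
}

#' Per-cell proportion of species lost between two periods
#'
#' For each grid cell, the proportion of the older period's species that are
#' absent from the newer period. To control for spatial unevenness of the
#' archival record, a cell is analysed only if it contains at least one
#' locality record of the older period (and has at least one species to
#' lose); other cells are flagged, not silently dropped.
#'
#' @param old,new `presence_matrix` objects for the older and newer period,
#'   sharing species set and grid.
#' @param records locality records of the *older* period: data.frame with
#'   projected `x`, `y`.
#' @param grid the shared `grid_spec`.
#' @return data.frame (class `cell_loss_table`): `cell_id`, `row`, `col`,
#'   `x_min`, `y_min`, `n_old`, `n_lost`, `p_cell`, `analysed`.
#' @export
cell_proportion_lost <- function(old, new, records, grid) {
  if (!identical(rownames(old$m), rownames(new$m))) {
    stop("presence matrices cover different species sets")
  }
  if (!identical(colnames(old$m), colnames(new$m))) {
    stop("presence matrices are on different grids")
  }
  rec <- as_locality_records(records)
  rec_cells <- unique(stats::na.omit(cell_index(grid, rec$x, rec$y)))
  n_old <- colSums(old$m)
  n_lost <- colSums(old$m == 1L & new$m == 0L)
  analysed <- colnames(old$m) %in% rec_cells & n_old > 0
  p_cell <- ifelse(n_old > 0, n_lost / n_old, NA_real_)
  p_cell[!analysed] <- NA_real_
  out <- data.frame(
    cell_id = grid$cells$cell_id,
    row = grid$cells$row,
    col = grid$cells$col,
    x_min = grid$cells$xmin,
    y_min = grid$cells$ymin,
    n_old = unname(n_old),
    n_lost = unname(n_lost),
    p_cell = unname(p_cell),
    analysed = unname(analysed),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_loss_table", "data.frame")
  out
}

#' Empirical logit
#'
#' `log((p + a) / (1 - p + a))` with adjustment `a = adjust / n`, keeping
#' proportions of 0 and 1 finite. Provided as the alternative response mode
#' for the spatial models (the default models the count pair directly with
#' a binomial GLM).
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param n denominator count(s) (>= 1).
#' @param adjust numerator of the adjustment (default 0.5, i.e. `a = 0.5/n`).
#' @return numeric vector.
#' @export
empirical_logit <- function(p, n, adjust = 0.5) {
  if (any(n < 1)) stop("empirical_logit requires n >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  a <- adjust / n
  log((p + a) / (1 - p + a))
}
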