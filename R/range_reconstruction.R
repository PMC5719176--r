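# Cumulative extent-of-occurrence reconstruction. Older-period ranges are
# built onto the next-younger period's completed range: each locality point
# falling outside the baseline is connected to its two nearest admissible
# features (other outside points, the nearest baseline polygon part, or the
# country border as fallback), the connection is realized as an attachment
# polygon, and everything is unioned, dissolved and clipped to the border.

#' Find the two nearest attachment features for a locality point
#'
#' Admissible features are (i) the other locality points of the layer under
#' construction that fall outside the baseline, and (ii) the nearest part of
#' the baseline multipolygon (anchored at the nearest point on its
#' boundary). The two nearest such features are chosen; when fewer than two
#' exist, the border fills in, anchored at the foot of the perpendicular
#' from the point to the border polyline (its nearest boundary point). Ties
#' break by distance, then feature kind (point < polygon < border), then
#' feature id.
#'
#' @param point length-2 numeric (projected km).
#' @param other_points matrix (n x 2) of the layer's other outside points
#'   (may have zero rows).
#' @param baseline baseline region (projected); may be empty.
#' @param border border region (projected); must be non-empty.
#' @param point_ids optional character ids for `other_points` (tie-breaks
#'   and logging).
#' @return list with `point` and `anchors`, a list of two entries each
#'   holding `xy`, `kind` ("point", "polygon" or "border"), `dist`, `id`.
#' @export
nearest_two_features <- function(point, other_points, baseline, border,
                                 point_ids = NULL) {
  stopifnot(length(point) == 2)
  border <- as_region(border)
  if (length(border) == 0) stop("border must be non-empty")
  cand <- list()
  if (!is.null(other_points) && nrow(other_points) > 0) {
    if (is.null(point_ids)) {
      point_ids <- sprintf("p%05d", seq_len(nrow(other_points)))
    }
    d <- sqrt((other_points[, 1] - point[1])^2 +
              (other_points[, 2] - point[2])^2)
    for (i in seq_len(nrow(other_points))) {
      cand[[length(cand) + 1]] <- list(xy = other_points[i, ], kind = "point",
                                       dist = d[i], id = point_ids[i])
    }
  }
  baseline <- as_region(baseline)
  if (length(baseline) > 0) {
    np <- nearest_point_on_boundary(point, baseline)
    cand[[length(cand) + 1]] <- list(xy = np$point, kind = "polygon",
                                     dist = np$dist,
                                     id = sprintf("part%d", np$ring))
  }
  if (length(cand) > 0) {
    kind_rank <- c(point = 1, polygon = 2, border = 3)
    ord <- order(vapply(cand, `[[`, 0, "dist"),
                 kind_rank[vapply(cand, `[[`, "", "kind")],
                 vapply(cand, `[[`, "", "id"))
    cand <- cand[ord]
  }
  anchors <- cand[seq_len(min(2, length(cand)))]
  while (length(anchors) < 2) {
    bf <- nearest_point_on_boundary(point, border)
    anchors[[length(anchors) + 1]] <- list(xy = bf$point, kind = "border",
                                           dist = bf$dist, id = "border")
  }
  list(point = point, anchors = anchors)
}

#' Realize a point-to-anchors connection as an attachment polygon
#'
#' Straight-line connections bound no area, so each connection pair is
#' realized as the triangle spanned by the locality point and its two
#' anchors — the smallest-area polygon consistent with connecting the point
#' to both features. Degenerate (collinear) triples fall back to buffering
#' the two connection segments by `epsilon`, giving a thin positive-area
#' corridor; zero-length segments contribute nothing.
#'
#' @param attachment result of [nearest_two_features()].
#' @param epsilon half-width (km) of the fallback corridor for degenerate
#'   triangles.
#' @return a region (possibly empty) in projected km.
#' @export
attachment_polygon <- function(attachment, epsilon = 1e-3) {
  p <- attachment$point
  a1 <- attachment$anchors[[1]]$xy
  a2 <- attachment$anchors[[2]]$xy
  tri <- list(x = c(p[1], a1[1], a2[1]), y = c(p[2], a1[2], a2[2]))
  area <- abs(ring_signed_area(tri))
  scale2 <- max((tri$x - p[1])^2 + (tri$y - p[2])^2, 1e-300)
  if (area > 1e-9 * scale2) {
    return(list(ring(tri$x, tri$y)))
  }
  # collinear (or coincident) vertices: buffer each nonzero segment
  segs <- list(list(p, a1), list(p, a2))
  rects <- list()
  for (s in segs) {
    v <- s[[2]] - s[[1]]
    len <- sqrt(sum(v^2))
    if (len == 0) next
    nrm <- c(-v[2], v[1]) / len * epsilon
    rects[[length(rects) + 1]] <- ring(
      c(s[[1]][1] + nrm[1], s[[2]][1] + nrm[1],
        s[[2]][1] - nrm[1], s[[1]][1] - nrm[1]),
      c(s[[1]][2] + nrm[2], s[[2]][2] + nrm[2],
        s[[2]][2] - nrm[2], s[[1]][2] - nrm[2])
    )
  }
  if (length(rects) == 0) return(list())
  region_union(rects)
}

#' Build one period's range from a baseline and older locality points
#'
#' The baseline is the next-younger period's completed range (the historical
#' range is built on the modern one; the Holocene range on the historical
#' one). Points inside the baseline contribute nothing; every outside point
#' is attached via [nearest_two_features()] / [attachment_polygon()], with
#' all attachments computed against the original baseline so the result is
#' independent of processing order. The output is the dissolved union of
#' baseline and attachments, clipped to the border, and therefore contains
#' the full baseline and every input point.
#'
#' @param baseline baseline region (projected km); may be empty (species
#'   with no current-day range).
#' @param points matrix (n x 2) of the period's locality points, projected.
#' @param border border region (projected).
#' @param epsilon degenerate-attachment buffer half-width (km); default
#'   1e-6 of the border's bounding-box diagonal.
#' @param point_ids optional ids used for deterministic tie-breaks.
#' @return dissolved, border-clipped region.
#' @export
build_period_range <- function(baseline, points, border, epsilon = NULL,
                               point_ids = NULL) {
  border <- as_region(border)
  baseline <- as_region(baseline)
  if (is.null(epsilon)) {
    bb <- region_bbox(border)
    epsilon <- 1e-6 * sqrt((bb["xmax"] - bb["xmin"])^2 +
                           (bb["ymax"] - bb["ymin"])^2)
  }
  if (is.null(points) || nrow(points) == 0) {
    return(region_intersect_or_keep(baseline, border))
  }
  if (is.null(point_ids)) point_ids <- sprintf("p%05d", seq_len(nrow(points)))
  ord <- order(point_ids)
  points <- points[ord, , drop = FALSE]
  point_ids <- point_ids[ord]

  outside <- !point_in_region(points[, 1], points[, 2], baseline)
  pieces <- baseline
  idx_out <- which(outside)
  for (i in idx_out) {
    others <- points[setdiff(idx_out, i), , drop = FALSE]
    other_ids <- point_ids[setdiff(idx_out, i)]
    att <- nearest_two_features(points[i, ], others, baseline, border,
                                point_ids = other_ids)
    poly <- attachment_polygon(att, epsilon = epsilon)
    pieces <- c(pieces, poly)
  }
  region_intersect_or_keep(region_union(pieces), border)
}

# clip to border; an empty first operand stays empty
region_intersect_or_keep <- function(a, border) {
  if (length(as_region(a)) == 0) return(list())
  region_intersect(a, border)
}

#' Reconstruct the full three-period range history for one species
#'
#' Stages the cumulative construction: the historical baseline is the modern
#' range unioned with any range parts flagged as recently extinct (those
#' parts are historical by definition); historical locality points extend it
#' to the historical range; Holocene points then extend the historical range
#' to the Holocene range. Areas are measured in the shared equal-area plane,
#' so the nesting A_hol >= A_hist >= A_mod holds by construction.
#'
#' @param species_id species identifier.
#' @param modern modern range region (projected, border-clipped); may be
#'   empty for regionally extinct species.
#' @param records the species' locality records: data.frame with `x`, `y`
#'   (projected km) and `period` in `{"holocene","historical"}`.
#' @param border border region (projected).
#' @param extinct optional region of extinct modern-range parts, merged into
#'   the historical baseline.
#' @param epsilon see [build_period_range()].
#' @return object of class `range_history`: list with `species_id`,
#'   `geometry` (named list modern/historical/holocene) and `area_km2`
#'   (named numeric).
#' @export
build_range_history <- function(species_id, modern, records, border,
                                extinct = NULL, epsilon = NULL) {
  border <- as_region(border)
  modern <- region_intersect_or_keep(as_region(modern), border)
  hist_base <- region_union(c(as_region(modern), as_region(extinct)))
  pts <- function(period) {
    r <- records[records$period == period, , drop = FALSE]
    list(xy = cbind(r$x, r$y),
         ids = if (!is.null(r$site_id)) as.character(r$site_id) else NULL)
  }
  h <- pts("historical")
  historical <- build_period_range(hist_base, h$xy, border,
                                   epsilon = epsilon, point_ids = h$ids)
  o <- pts("holocene")
  holocene <- build_period_range(historical, o$xy, border,
                                 epsilon = epsilon, point_ids = o$ids)
  geometry <- list(modern = modern, historical = historical,
                   holocene = holocene)
  areas <- vapply(geometry, region_area, 0)
  # containment is structural (each layer unions the previous one), but the
  # clipper quantizes coordinates at ~1e-9 relative, so measured areas can
  # invert by a few thousandths of a km^2; snap those inversions
  for (i in c("historical", "holocene")) {
    prev <- c(historical = "modern", holocene = "historical")[[i]]
    if (areas[[i]] < areas[[prev]]) {
      if (areas[[prev]] - areas[[i]] > 1e-6 * max(areas[[prev]], 1)) {
        stop("period areas are not nested for ", species_id)
      }
      areas[[i]] <- areas[[prev]]
    }
  }
  structure(
    list(species_id = species_id, geometry = geometry, area_km2 = areas),
    class = "range_history"
  )
}

#' @export
print.range_history <- function(x, ...) {
  cat("range_history for", x$species_id, "\n")
  a <- x$area_km2
  cat(sprintf("  holocene   %12.0f km^2\n", a[["holocene"]]))
  cat(sprintf("  historical %12.0f km^2 (%.1f%% remaining)\n",
              a[["historical"]],
              if (a[["holocene"]] > 0) 100 * a[["historical"]] / a[["holocene"]]
              else NA_real_))
  cat(sprintf("  modern     %12.0f km^2 (%.1f%% remaining)\n",
              a[["modern"]],
              if (a[["holocene"]] > 0) 100 * a[["modern"]] / a[["holocene"]]
              else NA_real_))
  invisible(x)
}

#' Area of a projected range in square kilometres
#'
#' Multipart areas are summed; holes (already dissolved into their
#' containers) are not double counted. The geometry must be in the
#' equal-area plane (km), which every region produced by the reconstruction
#' functions is.
#'
#' @param range a region, or a `range_history` (returns its named areas).
#' @return nonnegative area(s) in km^2.
#' @export
range_area_km2 <- function(range) {
  if (inherits(range, "range_history")) return(range$area_km2)
  region_area(range)
}

#' Proportion of range lost between two periods
#'
#' @param area_old,area_new areas (km^2) of the older and newer period;
#'   `area_new <= area_old` is guaranteed by the cumulative construction.
#' @return fraction in `[0, 1]`; `NA` (with a warning) where the older area
#'   is zero, flagging the species for exclusion.
#' @export
proportion_lost <- function(area_old, area_new) {
  out <- rep(NA_real_, length(area_old))
  bad <- !is.finite(area_old) | area_old <= 0
  if (any(bad)) {
    warning("proportion_lost undefined where the older area is 0; ",
            "species flagged NA")
  }
  ok <- !bad
  out[ok] <- (area_old[ok] - area_new[ok]) / area_old[ok]
  # allow for the geometry engine's ~1e-9 relative coordinate quantization
  if (any(out[ok] < -1e-6 | out[ok] > 1 + 1e-6)) {
    stop("areas are not nested: proportion lost outside [0, 1]")
  }
  pmin(pmax(out, 0), 1)
}

#' Per-species area and range-loss table
#'
#' @param histories list of `range_history` objects, or three numeric
#'   vectors of areas via `area_hol`, `area_hist`, `area_mod` plus
#'   `species`.
#' @param species,area_hol,area_hist,area_mod used when `histories` is
#'   missing: species ids and per-period areas (km^2).
#' @return data.frame with columns `species`, `area_hol_km2`,
#'   `area_hist_km2`, `area_mod_km2` and the interval proportions
#'   `p_lost_hol_hist`, `p_lost_hist_mod`, `p_lost_hol_mod` (each interval
#'   on its own older-period base).
#' @export
area_table <- function(histories = NULL, species = NULL, area_hol = NULL,
                       area_hist = NULL, area_mod = NULL) {
  if (!is.null(histories)) {
    species <- vapply(histories, `[[`, "", "species_id")
    a <- t(vapply(histories, `[[`, numeric(3), "area_km2"))
    area_hol <- a[, "holocene"]
    area_hist <- a[, "historical"]
    area_mod <- a[, "modern"]
  }
  data.frame(
    species = species,
    area_hol_km2 = area_hol,
    area_hist_km2 = area_hist,
    area_mod_km2 = area_mod,
    p_lost_hol_hist = proportion_lost(area_hol, area_hist),
    p_lost_hist_mod = proportion_lost(area_hist, area_mod),
    p_lost_hol_mod = proportion_lost(area_hol, area_mod),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Aggregate range-loss accounting across the fauna
#'
#' Pools the per-species areas: total proportion of combined original
#' Holocene range now lost, split into the part lost before AD 1900 (to the
#' historical layer) and after AD 1900 (historical to modern), both on the
#' combined Holocene base so the two parts sum to the total. Also reports
#' the percentage of species that have lost less than half of their
#' Holocene range.
#'
#' @param tab an [area_table()] data.frame.
#' @return list with `pct_lost_total`, `pct_lost_pre1900`,
#'   `pct_lost_post1900`, `pct_species_lost_lt50`, `n_species` (percent
#'   scale).
#' @export
range_loss_summary <- function(tab) {
  hol <- sum(tab$area_hol_km2)
  hist <- sum(tab$area_hist_km2)
  mod <- sum(tab$area_mod_km2)
  frac_lt50 <- mean((tab$area_hol_km2 - tab$area_mod_km2) /
                    tab$area_hol_km2 < 0.5)
  list(
    pct_lost_total = 100 * (hol - mod) / hol,
    pct_lost_pre1900 = 100 * (hol - hist) / hol,
    pct_lost_post1900 = 100 * (hist - mod) / hol,
    pct_species_lost_lt50 = 100 * frac_lt50,
    n_species = nrow(tab)
  )
}

#' Bundled range-area table for China's Holocene mammal fauna
#'
#' Range-area estimates for the 34 wild mammal species recorded from ten or
#' more Holocene sites in mainland China: maximum estimated Holocene range,
#' twentieth-century (historical) range and current-day range in km^2 in a
#' cylindrical equal-area projection, with body mass and the published
#' percent-remaining figures (`pct_hist`, `pct_mod`, relative to the
#' Holocene range) retained for cross-checking.
#'
#' @return data.frame with one row per species.
#' @export
china_mammal_ranges <- function() {
  path <- system.file("extdata", "china_mammal_ranges.csv",
                      package = "holorange", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
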