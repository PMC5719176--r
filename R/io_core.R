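# Readers and validators for the pipeline's inputs: locality CSVs, range
# polygons (GeoJSON), trait tables + Newick trees, and ESRI ASCII rasters.

LOCALITY_COLUMNS <- c("species", "lon", "lat", "period", "site_id", "source")

#' Read and validate a locality-record table
#'
#' Reads a CSV of dated, georeferenced occurrence records (columns
#' `species,lon,lat,period,site_id,source`), validates coordinates and
#' period labels row by row, and optionally rejects records falling outside
#' the study-region border. Row-level problems are collected, not fatal,
#' unless every row fails.
#'
#' @param path CSV file path, or a data.frame already in the schema.
#' @param border optional border region in lon/lat (a region as used by
#'   [region_union()]); points outside it are rejected. Points exactly on
#'   the boundary count as inside.
#' @param proj an [eoo_projection()]; accepted records gain projected `x`,
#'   `y` columns (km).
#' @param allow_periods period labels accepted in a point table; modern
#'   distributions enter as polygons, so the default excludes "modern".
#' @return object of class `locality_table`: list with `records` (accepted
#'   rows, normalized column order plus `x`,`y`), `rejected` (rows with a
#'   `reason` column), `n_accepted`, `n_rejected`.
#' @export
read_locality_table <- function(path, border = NULL, proj = eoo_projection(),
                                allow_periods = c("holocene", "historical")) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("locality file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  missing <- setdiff(LOCALITY_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("locality table schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, LOCALITY_COLUMNS]
  df$species <- normalize_species_id(df$species)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  period <- as_period(df$period, allow = allow_periods)

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(lon) | is.na(lat)] <- "unparseable coordinate"
  bad_range <- !is.na(lon) & !is.na(lat) &
    (lon < -180 | lon > 180 | lat < -90 | lat > 90)
  reason[is.na(reason) & bad_range] <- "coordinate out of range"
  reason[is.na(reason) & is.na(period)] <- "invalid or disallowed period"

  if (!is.null(border) && length(as_region(border)) > 0) {
    ok_so_far <- is.na(reason)
    if (any(ok_so_far)) {
      inside <- point_in_region(lon[ok_so_far], lat[ok_so_far], border)
      idx <- which(ok_so_far)[!inside]
      reason[idx] <- "outside border"
    }
  }

  keep <- is.na(reason)
  if (!any(keep)) stop("all locality rows failed validation")
  rec <- df[keep, , drop = FALSE]
  rec$lon <- lon[keep]
  rec$lat <- lat[keep]
  rec$period <- period[keep]
  if (!is.null(proj)) {
    xy <- project_equal_area(rec$lon, rec$lat, proj)
    rec$x <- xy[, 1]
    rec$y <- xy[, 2]
  }
  rownames(rec) <- NULL
  rej <- df[!keep, , drop = FALSE]
  if (nrow(rej) > 0) rej$reason <- reason[!keep]
  rownames(rej) <- NULL
  structure(
    list(records = rec, rejected = rej,
         n_accepted = nrow(rec), n_rejected = nrow(rej)),
    class = "locality_table"
  )
}

#' @export
print.locality_table <- function(x, ...) {
  cat("locality_table:", x$n_accepted, "accepted,",
      x$n_rejected, "rejected\n")
  if (x$n_rejected > 0) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' Write accepted locality records back to CSV
#'
#' Writes the accepted rows in the canonical column order so that a
#' read/write cycle round-trips the table.
#'
#' @param lt a `locality_table` (or a data.frame in the schema).
#' @param path output CSV path.
#' @export
write_locality_table <- function(lt, path) {
  rec <- if (inherits(lt, "locality_table")) lt$records else lt
  utils::write.csv(rec[, LOCALITY_COLUMNS], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

# records argument may be a locality_table or its records data.frame
as_locality_records <- function(records) {
  if (inherits(records, "locality_table")) records$records else records
}

#' Flag species meeting the minimum Holocene site count
#'
#' A species enters the analysis only if it is recorded from at least
#' `min_sites` *distinct* Holocene sites (site identity = the `site_id`
#' string; repeat records at one site count once). The default threshold of
#' 10 balances map-building robustness against discarding species.
#'
#' @param records locality records (`locality_table` or data.frame).
#' @param min_sites minimum number of distinct Holocene sites (>= 1).
#' @return species catalog data.frame: `species_id`, `display_name`,
#'   `n_holocene_sites`, `included`.
#' @export
filter_species_by_min_sites <- function(records, min_sites = 10) {
  stopifnot(min_sites >= 1)
  rec <- as_locality_records(records)
  if (nrow(rec) == 0) {
    warning("empty record list; returning empty catalog")
    return(data.frame(species_id = character(), display_name = character(),
                      n_holocene_sites = integer(), included = logical(),
                      stringsAsFactors = FALSE))
  }
  species <- sort(unique(rec$species))
  hol <- rec[rec$period == "holocene", c("species", "site_id")]
  counts <- vapply(species, function(s) {
    length(unique(hol$site_id[hol$species == s]))
  }, integer(1))
  data.frame(
    species_id = species,
    display_name = gsub("_", " ", species),
    n_holocene_sites = unname(counts),
    included = unname(counts) >= min_sites,
    stringsAsFactors = FALSE
  )
}

# --- GeoJSON polygons -------------------------------------------------------

# parse a GeoJSON geometry (Polygon / MultiPolygon) into a region in the
# geometry's native coordinates; polygon holes keep their ring identity and
# are resolved by the nonzero/parity conventions downstream
geojson_geometry_to_region <- function(geom) {
  coords_to_ring <- function(rc) {
    m <- do.call(rbind, lapply(rc, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    # GeoJSON rings repeat the first vertex at the end
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    list(x = m[, 1], y = m[, 2])
  }
  if (geom$type == "Polygon") {
    lapply(geom$coordinates, coords_to_ring)
  } else if (geom$type == "MultiPolygon") {
    unlist(lapply(geom$coordinates, function(poly) {
      lapply(poly, coords_to_ring)
    }), recursive = FALSE)
  } else {
    stop("unsupported GeoJSON geometry type: ", geom$type)
  }
}

#' Read polygon layers from a GeoJSON file
#'
#' Reads a FeatureCollection whose features carry a `species` property (or a
#' bare single geometry for e.g. a border) with coordinates in lon/lat WGS84
#' (EPSG:4326). Geometries are repaired by a dissolving self-union.
#'
#' @param path GeoJSON file path.
#' @return named list of regions in lon/lat (one entry per species; a single
#'   unnamed geometry yields one entry named "geometry").
#' @export
read_geojson_regions <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) {
    out <- list()
    for (f in g$features) {
      id <- f$properties$species
      if (is.null(id)) id <- f$properties$name
      if (is.null(id)) id <- sprintf("feature_%d", length(out) + 1)
      reg <- geojson_geometry_to_region(f$geometry)
      id <- normalize_species_id(id)
      out[[id]] <- if (is.null(out[[id]])) reg else c(out[[id]], reg)
    }
    lapply(out, region_union)
  } else if (identical(g$type, "Feature")) {
    setNames(list(region_union(geojson_geometry_to_region(g$geometry))),
             "geometry")
  } else {
    setNames(list(region_union(geojson_geometry_to_region(g))), "geometry")
  }
}

#' Write named regions to GeoJSON
#'
#' @param regions named list of regions in projected km (unprojected on
#'   write) or, with `proj = NULL`, already in lon/lat.
#' @param path output path.
#' @param proj an [eoo_projection()] used to return coordinates to lon/lat;
#'   `NULL` writes coordinates as they are.
#' @export
write_geojson_regions <- function(regions, path, proj = eoo_projection()) {
  features <- lapply(names(regions), function(id) {
    reg <- regions[[id]]
    if (!is.null(proj)) reg <- unproject_region(reg, proj)
    polys <- lapply(as_region(reg), function(r) {
      m <- cbind(r$x, r$y)
      m <- rbind(m, m[1, ])
      list(list(apply(m, 1, function(p) list(p[1], p[2]))))
    })
    # each ring is written as its own single-ring polygon; parity/nonzero
    # conventions make the collection equivalent to the dissolved region
    list(
      type = "Feature",
      properties = list(species = id),
      geometry = list(type = "MultiPolygon",
                      coordinates = do.call(c, polys))
    )
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read modern range polygons, split extinct parts, clip to border
#'
#' Modern (current-day) published ranges sometimes mark subregions where the
#' species is now extinct; those parts are removed from the modern layer and
#' returned separately so the reconstruction can merge them into the
#' historical baseline. All geometries are projected to the equal-area plane
#' and clipped to the border.
#'
#' @param path GeoJSON of modern ranges (features keyed by `species`).
#' @param border border region in lon/lat.
#' @param extinct_path optional GeoJSON of extinct-range parts, keyed by the
#'   same species ids.
#' @param proj an [eoo_projection()].
#' @return list with `modern` and `extinct`: named lists of projected,
#'   dissolved, border-clipped regions (extinct entries only for species that
#'   have them).
#' @export
read_range_polygons <- function(path, border, extinct_path = NULL,
                                proj = eoo_projection()) {
  raw <- read_geojson_regions(path)
  border_p <- region_union(project_region(border, proj))
  ext_raw <- if (!is.null(extinct_path)) read_geojson_regions(extinct_path)
             else list()
  modern <- list()
  extinct <- list()
  for (id in names(raw)) {
    m <- region_union(project_region(raw[[id]], proj))
    if (!is.null(ext_raw[[id]])) {
      e <- region_union(project_region(ext_raw[[id]], proj))
      extinct[[id]] <- region_intersect(e, border_p)
      m <- region_diff(m, e)
    }
    modern[[id]] <- region_intersect(m, border_p)
  }
  list(modern = modern, extinct = extinct)
}

# --- traits and tree --------------------------------------------------------

#' Read a species trait table and phylogeny, validated against a catalog
#'
#' The trait table needs `species`, `body_mass_kg` (> 0) and `trophic`
#' (1 = herbivore, 2 = omnivore, 3 = carnivore). The Newick tree must carry
#' branch lengths and its tips must cover all included species; surplus tips
#' are pruned. Species names are matched case-insensitively after
#' space/underscore normalization.
#'
#' @param traits_path CSV path or data.frame.
#' @param tree_path Newick path or an `ape::phylo` object.
#' @param catalog optional species catalog from
#'   [filter_species_by_min_sites()]; validation is restricted to included
#'   species. Without a catalog all trait-table species are used.
#' @return list with `traits` (data.frame, normalized ids), `tree` (pruned
#'   `phylo`) and `dropped_tips` (character).
#' @export
read_traits_and_tree <- function(traits_path, tree_path, catalog = NULL) {
  traits <- if (is.data.frame(traits_path)) traits_path
            else utils::read.csv(traits_path, stringsAsFactors = FALSE)
  need <- c("species", "body_mass_kg", "trophic")
  missing <- setdiff(need, names(traits))
  if (length(missing) > 0) {
    stop("trait table missing column(s): ", paste(missing, collapse = ", "))
  }
  traits$species <- normalize_species_id(traits$species)

  tree <- if (inherits(tree_path, "phylo")) tree_path
          else ape::read.tree(tree_path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree$tip.label <- normalize_species_id(tree$tip.label)

  wanted <- if (!is.null(catalog)) catalog$species_id[catalog$included]
            else traits$species
  wanted <- normalize_species_id(wanted)

  miss_tr <- setdiff(wanted, traits$species)
  miss_tip <- setdiff(wanted, tree$tip.label)
  if (length(miss_tr) > 0 || length(miss_tip) > 0) {
    stop("included species missing from ",
         if (length(miss_tr) > 0)
           paste0("traits: ", paste(miss_tr, collapse = ", ")) else "",
         if (length(miss_tr) > 0 && length(miss_tip) > 0) "; " else "",
         if (length(miss_tip) > 0)
           paste0("tree: ", paste(miss_tip, collapse = ", ")) else "")
  }

  traits <- traits[traits$species %in% wanted, , drop = FALSE]
  if (any(!is.finite(traits$body_mass_kg) | traits$body_mass_kg <= 0)) {
    stop("body_mass_kg must be positive for all included species")
  }
  if (any(!traits$trophic %in% 1:3)) {
    stop("trophic must be coded 1 (herbivore), 2 (omnivore) or 3 (carnivore)")
  }
  dropped <- setdiff(tree$tip.label, wanted)
  if (length(dropped) > 0) tree <- ape::drop.tip(tree, dropped)
  rownames(traits) <- traits$species
  list(traits = traits, tree = tree, dropped_tips = dropped)
}

# --- ESRI ASCII rasters -----------------------------------------------------

#' Read / write an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' cell values, first row northmost. Used here for the six environmental
#' predictor surfaces.
#'
#' @param path file path.
#' @return list with the header fields and `z`, an `nrows x ncols` matrix
#'   (row 1 = top/north) with `NA` for nodata.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA
  list(ncols = hdr$ncols, nrows = hdr$nrows,
       xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
       cellsize = hdr$cellsize,
       nodata = if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value,
       z = z)
}

#' @rdname read_esri_ascii
#' @param r raster list as returned by `read_esri_ascii`.
#' @export
write_esri_ascii <- function(r, path) {
  z <- r$z
  z[is.na(z)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", r$ncols),
    sprintf("nrows %d", r$nrows),
    sprintf("xllcorner %.10g", r$xllcorner),
    sprintf("yllcorner %.10g", r$yllcorner),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  body <- apply(z, 1, function(row) paste(format(row, trim = TRUE,
                                                 digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Cell-centre coordinates and values of a raster
#'
#' @param r raster list from [read_esri_ascii()].
#' @return data.frame with `x`, `y` (cell centres) and `value`.
#' @export
raster_cell_centers <- function(r) {
  xs <- r$xllcorner + (seq_len(r$ncols) - 0.5) * r$cellsize
  ys <- r$yllcorner + (r$nrows - seq_len(r$nrows) + 0.5) * r$cellsize
  data.frame(
    x = rep(xs, times = r$nrows),
    y = rep(ys, each = r$ncols),
    value = as.vector(t(r$z))
  )
}
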