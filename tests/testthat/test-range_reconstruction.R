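test_that("anchors are the two nearest admissible features", {
  border <- big_border(4)
  sq <- unit_square()

  # lone point with only the baseline available: polygon + border foot
  att <- nearest_two_features(c(2, 0.5), matrix(numeric(0), ncol = 2),
                              sq, border)
  kinds <- vapply(att$anchors, `[[`, "", "kind")
  expect_setequal(kinds, c("polygon", "border"))
  xy <- lapply(att$anchors, `[[`, "xy")
  expect_equal(xy[[which(kinds == "polygon")]], c(1, 0.5))
  expect_equal(xy[[which(kinds == "border")]], c(2, 0))

  # two external points closer than the polygon: both anchors are points
  pts <- rbind(c(2.1, 0.6), c(2.2, 0.4))
  att2 <- nearest_two_features(c(2, 0.5), pts, sq, border,
                               point_ids = c("p1", "p2"))
  expect_equal(vapply(att2$anchors, `[[`, "", "kind"), c("point", "point"))

  # multipart baseline: only the nearest part is the polygon candidate
  two_parts <- c(sq, list(rect_ring(3, 3, 3.5, 3.5)))
  att3 <- nearest_two_features(c(2, 0.5), matrix(numeric(0), ncol = 2),
                               two_parts, border)
  poly_anchor <- att3$anchors[[which(vapply(att3$anchors, `[[`, "",
                                            "kind") == "polygon")]]
  expect_equal(poly_anchor$xy, c(1, 0.5))
})

test_that("attachment polygons realize connections with the right area", {
  att <- list(point = c(2, 0.5),
              anchors = list(list(xy = c(1, 0.5)), list(xy = c(2, 0))))
  expect_equal(region_area(attachment_polygon(att)), 0.25, tolerance = 1e-9)

  # collinear triple: thin buffered corridor, union of the two overlapping
  # segment rectangles = longest segment x 2 epsilon
  att_col <- list(point = c(0, 0),
                  anchors = list(list(xy = c(1, 0)), list(xy = c(2, 0))))
  a <- region_area(attachment_polygon(att_col, epsilon = 1e-3))
  expect_equal(a, 2 * 2e-3, tolerance = 0.01)

  # anchor coinciding with the point contributes nothing
  att_zero <- list(point = c(0, 0),
                   anchors = list(list(xy = c(0, 0)), list(xy = c(0, 0))))
  expect_equal(region_area(attachment_polygon(att_zero)), 0)
})

test_that("building a period range unions baseline and attachments", {
  border <- big_border(4)
  sq <- unit_square()
  # no points: identity
  expect_equal(region_area(build_period_range(sq, NULL, border)), 1)

  # the single worked point: square + disjoint triangle = 1.25
  r1 <- build_period_range(sq, matrix(c(2, 0.5), 1), border)
  expect_equal(region_area(r1), 1.25, tolerance = 1e-6)
  # result contains the input point and the full baseline
  expect_true(point_in_region(2, 0.5, r1))
  expect_equal(region_area(region_diff(sq, r1)), 0)

  # two points generating overlapping triangles: union < sum of parts and
  # matches the Monte-Carlo rejection-sampling oracle within 1%
  pts <- rbind(c(2, 0.5), c(2.2, 0.7))
  r2 <- build_period_range(sq, pts, border, point_ids = c("a", "b"))
  atts <- lapply(seq_len(2), function(i) {
    attachment_polygon(nearest_two_features(pts[i, ], pts[-i, , drop = FALSE],
                                            sq, border,
                                            point_ids = "z"))
  })
  part_sum <- region_area(sq) + sum(vapply(atts, region_area, 0))
  expect_lt(region_area(r2), part_sum)
  raw <- c(sq, atts[[1]], atts[[2]])
  expect_lt(abs(region_area(r2) / mc_union_area(raw) - 1), 0.01)
})

test_that("construction is order-invariant, idempotent and monotone", {
  set.seed(3)
  border <- big_border(10)
  base <- list(ellipse_ring(5, 5, 1.5, 1, 0.4))
  pts <- cbind(runif(6, 0.5, 9.5), runif(6, 0.5, 9.5))
  ids <- paste0("p", 1:6)

  a1 <- build_period_range(base, pts, border, point_ids = ids)
  perm <- c(4, 2, 6, 1, 3, 5)
  a2 <- build_period_range(base, pts[perm, ], border, point_ids = ids[perm])
  expect_identical(a1, a2)                    # order affects nothing
  expect_identical(build_period_range(base, pts, border, point_ids = ids),
                   a1)                        # rebuild is bit-identical

  # adding points always keeps the baseline and every point covered (the
  # area itself is not monotone: a new nearby point can re-anchor an old
  # one away from a distant feature, replacing a large attachment triangle
  # with a small one)
  for (k in 1:6) {
    ak <- build_period_range(base, pts[1:k, , drop = FALSE], border,
                             point_ids = ids[1:k])
    expect_equal(region_area(region_diff(base, ak)), 0, tolerance = 1e-6)
    expect_true(all(point_in_region(pts[1:k, 1], pts[1:k, 2], ak,
                                    tol = 1e-6)))
  }
})

test_that("range histories nest and the extinct parts join the historical layer", {
  set.seed(9)
  border <- list(rect_ring(0, 0, 100, 100))
  modern <- list(rect_ring(40, 40, 60, 60))
  extinct <- list(rect_ring(60, 40, 70, 60))
  rec <- data.frame(
    x = c(runif(8, 5, 95), runif(8, 5, 95)),
    y = c(runif(8, 5, 95), runif(8, 5, 95)),
    period = rep(c("historical", "holocene"), each = 8),
    site_id = paste0("s", 1:16)
  )
  h <- build_range_history("spx", modern, rec, border, extinct = extinct)
  a <- h$area_km2
  expect_gte(a[["holocene"]], a[["historical"]])
  expect_gte(a[["historical"]], a[["modern"]])
  expect_equal(a[["modern"]], 400)
  # extinct block is historical but not modern
  expect_true(point_in_region(65, 50, h$geometry$historical))
  expect_false(point_in_region(65, 50, h$geometry$modern))
  # every record sits inside its period's range (and the Holocene one)
  expect_true(all(point_in_region(rec$x, rec$y, h$geometry$holocene,
                                  tol = 1e-6)))
  hist_rec <- rec[rec$period == "historical", ]
  expect_true(all(point_in_region(hist_rec$x, hist_rec$y,
                                  h$geometry$historical, tol = 1e-6)))
})

test_that("species with no modern range rebuild from points and border alone", {
  border <- list(rect_ring(0, 0, 100, 100))
  rec <- data.frame(x = c(10, 30, 20), y = c(10, 12, 30),
                    period = "holocene", site_id = c("a", "b", "c"))
  h <- build_range_history("gone", list(), rec, border)
  expect_equal(h$area_km2[["modern"]], 0)
  expect_equal(h$area_km2[["historical"]], 0)
  expect_gt(h$area_km2[["holocene"]], 0)
  expect_true(all(point_in_region(rec$x, rec$y, h$geometry$holocene)))
})

test_that("proportion lost matches published per-species arithmetic", {
  # giant panda: 749,840 km2 Holocene, 16,285 km2 today -> 97.8% lost
  expect_equal(round(proportion_lost(749840, 16285), 3), 0.978)
  # regional extinction: all range lost
  expect_equal(proportion_lost(963240, 0), 1)
  expect_equal(proportion_lost(5, 5), 0)
  expect_warning(out <- proportion_lost(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(suppressWarnings(proportion_lost(c(10), c(11))), "not nested")
})

test_that("area table and aggregate summary reproduce the fauna accounting", {
  t1 <- china_mammal_ranges()
  # two species already had no range by 1900, so the historical-modern
  # interval proportion is undefined for them (warned, flagged NA)
  tab <- suppressWarnings(
    area_table(species = t1$species, area_hol = t1$area_hol_km2,
               area_hist = t1$area_hist_km2, area_mod = t1$area_mod_km2)
  )
  expect_true(all(tab$p_lost_hol_mod >= tab$p_lost_hol_hist - 1e-12))
  s <- range_loss_summary(tab)
  expect_equal(round(s$pct_lost_total, 1), 22.8)
  expect_equal(round(s$pct_species_lost_lt50, 1), 73.5)
})
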