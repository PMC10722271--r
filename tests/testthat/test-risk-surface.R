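pt_el <- function(x, y, I0 = 10, Dmax = 100, decay = "linear", gamma = 1) {
  risk_element(geometry("point", cbind(x, y)), "village", I0, Dmax, decay,
               gamma)
}

test_that("decay kernels return hand-computed intensities", {
  lin <- pt_el(0, 0, I0 = 10, Dmax = 100)
  expect_equal(decay_intensity(50, lin), 5)        # linear midpoint
  expect_equal(decay_intensity(0, lin), 10)
  expect_equal(decay_intensity(100, lin), 0)       # zero at the max distance
  expect_equal(decay_intensity(250, lin), 0)

  convex <- pt_el(0, 0, 10, 100, "convex", 2)
  expect_equal(decay_intensity(50, convex), 10 * 0.5^2)   # 2.5
  concave <- pt_el(0, 0, 10, 100, "concave", 0.5)
  expect_equal(decay_intensity(75, concave), 10 * 0.25^0.5)
  const <- pt_el(0, 0, 10, 100, "constant")
  expect_equal(decay_intensity(c(0, 99.9, 100, 120), const), c(10, 10, 0, 0))

  # every kernel: I0 at the source, 0 at/after Dmax, nonincreasing between
  d <- seq(0, 150, by = 0.5)
  for (el in list(lin, convex, concave, const)) {
    y <- decay_intensity(d, el)
    expect_equal(y[1], 10)
    expect_true(all(y[d >= 100] == 0))
    expect_true(all(diff(y) <= 1e-12))
  }
  expect_error(decay_intensity(-1, lin), "nonnegative")
})

test_that("distance rasters match grid geometry for points and polygons", {
  tmpl <- raster_grid(matrix(0, 2, 2), 0, 0, 20)   # centers at 10/30
  d <- distance_to_element(tmpl, pt_el(10, 30))    # NW cell center
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[1, 2], 20)
  expect_equal(d$values[2, 1], 20)
  expect_equal(d$values[2, 2], 20 * sqrt(2))

  poly <- risk_element(
    geometry("polygon", rbind(c(0, 20), c(20, 20), c(20, 40), c(0, 40))),
    "artificial_forest", 4, 500)
  dp <- distance_to_element(tmpl, poly)
  expect_equal(dp$values[1, 1], 0)     # center covered by the polygon
  expect_equal(dp$values[1, 2], 10)    # one half-cell east of the edge

  tmpl_na <- tmpl; tmpl_na$values[2, 2] <- NA
  dna <- distance_to_element(tmpl_na, pt_el(10, 30))
  expect_true(is.na(dna$values[2, 2]))
})

test_that("risk surface is additive, has bounded support and handles the empty case", {
  tmpl <- raster_grid(matrix(0, 20, 25), 0, 0, 20)
  expect_true(all(build_risk_surface(tmpl, list())$values == 0))

  a <- pt_el(100, 100, 10, 150)
  b <- risk_element(geometry("polyline", rbind(c(0, 300), c(500, 300))),
                    "road", 6, 120)
  sa <- build_risk_surface(tmpl, list(a))
  sb <- build_risk_surface(tmpl, list(b))
  sab <- build_risk_surface(tmpl, list(a, b))
  expect_equal(sab$values, sa$values + sb$values, tolerance = 1e-12)

  # two coincident identical points double the singleton surface exactly
  s2 <- build_risk_surface(tmpl, list(a, a))
  expect_equal(s2$values, 2 * sa$values, tolerance = 1e-12)

  # support: cells farther than every Dmax are exactly zero
  dmax <- 150
  da <- distance_to_element(tmpl, a)$values
  db <- distance_to_element(tmpl, b)$values
  far <- da >= dmax & db >= dmax
  expect_true(any(far))
  expect_true(all(sab$values[far] == 0))
})

test_that("risk surface matches a brute-force per-cell oracle", {
  # independent oracle: explicit loops over cells, elements and segments
  tmpl <- raster_grid(matrix(0, 30, 40), 0, 0, 20)
  els <- list(
    pt_el(115, 210, 10, 300),
    pt_el(700, 500, 8, 250, "convex", 2),
    risk_element(geometry("polyline", rbind(c(0, 100), c(400, 180), c(800, 90))),
                 "road", 6, 200),
    risk_element(geometry("polygon",
                          rbind(c(300, 300), c(500, 320), c(480, 520), c(320, 480))),
                 "economic_forest", 5, 260, "concave", 0.5)
  )
  surf <- build_risk_surface(tmpl, els)
  decay_oracle <- function(d, I0, Dmax, kind, g) {
    if (d >= Dmax) return(0)
    switch(kind, linear = I0 * (1 - d / Dmax), constant = I0,
           convex = I0 * (1 - d / Dmax)^g, concave = I0 * (1 - d / Dmax)^g)
  }
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cx <- (j - 0.5) * 20
    cy <- nr * 20 - (i - 0.5) * 20
    total <- 0
    for (el in els) {
      co <- el$geometry$coords
      d <- switch(el$geometry$type,
        point = sqrt((cx - co[1, 1])^2 + (cy - co[1, 2])^2),
        polyline = {
          dd <- Inf
          for (k in seq_len(nrow(co) - 1))
            dd <- min(dd, oracle_seg_dist(cx, cy, co[k, 1], co[k, 2],
                                          co[k + 1, 1], co[k + 1, 2]))
          dd
        },
        polygon = {
          ring <- rbind(co, co[1, ])
          dd <- Inf
          for (k in seq_len(nrow(ring) - 1))
            dd <- min(dd, oracle_seg_dist(cx, cy, ring[k, 1], ring[k, 2],
                                          ring[k + 1, 1], ring[k + 1, 2]))
          # even-odd ray cast
          inside <- FALSE
          jv <- nrow(co)
          for (iv in seq_len(nrow(co))) {
            if ((co[iv, 2] > cy) != (co[jv, 2] > cy) &&
                cx < (co[jv, 1] - co[iv, 1]) * (cy - co[iv, 2]) /
                     (co[jv, 2] - co[iv, 2]) + co[iv, 1]) inside <- !inside
            jv <- iv
          }
          if (inside) 0 else dd
        })
      total <- total + decay_oracle(unname(d), el$intensity, el$max_distance,
                                    el$decay, el$exponent)
    }
    expect_equal(surf$values[i, j], total, tolerance = 1e-9)
  }
})

test_that("risk elements survive a GeoJSON round trip", {
  cfg <- tiny_config(seed = 8)
  els <- generate_risk_elements(cfg, c(village = 1, road = 1,
                                       economic_forest = 1))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_risk_geojson(els, path)
  back <- read_risk_geojson(path)
  expect_length(back, length(els))
  for (i in seq_along(els)) {
    expect_equal(back[[i]]$geometry$coords, els[[i]]$geometry$coords,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$element_type, els[[i]]$element_type)
    expect_equal(back[[i]]$max_distance, els[[i]]$max_distance)
  }
})

test_that("the shipped example element and group files load through the readers", {
  gj <- system.file("extdata", "example_risk_elements.geojson",
                    package = "divscape")
  els <- read_risk_geojson(gj)
  expect_length(els, 5)
  expect_setequal(vapply(els, `[[`, "", "element_type"),
                  c("village", "factory", "road", "artificial_forest",
                    "economic_forest"))
  tmpl <- raster_grid(matrix(0, 40, 40), 0, 0, 100)
  surf <- build_risk_surface(tmpl, els)
  expect_true(all(is.finite(surf$values)) && max(surf$values) > 0)

  centers <- read.csv(system.file("extdata", "example_group_centers.csv",
                                  package = "divscape"))
  hr <- build_home_ranges(centers)
  expect_equal(hr$group, LETTERS[1:5])
})
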