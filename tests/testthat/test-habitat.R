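test_that("stack summaries use the sample SD and propagate no-data", {
  g <- generate_grid(2, 1)
  s1 <- sdm_surface(c(0.2, 0.6), g, "presence", "a")
  s2 <- sdm_surface(c(0.4, NA), g, "presence", "b")
  out <- prediction_summary(list(s1, s2))
  expect_equal(as.numeric(out$mean)[1], 0.3)
  expect_equal(as.numeric(out$sd)[1], stats::sd(c(0.2, 0.4)))
  expect_equal(as.numeric(out$sd)[1], 0.1414, tolerance = 1e-3)
  expect_true(is.na(as.numeric(out$mean)[2]))  # incomplete stack cell
  expect_error(prediction_summary(list(s1)), "2 layers")
  expect_error(prediction_summary(list()), "empty")
  same <- prediction_summary(list(s1, s1, s1))
  expect_equal(as.numeric(same$sd), c(0, 0))
})

test_that("habitat categories follow the mean/SD threshold rules", {
  g <- generate_grid(4, 1)
  # constructed so the global thresholds are mean 0.3 and SD 0.1
  mu <- sdm_surface(c(0.5, 0.1, 0.1, 0.5), g, "presence", "mean")
  sdv <- sdm_surface(c(0.05, 0.25, 0.05, 0.05), g, "presence", "sd")
  hm <- classify_habitat(mu, sdv)
  expect_equal(hm$mean_threshold, 0.3)
  expect_equal(hm$sd_threshold, 0.1)
  expect_equal(hm$category,
               c("recurrent", "occasional", "unfavourable", "recurrent"))
  # high mean AND high SD -> occasional (SD rule takes precedence)
  mu2 <- sdm_surface(c(0.5, 0.1, 0.1, 0.1), g, "presence", "mean")
  sd2 <- sdm_surface(c(0.25, 0.05, 0.05, 0.05), g, "presence", "sd")
  expect_equal(classify_habitat(mu2, sd2)$category[1], "occasional")
})

test_that("threshold ties fall to the low side and NA is uncategorized", {
  g <- generate_grid(3, 1)
  mu <- sdm_surface(c(0.2, 0.4, NA), g, "p", "mean")   # threshold = 0.3
  sdv <- sdm_surface(c(0.1, 0.1, NA), g, "p", "sd")    # threshold = 0.1
  hm <- classify_habitat(mu, sdv)
  # SD == threshold is "low"; mean 0.2 < 0.3 -> unfavourable
  expect_equal(hm$category, c("unfavourable", "recurrent", "uncategorized"))
})

test_that("classification is invariant under common affine rescaling", {
  set.seed(77)
  g <- generate_grid(10, 10)
  mu <- sdm_surface(runif(100), g, "p", "mean")
  sdv <- sdm_surface(runif(100, 0, 0.3), g, "p", "sd")
  h1 <- classify_habitat(mu, sdv)
  h2 <- classify_habitat(sdm_surface(5 * as.numeric(mu) + 2, g, "p", "mean"),
                         sdm_surface(5 * as.numeric(sdv) + 2, g, "p", "sd"))
  expect_identical(h1$category, h2$category)
})

test_that("habitat partition and percentage invariants hold on random maps", {
  set.seed(78)
  for (i in 1:50) {
    g <- generate_grid(sample(3:8, 1), sample(3:8, 1))
    n <- g$n_cells
    mu_v <- runif(n); sd_v <- runif(n, 0, 0.4)
    drop <- sample(n, sample(0:(n %/% 4), 1))
    mu_v[drop] <- NA; sd_v[drop] <- NA
    hm <- classify_habitat(sdm_surface(mu_v, g, "p", "mean"),
                           sdm_surface(sd_v, g, "p", "sd"))
    expect_equal(sum(hm$counts), n)
    expect_equal(unname(hm$counts[["uncategorized"]]), length(drop))
    mask <- build_mask(rectangle_ring(c(0, g$n_x / 2), c(0, g$n_y)), g)
    rep <- mpa_comparison(hm, mask)
    pct <- rep$category_pct
    ok <- !is.na(pct$pct_inside)
    expect_equal(pct$pct_inside[ok] + pct$pct_outside[ok],
                 rep(100, sum(ok)), tolerance = 1e-9)
  }
})

test_that("abundance is the cell-wise product with its total", {
  g <- generate_grid(2, 1)
  s <- sdm_surface(c(1, 2), g, "n_sightings")
  gs <- sdm_surface(c(10, 5), g, "group_size_sum")
  ab <- abundance_surface(s, gs)
  expect_equal(as.numeric(ab$surface), c(10, 10))
  expect_equal(ab$total, 20)
  expect_equal(ab$mean_density, 10)
  zero <- abundance_surface(sdm_surface(c(0, 0), g, "n"), gs)
  expect_equal(zero$total, 0)
  # brute-force recomputation on a random pair
  set.seed(81)
  g2 <- generate_grid(6, 6)
  a <- sdm_surface(runif(36), g2, "n"); b <- sdm_surface(runif(36, 0, 30),
                                                         g2, "g")
  ab2 <- abundance_surface(a, b)
  expect_equal(ab2$total, sum(as.numeric(a) * as.numeric(b)),
               tolerance = 1e-12)
})

test_that("masks follow the point-in-polygon rule with closed forms", {
  g <- generate_grid(4, 4)
  all_in <- build_mask(rectangle_ring(c(-1, 5), c(-1, 5)), g)
  expect_true(all(all_in))
  none <- build_mask(rectangle_ring(c(10, 12), c(10, 12)), g)
  expect_false(any(none))
  # half-plane rectangle: centers with x < 2
  west <- build_mask(rectangle_ring(c(0, 2), c(0, 4)), g)
  expect_equal(as.logical(west), cell_centers(g)[, 1] < 2)
  # L-shape as union of two rectangles equals the union of masks
  l_shape <- build_mask(list(rectangle_ring(c(0, 2), c(0, 4)),
                             rectangle_ring(c(0, 4), c(0, 2))), g)
  south <- build_mask(rectangle_ring(c(0, 4), c(0, 2)), g)
  expect_equal(as.logical(l_shape), as.logical(west) | as.logical(south))
  # triangle under y = 2x (no cell center falls on an edge)
  tri <- build_mask(cbind(c(0, 4, 4, 0), c(0, 0, 8, 0)), g)
  ctr <- cell_centers(g)
  expect_equal(as.logical(tri), ctr[, 2] < 2 * ctr[, 1])
  expect_error(build_mask(cbind(c(0, 1), c(0, 1)), g), "3")
})

test_that("MPA comparison reports percentages and Welch t tests", {
  g <- generate_grid(4, 1)
  hm <- classify_habitat(
    sdm_surface(c(0.9, 0.9, 0.9, 0.1), g, "p", "mean"),
    sdm_surface(c(0.01, 0.01, 0.01, 0.01), g, "p", "sd"))
  # 3 recurrent + 1 unfavourable by construction (SD ties fall low)
  expect_equal(unname(hm$counts[["recurrent"]]), 3)
  mask <- build_mask(rectangle_ring(c(0, 2), c(0, 1)), g)  # 2 inside
  rep <- mpa_comparison(hm, mask)
  rec <- rep$category_pct[rep$category_pct$category == "recurrent", ]
  expect_equal(rec$pct_inside, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(rep$n_inside, 2)
  # shifted inside values give negative t (outside - inside) and small p
  set.seed(83)
  g2 <- generate_grid(10, 10)
  inside <- build_mask(rectangle_ring(c(0, 5), c(0, 10)), g2)
  vals <- rnorm(100) + 2 * as.logical(inside)
  hm2 <- classify_habitat(sdm_surface(vals, g2, "p", "mean"),
                          sdm_surface(runif(100, 0, 0.2), g2, "p", "sd"))
  r2 <- mpa_comparison(hm2, inside,
                       surfaces = list(p = sdm_surface(vals, g2, "p")))
  expect_lt(r2$t_tests$t, 0)
  expect_lt(r2$t_tests$p_value, 1e-6)
  expect_warning(mpa_comparison(hm2, build_mask(
    rectangle_ring(c(-1, 11), c(-1, 11)), g2)), "degenerate")
})

test_that("GeoJSON masks and JSON reports round-trip", {
  g <- generate_grid(4, 4)
  gj <- list(type = "Polygon",
             coordinates = list(list(list(0, 0), list(2, 0), list(2, 4),
                                     list(0, 4), list(0, 0))))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  mk <- read_mask_geojson(f, g)
  expect_equal(as.logical(mk), cell_centers(g)[, 1] < 2)
  hm <- classify_habitat(sdm_surface(runif(16), g, "p", "mean"),
                         sdm_surface(runif(16, 0, .2), g, "p", "sd"))
  rep <- mpa_comparison(hm, mk)
  out <- withr::local_tempfile(fileext = ".json")
  write_mpa_report(rep, out)
  back <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(back$key_inside_pct, rep$key_inside_pct, tolerance = 1e-9)
})
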