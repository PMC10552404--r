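test_that("ROI sampling averages exactly the enclosed vertices", {
  mesh <- tetrahedron_mesh(scale = 10)
  map <- c(1, 2, 3, 4)
  # site exactly at vertex 2, radius below the minimum edge length
  prof <- sample_map_at_sites(mesh, map, mesh$vertices[2, , drop = FALSE],
                              radius = 1, mask = rep(TRUE, 4))
  expect_equal(prof$values, 2)
  # site at the centroid of vertices 1-3, radius enclosing exactly those 3
  ctr <- colMeans(mesh$vertices[1:3, ])
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  r <- (sort(d)[3] + sort(d)[4]) / 2
  prof <- sample_map_at_sites(mesh, map, rbind(ctr), radius = r,
                              mask = rep(TRUE, 4))
  expect_equal(prof$values, mean(map[order(d)[1:3]]))
  # constant map: every profile value is the constant
  prof <- sample_map_at_sites(mesh, rep(7, 4), mesh$vertices, radius = 5,
                              mask = rep(TRUE, 4))
  expect_true(all(prof$values == 7))
  # empty ROIs are dropped; all empty is an error
  far <- rbind(c(1e5, 0, 0), mesh$vertices[1, ])
  prof <- sample_map_at_sites(mesh, map, far, radius = 1, mask = rep(TRUE, 4))
  expect_equal(prof$dropped, 1)
  expect_equal(prof$retained, 2)
  expect_error(
    sample_map_at_sites(mesh, map, rbind(c(1e5, 0, 0)), radius = 1,
                        mask = rep(TRUE, 4)),
    "empty"
  )
})

test_that("donor slopes equal the correlation and flag zero variance", {
  set.seed(61)
  x <- rnorm(50)
  expect_equal(donor_slope(x, x), 1)
  expect_equal(donor_slope(x, -x), -1)
  for (i in 1:10) {
    y <- rnorm(50)
    expect_equal(donor_slope(x, y), cor(x, y), tolerance = 1e-12)
    # covariance / variance oracle without standardisation
    expect_equal(donor_slope(x, y, standardize = FALSE),
                 cov(x, y) / var(x), tolerance = 1e-12)
  }
  expect_warning(s <- donor_slope(x, rep(1, 50)), "zero variance")
  expect_true(is.na(s))
  expect_error(donor_slope(1:2, 1:2), "3 retained sites")
})

test_that("decoding selects coupled genes and stays calibrated on null genes", {
  mesh <- make_mesh(3)
  target <- smooth_noise(mesh, 1, 20, mask = mesh$cortex_mask)[, 1]
  n_null <- 1000
  rho <- stats::setNames(c(rep(0.8, 50), rep(0, n_null)),
                         sprintf("G%05d", seq_len(50 + n_null)))
  ds <- simulate_donors(mesh, target, rho, n_donors = 6, n_samples = 300,
                        seed = 62)
  dec <- decode_map(mesh, target, ds, radius = 4, p_threshold = 0.01)
  power <- mean(dec$selected[1:50])
  null_rate <- mean(dec$selected[-(1:50)])
  expect_gte(power, 0.9)
  expect_lt(abs(null_rate - 0.01), 0.005)
  # null p-values are uniform
  ks <- suppressWarnings(stats::ks.test(dec$p[-(1:50)], "punif"))
  expect_gt(ks$p.value, 0.01)
  # selected flag is consistent with the threshold
  expect_true(all(dec$p[dec$selected] < 0.01))
})

test_that("decoding equals a naive per-gene loop oracle", {
  mesh <- make_mesh(2)
  target <- smooth_noise(mesh, 1, 20, mask = mesh$cortex_mask)[, 1]
  rho <- stats::setNames(runif(8, -0.8, 0.8), sprintf("g%02d", 1:8))
  ds <- simulate_donors(mesh, target, rho, n_donors = 4, n_samples = 40,
                        seed = 63)
  dec <- decode_map(mesh, target, ds, radius = 4)
  naive <- vapply(seq_along(rho), function(g) {
    slopes <- vapply(ds$donors, function(d) {
      prof <- sample_map_at_sites(mesh, target, d$coords, 4)
      donor_slope(prof$values, d$expr[prof$retained, g])
    }, numeric(1))
    tt <- stats::t.test(slopes)
    c(mean(slopes), unname(tt$statistic), tt$p.value)
  }, numeric(3))
  expect_equal(dec$mean_slope, naive[1, ], tolerance = 1e-12)
  expect_equal(dec$t, naive[2, ], tolerance = 1e-10)
  expect_equal(dec$p, naive[3, ], tolerance = 1e-10)
})

test_that("negating the map negates slopes and preserves p (sign symmetry)", {
  mesh <- make_mesh(2)
  target <- smooth_noise(mesh, 1, 15, mask = mesh$cortex_mask)[, 1]
  rho <- stats::setNames(c(0.7, 0, -0.5), c("a", "b", "c"))
  ds <- simulate_donors(mesh, target, rho, n_donors = 4, n_samples = 50,
                        seed = 64)
  d1 <- decode_map(mesh, target, ds)
  d2 <- decode_map(mesh, -target, ds)
  expect_equal(d2$mean_slope, -d1$mean_slope, tolerance = 1e-12)
  expect_equal(d2$p, d1$p, tolerance = 1e-12)
  expect_equal(abs(d2$t), abs(d1$t), tolerance = 1e-10)
})

test_that("identical nonzero donor slopes are degenerate, not significant noise", {
  mesh <- make_mesh(1)
  nv <- n_vertices(mesh)
  target <- seq_len(nv) / nv
  # rho = 1, no noise, no normalisation jitter: slopes identical across donors
  ds <- simulate_donors(mesh, target, c(g = 1), n_donors = 3, n_samples = 12,
                        noise_sd = 0, jitter_mm = 0, seed = 65)
  dec <- decode_map(mesh, target, ds, radius = 0.5)
  expect_true("g" %in% attr(dec, "degenerate"))
  expect_equal(dec$p[1], .Machine$double.xmin)
  expect_true(dec$selected[1])
})

test_that("GLS decoding converges to OLS as the length scale vanishes", {
  mesh <- make_mesh(2)
  target <- smooth_noise(mesh, 1, 15, mask = mesh$cortex_mask)[, 1]
  rho <- stats::setNames(runif(6, -0.6, 0.6), paste0("g", 1:6))
  ds <- simulate_donors(mesh, target, rho, n_donors = 4, n_samples = 60,
                        seed = 66)
  ols <- decode_map(mesh, target, ds)
  gls <- gls_decode_map(mesh, target, ds, length_scale = 1e-6)
  expect_equal(gls$t, ols$t, tolerance = 1e-6)
  expect_equal(gls$mean_slope, ols$mean_slope, tolerance = 1e-6)
})

test_that("GLS slopes recover planted coupling and calibrate smooth nulls", {
  mesh <- make_mesh(3)
  target <- smooth_noise(mesh, 1, 20, mask = mesh$cortex_mask)[, 1]
  # planted coupling: GLS estimates remain centred on rho
  rho <- stats::setNames(rep(0.6, 30), paste0("c", 1:30))
  ds <- simulate_donors(mesh, target, rho, n_donors = 6, n_samples = 150,
                        seed = 67)
  gls <- gls_decode_map(mesh, target, ds, length_scale = 10)
  expect_lt(abs(mean(gls$mean_slope) - 0.6), 2 * sd(gls$mean_slope) / sqrt(30) + 0.05)

  # spatially autocorrelated null expression: GLS at least as calibrated as OLS
  set.seed(68)
  n_genes <- 400
  donors <- lapply(1:6, function(d) {
    sites <- sample(which(mesh$cortex_mask), 150)
    fields <- smooth_noise(mesh, n_genes, 20, mask = mesh$cortex_mask)
    list(coords = mesh$vertices[sites, ], expr = fields[sites, ])
  })
  ds_null <- structure(list(donors = lapply(donors, function(d) {
    colnames(d$expr) <- paste0("n", seq_len(n_genes))
    d
  }), genes = paste0("n", seq_len(n_genes)), normalized = FALSE),
  class = "expr_dataset")
  ols0 <- decode_map(mesh, target, ds_null)
  gls0 <- gls_decode_map(mesh, target, ds_null, length_scale = 10)
  rate_ols <- mean(ols0$selected)
  rate_gls <- mean(gls0$selected)
  expect_lte(abs(rate_gls - 0.01), abs(rate_ols - 0.01) + 0.01)
  expect_lt(rate_gls, 0.05)
})

test_that("list overlap percentages follow the union convention", {
  a <- paste0("g", 1:10)
  b <- paste0("g", 6:15)
  res <- list_overlap(list(A = a, B = b))
  expect_equal(res$n_overlap, 5)
  expect_equal(res$pct_of_union, round(100 * 5 / 15, 1))
  same <- list_overlap(list(A = a, B = a))
  expect_equal(same$pct_of_union, 100)
  disj <- list_overlap(list(A = a, B = paste0("x", 1:4)))
  expect_equal(disj$pct_of_union, 0)
  expect_error(list_overlap(list(A = a)), ">= 2 lists")
  expect_error(list_overlap(list(A = character(), B = character())), "empty")
})
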