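test_that("smoothing at FWHM 0 is the identity and constants are fixed points", {
  mesh <- make_mesh(2)
  x <- rnorm(n_vertices(mesh))
  expect_identical(smooth_map(mesh, x, 0), x)
  cc <- smooth_map(mesh, rep(3.3, n_vertices(mesh)), 12)
  expect_lt(max(abs(cc - 3.3)), 1e-10)
  # area-weighted mean conserved
  a <- vertex_areas(mesh)
  xs <- smooth_map(mesh, x, 12)
  expect_lt(abs(sum(a * xs) - sum(a * x)) / max(abs(sum(a * x)), 1), 1e-8)
})

test_that("a smoothed impulse has the requested kernel width", {
  mesh <- make_mesh(5, radius = 80, cap_degrees = 0)
  v0 <- 123
  x <- numeric(n_vertices(mesh))
  x[v0] <- 1
  fwhm <- 15
  xs <- smooth_map(mesh, x, fwhm)
  # spatial sd from the 2-D second moment over arc distance: E[r^2] = 2 sigma^2
  ctr <- mesh$vertices[v0, ]
  r <- 80 * acos(pmin(1, pmax(-1, (mesh$vertices %*% ctr) / 80^2)))
  w <- pmax(xs, 0)
  sigma <- sqrt(sum(w * r^2) / sum(w) / 2)
  expect_lt(abs(sigma - fwhm / 2.355) / (fwhm / 2.355), 0.1)
})

test_that("residual smoothness estimation recovers the smoothing FWHM", {
  mesh <- make_mesh(4, cap_degrees = 0)
  set.seed(51)
  for (w in c(10, 15, 20)) {
    fields <- smooth_noise(mesh, 50, w)
    sm <- estimate_smoothness(fields, mesh, mask = rep(TRUE, n_vertices(mesh)))
    expect_lt(abs(sm$fwhm - w) / w, 0.15)
  }
  # unsmoothed white noise: roughness at the mesh-edge scale, below any kernel
  white <- matrix(rnorm(n_vertices(mesh) * 50), ncol = 50)
  sm0 <- estimate_smoothness(white, mesh, mask = rep(TRUE, n_vertices(mesh)))
  expect_lt(sm0$fwhm, 10)
})

test_that("total resels are invariant to joint rescaling of mesh and FWHM", {
  set.seed(52)
  mesh1 <- make_mesh(3, radius = 80, cap_degrees = 0)
  fields <- smooth_noise(mesh1, 40, 15)
  sm1 <- estimate_smoothness(fields, mesh1, mask = rep(TRUE, n_vertices(mesh1)))
  mesh2 <- make_mesh(3, radius = 160, cap_degrees = 0)
  # same fields on the doubled mesh are smooth at doubled FWHM
  sm2 <- estimate_smoothness(fields, mesh2, mask = rep(TRUE, n_vertices(mesh2)))
  expect_lt(abs(sm2$fwhm - 2 * sm1$fwhm) / (2 * sm1$fwhm), 0.02)
  expect_lt(abs(sm2$resels["R2"] - sm1$resels["R2"]) / sm1$resels["R2"], 0.02)
})

test_that("the Euler characteristic of the masked sphere-with-cap is 1", {
  mesh <- make_mesh(3)  # default 20-degree polar cap masked out
  set.seed(53)
  fields <- smooth_noise(mesh, 10, 12, mask = mesh$cortex_mask)
  sm <- estimate_smoothness(fields[mesh$cortex_mask, ], mesh)
  expect_equal(unname(sm$resels["R0"]), 1)
  expect_gt(unname(sm$resels["R1"]), 0)
})

test_that("cluster labeling matches brute-force flood fill", {
  mesh <- make_mesh(3, cap_degrees = 0)
  mask <- rep(TRUE, n_vertices(mesh))
  # two suprathreshold discs separated by a subthreshold ring
  c1 <- which.max(mesh$vertices[, 3])
  c2 <- which.min(mesh$vertices[, 3])
  tmap <- 5 * effect_disc(mesh, c1, 40) + 4 * effect_disc(mesh, c2, 40)
  cl <- find_clusters(tmap, mesh, df = 40, alpha_form = 0.05, mask = mask)
  expect_equal(nrow(cl), 2)
  u <- attr(cl, "threshold")
  oracle <- flood_fill_clusters(mesh, tmap > u)
  got <- cl$members[order(vapply(cl$members, min, 1L))]
  oracle <- oracle[order(vapply(oracle, min, 1L))]
  expect_equal(got, oracle, ignore_attr = TRUE)

  # random maps, both tails
  set.seed(54)
  for (i in 1:5) {
    tm <- smooth_noise(mesh, 1, 20) * 3
    cl <- find_clusters(tm, mesh, df = 40, alpha_form = 0.05, mask = mask)
    pos <- flood_fill_clusters(mesh, !is.na(tm) & tm > u)
    neg <- flood_fill_clusters(mesh, !is.na(tm) & tm < -u)
    expect_equal(nrow(cl), length(pos) + length(neg))
    all_members <- c(pos, neg)
    expect_setequal(
      vapply(cl$members, paste, "", collapse = ","),
      vapply(all_members, paste, "", collapse = ",")
    )
  }
})

test_that("degenerate threshold cases behave", {
  mesh <- make_mesh(2, cap_degrees = 0)
  mask <- rep(TRUE, n_vertices(mesh))
  cl0 <- find_clusters(numeric(n_vertices(mesh)), mesh, df = 30, mask = mask)
  expect_equal(nrow(cl0), 0)
  tm <- numeric(n_vertices(mesh))
  tm[7] <- 10
  cl1 <- find_clusters(tm, mesh, df = 30, mask = mask)
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$n_vertices, 1)
  expect_equal(cl1$members[[1]], 7)
})

test_that("RFT corrected p has its limit value at zero extent and is monotone", {
  mesh <- make_mesh(3, cap_degrees = 0)
  set.seed(55)
  fields <- smooth_noise(mesh, 30, 15)
  sm <- estimate_smoothness(fields, mesh, mask = rep(TRUE, n_vertices(mesh)))
  df <- 40
  u <- qt(1 - 0.025, df)
  # k = 0 cap of the formula (per tail, density route has the closed form)
  rho <- surfgene:::t_field_ec_density(u, df)
  Em <- sum(sm$resels * rho)
  p0 <- rft_cluster_p(0, sm, u, df, two_tailed = FALSE, method = "density")
  expect_equal(p0, 1 - exp(-Em), tolerance = 1e-10)
  for (method in c("discrete-ec", "density")) {
    pk <- rft_cluster_p(c(0, 1, 2, 5, 10), sm, u, df, two_tailed = FALSE,
                        method = method)
    expect_true(all(diff(pk) < 0))
    # two-tailed doubling caps at 1 but stays monotone non-increasing
    pk2 <- rft_cluster_p(c(0, 1, 2, 5, 10), sm, u, df, method = method)
    expect_true(all(diff(pk2) <= 0))
    # monotone decreasing in the forming threshold too
    pu <- vapply(c(2, 2.5, 3, 3.5),
                 function(uu) rft_cluster_p(2, sm, uu, df, two_tailed = FALSE,
                                            method = method),
                 numeric(1))
    expect_true(all(diff(pu) < 0))
  }
  sm_bad <- sm
  sm_bad$resels["R2"] <- 0
  expect_error(rft_cluster_p(1, sm_bad, u, df), "resel")
})

test_that("corrected cluster p never undercuts the peak's uncorrected tail p", {
  mesh <- make_mesh(3)
  sim <- simulate_cohort(mesh, sizes = c(asd_only = 15, adhd_only = 15,
                                         asd_adhd = 15, td = 15), seed = 56)
  fit <- fit_glm(sim$maps, build_design(sim$subjects), mask = mesh$cortex_mask)
  tab <- rft_cluster_table(fit, "asd", mesh)
  if (nrow(tab)) {
    peak_p <- 2 * pt(tab$peak_t, fit$df_residual, lower.tail = FALSE)
    expect_true(all(tab$p_rft >= peak_p - 1e-12))
  }
  expect_true(TRUE)
})

test_that("permutation inference is deterministic and detects planted effects", {
  mesh <- make_mesh(3)
  disc <- effect_disc(mesh, which(mesh$cortex_mask)[100], 35)
  sim <- simulate_cohort(
    mesh, sizes = c(asd_only = 20, adhd_only = 20, asd_adhd = 20, td = 20),
    effects = list(asd = list(pattern = disc, amplitude = 0.4)),
    seed = 57
  )
  X <- build_design(sim$subjects)
  p1 <- permutation_cluster_test(sim$maps, X, "asd", mesh, n_perm = 120,
                                 seed = 9)
  p2 <- permutation_cluster_test(sim$maps, X, "asd", mesh, n_perm = 120,
                                 seed = 9)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_equal(min(p1$p_perm), 1 / 121, tolerance = 1e-12)
  expect_error(permutation_cluster_test(sim$maps, X, "asd", mesh, n_perm = 10),
               "n_perm")
  expect_error(permutation_cluster_test(sim$maps, X, "nope", mesh,
                                        n_perm = 120), "term")
})

test_that("RFT and permutation corrected p agree in rank on null clusters", {
  mesh <- make_mesh(3)
  p_rft <- c()
  p_perm <- c()
  for (seed in 58:60) {
    sim <- simulate_cohort(mesh, sizes = c(asd_only = 15, adhd_only = 15,
                                           asd_adhd = 15, td = 15),
                           seed = seed)
    X <- build_design(sim$subjects)
    perm <- permutation_cluster_test(sim$maps, X, "interaction", mesh,
                                     n_perm = 199, seed = seed)
    if (nrow(perm) == 0) next
    sm <- attr(perm, "smoothness")
    u <- attr(perm, "threshold")
    df <- attr(perm, "df")
    p_rft <- c(p_rft,
               rft_cluster_p(perm$extent_resels, sm, u, df, two_tailed = FALSE))
    p_perm <- c(p_perm, perm$p_perm)
  }
  expect_gt(length(p_rft), 10)
  expect_gt(suppressWarnings(cor(p_rft, p_perm, method = "spearman")), 0.8)
})
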