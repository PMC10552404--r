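test_that("minimal factorial design has the expected columns and full rank", {
  set.seed(30)
  subjects <- tibble::tibble(
    asd = rep(c(0, 1, 0, 1), 3), adhd = rep(c(0, 0, 1, 1), 3),
    sex = sample(rep(c("male", "female"), 6)),
    age = runif(12, 8, 30), fsiq = rnorm(12, 100, 15),
    site = "site1", global_measure = rnorm(12, 2.7, 0.1)
  )
  X <- build_design(subjects)
  expect_equal(colnames(X),
               c("intercept", "asd", "adhd", "interaction", "sex_male",
                 "age", "age2", "fsiq", "global"))
  expect_equal(qr(unclass(X))$rank, ncol(X))
  expect_lt(abs(mean(X[, "age"])), 1e-10)
  expect_lt(abs(mean(X[, "fsiq"])), 1e-10)
})

test_that("the interaction column is the product of the group columns", {
  for (seed in 1:5) {
    subjects <- balanced_cohort(seed = seed)
    X <- build_design(subjects)
    expect_equal(X[, "interaction"], X[, "asd"] * X[, "adhd"])
  }
})

test_that("an empty factorial cell is rejected by name", {
  subjects <- balanced_cohort()
  subjects <- subjects[!(subjects$asd == 1 & subjects$adhd == 1), ]
  expect_error(build_design(subjects), "asd=1, adhd=1")
})

test_that("per-vertex OLS is calibrated under the null", {
  set.seed(31)
  subjects <- balanced_cohort(n_per_cell = 25)
  X <- build_design(subjects)
  maps <- matrix(rnorm(500 * nrow(subjects)), 500)
  fit <- fit_glm(maps, X)
  tcrit <- qt(0.975, fit$df_residual)
  rate <- mean(abs(fit$tstat$interaction) > tcrit)
  expect_lt(abs(rate - 0.05), 0.015)
  # residuals orthogonal to the design at every vertex
  ortho <- crossprod(unclass(X), t(fit$residuals))
  expect_lt(max(abs(ortho)) / max(abs(maps)), 1e-6)
})

test_that("t-maps are invariant to re-centring continuous covariates", {
  set.seed(32)
  subjects <- balanced_cohort(n_per_cell = 10)
  maps <- matrix(rnorm(50 * nrow(subjects)), 50)
  f1 <- fit_glm(maps, build_design(subjects, center = TRUE))
  f2 <- fit_glm(maps, build_design(subjects, center = FALSE))
  for (tm in names(f1$tstat)) {
    expect_equal(f1$tstat[[tm]], f2$tstat[[tm]], tolerance = 1e-8)
  }
})

test_that("maps equal to a design column are flagged degenerate", {
  subjects <- balanced_cohort(n_per_cell = 4)
  X <- build_design(subjects)
  maps <- matrix(rep(X[, "asd"], each = 1), 3, nrow(subjects), byrow = TRUE)
  fit <- fit_glm(maps, X)
  expect_true(all(1:3 %in% fit$degenerate))
  expect_true(all(is.na(unlist(fit$tstat))))
})

test_that("non-finite map values inside the mask are reported by vertex", {
  subjects <- balanced_cohort(n_per_cell = 4)
  X <- build_design(subjects)
  maps <- matrix(rnorm(5 * nrow(subjects)), 5)
  maps[3, 2] <- NA
  expect_error(fit_glm(maps, X), "vertices: 3")
})

test_that("Cohen's f equals a brute-force two-model refit oracle", {
  set.seed(33)
  subjects <- balanced_cohort(n_per_cell = 8)
  X <- build_design(subjects)
  maps <- matrix(rnorm(40 * nrow(subjects)), 40)
  fit <- fit_glm(maps, X)
  for (term in c("asd", "interaction", "fsiq")) {
    f <- cohens_f(fit, term)
    cn <- attr(X, "terms")[[term]]
    oracle <- vapply(seq_len(40), function(v) {
      y <- maps[v, ]
      full <- lm.fit(unclass(X), y)
      red <- lm.fit(unclass(X)[, setdiff(colnames(X), cn), drop = FALSE], y)
      sst <- sum((y - mean(y))^2)
      r2f <- 1 - sum(full$residuals^2) / sst
      r2r <- 1 - sum(red$residuals^2) / sst
      sqrt(max(r2f - r2r, 0) / (1 - r2f))
    }, numeric(1))
    expect_equal(as.vector(f), oracle, tolerance = 1e-10)
  }
})

test_that("Cohen's f is near zero for absent effects and labels benchmarks", {
  set.seed(34)
  subjects <- balanced_cohort(n_per_cell = 40)
  X <- build_design(subjects)
  maps <- matrix(rnorm(100 * nrow(subjects)), 100)
  fit <- fit_glm(maps, X)
  f <- cohens_f(fit, "asd")
  expect_lt(stats::median(f, na.rm = TRUE), 0.12)
  expect_equal(as.character(cohens_f_label(c(0.1, 0.25, 0.5, 0.75))),
               c("negligible", "small", "medium", "large"))
})

test_that("the ASD-subset model recovers the co-occurring-ADHD effect", {
  mesh <- make_mesh(3)
  disc <- effect_disc(mesh, which(mesh$cortex_mask)[150], 30)
  # thinning specific to the ASD+ADHD cell: interaction amplitude < 0
  sim <- simulate_cohort(
    mesh, sizes = c(asd_only = 60, adhd_only = 30, asd_adhd = 60, td = 60),
    effects = list(interaction = list(pattern = disc, amplitude = -0.3)),
    seed = 17
  )
  full <- fit_glm(sim$maps, build_design(sim$subjects), mask = mesh$cortex_mask)
  sub <- fit_asd_subset(sim$maps, sim$subjects, mask = mesh$cortex_mask)
  expect_equal(sub$df_residual,
               120 - ncol(unclass(build_design(sim$subjects[sim$subjects$asd == 1, ],
                                               model = "group"))))
  in_disc <- which(disc == 1 & mesh$cortex_mask)
  expect_lt(mean(sub$tstat$group[in_disc]), -1)
  # full-model interaction and subset group effect agree in sign in the region
  expect_gt(cor(full$tstat$interaction[in_disc], sub$tstat$group[in_disc]), 0)
  expect_lt(mean(full$tstat$interaction[in_disc]), 0)
})

test_that("the subset model requires both ADHD subgroups", {
  subjects <- balanced_cohort()
  subjects$adhd[subjects$asd == 1] <- 0
  maps <- matrix(rnorm(10 * nrow(subjects)), 10)
  expect_error(fit_asd_subset(maps, subjects), "nonempty")
})

test_that("ComBat adjustment removes a planted site shift, keeps group effects", {
  set.seed(35)
  n_per_site <- 30
  site <- rep(c("A", "B"), each = n_per_site)
  group <- rep(c(0, 1), n_per_site)
  delta <- 0.5
  nv <- 80
  true_effect <- 0.4
  maps <- matrix(rnorm(nv * 2 * n_per_site, sd = 0.3), nv)
  maps <- maps + outer(rep(true_effect, nv), group)
  maps <- maps + outer(rep(delta, nv), as.numeric(site == "B"))
  adj <- combat_adjust(maps, site, design = cbind(group = group))
  site_diff <- rowMeans(adj[, site == "B"]) - rowMeans(adj[, site == "A"])
  expect_lt(mean(abs(site_diff)), 0.1 * delta)
  grp_diff <- rowMeans(adj[, group == 1]) - rowMeans(adj[, group == 0])
  expect_lt(abs(mean(grp_diff) - true_effect), 0.1 * true_effect)
  expect_warning(same <- combat_adjust(maps, rep("A", ncol(maps))), "single batch")
  expect_equal(same, maps)
})
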