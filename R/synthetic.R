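#' Reference cohort profile for the simulator
#'
#' Group-level demographic summaries of the four-subgroup factorial design
#' the simulator emulates: autistic individuals without ADHD ("asd_only"),
#' ADHD without autism ("adhd_only"), the co-occurring group ("asd_adhd"),
#' and typically developing controls ("td"), with the published LEAP
#' structural-imaging subsample sizes, sex counts, and age/FSIQ/global
#' anatomy means and SDs. Total surface area SDs are on the 0.02-0.03 m^2
#' scale (SDs of the order of the mean would imply negative areas).
#'
#' @return A tibble with one row per subgroup: `group`, `n`, `n_male`,
#'   `age_mean`, `age_sd` (years), `fsiq_mean`, `fsiq_sd` (points),
#'   `ct_mean`, `ct_sd` (mm, mean cortical thickness), `sa_mean`, `sa_sd`
#'   (m^2, total surface area).
#' @export
default_cohort_summary <- function() {
  tibble::tibble(
    group = c("asd_only", "adhd_only", "asd_adhd", "td"),
    asd = c(1L, 0L, 1L, 0L),
    adhd = c(0L, 1L, 1L, 0L),
    n = c(170L, 25L, 142L, 196L),
    n_male = c(112L, 14L, 107L, 124L),
    age_mean = c(18.45, 17.80, 16.38, 17.19),
    age_sd = c(5.6, 4.9, 5.30, 5.9),
    fsiq_mean = c(101.98, 79.8, 94.93, 108.44),
    fsiq_sd = c(18.8, 21.1, 20.8, 14.1),
    ct_mean = c(2.67, 2.67, 2.69, 2.68),
    ct_sd = c(0.12, 0.13, 0.14, 0.11),
    sa_mean = c(0.21, 0.21, 0.23, 0.23),
    sa_sd = c(0.026, 0.029, 0.023, 0.023)
  )
}

#' Smooth disc effect pattern on a mesh
#'
#' A convenience pattern for planting localised effects: 1 inside a
#' geodesic-like (chordal) disc around a centre vertex, 0 outside, with an
#' optional raised-cosine edge.
#'
#' @param mesh a [surf_mesh()].
#' @param center_vertex 1-based vertex index of the disc centre.
#' @param radius_mm disc radius (Euclidean, mm).
#' @param soft_mm width of the raised-cosine roll-off beyond the radius
#'   (default 0 = hard edge).
#' @return numeric vertex-length pattern in `[0, 1]`.
#' @export
effect_disc <- function(mesh, center_vertex, radius_mm, soft_mm = 0) {
  stopifnot(radius_mm > 0, soft_mm >= 0)
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, mesh$vertices[center_vertex, ])^2))
  p <- as.numeric(d <= radius_mm)
  if (soft_mm > 0) {
    edge <- d > radius_mm & d <= radius_mm + soft_mm
    p[edge] <- 0.5 * (1 + cos(pi * (d[edge] - radius_mm) / soft_mm))
  }
  p
}

norm_effects <- function(effects, nv) {
  out <- lapply(effects, function(e) {
    if (is.list(e)) {
      stopifnot(!is.null(e$pattern))
      amp <- e$amplitude %||% 1
      e <- amp * e$pattern
    }
    if (length(e) != nv) stop("effect pattern length must equal the vertex count")
    e
  })
  out
}

#' Simulate a factorial cohort with per-subject vertex maps
#'
#' Generates a four-cell (ASD x ADHD) cohort whose covariates mimic the
#' reference profile of [default_cohort_summary()] and whose per-subject
#' vertex maps follow the analysis model: a treatment-coded design effect
#' for every planted term plus smooth, spatially correlated Gaussian noise
#' produced by the same mesh smoother the analysis stage uses.
#'
#' Each subject's map is
#' `intercept + sum_t effect_t * x_t + site_shift + noise`, where `x_t` is
#' the subject's value on term `t` (`asd`, `adhd`, `interaction` = their
#' product, `sex` male = 1, and mean-centred `age`, `fsiq`), and noise is a
#' Gaussian field of the requested FWHM and marginal SD. The per-subject
#' global measure (mean cortical thickness for `modality = "ct"`, total
#' surface area in m^2 for `"sa"`) is computed from the map itself.
#'
#' @param mesh a [surf_mesh()].
#' @param sizes named integer vector of cell sizes
#'   (`asd_only`, `adhd_only`, `asd_adhd`, `td`); defaults to the reference
#'   profile's 170/25/142/196.
#' @param effects named list of planted effect patterns (vertex-length
#'   vectors in map units, or `list(pattern=, amplitude=)`), with names in
#'   `intercept`, `asd`, `adhd`, `interaction`, `sex`, `age`, `fsiq`.
#'   An `intercept` entry replaces the default flat baseline.
#' @param baseline flat baseline level when no intercept pattern is given
#'   (default 2.7 mm, a typical cortical thickness).
#' @param noise_fwhm spatial FWHM of the noise fields, mm (default 15).
#' @param noise_sd marginal SD of the noise fields, map units (default 0.25).
#' @param modality `"ct"` or `"sa"`; decides units of the global measure.
#' @param n_sites number of acquisition sites, assigned round-robin
#'   (default 6).
#' @param site_shift optional numeric vector of per-site additive offsets
#'   (map units, recycled to `n_sites`); default 0.
#' @param profile covariate profile table, defaults to
#'   [default_cohort_summary()].
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @return list with `subjects` (tibble: subject_id, asd, adhd, group, sex,
#'   age, fsiq, site, global_measure) and `maps` (matrix, vertices x
#'   subjects).
#' @export
simulate_cohort <- function(mesh,
                            sizes = NULL,
                            effects = list(),
                            baseline = 2.7,
                            noise_fwhm = 15,
                            noise_sd = 0.25,
                            modality = c("ct", "sa"),
                            n_sites = 6,
                            site_shift = 0,
                            profile = default_cohort_summary(),
                            seed = NULL) {
  modality <- match.arg(modality)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sizes)) sizes <- stats::setNames(profile$n, profile$group)
  grp_names <- c("asd_only", "adhd_only", "asd_adhd", "td")
  if (!all(grp_names %in% names(sizes))) {
    stop("sizes must be named with: ", paste(grp_names, collapse = ", "))
  }
  sizes <- sizes[grp_names]
  if (sum(sizes) == 0) stop("all group sizes are zero")
  nv <- n_vertices(mesh)
  effects <- norm_effects(effects, nv)

  rows <- purrr::map(grp_names, function(g) {
    k <- sizes[[g]]
    if (k == 0) return(NULL)
    pr <- profile[profile$group == g, ]
    male <- rep(FALSE, k)
    if (k > 0) male[sample.int(k, min(k, round(k * pr$n_male / pr$n)))] <- TRUE
    tibble::tibble(
      group = g,
      asd = pr$asd, adhd = pr$adhd,
      sex = ifelse(male, "male", "female"),
      age = pmax(6, stats::rnorm(k, pr$age_mean, pr$age_sd)),
      fsiq = pmax(40, stats::rnorm(k, pr$fsiq_mean, pr$fsiq_sd))
    )
  })
  subjects <- dplyr::bind_rows(rows)
  n <- nrow(subjects)
  subjects <- dplyr::mutate(
    subjects,
    subject_id = sprintf("sub-%04d", seq_len(n)),
    site = paste0("site", ((seq_len(n) - 1L) %% n_sites) + 1L),
    .before = 1
  )

  noise <- smooth_noise(mesh, n, noise_fwhm, sd = noise_sd,
                        mask = mesh$cortex_mask)
  intercept <- effects$intercept %||% rep(baseline, nv)
  maps <- matrix(intercept, nv, n)
  xval <- list(
    asd = subjects$asd,
    adhd = subjects$adhd,
    interaction = subjects$asd * subjects$adhd,
    sex = as.numeric(subjects$sex == "male"),
    age = subjects$age - mean(subjects$age),
    fsiq = subjects$fsiq - mean(subjects$fsiq)
  )
  for (term in setdiff(names(effects), "intercept")) {
    if (!term %in% names(xval)) stop("unknown effect term: ", term)
    maps <- maps + outer(effects[[term]], xval[[term]])
  }
  shift <- rep_len(site_shift, n_sites)
  site_i <- as.integer(sub("^site", "", subjects$site))
  maps <- maps + matrix(shift[site_i], nv, n, byrow = TRUE)
  maps <- maps + noise
  maps[!mesh$cortex_mask, ] <- 0
  colnames(maps) <- subjects$subject_id

  gm <- if (modality == "ct") {
    colMeans(maps[mesh$cortex_mask, , drop = FALSE])
  } else {
    colSums(maps[mesh$cortex_mask, , drop = FALSE]) * 1e-6  # mm^2 -> m^2
  }
  subjects$global_measure <- as.numeric(gm)
  list(subjects = subjects, maps = maps)
}

#' Simulate a multi-donor spatial expression dataset
#'
#' Emulates a donor-wise sampled expression atlas with a known spatial
#' coupling to a target map: for each donor, sampling sites are drawn from
#' masked mesh vertices (coordinates jittered by at most `jitter_mm`), and
#' each gene's expression at the sites is
#' `rho * z(target) + sqrt(1 - rho^2) * noise`, where `z(target)` is the
#' target map standardised over that donor's sites. With `normalize =
#' TRUE` each gene is re-standardised (z-scored) within donor, the
#' default normalisation the decoding stage assumes.
#'
#' @param mesh a [surf_mesh()].
#' @param target_map vertex-length numeric map the expression is coupled to.
#' @param genes named numeric vector of spatial coupling values `rho`
#'   (|rho| <= 1), names are gene symbols.
#' @param n_donors number of donors (>= 2; default 6).
#' @param n_samples sampling sites per donor (>= 3; default 300).
#' @param noise_sd SD multiplier of the decoupled noise component
#'   (default 1, which makes the site-level correlation equal `rho`).
#' @param jitter_mm maximum coordinate jitter, mm (default 1).
#' @param normalize z-score each gene within donor (default TRUE).
#' @param seed optional integer seed.
#' @return An object of class `expr_dataset`: list with `donors` (each a
#'   list of `coords` (sites x 3) and `expr` (sites x genes)), `genes`,
#'   and `normalized`.
#' @export
simulate_donors <- function(mesh, target_map, genes,
                            n_donors = 6, n_samples = 300,
                            noise_sd = 1, jitter_mm = 1,
                            normalize = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_donors < 2) stop("need at least 2 donors for a one-sample t test")
  if (n_samples < 3) stop("need at least 3 sampling sites per donor")
  if (any(abs(genes) > 1)) stop("|rho| must be <= 1 for every gene")
  if (is.null(names(genes))) names(genes) <- sprintf("G%05d", seq_along(genes))
  nv <- n_vertices(mesh)
  stopifnot(length(target_map) == nv)
  cortex <- which(mesh$cortex_mask)
  donors <- purrr::map(seq_len(n_donors), function(d) {
    sites <- sample(cortex, n_samples, replace = n_samples > length(cortex))
    dir <- matrix(stats::rnorm(n_samples * 3), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    coords <- mesh$vertices[sites, , drop = FALSE] +
      dir * stats::runif(n_samples, 0, jitter_mm)
    z <- as.numeric(scale(target_map[sites]))
    if (anyNA(z)) z <- rep(0, n_samples)  # constant target over sites
    eps <- matrix(stats::rnorm(n_samples * length(genes)), n_samples)
    expr <- outer(z, genes) + sweep(eps, 2, sqrt(1 - genes^2) * noise_sd, `*`)
    if (normalize) expr <- scale(expr)
    colnames(expr) <- names(genes)
    list(coords = coords, expr = unname_scale(expr))
  })
  structure(
    list(donors = donors, genes = names(genes), normalized = normalize),
    class = "expr_dataset"
  )
}

unname_scale <- function(x) {
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %d donors, %d genes, %s sites/donor, normalized=%s\n",
    length(x$donors), length(x$genes),
    paste(unique(vapply(x$donors, function(d) nrow(d$expr), 1L)), collapse = "/"),
    x$normalized
  ))
  invisible(x)
}

#' Gene-set collections with planted enrichment
#'
#' Samples gene sets from a synthetic universe. Sets named in `planted`
#' share the requested fraction of their members with `target_list`
#' (sampled from it), so downstream enrichment has known positives; all
#' other members are drawn from the rest of the universe.
#'
#' @param universe_n size of the gene universe (default 20787, the
#'   background size used throughout the enrichment stage).
#' @param set_sizes named (or unnamed) integer vector of set sizes.
#' @param planted named numeric vector of overlap fractions in `[0, 1]`;
#'   names must match names of `set_sizes`.
#' @param target_list character vector of genes the planted overlap is
#'   taken from (required when `planted` is non-empty).
#' @param seed optional integer seed.
#' @return An object of class `gene_sets`: list with `sets` (named list of
#'   character vectors) and `universe` (character vector of all symbols).
#' @export
make_gene_sets <- function(universe_n = 20787, set_sizes,
                           planted = NULL, target_list = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(set_sizes > universe_n)) stop("set sizes must be <= universe_n")
  if (is.null(names(set_sizes))) {
    names(set_sizes) <- sprintf("set%02d", seq_along(set_sizes))
  }
  universe <- sprintf("G%05d", seq_len(universe_n))
  if (!is.null(planted)) {
    if (any(planted < 0 | planted > 1)) stop("overlap fractions must be in [0, 1]")
    if (is.null(target_list)) stop("planted overlap requires a target_list")
    if (!all(names(planted) %in% names(set_sizes))) {
      stop("planted names must match set_sizes names")
    }
    target_list <- intersect(target_list, universe)
  }
  sets <- purrr::imap(as.list(set_sizes), function(m, nm) {
    frac <- if (!is.null(planted) && nm %in% names(planted)) planted[[nm]] else 0
    k <- min(round(frac * m), length(target_list))
    inside <- if (k > 0) sample(target_list, k) else character()
    pool <- setdiff(universe, target_list)
    c(inside, sample(pool, m - k))
  })
  structure(list(sets = sets, universe = universe), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}
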