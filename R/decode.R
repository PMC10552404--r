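#' Sample a surface map at donor sampling sites
#'
#' For every sampling site a spherical region of interest of the given
#' radius is drawn and the map is averaged (unweighted) over the masked
#' mesh vertices inside it (Euclidean distance in mesh space). Sites whose
#' ROI contains no masked vertex are dropped and recorded, mirroring the
#' restriction of the decoding to cortical tissue.
#'
#' @param mesh a [surf_mesh()].
#' @param map vertex-length numeric map.
#' @param sites numeric matrix of site coordinates (sites x 3, mm).
#' @param radius ROI radius in mm (default 4).
#' @param mask logical vertex mask; defaults to the mesh cortex mask.
#' @return list with `values` (mean map value per retained site),
#'   `retained` (indices of retained sites), `dropped` (indices of empty
#'   ROIs).
#' @export
sample_map_at_sites <- function(mesh, map, sites, radius = 4, mask = NULL) {
  stopifnot(radius > 0, length(map) == n_vertices(mesh))
  if (is.null(mask)) mask <- mesh$cortex_mask
  v <- mesh$vertices[mask, , drop = FALSE]
  mv <- map[mask]
  sites <- as.matrix(sites)
  r2 <- radius^2
  vals <- vapply(seq_len(nrow(sites)), function(s) {
    d2 <- (v[, 1] - sites[s, 1])^2 + (v[, 2] - sites[s, 2])^2 +
      (v[, 3] - sites[s, 3])^2
    inside <- d2 <= r2
    if (!any(inside)) NA_real_ else mean(mv[inside])
  }, numeric(1))
  retained <- which(!is.na(vals))
  if (!length(retained)) stop("all ROIs are empty: no masked vertex within ", radius, " mm of any site")
  list(values = vals[retained], retained = retained,
       dropped = which(is.na(vals)))
}

#' Per-donor expression-map slope
#'
#' Simple least-squares slope of a gene's expression on the map profile;
#' with both variables standardised (the default) the slope equals the
#' Pearson correlation, the quantity the decoding's random-effects test
#' aggregates across donors.
#'
#' @param profile numeric map values at the donor's retained sites.
#' @param expression numeric expression of one gene at the same sites.
#' @param standardize z-score both variables first (default TRUE).
#' @return the slope (scalar); `NA` with a warning if either variable has
#'   zero variance.
#' @export
donor_slope <- function(profile, expression, standardize = TRUE) {
  if (length(profile) < 3) stop("need >= 3 retained sites for a slope")
  if (length(profile) != length(expression)) stop("length mismatch")
  sx <- stats::sd(profile)
  sy <- stats::sd(expression)
  if (sx == 0 || sy == 0) {
    warning("zero variance: slope undefined")
    return(NA_real_)
  }
  if (standardize) {
    x <- (profile - mean(profile)) / sx
    y <- (expression - mean(expression)) / sy
  } else {
    x <- profile
    y <- expression
  }
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

z_cols <- function(m) {
  s <- apply(m, 2, stats::sd)
  s[s == 0] <- NA_real_
  scale(m, scale = s)
}

# per-donor slopes for all genes at once; gls_length NULL = OLS
donor_slopes_all <- function(mesh, map, dataset, radius, mask,
                             gls_length = NULL, jitter_tol = 1e-8) {
  purrr::map(dataset$donors, function(d) {
    prof <- sample_map_at_sites(mesh, map, d$coords, radius, mask)
    x <- prof$values
    if (stats::sd(x) == 0) {
      return(rep(NA_real_, length(dataset$genes)))
    }
    x <- as.numeric(scale(x))
    Y <- z_cols(d$expr[prof$retained, , drop = FALSE])
    if (is.null(gls_length)) {
      drop(crossprod(Y, x)) / sum(x^2)
    } else {
      co <- d$coords[prof$retained, , drop = FALSE]
      D <- as.matrix(stats::dist(co))
      V <- exp(-D / gls_length)
      L <- tryCatch(chol(V), error = function(e) {
        warning("singular site correlation matrix: jitter applied")
        chol(V + diag(jitter_tol * nrow(V)))
      })
      xt <- backsolve(L, x, transpose = TRUE)
      Yt <- backsolve(L, Y, transpose = TRUE)
      drop(crossprod(Yt, xt)) / sum(xt^2)
    }
  })
}

slopes_to_result <- function(slopes, genes, p_threshold) {
  S <- do.call(rbind, slopes)  # donors x genes
  colnames(S) <- genes
  n_valid <- colSums(!is.na(S))
  excluded <- sum(n_valid < 2)
  mean_slope <- colMeans(S, na.rm = TRUE)
  sd_slope <- apply(S, 2, stats::sd, na.rm = TRUE)
  tstat <- mean_slope / (sd_slope / sqrt(n_valid))
  degenerate <- !is.na(sd_slope) &
    sd_slope <= 1e-10 * pmax(abs(mean_slope), 1e-10) & mean_slope != 0
  tstat[degenerate] <- sign(mean_slope[degenerate]) * Inf
  p <- 2 * stats::pt(abs(tstat), df = n_valid - 1, lower.tail = FALSE)
  p[degenerate] <- .Machine$double.xmin
  res <- tibble::tibble(
    gene = genes,
    mean_slope = unname(mean_slope),
    t = unname(tstat),
    df = unname(n_valid - 1),
    p = unname(p),
    sign = dplyr::if_else(mean_slope >= 0, "pos", "neg"),
    selected = !is.na(p) & p < p_threshold & n_valid >= 2
  )
  res$selected[n_valid < 2] <- FALSE
  res$p[n_valid < 2] <- NA_real_
  attr(res, "slopes") <- S
  attr(res, "excluded") <- excluded
  attr(res, "degenerate") <- genes[degenerate]
  res
}

#' Gene-expression decoding of a statistical surface map
#'
#' The decoding procedure for a statistical map against a multi-donor
#' spatial expression dataset: the map is averaged in spherical ROIs at
#' each donor's sampling sites, each gene's (within-donor z-scored)
#' expression is regressed on the (z-scored) map profile so the per-donor
#' slope encodes the spatial correlation, and the slopes are subjected to
#' a one-sample t test across donors (`df = n_donors - 1`, two-sided).
#' Genes are selected at `p < p_threshold` and carry the sign of their
#' mean slope; both tails are of equal interest.
#'
#' Genes with fewer than 2 valid donor slopes are excluded (count in
#' attribute `excluded`). Genes whose donor slopes are identical and
#' nonzero have zero slope variance; they are flagged degenerate and
#' reported at the minimum representable p.
#'
#' @param mesh a [surf_mesh()].
#' @param map vertex-length statistical map (e.g., a t-map).
#' @param dataset an `expr_dataset` (see [simulate_donors()] /
#'   [read_expression()]).
#' @param radius ROI radius in mm (default 4).
#' @param p_threshold selection threshold (default 0.01).
#' @param mask logical vertex mask; defaults to the mesh cortex mask.
#' @return A tibble, one row per gene: `gene`, `mean_slope`, `t`, `df`,
#'   `p`, `sign`, `selected`; attribute `slopes` holds the donors x genes
#'   slope matrix.
#' @export
decode_map <- function(mesh, map, dataset, radius = 4, p_threshold = 0.01,
                       mask = NULL) {
  if (is.null(mask)) mask <- mesh$cortex_mask
  slopes <- donor_slopes_all(mesh, map, dataset, radius, mask)
  slopes_to_result(slopes, dataset$genes, p_threshold)
}

#' @rdname decode_map
#' @param length_scale exponential correlation length of the site-site
#'   error model `exp(-d / length_scale)`, mm (default 10). As
#'   `length_scale -> 0` the GLS slopes converge to the OLS slopes of
#'   [decode_map()].
#' @details `gls_decode_map()` replaces each donor's OLS slope with a
#'   generalised least-squares slope under an exponential spatial
#'   correlation model, which keeps the false-selection rate of the
#'   decoding closer to nominal when expression maps are spatially
#'   autocorrelated.
#' @export
gls_decode_map <- function(mesh, map, dataset, radius = 4, p_threshold = 0.01,
                           length_scale = 10, mask = NULL) {
  stopifnot(length_scale > 0)
  if (is.null(mask)) mask <- mesh$cortex_mask
  slopes <- donor_slopes_all(mesh, map, dataset, radius, mask,
                             gls_length = length_scale)
  slopes_to_result(slopes, dataset$genes, p_threshold)
}

#' Pairwise overlap between decoded gene lists
#'
#' Intersection sizes between named gene lists, with the percentage
#' expressed relative to the union of all listed genes (the total number
#' of genes significantly associated with any of the phenotypes).
#'
#' @param lists named list of character vectors.
#' @return A tibble: `list_a`, `list_b`, `n_a`, `n_b`, `n_overlap`,
#'   `pct_of_union` (100 * overlap / |union of all lists|).
#' @export
list_overlap <- function(lists) {
  if (length(lists) < 2) stop("need >= 2 lists")
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  lists <- lapply(lists, unique)
  uni <- unique(unlist(lists))
  if (!length(uni)) stop("empty union of gene lists")
  pairs <- utils::combn(names(lists), 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    ov <- length(intersect(lists[[pr[1]]], lists[[pr[2]]]))
    tibble::tibble(
      list_a = pr[1], list_b = pr[2],
      n_a = length(lists[[pr[1]]]), n_b = length(lists[[pr[2]]]),
      n_overlap = ov,
      pct_of_union = round(100 * ov / length(uni), 1)
    )
  }) |> dplyr::bind_rows()
}
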