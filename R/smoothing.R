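#' Surface smoothing by iterated neighbour diffusion
#'
#' Smoothing on the mesh graph approximates a geodesic Gaussian kernel of a
#' requested full width at half maximum (FWHM): each iteration moves a
#' fraction of every vertex's value along its edges, and repeated iterations
#' converge on a Gaussian by the central limit theorem. One iteration applies
#' `S = I + lambda * A^-1 (W - D)` with `A` the diagonal of barycentric
#' vertex areas, `W` the 0/1 edge adjacency, and `D` its degree diagonal.
#' Because `W` is symmetric, the area-weighted mean `sum(a_i x_i)` is
#' conserved exactly at every step, and constant maps are fixed points.
#'
#' The per-iteration spatial variance is known in closed form
#' (`lambda / a_i * sum_j h_ij^2` at vertex `i`, with `h_ij` edge lengths),
#' so the pair (number of iterations, `lambda`) is calibrated analytically to
#' total variance `(FWHM / 2.355)^2` — no empirical tuning loop.
#'
#' @param mesh a [surf_mesh()].
#' @param fwhm target kernel FWHM in mm; `0` returns the identity.
#' @param mask optional logical vertex mask; smoothing is restricted to the
#'   induced submesh, so disconnected mask components are smoothed
#'   independently and masked-out vertices are left untouched.
#' @return `smoothing_operator()`: list with the sparse one-step operator
#'   `S`, the iteration count `n_iter`, the step size `lambda`, and the
#'   per-iteration variance `step_var` (mm^2).
#' @export
smoothing_operator <- function(mesh, fwhm, mask = NULL) {
  n <- n_vertices(mesh)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(fwhm >= 0, length(mask) == n)
  idx <- which(mask)
  if (fwhm == 0 || length(idx) < 2) {
    return(list(S = Matrix::Diagonal(length(idx)), n_iter = 0L,
                lambda = 0, step_var = 0, mask = mask))
  }
  e <- mesh_edges(mesh)
  keep <- mask[e[, 1]] & mask[e[, 2]]
  e <- e[keep, , drop = FALSE]
  h2 <- edge_lengths(mesh, e)^2
  pos <- integer(n)
  pos[idx] <- seq_along(idx)
  a <- vertex_areas(mesh)[idx]
  m <- length(idx)
  W <- Matrix::sparseMatrix(
    i = c(pos[e[, 1]], pos[e[, 2]]), j = c(pos[e[, 2]], pos[e[, 1]]),
    x = 1, dims = c(m, m)
  )
  deg <- Matrix::rowSums(W)
  # per-vertex second moment of one unit-lambda step, area-normalised
  s2 <- numeric(m)
  for (cI in 1:2) {
    add <- tapply(h2, pos[e[, cI]], sum)
    at <- as.integer(names(add))
    s2[at] <- s2[at] + add
  }
  # s2/a is the full 2-D second moment of one unit-lambda step; the
  # per-axis variance that composes with the Gaussian FWHM is half of it
  cbar <- mean(s2 / a) / 2
  v_target <- (fwhm / 2.355)^2
  lambda_max <- 0.9 * min(a[deg > 0] / deg[deg > 0])
  n_iter <- max(1L, as.integer(ceiling(v_target / (lambda_max * cbar))))
  lambda <- v_target / (n_iter * cbar)
  S <- Matrix::Diagonal(m) +
    lambda * Matrix::Diagonal(x = 1 / a) %*% (W - Matrix::Diagonal(x = deg))
  list(S = S, n_iter = n_iter, lambda = lambda,
       step_var = lambda * cbar, mask = mask)
}

#' @rdname smoothing_operator
#' @param map numeric vector (one value per vertex) or matrix
#'   (vertices x maps).
#' @return `smooth_map()`: smoothed map(s), same shape as `map`.
#' @examples
#' m <- make_mesh(2)
#' x <- rnorm(n_vertices(m))
#' xs <- smooth_map(m, x, fwhm = 10)
#' @export
smooth_map <- function(mesh, map, fwhm, mask = NULL) {
  op <- smoothing_operator(mesh, fwhm, mask)
  apply_smoother(map, op)
}

apply_smoother <- function(map, op) {
  vec <- is.null(dim(map))
  x <- if (vec) matrix(map, ncol = 1) else as.matrix(map)
  if (nrow(x) != length(op$mask)) stop("map length does not match mesh")
  if (op$n_iter > 0L) {
    sub <- x[op$mask, , drop = FALSE]
    for (k in seq_len(op$n_iter)) sub <- as.matrix(op$S %*% sub)
    x[op$mask, ] <- sub
  }
  if (vec) drop(x) else x
}

#' Smooth spatially correlated Gaussian noise on a mesh
#'
#' White Gaussian noise is smoothed to the requested FWHM and each field is
#' rescaled to the requested marginal standard deviation over the masked
#' vertices. This is the noise model of the cohort simulator and of the
#' null simulations used to calibrate cluster inference. Draws come from
#' the current RNG state, so the generator is a pure function of
#' (arguments, seed).
#'
#' @inheritParams smoothing_operator
#' @param n_maps number of independent fields.
#' @param sd target marginal standard deviation of each field (map units).
#' @return numeric matrix, vertices x `n_maps`; masked-out vertices are 0.
#' @export
smooth_noise <- function(mesh, n_maps, fwhm, sd = 1, mask = NULL) {
  n <- n_vertices(mesh)
  if (is.null(mask)) mask <- rep(TRUE, n)
  op <- smoothing_operator(mesh, fwhm, mask)
  x <- matrix(0, n, n_maps)
  x[mask, ] <- stats::rnorm(sum(mask) * n_maps)
  x <- apply_smoother(x, op)
  s <- apply(x[mask, , drop = FALSE], 2, stats::sd)
  s[s == 0] <- 1
  x[mask, ] <- sweep(x[mask, , drop = FALSE], 2, sd / s, `*`)
  x
}
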