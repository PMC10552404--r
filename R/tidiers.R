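#' Tidy a vertex-wise GLM fit
#'
#' One row per (masked vertex, tested term) with the coefficient and
#' t-statistic, in the broom convention.
#'
#' @param x a [fit_glm()] result.
#' @param ... unused.
#' @return tibble: `vertex`, `term`, `estimate`, `statistic`.
#' @export
tidy.surf_glm <- function(x, ...) {
  vs <- which(x$mask)
  purrr::imap(x$tstat, function(tv, term) {
    cn <- design_term_cols(x$design, term)
    tibble::tibble(
      vertex = vs,
      term = term,
      estimate = unname(x$coef[cn, ]),
      statistic = tv[vs]
    )
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.surf_glm
#' @export
glance.surf_glm <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$data),
    n_vertices = ncol(x$data),
    df_residual = x$df_residual,
    n_terms_tested = length(x$tstat),
    n_degenerate = length(x$degenerate)
  )
}

#' Tidy a smoothness estimate
#' @param x an [estimate_smoothness()] result.
#' @param ... unused.
#' @return one-row tibble: `fwhm`, `resels_0/1/2`, `total_area`.
#' @export
glance.smoothness <- function(x, ...) {
  tibble::tibble(
    fwhm = x$fwhm,
    resels_0 = unname(x$resels["R0"]),
    resels_1 = unname(x$resels["R1"]),
    resels_2 = unname(x$resels["R2"]),
    total_area = x$total_area
  )
}

map_to_latlon <- function(mesh, map) {
  v <- mesh$vertices
  r <- sqrt(rowSums(v^2))
  tibble::tibble(
    lon = atan2(v[, 2], v[, 1]) * 180 / pi,
    lat = asin(pmin(1, pmax(-1, v[, 3] / r))) * 180 / pi,
    value = map,
    cortex = mesh$cortex_mask
  )
}

#' Plot a vertex map as a longitude-latitude projection
#'
#' A quick-look flat projection of a spherical surface map; masked-out
#' vertices are drawn grey.
#'
#' @param mesh a [surf_mesh()].
#' @param map vertex-length numeric map.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_vertex_map <- function(mesh, map, title = NULL) {
  df <- map_to_latlon(mesh, map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_point(data = df[!df$cortex, ], colour = "grey80", size = 0.6) +
    ggplot2::geom_point(data = df[df$cortex, ],
                        ggplot2::aes(colour = .data$value), size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey95",
                                    high = "#b2182b") +
    ggplot2::labs(title = title, x = "longitude", y = "latitude",
                  colour = "value") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot.surf_glm()` draws the t-map of one tested term as a flat
#' projection (requires the mesh the fit was made on).
#'
#' @param object the fitted object.
#' @param mesh the [surf_mesh()] the maps live on.
#' @param term term name (default: first tested term).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.surf_glm <- function(object, mesh, term = names(object$tstat)[1], ...) {
  plot_vertex_map(mesh, object$tstat[[term]],
                  title = paste0("t-map: ", term,
                                 " (df = ", object$df_residual, ")"))
}

#' Enrichment odds-ratio panel
#'
#' Dot plot of enrichment odds ratios per (decoded list, gene set), sized
#' by overlap and marked when FDR-significant.
#'
#' @param enrichment result of [enrich_all()].
#' @return a ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$list, y = .data$set)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                     colour = log2(pmax(.data$odds_ratio, 1e-3)))) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$significant),
                        shape = 0, size = 6, colour = "red") +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey90",
                                    high = "#b2182b") +
    ggplot2::labs(x = "decoded list", y = "gene set",
                  colour = "log2 OR", size = "overlap") +
    ggplot2::theme_minimal()
}

#' Decoding volcano plot
#'
#' Mean spatial slope against -log10 p per gene, with the selection
#' threshold drawn.
#'
#' @param decoding result of [decode_map()] / [gls_decode_map()].
#' @param p_threshold selection threshold line (default 0.01).
#' @return a ggplot object.
#' @export
plot_decoding <- function(decoding, p_threshold = 0.01) {
  ggplot2::ggplot(decoding,
                  ggplot2::aes(x = .data$mean_slope,
                               y = -log10(pmax(.data$p, 1e-300)),
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "mean donor slope (spatial correlation)",
                  y = "-log10 p", colour = "selected") +
    ggplot2::theme_minimal()
}
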