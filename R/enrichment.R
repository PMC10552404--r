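#' Hypergeometric gene-set enrichment of one list against one set
#'
#' Tests whether a decoded gene list overlaps a gene set more than chance
#' given a finite background universe: with `N = background_n` genes,
#' `n = |list|`, `m = |set|`, and observed overlap `k`, the p-value is the
#' upper-tail hypergeometric probability `P(X >= k)`, and the odds ratio
#' is the sample contingency OR
#' `k (N - n - m + k) / ((n - k)(m - k))` (infinite when a zero cell makes
#' the denominator vanish; the optional Haldane correction adds 0.5 to
#' every cell instead). Genes outside the universe implied by
#' `background_n` are assumed already dropped; the function checks only
#' that the background can hold the union.
#'
#' @param list_genes character vector, the decoded gene list.
#' @param set_genes character vector, the gene set.
#' @param background_n size of the background universe (default 20787).
#' @param haldane apply the Haldane 0.5 correction to the odds ratio
#'   (default FALSE).
#' @return A one-row tibble: `n` (list size), `m` (set size), `k`
#'   (overlap), `background`, `odds_ratio`, `p`.
#' @export
hypergeom_enrich <- function(list_genes, set_genes, background_n = 20787,
                             haldane = FALSE) {
  list_genes <- unique(list_genes)
  set_genes <- unique(set_genes)
  n <- length(list_genes)
  m <- length(set_genes)
  k <- length(intersect(list_genes, set_genes))
  if (background_n < length(union(list_genes, set_genes))) {
    stop("background_n smaller than |list union set|")
  }
  N <- background_n
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  or <- if (haldane) {
    ((k + 0.5) * (N - n - m + k + 0.5)) / ((n - k + 0.5) * (m - k + 0.5))
  } else if ((n - k) == 0 || (m - k) == 0) {
    Inf
  } else {
    (k * (N - n - m + k)) / ((n - k) * (m - k))
  }
  tibble::tibble(n = n, m = m, k = k, background = N,
                 odds_ratio = or, p = p)
}

#' Enrichment of decoded lists across gene-set collections, with BH-FDR
#'
#' Runs [hypergeom_enrich()] for every (list, set) pair and applies
#' Benjamini-Hochberg FDR correction. The FDR family defaults to the set
#' tests within each decoded list (`family = "per_list"`); a global family
#' across all pairs is available as a switch.
#'
#' @param lists named list of decoded gene lists (character vectors).
#' @param sets named list of gene sets, or a `gene_sets` object.
#' @param background_n background universe size (default 20787).
#' @param alpha FDR significance threshold (default 0.05).
#' @param family `"per_list"` (default) or `"global"`.
#' @param haldane passed to [hypergeom_enrich()].
#' @return A tibble, one row per (list, set): `list`, `set`, `n`, `m`,
#'   `k`, `odds_ratio`, `p`, `q`, `significant`.
#' @export
enrich_all <- function(lists, sets, background_n = 20787, alpha = 0.05,
                       family = c("per_list", "global"), haldane = FALSE) {
  family <- match.arg(family)
  if (inherits(sets, "gene_sets")) sets <- sets$sets
  if (!length(lists) || !length(sets)) stop("need >= 1 list and >= 1 set")
  if (is.null(names(lists))) names(lists) <- paste0("list", seq_along(lists))
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  res <- purrr::imap(lists, function(lg, ln) {
    purrr::imap(sets, function(sg, sn) {
      dplyr::bind_cols(
        tibble::tibble(list = ln, set = sn),
        hypergeom_enrich(lg, sg, background_n, haldane)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  res <- if (family == "per_list") {
    res |>
      dplyr::group_by(.data$list) |>
      dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(res, q = stats::p.adjust(.data$p, method = "BH"))
  }
  dplyr::mutate(res, significant = .data$q < alpha)
}
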