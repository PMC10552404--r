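#' Read and write GMT gene-set files
#'
#' Tab-separated GMT lines: set name, description, then member genes.
#' Duplicate genes within a set are removed; empty sets (fewer than three
#' fields) raise an error naming the line; an empty file yields an empty
#' collection with a warning.
#'
#' @param path GMT file path.
#' @return `read_gene_sets()`: a `gene_sets` object (universe = union of
#'   all members).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(sets = list(), universe = character()),
                     class = "gene_sets"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("%s: line %d has %d field(s); GMT needs name, description, genes...",
                   path, i, length(f)))
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  structure(list(sets = sets, universe = unique(unlist(sets))),
            class = "gene_sets")
}

#' @rdname read_gene_sets
#' @param sets a `gene_sets` object or named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_sets")) sets <- sets$sets
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, descriptions[[match(nm, names(sets))]], g), collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read and write per-vertex map tables
#'
#' Tab-separated tables with one row per vertex and one named column per
#' map (ct, sa, tstat_asd, ...). A leading comment line
#' `# n_vertices=<N> index_base=0` records the vertex count (checked
#' against the mesh on read) and the 0-based file index convention.
#'
#' @param maps numeric matrix (vertices x maps) or vector; column names
#'   name the maps.
#' @param path TSV path.
#' @return `read_vertex_maps()`: numeric matrix, vertices x maps.
#' @export
write_vertex_maps <- function(maps, path) {
  if (is.null(dim(maps))) maps <- matrix(maps, ncol = 1, dimnames = list(NULL, "map"))
  if (is.null(colnames(maps))) colnames(maps) <- paste0("map", seq_len(ncol(maps)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_vertices=%d index_base=0", nrow(maps)), con)
  utils::write.table(maps, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vertex_maps
#' @param expect_vertices optional vertex count to validate against (e.g.,
#'   `n_vertices(mesh)`).
#' @export
read_vertex_maps <- function(path, expect_vertices = NULL) {
  if (!file.exists(path)) stop("vertex map file not found: ", path)
  first <- readLines(path, n = 1)
  declared <- NA_integer_
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("n_vertices=(\\d+)", first))[[1]]
    if (length(m) == 2) declared <- as.integer(m[2])
  }
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  x <- as.matrix(x)
  if (!is.na(declared) && nrow(x) != declared) {
    stop(path, ": header declares ", declared, " vertices but table has ", nrow(x))
  }
  if (!is.null(expect_vertices) && nrow(x) != expect_vertices) {
    stop(path, ": expected ", expect_vertices, " vertices, found ", nrow(x))
  }
  x
}

#' Read and write phenotype tables
#'
#' Plain TSV with the subject table columns (`subject_id`, `asd`, `adhd`,
#' `sex`, `age`, `fsiq`, `site`, `global_measure`, ...).
#'
#' @param subjects phenotype tibble.
#' @param path TSV path.
#' @export
write_phenotypes <- function(subjects, path) {
  readr::write_tsv(subjects, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read and write multi-donor expression datasets
#'
#' A dataset directory holds, per donor, `<donor>_coords.tsv` (columns
#' x/y/z, mm, mesh space) and `<donor>_expr.tsv` (sites x genes, named
#' columns), plus `genes.txt` (the shared gene order) and `meta.json`
#' (`normalized` flag).
#'
#' @param dataset an `expr_dataset`.
#' @param dir directory path (created if needed).
#' @export
write_expression <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$donors)) {
    d <- dataset$donors[[i]]
    nm <- sprintf("donor%02d", i)
    co <- as.data.frame(d$coords)
    names(co) <- c("x", "y", "z")
    readr::write_tsv(co, file.path(dir, paste0(nm, "_coords.tsv")))
    ex <- as.data.frame(d$expr)
    names(ex) <- dataset$genes
    readr::write_tsv(ex, file.path(dir, paste0(nm, "_expr.tsv")))
  }
  writeLines(dataset$genes, file.path(dir, "genes.txt"))
  jsonlite::write_json(list(normalized = dataset$normalized,
                            n_donors = length(dataset$donors)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  if (!dir.exists(dir)) stop("expression directory not found: ", dir)
  genes <- readLines(file.path(dir, "genes.txt"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  coord_files <- sort(list.files(dir, "_coords\\.tsv$", full.names = TRUE))
  donors <- purrr::map(coord_files, function(cf) {
    ef <- sub("_coords\\.tsv$", "_expr.tsv", cf)
    co <- as.matrix(readr::read_tsv(cf, show_col_types = FALSE))
    ex <- as.matrix(readr::read_tsv(ef, show_col_types = FALSE))
    if (!identical(colnames(ex), genes)) stop(ef, ": gene columns differ from genes.txt")
    list(coords = co, expr = ex)
  })
  structure(list(donors = donors, genes = genes,
                 normalized = isTRUE(meta$normalized)),
            class = "expr_dataset")
}

#' Pipeline run configuration
#'
#' Collects the thresholds and stage parameters of a pipeline run with
#' their defaults: 15-mm smoothing, cluster-forming and cluster-level
#' p < 0.05 (two-tailed), 4-mm decoding ROIs, a liberal decoding selection
#' threshold of p < 0.01 (both tails), and a background universe of 20787
#' genes for enrichment.
#'
#' @param seed integer RNG seed for all stochastic stages.
#' @param smoothing_fwhm smoothing kernel FWHM, mm (>= 0).
#' @param cluster_alpha cluster-forming/cluster-level threshold in (0,1),
#'   two-tailed.
#' @param roi_radius decoding ROI radius, mm (> 0).
#' @param decode_p decoding selection threshold in (0,1).
#' @param background_n enrichment background universe size.
#' @param enrich_alpha FDR threshold for enrichment significance.
#' @param mesh_subdivisions icosphere subdivisions for simulated meshes.
#' @param n_donors,n_sites expression simulation dimensions.
#' @param n_genes simulated gene count (a fifth are spatially coupled).
#' @param stages character vector of stages to run, in order.
#' @param paths named list of input paths used when `"simulate"` is not in
#'   `stages` (`mesh`, `phenotypes`, `maps`, `expression`, `gene_sets`).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       smoothing_fwhm = 15,
                       cluster_alpha = 0.05,
                       roi_radius = 4,
                       decode_p = 0.01,
                       background_n = 20787,
                       enrich_alpha = 0.05,
                       mesh_subdivisions = 3,
                       n_donors = 6,
                       n_sites = 300,
                       n_genes = 120,
                       stages = c("simulate", "demographics", "glm", "rft",
                                  "decode", "enrich"),
                       paths = list()) {
  for (p in c(cluster_alpha, decode_p, enrich_alpha)) {
    if (!(p > 0 && p < 1)) stop("probabilities must be in (0, 1)")
  }
  if (smoothing_fwhm < 0) stop("smoothing_fwhm must be >= 0")
  if (roi_radius <= 0) stop("roi_radius must be > 0")
  structure(
    list(seed = as.integer(seed), smoothing_fwhm = smoothing_fwhm,
         cluster_alpha = cluster_alpha, roi_radius = roi_radius,
         decode_p = decode_p, background_n = background_n,
         enrich_alpha = enrich_alpha,
         mesh_subdivisions = mesh_subdivisions,
         n_donors = n_donors, n_sites = n_sites, n_genes = n_genes,
         stages = stages, paths = paths),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path flat key-value YAML-subset config file (`key: value` lines,
#'   `stages` as a comma-separated list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'")
    kv[[m[2]]] <- trimws(m[3])
  }
  args <- list()
  num_keys <- c("seed", "smoothing_fwhm", "cluster_alpha", "roi_radius",
                "decode_p", "background_n", "enrich_alpha",
                "mesh_subdivisions", "n_donors", "n_sites", "n_genes")
  for (k in intersect(names(kv), num_keys)) args[[k]] <- as.numeric(kv[[k]])
  if ("stages" %in% names(kv)) {
    args$stages <- trimws(strsplit(kv$stages, ",")[[1]])
  }
  path_keys <- c("mesh", "phenotypes", "maps", "expression", "gene_sets")
  pk <- intersect(names(kv), path_keys)
  if (length(pk)) args$paths <- kv[pk]
  do.call(run_config, args)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, demographics, glm,
#' rft, decode, enrich — writing each stage's outputs as delimited text
#' plus JSON summaries under `out_dir`, and a `manifest.json` recording
#' the seed, thresholds, package version, and completed stages. With the
#' same config and seed, all outputs are bit-identical. Progress is
#' logged to stderr with stage tags.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("surfgene")),
                   thresholds = list(smoothing_fwhm = config$smoothing_fwhm,
                                     cluster_alpha = config$cluster_alpha,
                                     roi_radius = config$roi_radius,
                                     decode_p = config$decode_p,
                                     background_n = config$background_n,
                                     enrich_alpha = config$enrich_alpha),
                   stages = character())
  st <- config$stages
  mesh <- NULL; subjects <- NULL; maps <- NULL
  expr <- NULL; gsets <- NULL; truth <- list()

  if ("simulate" %in% st) {
    log_stage("simulate", "generating mesh, cohort, expression, gene sets")
    mesh <- make_mesh(config$mesh_subdivisions)
    ctr <- which(mesh$cortex_mask)
    disc1 <- effect_disc(mesh, ctr[10], 25)
    disc2 <- effect_disc(mesh, ctr[length(ctr) %/% 2], 25)
    disc3 <- effect_disc(mesh, ctr[length(ctr) - 10], 25)
    effects <- list(
      asd = list(pattern = disc1, amplitude = 0.08),
      adhd = list(pattern = disc2, amplitude = -0.08),
      interaction = list(pattern = disc3, amplitude = 0.1)
    )
    sim <- simulate_cohort(mesh, effects = effects,
                           noise_fwhm = config$smoothing_fwhm)
    subjects <- sim$subjects
    maps <- sim$maps
    n_coupled <- max(2, config$n_genes %/% 5)
    rho <- stats::setNames(
      c(rep(0.8, n_coupled), rep(0, config$n_genes - n_coupled)),
      sprintf("G%05d", seq_len(config$n_genes))
    )
    expr <- simulate_donors(mesh, disc3, rho, n_donors = config$n_donors,
                            n_samples = config$n_sites)
    truth$coupled_genes <- names(rho)[rho != 0]
    gsets <- make_gene_sets(
      universe_n = config$background_n,
      set_sizes = c(planted = 50, null1 = 50, null2 = 80),
      planted = c(planted = 0.4),
      target_list = truth$coupled_genes
    )
    write_mesh(mesh, file.path(out_dir, "mesh.ply"))
    write_phenotypes(subjects, file.path(out_dir, "phenotypes.tsv"))
    write_vertex_maps(maps, file.path(out_dir, "subject_maps.tsv"))
    write_expression(expr, file.path(out_dir, "expression"))
    write_gene_sets(gsets, file.path(out_dir, "gene_sets.gmt"))
    manifest$stages <- c(manifest$stages, "simulate")
  } else {
    p <- config$paths
    need <- c("mesh", "phenotypes", "maps")
    if ("decode" %in% st) need <- c(need, "expression")
    if ("enrich" %in% st) need <- c(need, "gene_sets")
    for (k in need) {
      if (is.null(p[[k]])) stop("config lacks input path '", k, "'")
      if (!file.exists(p[[k]]) && !dir.exists(p[[k]])) {
        stop("missing input for stage(s) ", paste(st, collapse = "/"),
             ": ", p[[k]])
      }
    }
    mesh <- read_mesh(p$mesh)
    subjects <- read_phenotypes(p$phenotypes)
    maps <- read_vertex_maps(p$maps, expect_vertices = n_vertices(mesh))
    if ("decode" %in% st) expr <- read_expression(p$expression)
    if ("enrich" %in% st) gsets <- read_gene_sets(p$gene_sets)
  }

  if ("demographics" %in% st) {
    log_stage("demographics", "group comparison statistics")
    demo <- compare_groups(subjects)
    readr::write_tsv(demo, file.path(out_dir, "demographics.tsv"))
    manifest$stages <- c(manifest$stages, "demographics")
  }

  fit <- NULL
  if (any(c("glm", "rft", "decode") %in% st)) {
    log_stage("glm", "vertex-wise factorial model")
    design <- build_design(subjects)
    fit <- fit_glm(maps, design, mask = mesh$cortex_mask)
    tmaps <- do.call(cbind, fit$tstat)
    colnames(tmaps) <- paste0("tstat_", names(fit$tstat))
    write_vertex_maps(tmaps, file.path(out_dir, "tmaps.tsv"))
    fmaps <- vapply(names(fit$tstat), function(tm) cohens_f(fit, tm),
                    numeric(n_vertices(mesh)))
    colnames(fmaps) <- paste0("cohens_f_", names(fit$tstat))
    write_vertex_maps(fmaps, file.path(out_dir, "effect_sizes.tsv"))
    jsonlite::write_json(
      list(n_subjects = nrow(subjects), df_residual = fit$df_residual,
           terms = names(fit$tstat)),
      file.path(out_dir, "glm_summary.json"), auto_unbox = TRUE
    )
    manifest$stages <- c(manifest$stages, "glm")
  }

  if ("rft" %in% st) {
    log_stage("rft", "cluster-corrected inference")
    cl <- purrr::map(names(fit$tstat), function(tm) {
      tab <- rft_cluster_table(fit, tm, mesh, alpha = config$cluster_alpha)
      if (nrow(tab)) dplyr::mutate(tab, term = tm, .before = 1) else NULL
    }) |> dplyr::bind_rows()
    if (nrow(cl)) cl$members <- NULL
    readr::write_tsv(cl, file.path(out_dir, "clusters.tsv"))
    manifest$stages <- c(manifest$stages, "rft")
  }

  decoded <- list()
  if ("decode" %in% st) {
    log_stage("decode", "spatial expression decoding of t-maps")
    for (tm in names(fit$tstat)) {
      dec <- decode_map(mesh, fit$tstat[[tm]], expr,
                        radius = config$roi_radius,
                        p_threshold = config$decode_p)
      readr::write_tsv(dec, file.path(out_dir, paste0("decoded_", tm, ".tsv")))
      decoded[[tm]] <- dec$gene[dec$selected]
    }
    ov <- tryCatch(list_overlap(decoded), error = function(e) NULL)
    if (!is.null(ov)) readr::write_tsv(ov, file.path(out_dir, "list_overlap.tsv"))
    manifest$stages <- c(manifest$stages, "decode")
  }

  if ("enrich" %in% st) {
    log_stage("enrich", "hypergeometric gene-set enrichment")
    if (!length(decoded)) stop("enrich stage needs decoded gene lists (enable decode)")
    nonempty <- decoded[lengths(decoded) > 0]
    if (length(nonempty)) {
      enr <- enrich_all(nonempty, gsets, background_n = config$background_n,
                        alpha = config$enrich_alpha)
      readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    }
    manifest$stages <- c(manifest$stages, "enrich")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
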