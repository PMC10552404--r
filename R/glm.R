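#' Design matrix for the factorial surface model
#'
#' Builds the treatment-coded design of the vertex-wise model
#' `Y = b0 + b1 ASD + b2 ADHD + b3 ASD*ADHD + b4 Sex + b5 Age + b6 Age^2
#'  + b7 FSIQ + b8 Site + b9 Global + e`:
#' 0/1 indicators for ASD, ADHD and male sex (reference = typically
#' developing, female), their product as the interaction column, mean-centred
#' continuous covariates (the quadratic age term is the square of centred
#' age, itself re-centred, which reduces collinearity), and k-1 site
#' dummies against the first site level.
#'
#' With `model = "group"` the ASD-subset design is built instead:
#' `Y = b0 + b1 Group + Sex + Age + Age^2 + FSIQ + Site + Global + e`,
#' where Group is ADHD status within the ASD-only sample.
#'
#' @param subjects phenotype tibble with columns `asd`, `adhd`, `sex`,
#'   `age`, `fsiq`, `site`, `global_measure`.
#' @param model `"factorial"` (default) or `"group"` (ASD subset, Group =
#'   ADHD status).
#' @param include_interaction include the ASD-by-ADHD product column
#'   (factorial model only; default TRUE).
#' @param center mean-centre continuous covariates (default TRUE).
#' @return An object of class `surf_design`: the numeric design matrix with
#'   named columns, plus attributes `terms` (term -> column names) and
#'   `centers` (the subtracted means).
#' @export
build_design <- function(subjects, model = c("factorial", "group"),
                         include_interaction = TRUE, center = TRUE) {
  model <- match.arg(model)
  need <- c("asd", "adhd", "sex", "age", "fsiq", "site", "global_measure")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subjects lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(subjects)
  asd <- as.numeric(subjects$asd)
  adhd <- as.numeric(subjects$adhd)
  if (model == "factorial" && include_interaction) {
    cells <- table(factor(asd, c(0, 1)), factor(adhd, c(0, 1)))
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "empty factorial cell (asd=%d, adhd=%d): interaction not estimable",
        empty[1] - 1, empty[2] - 1
      ))
    }
  }
  ctr <- function(x) if (center) x - mean(x) else x
  centers <- c(age = if (center) mean(subjects$age) else 0,
               fsiq = if (center) mean(subjects$fsiq) else 0,
               global = if (center) mean(subjects$global_measure) else 0)
  age_c <- ctr(subjects$age)
  cols <- list(intercept = rep(1, n))
  terms <- list(intercept = "intercept")
  if (model == "factorial") {
    cols$asd <- asd
    cols$adhd <- adhd
    terms$asd <- "asd"
    terms$adhd <- "adhd"
    if (include_interaction) {
      cols$interaction <- asd * adhd
      terms$interaction <- "interaction"
    }
  } else {
    if (!all(asd == 1)) stop("group model expects an ASD-only subset (asd == 1)")
    if (length(unique(adhd)) < 2) stop("both ADHD subgroups must be nonempty in the subset")
    cols$group <- adhd
    terms$group <- "group"
  }
  cols$sex_male <- as.numeric(subjects$sex == "male")
  cols$age <- age_c
  cols$age2 <- ctr(age_c^2)
  cols$fsiq <- ctr(subjects$fsiq)
  terms$sex <- "sex_male"
  terms$age <- "age"
  terms$age2 <- "age2"
  terms$fsiq <- "fsiq"
  site <- factor(subjects$site)
  if (nlevels(site) > 1) {
    sd_cols <- stats::model.matrix(~site)[, -1, drop = FALSE]
    colnames(sd_cols) <- paste0("site_", levels(site)[-1])
    for (cn in colnames(sd_cols)) cols[[cn]] <- sd_cols[, cn]
    terms$site <- colnames(sd_cols)
  }
  cols$global <- ctr(subjects$global_measure)
  terms$global <- "global"
  X <- do.call(cbind, cols)
  if (nrow(X) >= ncol(X) && qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient")
  }
  structure(X, class = c("surf_design", class(X)),
            terms = terms, centers = centers)
}

design_term_cols <- function(design, term) {
  terms <- attr(design, "terms")
  if (!term %in% names(terms)) {
    stop("term '", term, "' not in design (have: ",
         paste(names(terms), collapse = ", "), ")")
  }
  terms[[term]]
}

#' Vertex-wise ordinary least squares
#'
#' Fits the design to every masked vertex by OLS and returns per-term
#' t-statistic maps, retaining residuals (for smoothness estimation) and
#' the data (for effect-size refits). Vertices with zero residual variance
#' are flagged degenerate and carry `NA` t-statistics.
#'
#' @param maps matrix of per-subject vertex maps (vertices x subjects).
#' @param design a [build_design()] matrix.
#' @param terms_to_test character vector of term names to return t-maps
#'   for (default: the group terms present).
#' @param mask optional logical vertex mask (default: all vertices).
#' @return An object of class `surf_glm`: list with `coef` (terms x
#'   vertices, masked vertices only), `tstat` (named list of vertex-length
#'   t-maps, `NA` off-mask), `residuals` (masked vertices x subjects),
#'   `df_residual`, `sigma2`, `mask`, `design`, `data` (masked maps),
#'   `degenerate` (vertex indices).
#' @export
fit_glm <- function(maps, design, terms_to_test = NULL, mask = NULL) {
  maps <- as.matrix(maps)
  X <- unclass(design)
  n <- nrow(X)
  if (ncol(maps) != n) stop("maps must have one column per design row")
  nv <- nrow(maps)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  if (is.null(terms_to_test)) {
    terms_to_test <- intersect(c("asd", "adhd", "interaction", "group"),
                               names(attr(design, "terms")))
  }
  Y <- t(maps[mask, , drop = FALSE])  # subjects x masked vertices
  if (!all(is.finite(Y))) {
    bad <- which(mask)[!apply(is.finite(Y), 2, all)]
    stop("non-finite map values inside mask at vertices: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  p <- ncol(X)
  if (n <= p) stop("need more subjects than design columns")
  qrx <- qr(X)
  coef <- qr.coef(qrx, Y)                 # p x Vm
  res <- Y - X %*% coef                   # n x Vm
  df <- n - qrx$rank
  sse <- colSums(res^2)
  sigma2 <- sse / df
  xtx_inv <- solve(crossprod(X))
  rownames(xtx_inv) <- colnames(xtx_inv) <- colnames(X)
  degen <- sigma2 <= 1e-12 * pmax(colSums(Y^2) / n, 1e-300)
  degenerate <- which(mask)[degen]
  tstat <- lapply(terms_to_test, function(term) {
    cn <- design_term_cols(design, term)
    if (length(cn) > 1) {
      stop("t-maps are defined for single-column terms; '", term,
           "' spans ", length(cn), " columns")
    }
    se <- sqrt(sigma2 * xtx_inv[cn, cn])
    tv <- rep(NA_real_, nv)
    tm <- coef[cn, ] / se
    tm[se == 0 | degen] <- NA_real_  # perfect fits: t formally infinite
    tv[mask] <- tm
    tv
  })
  names(tstat) <- terms_to_test
  structure(
    list(coef = coef, tstat = tstat, residuals = t(res),
         df_residual = df, sigma2 = sigma2, mask = mask,
         design = design, data = Y, degenerate = degenerate),
    class = "surf_glm"
  )
}

#' @export
print.surf_glm <- function(x, ...) {
  cat(sprintf(
    "<surf_glm> %d subjects, %d masked vertices, df_residual = %d, t-maps: %s\n",
    nrow(x$data), ncol(x$data), x$df_residual,
    paste(names(x$tstat), collapse = ", ")
  ))
  invisible(x)
}

#' ASD-subset model: ADHD effect within autistic participants
#'
#' Restricts the cohort to `asd == 1`, builds the group design (Group =
#' ADHD status plus the usual covariates) and fits it; the contract is
#' otherwise identical to [fit_glm()].
#'
#' @inheritParams fit_glm
#' @param subjects the full phenotype tibble; rows with `asd == 1` are used.
#' @return A `surf_glm` with a `"group"` t-map.
#' @export
fit_asd_subset <- function(maps, subjects, mask = NULL) {
  keep <- subjects$asd == 1
  if (!any(keep)) stop("no ASD participants in the table")
  sub <- subjects[keep, , drop = FALSE]
  if (length(unique(sub$adhd)) < 2) {
    stop("both ADHD subgroups must be nonempty within the ASD subset")
  }
  design <- build_design(sub, model = "group")
  fit_glm(maps[, keep, drop = FALSE], design, terms_to_test = "group",
          mask = mask)
}

#' Cohen's f effect-size map for a model term
#'
#' `f = sqrt((R2_full - R2_reduced) / (1 - R2_full))` per vertex, where the
#' reduced model drops the term's column(s) and is refit to the stored data.
#' Conventional benchmarks: 0.25 small, 0.5 medium, 0.75 large.
#'
#' @param fit a [fit_glm()] result.
#' @param term term name in the fit's design.
#' @return numeric vertex-length map of f (`NA` off-mask or where
#'   `R2_full = 1`, flagged via attribute `degenerate`).
#' @export
cohens_f <- function(fit, term) {
  X <- unclass(fit$design)
  cn <- design_term_cols(fit$design, term)
  Y <- fit$data
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  sse_full <- rowSums(fit$residuals^2) # residuals are Vm x n
  Xr <- X[, setdiff(colnames(X), cn), drop = FALSE]
  res_r <- Y - Xr %*% qr.coef(qr(Xr), Y)
  sse_red <- colSums(res_r^2)
  r2f <- 1 - sse_full / sst
  r2r <- 1 - sse_red / sst
  degen <- sse_full <= 1e-12 * pmax(sst, 1e-300)
  fval <- sqrt(pmax(r2f - r2r, 0) / (1 - r2f))
  fval[degen] <- NA_real_
  out <- rep(NA_real_, length(fit$mask))
  out[fit$mask] <- fval
  attr(out, "degenerate") <- which(fit$mask)[degen]
  out
}

#' @rdname cohens_f
#' @param f numeric Cohen's f values.
#' @return `cohens_f_label()`: factor with levels negligible/small/medium/
#'   large (cuts at 0.25, 0.5, 0.75).
#' @export
cohens_f_label <- function(f) {
  cut(f, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE)
}

#' ComBat-style site harmonisation of vertex maps
#'
#' Removes additive and multiplicative site (batch) effects from
#' per-subject vertex maps by parametric empirical-Bayes location/scale
#' adjustment (delegated to `sva::ComBat`), preserving the biological
#' covariate effects supplied in `design`. Vertices with zero variance
#' across subjects (e.g., masked-out rows) pass through unchanged.
#'
#' @param maps matrix, vertices x subjects.
#' @param batch site labels, one per subject (>= 2 batches, each >= 2
#'   subjects; a single batch returns the input with a warning).
#' @param design optional numeric matrix of biological covariates to
#'   preserve (no intercept needed; e.g., group indicator columns).
#' @return adjusted maps, same shape.
#' @export
combat_adjust <- function(maps, batch, design = NULL) {
  maps <- as.matrix(maps)
  batch <- as.factor(batch)
  if (length(batch) != ncol(maps)) stop("one batch label per subject required")
  if (nlevels(batch) < 2) {
    warning("single batch: returning maps unchanged")
    return(maps)
  }
  if (any(table(batch) < 2)) stop("every batch needs >= 2 subjects")
  keep <- apply(maps, 1, stats::var) > 0
  mod <- if (is.null(design)) NULL else cbind(1, as.matrix(design))
  adj <- maps
  adj[keep, ] <- suppressMessages(
    sva::ComBat(dat = maps[keep, , drop = FALSE], batch = batch, mod = mod)
  )
  adj
}
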