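# Small meshes and cohorts built in code for the tests.

# regular tetrahedron (smallest closed triangulation)
tetrahedron_mesh <- function(scale = 1) {
  v <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  ) * scale
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  surf_mesh(v, f)
}

tetrahedron_off_lines <- function() {
  c(
    "OFF",
    "4 4 0",
    "1 1 1", "1 -1 -1", "-1 1 -1", "-1 -1 1",
    "3 0 1 2", "3 0 3 1", "3 0 2 3", "3 1 3 2"
  )
}

# balanced small factorial cohort for design/fit tests
balanced_cohort <- function(n_per_cell = 5, n_sites = 2, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(asd = 0:1, adhd = 0:1)
  subjects <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(
      asd = grid$asd[i], adhd = grid$adhd[i],
      sex = sample(c("male", "female"), n_per_cell, replace = TRUE),
      age = runif(n_per_cell, 8, 30),
      fsiq = rnorm(n_per_cell, 100, 15),
      global_measure = rnorm(n_per_cell, 2.7, 0.1)
    )
  }))
  n <- nrow(subjects)
  subjects$site <- paste0("site", ((seq_len(n) - 1L) %% n_sites) + 1L)
  subjects$subject_id <- sprintf("sub-%03d", seq_len(n))
  tibble::as_tibble(subjects)
}

# brute-force connected components by flood fill over mesh edges
flood_fill_clusters <- function(mesh, in_set) {
  e <- mesh_edges(mesh)
  nbrs <- vector("list", n_vertices(mesh))
  for (r in seq_len(nrow(e))) {
    nbrs[[e[r, 1]]] <- c(nbrs[[e[r, 1]]], e[r, 2])
    nbrs[[e[r, 2]]] <- c(nbrs[[e[r, 2]]], e[r, 1])
  }
  seen <- logical(n_vertices(mesh))
  comps <- list()
  for (v in which(in_set)) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    members <- integer()
    while (length(queue)) {
      x <- queue[1]
      queue <- queue[-1]
      members <- c(members, x)
      for (w in nbrs[[x]]) {
        if (in_set[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# construct raw data with exactly the requested n, mean, sd per group
data_matching_summary <- function(n, mean, sd) {
  lapply(seq_along(n), function(i) {
    x <- seq_len(n[i])
    x <- (x - base::mean(x)) / stats::sd(x)
    x * sd[i] + mean[i]
  })
}

# exact upper-tail hypergeometric by enumeration over overlap counts
hypergeom_tail_enum <- function(k, m, n, N) {
  kk <- k:min(m, n)
  sum(choose(m, kk) * choose(N - m, n - kk)) / choose(N, n)
}
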