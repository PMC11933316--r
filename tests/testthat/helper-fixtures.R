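# Shared fixtures and the independent grid-search oracle.

# Tiny two-sample design: one baseline, one condition contrast.
toy_design <- function(cond = "DAC_D2", n_base = 1L, n_cond = 1L) {
  samples <- c(sprintf("REP1_BASE_D0_%d", seq_len(n_base)),
               sprintf("REP1_COND_%d", seq_len(n_cond)))
  D <- matrix(0, n_base + n_cond, 1, dimnames = list(samples, cond))
  D[n_base + seq_len(n_cond), 1] <- 1
  D
}

# Small simulated screen shared across tests (cheap: 40 genes).
small_screen <- function(seed = 11L, frac_resist = 0, frac_sens = 0,
                         effect_size = 0, n_genes = 40L, depth = 5e4) {
  lib <- make_library(n_genes, 4L, 10L)
  truth <- draw_effects(lib, frac_resist, frac_sens, effect_size,
                        seed = seed)
  cfg <- sim_config(n_genes = n_genes, sgrnas_per_gene = 4L, n_ntc = 10L,
                    depth_per_sample = depth, seed = seed)
  list(lib = lib, truth = truth, cfg = cfg,
       counts = simulate_screen(lib, truth, cfg))
}

# Exhaustive profile-likelihood oracle for a single-condition gene fit.
# For every beta on the grid, each per-guide baseline is profiled out by
# bisection on the score function sum_r (k - mu) / (1 + alpha mu), which is
# strictly decreasing in log b; the profile log-likelihood is then evaluated
# with nb_loglik and the arg-max grid point returned. Independent of the
# Newton path used by fit_gene.
grid_oracle_beta <- function(K, design, size_factors, alphas,
                             grid = seq(-10, 10, by = 1e-3)) {
  stopifnot(ncol(design) == 1L)
  n_i <- nrow(K); n_r <- ncol(K)
  alphas <- rep_len(alphas, n_i)
  # E[g, r] = s_r * exp(D_r * beta_g), common to all guides
  E <- exp(outer(grid, design[, 1L])) *
    matrix(size_factors, length(grid), n_r, byrow = TRUE)
  prof_ll <- numeric(length(grid))
  for (i in seq_len(n_i)) {
    k <- K[i, ]
    a <- alphas[i]
    lo <- rep(-30, length(grid)); hi <- rep(30, length(grid))
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      mu <- exp(mid) * E
      score <- rowSums((matrix(k, length(grid), n_r, byrow = TRUE) - mu) /
                         (1 + a * mu))
      up <- score > 0
      lo[up] <- mid[up]; hi[!up] <- mid[!up]
    }
    mu <- exp((lo + hi) / 2) * E
    prof_ll <- prof_ll + rowSums(matrix(
      nb_loglik(rep(k, each = length(grid)), pmax(as.vector(mu), 1e-300), a),
      length(grid), n_r))
  }
  grid[which.max(prof_ll)]
}
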