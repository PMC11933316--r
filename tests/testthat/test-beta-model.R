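test_that("nb_loglik matches closed forms and the Poisson limit", {
  # k = 0, mu = 1, alpha = 1: (1/(1 + alpha mu))^(1/alpha) = 1/2
  expect_equal(nb_loglik(0, 1, 1), log(0.5), tolerance = 1e-12)
  # alpha -> 0 recovers Poisson: P(0 | mu = 1) = e^-1
  expect_equal(nb_loglik(0, 1, 0), -1, tolerance = 1e-12)
  expect_equal(nb_loglik(0, 1, 1e-13), -1, tolerance = 1e-6)
  # near-Poisson at k = 2, mu = 2: log(2^2 e^-2 / 2!) = -2 + log 2
  expect_equal(nb_loglik(2, 2, 1e-8), -2 + log(2), tolerance = 1e-4)
  # continuity across the alpha switchover
  expect_equal(nb_loglik(5, 3, 1e-11), nb_loglik(5, 3, 1e-13),
               tolerance = 1e-6)
  expect_error(nb_loglik(1, 0, 1), "positive")
  expect_error(nb_loglik(-1, 1, 1), "non-negative")
  expect_error(nb_loglik(1, 1, -0.1), "non-negative")
})

test_that("nb pmf sums to one over its support", {
  for (pars in list(c(5, 0.5), c(100, 1), c(50, 0.01), c(100, 0))) {
    mu <- pars[1]; a <- pars[2]
    total <- sum(exp(nb_loglik(0:20000, mu, a)))
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("dispersion estimation follows the method of moments with a floor", {
  m <- rbind(sg1 = c(100L, 100L), sg2 = c(50L, 150L))
  colnames(m) <- c("REP1_DMSO_D2", "REP2_DMSO_D2")
  a <- estimate_dispersion(m, c(1, 1), grouping = c("g", "g"))
  # zero variance floors at alpha_min
  expect_equal(unname(a["sg1"]), 0.01)
  # (5000 - 100) / 100^2 = 0.49
  expect_equal(unname(a["sg2"]), 0.49, tolerance = 1e-12)

  # Poisson counts land at the floor for most guides
  set.seed(7)
  mp <- matrix(rpois(500 * 100, 500), 500, 100)
  rownames(mp) <- paste0("sg", seq_len(500))
  colnames(mp) <- paste0("REP", seq_len(100), "_DMSO_D2")
  ap <- estimate_dispersion(mp, rep(1, 100), grouping = rep("g", 100))
  expect_gt(mean(ap == 0.01), 0.9)

  expect_warning(
    a1 <- estimate_dispersion(m[, 1, drop = FALSE], 1, grouping = "g"),
    "no replicate group")
  expect_true(all(a1 == 0.01))
})

test_that("fit_gene reproduces Poisson-limit closed forms", {
  D <- toy_design()
  # one guide: beta = log(800/100)
  f <- fit_gene(matrix(c(100L, 800L), 1, 2), D, c(1, 1), 1e-8)
  expect_equal(unname(f$beta), log(8), tolerance = 1e-3)
  expect_true(f$converged)
  expect_true(is.finite(f$se) && f$se > 0)
  expect_equal(unname(f$z), unname(f$beta / f$se))

  # two guides pool: beta = log(sum cond / sum base) = log(500/200)
  f2 <- fit_gene(rbind(c(100L, 400L), c(100L, 100L)), D, c(1, 1), 1e-8)
  expect_equal(unname(f2$beta), log(2.5), tolerance = 1e-3)

  # identical condition and baseline counts: beta = 0
  f3 <- fit_gene(rbind(c(120L, 120L), c(80L, 80L)), D, c(1, 1), 1e-8)
  expect_equal(unname(f3$beta), 0, tolerance = 1e-6)

  expect_error(fit_gene(matrix(c(0L, 0L), 1, 2), D, c(1, 1), 0.01),
               "positive total count")
})

test_that("fit_gene agrees with the exhaustive profile-likelihood oracle", {
  set.seed(19)
  grid <- seq(-10, 10, by = 1e-3)
  for (case in 1:6) {
    n_i <- sample(1:4, 1)
    n_cond <- sample(1:2, 1)
    D <- toy_design(n_base = 1L, n_cond = n_cond)
    K <- matrix(rpois(n_i * (1 + n_cond), lambda = sample(20:2000, 1)),
                n_i, 1 + n_cond)
    storage.mode(K) <- "integer"
    alphas <- runif(n_i, 0, 0.5)
    s <- runif(1 + n_cond, 0.5, 2)
    f <- fit_gene(K, D, s, alphas)
    bo <- grid_oracle_beta(K, D, s, alphas, grid)
    expect_lt(abs(unname(f$beta) - bo), 2e-3)
  }
})

test_that("beta estimates respect scale and symmetry invariances", {
  D <- toy_design()
  K <- rbind(c(150L, 420L), c(90L, 70L))
  f <- fit_gene(K, D, c(1, 1), c(0.05, 0.2))
  # common size-factor rescaling is absorbed by the baselines
  f_scaled <- fit_gene(K, D, c(3, 3), c(0.05, 0.2))
  expect_equal(f_scaled$beta, f$beta, tolerance = 1e-6)
  expect_equal(f_scaled$baselines, f$baselines / 3, tolerance = 1e-5)

  # swapping baseline and condition negates beta in the Poisson limit
  D_sw <- D; D_sw[, 1] <- 1 - D_sw[, 1]
  f_sw <- fit_gene(K, D_sw, c(1, 1), 1e-8)
  f_pois <- fit_gene(K, D, c(1, 1), 1e-8)
  expect_equal(unname(f_sw$beta), -unname(f_pois$beta), tolerance = 1e-5)

  # a contrast of a sample against itself is zero
  f_id <- fit_gene(rbind(c(200L, 200L)), D, c(1, 1), 0.1)
  expect_equal(unname(f_id$beta), 0, tolerance = 1e-6)
})

test_that("fit_screen is deterministic and calibrated on a null screen", {
  # baseline fitness zeroed and exact (unit) size factors supplied, so the
  # check isolates the calibration of the MLE machinery itself
  lib <- make_library(150L, 4L, 10L)
  truth <- draw_effects(lib, 0, 0, 0, seed = 61L, g_sd = 0)
  cfg <- sim_config(n_genes = 150L, sgrnas_per_gene = 4L, n_ntc = 10L,
                    depth_per_sample = 3e5, seed = 61L)
  cm <- simulate_screen(lib, truth, cfg)
  sf <- stats::setNames(rep(1, ncol(cm$counts)), colnames(cm$counts))
  sc <- list(lib = lib, counts = cm)
  bt <- fit_screen(sc$counts, sc$lib, size_factors = sf)
  expect_true(all(c("gene", "condition", "beta", "se", "z", "converged",
                    "replicate") %in% names(bt)))
  expect_setequal(unique(bt$replicate), 1:2)
  # non-targeting records never fitted as genes
  expect_false("NTC" %in% bt$gene)
  # deterministic given inputs
  bt2 <- fit_screen(sc$counts, sc$lib, size_factors = sf)
  expect_identical(bt, bt2)
  # Wald z over a null screen is roughly standard normal
  z <- bt$z[is.finite(bt$z)]
  expect_lt(abs(mean(z)), 0.2)
  expect_gt(sd(z), 0.7)
  expect_lt(sd(z), 1.3)
})

test_that("cell-cycle rescaling normalizes reference medians per condition", {
  tab <- data.frame(
    gene = rep(c("A", "B", "C"), 2),
    condition = rep(c("DAC_D6", "DMSO_D6"), each = 3),
    beta = c(-3, 2, 1, 0.5, -1, 2),
    se = rep(1, 6), z = NA_real_, converged = TRUE,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("beta_table", "data.frame")
  out <- cellcycle_normalize(tab)
  # per-condition reference median |beta| becomes 1
  for (cc in unique(out$condition)) {
    expect_equal(median(abs(out$beta[out$condition == cc])), 1,
                 tolerance = 1e-9)
  }
  # worked example: reference median 2 rescales -3 to -1.5
  expect_equal(out$beta[tab$condition == "DAC_D6" & tab$gene == "A"], -1.5)
  # se scales alongside beta, so z is unchanged
  expect_equal(out$beta / out$se, tab$beta / tab$se)
  expect_true(!is.null(attr(out, "kappa")))

  # a constant rescaling is monotone: ordering within a condition kept
  ord_before <- order(tab$beta[tab$condition == "DAC_D6"])
  ord_after <- order(out$beta[out$condition == "DAC_D6"])
  expect_identical(ord_before, ord_after)

  expect_error(cellcycle_normalize(tab, character(0)), "non-empty")
  expect_error(cellcycle_normalize(tab, "ZZZ"), "no reference gene")
  zero <- tab; zero$beta[zero$condition == "DMSO_D6"] <- 0
  class(zero) <- class(tab)
  expect_warning(cellcycle_normalize(zero), "unscaled")
})

test_that("design matrices build from metadata and round-trip", {
  info <- parse_sample_names(c("REP1_BASE_D0", "REP1_DMSO_D2",
                               "REP1_DAC_D2", "REP1_DAC_D6"))
  D <- build_design(info)
  expect_equal(colnames(D), c("DAC_D2", "DAC_D6", "DMSO_D2"))
  expect_equal(unname(rowSums(D)), c(0, 1, 1, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(D, path)
  expect_equal(read_design(path), D)
  expect_error(build_design(info[2:4, ]), "baseline")
})
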