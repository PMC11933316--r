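make_beta <- function(genes, days, beta, arm, replicate = NULL) {
  tab <- expand.grid(gene = genes, day = days, stringsAsFactors = FALSE)
  tab$condition <- sprintf("%s_D%d", arm, tab$day)
  tab$beta <- beta
  tab$se <- 1; tab$z <- tab$beta; tab$converged <- TRUE
  if (!is.null(replicate)) tab$replicate <- replicate
  tab$day <- NULL
  class(tab) <- c("beta_table", "data.frame")
  tab
}

test_that("differential beta is the drug-minus-vehicle subtraction", {
  dac <- make_beta(c("A", "B"), c(6, 8), c(1.5, 0.5, 2, 1), "DAC")
  dmso <- make_beta(c("A", "B"), c(6, 8), c(0.5, 0.5, 1, 3), "DMSO")
  d <- differential_beta(dac, dmso)
  expect_equal(d$diff_beta[d$gene == "A" & d$day == 6], 1.0)
  # antisymmetry under swapping the inputs
  d_sw <- differential_beta(dmso, dac)
  d_sw$condition <- NULL
  expect_equal(d_sw$diff_beta, -d$diff_beta)
  # identical arms give all zeros
  expect_true(all(differential_beta(dac, dac)$diff_beta == 0))
  # genes on one side only are dropped with a warning
  dac_extra <- make_beta(c("A", "B", "C"), 6, c(1, 2, 3), "DAC")
  expect_warning(d2 <- differential_beta(dac_extra, dmso), "dropped")
  expect_false("C" %in% d2$gene)
  # disjoint days is an error
  expect_error(
    differential_beta(make_beta("A", 2, 1, "DAC"),
                      make_beta("A", 4, 1, "DMSO")),
    "no shared days")
})

test_that("replicate averaging is the arithmetic mean and order-invariant", {
  d1 <- data.frame(gene = "A", day = 6, diff_beta = 1.0, replicate = 1L)
  d2 <- data.frame(gene = "A", day = 6, diff_beta = 3.0, replicate = 2L)
  both <- rbind(d1, d2)
  class(both) <- c("diff_beta", "data.frame")
  expect_equal(average_replicates(both)$diff_beta, 2.0)
  perm <- both[2:1, ]
  class(perm) <- class(both)
  expect_equal(average_replicates(perm), average_replicates(both))
  # single replicate (no column) is identity
  single <- data.frame(gene = "A", day = 6, diff_beta = 5)
  expect_identical(average_replicates(single), single)
  # replicate index mismatch errors
  bad <- rbind(both, data.frame(gene = "B", day = 6, diff_beta = 0,
                                replicate = 2L))
  class(bad) <- class(both)
  expect_error(average_replicates(bad), "index")
})

test_that("the mean +/- 2 sigma rule calls the worked example exactly", {
  d <- data.frame(gene = paste0("G", 1:10), day = 6,
                  diff_beta = c(rep(0, 8), 3, -3))
  h <- select_hits(d, k_sigma = 2)
  # population sigma = sqrt(18/10)
  expect_equal(h$thresholds$sigma, sqrt(1.8), tolerance = 1e-12)
  expect_equal(h$thresholds$sigma, 1.3416, tolerance = 1e-4)
  expect_equal(h$thresholds$hi, 2 * sqrt(1.8), tolerance = 1e-12)
  expect_equal(sum(h$calls == 1L), 1L)
  expect_equal(sum(h$calls == -1L), 1L)
  expect_equal(unname(h$calls["G9", "D6"]), 1L)
  expect_equal(unname(h$calls["G10", "D6"]), -1L)

  # all-equal scores: zero sigma, zero calls, warning
  flat <- data.frame(gene = paste0("G", 1:5), day = 2, diff_beta = 1)
  expect_warning(h0 <- select_hits(flat), "zero sigma")
  expect_true(all(h0$calls == 0L))

  expect_error(select_hits(data.frame(gene = "G1", day = 2, diff_beta = 1)),
               "fewer than 2")
  multi <- data.frame(gene = "A", day = 2, diff_beta = 1:2,
                      replicate = 1:2)
  expect_error(select_hits(multi), "replicate-averaged")
})

test_that("calls obey location equivariance and sign-flip antisymmetry", {
  set.seed(5)
  d <- data.frame(gene = paste0("G", 1:500), day = 8,
                  diff_beta = rnorm(500))
  h <- select_hits(d)
  shifted <- d; shifted$diff_beta <- d$diff_beta + 11.5
  expect_identical(select_hits(shifted)$calls, h$calls)
  negated <- d; negated$diff_beta <- -d$diff_beta
  expect_identical(select_hits(negated)$calls, -h$calls)
})

test_that("the called fraction under a Gaussian null matches the tail mass", {
  set.seed(13)
  d <- data.frame(gene = paste0("G", 1:20000), day = 6,
                  diff_beta = rnorm(20000))
  h <- select_hits(d)
  frac <- mean(h$calls != 0L)
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.006)
})

test_that("the high-fidelity rule matches exhaustive triple enumeration", {
  # all 27 call triples over days {6, 8, 10}
  triples <- expand.grid(D6 = -1:1, D8 = -1:1, D10 = -1:1)
  genes <- paste0("G", seq_len(nrow(triples)))
  calls <- as.matrix(triples)
  rownames(calls) <- genes
  ht <- structure(list(calls = calls, thresholds = NULL),
                  class = "hit_table")
  ht <- high_fidelity_hits(ht, days = c(6, 8, 10), min_days = 2L)
  want_pos <- rowSums(calls == 1L) >= 2L
  want_neg <- rowSums(calls == -1L) >= 2L
  # with 3 days, both directions can never reach 2 simultaneously
  expect_false(any(want_pos & want_neg))
  expect_equal(ht$flags$hf_pos, unname(want_pos))
  expect_equal(ht$flags$hf_neg, unname(want_neg))
  expect_false(any(ht$flags$ambiguous))
  # spot checks from the rule's definition
  pick <- function(d6, d8, d10)
    which(triples$D6 == d6 & triples$D8 == d8 & triples$D10 == d10)
  expect_true(ht$flags$hf_pos[pick(1, 1, 0)])
  expect_true(ht$flags$hf_pos[pick(1, -1, 1)])
  expect_false(ht$flags$hf_pos[pick(1, -1, 0)])
  expect_false(ht$flags$hf_neg[pick(1, -1, 0)])

  # ambiguity arises with four eligible days
  calls4 <- rbind(G1 = c(1L, 1L, -1L, -1L))
  colnames(calls4) <- c("D4", "D6", "D8", "D10")
  ht4 <- structure(list(calls = calls4), class = "hit_table")
  ht4 <- high_fidelity_hits(ht4, days = c(4, 6, 8, 10))
  expect_true(ht4$flags$ambiguous)
  expect_false(ht4$flags$hf_pos || ht4$flags$hf_neg)

  # days outside the eligible set are ignored
  calls5 <- rbind(G1 = c(1L, 1L, 1L, 0L, 0L))
  colnames(calls5) <- c("D2", "D4", "D6", "D8", "D10")
  ht5 <- structure(list(calls = calls5), class = "hit_table")
  ht5 <- high_fidelity_hits(ht5)
  expect_false(ht5$flags$hf_pos)

  expect_error(high_fidelity_hits(ht5, days = c(42)), "none of")
})

test_that("high-fidelity flags are monotone in matching-direction calls", {
  base <- rbind(G1 = c(1L, 0L, 0L))
  colnames(base) <- c("D6", "D8", "D10")
  flag_of <- function(calls) {
    ht <- structure(list(calls = calls), class = "hit_table")
    high_fidelity_hits(ht)$flags$hf_pos
  }
  expect_false(flag_of(base))
  for (j in 2:3) {
    up <- base; up[1, j] <- 1L
    expect_true(flag_of(up))
  }
})

test_that("trajectory clustering recovers separable groups deterministically", {
  days <- c(2, 4, 6, 8, 10)
  genes <- c(paste0("UP", 1:5), paste0("DN", 1:5))
  set.seed(3)
  d <- expand.grid(gene = genes, day = days, stringsAsFactors = FALSE)
  d$diff_beta <- ifelse(grepl("UP", d$gene), 2, -2) + rnorm(nrow(d), 0, 0.05)
  cl <- cluster_trajectories(d, k = 2)
  expect_equal(unname(cl$cluster[paste0("UP", 1:5)]), rep(1L, 5))
  expect_equal(unname(cl$cluster[paste0("DN", 1:5)]), rep(2L, 5))
  # relabelling is by descending final-day centroid
  expect_gt(cl$centroids[1, "D10"], cl$centroids[2, "D10"])

  # k = 1 gives the global mean trajectory as centroid
  cl1 <- cluster_trajectories(d, k = 1)
  expect_true(all(cl1$cluster == 1L))
  M <- tapply(d$diff_beta, d$day, mean)
  expect_equal(unname(cl1$centroids[1, ]), as.vector(M), tolerance = 1e-12)

  # duplicating every gene row leaves centroids unchanged (Ward on
  # duplicated points)
  d_dup <- d
  d_dup$gene <- paste0(d_dup$gene, "_copy")
  cl_dup <- cluster_trajectories(rbind(d, d_dup), k = 2)
  expect_equal(cl_dup$centroids, cl$centroids, tolerance = 1e-12)

  expect_error(cluster_trajectories(d, k = 99), "exceeds")
})

test_that("clustering agrees with an independent average-linkage check on
           well-separated data", {
  # on perfectly separated constant trajectories any sane linkage agrees;
  # cross-check Ward against complete linkage as an independent reference
  days <- c(2, 4, 6)
  d <- expand.grid(gene = paste0("G", 1:9), day = days,
                   stringsAsFactors = FALSE)
  lev <- rep(c(-3, 0, 3), each = 3)
  d$diff_beta <- lev[match(d$gene, paste0("G", 1:9))]
  cl <- cluster_trajectories(d, k = 3)
  M <- matrix(lev[match(paste0("G", 1:9), paste0("G", 1:9))], 9, 1)
  ref <- cutree(hclust(dist(cbind(lev, lev, lev)), "complete"), 3)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl$cluster[paste0("G", 1:9)], ref))), 3L)
})
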