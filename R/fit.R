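#' Build a condition design matrix from sample metadata
#'
#' One indicator column per (condition, day) contrast, named e.g. `DMSO_D6`;
#' Day-0 baseline samples get an all-zero row. Each sample maps to at most
#' one column.
#'
#' @param sample_info data frame with columns `sample`, `condition`, `day`.
#' @return 0/1 matrix, rows = samples, columns = condition contrasts.
#' @export
build_design <- function(sample_info) {
  is_base <- sample_info$condition == "BASE" | sample_info$day == 0L
  if (!any(is_base)) stop("design needs at least one Day-0 baseline sample")
  cond <- sample_info[!is_base, , drop = FALSE]
  labels <- sprintf("%s_D%d", cond$condition, cond$day)
  cols <- unique(labels[order(cond$condition, cond$day)])
  D <- matrix(0, nrow(sample_info), length(cols),
              dimnames = list(sample_info$sample, cols))
  D[cbind(which(!is_base), match(labels, cols))] <- 1
  D
}

#' Read / write a design matrix TSV
#'
#' Format: `sample<TAB>baseline<TAB><condition columns...>` with 0/1 entries;
#' `baseline` marks Day-0 samples (all-zero condition row).
#'
#' @param design 0/1 design matrix as from [build_design()].
#' @param path file path.
#' @export
write_design <- function(design, path) {
  out <- data.frame(sample = rownames(design),
                    baseline = as.integer(rowSums(design) == 0),
                    design, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("sample", "baseline")))
    stop("malformed design header: expected sample<TAB>baseline<TAB>...")
  D <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(D) <- df$sample
  if (any(D != 0 & D != 1)) stop("design entries must be 0/1")
  if (any(rowSums(D) > 1)) stop("a sample maps to more than one condition")
  D
}

# Observed-information weight of one observation on the log-mean scale:
# second derivative of the NB log-likelihood w.r.t. eta = log mu is
# -mu (1 + alpha k) / (1 + alpha mu)^2.
nb_obs_weight <- function(k, mu, alpha) {
  mu * (1 + alpha * k) / (1 + alpha * mu)^2
}

#' Fit one gene's beta-scores by negative-binomial maximum likelihood
#'
#' The log-linear model for guide `i` in sample `r` is
#' `log mu_ir = log s_r + log b_i + sum_c D_rc beta_c`,
#' i.e. a per-guide baseline abundance `b_i` shared across all samples and
#' a gene-level selection coefficient `beta_c` per condition contrast,
#' fitted jointly by damped Newton iteration on `(log b, beta)` with the
#' observed information and step-halving whenever a step would decrease the
#' likelihood. Standard errors come from the diagonal of the inverse
#' observed-information matrix; `z = beta / se`.
#'
#' @param gene_counts integer matrix, guides x samples.
#' @param design 0/1 design matrix, samples x contrasts ([build_design()]).
#' @param size_factors per-sample positive scalars.
#' @param dispersions per-guide NB overdispersion alpha (recycled if scalar).
#' @param tol convergence threshold on the largest parameter update.
#' @param max_iter iteration cap; the last iterate is returned (flagged
#'   unconverged) when reached.
#' @param beta_max hard bound on `|beta_c|`: a contrast whose counts are all
#'   zero has its maximum at `beta = -Inf`, which is truncated to this bound
#'   (selection stronger than `e^15` per contrast is not measurable at
#'   screen depth).
#' @return list with `beta`, `se`, `z` (named by contrast), `baselines`
#'   (fitted `b_i`), `converged`, `iterations`, `loglik`.
#' @export
fit_gene <- function(gene_counts, design, size_factors, dispersions,
                     tol = 1e-6, max_iter = 100L, beta_max = 15) {
  K <- as.matrix(gene_counts)
  if (nrow(design) != ncol(K))
    stop("design rows must match count columns")
  if (sum(K) == 0) stop("gene has no sgRNA with positive total count")
  n_i <- nrow(K); n_r <- ncol(K); n_c <- ncol(design)
  s <- rep_len(size_factors, n_r)
  alpha <- rep_len(dispersions, n_i)
  A <- matrix(alpha, n_i, n_r)

  is_base <- rowSums(design) == 0
  if (!any(is_base)) stop("design needs at least one baseline sample")
  b0 <- rowMeans(sweep(K[, is_base, drop = FALSE], 2L, s[is_base], "/"))
  logb <- log(pmax(b0, 1e-4))
  beta <- numeric(n_c)

  mu_of <- function(logb, beta) {
    eta <- as.vector(design %*% beta)
    tcrossprod(exp(logb), s * exp(eta))
  }
  # log-likelihood up to mu-independent constants: NB term
  # k log mu - (k + 1/alpha) log(1 + alpha mu), Poisson limit k log mu - mu
  P <- matrix(alpha < 1e-12, n_i, n_r)
  k_plus_inv_alpha <- K + 1 / pmax(A, 1e-12)
  ll_of <- function(mu) {
    t2 <- k_plus_inv_alpha * log1p(A * mu)
    t2[P] <- mu[P]
    sum(K * log(pmax(mu, 1e-300)) - t2)
  }

  # Damped Newton on the joint parameter (log b, beta) with the observed
  # information; rows and contrasts couple only through the shared samples,
  # so the information matrix is small (n_i + n_c) and cheap to solve.
  hessian_of <- function(mu) {
    W <- nb_obs_weight(K, mu, A)
    H <- matrix(0, n_i + n_c, n_i + n_c)
    H[seq_len(n_i), seq_len(n_i)] <- diag(rowSums(W), n_i)
    if (n_c > 0L) {
      Hbc <- W %*% design
      H[seq_len(n_i), n_i + seq_len(n_c)] <- Hbc
      H[n_i + seq_len(n_c), seq_len(n_i)] <- t(Hbc)
      H[n_i + seq_len(n_c), n_i + seq_len(n_c)] <-
        crossprod(design, colSums(W) * design)
    }
    H
  }
  mu <- mu_of(logb, beta)
  ll <- ll_of(mu)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    resid <- (K - mu) / (1 + A * mu)
    grad <- c(rowSums(resid),
              if (n_c > 0L) as.vector(crossprod(design, colSums(resid))))
    H <- hessian_of(mu)
    delta <- tryCatch(solve(H + diag(1e-10, nrow(H)), grad),
                      error = function(e) grad / pmax(diag(H), 1e-8))
    step <- 1
    repeat {
      logb_new <- pmin(pmax(logb + step * delta[seq_len(n_i)], -30), 30)
      beta_new <- pmin(pmax(beta + step * delta[n_i + seq_len(n_c)],
                            -beta_max), beta_max)
      mu_new <- mu_of(logb_new, beta_new)
      ll_new <- ll_of(mu_new)
      if (ll_new >= ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    max_step <- max(abs(c(logb_new - logb, beta_new - beta)))
    logb <- logb_new; beta <- beta_new; mu <- mu_new; ll <- ll_new
    if (max_step < tol) { converged <- TRUE; break }
  }

  # observed information at the optimum; invert for Wald SEs
  H <- hessian_of(mu)
  se <- rep(NA_real_, n_c)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(cov)) {
    v <- diag(cov)[n_i + seq_len(n_c)]
    se <- sqrt(pmax(v, 0))
  }
  names(beta) <- names(se) <- colnames(design)
  list(beta = beta, se = se, z = beta / se,
       baselines = stats::setNames(exp(logb), rownames(K)),
       converged = converged, iterations = it,
       loglik = sum(nb_loglik(K, pmax(mu, 1e-300), A)))
}

#' Fit beta-scores for every targeting gene of a screen
#'
#' Applies [fit_gene()] gene by gene. Non-targeting and positive-control
#' guides are excluded from gene fits. With `per_replicate = TRUE` (the
#' default) each replicate is fitted independently against its own Day-0
#' baseline, for downstream replicate averaging of differential scores; the
#' joint fit pools all samples.
#'
#' @param counts a [count_matrix].
#' @param library an [sgrna_library] covering the count rows.
#' @param design optional design matrix; defaults to [build_design()] on the
#'   (per-replicate subset of the) sample metadata.
#' @param per_replicate fit replicates independently.
#' @param size_factors per-sample scalars; defaults to
#'   [size_factors_control()] on the library's non-targeting guides (all
#'   guides if the library has none).
#' @param dispersions per-guide alpha; defaults to [estimate_dispersion()].
#' @param ... passed to [fit_gene()] (`tol`, `max_iter`).
#' @return a `beta_table` data frame with columns `gene`, `condition`,
#'   `beta`, `se`, `z`, `converged` and, for per-replicate fits,
#'   `replicate`.
#' @export
fit_screen <- function(counts, library, design = NULL, per_replicate = TRUE,
                       size_factors = NULL, dispersions = NULL, ...) {
  rows <- rownames(counts$counts)
  missing_sg <- setdiff(rows, library$sgRNA)
  if (length(missing_sg))
    stop("count rows absent from library: ",
         paste(utils::head(missing_sg, 5L), collapse = ", "))
  lib <- library[match(rows, library$sgRNA), , drop = FALSE]

  if (is.null(size_factors)) {
    ctl <- lib$sgRNA[lib$class == "nontargeting"]
    if (length(ctl) == 0L) ctl <- lib$sgRNA
    size_factors <- size_factors_control(counts, ctl)
  }
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, size_factors)
  dispersions <- rep_len(dispersions, length(rows))
  names(dispersions) <- rows

  targeting <- lib$class == "targeting"
  genes <- split(which(targeting), lib$gene[targeting])

  fit_block <- function(col_idx, replicate = NULL) {
    info <- counts$samples[col_idx, , drop = FALSE]
    D <- if (is.null(design)) build_design(info) else
      design[info$sample, , drop = FALSE]
    s <- size_factors[col_idx]
    res <- vector("list", length(genes))
    skipped <- character(0)
    for (gi in seq_along(genes)) {
      idx <- genes[[gi]]
      K <- counts$counts[idx, col_idx, drop = FALSE]
      if (sum(K) == 0) { skipped <- c(skipped, names(genes)[gi]); next }
      f <- fit_gene(K, D, s, dispersions[idx], ...)
      res[[gi]] <- data.frame(
        gene = names(genes)[gi], condition = names(f$beta),
        beta = unname(f$beta), se = unname(f$se), z = unname(f$z),
        converged = f$converged, stringsAsFactors = FALSE
      )
    }
    if (length(skipped))
      warning("skipped all-zero gene(s): ",
              paste(utils::head(skipped, 5L), collapse = ", "))
    out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
    if (!is.null(replicate)) out$replicate <- replicate
    out
  }

  if (per_replicate) {
    reps <- sort(unique(counts$samples$replicate))
    out <- do.call(rbind, lapply(reps, function(r)
      fit_block(which(counts$samples$replicate == r), replicate = r)))
  } else {
    out <- fit_block(seq_len(ncol(counts$counts)))
  }
  rownames(out) <- NULL
  class(out) <- c("beta_table", "data.frame")
  out
}

#' Rescale beta-scores to a reference gene set (cell-cycle normalization)
#'
#' Per condition contrast (and replicate, when present), the scale
#' `kappa = median |beta|` over a reference gene set is computed and both
#' `beta` and `se` are divided by it, making scores comparable across
#' conditions whose overall selection pressure differs. A zero reference
#' median leaves the column unscaled (`kappa = 1`, with a warning). The
#' applied scales are recorded in the `"kappa"` attribute.
#'
#' @param beta_table a `beta_table` from [fit_screen()].
#' @param reference_genes character vector; defaults to every gene in the
#'   table (an essential-gene list can be supplied instead).
#' @return the rescaled `beta_table`, with attribute `"kappa"` (data frame
#'   of the per-column scales).
#' @export
cellcycle_normalize <- function(beta_table, reference_genes = NULL) {
  if (is.null(reference_genes)) reference_genes <- unique(beta_table$gene)
  if (length(reference_genes) == 0L)
    stop("reference gene set must be non-empty")
  if (!any(beta_table$gene %in% reference_genes))
    stop("no reference gene present in the beta table")
  has_rep <- "replicate" %in% names(beta_table)
  key <- if (has_rep)
    interaction(beta_table$replicate, beta_table$condition, drop = TRUE)
  else as.factor(beta_table$condition)

  out <- beta_table
  kap <- data.frame(key = levels(key), kappa = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(levels(key))) {
    sel <- key == levels(key)[j]
    ref <- sel & beta_table$gene %in% reference_genes
    k <- stats::median(abs(beta_table$beta[ref]))
    if (!is.finite(k) || k == 0) {
      warning("zero reference median |beta| in ", levels(key)[j],
              "; leaving column unscaled")
      k <- 1
    }
    out$beta[sel] <- beta_table$beta[sel] / k
    out$se[sel] <- beta_table$se[sel] / k
    kap$kappa[j] <- k
  }
  attr(out, "kappa") <- kap
  out
}

#' Write a beta table TSV
#'
#' @param beta_table a `beta_table`.
#' @param path file path.
#' @export
write_beta <- function(beta_table, path) {
  utils::write.table(beta_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
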