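#' Method-of-moments sgRNA dispersion estimation
#'
#' Per-sgRNA overdispersion `alpha` (with `Var = mu + alpha * mu^2`) is
#' estimated from size-factor-normalized counts within replicate groups —
#' samples sharing a condition and day — as
#' `alpha_hat = (s^2 - m) / m^2` (sample variance, `n - 1` denominator),
#' pooled across groups by a count-weighted average (weight = the sgRNA's
#' total normalized count in the group) and clipped to
#' `[alpha_min, alpha_max]`. Poisson-distributed counts therefore land at
#' the `alpha_min` floor.
#'
#' @param counts a [count_matrix] or integer matrix.
#' @param size_factors per-sample positive scalars.
#' @param grouping factor/vector over samples defining replicate groups;
#'   defaults to `condition_day` from the stored sample metadata.
#' @param alpha_min,alpha_max clipping bounds.
#' @return named numeric vector of per-sgRNA dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors, grouping = NULL,
                                alpha_min = 0.01, alpha_max = 10) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(grouping)) {
    if (!inherits(counts, "count_matrix"))
      stop("grouping required for a bare matrix")
    grouping <- paste(counts$samples$condition, counts$samples$day, sep = "_")
  }
  grouping <- as.factor(grouping)
  norm <- sweep(m, 2L, size_factors, "/")

  groups <- levels(grouping)
  sizes <- table(grouping)
  usable <- groups[sizes[groups] >= 2L]
  if (length(usable) == 0L) {
    warning("no replicate group with >= 2 samples; ",
            "falling back to alpha_min for every sgRNA")
    return(stats::setNames(rep(alpha_min, nrow(m)), rownames(m)))
  }
  num <- numeric(nrow(m))
  den <- numeric(nrow(m))
  for (gname in usable) {
    sub <- norm[, grouping == gname, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    a <- ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
    w <- rowSums(sub)
    ok <- !is.na(a)
    num[ok] <- num[ok] + w[ok] * a[ok]
    den[ok] <- den[ok] + w[ok]
  }
  alpha <- ifelse(den > 0, num / den, alpha_min)
  alpha <- pmin(pmax(alpha, alpha_min), alpha_max)
  stats::setNames(alpha, rownames(m))
}
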