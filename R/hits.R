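parse_condition_labels <- function(condition) {
  m <- regmatches(condition,
                  regexec("^(BASE|DMSO|DAC)_D([0-9]+)$", condition))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("condition label(s) not of the form COND_Dday: ",
         paste(unique(condition[bad]), collapse = ", "))
  data.frame(arm = vapply(m, `[`, "", 2L),
             day = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Differential beta-scores between drug and vehicle arms
#'
#' For each gene and day present in both inputs,
#' `diff_beta = beta_drug - beta_vehicle`. Genes missing from either side
#' are dropped with a warning; replicate labels, when present in both
#' inputs, are matched and carried through.
#'
#' @param beta_dac `beta_table` rows for the drug arm (condition labels
#'   `DAC_D{day}`).
#' @param beta_dmso `beta_table` rows for the vehicle arm (`DMSO_D{day}`).
#' @return a `diff_beta` data frame: `gene`, `day`, `diff_beta`
#'   (and `replicate` for per-replicate input).
#' @export
differential_beta <- function(beta_dac, beta_dmso) {
  a <- cbind(beta_dac, parse_condition_labels(beta_dac$condition))
  b <- cbind(beta_dmso, parse_condition_labels(beta_dmso$condition))
  shared_days <- intersect(a$day, b$day)
  if (length(shared_days) == 0L)
    stop("no shared days between the two beta tables")
  has_rep <- "replicate" %in% names(a) && "replicate" %in% names(b)
  keycols <- c("gene", "day", if (has_rep) "replicate")
  a_key <- do.call(paste, c(a[keycols], sep = "\r"))
  b_key <- do.call(paste, c(b[keycols], sep = "\r"))
  dropped <- union(setdiff(a$gene, b$gene), setdiff(b$gene, a$gene))
  if (length(dropped))
    warning("gene(s) present on one side only, dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  idx <- match(a_key, b_key)
  keep <- !is.na(idx) & a$day %in% shared_days
  out <- data.frame(gene = a$gene[keep], day = a$day[keep],
                    diff_beta = a$beta[keep] - b$beta[idx[keep]],
                    stringsAsFactors = FALSE)
  if (has_rep) out$replicate <- a$replicate[keep]
  ord <- if (has_rep) order(out$day, out$replicate, out$gene)
         else order(out$day, out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diff_beta", "data.frame")
  out
}

#' Split a per-replicate beta table by arm and difference it
#'
#' Convenience wrapper: extracts the `DAC_*` and `DMSO_*` condition rows of
#' one `beta_table` and calls [differential_beta()].
#'
#' @param beta_table a `beta_table` containing both arms.
#' @return a `diff_beta` data frame.
#' @export
differential_beta_table <- function(beta_table) {
  lab <- parse_condition_labels(beta_table$condition)
  differential_beta(beta_table[lab$arm == "DAC", , drop = FALSE],
                    beta_table[lab$arm == "DMSO", , drop = FALSE])
}

#' Average differential beta-scores across replicates
#'
#' Arithmetic mean of `diff_beta` per (gene, day). All replicates must carry
#' the identical (gene, day) index.
#'
#' @param diff a `diff_beta` table with a `replicate` column (a table
#'   without one is returned unchanged).
#' @return a replicate-averaged `diff_beta` table.
#' @export
average_replicates <- function(diff) {
  if (!"replicate" %in% names(diff)) return(diff)
  reps <- unique(diff$replicate)
  key <- paste(diff$gene, diff$day, sep = "\r")
  ref <- sort(unique(key))
  for (r in reps) {
    if (!identical(sort(key[diff$replicate == r]), ref))
      stop("replicate ", r, " does not share the (gene, day) index")
  }
  agg <- stats::aggregate(diff_beta ~ gene + day, data = diff, FUN = mean)
  agg <- agg[order(agg$day, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("diff_beta", "data.frame")
  agg
}

#' Call per-day hits by the mean +/- k sigma rule
#'
#' Per day, the mean and population standard deviation (denominator `n`) of
#' the differential beta-scores over all genes are computed; a gene is
#' called positively selected (`+1`) when its score strictly exceeds
#' `mean + k_sigma * sigma` and negatively selected (`-1`) when strictly
#' below `mean - k_sigma * sigma`. A day with zero spread yields no calls
#' (with a warning).
#'
#' @param diff a replicate-averaged `diff_beta` table (average first with
#'   [average_replicates()]; multiple replicates raise an error).
#' @param k_sigma threshold multiplier.
#' @return a `hit_table` list: `calls` (gene x day integer matrix in
#'   `{-1, 0, +1}`) and `thresholds` (data frame
#'   `day, mean, sigma, lo, hi`).
#' @export
select_hits <- function(diff, k_sigma = 2) {
  if ("replicate" %in% names(diff) && length(unique(diff$replicate)) > 1L)
    stop("select_hits expects replicate-averaged scores; ",
         "run average_replicates() first")
  days <- sort(unique(diff$day))
  genes <- sort(unique(diff$gene))
  calls <- matrix(0L, length(genes), length(days),
                  dimnames = list(genes, paste0("D", days)))
  thr <- data.frame(day = days, mean = NA_real_, sigma = NA_real_,
                    lo = NA_real_, hi = NA_real_)
  for (j in seq_along(days)) {
    sel <- diff$day == days[j] & is.finite(diff$diff_beta)
    x <- diff$diff_beta[sel]
    if (length(x) < 2L)
      stop("day ", days[j], " has fewer than 2 finite scores")
    m <- mean(x)
    sg <- sqrt(mean((x - m)^2))
    thr$mean[j] <- m; thr$sigma[j] <- sg
    thr$lo[j] <- m - k_sigma * sg; thr$hi[j] <- m + k_sigma * sg
    if (sg == 0) {
      warning("zero sigma on day ", days[j], "; no calls made")
      next
    }
    gi <- match(diff$gene[sel], genes)
    calls[gi, j] <- ifelse(x > thr$hi[j], 1L,
                           ifelse(x < thr$lo[j], -1L, 0L))
  }
  structure(list(calls = calls, thresholds = thr), class = "hit_table")
}

#' Flag high-fidelity hits recurring across late timepoints
#'
#' A gene is a high-fidelity positive (negative) hit when it is called
#' `+1` (`-1`) on at least `min_days` of the listed `days`. A gene meeting
#' both directions is flagged `ambiguous` instead, with both
#' high-fidelity flags cleared.
#'
#' @param hit_table a `hit_table` from [select_hits()].
#' @param days timepoints (days) eligible for the recurrence rule.
#' @param min_days minimum number of same-direction calls among `days`.
#' @return the `hit_table` with an added `flags` data frame
#'   (`gene, hf_pos, hf_neg, ambiguous`).
#' @export
high_fidelity_hits <- function(hit_table, days = c(6, 8, 10), min_days = 2L) {
  cols <- intersect(paste0("D", days), colnames(hit_table$calls))
  if (length(cols) == 0L)
    stop("none of the requested days are present in the hit table")
  sub <- hit_table$calls[, cols, drop = FALSE]
  n_pos <- rowSums(sub == 1L)
  n_neg <- rowSums(sub == -1L)
  hf_pos <- n_pos >= min_days
  hf_neg <- n_neg >= min_days
  ambiguous <- hf_pos & hf_neg
  hf_pos[ambiguous] <- FALSE
  hf_neg[ambiguous] <- FALSE
  hit_table$flags <- data.frame(gene = rownames(hit_table$calls),
                                hf_pos = hf_pos, hf_neg = hf_neg,
                                ambiguous = ambiguous,
                                row.names = NULL, stringsAsFactors = FALSE)
  hit_table
}

#' Cluster hit trajectories
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of
#' replicate-averaged differential-beta trajectories, cut at `k` clusters.
#' Clusters are relabelled `1..k` by descending centroid value at the final
#' day, so cluster 1 is the strongest late positive selection.
#'
#' @param diff a replicate-averaged `diff_beta` table.
#' @param genes genes to cluster (e.g. the high-fidelity set); defaults to
#'   all genes in `diff`. Genes with missing days are dropped with a
#'   warning.
#' @param k number of clusters.
#' @return list with `cluster` (named integer vector), `centroids`
#'   (k x days matrix) and `hclust` (the dendrogram object).
#' @export
cluster_trajectories <- function(diff, genes = NULL, k = 6L) {
  if (is.null(genes)) genes <- unique(diff$gene)
  days <- sort(unique(diff$day))
  M <- matrix(NA_real_, length(genes), length(days),
              dimnames = list(genes, paste0("D", days)))
  sel <- diff$gene %in% genes
  M[cbind(match(diff$gene[sel], genes), match(diff$day[sel], days))] <-
    diff$diff_beta[sel]
  complete <- rowSums(is.na(M)) == 0L
  if (!all(complete)) {
    warning("dropping ", sum(!complete), " gene(s) with incomplete ",
            "trajectories")
    M <- M[complete, , drop = FALSE]
  }
  if (k > nrow(M))
    stop("k = ", k, " exceeds the number of genes (", nrow(M), ")")
  hc <- stats::hclust(stats::dist(M), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  cent <- t(vapply(seq_len(k), function(cl)
    colMeans(M[raw == cl, , drop = FALSE]), numeric(ncol(M))))
  ord <- order(cent[, ncol(cent)], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cluster <- stats::setNames(relabel[raw], rownames(M))
  centroids <- cent[ord, , drop = FALSE]
  dimnames(centroids) <- list(paste0("cluster", seq_len(k)), colnames(M))
  list(cluster = cluster, centroids = centroids, hclust = hc)
}

#' Write hit-calling outputs as TSV
#'
#' `write_hits()` emits one row per gene with its per-day calls and
#' high-fidelity flags; `write_thresholds()` the per-day
#' `mean/sigma/lo/hi`; `write_diff()` the long differential table;
#' `write_clusters()` the cluster assignment.
#'
#' @param hit_table a flagged `hit_table`.
#' @param path file path.
#' @export
write_hits <- function(hit_table, path) {
  out <- data.frame(gene = rownames(hit_table$calls), hit_table$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(hit_table$flags))
    out <- cbind(out, hit_table$flags[match(out$gene, hit_table$flags$gene),
                                      c("hf_pos", "hf_neg", "ambiguous")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
write_thresholds <- function(hit_table, path) {
  utils::write.table(hit_table$thresholds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @param diff a `diff_beta` table.
#' @export
write_diff <- function(diff, path) {
  utils::write.table(diff, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @param clusters result of [cluster_trajectories()].
#' @export
write_clusters <- function(clusters, path) {
  out <- data.frame(gene = names(clusters$cluster),
                    cluster = unname(clusters$cluster),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
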