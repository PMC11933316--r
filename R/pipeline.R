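#' Run the genome-wide temporal screen workflow
#'
#' Wires the full analysis: control-based size factors, per-replicate
#' negative-binomial beta-score fits against the shared Day-0 baseline,
#' cell-cycle rescaling, differential beta (drug minus vehicle), replicate
#' averaging, mean +/- k sigma per-day calls, the high-fidelity recurrence
#' filter, and Ward clustering of the high-fidelity trajectories. Writes
#' `beta.tsv`, `diff.tsv`, `hits.tsv`, `thresholds.tsv`, `clusters.tsv`
#' and a `manifest.json` recording input checksums, parameters and package
#' version, so a run is reproducible from its manifest.
#'
#' @param counts path to a count TSV or a [count_matrix].
#' @param library path to a library CSV or an [sgrna_library].
#' @param out_dir output directory (created if needed).
#' @param k_sigma threshold multiplier for [select_hits()].
#' @param hf_days,min_days recurrence rule of [high_fidelity_hits()].
#' @param k_clusters cluster count for [cluster_trajectories()]; clustering
#'   is skipped (with a note in the manifest) when fewer high-fidelity
#'   genes than clusters exist.
#' @param per_replicate fit replicates independently (default).
#' @param reference_genes cell-cycle normalization reference set.
#' @return invisibly, a list with the in-memory results
#'   (`beta`, `diff`, `hits`, `clusters`, `manifest`).
#' @export
run_genomewide <- function(counts, library, out_dir,
                           k_sigma = 2, hf_days = c(6, 8, 10),
                           min_days = 2L, k_clusters = 6L,
                           per_replicate = TRUE, reference_genes = NULL) {
  paths <- character(0)
  if (is.character(library)) { paths["library"] <- library
    library <- read_library(library) }
  if (is.character(counts)) { paths["counts"] <- counts
    counts <- read_counts(counts, library) }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_seen <- character(0)
  wh <- function(w) { warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning") }

  res <- withCallingHandlers({
    beta <- fit_screen(counts, library, per_replicate = per_replicate)
    beta <- cellcycle_normalize(beta, reference_genes)
    diff <- differential_beta_table(beta)
    avg <- average_replicates(diff)
    hits <- select_hits(avg, k_sigma = k_sigma)
    hits <- high_fidelity_hits(hits, days = hf_days, min_days = min_days)
    hf_genes <- hits$flags$gene[hits$flags$hf_pos | hits$flags$hf_neg]
    clusters <- NULL
    if (length(hf_genes) >= k_clusters) {
      clusters <- cluster_trajectories(avg[avg$gene %in% hf_genes, ,
                                           drop = FALSE], k = k_clusters)
    } else {
      warning("fewer high-fidelity genes (", length(hf_genes),
              ") than clusters requested; clustering skipped")
    }
    list(beta = beta, diff = avg, diff_replicates = diff, hits = hits,
         clusters = clusters)
  }, warning = wh)

  write_beta(res$beta, file.path(out_dir, "beta.tsv"))
  write_diff(res$diff, file.path(out_dir, "diff.tsv"))
  write_hits(res$hits, file.path(out_dir, "hits.tsv"))
  write_thresholds(res$hits, file.path(out_dir, "thresholds.tsv"))
  if (!is.null(res$clusters))
    write_clusters(res$clusters, file.path(out_dir, "clusters.tsv"))

  manifest <- run_manifest("genomewide", paths,
                           params = list(k_sigma = k_sigma,
                                         hf_days = hf_days,
                                         min_days = min_days,
                                         k_clusters = k_clusters,
                                         per_replicate = per_replicate),
                           warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Run the tiling (domain-scanning) workflow
#'
#' Computes control-normalized per-sgRNA survival rates and domain-as-gene
#' beta-scores; writes `surv.tsv`, `domain_beta.tsv` and `manifest.json`.
#'
#' @inheritParams run_genomewide
#' @param days days for the survival rates; default every paired day.
#' @return invisibly, a list with `surv`, `domain_beta`, `manifest`.
#' @export
run_tiling <- function(counts, library, out_dir, days = NULL,
                       per_replicate = TRUE) {
  paths <- character(0)
  if (is.character(library)) { paths["library"] <- library
    library <- read_library(library) }
  if (is.character(counts)) { paths["counts"] <- counts
    counts <- read_counts(counts, library) }
  if (!any(library$class == "nontargeting"))
    stop("tiling analysis requires non-targeting control sgRNAs ",
         "for survival-rate normalization")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_seen <- character(0)
  wh <- function(w) { warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning") }
  res <- withCallingHandlers({
    surv <- survival_rates(counts, library, days = days)
    db <- domain_beta(counts, library, per_replicate = per_replicate)
    list(surv = surv, domain_beta = db)
  }, warning = wh)

  write_survival(res$surv, file.path(out_dir, "surv.tsv"))
  write_beta(res$domain_beta, file.path(out_dir, "domain_beta.tsv"))
  manifest <- run_manifest("tiling", paths,
                           params = list(days = days,
                                         per_replicate = per_replicate),
                           warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

run_manifest <- function(workflow, paths, params, warnings) {
  hashes <- if (length(paths))
    as.list(tools::md5sum(unname(paths))) else list()
  if (length(paths)) names(hashes) <- names(paths)
  list(workflow = workflow,
       package_version = as.character(utils::packageVersion("screenpulse")),
       r_version = as.character(getRversion()),
       inputs = hashes, parameters = params,
       warnings = as.list(warnings))
}
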