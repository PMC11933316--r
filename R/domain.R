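#' Per-sgRNA survival rates in a tiling screen
#'
#' For each sampling day with a paired drug/vehicle measurement: counts are
#' depth-normalized to counts-per-million, a 0.5 pseudocount is added,
#' replicates are averaged per (condition, day), the per-guide ratio
#' `rho = DAC / DMSO` is formed, and each ratio is divided by the mean ratio
#' of the non-targeting controls, so the control mean is exactly 1 at every
#' day. Values below 1 indicate drug sensitization of cells carrying the
#' guide, values above 1 resistance.
#'
#' @param counts a [count_matrix] with DMSO and DAC samples.
#' @param library an [sgrna_library] (tiling annotations are carried into
#'   the output).
#' @param ntc_ids non-targeting control sgRNA ids; defaults to the library's
#'   `nontargeting` class.
#' @param days days to evaluate; defaults to every day with both arms
#'   present. Days missing one arm are skipped with a warning.
#' @param pseudocount added to the CPM values before ratio formation.
#' @return data frame `sgRNA, gene, domain, cds_pos, day, survival_rate`.
#' @export
survival_rates <- function(counts, library, ntc_ids = NULL, days = NULL,
                           pseudocount = 0.5) {
  if (is.null(ntc_ids))
    ntc_ids <- library$sgRNA[library$class == "nontargeting"]
  if (length(ntc_ids) == 0L)
    stop("survival-rate normalization requires non-targeting control sgRNAs")
  rows <- rownames(counts$counts)
  if (!all(ntc_ids %in% rows))
    stop("control sgRNA(s) missing from counts: ",
         paste(setdiff(ntc_ids, rows), collapse = ", "))

  cpm <- sweep(counts$counts, 2L, colSums(counts$counts), "/") * 1e6 +
    pseudocount
  info <- counts$samples
  arm_mean <- function(cond, day) {
    sel <- info$condition == cond & info$day == day
    if (!any(sel)) return(NULL)
    rowMeans(cpm[, sel, drop = FALSE])
  }

  cand <- sort(unique(info$day[info$condition %in% c("DMSO", "DAC")]))
  if (is.null(days)) days <- cand
  out <- list()
  for (d in days) {
    dac <- arm_mean("DAC", d)
    dmso <- arm_mean("DMSO", d)
    if (is.null(dac) || is.null(dmso)) {
      warning("day ", d, " lacks a paired DAC/DMSO sample; skipped")
      next
    }
    rho <- dac / dmso
    ntc_mean <- mean(rho[ntc_ids])
    if (!is.finite(ntc_mean) || ntc_mean == 0)
      stop("non-targeting control mean ratio is zero on day ", d)
    s <- rho / ntc_mean
    lib_idx <- match(rows, library$sgRNA)
    out[[length(out) + 1L]] <- data.frame(
      sgRNA = rows, gene = library$gene[lib_idx],
      domain = library$domain[lib_idx], cds_pos = library$cds_pos[lib_idx],
      day = d, survival_rate = unname(s), stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) stop("no day with paired DAC/DMSO samples")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Domain-as-gene beta-scores for a tiling screen
#'
#' Regroups the tiling guides by their protein-domain label — each domain is
#' treated as a "gene" targeted by its guides — and delegates to
#' [fit_screen()]. Non-targeting and positive-control guides are excluded
#' from the domain groups; domains without guides are skipped.
#'
#' @param counts a [count_matrix].
#' @param library a tiling [sgrna_library] with `domain` labels.
#' @param ... passed to [fit_screen()] (`design`, `per_replicate`, ...).
#' @return a `beta_table` whose `gene` column holds domain labels.
#' @export
domain_beta <- function(counts, library, ...) {
  if (all(is.na(library$domain)))
    stop("library carries no domain labels")
  lib <- library
  keep_domain <- lib$class == "targeting" & !is.na(lib$domain)
  lib$gene[keep_domain] <- lib$domain[keep_domain]
  # guides outside any domain are dropped from the fits but kept for
  # normalization by reclassifying untargeted rows
  lib$class[lib$class == "targeting" & is.na(lib$domain)] <- "control"
  class(lib) <- class(library)
  fit_screen(counts, lib, ...)
}

#' Write a survival-rate table TSV
#'
#' @param surv output of [survival_rates()].
#' @param path file path.
#' @export
write_survival <- function(surv, path) {
  out <- surv
  out$domain[is.na(out$domain)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
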