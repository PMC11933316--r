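#' Simulation configuration
#'
#' Collects the parameters of the synthetic pooled-screen generator. The
#' defaults mirror the screen design the analysis targets: two replicates,
#' DMSO and DAC arms sampled at days 0, 2, 4, 6, 8 and 10, a genome-scale
#' library at roughly 100-fold sequencing representation, and
#' negative-binomial count noise.
#'
#' @param n_genes number of targeting genes.
#' @param sgrnas_per_gene guides per gene.
#' @param n_ntc non-targeting control guides.
#' @param timepoints_days strictly increasing sampling days, must include 0.
#' @param n_replicates number of screen replicates.
#' @param depth_per_sample expected total reads per sample; a warning is
#'   issued below 10 reads per sgRNA.
#' @param dispersion_sim negative-binomial overdispersion alpha used for
#'   sampling, with `Var = mu + alpha * mu^2`.
#' @param skew_sigma log-normal standard deviation of the initial library
#'   representation.
#' @param tau_days time constant (days) converting an effect size to
#'   per-day log-growth: an effect `e` contributes `e * t / tau_days` to the
#'   log-abundance at day `t`.
#' @param seed base seed; all sampling streams are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, sgrnas_per_gene = 4L, n_ntc = 100L,
                       timepoints_days = c(0L, 2L, 4L, 6L, 8L, 10L),
                       n_replicates = 2L, depth_per_sample = 1e6,
                       dispersion_sim = 0.05, skew_sigma = 0.5,
                       tau_days = 2, seed = 1L) {
  tp <- as.integer(timepoints_days)
  if (length(tp) < 1L || tp[1L] != 0L || is.unsorted(tp, strictly = TRUE))
    stop("timepoints_days must be strictly increasing and include day 0")
  if (dispersion_sim < 0) stop("dispersion_sim must be >= 0")
  if (tau_days <= 0) stop("tau_days must be positive")
  if (n_genes < 1 || sgrnas_per_gene < 1) stop("library sizes must be positive")
  n_sg <- n_genes * sgrnas_per_gene + n_ntc
  if (depth_per_sample < 10 * n_sg)
    warning("depth_per_sample below 10 reads per sgRNA; ",
            "counts will be representation-limited")
  cfg <- list(n_genes = as.integer(n_genes),
              sgrnas_per_gene = as.integer(sgrnas_per_gene),
              n_ntc = as.integer(n_ntc), timepoints_days = tp,
              n_replicates = as.integer(n_replicates),
              depth_per_sample = depth_per_sample,
              dispersion_sim = dispersion_sim, skew_sigma = skew_sigma,
              tau_days = tau_days, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the [sim_config()] argument names; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown sim_config field(s): ", paste(extra, collapse = ", "))
  do.call(sim_config, vals)
}

#' Draw ground-truth effects for a simulated screen
#'
#' Assigns per-gene fitness effects and per-guide properties, returned as a
#' truth table for recovery tests:
#' \itemize{
#'   \item a fraction `frac_resist` of targeting genes receives a treatment
#'     interaction `e = +effect_size` (drug-resistance when knocked out), a
#'     fraction `frac_sens` receives `e = -effect_size` (sensitization), the
#'     remainder `e = 0`;
#'   \item condition-shared baseline fitness `g ~ Normal(0, g_sd)`;
#'   \item per-guide cutting efficiency `w ~ Beta(5, 1)` for targeting
#'     guides, `w = 0` (and `g = e = 0`) for non-targeting guides;
#'   \item initial library representation `p(0)` drawn log-normal with
#'     log-sd `skew_sigma` and normalized to sum to one.
#' }
#'
#' @param library an [sgrna_library].
#' @param frac_resist,frac_sens fractions of genes planted as resistance /
#'   sensitization hits; must lie in `[0, 1]` and sum to at most 1.
#' @param effect_size treatment-interaction magnitude (log-fitness per
#'   `tau_days`).
#' @param seed integer seed.
#' @param g_sd standard deviation of the baseline-fitness null distribution.
#' @param skew_sigma log-normal SD of the initial representation.
#' @return a `sim_truth` list with data frames `genes`
#'   (`gene, baseline_effect, treatment_effect`) and `sgrnas`
#'   (`sgRNA, gene, efficiency, initial_fraction`).
#' @export
draw_effects <- function(library, frac_resist = 0.05, frac_sens = 0.05,
                         effect_size = 1.0, seed = 1L, g_sd = 0.1,
                         skew_sigma = 0.5) {
  if (frac_resist < 0 || frac_resist > 1 || frac_sens < 0 || frac_sens > 1)
    stop("frac_resist and frac_sens must lie in [0, 1]")
  if (frac_resist + frac_sens > 1)
    stop("frac_resist + frac_sens must not exceed 1")
  restore <- set_local_seed(seed)
  on.exit(restore())

  targeting <- library$class == "targeting"
  genes <- unique(library$gene[targeting])
  n_genes <- length(genes)
  n_res <- floor(frac_resist * n_genes)
  n_sen <- floor(frac_sens * n_genes)
  hit_idx <- sample.int(n_genes, n_res + n_sen)
  e <- numeric(n_genes)
  e[hit_idx[seq_len(n_res)]] <- effect_size
  if (n_sen > 0L) e[hit_idx[n_res + seq_len(n_sen)]] <- -effect_size
  g <- stats::rnorm(n_genes, 0, g_sd)

  gene_tab <- data.frame(gene = genes, baseline_effect = g,
                         treatment_effect = e, stringsAsFactors = FALSE)

  w <- numeric(nrow(library))
  w[targeting] <- stats::rbeta(sum(targeting), 5, 1)
  p0 <- stats::rlnorm(nrow(library), 0, skew_sigma)
  p0 <- p0 / sum(p0)
  sg_tab <- data.frame(sgRNA = library$sgRNA, gene = library$gene,
                       efficiency = w, initial_fraction = p0,
                       stringsAsFactors = FALSE)
  structure(list(genes = gene_tab, sgrnas = sg_tab), class = "sim_truth")
}

# Gamma-Poisson draw of NegBin(mean mu, Var = mu + alpha mu^2); valid for
# non-integer 1/alpha, exact Poisson at alpha = 0.
rnb_gamma_pois <- function(mu, alpha) {
  if (alpha <= 0) return(stats::rpois(length(mu), mu))
  lam <- stats::rgamma(length(mu), shape = 1 / alpha, rate = 1 / (alpha * mu))
  stats::rpois(length(lam), lam)
}

#' Expected relative sgRNA abundance under the selection model
#'
#' The generator's abundance model: guide `i` of gene `g` grows as
#' `p_i(t) proportional to p_i(0) * exp((g_g + [DAC] * e_g) * w_i * t / tau)`,
#' renormalized to sum to one across the library.
#'
#' @param truth a `sim_truth` from [draw_effects()].
#' @param day sampling day.
#' @param condition `"BASE"`, `"DMSO"` or `"DAC"`.
#' @param tau_days time constant in days.
#' @return numeric vector of relative abundances summing to one, in the
#'   order of `truth$sgrnas`.
#' @export
expected_abundance <- function(truth, day, condition, tau_days) {
  sg <- truth$sgrnas
  idx <- match(sg$gene, truth$genes$gene)
  g <- ifelse(is.na(idx), 0, truth$genes$baseline_effect[idx])
  e <- ifelse(is.na(idx), 0, truth$genes$treatment_effect[idx])
  rate <- g + if (identical(condition, "DAC")) e else 0
  p <- sg$initial_fraction * exp(rate * sg$efficiency * day / tau_days)
  p / sum(p)
}

#' Simulate a pooled-screen count matrix
#'
#' Draws sgRNA counts for every (replicate, condition, day) sample from the
#' selection model of [expected_abundance()] with negative-binomial noise
#' (`Var = mu + alpha * mu^2`, via a Gamma-Poisson mixture). Day 0 is shared
#' between the two arms of a replicate: each replicate has a single
#' `REP{r}_BASE_D0` sample. Sampling uses one derived seed per
#' (replicate, condition, day) stream, so results do not depend on sampling
#' order.
#'
#' @param library an [sgrna_library].
#' @param truth a `sim_truth` covering every sgRNA in `library`.
#' @param config a [sim_config()].
#' @return a [count_matrix].
#' @export
simulate_screen <- function(library, truth, config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!setequal(truth$sgrnas$sgRNA, library$sgRNA) ||
      nrow(truth$sgrnas) != nrow(library))
    stop("truth table does not cover the library's sgRNAs")
  ord <- match(library$sgRNA, truth$sgrnas$sgRNA)
  truth <- list(genes = truth$genes, sgrnas = truth$sgrnas[ord, , drop = FALSE])
  class(truth) <- "sim_truth"

  tp <- config$timepoints_days
  later <- tp[tp > 0L]
  plan <- rbind(
    expand.grid(replicate = seq_len(config$n_replicates),
                condition = "BASE", day = 0L, stringsAsFactors = FALSE),
    expand.grid(replicate = seq_len(config$n_replicates),
                condition = c("DMSO", "DAC"), day = later,
                stringsAsFactors = FALSE)
  )
  plan <- plan[order(plan$replicate, match(plan$condition,
                                           c("BASE", "DMSO", "DAC")),
                     plan$day), , drop = FALSE]
  rownames(plan) <- NULL
  plan$sample <- sprintf("REP%d_%s_D%d", plan$replicate, plan$condition,
                         plan$day)
  seeds <- substream_seeds(config$seed, nrow(plan))

  counts <- matrix(0L, nrow(library), nrow(plan),
                   dimnames = list(library$sgRNA, plan$sample))
  for (j in seq_len(nrow(plan))) {
    p <- expected_abundance(truth, plan$day[j], plan$condition[j],
                            config$tau_days)
    restore <- set_local_seed(seeds[j])
    counts[, j] <- rnb_gamma_pois(config$depth_per_sample * p,
                                  config$dispersion_sim)
    restore()
  }
  new_count_matrix(counts, library$gene,
                   plan[, c("sample", "condition", "day", "replicate")])
}

#' Write / read a simulation truth table
#'
#' Two stacked TSV sections: per-gene effects
#' (`gene, baseline_effect, treatment_effect`) and per-sgRNA properties
#' (`sgRNA, gene, efficiency, initial_fraction`), separated by a blank line.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(truth$genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  utils::write.table(truth$sgrnas, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "")[1L]
  genes <- utils::read.delim(text = lines[seq_len(sep - 1L)],
                             stringsAsFactors = FALSE)
  sgrnas <- utils::read.delim(text = lines[(sep + 1L):length(lines)],
                              stringsAsFactors = FALSE)
  structure(list(genes = genes, sgrnas = sgrnas), class = "sim_truth")
}
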