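#' sgRNA library tables
#'
#' An sgRNA library is a data frame with one row per guide and columns
#' `sgRNA` (unique identifier), `gene` (target gene, `"NTC"` for
#' non-targeting guides), `class` (one of `"targeting"`, `"nontargeting"`,
#' `"control"`), and, for tiling libraries, `domain` (protein domain label)
#' and `cds_pos` (1-based nucleotide position of the cut site within the
#' coding sequence). Non-tiling libraries carry `NA` in the last two columns.
#'
#' @name sgrna_library
NULL

LIBRARY_CLASSES <- c("targeting", "nontargeting", "control")

new_sgrna_library <- function(df) {
  stopifnot(all(c("sgRNA", "gene", "class") %in% names(df)))
  if (is.null(df$domain)) df$domain <- NA_character_
  if (is.null(df$cds_pos)) df$cds_pos <- NA_integer_
  df <- df[, c("sgRNA", "gene", "class", "domain", "cds_pos")]
  rownames(df) <- NULL
  validate_sgrna_library(df)
  class(df) <- c("sgrna_library", "data.frame")
  df
}

validate_sgrna_library <- function(df) {
  if (anyDuplicated(df$sgRNA))
    stop("duplicate sgRNA identifiers: ",
         paste(unique(df$sgRNA[duplicated(df$sgRNA)]), collapse = ", "))
  if (any(!nzchar(df$gene) | is.na(df$gene)))
    stop("every library record needs a non-empty gene id")
  bad <- setdiff(unique(df$class), LIBRARY_CLASSES)
  if (length(bad))
    stop("unknown sgRNA class: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Construct a synthetic genome-wide sgRNA library
#'
#' Builds a Brunello-style library layout: `n_genes` targeting genes with
#' `sgrnas_per_gene` guides each, plus `n_ntc` non-targeting control guides
#' (gene id `"NTC"`, class `"nontargeting"`). Identifier construction is
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generators.
#'
#' @param n_genes positive integer, number of targeting genes.
#' @param sgrnas_per_gene positive integer, guides per gene.
#' @param n_ntc non-negative integer, number of non-targeting controls.
#' @param seed integer, unused source of randomness kept for determinism
#'   contracts across the simulator API.
#' @return An [sgrna_library] data frame with
#'   `n_genes * sgrnas_per_gene + n_ntc` rows.
#' @examples
#' lib <- make_library(n_genes = 2, sgrnas_per_gene = 4, n_ntc = 3)
#' nrow(lib)                      # 11
#' sum(lib$class == "nontargeting")  # 3
#' @export
make_library <- function(n_genes, sgrnas_per_gene, n_ntc = 0L, seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (!is.numeric(sgrnas_per_gene) || length(sgrnas_per_gene) != 1L ||
      sgrnas_per_gene < 1)
    stop("sgrnas_per_gene must be a positive integer")
  if (!is.numeric(n_ntc) || n_ntc < 0)
    stop("n_ntc must be a non-negative integer")
  n_genes <- as.integer(n_genes)
  sgrnas_per_gene <- as.integer(sgrnas_per_gene)
  n_ntc <- as.integer(n_ntc)

  genes <- sprintf("GENE%04d", seq_len(n_genes))
  targ <- data.frame(
    sgRNA = paste0(rep(genes, each = sgrnas_per_gene), "_sg",
                   rep(seq_len(sgrnas_per_gene), times = n_genes)),
    gene = rep(genes, each = sgrnas_per_gene),
    class = "targeting",
    stringsAsFactors = FALSE
  )
  ntc <- if (n_ntc > 0L) {
    data.frame(
      sgRNA = sprintf("NTC_sg%03d", seq_len(n_ntc)),
      gene = "NTC",
      class = "nontargeting",
      stringsAsFactors = FALSE
    )
  } else {
    targ[0L, ]
  }
  new_sgrna_library(rbind(targ, ntc))
}

#' Default KDM1A-style domain specification
#'
#' A synthetic stand-in for a demethylase domain-scanning design: five
#' domains over a 2559-nt coding sequence (an 852-residue protein) with
#' per-domain guide counts summing to 58. The real design's per-domain
#' coordinates and counts are not public, so these intervals are a plausible
#' synthetic layout: an N-terminal flexible region (NFR), the SWIRM domain,
#' the amine-oxidase domain split in two by the TOWER insertion.
#'
#' @return data frame with columns `domain`, `start`, `end`, `n_sgrna`
#'   (1-based inclusive nucleotide intervals on the coding sequence).
#' @export
kdm1a_domain_spec <- function() {
  data.frame(
    domain = c("NFR", "SWIRM", "AOD_N", "TOWER", "AOD_C"),
    start = c(1L, 516L, 813L, 1248L, 1608L),
    end = c(515L, 812L, 1247L, 1607L, 2559L),
    n_sgrna = c(10L, 10L, 14L, 10L, 14L),
    stringsAsFactors = FALSE
  )
}

#' Construct a tiling (domain-scanning) sgRNA library
#'
#' Targeting guides are placed at seeded random, strictly increasing
#' positions within each domain's coding-sequence interval and labelled with
#' the domain name. The library additionally carries `n_ntc` non-targeting
#' guides and `n_control` positive-control guides (class `"control"`,
#' gene `control_gene`).
#'
#' @param domain_spec data frame with columns `domain`, `start`, `end`
#'   (1-based inclusive nucleotide intervals), `n_sgrna`. Defaults to
#'   [kdm1a_domain_spec()].
#' @param n_tiling expected total number of tiling guides; an error is
#'   raised when the per-domain counts do not sum to it.
#' @param n_ntc number of non-targeting control guides.
#' @param n_control number of positive-control guides.
#' @param target_gene gene id for the tiled gene.
#' @param control_gene gene id for the positive controls.
#' @param seed integer seed for the guide positions.
#' @return An [sgrna_library] with `n_tiling + n_ntc + n_control` rows.
#' @examples
#' lib <- make_tiling_library()
#' nrow(lib)  # 70
#' table(lib$class)
#' @export
make_tiling_library <- function(domain_spec = kdm1a_domain_spec(),
                                n_tiling = 58L, n_ntc = 10L, n_control = 2L,
                                target_gene = "KDM1A",
                                control_gene = "DCK", seed = 1L) {
  need <- c("domain", "start", "end", "n_sgrna")
  if (!all(need %in% names(domain_spec)))
    stop("domain_spec needs columns ", paste(need, collapse = ", "))
  if (any(domain_spec$end < domain_spec$start))
    stop("domain intervals must have end >= start")
  if (sum(domain_spec$n_sgrna) != n_tiling)
    stop("per-domain sgRNA counts sum to ", sum(domain_spec$n_sgrna),
         ", expected n_tiling = ", n_tiling)
  if (any(domain_spec$n_sgrna > domain_spec$end - domain_spec$start + 1L))
    stop("a domain interval is shorter than its requested sgRNA count")
  sp <- domain_spec[order(domain_spec$start), , drop = FALSE]
  if (nrow(sp) > 1L && any(sp$start[-1L] <= sp$end[-nrow(sp)]))
    warning("domain intervals overlap")

  withr_seed <- set_local_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  rows <- lapply(seq_len(nrow(domain_spec)), function(j) {
    d <- domain_spec[j, ]
    pos <- sort(sample(seq.int(d$start, d$end), d$n_sgrna))
    data.frame(
      sgRNA = sprintf("%s_%s_sg%02d", target_gene, d$domain,
                      seq_len(d$n_sgrna)),
      gene = target_gene,
      class = "targeting",
      domain = d$domain,
      cds_pos = as.integer(pos),
      stringsAsFactors = FALSE
    )
  })
  tiling <- do.call(rbind, rows)
  ntc <- if (n_ntc > 0L) data.frame(
    sgRNA = sprintf("NTC_sg%03d", seq_len(n_ntc)),
    gene = "NTC", class = "nontargeting",
    domain = NA_character_, cds_pos = NA_integer_,
    stringsAsFactors = FALSE
  )
  ctl <- if (n_control > 0L) data.frame(
    sgRNA = sprintf("%s_sg%02d", control_gene, seq_len(n_control)),
    gene = control_gene, class = "control",
    domain = NA_character_, cds_pos = NA_integer_,
    stringsAsFactors = FALSE
  )
  new_sgrna_library(rbind(tiling, ntc, ctl))
}

#' Read / write a library CSV
#'
#' The on-disk format is a CSV with header `sgRNA,gene,class,domain,cds_pos`;
#' `domain` and `cds_pos` are empty for non-tiling guides.
#'
#' @param path file path.
#' @return `read_library()` returns an [sgrna_library]; `write_library()`
#'   returns `path` invisibly.
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          sgRNA = "character", gene = "character",
                          class = "character", domain = "character",
                          cds_pos = "integer"
                        ))
  need <- c("sgRNA", "gene", "class", "domain", "cds_pos")
  if (!identical(names(df), need))
    stop("malformed library header in ", path, ": expected ",
         paste(need, collapse = ","))
  df$domain[!nzchar(df$domain) | is.na(df$domain)] <- NA_character_
  new_sgrna_library(df)
}

#' @rdname read_library
#' @param library an [sgrna_library].
#' @export
write_library <- function(library, path) {
  out <- as.data.frame(library)
  out$domain[is.na(out$domain)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Seed handling: save and restore the caller's RNG state so seeded package
# functions do not perturb the session stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Deterministic substream seeds below 2^31, derived once from a base seed.
substream_seeds <- function(seed, n) {
  restore <- set_local_seed(seed)
  on.exit(restore())
  sample.int(2147483646L, n)
}
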