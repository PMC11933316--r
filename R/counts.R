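#' sgRNA count matrices
#'
#' A `count_matrix` bundles a non-negative integer sgRNA-by-sample count
#' matrix with per-sample metadata and optional size factors:
#' \describe{
#'   \item{counts}{integer matrix, rownames = sgRNA ids, colnames = sample
#'     names of the form `REP{r}_{COND}_D{day}` (`REP{r}_BASE_D0` for the
#'     shared Day-0 baseline of a replicate).}
#'   \item{gene}{character vector of gene ids aligned to the rows.}
#'   \item{samples}{data frame with columns `sample`, `condition`
#'     (`BASE`/`DMSO`/`DAC`), `day`, `replicate`.}
#'   \item{size_factors}{optional strictly positive per-sample scalars.}
#' }
#'
#' @name count_matrix
NULL

new_count_matrix <- function(counts, gene, samples, size_factors = NULL) {
  storage.mode(counts) <- "integer"
  if (any(counts < 0L, na.rm = TRUE)) stop("counts must be non-negative")
  if (length(gene) != nrow(counts))
    stop("gene annotation does not match count rows")
  if (nrow(samples) != ncol(counts))
    stop("sample metadata does not match count columns")
  if (!is.null(size_factors) && any(size_factors <= 0))
    stop("size factors must be strictly positive")
  obj <- list(counts = counts, gene = as.character(gene),
              samples = samples, size_factors = size_factors)
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "sgRNAs x", ncol(x$counts),
      "samples\n")
  cat("conditions:", paste(sort(unique(x$samples$condition)), collapse = " "),
      "| days:", paste(sort(unique(x$samples$day)), collapse = " "),
      "| replicates:", length(unique(x$samples$replicate)), "\n")
  if (!is.null(x$size_factors)) cat("size factors attached\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Parse screen sample names
#'
#' Sample names follow `REP{r}_{COND}_D{day}` with `COND` one of `BASE`,
#' `DMSO`, `DAC` (`BASE` only at Day 0).
#'
#' @param x character vector of sample names.
#' @return data frame with columns `sample`, `condition`, `day`, `replicate`.
#' @export
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^REP([0-9]+)_(BASE|DMSO|DAC)_D([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed sample name(s): ", paste(x[bad], collapse = ", "),
         " (expected REP{r}_{BASE|DMSO|DAC}_D{day})")
  data.frame(
    sample = x,
    condition = vapply(m, `[`, "", 3L),
    day = as.integer(vapply(m, `[`, "", 4L)),
    replicate = as.integer(vapply(m, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Read an sgRNA count table
#'
#' Tab-separated with header `sgRNA<TAB>gene<TAB><sample>...`; sample columns
#' must parse per [parse_sample_names()]. Counts must be non-negative
#' integers; format violations are reported with the offending line number.
#'
#' @param path file path.
#' @param library optional [sgrna_library]; when supplied, count rows whose
#'   sgRNA is absent from the library raise an error unless
#'   `allow_unknown = TRUE`.
#' @param allow_unknown keep rows not present in `library` instead of
#'   erroring.
#' @return a [count_matrix].
#' @export
read_counts <- function(path, library = NULL, allow_unknown = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "sgRNA" || names(df)[2L] != "gene")
    stop("malformed count header in ", path,
         ": expected sgRNA<TAB>gene<TAB><samples>")
  dup <- duplicated(df$sgRNA)
  if (any(dup))
    stop("duplicate sgRNA id at line ", which(dup)[1L] + 1L, ": ",
         df$sgRNA[which(dup)[1L]])
  samp <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(samp))
    stop("non-numeric count field in ", path)
  bad <- which(samp < 0 | samp != floor(samp), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at line ", bad[1L, 1L] + 1L,
         ", sample ", colnames(samp)[bad[1L, 2L]])
  if (!is.null(library)) {
    unknown <- setdiff(df$sgRNA, library$sgRNA)
    if (length(unknown) && !allow_unknown)
      stop("count file contains sgRNA(s) absent from the library: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  rownames(samp) <- df$sgRNA
  new_count_matrix(samp, df$gene, parse_sample_names(colnames(samp)))
}

#' Write an sgRNA count table
#'
#' @param counts a [count_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  out <- data.frame(sgRNA = rownames(counts$counts), gene = counts$gene,
                    counts$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Control-based median-ratio size factors
#'
#' DESeq-style median-of-ratios normalization restricted to a control guide
#' set: for each control sgRNA with all-positive counts, the geometric mean
#' across samples is computed; the size factor of a sample is the median over
#' those controls of count / geometric mean. Controls with any zero count are
#' dropped from the median; if that empties the control set, all sgRNAs with
#' all-positive counts are used instead (with a warning).
#'
#' @param counts a [count_matrix] or an integer matrix.
#' @param control_ids character vector of control sgRNA ids.
#' @return named numeric vector of strictly positive per-sample size factors.
#' @examples
#' m <- rbind(A = c(10L, 20L), B = c(100L, 100L))
#' colnames(m) <- c("REP1_BASE_D0", "REP1_DAC_D2")
#' size_factors_control(m, "A")  # c(0.7071, 1.4142)
#' @export
size_factors_control <- function(counts, control_ids) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (length(control_ids) == 0L) stop("control_ids must be non-empty")
  missing_ctl <- setdiff(control_ids, rownames(m))
  if (length(missing_ctl))
    stop("control sgRNA(s) not present in counts: ",
         paste(utils::head(missing_ctl, 5L), collapse = ", "))
  ratio_set <- function(ids) {
    sub <- m[ids, , drop = FALSE]
    keep <- rowSums(sub == 0L) == 0L
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    g <- exp(rowMeans(log(sub)))
    sub / g
  }
  ratios <- ratio_set(control_ids)
  if (is.null(ratios)) {
    warning("all control sgRNAs have a zero count in some sample; ",
            "falling back to all all-positive sgRNAs")
    ratios <- ratio_set(rownames(m))
    if (is.null(ratios))
      stop("normalization failed: no sgRNA has all-positive counts")
  }
  s <- apply(ratios, 2L, stats::median)
  names(s) <- colnames(m)
  s
}

#' Size-factor-normalized counts
#'
#' Raw counts divided column-wise by per-sample size factors. Raw counts are
#' never overwritten; the likelihood model consumes raw counts plus size
#' factors, normalized counts are for inspection and moment estimates.
#'
#' @param counts a [count_matrix] or matrix.
#' @param size_factors per-sample positive scalars; defaults to the ones
#'   stored in `counts`.
#' @return numeric matrix of normalized counts.
#' @export
normalized_counts <- function(counts, size_factors = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(size_factors) && inherits(counts, "count_matrix"))
    size_factors <- counts$size_factors
  if (is.null(size_factors)) stop("size_factors required")
  sweep(m, 2L, size_factors, "/")
}
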