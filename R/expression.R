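#' Construct a gene-level count matrix with sample metadata
#'
#' The basic container for the pipeline: integer fragment counts per gene
#' per sample, per-gene exonic lengths, and a metadata table describing
#' each sample (sex, organ, developmental stage, replicate).
#'
#' @param counts integer matrix, genes x samples, with gene IDs as row
#'   names and sample IDs as column names.
#' @param gene_length positive integer vector of per-gene lengths in bp,
#'   named by gene ID (or in row order of `counts`).
#' @param samples data.frame with columns `sample_id`, `sex`
#'   (female/male/supermale), `organ` (tepal/pistil/stamen/bud/speartip),
#'   `stage`, `replicate`; one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_length, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated gene ID: %s",
          rownames(counts)[anyDuplicated(rownames(counts))])
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  storage.mode(counts) <- "integer"

  if (!is.null(names(gene_length))) {
    missing <- setdiff(rownames(counts), names(gene_length))
    if (length(missing))
      stopf("gene_length missing for gene '%s'", missing[1])
    gene_length <- gene_length[rownames(counts)]
  } else {
    if (length(gene_length) != nrow(counts))
      stopf("gene_length has %d entries for %d genes",
            length(gene_length), nrow(counts))
    names(gene_length) <- rownames(counts)
  }
  if (any(gene_length <= 0)) stopf("gene lengths must be positive")

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "organ", "stage", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stopf("sample metadata lacks column '%s'", miss[1])
  if (anyDuplicated(samples$sample_id))
    stopf("duplicated sample_id in metadata: %s",
          samples$sample_id[anyDuplicated(samples$sample_id)])
  absent <- setdiff(colnames(counts), samples$sample_id)
  if (length(absent))
    stopf("sample '%s' present in counts but absent from metadata", absent[1])
  bad_sex <- setdiff(unique(samples$sex), SEXES)
  if (length(bad_sex)) stopf("unknown sex level '%s'", bad_sex[1])
  bad_org <- setdiff(unique(samples$organ), ORGANS)
  if (length(bad_org)) stopf("unknown organ level '%s'", bad_org[1])
  # metadata kept in count-column order
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  structure(
    list(counts = counts,
         gene_length = as.integer(gene_length),
         samples = samples),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("organs:", paste(unique(x$samples$organ), collapse = ", "), "\n")
  cat("sexes: ", paste(unique(x$samples$sex), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and sample metadata from TSV files
#'
#' The counts file holds one row per gene: `gene_id`, `gene_length_bp`,
#' then one column of integer fragment counts per sample. The metadata
#' file holds `sample_id`, `sex`, `organ`, `stage`, `replicate`. Every
#' sample column in the counts header must appear in the metadata.
#'
#' @param counts_path path to the counts TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stopf("counts file not found: %s", counts_path)
  if (!file.exists(metadata_path))
    stopf("metadata file not found: %s", metadata_path)
  tab <- read_tsv(counts_path)
  if (ncol(tab) < 3 || names(tab)[1] != "gene_id" ||
      names(tab)[2] != "gene_length_bp")
    stopf("counts TSV must start with columns gene_id, gene_length_bp")
  meta <- read_tsv(metadata_path)
  sample_ids <- names(tab)[-(1:2)]
  absent <- setdiff(sample_ids, meta$sample_id)
  if (length(absent))
    stopf("sample '%s' in counts header missing from metadata", absent[1])

  cn <- as.matrix(tab[, -(1:2), drop = FALSE])
  bad <- which(is.na(cn) | cn != round(cn), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-integer count at gene row %d, sample column '%s'",
          bad[1, 1], sample_ids[bad[1, 2]])
  rownames(cn) <- tab$gene_id
  count_matrix(cn, stats::setNames(tab$gene_length_bp, tab$gene_id),
               meta[match(sample_ids, meta$sample_id), , drop = FALSE])
}

#' Write a count matrix (and its metadata) back to TSV
#'
#' Inverse of [read_counts()]; used by the fixture generator.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,metadata_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(cm, counts_path, metadata_path) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   gene_length_bp = cm$gene_length,
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$samples, metadata_path)
  invisible(c(counts_path, metadata_path))
}

#' Compute FPKM values from fragment counts
#'
#' FPKM (fragments per kilobase of exon per million mapped fragments) for
#' gene g in sample s is `c_gs * 1e9 / (L_g * N_s)`, where `c_gs` is the
#' fragment count, `L_g` the gene length in bp and `N_s` the sample's
#' library size. By default `N_s` is the column sum of the counts, which
#' keeps the computation self-contained; a per-sample override can be
#' supplied when an external mapped-fragment total is preferred.
#'
#' @param cm a [count_matrix()].
#' @param library_size optional named numeric vector of per-sample library
#'   sizes overriding the column sums.
#' @return An object of class `expression_matrix` with fields `fpkm`
#'   (genes x samples), `gene_length`, `library_size` and `samples`.
#' @export
compute_fpkm <- function(cm, library_size = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  N <- colSums(cm$counts)
  if (!is.null(library_size)) {
    missing <- setdiff(colnames(cm$counts), names(library_size))
    if (length(missing))
      stopf("library_size override missing sample '%s'", missing[1])
    N <- library_size[colnames(cm$counts)]
  }
  zero <- names(N)[N <= 0]
  if (length(zero))
    stopf("sample '%s' has zero total counts; FPKM undefined", zero[1])
  fpkm <- sweep(cm$counts * 1e9 / cm$gene_length, 2, N, "/")
  structure(
    list(fpkm = fpkm,
         gene_length = cm$gene_length,
         library_size = N,
         samples = cm$samples),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (FPKM): %d genes x %d samples\n",
              nrow(x$fpkm), ncol(x$fpkm)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$fpkm)

#' Log10-transform an FPKM matrix
#'
#' Elementwise `log10(FPKM + pseudocount)`. The default pseudocount of 1
#' maps FPKM 0 to 0 on the log scale, the convention used for expression
#' heat maps.
#'
#' @param em an `expression_matrix` (or a bare numeric matrix).
#' @param pseudocount non-negative offset; must be > 0 when the matrix
#'   contains zeros.
#' @return Numeric matrix of log10-transformed values.
#' @export
log_transform <- function(em, pseudocount = 1) {
  m <- if (inherits(em, "expression_matrix")) em$fpkm else as.matrix(em)
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  if (pseudocount == 0 && any(m == 0))
    stopf("matrix contains zeros; a positive pseudocount is required")
  log10(m + pseudocount)
}

#' Filter genes by a minimum FPKM threshold
#'
#' Retains genes whose FPKM strictly exceeds `threshold` in at least one
#' sample (`mode = "any_sample"`) or in every sample
#' (`mode = "all_samples"`). Strict inequality implements the "higher
#' than" reading of the thresholds used throughout this pipeline.
#'
#' @param em an `expression_matrix`.
#' @param threshold non-negative FPKM cutoff.
#' @param mode `"any_sample"` (default) or `"all_samples"`.
#' @return An `expression_matrix` restricted to the retained genes.
#' @export
filter_min_fpkm <- function(em, threshold,
                            mode = c("any_sample", "all_samples")) {
  stopifnot(inherits(em, "expression_matrix"))
  mode <- match.arg(mode)
  if (threshold < 0) stopf("threshold must be non-negative")
  keep <- if (mode == "any_sample") {
    apply(em$fpkm > threshold, 1, any)
  } else {
    apply(em$fpkm > threshold, 1, all)
  }
  em$fpkm <- em$fpkm[keep, , drop = FALSE]
  em$gene_length <- em$gene_length[keep]
  em
}
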