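#' Define a sex contrast within one organ and stage
#'
#' A contrast compares two sexes within a single floral organ (or tissue)
#' at one developmental stage; samples from any other organ or stage are
#' never consulted when extracting SDEGs for the contrast.
#'
#' @param organ one of tepal, pistil, stamen, bud, speartip.
#' @param stage stage label as used in the sample metadata.
#' @param sex_a,sex_b the two sexes compared; must differ.
#' @return An object of class `contrast`.
#' @export
contrast <- function(organ, stage, sex_a, sex_b) {
  if (!organ %in% ORGANS) stopf("unknown organ '%s'", organ)
  if (!sex_a %in% SEXES) stopf("unknown sex '%s'", sex_a)
  if (!sex_b %in% SEXES) stopf("unknown sex '%s'", sex_b)
  if (identical(sex_a, sex_b)) stopf("contrast sexes must differ")
  structure(list(organ = organ, stage = as.character(stage),
                 sex_a = sex_a, sex_b = sex_b),
            class = "contrast")
}

#' @export
format.contrast <- function(x, ...) {
  sprintf("%s_%s_%s_vs_%s", x$organ, x$stage, x$sex_a, x$sex_b)
}

#' @export
print.contrast <- function(x, ...) {
  cat("contrast:", format(x), "\n"); invisible(x)
}

contrast_samples <- function(em, ct, sex) {
  s <- em$samples
  s$sample_id[s$organ == ct$organ & s$stage == ct$stage & s$sex == sex]
}

#' Extract sex-dependently expressed genes (SDEGs) for one contrast
#'
#' A gene is an SDEG favoring sex X when its mean FPKM across X's
#' replicates exceeds `fpkm_threshold` AND exceeds `fold_threshold` times
#' the mean FPKM in the other sex, both strictly. Replicates are combined
#' by the arithmetic mean of FPKM per side before testing. With the
#' defaults (5, 5) this is the published SDEG criterion: FPKM higher than
#' 5 and more than 5-fold higher in one sex than in the other. A side
#' with mean 0 never blocks the other side (the ratio condition reduces
#' to mean > 0 there, already implied by mean > threshold).
#'
#' @param em an `expression_matrix`.
#' @param ct a [contrast()]; both sides must have at least one sample.
#' @param fpkm_threshold minimum mean FPKM in the favored sex (default 5).
#' @param fold_threshold minimum fold difference over the other sex
#'   (default 5).
#' @return A list of two `sdeg_set` objects, named by favored sex, each
#'   with fields `contrast`, `favored_sex`, `gene_ids`, `fpkm_threshold`,
#'   `fold_threshold`.
#' @export
extract_sdegs <- function(em, ct, fpkm_threshold = 5, fold_threshold = 5) {
  stopifnot(inherits(em, "expression_matrix"), inherits(ct, "contrast"))
  ids_a <- contrast_samples(em, ct, ct$sex_a)
  ids_b <- contrast_samples(em, ct, ct$sex_b)
  if (!length(ids_a))
    stopf("contrast side '%s' has no samples in %s at stage %s",
          ct$sex_a, ct$organ, ct$stage)
  if (!length(ids_b))
    stopf("contrast side '%s' has no samples in %s at stage %s",
          ct$sex_b, ct$organ, ct$stage)
  mean_a <- rowMeans(em$fpkm[, ids_a, drop = FALSE])
  mean_b <- rowMeans(em$fpkm[, ids_b, drop = FALSE])
  pick <- function(hi, lo, sex) {
    genes <- rownames(em$fpkm)[hi > fpkm_threshold & hi > fold_threshold * lo]
    structure(list(contrast = ct, favored_sex = sex, gene_ids = genes,
                   fpkm_threshold = fpkm_threshold,
                   fold_threshold = fold_threshold),
              class = "sdeg_set")
  }
  out <- list(pick(mean_a, mean_b, ct$sex_a), pick(mean_b, mean_a, ct$sex_b))
  names(out) <- c(ct$sex_a, ct$sex_b)
  out
}

#' @export
format.sdeg_set <- function(x, ...) {
  sprintf("%s_%s_%s", x$contrast$organ, x$contrast$stage, x$favored_sex)
}

#' @export
print.sdeg_set <- function(x, ...) {
  cat(sprintf("sdeg_set %s: %d genes (FPKM > %g, fold > %g)\n",
              format(x), length(x$gene_ids),
              x$fpkm_threshold, x$fold_threshold))
  invisible(x)
}

#' Jaccard index of two gene-ID sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param a,b character vectors of gene IDs (duplicates ignored).
#' @return A number in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over SDEG sets
#'
#' @param sets a non-empty list of `sdeg_set` objects (or bare character
#'   vectors); names are taken from the list or via `format()`.
#' @return Symmetric numeric matrix of pairwise Jaccard indices.
#' @export
jaccard_matrix <- function(sets) {
  if (!length(sets)) stopf("at least one set is required")
  ids <- lapply(sets, function(s)
    if (inherits(s, "sdeg_set")) s$gene_ids else as.character(s))
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(sets, function(s)
      if (inherits(s, "sdeg_set")) format(s) else NA_character_,
      character(1))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n))
    for (j in i:n)
      m[i, j] <- m[j, i] <- jaccard_index(ids[[i]], ids[[j]])
  m
}

#' Write SDEG sets to a two-column TSV (set_name, gene_id)
#'
#' @param sets list of `sdeg_set` objects.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sdeg_sets <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    if (length(s$gene_ids) == 0) return(NULL)
    data.frame(set_name = format(s), gene_id = s$gene_ids,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(set_name = character(), gene_id = character())
  write_tsv(rows, path)
}
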