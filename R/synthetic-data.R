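#' Default experimental design of the emulated floral-organ study
#'
#' Two sexes (female and supermale) by three floral organs (tepal,
#' pistil, stamen) sampled at a postmeiotic stage with two biological
#' replicates each, plus staged whole-bud samples (premeiotic, meiotic,
#' postmeiotic; female and male) and speartip samples, mirroring the
#' layout of a dioecious-asparagus floral transcriptome experiment.
#'
#' @return data.frame with columns `sex`, `organ`, `stage`,
#'   `n_replicates`.
#' @export
default_design <- function() {
  rbind(
    expand.grid(sex = c("female", "supermale"),
                organ = c("tepal", "pistil", "stamen"),
                stage = "postmeiotic", n_replicates = 2,
                stringsAsFactors = FALSE),
    expand.grid(sex = c("female", "male"),
                organ = "bud",
                stage = c("premeiotic", "meiotic", "postmeiotic"),
                n_replicates = 2, stringsAsFactors = FALSE),
    expand.grid(sex = c("female", "male"),
                organ = "speartip",
                stage = "vegetative", n_replicates = 2,
                stringsAsFactors = FALSE)
  )
}

#' Configuration for the synthetic floral-transcriptome generator
#'
#' Bundles and validates every knob of the simulation: the experimental
#' design, the negative-binomial noise model (variance = mu + mu^2 /
#' `nb_dispersion`), the planted sex-biased genes per contrast, and the
#' annotation layer (homolog fraction, term catalog size, planted
#' enriched terms).
#'
#' @param n_genes number of genes to simulate.
#' @param design data.frame as in [default_design()].
#' @param gene_length_range (min, max) gene length in bp.
#' @param baseline_mean_log10_range (min, max) of log10 relative baseline
#'   abundance per gene; the realised range of expected FPKM follows from
#'   normalisation over the transcriptome.
#' @param frac_sex_biased_per_contrast fraction of genes planted with a
#'   sex bias in each two-sex (organ, stage) contrast of the design.
#' @param fold_change_range (min, max) multiplicative fold change for
#'   planted genes; values above 5 make the planted genes detectable by
#'   the 5-fold SDEG rule.
#' @param nb_dispersion negative-binomial dispersion theta (> 0).
#' @param library_size_range (min, max) target total fragments per sample.
#' @param frac_annotated fraction of genes given a true homologous
#'   protein.
#' @param n_terms number of annotation terms in each generated catalog.
#' @param planted_terms_per_contrast number of terms made over-frequent
#'   among each contrast's planted biased genes.
#' @param seed integer RNG seed; identical configs reproduce identical
#'   fixtures bit for bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       design = default_design(),
                       gene_length_range = c(300, 4000),
                       baseline_mean_log10_range = c(-1, 2.5),
                       frac_sex_biased_per_contrast = 0.05,
                       fold_change_range = c(10, 50),
                       nb_dispersion = 10,
                       library_size_range = c(2e6, 4e6),
                       frac_annotated = 0.6,
                       n_terms = 40,
                       planted_terms_per_contrast = 2,
                       seed = 1) {
  chk_pair <- function(x, field, positive = FALSE) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
      stopf("invalid config field '%s': need an ordered (min, max) pair", field)
    if (positive && any(x <= 0))
      stopf("invalid config field '%s': values must be positive", field)
  }
  chk_frac <- function(x, field) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stopf("invalid config field '%s': must be a fraction in [0, 1]", field)
  }
  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes))
    stopf("invalid config field 'n_genes': must be a positive integer")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  miss <- setdiff(c("sex", "organ", "stage", "n_replicates"), names(design))
  if (length(miss))
    stopf("invalid config field 'design': lacks column '%s'", miss[1])
  if (any(design$n_replicates < 1))
    stopf("invalid config field 'design': n_replicates must be >= 1")
  chk_pair(gene_length_range, "gene_length_range", positive = TRUE)
  chk_pair(baseline_mean_log10_range, "baseline_mean_log10_range")
  chk_frac(frac_sex_biased_per_contrast, "frac_sex_biased_per_contrast")
  chk_pair(fold_change_range, "fold_change_range", positive = TRUE)
  if (length(nb_dispersion) != 1 || !is.finite(nb_dispersion) ||
      nb_dispersion <= 0)
    stopf("invalid config field 'nb_dispersion': must be a positive real")
  chk_pair(library_size_range, "library_size_range", positive = TRUE)
  chk_frac(frac_annotated, "frac_annotated")
  if (n_terms < 0 || n_terms != round(n_terms))
    stopf("invalid config field 'n_terms': must be a non-negative integer")
  if (planted_terms_per_contrast < 0 ||
      planted_terms_per_contrast != round(planted_terms_per_contrast))
    stopf("invalid config field 'planted_terms_per_contrast': must be a non-negative integer")
  if (planted_terms_per_contrast > n_terms)
    stopf("invalid config field 'planted_terms_per_contrast': exceeds n_terms")
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
    stopf("invalid config field 'seed': must be an integer")
  structure(list(
    n_genes = as.integer(n_genes), design = design,
    gene_length_range = gene_length_range,
    baseline_mean_log10_range = baseline_mean_log10_range,
    frac_sex_biased_per_contrast = frac_sex_biased_per_contrast,
    fold_change_range = fold_change_range,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    frac_annotated = frac_annotated,
    n_terms = as.integer(n_terms),
    planted_terms_per_contrast = as.integer(planted_terms_per_contrast),
    seed = as.integer(seed)), class = "sim_config")
}

# two-sex (organ, stage) cells of the design define the planted contrasts
design_contrasts <- function(design) {
  cells <- unique(design[, c("organ", "stage")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sexes <- sort(unique(design$sex[design$organ == cells$organ[i] &
                                      design$stage == cells$stage[i]]))
    if (length(sexes) == 2) {
      ct <- contrast(cells$organ[i], cells$stage[i], sexes[1], sexes[2])
      out[[format(ct)]] <- ct
    }
  }
  out
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws gene lengths and log-uniform baseline abundances, plants
#' multiplicative sex-biased fold changes for a fraction of genes in each
#' two-sex (organ, stage) contrast of the design, converts abundances to
#' expected fragment counts at a sampled library size, and draws observed
#' counts from a negative-binomial model with variance
#' `mu + mu^2 / nb_dispersion`. Also fixes the true gene-to-protein
#' homolog map used by the downstream annotation generators.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`,
#'   a `ground_truth` list with fields `biased_genes` (per contrast: a
#'   data.frame gene_id / sex / fold_change), `contrasts`,
#'   `homolog_truth` (named gene -> protein vector, injective),
#'   `baseline_fpkm` (expected unbiased FPKM per gene) and
#'   `enriched_terms` (filled by [generate_term_catalog()]).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  len <- as.integer(round(stats::runif(n, config$gene_length_range[1],
                                       config$gene_length_range[2])))
  abund <- 10^stats::runif(n, config$baseline_mean_log10_range[1],
                           config$baseline_mean_log10_range[2])

  design <- config$design
  samples <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    r <- seq_len(design$n_replicates[i])
    data.frame(sample_id = sprintf("%s_%s_%s_rep%d", design$sex[i],
                                   design$organ[i], design$stage[i], r),
               sex = design$sex[i], organ = design$organ[i],
               stage = design$stage[i], replicate = r,
               stringsAsFactors = FALSE)
  }))

  contrasts <- design_contrasts(design)
  n_biased <- round(config$frac_sex_biased_per_contrast * n)
  unclaimed <- gene_ids
  biased <- list()
  mult <- matrix(1, n, nrow(samples),
                 dimnames = list(gene_ids, samples$sample_id))
  for (cname in names(contrasts)) {
    ct <- contrasts[[cname]]
    take <- min(n_biased, length(unclaimed))
    if (take == 0) {
      biased[[cname]] <- data.frame(gene_id = character(), sex = character(),
                                    fold_change = numeric(),
                                    stringsAsFactors = FALSE)
      next
    }
    genes <- sample(unclaimed, take)
    unclaimed <- setdiff(unclaimed, genes)
    sex <- sample(c(ct$sex_a, ct$sex_b), take, replace = TRUE)
    fc <- stats::runif(take, config$fold_change_range[1],
                       config$fold_change_range[2])
    biased[[cname]] <- data.frame(gene_id = genes, sex = sex,
                                  fold_change = fc, stringsAsFactors = FALSE)
    for (s in c(ct$sex_a, ct$sex_b)) {
      cols <- samples$sample_id[samples$organ == ct$organ &
                                  samples$stage == ct$stage &
                                  samples$sex == s]
      rows <- genes[sex == s]
      if (length(rows) && length(cols))
        mult[rows, cols] <- mult[rows, cols] * fc[sex == s]
    }
  }

  lib <- round(stats::runif(nrow(samples), config$library_size_range[1],
                            config$library_size_range[2]))
  mu <- matrix(0, n, nrow(samples),
               dimnames = list(gene_ids, samples$sample_id))
  w_len <- abund * len
  for (j in seq_len(nrow(samples))) {
    w <- w_len * mult[, j]
    mu[, j] <- lib[j] * w / sum(w)
  }
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
    nrow = n, dimnames = dimnames(mu))

  n_annot <- round(config$frac_annotated * n)
  annotated <- if (n_annot > 0) sort(sample(gene_ids, n_annot)) else character()
  homolog <- stats::setNames(sprintf("ATPROT%05d", seq_along(annotated)),
                             annotated)

  truth <- structure(list(
    biased_genes = biased,
    contrasts = contrasts,
    homolog_truth = homolog,
    baseline_fpkm = stats::setNames(abund * 1e9 / sum(w_len), gene_ids),
    enriched_terms = list()), class = "ground_truth")

  list(counts = count_matrix(counts, stats::setNames(len, gene_ids), samples),
       truth = truth)
}

#' Generate a BLAST-style hit table consistent with a homolog truth
#'
#' Every annotated gene receives one hit to its true protein with
#' E-value below 1e-20, plus decoy hits to wrong proteins with E-values
#' drawn log-uniformly over `decoy_e_range`. The default decoy range
#' (1e-40 to 1e-5) straddles the 1e-20 cutoff so both the E-value filter
#' and the greedy ranking are exercised; narrowing it to weak values only
#' makes the true map fully recoverable.
#'
#' @param truth a `ground_truth` from [generate_counts()].
#' @param config the same [sim_config()].
#' @param n_decoys_per_gene decoy hits added per annotated gene.
#' @param decoy_e_range (min, max) E-value range for decoy hits.
#' @return data.frame in 12-column outfmt-6 layout (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
generate_blast_hits <- function(truth, config, n_decoys_per_gene = 2,
                                decoy_e_range = c(1e-40, 1e-5)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- names(truth$homolog_truth)
  cols12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(genes)) {
    m <- as.data.frame(matrix(nrow = 0, ncol = 12,
                              dimnames = list(NULL, cols12)))
    return(m)
  }
  prots <- unname(truth$homolog_truth)
  # decoy subjects drawn from true proteins plus unrelated extras
  universe <- c(prots, sprintf("ATDECOY%04d", seq_len(max(1, length(prots) %/% 5))))

  true_e <- 10^stats::runif(length(genes), -40, -21)
  rows <- list(data.frame(qseqid = genes, sseqid = prots, evalue = true_e,
                          stringsAsFactors = FALSE))
  if (n_decoys_per_gene > 0) {
    nd <- n_decoys_per_gene * length(genes)
    dq <- rep(genes, each = n_decoys_per_gene)
    ds <- sample(universe, nd, replace = TRUE)
    # a decoy to the gene's own true protein would duplicate the true hit
    own <- ds == truth$homolog_truth[dq]
    while (any(own)) {
      ds[own] <- sample(universe, sum(own), replace = TRUE)
      own <- ds == truth$homolog_truth[dq]
    }
    de <- 10^stats::runif(nd, log10(decoy_e_range[1]), log10(decoy_e_range[2]))
    rows <- c(rows, list(data.frame(qseqid = dq, sseqid = ds, evalue = de,
                                    stringsAsFactors = FALSE)))
  }
  hits <- do.call(rbind, rows)
  n <- nrow(hits)
  aln <- as.integer(round(stats::runif(n, 50, 400)))
  hits$pident <- round(stats::runif(n, 40, 99), 2)
  hits$length <- aln
  hits$mismatch <- as.integer(round(aln * (100 - hits$pident) / 100))
  hits$gapopen <- 0L
  hits$qstart <- 1L
  hits$qend <- aln * 3L
  hits$sstart <- 1L
  hits$send <- aln
  # stronger hits get larger bit scores, with jitter
  hits$bitscore <- round(-log10(hits$evalue) * 2 + stats::runif(n, 0, 5), 1)
  hits[, cols12]
}

#' Write a hit table in headerless outfmt-6 style
#'
#' @param hits data.frame from [generate_blast_hits()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a term-association catalog with planted enrichment
#'
#' Assigns annotation terms to proteins at a background rate (about three
#' terms per protein on average), then plants
#' `planted_terms_per_contrast` terms on each contrast's biased genes'
#' proteins at high frequency (0.9) so that over-representation is
#' recoverable by the binomial test. Planted terms are disjoint across
#' contrasts. With `planted_terms_per_contrast = 0` term frequencies are
#' independent of bias status (a pure null catalog).
#'
#' @param truth a `ground_truth` from [generate_counts()].
#' @param config the same [sim_config()].
#' @param annotation_type `"GO"` or `"pathway"`; controls term naming
#'   and the RNG stream so the two catalogs differ.
#' @return list with `associations` (data.frame `protein_id`,
#'   `term_id`) and `enriched_terms` (named list: contrast -> planted
#'   term IDs).
#' @export
generate_term_catalog <- function(truth, config,
                                  annotation_type = c("GO", "pathway")) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  annotation_type <- match.arg(annotation_type)
  set.seed(config$seed + if (annotation_type == "GO") 2L else 3L)
  terms <- if (annotation_type == "GO") {
    sprintf("GO:%07d", seq_len(config$n_terms))
  } else {
    sprintf("PWY-%04d", seq_len(config$n_terms))
  }
  prots <- unname(truth$homolog_truth)
  empty <- list(associations = data.frame(protein_id = character(),
                                          term_id = character(),
                                          stringsAsFactors = FALSE),
                enriched_terms = stats::setNames(
                  rep(list(character()), length(truth$biased_genes)),
                  names(truth$biased_genes)))
  if (!length(prots) || !length(terms)) return(empty)

  p_base <- min(1, 3 / length(terms))
  hit <- matrix(stats::runif(length(prots) * length(terms)) < p_base,
                nrow = length(prots), dimnames = list(prots, terms))

  enriched <- list()
  pool <- terms
  for (cname in names(truth$biased_genes)) {
    k <- min(config$planted_terms_per_contrast, length(pool))
    planted <- if (k > 0) sample(pool, k) else character()
    pool <- setdiff(pool, planted)
    enriched[[cname]] <- planted
    bg <- truth$biased_genes[[cname]]$gene_id
    bp <- unname(truth$homolog_truth[intersect(bg, names(truth$homolog_truth))])
    if (length(bp) && length(planted)) {
      hit[bp, planted] <- stats::runif(length(bp) * length(planted)) < 0.9
    }
  }
  idx <- which(hit, arr.ind = TRUE)
  assoc <- data.frame(protein_id = prots[idx[, 1]], term_id = terms[idx[, 2]],
                      stringsAsFactors = FALSE)
  assoc <- assoc[order(assoc$protein_id, assoc$term_id), , drop = FALSE]
  rownames(assoc) <- NULL
  list(associations = assoc, enriched_terms = enriched)
}

#' Write a complete runnable fixture bundle
#'
#' Produces, in `dir`, every file the pipeline reads — `counts.tsv`,
#' `samples.tsv`, `blast_hits.tsv`, `go_associations.tsv`,
#' `pathway_associations.tsv` — plus `ground_truth.json` recording the
#' planted biased genes, the true homolog map and the planted enriched
#' terms. Identical configs produce byte-identical bundles.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param ... passed to [generate_blast_hits()].
#' @return invisibly, a list with the generated objects (`counts`,
#'   `truth`, `hits`, `go`, `pathway`) and the file `paths`.
#' @export
write_fixture_bundle <- function(config, dir, ...) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_counts(config)
  hits <- generate_blast_hits(sim$truth, config, ...)
  go <- generate_term_catalog(sim$truth, config, "GO")
  pwy <- generate_term_catalog(sim$truth, config, "pathway")
  sim$truth$enriched_terms <- list(GO = go$enriched_terms,
                                   pathway = pwy$enriched_terms)

  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "samples.tsv"),
                blast = file.path(dir, "blast_hits.tsv"),
                go = file.path(dir, "go_associations.tsv"),
                pathway = file.path(dir, "pathway_associations.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  write_counts(sim$counts, paths$counts, paths$metadata)
  write_blast_tab(hits, paths$blast)
  write_tsv(go$associations, paths$go)
  write_tsv(pwy$associations, paths$pathway)

  truth_json <- list(
    biased_genes = sim$truth$biased_genes,
    homolog_truth = as.list(sim$truth$homolog_truth),
    enriched_terms = sim$truth$enriched_terms,
    baseline_fpkm = as.list(sim$truth$baseline_fpkm))
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(counts = sim$counts, truth = sim$truth, hits = hits,
                 go = go, pathway = pwy, paths = paths))
}
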