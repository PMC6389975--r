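#' Assemble and validate a pipeline configuration
#'
#' Collects the five input paths, the published analysis constants
#' (expression floor 5, fold threshold 5, homology E-value cutoff 1e-20,
#' FDR 0.01, heat-map expression floor 100) and the run options into one
#' validated object. `contrasts = "auto"` derives the contrast list from
#' the sample metadata: every (organ, stage) cell containing exactly two
#' sexes becomes one contrast.
#'
#' @param counts,metadata,blast,go,pathway input file paths (counts TSV,
#'   sample metadata TSV, BLAST tabular hits, and the two
#'   protein-to-term association TSVs).
#' @param out_dir output directory.
#' @param fpkm_threshold SDEG expression floor (default 5).
#' @param fold_threshold SDEG fold-change threshold (default 5).
#' @param e_cutoff homology E-value cutoff (default 1e-20).
#' @param fdr_q false-discovery rate for the enrichment significance
#'   level (default 0.01).
#' @param heatmap_fpkm_floor expression filter for the clustering heat
#'   map (default 100).
#' @param pseudocount log-transform offset (default 1).
#' @param contrasts `"auto"` or a list of [contrast()] objects (or lists
#'   with fields organ/stage/sex_a/sex_b).
#' @param seed integer seed echoed into the manifest (the pipeline itself
#'   is deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, blast, go, pathway, out_dir,
                            fpkm_threshold = 5, fold_threshold = 5,
                            e_cutoff = 1e-20, fdr_q = 0.01,
                            heatmap_fpkm_floor = 100, pseudocount = 1,
                            contrasts = "auto", seed = 1) {
  num <- list(fpkm_threshold = fpkm_threshold, fold_threshold = fold_threshold,
              e_cutoff = e_cutoff, fdr_q = fdr_q,
              heatmap_fpkm_floor = heatmap_fpkm_floor)
  for (nm in names(num))
    if (length(num[[nm]]) != 1 || !is.finite(num[[nm]]) || num[[nm]] <= 0)
      stopf("invalid config field '%s': must be a positive number", nm)
  if (pseudocount < 0) stopf("invalid config field 'pseudocount'")
  if (!identical(contrasts, "auto")) {
    contrasts <- lapply(contrasts, function(ct) {
      if (inherits(ct, "contrast")) ct
      else contrast(ct$organ, ct$stage, ct$sex_a, ct$sex_b)
    })
  }
  structure(list(counts = counts, metadata = metadata, blast = blast,
                 go = go, pathway = pathway, out_dir = out_dir,
                 fpkm_threshold = fpkm_threshold,
                 fold_threshold = fold_threshold,
                 e_cutoff = e_cutoff, fdr_q = fdr_q,
                 heatmap_fpkm_floor = heatmap_fpkm_floor,
                 pseudocount = pseudocount, contrasts = contrasts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file carries the same fields as [pipeline_config()], with the
#' input paths grouped under `inputs:` (keys counts, metadata, blast, go,
#' pathway). Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file path.
#' @param overrides named list of fields overriding the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  args <- list(counts = resolve(y$inputs$counts),
               metadata = resolve(y$inputs$metadata),
               blast = resolve(y$inputs$blast),
               go = resolve(y$inputs$go),
               pathway = resolve(y$inputs$pathway),
               out_dir = resolve(y$out_dir %||% "results"))
  for (nm in c("fpkm_threshold", "fold_threshold", "e_cutoff", "fdr_q",
               "heatmap_fpkm_floor", "pseudocount", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$contrasts)) args$contrasts <- y$contrasts
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e),
          class = "sdegtools_stage_error")
  })
}

#' Run the full downstream pipeline
#'
#' Executes counts -> FPKM -> SDEG extraction -> one-to-one homology ->
#' annotation transfer -> GO and pathway enrichment -> Jaccard,
#' correlation and clustering reports, writing every stage output under
#' `config$out_dir` and returning (and writing) a manifest that records
#' input checksums, parameter values, stage row counts, the derived
#' significance levels and output checksums. Re-running on identical
#' inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  inputs <- c(counts = config$counts, metadata = config$metadata,
              blast = config$blast, go = config$go, pathway = config$pathway)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stopf("stage 'input' failed: file not found: %s", missing[1])

  cm <- run_stage("load_counts", read_counts(config$counts, config$metadata))
  say("load_counts: %d genes x %d samples", nrow(cm$counts), ncol(cm$counts))

  em <- run_stage("fpkm", compute_fpkm(cm))
  run_stage("fpkm", {
    df <- data.frame(gene_id = rownames(em$fpkm), em$fpkm,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, out("fpkm.tsv"))
  })

  contrasts <- config$contrasts
  if (identical(contrasts, "auto"))
    contrasts <- design_contrasts(cm$samples)
  if (!length(contrasts))
    stopf("stage 'sdeg' failed: no two-sex contrasts found in the metadata")

  sdeg_sets <- run_stage("sdeg", {
    sets <- list()
    for (ct in contrasts) {
      pair <- extract_sdegs(em, ct, config$fpkm_threshold,
                            config$fold_threshold)
      for (s in pair) sets[[format(s)]] <- s
    }
    sets
  })
  for (s in sdeg_sets) say("sdeg %s: %d genes", format(s), length(s$gene_ids))
  run_stage("sdeg", write_sdeg_sets(sdeg_sets, out("sdeg_sets.tsv")))

  jac <- run_stage("jaccard", jaccard_matrix(sdeg_sets))
  run_stage("jaccard", {
    df <- data.frame(set_name = rownames(jac), jac, check.names = FALSE)
    write_tsv(df, out("jaccard_matrix.tsv"))
  })

  o2o <- run_stage("homology", {
    hits <- read_blast_tab(config$blast)
    assign_one_to_one(hits, config$e_cutoff)
  })
  rate <- report_annotation_rate(nrow(o2o$pairs), nrow(cm$counts))
  say("homology: %d of %d genes assigned (%s)", nrow(o2o$pairs),
      nrow(cm$counts), rate$label)
  run_stage("homology", write_one_to_one(o2o, out("one_to_one.tsv")))

  alphas <- list()
  enrich_counts <- list()
  for (type in c("go", "pathway")) {
    et <- run_stage(paste0("enrichment_", type), {
      assoc <- read_term_associations(config[[type]])
      gene_terms <- transfer_annotations(o2o, assoc)
      bg <- build_background(gene_terms, em, config$fpkm_threshold)
      enrich_sets(sdeg_sets, gene_terms, bg, config$fdr_q)
    })
    alphas[[type]] <- attr(et, "alpha")
    enrich_counts[[type]] <- nrow(et)
    say("enrichment_%s: %d records, alpha = %g", type, nrow(et),
        attr(et, "alpha"))
    run_stage(paste0("enrichment_", type),
              write_enrichment(et, out(sprintf("enrichment_%s.tsv", type))))
  }

  run_stage("correlation", {
    pm <- pearson_matrix(em)
    df <- data.frame(sample_id = rownames(pm), pm, check.names = FALSE)
    write_tsv(df, out("correlation_matrix.tsv"))
  })

  n_heatmap_genes <- run_stage("clustering", {
    emf <- filter_min_fpkm(em, config$heatmap_fpkm_floor, "any_sample")
    lt <- log_transform(emf, config$pseudocount)
    samp_lr <- hcluster(manhattan_log_distance(lt, "samples"), "ward")
    writeLines(linkage_newick(samp_lr), out("sample_dendrogram.newick"))
    if (nrow(lt) >= 2) {
      gene_lr <- hcluster(manhattan_log_distance(lt, "genes"),
                          "group_average")
      writeLines(linkage_newick(gene_lr), out("gene_dendrogram.newick"))
      norm <- normalize_for_heatmap(lt)
      df <- data.frame(gene_id = rownames(norm), norm, check.names = FALSE)
      write_tsv(df, out("heatmap_matrix.tsv"))
    }
    nrow(lt)
  })
  say("clustering: %d genes above FPKM %g", n_heatmap_genes,
      config$heatmap_fpkm_floor)

  outputs <- list.files(config$out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  out_md5 <- tools::md5sum(file.path(config$out_dir, outputs))
  names(out_md5) <- outputs
  in_md5 <- tools::md5sum(unname(inputs))
  names(in_md5) <- names(inputs)
  manifest <- list(
    parameters = list(fpkm_threshold = config$fpkm_threshold,
                      fold_threshold = config$fold_threshold,
                      e_cutoff = config$e_cutoff, fdr_q = config$fdr_q,
                      heatmap_fpkm_floor = config$heatmap_fpkm_floor,
                      pseudocount = config$pseudocount, seed = config$seed),
    inputs = as.list(in_md5),
    stage_counts = list(
      genes = nrow(cm$counts), samples = ncol(cm$counts),
      sdeg_per_set = lapply(sdeg_sets, function(s) length(s$gene_ids)),
      genes_assigned = nrow(o2o$pairs),
      annotation_rate_percent = rate$percent,
      enrichment_records = enrich_counts,
      heatmap_genes = n_heatmap_genes),
    alpha = alphas,
    outputs = as.list(out_md5))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Annotation rate as a percentage
#'
#' Reports the share of genes that received a homolog assignment, both
#' raw and rounded to the nearest whole percent (the form usually quoted
#' in text, e.g. "approximately 38\%").
#'
#' @param n_assigned number of genes assigned (0 <= n_assigned <=
#'   n_total).
#' @param n_total total number of genes (> 0).
#' @return list with `percent` (raw), `rounded` (integer percent) and
#'   `label` (e.g. `"38\%"`).
#' @export
report_annotation_rate <- function(n_assigned, n_total) {
  if (length(n_total) != 1 || n_total <= 0)
    stopf("n_total must be a positive count")
  if (n_assigned < 0 || n_assigned > n_total)
    stopf("n_assigned must lie between 0 and n_total")
  pct <- 100 * n_assigned / n_total
  rounded <- as.integer(round(pct))
  list(percent = pct, rounded = rounded, label = sprintf("%d%%", rounded))
}
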