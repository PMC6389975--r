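blast_line <- function(q, s, e, b) {
  paste(q, s, "90.0", "100", "10", "0", "1", "300", "1", "100", e, b,
        sep = "\t")
}

test_that("read_blast_tab parses outfmt-6 columns and flags bad lines", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "hits.tsv")
  writeLines(c(blast_line("g1", "p1", "1e-30", "120"),
               blast_line("g1", "p2", "1e-25", "110"),
               blast_line("g2", "p1", "1e-22", "100")), f)
  hits <- read_blast_tab(f)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_gene, c("g1", "g1", "g2"))
  expect_equal(hits$e_value, c(1e-30, 1e-25, 1e-22))
  expect_equal(hits$bitscore[1], 120)

  writeLines(character(), f)
  expect_equal(nrow(read_blast_tab(f)), 0)

  writeLines(c(blast_line("g1", "p1", "1e-30", "120"), "g2\tp2\t1e-10"), f)
  expect_error(read_blast_tab(f), "line 2")
})

test_that("assign_one_to_one follows the greedy lowest-E-value rule", {
  hits <- data.frame(
    query_gene = c("g1", "g1", "g2"),
    subject_protein = c("p1", "p2", "p1"),
    e_value = c(1e-30, 1e-25, 1e-22),
    bitscore = c(120, 110, 100), stringsAsFactors = FALSE)
  m <- assign_one_to_one(hits)
  # g1 takes p1 first; g1 already assigned when (g1,p2) is considered,
  # p1 already taken when (g2,p1) is considered
  expect_equal(m$gene_to_protein, c(g1 = "p1"))
  expect_equal(m$protein_to_gene, c(p1 = "g1"))

  # boundary: E exactly at the cutoff is discarded (strict <)
  one <- data.frame(query_gene = "g", subject_protein = "p",
                    e_value = 1e-20, bitscore = 50)
  expect_equal(nrow(assign_one_to_one(one)$pairs), 0)

  # a perfect matching with distinct E-values is fully assigned
  perfect <- data.frame(
    query_gene = c("g1", "g2", "g3"),
    subject_protein = c("p3", "p1", "p2"),
    e_value = c(1e-40, 1e-33, 1e-22),
    bitscore = c(200, 150, 90), stringsAsFactors = FALSE)
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    m <- assign_one_to_one(perfect[perm, ])
    expect_equal(sort(names(m$gene_to_protein)), c("g1", "g2", "g3"))
    expect_equal(m$gene_to_protein[["g1"]], "p3")
  }
})

test_that("assign_one_to_one matches the independent greedy oracle", {
  set.seed(17)
  for (i in 1:60) {
    hits <- random_hit_table(n_genes = sample(3:25, 1),
                             n_prots = sample(3:25, 1),
                             n_hits = sample(5:80, 1))
    m <- assign_one_to_one(hits)
    o <- oracle_greedy_assign(hits)
    got <- m$pairs[order(m$pairs$gene), c("gene", "protein")]
    want <- o[order(o$gene), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    # injectivity both ways
    expect_false(anyDuplicated(m$pairs$gene) > 0)
    expect_false(anyDuplicated(m$pairs$protein) > 0)
    expect_true(all(m$pairs$e_value < 1e-20))
    # input-order invariance
    m2 <- assign_one_to_one(hits[sample(nrow(hits)), ])
    expect_equal(m$pairs, m2$pairs)
    # assigned list is sorted by non-decreasing e-value (greedy replay)
    expect_true(!is.unsorted(m$pairs$e_value))
  }
})

test_that("transfer_annotations copies exactly the assigned protein's terms", {
  m <- assign_one_to_one(data.frame(
    query_gene = c("g1", "g2"), subject_protein = c("p1", "p2"),
    e_value = c(1e-30, 1e-25), bitscore = c(100, 90)))
  terms <- list(p1 = c("GO:1", "GO:2"), p3 = "GO:9")
  gt <- transfer_annotations(m, terms)
  expect_equal(gt$g1, c("GO:1", "GO:2"))
  expect_equal(gt$g2, character())   # assigned but term-less protein
  expect_null(gt$g3)                 # unassigned gene absent

  # counting identity on a generated bundle
  cfg <- tiny_sim_config(seed = 3)
  sim <- generate_counts(cfg)
  cat <- generate_term_catalog(sim$truth, cfg, "GO")
  pt <- split(cat$associations$term_id, cat$associations$protein_id)
  truth_map <- sim$truth$homolog_truth
  hits <- data.frame(query_gene = names(truth_map),
                     subject_protein = unname(truth_map),
                     e_value = 1e-30, bitscore = 100,
                     stringsAsFactors = FALSE)
  m <- assign_one_to_one(hits)
  gt <- transfer_annotations(m, pt)
  expect_equal(sum(lengths(gt)),
               sum(lengths(pt[unname(m$gene_to_protein)])))
})

test_that("the generated hit table recovers the planted homolog map", {
  cfg <- tiny_sim_config(seed = 5)
  sim <- generate_counts(cfg)
  hits <- generate_blast_hits(sim$truth, cfg)
  # every true pair present with E < 1e-20
  key <- paste(hits$qseqid, hits$sseqid)
  truth_key <- paste(names(sim$truth$homolog_truth),
                     unname(sim$truth$homolog_truth))
  strong <- key[hits$evalue < 1e-20]
  expect_true(all(truth_key %in% strong))

  # with decoys at least 10 log10 units weaker, >= 95% of truth is recovered
  weak <- generate_blast_hits(sim$truth, cfg,
                              decoy_e_range = c(1e-10, 1e-5))
  parsed <- data.frame(query_gene = weak$qseqid,
                       subject_protein = weak$sseqid,
                       e_value = weak$evalue, bitscore = weak$bitscore,
                       stringsAsFactors = FALSE)
  m <- assign_one_to_one(parsed)
  assigned <- m$gene_to_protein[names(sim$truth$homolog_truth)]
  recovered <- sum(!is.na(assigned) &
                     assigned == unname(sim$truth$homolog_truth)) /
    length(sim$truth$homolog_truth)
  expect_gte(recovered, 0.95)

  # frac_annotated = 0 gives an empty table
  cfg0 <- tiny_sim_config(seed = 5, frac_annotated = 0)
  sim0 <- generate_counts(cfg0)
  expect_equal(nrow(generate_blast_hits(sim0$truth, cfg0)), 0)
})

test_that("generated hit tables round-trip through the tabular writer", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sim_config(seed = 9)
  sim <- generate_counts(cfg)
  hits <- generate_blast_hits(sim$truth, cfg)
  f <- file.path(dir, "hits.tsv")
  write_blast_tab(hits, f)
  parsed <- read_blast_tab(f)
  expect_equal(parsed$query_gene, hits$qseqid)
  expect_equal(parsed$subject_protein, hits$sseqid)
  expect_equal(parsed$e_value, hits$evalue)
  expect_equal(parsed$bitscore, hits$bitscore)
})
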