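test_that("build_background defines valid genes and expected probabilities", {
  em <- random_expression(n_genes = 12)
  em$fpkm[] <- 10  # everything expressed above the floor
  genes <- rownames(em$fpkm)
  gene_terms <- stats::setNames(
    c(rep(list("T1"), 2), rep(list(c("T2", "T3")), 8),
      list(character()), list(character())), genes)
  bg <- build_background(gene_terms, em, fpkm_floor = 5)
  expect_setequal(bg$valid_genes, genes[1:10])  # term-less genes excluded
  expect_equal(unname(bg$expected_probability["T1"]), 0.2)
  expect_equal(unname(bg$expected_probability["T2"]), 0.8)

  # a term on every valid gene has expected probability 1
  gene_terms2 <- stats::setNames(rep(list("ALL"), 12), genes)
  expect_equal(unname(build_background(gene_terms2, em)$
                        expected_probability["ALL"]), 1)

  # counting identity: term counts total the per-gene term counts
  set.seed(61)
  gene_terms3 <- stats::setNames(
    lapply(seq_along(genes),
           function(i) sample(paste0("T", 1:6), sample(0:4, 1))), genes)
  bg3 <- build_background(gene_terms3, em)
  expect_equal(sum(bg3$per_term_counts),
               sum(lengths(gene_terms3[bg3$valid_genes])))

  # expression floor matters: genes below it are not valid
  em$fpkm[1, ] <- 1
  bg4 <- build_background(gene_terms, em, fpkm_floor = 5)
  expect_false(genes[1] %in% bg4$valid_genes)

  em$fpkm[] <- 0.1
  expect_error(build_background(gene_terms, em), "valid genes")
})

test_that("binomial_cdf matches enumeration and honors edge identities", {
  expect_equal(binomial_cdf(1, 3, 0.5), 0.5)
  expect_equal(binomial_cdf(0, 10, 0.1), 0.9^10, tolerance = 1e-12)
  expect_error(binomial_cdf(5, 3, 0.5), "k")
  expect_error(binomial_cdf(1, 3, 1.5), "p")

  for (n in c(0, 1, 7)) {
    expect_equal(binomial_cdf(n, n, 0.37), 1)
    if (n > 0) {
      expect_equal(binomial_cdf(0, n, 0), 1)
      expect_equal(binomial_cdf(n - 1, n, 1), 0)
    }
  }
  # upper tail complements the lower tail; P(X >= 0) = 1
  expect_equal(binomial_sf(0, 10, 0.3), 1)
  expect_equal(binomial_sf(4, 10, 0.3) + binomial_cdf(3, 10, 0.3), 1)

  for (n in c(2, 5, 9)) {
    for (p in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        expect_equal(binomial_cdf(k, n, p), oracle_binom_cdf(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("fdr_significance_level reproduces the BH step-up critical value", {
  expect_equal(fdr_significance_level(c(0.001, 0.005, 0.02, 0.8), 0.01),
               0.005)
  expect_equal(fdr_significance_level(rep(1, 5), 0.01), 0)
  expect_equal(fdr_significance_level(0.001, 0.01), 0.001)
  expect_error(fdr_significance_level(numeric(0)), "empty")
  expect_error(fdr_significance_level(c(0.5, 1.2)), "0, 1")

  set.seed(71)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    pv <- stats::runif(m)^sample(1:3, 1)  # skew some families small
    q <- sample(c(0.01, 0.05, 0.1), 1)
    alpha <- fdr_significance_level(pv, q)
    expect_equal(alpha, oracle_bh_alpha(pv, q))
    # the derived level calls exactly the BH discoveries
    if (alpha > 0)
      expect_equal(sum(pv <= alpha),
                   sum(stats::p.adjust(pv, "BH") <= q))
  }
})

test_that("enrich_sets computes counts, tails and calls per the published rule", {
  em <- random_expression(n_genes = 60)
  em$fpkm[] <- 50
  genes <- rownames(em$fpkm)
  # term A on the first 30 genes (p0 = 0.5); term B on the first 6 (p0 = 0.1)
  gene_terms <- stats::setNames(lapply(seq_along(genes), function(i) {
    c(if (i <= 30) "A", if (i <= 6) "B", "ANY")
  }), genes)
  bg <- build_background(gene_terms, em)
  expect_equal(unname(bg$expected_probability["A"]), 0.5)

  # a set stacked with term-B genes: B overrepresented, A near null
  set1 <- genes[1:6]
  et <- enrich_sets(list(hot = set1), gene_terms, bg, q = 0.01)
  rec <- et[et$set_name == "hot" & et$term == "B", ]
  expect_equal(rec$n, 6)
  expect_equal(rec$k, 6)
  expect_equal(rec$cumulative_probability, 1)
  expect_equal(rec$call, "overrepresented")
  recA <- et[et$term == "A", ]
  expect_equal(recA$k, 6)

  # cumulative probabilities agree with the enumeration oracle
  for (r in seq_len(nrow(et))) {
    expect_equal(et$cumulative_probability[r],
                 oracle_binom_cdf(et$k[r], et$n[r], et$p0[r]),
                 tolerance = 1e-9)
  }

  # an empty set warns and yields only not_significant calls
  expect_warning(
    et0 <- enrich_sets(list(void = "not_a_gene"), gene_terms, bg),
    "void")
  expect_true(all(et0$call == "not_significant"))

  # genes without annotation never enter n or k
  set2 <- c(genes[1:5], "phantom1", "phantom2")
  et2 <- enrich_sets(list(s = set2), gene_terms, bg)
  expect_true(all(et2$n == 5))
})

test_that("over- and under-calls are mutually exclusive and k-monotone", {
  em <- random_expression(n_genes = 40)
  em$fpkm[] <- 20
  genes <- rownames(em$fpkm)
  set.seed(77)
  gene_terms <- stats::setNames(
    lapply(seq_along(genes),
           function(i) unique(c("ANY", sample(paste0("T", 1:8), 2)))), genes)
  bg <- build_background(gene_terms, em)
  sets <- list(a = sample(genes, 12), b = sample(genes, 20))
  et <- enrich_sets(sets, gene_terms, bg, q = 0.05)
  alpha <- attr(et, "alpha")
  expect_lt(alpha, 0.5)
  expect_false(any(et$cumulative_probability < alpha &
                     et$cumulative_probability > 1 - alpha))
  # increasing k at fixed n, p0 never moves a call from over to under
  calls <- vapply(0:20, function(k) {
    p <- binomial_cdf(k, 20, 0.3)
    if (p < 0.01) "under" else if (p > 0.99) "over" else "ns"
  }, character(1))
  expect_false(is.unsorted(match(calls, c("under", "ns", "over"))))
})

test_that("planted enriched terms are recovered through the full chain", {
  cfg <- tiny_sim_config(seed = 19)
  sim <- generate_counts(cfg)
  em <- compute_fpkm(sim$counts)
  cat <- generate_term_catalog(sim$truth, cfg, "GO")
  pt <- split(cat$associations$term_id, cat$associations$protein_id)
  gene_terms <- stats::setNames(
    lapply(names(sim$truth$homolog_truth), function(g) {
      t <- pt[[sim$truth$homolog_truth[[g]]]]
      if (is.null(t)) character() else as.character(t)
    }),
    names(sim$truth$homolog_truth))
  bg <- build_background(gene_terms, em, fpkm_floor = 5)

  sets <- list()
  for (ct in sim$truth$contrasts) {
    pair <- extract_sdegs(em, ct)
    for (s in pair) sets[[format(s)]] <- s
  }
  et <- enrich_sets(sets, gene_terms, bg, q = 0.01)
  for (cname in names(sim$truth$contrasts)) {
    ct <- sim$truth$contrasts[[cname]]
    set_names <- paste(ct$organ, ct$stage, c(ct$sex_a, ct$sex_b), sep = "_")
    for (term in cat$enriched_terms[[cname]]) {
      calls <- et$call[et$term == term & et$set_name %in% set_names]
      expect_true("overrepresented" %in% calls,
                  label = sprintf("planted term %s flagged in contrast %s",
                                  term, cname))
    }
  }
})
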