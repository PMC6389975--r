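# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they test.

# P(X <= k) for X ~ Binomial(n, p) by exhaustive enumeration of all 2^n
# trial outcomes; feasible for n <= ~14.
oracle_binom_cdf <- function(k, n, p) {
  if (n == 0) return(1)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  succ <- rowSums(outcomes)
  prob <- p^succ * (1 - p)^(n - succ)
  sum(prob[succ <= k])
}

# BH critical value by explicit search over every rank.
oracle_bh_alpha <- function(pv, q) {
  ps <- sort(pv)
  m <- length(ps)
  alpha <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i / m * q) alpha <- max(alpha, ps[i])
  }
  alpha
}

# Greedy one-to-one assignment by repeated best-hit extraction from the
# remaining hits (different algorithmic shape from the single sorted
# pass in the package): at each round the minimum-E hit is located by
# successive filtering on the tie-break keys, accepted, and every hit
# sharing its gene or protein is removed.
oracle_greedy_assign <- function(hits, e_cutoff = 1e-20) {
  q <- hits$query_gene; s <- hits$subject_protein
  e <- hits$e_value; b <- hits$bitscore
  alive <- e < e_cutoff
  genes <- character(0); prots <- character(0)
  while (any(alive)) {
    cand <- which(alive)
    cand <- cand[e[cand] == min(e[cand])]
    cand <- cand[b[cand] == max(b[cand])]
    cand <- cand[q[cand] == min(q[cand])]
    cand <- cand[s[cand] == min(s[cand])]
    i <- cand[1]
    genes <- c(genes, q[i]); prots <- c(prots, s[i])
    alive <- alive & q != q[i] & s != s[i]
  }
  data.frame(gene = genes, protein = prots, stringsAsFactors = FALSE)
}

# UPGMA (unweighted group average) agglomeration recomputing every
# between-cluster average from the original distance matrix at each step.
oracle_upgma_heights <- function(dm) {
  dm <- as.matrix(dm)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# random hit table over small bipartite gene/protein universes
random_hit_table <- function(n_genes = 20, n_prots = 20, n_hits = 60) {
  data.frame(
    query_gene = sprintf("g%02d", sample.int(n_genes, n_hits, replace = TRUE)),
    subject_protein = sprintf("p%02d", sample.int(n_prots, n_hits, replace = TRUE)),
    e_value = 10^stats::runif(n_hits, -45, -5),
    bitscore = round(stats::runif(n_hits, 50, 300), 1),
    stringsAsFactors = FALSE)
}

# small expression matrix straight from a count matrix construction
random_expression <- function(n_genes = 30, sample_ids = paste0("s", 1:4),
                              sexes = rep(c("female", "supermale"), 2),
                              organs = rep("pistil", length(sample_ids)),
                              stages = rep("postmeiotic", length(sample_ids)),
                              max_count = 2000L) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  counts <- matrix(sample.int(max_count, n_genes * length(sample_ids),
                              replace = TRUE),
                   nrow = n_genes,
                   dimnames = list(genes, sample_ids))
  reps <- stats::ave(seq_along(sample_ids),
                     paste(sexes, organs, stages), FUN = seq_along)
  cm <- count_matrix(counts,
                     stats::setNames(sample.int(5000, n_genes) + 200L, genes),
                     data.frame(sample_id = sample_ids, sex = sexes,
                                organ = organs, stage = stages,
                                replicate = reps, stringsAsFactors = FALSE))
  compute_fpkm(cm)
}

# compact simulation config used across tests
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(
    n_genes = 300,
    design = data.frame(
      sex = rep(c("female", "supermale"), 2),
      organ = rep(c("pistil", "stamen"), each = 2),
      stage = "postmeiotic", n_replicates = 2,
      stringsAsFactors = FALSE),
    seed = seed, ...)
}
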