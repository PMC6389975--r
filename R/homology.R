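#' Read BLAST tabular hits (outfmt 6 layout)
#'
#' Parses the standard 12-column tab-separated BLAST output. Only the
#' query ID (column 1), subject ID (column 2), E-value (column 11) and
#' bit score (column 12) are retained; the alignment-detail columns are
#' ignored.
#'
#' @param path path to the tabular hits file; an empty file yields an
#'   empty hit table.
#' @return data.frame with columns `query_gene`, `subject_protein`,
#'   `e_value`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stopf("BLAST hits file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query_gene = character(), subject_protein = character(),
                      e_value = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stopf("malformed BLAST tabular line %d: expected 12 fields, found %d",
          which(nf < 12)[1], nf[which(nf < 12)[1]])
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 11L)))
  bs <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 12L)))
  bad <- which(is.na(ev) | is.na(bs))
  if (length(bad))
    stopf("malformed BLAST tabular line %d: non-numeric E-value or bitscore",
          bad[1])
  if (any(ev < 0)) stopf("negative E-value on line %d", which(ev < 0)[1])
  data.frame(query_gene = vapply(parts, `[`, "", 1L),
             subject_protein = vapply(parts, `[`, "", 2L),
             e_value = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Build a one-to-one gene-to-protein map by lowest E-value
#'
#' Implements the best-hit one-to-one assignment rule: hits at or above
#' the E-value cutoff are discarded (strict `<` keeps a hit), the
#' remaining hits are ranked by ascending E-value — ties broken by
#' descending bit score, then query ID, then subject ID — and scanned
#' greedily: a hit is accepted exactly when both its gene and its protein
#' are still unassigned. The result is injective in both directions and
#' independent of the input order of the hits.
#'
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param e_cutoff E-value cutoff; hits must satisfy `e_value < e_cutoff`
#'   (default 1e-20).
#' @return An object of class `one_to_one_map`: data.frame `pairs` with
#'   columns `gene`, `protein`, `e_value` sorted by assignment order,
#'   plus named lookup vectors `gene_to_protein` and `protein_to_gene`.
#' @export
assign_one_to_one <- function(hits, e_cutoff = 1e-20) {
  req <- c("query_gene", "subject_protein", "e_value", "bitscore")
  miss <- setdiff(req, names(hits))
  if (length(miss)) stopf("hits table lacks column '%s'", miss[1])
  h <- hits[hits$e_value < e_cutoff, , drop = FALSE]
  empty_map <- function() {
    structure(list(
      pairs = data.frame(gene = character(), protein = character(),
                         e_value = numeric(), stringsAsFactors = FALSE),
      gene_to_protein = stats::setNames(character(), character()),
      protein_to_gene = stats::setNames(character(), character()),
      e_cutoff = e_cutoff), class = "one_to_one_map")
  }
  if (!nrow(h)) return(empty_map())
  ord <- order(h$e_value, -h$bitscore, h$query_gene, h$subject_protein)
  h <- h[ord, , drop = FALSE]
  # greedy scan: vectorised by repeated duplicate-stripping would be
  # incorrect (an early rejection can free a later pair), so walk once
  gene_taken <- new.env(parent = emptyenv())
  prot_taken <- new.env(parent = emptyenv())
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    g <- h$query_gene[i]; p <- h$subject_protein[i]
    if (is.null(gene_taken[[g]]) && is.null(prot_taken[[p]])) {
      keep[i] <- TRUE
      gene_taken[[g]] <- TRUE
      prot_taken[[p]] <- TRUE
    }
  }
  sel <- h[keep, , drop = FALSE]
  structure(list(
    pairs = data.frame(gene = sel$query_gene, protein = sel$subject_protein,
                       e_value = sel$e_value, stringsAsFactors = FALSE),
    gene_to_protein = stats::setNames(sel$subject_protein, sel$query_gene),
    protein_to_gene = stats::setNames(sel$query_gene, sel$subject_protein),
    e_cutoff = e_cutoff), class = "one_to_one_map")
}

#' @export
print.one_to_one_map <- function(x, ...) {
  cat(sprintf("one_to_one_map: %d gene-protein pairs (E < %g)\n",
              nrow(x$pairs), x$e_cutoff))
  invisible(x)
}

#' Transfer term annotations through a one-to-one homolog map
#'
#' Each assigned gene inherits exactly the term set of its assigned
#' protein; unassigned genes are absent from the output. Assigned genes
#' whose protein has no terms map to an empty set.
#'
#' @param m a `one_to_one_map` from [assign_one_to_one()].
#' @param protein_terms named list mapping protein ID to a character
#'   vector of term IDs, or a data.frame with columns `protein_id`,
#'   `term_id`.
#' @return Named list mapping gene ID to a character vector of term IDs.
#' @export
transfer_annotations <- function(m, protein_terms) {
  stopifnot(inherits(m, "one_to_one_map"))
  if (is.data.frame(protein_terms)) {
    protein_terms <- split(protein_terms$term_id, protein_terms$protein_id)
  }
  out <- lapply(m$gene_to_protein, function(p) {
    t <- protein_terms[[p]]
    if (is.null(t)) character() else unique(as.character(t))
  })
  names(out) <- names(m$gene_to_protein)
  out
}

#' Read a protein-to-term association TSV
#'
#' Two tab-separated columns, `protein_id` and `term_id`, one association
#' per line, with a header row.
#'
#' @param path file path.
#' @return data.frame with columns `protein_id`, `term_id`.
#' @export
read_term_associations <- function(path) {
  if (!file.exists(path)) stopf("term association file not found: %s", path)
  tab <- read_tsv(path, colClasses = "character")
  miss <- setdiff(c("protein_id", "term_id"), names(tab))
  if (length(miss)) stopf("association table lacks column '%s'", miss[1])
  tab
}

#' Write a one-to-one map as a three-column TSV
#'
#' @param m a `one_to_one_map`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_one_to_one <- function(m, path) {
  df <- m$pairs
  names(df) <- c("gene_id", "protein_id", "e_value")
  write_tsv(df, path)
}
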