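#' @name integration
#' @title Set-level integration statistics
#'
#' @description
#' Downstream utilities operating on gene sets and tables: Benjamini-
#' Hochberg adjustment, differential-expression thresholding (strict
#' `q < 0.05` and `|log2FC| > 1`), exclusive-region overlap summaries,
#' bivalent-fraction computation, and gene-effect co-dependency by Pearson
#' correlation across cell lines.
NULL

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j with p_j >= p_i of p_j * m / rank_j`, clipped at 1;
#' order-preserving. Implemented directly from the step-up formula.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same order and names as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    validation_error("p-values must lie in (0, 1]")
  m <- length(p)
  if (!m) return(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  names(q) <- names(p)
  q
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `pvalue` (and optionally a
#' precomputed `qvalue`). When `qvalue` is absent it is added with
#' [bh_adjust()].
#'
#' @param path Path to the TSV.
#' @return Data frame `gene_id`, `log2fc`, `pvalue`, `qvalue`.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing))
    validation_error("DE table missing columns: ",
                     paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    validation_error("duplicate gene_id in DE table")
  if (is.null(df$qvalue)) df$qvalue <- bh_adjust(df$pvalue)
  df
}

#' Threshold a DE table into up/down gene sets
#'
#' Strict inequalities, matching "FDR below 0.05 and a log fold change
#' greater than 1": `up = {q < q_max, log2fc > lfc_min}`,
#' `down = {q < q_max, log2fc < -lfc_min}`. A gene at exactly the boundary
#' is excluded.
#'
#' @param table Data frame with `gene_id`, `log2fc`, `qvalue`.
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param q_max FDR threshold (default 0.05).
#' @return List with sorted character vectors `up` and `down`.
#' @export
de_gene_sets <- function(table, lfc_min = 1, q_max = 0.05) {
  if (is.null(table$qvalue)) validation_error("qvalue column required")
  up <- table$gene_id[table$qvalue < q_max & table$log2fc > lfc_min]
  down <- table$gene_id[table$qvalue < q_max & table$log2fc < -lfc_min]
  list(up = sort(up), down = sort(down))
}

#' Exclusive-region overlap summary (venn counts)
#'
#' For 2 or 3 named sets, counts every exclusive region (present in
#' exactly that combination of sets). Region labels join set names with
#' `&`. Counts sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Data frame `region`, `count`.
#' @export
overlap_summary <- function(sets) {
  if (!length(names(sets)) || any(!nzchar(names(sets))))
    validation_error("sets must be named")
  if (length(sets) < 2 || length(sets) > 3)
    validation_error("overlap_summary takes 2 or 3 sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL,
                                                                  names(sets)))
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- as.logical(combos[i, ])
    inreg <- if (length(universe))
      apply(membership, 1, function(r) all(r == mask)) else logical(0)
    data.frame(region = paste(names(sets)[mask], collapse = "&"),
               count = sum(inreg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bivalent fraction of a gene set
#'
#' `|set intersect bivalent| / |set|` against a set of bivalency calls.
#' Genes absent from the bivalency universe are dropped (with a message).
#' The fraction is `NA` for an empty (post-drop) set.
#'
#' @param gene_set Character vector of gene ids.
#' @param bivalency A `bivalency_calls` data frame.
#' @return List `n`, `n_bivalent`, `fraction`.
#' @export
bivalent_fraction <- function(gene_set, bivalency) {
  gene_set <- unique(gene_set)
  unknown <- setdiff(gene_set, bivalency$gene_id)
  if (length(unknown)) {
    message(length(unknown), " gene(s) outside bivalency universe dropped")
    gene_set <- setdiff(gene_set, unknown)
  }
  nb <- sum(gene_set %in% bivalent_gene_set(bivalency))
  list(n = length(gene_set), n_bivalent = nb,
       fraction = if (length(gene_set)) nb / length(gene_set) else NA_real_)
}

#' Read a gene-effect matrix
#'
#' TSV: first column `gene_id`, remaining columns one per cell line.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, genes in rows, cell lines in columns.
#' @export
read_effect_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Top co-dependent genes by effect-profile correlation
#'
#' Pearson correlation between the query gene's effect vector and every
#' other gene's, using pairwise-complete observations with at least
#' `min_shared` shared cell lines. Zero-variance pairs are skipped with a
#' warning. Ties in `r` break by gene id.
#'
#' @param matrix Gene-effect matrix (genes x cell lines).
#' @param query Query gene id (present in the matrix).
#' @param k Number of co-dependent genes to return.
#' @param min_shared Minimum shared non-missing cell lines (default 10).
#' @return Data frame `gene_id`, `r`, `n_lines`, top `k` by `r`
#'   descending; the query itself is excluded.
#' @export
codependency <- function(matrix, query, k, min_shared = 10L) {
  if (!(query %in% rownames(matrix)))
    validation_error("query gene not in matrix: ", query)
  if (k < 1) validation_error("k must be >= 1")
  q <- matrix[query, ]
  others <- setdiff(rownames(matrix), query)
  rows <- lapply(others, function(g) {
    v <- matrix[g, ]
    ok <- complete.cases(q, v)
    if (sum(ok) < min_shared) return(NULL)
    if (stats::sd(q[ok]) == 0 || stats::sd(v[ok]) == 0) {
      warning("zero-variance pair skipped: ", query, " / ", g)
      return(NULL)
    }
    data.frame(gene_id = g, r = cor(q[ok], v[ok]), n_lines = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), r = numeric(),
                      n_lines = integer(), stringsAsFactors = FALSE))
  out <- out[order(-out$r, out$gene_id), , drop = FALSE]
  out <- head(out, k)
  rownames(out) <- NULL
  out
}
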