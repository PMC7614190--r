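#' @name quantification
#' @title Reads-in-peaks quantification and log fold change
#'
#' @description
#' Counts are tabulated per peak and sample, normalized to reads per million
#' mapped reads (RPM; the denominator is the sample's total library size,
#' not reads in peaks), summed per gene over the gene's scoring region, and
#' contrasted knockout vs control as a log2 fold change with a small
#' symmetric pseudocount.
NULL

#' Per-sample read counts in peaks
#'
#' @param sample_id Sample label.
#' @param assay Mark/factor label.
#' @param condition Condition label (e.g. `"control"`, `"MEN1_KO"`).
#' @param library_size Total mapped reads in the sample (positive integer,
#'   at least the sum of the counts).
#' @param counts Named non-negative integer vector, names are peak ids.
#' @param peaks Optional `peak_set`; when given, every counted peak id must
#'   exist in it.
#' @param check_sum Enforce `sum(counts) <= library_size` (default TRUE).
#'   [count_fragments_in_peaks()] disables it: a fragment spanning two
#'   peaks counts in both, so summed counts may legitimately exceed the
#'   fragment total.
#' @return A `sample_counts` object.
#' @export
sample_counts <- function(sample_id, assay, condition, library_size, counts,
                          peaks = NULL, check_sum = TRUE) {
  if (length(library_size) != 1 || library_size <= 0)
    validation_error("library_size must be a positive scalar")
  if (any(counts < 0)) validation_error("negative counts")
  if (check_sum && sum(counts) > library_size)
    validation_error("library_size (", library_size,
                     ") smaller than summed counts (", sum(counts), ")")
  if (!is.null(peaks)) {
    unknown <- setdiff(names(counts), peaks$peak_id)
    if (length(unknown))
      validation_error("counted peak absent from peak set: ", unknown[1])
    # complete to the full peak universe
    full <- setNames(integer(length(peaks$peak_id)), peaks$peak_id)
    full[names(counts)] <- as.integer(counts)
    counts <- full
  }
  structure(list(sample_id = sample_id, assay = assay, condition = condition,
                 library_size = as.numeric(library_size),
                 counts = counts),
            class = "sample_counts")
}

#' Tabulate fragments into peaks
#'
#' Each fragment increments every peak it overlaps by at least 1 bp exactly
#' once (a fragment spanning two peaks counts in both). Fragments
#' overlapping no peak contribute to the library size only.
#'
#' @param fragments Data frame of fragment intervals (`chrom`, `start`,
#'   `end`; 0-based half-open), e.g. from [read_fragments()].
#' @param peaks A `peak_set`.
#' @param library_size Total mapped reads; must be at least the number of
#'   fragments.
#' @inheritParams sample_counts
#' @return A `sample_counts` covering every peak in `peaks`.
#' @export
count_fragments_in_peaks <- function(fragments, peaks, library_size,
                                     sample_id = "sample",
                                     condition = "control") {
  if (library_size < nrow(fragments))
    validation_error("library_size (", library_size,
                     ") smaller than fragment count (", nrow(fragments), ")")
  counts <- setNames(integer(nrow(peaks)), peaks$peak_id)
  if (nrow(fragments)) {
    hits <- overlap_pairs(fragments, peaks)
    tab <- tabulate(hits$peak_idx, nbins = nrow(peaks))
    counts[] <- tab
  }
  sample_counts(sample_id, peak_assay(peaks), condition, library_size,
                counts, check_sum = FALSE)
}

#' Read a fragments BED3 file
#'
#' Unlike [read_bed()], duplicate and overlapping records are kept: each row
#' is one sequenced fragment.
#'
#' @param path Path to a BED3 file.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_fragments <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) parse_error("fragment BED needs at least 3 columns")
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  if (!is.numeric(df$start) || !is.numeric(df$end))
    parse_error("non-integer fragment coordinates in ", path)
  if (any(df$start >= df$end))
    validation_error("fragment with start >= end in ", path)
  df
}

#' RPM-normalize one or more samples
#'
#' `RPM = count * 1e6 / library_size`. Given a list of `sample_counts`
#' sharing a peak universe, returns a peaks-by-samples `rpm_table` matrix
#' carrying per-sample condition labels.
#'
#' @param counts A `sample_counts` or list of them.
#' @return Numeric matrix (class `rpm_table`), rows peaks, columns samples,
#'   with attributes `conditions` (named by sample) and `assay`.
#' @export
rpm_normalize <- function(counts) {
  if (inherits(counts, "sample_counts")) counts <- list(counts)
  if (!length(counts)) validation_error("no samples")
  for (s in counts)
    if (s$library_size <= 0) validation_error("library_size must be > 0")
  universe <- names(counts[[1]]$counts)
  cols <- lapply(counts, function(s) {
    if (!identical(names(s$counts), universe))
      validation_error("samples disagree on peak universe")
    s$counts * 1e6 / s$library_size
  })
  m <- do.call(cbind, cols)
  rownames(m) <- universe
  colnames(m) <- vapply(counts, `[[`, "", "sample_id")
  structure(m,
            conditions = setNames(vapply(counts, `[[`, "", "condition"),
                                  colnames(m)),
            assay = counts[[1]]$assay,
            class = c("rpm_table", class(m)))
}

#' @rdname rpm_normalize
#' @param x An `rpm_table` or `gene_signal` matrix.
#' @export
conditions <- function(x) attr(x, "conditions")

#' Per-gene mark signal
#'
#' Sums RPM over all peaks overlapping each gene's scoring region (gene
#' body extended upstream by `promoter_extension`). A peak overlapping two
#' genes' regions contributes to both. Genes with no overlapping peak get 0.
#'
#' @param rpm An `rpm_table` covering all peaks in `peaks`.
#' @param peaks The `peak_set` the RPM values were computed on.
#' @param genes A `gene_models` data frame.
#' @param promoter_extension Upstream extension in bp (default 1000).
#' @param min_overlap Minimum peak/region overlap in bp (default 1).
#' @return Genes-by-samples matrix (class `gene_signal`) with the samples'
#'   `conditions` attribute propagated.
#' @export
gene_signal <- function(rpm, peaks, genes, promoter_extension = 1000L,
                        min_overlap = 1L) {
  missing <- setdiff(peaks$peak_id, rownames(rpm))
  if (length(missing))
    validation_error("rpm table missing peak ", missing[1])
  regions <- scoring_region(genes, promoter_extension)
  hits <- overlap_pairs(regions, peaks, min_overlap)
  out <- matrix(0, nrow(genes), ncol(rpm),
                dimnames = list(genes$gene_id, colnames(rpm)))
  if (nrow(hits)) {
    vals <- rpm[peaks$peak_id[hits$peak_idx], , drop = FALSE]
    for (j in seq_len(ncol(out))) {
      acc <- rowsum(vals[, j], hits$region_idx)
      out[as.integer(rownames(acc)), j] <- acc[, 1]
    }
  }
  structure(out, conditions = conditions(rpm),
            class = c("gene_signal", class(out)))
}

# Average columns of a signal/rpm matrix within one condition (or all
# columns when cond is NULL). agg = "mean" (default) or "sum".
condition_profile <- function(x, cond = NULL, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  cols <- if (is.null(cond)) seq_len(ncol(x)) else
    which(conditions(x) == cond)
  if (!length(cols)) validation_error("no samples for condition ", cond)
  f <- if (agg == "mean") rowMeans else rowSums
  f(x[, cols, drop = FALSE])
}

#' Knockout-vs-control log2 fold change per gene
#'
#' Replicate samples within each input are aggregated on the RPM scale
#' (arithmetic mean by default), then
#' `log2((ko + pseudocount) / (ctrl + pseudocount))`.
#'
#' @param ko,ctrl `gene_signal` matrices (or named numeric vectors) over
#'   the same gene universe.
#' @param pseudocount Positive pseudocount on the RPM scale (default 0.5).
#' @param replicate_agg `"mean"` (default) or `"sum"` across replicates.
#' @return Named numeric vector of log2 fold changes (class `gene_lfc`)
#'   with attribute `pseudocount`.
#' @export
gene_lfc <- function(ko, ctrl, pseudocount = 0.5,
                     replicate_agg = c("mean", "sum")) {
  replicate_agg <- match.arg(replicate_agg)
  if (pseudocount <= 0) validation_error("pseudocount must be > 0")
  vec <- function(x) {
    if (is.matrix(x)) condition_profile(x, NULL, replicate_agg) else x
  }
  a <- vec(ko); b <- vec(ctrl)
  if (!identical(sort(names(a)), sort(names(b))))
    validation_error("ko and ctrl gene universes differ")
  b <- b[names(a)]
  structure(log2((a + pseudocount) / (b + pseudocount)),
            pseudocount = pseudocount, class = "gene_lfc")
}

#' Write a signal or RPM matrix as TSV
#'
#' @param x Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the identifier column (default `"id"`).
#' @export
write_signal_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
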