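#' Classify promoter chromatin state from paired peak sets
#'
#' A gene is *bivalent* when peaks from both the H3K4me3 and H3K27me3 sets
#' overlap its TSS window (`[TSS - half_width, TSS + half_width)`, any
#' overlap of at least `min_overlap` bp); *k4_only* / *k27_only* when only
#' one set does; *unmarked* otherwise. The four states partition the gene
#' universe.
#'
#' @param genes A `gene_models` data frame. Strand must be defined for every
#'   gene (the TSS is strand-dependent); this is enforced at load.
#' @param k4 `peak_set` of H3K4me3 peaks.
#' @param k27 `peak_set` of H3K27me3 peaks.
#' @param half_width TSS window half-width in bp (default 2000).
#' @param min_overlap Minimum peak/window overlap in bp (default 1).
#' @param check_assays Reject peak sets whose assay labels look swapped
#'   (default TRUE; a set labelled `H3K27me3` passed as `k4` is an error).
#' @return A `bivalency_calls` data frame: `gene_id`, `state`,
#'   `n_k4_peaks`, `n_k27_peaks`, plus list-columns `k4_peaks`, `k27_peaks`
#'   of the overlapping peak ids.
#' @export
classify_bivalency <- function(genes, k4, k27, half_width = 2000L,
                               min_overlap = 1L, check_assays = TRUE) {
  if (check_assays) {
    a4 <- peak_assay(k4); a27 <- peak_assay(k27)
    if (!is.null(a4) && grepl("K27", a4, ignore.case = TRUE))
      validation_error("k4 peak set is labelled '", a4, "'")
    if (!is.null(a27) && grepl("K4me", a27, ignore.case = TRUE))
      validation_error("k27 peak set is labelled '", a27, "'")
  }
  windows <- tss_window(genes, half_width)
  ids_per_gene <- function(pk) {
    hits <- overlap_pairs(windows, pk, min_overlap)
    out <- rep(list(character(0)), nrow(genes))
    if (nrow(hits)) {
      sp <- split(pk$peak_id[hits$peak_idx], hits$region_idx)
      out[as.integer(names(sp))] <- lapply(sp, sort)
    }
    out
  }
  l4 <- ids_per_gene(k4)
  l27 <- ids_per_gene(k27)
  n4 <- lengths(l4); n27 <- lengths(l27)
  state <- ifelse(n4 > 0 & n27 > 0, "bivalent",
           ifelse(n4 > 0, "k4_only",
           ifelse(n27 > 0, "k27_only", "unmarked")))
  out <- data.frame(gene_id = genes$gene_id, state = state,
                    n_k4_peaks = n4, n_k27_peaks = n27,
                    stringsAsFactors = FALSE)
  out$k4_peaks <- l4
  out$k27_peaks <- l27
  class(out) <- c("bivalency_calls", "data.frame")
  out
}

#' Gene ids called bivalent
#'
#' @param calls A `bivalency_calls` data frame.
#' @return Sorted character vector of bivalent gene ids.
#' @export
bivalent_gene_set <- function(calls) {
  sort(calls$gene_id[calls$state == "bivalent"])
}

#' Write bivalency calls as TSV
#'
#' Columns: `gene_id`, `state`, `n_k4_peaks`, `n_k27_peaks`.
#'
#' @param calls A `bivalency_calls` data frame.
#' @param path Output path.
#' @export
write_bivalency_tsv <- function(calls, path) {
  write.table(calls[c("gene_id", "state", "n_k4_peaks", "n_k27_peaks")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
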