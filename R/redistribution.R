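#' @name redistribution
#' @title Occupancy redistribution analysis
#'
#' @description
#' The reduced/increased occupancy workflow: restrict to peaks covered in
#' both the factor (e.g. KMT2A) and H3K4me3 data (at least `min_rpm` RPM in
#' at least one sample of each), call each covered peak reduced, increased
#' or unchanged from the knockout-minus-control RPM difference, roll peak
#' calls up to genes via TSS windows, and summarize each gene group's
#' bivalent composition and mark shifts.
NULL

#' Peaks covered in both assays
#'
#' Retains peaks whose maximum RPM over samples is at least `min_rpm` in
#' *both* tables ("at least 1 read per million" is inclusive). The two
#' tables must be quantified over the same peak universe (typically the
#' factor's peak set quantified in both assays).
#'
#' @param kmt2a_rpm,k4_rpm `rpm_table` matrices over a shared peak universe.
#' @param min_rpm Coverage threshold in RPM (default 1).
#' @return Sorted character vector of covered peak ids.
#' @export
filter_covered_peaks <- function(kmt2a_rpm, k4_rpm, min_rpm = 1) {
  if (!nrow(kmt2a_rpm) || !nrow(k4_rpm))
    validation_error("empty RPM table")
  missing <- setdiff(rownames(kmt2a_rpm), rownames(k4_rpm))
  if (length(missing))
    validation_error("peak absent from H3K4me3 table: ", missing[1])
  a <- apply(kmt2a_rpm, 1, max)
  b <- apply(k4_rpm[rownames(kmt2a_rpm), , drop = FALSE], 1, max)
  sort(rownames(kmt2a_rpm)[a >= min_rpm & b >= min_rpm])
}

#' Classify per-peak occupancy changes
#'
#' For each covered peak, `delta` is the knockout condition-mean RPM minus
#' the control condition-mean RPM (replicates averaged). `delta >=
#' delta_rpm` is *increased*, `delta <= -delta_rpm` *reduced* (boundaries
#' inclusive: a change "of 1 RPM" counts), otherwise *unchanged*.
#'
#' @param rpm_ctrl,rpm_ko `rpm_table` matrices (one or more replicate
#'   columns each) over universes containing `covered`.
#' @param covered Character vector of covered peak ids
#'   (from [filter_covered_peaks()]).
#' @param delta_rpm Change threshold in RPM (default 1).
#' @param replicate_agg `"mean"` (default) or `"sum"` across replicates.
#' @return A `peak_changes` data frame: `peak_id`, `delta`, `category`.
#' @export
classify_peak_changes <- function(rpm_ctrl, rpm_ko, covered, delta_rpm = 1,
                                  replicate_agg = c("mean", "sum")) {
  replicate_agg <- match.arg(replicate_agg)
  for (tbl in list(ctrl = rpm_ctrl, ko = rpm_ko)) {
    missing <- setdiff(covered, rownames(tbl))
    if (length(missing))
      validation_error("covered peak missing from RPM table: ", missing[1])
  }
  f <- if (replicate_agg == "mean") rowMeans else rowSums
  ctrl <- f(rpm_ctrl[covered, , drop = FALSE])
  ko <- f(rpm_ko[covered, , drop = FALSE])
  delta <- ko - ctrl
  category <- ifelse(delta >= delta_rpm, "increased",
              ifelse(delta <= -delta_rpm, "reduced", "unchanged"))
  out <- data.frame(peak_id = covered, delta = unname(delta),
                    category = unname(category), stringsAsFactors = FALSE)
  class(out) <- c("peak_changes", "data.frame")
  out
}

#' Roll peak change calls up to genes
#'
#' A gene's category comes from the covered peaks overlapping its TSS
#' window: *increased* if at least one increased peak and no reduced peak,
#' *reduced* symmetrically, *unchanged* if covered but neither direction.
#' When a window contains both directions the larger summed `|delta|` per
#' direction wins, a tie is *unchanged*. Genes whose window contains no
#' covered peak are *not_covered*.
#'
#' @param peak_changes A `peak_changes` data frame.
#' @param genes A `gene_models` data frame.
#' @param peaks The `peak_set` the changes were computed on.
#' @param half_width TSS window half-width in bp (default 2000).
#' @param min_overlap Minimum peak/window overlap in bp (default 1).
#' @return Data frame `gene_id`, `category`, `n_increased`, `n_reduced`,
#'   `n_unchanged` (class `gene_changes`).
#' @export
rollup_to_genes <- function(peak_changes, genes, peaks, half_width = 2000L,
                            min_overlap = 1L) {
  windows <- tss_window(genes, half_width)
  covered_idx <- which(peaks$peak_id %in% peak_changes$peak_id)
  sub <- peaks[covered_idx, , drop = FALSE]
  hits <- overlap_pairs(windows, sub, min_overlap)
  pc <- peak_changes[match(sub$peak_id, peak_changes$peak_id), ]
  n_inc <- n_red <- n_unc <- integer(nrow(genes))
  sum_inc <- sum_red <- numeric(nrow(genes))
  covered_any <- logical(nrow(genes))
  if (nrow(hits)) {
    cat_h <- pc$category[hits$peak_idx]
    del_h <- pc$delta[hits$peak_idx]
    add <- function(mask, val) {
      acc <- rowsum(val[mask], hits$region_idx[mask])
      out <- numeric(nrow(genes))
      out[as.integer(rownames(acc))] <- acc[, 1]
      out
    }
    ones <- rep(1, nrow(hits))
    n_inc <- as.integer(add(cat_h == "increased", ones))
    n_red <- as.integer(add(cat_h == "reduced", ones))
    n_unc <- as.integer(add(cat_h == "unchanged", ones))
    sum_inc <- add(cat_h == "increased", abs(del_h))
    sum_red <- add(cat_h == "reduced", abs(del_h))
    covered_any[unique(hits$region_idx)] <- TRUE
  }
  category <- rep("not_covered", nrow(genes))
  category[covered_any] <- "unchanged"
  category[n_inc > 0 & n_red == 0] <- "increased"
  category[n_red > 0 & n_inc == 0] <- "reduced"
  both <- n_inc > 0 & n_red > 0
  category[both & sum_inc > sum_red] <- "increased"
  category[both & sum_red > sum_inc] <- "reduced"
  # both directions, equal weight -> unchanged (tie rule)
  out <- data.frame(gene_id = genes$gene_id, category = category,
                    n_increased = n_inc, n_reduced = n_red,
                    n_unchanged = n_unc, stringsAsFactors = FALSE)
  class(out) <- c("gene_changes", "data.frame")
  out
}

#' Bivalent composition of each change group
#'
#' For each gene category, the number of genes, how many are bivalent
#' (per the supplied calls, computed on the control condition), and the
#' bivalent fraction. Empty categories are omitted.
#'
#' @param gene_changes A `gene_changes` data frame (or any data frame with
#'   `gene_id` and `category`).
#' @param bivalency A `bivalency_calls` data frame.
#' @return Data frame `group`, `n_genes`, `n_bivalent`, `fraction_bivalent`.
#' @export
group_composition <- function(gene_changes, bivalency) {
  biv <- bivalent_gene_set(bivalency)
  groups <- sort(unique(gene_changes$category))
  rows <- lapply(groups, function(g) {
    ids <- gene_changes$gene_id[gene_changes$category == g]
    if (!length(ids)) return(NULL)
    nb <- sum(ids %in% biv)
    data.frame(group = g, n_genes = length(ids), n_bivalent = nb,
               fraction_bivalent = nb / length(ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mark-shift summary per change group
#'
#' Median and quartiles of per-gene log2 fold changes of companion marks
#' (e.g. H3K4me3, H3K27me3, SUZ12) within each gene category. Categories
#' with no genes contribute no rows.
#'
#' @param gene_changes A `gene_changes` data frame.
#' @param lfc_tables Named list of `gene_lfc` vectors sharing the gene
#'   universe, e.g. `list(H3K4me3 = ..., H3K27me3 = ..., SUZ12 = ...)`.
#' @return Data frame `group`, `mark`, `n`, `q25`, `median`, `q75`.
#' @export
mark_shift_summary <- function(gene_changes, lfc_tables) {
  universe <- names(lfc_tables[[1]])
  for (l in lfc_tables)
    if (!identical(sort(names(l)), sort(universe)))
      validation_error("LFC tables disagree on gene universe")
  rows <- list()
  for (g in sort(unique(gene_changes$category))) {
    ids <- gene_changes$gene_id[gene_changes$category == g]
    ids <- intersect(ids, universe)
    if (!length(ids)) next
    for (mark in names(lfc_tables)) {
      v <- unclass(lfc_tables[[mark]])[ids]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, mark = mark, n = length(v),
                   q25 = q[1], median = q[2], q75 = q[3],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
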