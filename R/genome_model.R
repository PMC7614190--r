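#' @name genome-model
#' @title Gene and peak data model
#'
#' @description
#' Genes and peaks are plain data frames with a small amount of validation,
#' in the BED coordinate convention: 0-based half-open `[start, end)`.
#' A `gene_models` frame has columns `gene_id`, `name`, `chrom`, `start`,
#' `end`, `strand`; a `peak_set` frame has `peak_id`, `chrom`, `start`,
#' `end` and carries its assay label (e.g. `"H3K4me3"`, `"KMT2A"`) as an
#' attribute.
NULL

new_gene_models <- function(df) {
  required <- c("gene_id", "name", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing))
    validation_error("gene table missing columns: ",
                     paste(missing, collapse = ", "))
  df <- df[required]
  df$gene_id <- as.character(df$gene_id)
  df$name <- as.character(df$name)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad))
    validation_error("strand must be '+' or '-' (gene ",
                     df$gene_id[bad[1]], ")")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    validation_error("invalid interval for gene ", df$gene_id[bad[1]],
                     ": [", df$start[bad[1]], ",", df$end[bad[1]], ")")
  if (anyDuplicated(df$gene_id))
    validation_error("duplicate gene_id: ",
                     df$gene_id[duplicated(df$gene_id)][1])
  if (any(!nzchar(df$chrom)))
    validation_error("empty chromosome name")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read a gene table
#'
#' Reads a tab-separated gene table with header columns `gene_id`, `name`,
#' `chrom`, `start`, `end`, `strand`. Coordinates are 0-based half-open.
#' Rows with `start >= end`, duplicate `gene_id`, or a strand other than
#' `+`/`-` are rejected.
#'
#' @param path Path to the TSV file.
#' @return A `gene_models` data frame.
#' @seealso [read_gtf_genes()] for a minimal GTF alternative.
#' @export
read_gene_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) validation_error("empty gene table: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(header)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < n)
      parse_error("gene table line ", i + 1L, ": expected ", n,
                  " fields, got ", length(f))
    f[seq_len(n)]
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (col in c("start", "end")) {
    if (is.null(df[[col]])) validation_error("gene table missing column ", col)
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | as.character(v) != df[[col]])
    if (length(bad))
      parse_error("gene table line ", bad[1] + 1L,
                  ": non-integer ", col, " '", df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  new_gene_models(df)
}

#' Read gene models from a minimal GTF subset
#'
#' Accepts GTF lines with feature type `gene` and attributes `gene_id` and
#' (optionally) `gene_name`. GTF coordinates are 1-based closed and are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to the GTF file.
#' @return A `gene_models` data frame.
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                 logical(1))
  fields <- fields[keep]
  if (!length(fields)) validation_error("no 'gene' features in ", path)
  attr1 <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, ' "([^"]*)"'), "\\1", m)
  }
  rows <- lapply(fields, function(f) {
    gid <- attr1(f[9], "gene_id")
    if (is.na(gid)) parse_error("GTF gene record without gene_id attribute")
    gname <- attr1(f[9], "gene_name")
    data.frame(gene_id = gid,
               name = if (is.na(gname)) gid else gname,
               chrom = f[1],
               start = as.integer(f[4]) - 1L,  # GTF 1-based -> 0-based
               end = as.integer(f[5]),
               strand = f[7],
               stringsAsFactors = FALSE)
  })
  new_gene_models(do.call(rbind, rows))
}

#' Construct a peak set
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and optionally
#'   `peak_id` (synthesized as `"chrom:start-end"` when absent).
#' @param assay Assay label (mark or factor, e.g. `"H3K4me3"`).
#' @param merge Merge overlapping intervals within the set (union, ids
#'   concatenated with `|`). Merging prevents double-counting in summed
#'   signals; on by default.
#' @return A `peak_set` data frame with attribute `assay`.
#' @export
peak_set <- function(df, assay, merge = TRUE) {
  if (is.null(df$peak_id))
    df$peak_id <- paste0(df$chrom, ":", df$start, "-", df$end)
  df <- df[c("peak_id", "chrom", "start", "end")]
  df$peak_id <- as.character(df$peak_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    validation_error("invalid peak interval [", df$start[bad[1]], ",",
                     df$end[bad[1]], ")")
  if (merge && nrow(df) > 1) df <- merge_peaks(df)
  if (anyDuplicated(df$peak_id))
    validation_error("duplicate peak_id: ",
                     df$peak_id[duplicated(df$peak_id)][1])
  df <- df[order(df$chrom, df$start, df$peak_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  attr(df, "assay") <- assay
  df
}

#' @rdname peak_set
#' @param x A `peak_set`.
#' @export
peak_assay <- function(x) attr(x, "assay")

# Union of overlapping intervals within one set; member ids joined with "|"
# in start order. Keeps downstream sums free of double counting.
merge_peaks <- function(df) {
  gr <- to_granges(df$chrom, df$start, df$end)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  ids <- vapply(seq_along(red), function(i) {
    members <- revmap[[i]]
    members <- members[order(df$start[members], df$peak_id[members])]
    paste(df$peak_id[members], collapse = "|")
  }, character(1))
  data.frame(peak_id = ids,
             chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

# 0-based half-open -> GRanges (1-based closed)
to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Read a BED file as a peak set
#'
#' BED3+ (tab-separated, 0-based half-open). Column 4, when present, is the
#' peak id; otherwise ids are synthesized as `"chrom:start-end"`. Columns
#' beyond the fourth are ignored. Overlapping records are merged on load
#' unless `merge = FALSE`.
#'
#' @param path Path to the BED file.
#' @param assay Assay label to attach.
#' @inheritParams peak_set
#' @return A `peak_set`.
#' @export
read_bed <- function(path, assay = "unknown", merge = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_set(data.frame(peak_id = character(), chrom = character(),
                               start = integer(), end = integer()), assay))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate space-separated input
  one <- lengths(fields) == 1L
  fields[one] <- strsplit(lines[one], "[ \t]+")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3)
      parse_error("BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      parse_error("BED line ", i, ": non-integer coordinates '",
                  f[2], "', '", f[3], "'")
    if (s >= e)
      validation_error("BED line ", i, ": start >= end (", s, " >= ", e, ")")
    data.frame(peak_id = if (length(f) >= 4) f[4] else
                 paste0(f[1], ":", s, "-", e),
               chrom = f[1], start = s, end = e, stringsAsFactors = FALSE)
  })
  peak_set(do.call(rbind, rows), assay, merge = merge)
}

#' Write intervals as BED4
#'
#' @param x A `peak_set` or data frame with `chrom`, `start`, `end` and
#'   optionally `peak_id`/`name`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  id <- if (!is.null(x$peak_id)) x$peak_id else
    if (!is.null(x$name)) x$name else
      paste0(x$chrom, ":", x$start, "-", x$end)
  writeLines(paste(x$chrom, x$start, x$end, id, sep = "\t"), path)
  invisible(path)
}

#' Transcription start site
#'
#' The 5' end of the gene model: `start` for `+` strand genes, `end - 1`
#' (the last covered base) for `-` strand genes.
#'
#' @param genes A `gene_models` data frame.
#' @return Integer vector of TSS positions, named by `gene_id`.
#' @export
tss <- function(genes) {
  pos <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  setNames(as.integer(pos), genes$gene_id)
}

#' Symmetric window around each TSS
#'
#' `[tss - half_width, tss + half_width)`, clipped at coordinate 0. This is
#' the window used for bivalency classification and the redistribution
#' rollup ("within 2 kb of the TSS").
#'
#' @param genes A `gene_models` data frame.
#' @param half_width Half-width in bp (default 2000).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
tss_window <- function(genes, half_width = 2000L) {
  if (half_width <= 0) validation_error("half_width must be > 0")
  t <- unname(tss(genes))
  data.frame(gene_id = genes$gene_id,
             chrom = genes$chrom,
             start = pmax(0L, as.integer(t - half_width)),
             end = as.integer(t + half_width),
             stringsAsFactors = FALSE)
}

#' Scoring region: gene body plus upstream promoter extension
#'
#' The gene body extended upstream of the TSS (strand-aware) by
#' `promoter_extension` bp; the region over which per-gene mark signal is
#' summed ("within a gene body and within 1 kb of the promoter").
#'
#' @param genes A `gene_models` data frame.
#' @param promoter_extension Upstream extension in bp (default 1000).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
scoring_region <- function(genes, promoter_extension = 1000L) {
  if (promoter_extension < 0)
    validation_error("promoter_extension must be >= 0")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - as.integer(promoter_extension)),
                  genes$start)
  end <- ifelse(plus, genes$end, genes$end + as.integer(promoter_extension))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Peaks overlapping a region
#'
#' Returns the peaks whose interval overlaps `region` by at least
#' `min_overlap` bp on the same chromosome, in stable `(start, peak_id)`
#' order.
#'
#' @param peaks A `peak_set`.
#' @param region A list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_overlap Minimum overlap in bp (default 1: any overlap).
#' @return The subset of `peaks` rows overlapping the region.
#' @export
assign_peaks <- function(peaks, region, min_overlap = 1L) {
  same <- peaks$chrom == region$chrom
  ov <- pmin(peaks$end, region$end) - pmax(peaks$start, region$start)
  keep <- same & ov >= min_overlap
  out <- peaks[keep, , drop = FALSE]
  out <- out[order(out$start, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized region->peak assignment used by downstream modules.
# Returns data.frame(region_idx, peak_idx) for every overlap of at least
# min_overlap bp.
overlap_pairs <- function(regions, peaks, min_overlap = 1L) {
  if (!nrow(regions) || !nrow(peaks))
    return(data.frame(region_idx = integer(), peak_idx = integer()))
  qr <- to_granges(regions$chrom, regions$start, regions$end)
  sb <- to_granges(peaks$chrom, peaks$start, peaks$end)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qr, sb, minoverlap = min_overlap))
  data.frame(region_idx = S4Vectors::queryHits(hits),
             peak_idx = S4Vectors::subjectHits(hits))
}

#' Write TSS windows and scoring regions to BED
#'
#' Convenience driver behind the `regions` CLI stage.
#'
#' @param genes A `gene_models` data frame.
#' @param path Output BED path (TSS windows; ids are `gene_id`).
#' @inheritParams tss_window
#' @export
write_regions_bed <- function(genes, path, half_width = 2000L) {
  w <- tss_window(genes, half_width)
  write_bed(data.frame(chrom = w$chrom, start = w$start, end = w$end,
                       peak_id = w$gene_id), path)
}
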