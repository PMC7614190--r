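# Small fixture builders shared across test files.

toy_genes <- function() {
  new_df <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    name = c("G1", "G2", "G3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(8000L, 30000L, 500L),
    end = c(12000L, 42000L, 900L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write.table(new_df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  read_gene_table(tf)
}

toy_peaks <- function(assay = "H3K4me3",
                      df = data.frame(
                        peak_id = c("pk1", "pk2", "pk3"),
                        chrom = c("chr1", "chr1", "chr2"),
                        start = c(7000L, 9500L, 400L),
                        end = c(8200L, 10500L, 600L),
                        stringsAsFactors = FALSE)) {
  peak_set(df, assay)
}

random_peakset <- function(n, chrom = "chr1", max_pos = 10000L,
                           assay = "mark") {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(500L, n, replace = TRUE)
  peak_set(data.frame(chrom = chrom, start = start, end = start + width,
                      stringsAsFactors = FALSE), assay)
}

# Deterministic distinct spacers (base-4 encoding of the index).
random_spacers_test <- function(n, len = 10L) {
  vapply(seq_len(n), function(i) {
    digits <- integer(len)
    x <- i
    for (j in seq_len(len)) { digits[j] <- x %% 4; x <- x %/% 4 }
    paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
  }, character(1))
}

write_tsv_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
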