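#' @name screen-analysis
#' @title FACS-sorted CRISPR knockout screen analysis
#'
#' @description
#' sgRNA reads are counted by exact spacer match after trimming the
#' vector-derived constant prefix (reads matching more than one guide are
#' discarded as ambiguous, reproducing multi-aligner removal); per-guide
#' enrichment is the sorted-vs-unsorted RPM log2 ratio; genes are ranked by
#' the RSA statistic — the minimum hypergeometric upper-tail probability
#' over the ranks of a gene's guides among all ranked guides — and tiered
#' into high / moderate / low confidence bins, with an enriched-guide count
#' gate (at least 4 enriched sgRNA).
NULL

CONTROL_CLASSES <- c("non_targeting", "safe_targeting")

#' Construct a guide library
#'
#' @param df Data frame with columns `guide_id`, `target` (a gene id or
#'   one of `"non_targeting"` / `"safe_targeting"`), `spacer`.
#' @param constant_prefix Vector-derived constant sequence preceding the
#'   spacer in sequencing reads.
#' @return A `guide_library` data frame with attribute `constant_prefix`.
#' @export
guide_library <- function(df, constant_prefix = "") {
  required <- c("guide_id", "target", "spacer")
  missing <- setdiff(required, names(df))
  if (length(missing))
    validation_error("guide library missing columns: ",
                     paste(missing, collapse = ", "))
  df <- df[required]
  df$guide_id <- as.character(df$guide_id)
  df$target <- as.character(df$target)
  df$spacer <- toupper(as.character(df$spacer))
  if (!nrow(df)) validation_error("empty guide library")
  if (anyDuplicated(df$guide_id))
    validation_error("duplicate guide_id: ",
                     df$guide_id[duplicated(df$guide_id)][1])
  if (any(grepl("[^ACGT]", df$spacer)))
    validation_error("spacer with non-ACGT characters")
  rownames(df) <- NULL
  class(df) <- c("guide_library", "data.frame")
  attr(df, "constant_prefix") <- toupper(constant_prefix)
  df
}

#' Read a guide library TSV
#'
#' Columns: `guide_id`, `target`, `spacer` (header required).
#'
#' @param path Path to the TSV.
#' @inheritParams guide_library
#' @export
read_guide_library <- function(path, constant_prefix = "") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  guide_library(df, constant_prefix)
}

#' Count sgRNA reads against a library
#'
#' Each read is trimmed at the first occurrence of the library's constant
#' prefix; the following spacer-length window is compared with the library
#' by exact match. A window matching exactly one guide is assigned; a
#' window matching a spacer shared by several guides is ambiguous and
#' discarded; anything else (including reads lacking the prefix) is
#' unmatched. `assigned + ambiguous + unmatched` always equals the number
#' of reads.
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ
#'   file (parsed with [Biostrings::readDNAStringSet()]).
#' @param library A `guide_library`.
#' @return List: `counts` (named integer vector over all guide ids),
#'   `assigned`, `ambiguous`, `unmatched`, `total`.
#' @export
count_guides <- function(reads, library) {
  if (!inherits(library, "guide_library") || !nrow(library))
    validation_error("empty guide library")
  if (length(reads) == 1 && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  reads <- toupper(reads)
  prefix <- attr(library, "constant_prefix")
  spacers <- library$spacer
  # spacer -> guide index; shared spacers are inherently ambiguous
  dup_spacers <- unique(spacers[duplicated(spacers)])
  lens <- sort(unique(nchar(spacers)))
  counts <- setNames(integer(nrow(library)), library$guide_id)
  n <- length(reads)
  if (!n)
    return(list(counts = counts, assigned = 0L, ambiguous = 0L,
                unmatched = 0L, total = 0L))
  if (nzchar(prefix)) {
    pos <- regexpr(prefix, reads, fixed = TRUE)
    spacer_start <- ifelse(pos > 0, pos + nchar(prefix), NA_integer_)
  } else {
    spacer_start <- rep(1L, n)
  }
  assigned_guide <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  for (L in lens) {
    idx <- which(nchar(spacers) == L & !(spacers %in% dup_spacers))
    win <- substr(reads, spacer_start, spacer_start + L - 1L)
    win[is.na(spacer_start) | nchar(win) < L] <- NA_character_
    hit <- match(win, spacers[idx])
    amb <- !is.na(win) & win %in% dup_spacers
    newly <- !is.na(hit)
    # a window matching guides of two different spacer lengths is ambiguous
    clash <- newly & !is.na(assigned_guide)
    ambiguous <- ambiguous | amb | clash
    assigned_guide[newly & is.na(assigned_guide)] <-
      idx[hit[newly & is.na(assigned_guide)]]
  }
  assigned_guide[ambiguous] <- NA_integer_
  tab <- tabulate(assigned_guide[!is.na(assigned_guide)],
                  nbins = nrow(library))
  counts[] <- tab
  n_assigned <- sum(tab)
  n_amb <- sum(ambiguous)
  list(counts = counts, assigned = n_assigned, ambiguous = n_amb,
       unmatched = n - n_assigned - n_amb, total = n)
}

#' Assemble sorted/unsorted screen counts
#'
#' @param sorted,unsorted Results of [count_guides()] (or bare named count
#'   vectors over the same guide universe).
#' @return A `screen_counts` object: guides-by-2 integer matrix with
#'   columns `sorted`, `unsorted`, plus a `totals` attribute.
#' @export
screen_counts <- function(sorted, unsorted) {
  grab <- function(x) if (is.list(x)) x$counts else x
  s <- grab(sorted); u <- grab(unsorted)
  if (!identical(names(s), names(u)))
    validation_error("sorted/unsorted guide universes differ")
  m <- cbind(sorted = as.integer(s), unsorted = as.integer(u))
  rownames(m) <- names(s)
  totals <- lapply(list(sorted = sorted, unsorted = unsorted), function(x)
    if (is.list(x)) x[c("assigned", "ambiguous", "unmatched", "total")]
    else list(assigned = sum(grab(x)), ambiguous = 0L, unmatched = 0L,
              total = sum(grab(x))))
  structure(m, totals = totals, class = c("screen_counts", class(m)))
}

#' Per-guide enrichment score
#'
#' `log2((RPM_sorted + pseudocount) / (RPM_unsorted + pseudocount))`, with
#' RPM computed from each sample's assigned-read total.
#'
#' @param counts A `screen_counts` object.
#' @param pseudocount Pseudocount on the RPM scale (default 0.5).
#' @return Named numeric vector of scores per guide.
#' @export
guide_enrichment <- function(counts, pseudocount = 0.5) {
  tot <- colSums(counts)
  if (any(tot == 0))
    validation_error("sample with zero assigned reads: ",
                     colnames(counts)[tot == 0][1])
  rpm <- sweep(unclass(counts), 2, tot, "/") * 1e6
  setNames(log2((rpm[, "sorted"] + pseudocount) /
                (rpm[, "unsorted"] + pseudocount)),
           rownames(counts))
}

#' RSA gene ranking
#'
#' Guides are ranked by score (descending, ties broken by guide id). For a
#' gene with `k` guides at 1-based ranks `r_1 < ... < r_k` among `N` ranked
#' guides, `p_j` is the hypergeometric upper tail `P(X >= j)` with
#' population `N`, `k` successes and `r_j` draws, and the gene's p-value is
#' `min_j p_j` (the non-iterative min-tail form of the statistic). Control
#' guides (non-targeting, safe-targeting) stay in the ranked universe but
#' receive no gene p-value.
#'
#' @param scores Named numeric vector of per-guide scores (all ranked
#'   guides, controls included).
#' @param library A `guide_library` mapping guides to genes.
#' @return Data frame `gene_id`, `n_guides`, `p`, `logp` (log10 p), sorted
#'   by `p` then `gene_id`.
#' @export
rsa_rank <- function(scores, library) {
  unknown <- setdiff(names(scores), library$guide_id)
  if (length(unknown))
    validation_error("scored guide absent from library: ", unknown[1])
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  N <- length(ranked)
  rank_of <- setNames(seq_len(N), ranked)
  targets <- setNames(library$target, library$guide_id)
  gene_ids <- sort(unique(library$target[
    !(library$target %in% CONTROL_CLASSES)]))
  rows <- lapply(gene_ids, function(g) {
    guides <- library$guide_id[library$target == g]
    guides <- guides[guides %in% names(rank_of)]
    if (!length(guides)) {
      warning("gene ", g, " has no scored guides; omitted")
      return(NULL)
    }
    r <- sort(unname(rank_of[guides]))
    k <- length(r)
    p <- min(phyper(seq_len(k) - 1, k, N - k, r, lower.tail = FALSE))
    data.frame(gene_id = g, n_guides = k, p = p, logp = log10(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

TIER_LEVELS <- c("high", "moderate", "low", "none")

#' Confidence tiers for screen hits
#'
#' A gene needs at least `min_enriched` guides with score at or above
#' `enriched_threshold`; genes below that gate are tier `none` regardless
#' of p-value. Otherwise the p-value bins are: `high` p < 1e-5, `moderate`
#' 1e-5 <= p < 1e-4, `low` 1e-4 <= p < 1e-3, else `none` (half-open bins,
#' boundaries closed downward).
#'
#' @param rsa Output of [rsa_rank()].
#' @param scores Named per-guide score vector (as passed to [rsa_rank()]).
#' @param library A `guide_library`.
#' @param enriched_threshold Score cutoff defining an enriched guide
#'   (default 1, i.e. 2-fold RPM enrichment).
#' @param min_enriched Enriched-guide gate (default 4).
#' @return A `screen_result` data frame: `gene_id`, `n_guides`, `p`,
#'   `logp`, `n_enriched`, `tier`, sorted by `p`.
#' @export
tier_hits <- function(rsa, scores, library, enriched_threshold = 1,
                      min_enriched = 4L) {
  enriched <- names(scores)[scores >= enriched_threshold]
  n_enr <- vapply(rsa$gene_id, function(g)
    sum(library$guide_id[library$target == g] %in% enriched), integer(1))
  tier <- ifelse(n_enr < min_enriched, "none",
          ifelse(rsa$p < 1e-5, "high",
          ifelse(rsa$p < 1e-4, "moderate",
          ifelse(rsa$p < 1e-3, "low", "none"))))
  out <- rsa
  out$n_enriched <- unname(n_enr)
  out$tier <- factor(tier, levels = TIER_LEVELS)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Intersect two screens' hits
#'
#' Genes reaching `min_tier` or better in both results, sorted by the worse
#' (larger) of the two p-values — the dual-screen prioritization used to
#' limit false positives among moderate/low hits.
#'
#' @param a,b `screen_result` data frames.
#' @param min_tier Minimum tier, default `"low"`.
#' @return Data frame `gene_id`, `p_a`, `p_b`, `tier_a`, `tier_b`,
#'   `p_worse`, best first.
#' @export
intersect_screens <- function(a, b, min_tier = "low") {
  keep <- function(x) {
    lev <- match(as.character(x$tier), TIER_LEVELS)
    x[lev <= match(min_tier, TIER_LEVELS), , drop = FALSE]
  }
  ka <- keep(a); kb <- keep(b)
  common <- intersect(ka$gene_id, kb$gene_id)
  ia <- ka[match(common, ka$gene_id), ]
  ib <- kb[match(common, kb$gene_id), ]
  out <- data.frame(gene_id = common, p_a = ia$p, p_b = ib$p,
                    tier_a = as.character(ia$tier),
                    tier_b = as.character(ib$tier),
                    p_worse = pmax(ia$p, ib$p), stringsAsFactors = FALSE)
  out <- out[order(out$p_worse, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a screen result as TSV
#'
#' @param result A `screen_result`.
#' @param path Output path.
#' @export
write_screen_tsv <- function(result, path) {
  df <- as.data.frame(result)
  df$tier <- as.character(df$tier)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
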