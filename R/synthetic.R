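#' @name synthetic-data
#' @title Synthetic data with planted ground truth
#'
#' @description
#' Generators for every pipeline input: a toy genome with designed
#' active / bivalent / repressed / unmarked gene classes; multi-mark peak
#' and count data in control and knockout conditions with a planted
#' occupancy redistribution (factor lost from active genes, gained at a
#' designated poised subset with concomitant H3K4me3 gain and
#' H3K27me3/SUZ12 loss); sorted-vs-unsorted screen counts with planted
#' repressors; and gene-effect matrices with planted correlation blocks.
#' Every generator is a deterministic function of its arguments and `seed`.
NULL

MARK_ASSAYS <- c("H3K4me3", "H3K27me3", "KMT2A", "Menin", "SUZ12",
                 "H2AK119Ub")

# Baseline RPM means per gene class and assay (control condition).
# Active promoters carry H3K4me3 with KMT2A and Menin; bivalent promoters
# carry both methyl marks plus polycomb (SUZ12, H2AK119Ub) and low KMT2A
# without Menin; repressed promoters carry polycomb marks only.
CLASS_BASELINE <- rbind(
  active    = c(H3K4me3 = 30, H3K27me3 = 0,  KMT2A = 20, Menin = 15,
                SUZ12 = 0, H2AK119Ub = 0),
  bivalent  = c(H3K4me3 = 8,  H3K27me3 = 10, KMT2A = 3,  Menin = 0,
                SUZ12 = 8, H2AK119Ub = 6),
  repressed = c(H3K4me3 = 0,  H3K27me3 = 12, KMT2A = 0,  Menin = 0,
                SUZ12 = 0, H2AK119Ub = 8),
  unmarked  = c(H3K4me3 = 0,  H3K27me3 = 0,  KMT2A = 0,  Menin = 0,
                SUZ12 = 0, H2AK119Ub = 0))

# Knockout fold-effects at redistributed genes.
DEFAULT_EFFECTS <- list(
  kmt2a_loss_fold = 0.25,   # factor depleted at redistributed_loss genes
  kmt2a_gain_fold = 4,      # factor gained at redistributed_gain genes
  k4_gain_fold = 2,         # H3K4me3 up at gain genes
  k27_gain_fold = 0.5,      # H3K27me3 down at gain genes
  suz12_gain_fold = 0.5,    # SUZ12 down at gain genes
  kmt2a_poised_rpm = 3,     # baseline factor occupancy floor at gain genes
  k4_acquired_rpm = 4)      # KO H3K4me3 floor at gain genes

#' Generate a toy genome with designed gene classes
#'
#' Genes are laid out on synthetic chromosomes with guaranteed spacing so
#' TSS windows never overlap; classes are drawn multinomially with the
#' given fractions. The ground truth also designates the redistribution
#' gene sets (loss genes drawn from the active class; gain genes drawn
#' from the bivalent class with probability `gain_bivalent_fraction`, else
#' from the repressed class — echoing the observation that about 63% of
#' genes gaining occupancy were bivalent beforehand) and the planted
#' screen repressors.
#'
#' @param n_genes Number of genes (default 1000).
#' @param class_fractions Named fractions over
#'   `active`, `bivalent`, `repressed`, `unmarked`; must sum to 1.
#' @param gene_length Length range in bp (default 2000-20000).
#' @param spacing Gap between consecutive genes in bp; must be at least
#'   `2 * tss_half_width` (default 10000).
#' @param seed Integer seed.
#' @param tss_half_width TSS window half-width the layout must respect
#'   (default 2000).
#' @param loss_fraction Fraction of active genes designated to lose the
#'   factor upon knockout (default 0.9).
#' @param gain_fraction Fraction of all genes designated to gain the
#'   factor (default 0.1).
#' @param gain_bivalent_fraction Designed bivalent fraction of the gain
#'   set (default 0.63).
#' @param n_repressors Planted screen repressors (default 20, capped at
#'   `n_genes`).
#' @param genes_per_chrom Genes per synthetic chromosome (default 200).
#' @return List with elements `genes` (a `gene_models`) and `truth`
#'   (a `ground_truth` list).
#' @export
make_genome <- function(n_genes = 1000L,
                        class_fractions = c(active = 0.4, bivalent = 0.3,
                                            repressed = 0.2, unmarked = 0.1),
                        gene_length = c(2000L, 20000L),
                        spacing = 10000L,
                        seed = 1L,
                        tss_half_width = 2000L,
                        loss_fraction = 0.9,
                        gain_fraction = 0.1,
                        gain_bivalent_fraction = 0.63,
                        n_repressors = 20L,
                        genes_per_chrom = 200L) {
  if (n_genes < 1) validation_error("n_genes must be >= 1")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    validation_error("class_fractions must sum to 1")
  if (spacing < 2 * tss_half_width)
    validation_error("spacing (", spacing, ") infeasible: needs >= 2 * ",
                     "tss_half_width (", 2 * tss_half_width, ")")
  set.seed(seed)
  classes <- names(class_fractions)
  cls <- sample(classes, n_genes, replace = TRUE, prob = class_fractions)
  len <- sample(seq(gene_length[1], gene_length[2]), n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  chrom_idx <- (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L
  pos_in_chrom <- (seq_len(n_genes) - 1L) %% genes_per_chrom
  pad <- 2L * tss_half_width + 1000L
  start <- integer(n_genes)
  for (ci in unique(chrom_idx)) {
    idx <- which(chrom_idx == ci)
    offs <- cumsum(c(0L, len[idx][-length(idx)] + spacing))
    start[idx] <- pad + offs
  }
  ids <- sprintf("g%04d", seq_len(n_genes))
  genes <- new_gene_models(data.frame(
    gene_id = ids, name = toupper(ids),
    chrom = paste0("chrS", chrom_idx),
    start = start, end = start + len, strand = strand,
    stringsAsFactors = FALSE))
  gene_classes <- setNames(cls, ids)
  active <- ids[cls == "active"]
  bivalent <- ids[cls == "bivalent"]
  repressed <- ids[cls == "repressed"]
  loss <- sort(sample(active, round(loss_fraction * length(active))))
  n_gain <- round(gain_fraction * n_genes)
  n_gain_biv <- min(round(gain_bivalent_fraction * n_gain), length(bivalent))
  n_gain_rep <- min(n_gain - n_gain_biv, length(repressed))
  gain <- sort(c(sample(bivalent, n_gain_biv),
                 sample(repressed, n_gain_rep)))
  repressors <- sort(sample(ids, min(n_repressors, n_genes)))
  truth <- structure(list(
    gene_classes = gene_classes,
    redistributed_gain = gain,
    redistributed_loss = loss,
    planted_repressors = repressors,
    params = list(n_genes = n_genes,
                  class_fractions = as.list(class_fractions),
                  gene_length = gene_length, spacing = spacing,
                  tss_half_width = tss_half_width,
                  loss_fraction = loss_fraction,
                  gain_fraction = gain_fraction,
                  gain_bivalent_fraction = gain_bivalent_fraction,
                  seed = seed)),
    class = "ground_truth")
  list(genes = genes, truth = truth)
}

# Per-gene, per-assay mean RPM for one condition given the planted truth.
mark_means <- function(genes, truth, condition,
                       effects = DEFAULT_EFFECTS) {
  cls <- truth$gene_classes[genes$gene_id]
  mu <- CLASS_BASELINE[cls, , drop = FALSE]
  rownames(mu) <- genes$gene_id
  gain <- intersect(truth$redistributed_gain, genes$gene_id)
  loss <- intersect(truth$redistributed_loss, genes$gene_id)
  # gain genes are poised: low but detectable baseline factor occupancy
  mu[gain, "KMT2A"] <- pmax(mu[gain, "KMT2A"], effects$kmt2a_poised_rpm)
  if (condition == "knockout") {
    mu[loss, "KMT2A"] <- mu[loss, "KMT2A"] * effects$kmt2a_loss_fold
    mu[gain, "KMT2A"] <- mu[gain, "KMT2A"] * effects$kmt2a_gain_fold
    mu[gain, "H3K4me3"] <- pmax(mu[gain, "H3K4me3"] * effects$k4_gain_fold,
                                effects$k4_acquired_rpm)
    mu[gain, "H3K27me3"] <- mu[gain, "H3K27me3"] * effects$k27_gain_fold
    mu[gain, "SUZ12"] <- mu[gain, "SUZ12"] * effects$suz12_gain_fold
  }
  mu
}

#' Simulate multi-mark peak and count data
#'
#' Promoter peaks (1 kb, centered on the TSS) are planted per gene class;
#' per-peak counts per replicate are negative binomial around
#' class-and-condition means scaled to the requested depth. Knockout
#' applies the configured fold-effects at the redistributed gain/loss
#' genes. Peak ids are shared across assays at a gene (`<gene_id>_pk`),
#' so all assays can be quantified over a common universe.
#'
#' @param genes `gene_models` from [make_genome()].
#' @param truth Matching `ground_truth`.
#' @param condition `"control"` or `"knockout"`.
#' @param depth Library size (fragments) per sample (default 1e6; must be
#'   at least 1e4).
#' @param n_replicates Replicates per condition (default 2).
#' @param dispersion Negative-binomial dispersion (default 0.05;
#'   `variance = mu + dispersion * mu^2`).
#' @param seed Integer seed.
#' @param effects Knockout fold-effect list (see `DEFAULT_EFFECTS` in the
#'   source); replace entries to change the planted world.
#' @param peak_call_min_rpm Minimum mean RPM for a peak to be "called" in
#'   this condition's peak sets (default 0.5).
#' @return List per assay name with elements:
#'   `peaks` — list of condition-called `peak_set`s;
#'   `universe` — list of `peak_set`s over every site with signal in
#'   either condition (quantification universe);
#'   `counts` — list (per assay) of lists of `sample_counts` over the
#'   universe;
#'   `rpm` — list of `rpm_table` matrices.
#' @export
simulate_mark_data <- function(genes, truth,
                               condition = c("control", "knockout"),
                               depth = 1e6, n_replicates = 2L,
                               dispersion = 0.05, seed = 1L,
                               effects = DEFAULT_EFFECTS,
                               peak_call_min_rpm = 0.5) {
  condition <- match.arg(condition)
  if (depth < 1e4) validation_error("depth must be >= 1e4")
  set.seed(seed)
  t_pos <- tss(genes)
  half <- 500L
  peak_df <- data.frame(peak_id = paste0(genes$gene_id, "_pk"),
                        chrom = genes$chrom,
                        start = pmax(0L, t_pos - half),
                        end = t_pos + half,
                        stringsAsFactors = FALSE)
  mu_cond <- mark_means(genes, truth, condition, effects)
  mu_ctrl <- mark_means(genes, truth, "control", effects)
  mu_ko <- mark_means(genes, truth, "knockout", effects)
  sample_tag <- if (condition == "control") "ctrl" else "ko"
  out <- list(peaks = list(), universe = list(), counts = list(),
              rpm = list())
  for (assay in colnames(mu_cond)) {
    in_universe <- pmax(mu_ctrl[, assay], mu_ko[, assay]) > 0
    called <- mu_cond[, assay] >= peak_call_min_rpm
    universe <- peak_set(peak_df[in_universe, , drop = FALSE], assay,
                         merge = FALSE)
    peaks <- peak_set(peak_df[called, , drop = FALSE], assay, merge = FALSE)
    mu_u <- mu_cond[sub("_pk$", "", universe$peak_id), assay]
    mu_counts <- mu_u * depth / 1e6
    reps <- lapply(seq_len(n_replicates), function(r) {
      cnt <- rnbinom(length(mu_counts), mu = mu_counts,
                     size = 1 / dispersion)
      sample_counts(sprintf("%s_%s_rep%d", assay, sample_tag, r),
                    assay, condition, depth,
                    setNames(as.integer(cnt), universe$peak_id))
    })
    out$peaks[[assay]] <- peaks
    out$universe[[assay]] <- universe
    out$counts[[assay]] <- reps
    out$rpm[[assay]] <- rpm_normalize(reps)
  }
  out
}

#' Emit fragment intervals realizing a set of peak counts
#'
#' For round-trip testing of the fragment counter: for each peak, its
#' counted number of fragments is placed uniformly inside the peak; the
#' remaining `library_size - sum(counts)` background fragments are placed
#' in a peak-free tail region beyond the last peak.
#'
#' @param counts A `sample_counts`.
#' @param peaks The matching `peak_set`.
#' @param fragment_length Fragment length in bp (default 100; peaks must
#'   be wider).
#' @param seed Integer seed.
#' @return Data frame `chrom`, `start`, `end`, one row per fragment.
#' @export
fragments_from_counts <- function(counts, peaks, fragment_length = 100L,
                                  seed = 1L) {
  set.seed(seed)
  n <- counts$counts[peaks$peak_id]
  widths <- peaks$end - peaks$start
  if (any(widths[n > 0] < fragment_length))
    validation_error("peak narrower than fragment_length")
  rows <- lapply(which(n > 0), function(i) {
    s <- peaks$start[i] +
      sample.int(widths[i] - fragment_length + 1L, n[i], replace = TRUE) - 1L
    data.frame(chrom = peaks$chrom[i], start = s,
               end = s + fragment_length, stringsAsFactors = FALSE)
  })
  n_bg <- counts$library_size - sum(n)
  if (n_bg > 0) {
    tail_chrom <- peaks$chrom[which.max(peaks$end)]
    tail_start <- max(peaks$end) + 10000L
    s <- tail_start + sample.int(1e6L, n_bg, replace = TRUE)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = tail_chrom, start = s, end = s + fragment_length,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_spacers <- function(n, length = 20L) {
  repeat {
    sp <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(sp)) return(sp)
  }
}

DEFAULT_CONSTANT_PREFIX <- "TTGTGGAAAGGACGAAACACCG"

#' Simulate a FACS-sort screen
#'
#' Builds a guide library over the truth's gene universe (plus
#' non-targeting and safe-targeting controls), then draws unsorted counts
#' from a gamma-weighted multinomial (negative-binomial marginals around
#' equal abundance) and sorted counts after multiplying the weights of
#' planted repressors' *active* guides (per-guide
#' `Bernoulli(active_guide_fraction)`) by `enrichment_fold`.
#'
#' @param truth A `ground_truth` (uses `planted_repressors` and the gene
#'   universe).
#' @param guides_per_gene Guides per gene (default 10).
#' @param active_guide_fraction Fraction of a planted gene's guides that
#'   are phenotypically active (default 0.7).
#' @param active_guide_mode `"bernoulli"` (default): each guide of a
#'   planted gene is active independently with probability
#'   `active_guide_fraction`; `"fixed"`: exactly
#'   `round(active_guide_fraction * guides_per_gene)` randomly chosen
#'   guides per planted gene are active (e.g. exactly 7 of 10).
#' @param enrichment_fold Sorted-population weight multiplier for active
#'   guides of planted repressors (default 8; must be >= 1).
#' @param depth Reads per sample (default 5e6). A depth below
#'   `10 * total guides` warns (underpowered) but proceeds.
#' @param n_control_guides Total control guides, split evenly between
#'   non-targeting and safe-targeting (default 200).
#' @param dispersion Abundance dispersion (default 0.05).
#' @param seed Integer seed.
#' @param spacer_length Spacer length in bp (default 20).
#' @return List: `library` (a `guide_library`), `counts`
#'   (a `screen_counts`), `active_guides` (ids of the enriched guides).
#' @export
simulate_screen <- function(truth, guides_per_gene = 10L,
                            active_guide_fraction = 0.7,
                            enrichment_fold = 8, depth = 5e6,
                            n_control_guides = 200L, dispersion = 0.05,
                            seed = 1L, spacer_length = 20L,
                            active_guide_mode = c("bernoulli", "fixed")) {
  if (enrichment_fold < 1)
    validation_error("enrichment_fold must be >= 1")
  active_guide_mode <- match.arg(active_guide_mode)
  set.seed(seed)
  gene_ids <- names(truth$gene_classes)
  n_nt <- n_control_guides %/% 2L
  n_st <- n_control_guides - n_nt
  lib_df <- data.frame(
    guide_id = c(paste0(rep(gene_ids, each = guides_per_gene), "_sg",
                        rep(seq_len(guides_per_gene), length(gene_ids))),
                 sprintf("nt_sg%03d", seq_len(n_nt)),
                 sprintf("st_sg%03d", seq_len(n_st))),
    target = c(rep(gene_ids, each = guides_per_gene),
               rep("non_targeting", n_nt), rep("safe_targeting", n_st)),
    stringsAsFactors = FALSE)
  lib_df$spacer <- random_spacers(nrow(lib_df), spacer_length)
  lib <- guide_library(lib_df, DEFAULT_CONSTANT_PREFIX)
  if (depth < 10 * nrow(lib))
    warning("depth < 10x library size: screen underpowered")
  w <- rgamma(nrow(lib), shape = 1 / dispersion, scale = dispersion)
  planted_guide <- lib$target %in% truth$planted_repressors
  if (active_guide_mode == "bernoulli") {
    active <- planted_guide & (runif(nrow(lib)) < active_guide_fraction)
  } else {
    n_active <- round(active_guide_fraction * guides_per_gene)
    active <- logical(nrow(lib))
    for (gid in truth$planted_repressors) {
      idx <- which(lib$target == gid)
      active[sample(idx, min(n_active, length(idx)))] <- TRUE
    }
  }
  w_sorted <- w * ifelse(active, enrichment_fold, 1)
  unsorted <- as.integer(rmultinom(1, depth, w))
  sorted <- as.integer(rmultinom(1, depth, w_sorted))
  counts <- screen_counts(setNames(sorted, lib$guide_id),
                          setNames(unsorted, lib$guide_id))
  list(library = lib, counts = counts,
       active_guides = lib$guide_id[active])
}

#' Emit screen reads as FASTQ
#'
#' One read per counted guide occurrence: constant prefix + spacer, fixed
#' quality. Re-counting the emitted file with [count_guides()] reproduces
#' the counts exactly when no spacers are shared.
#'
#' @param counts Named integer vector (counts per guide id).
#' @param library A `guide_library`.
#' @param path Output FASTQ path.
#' @export
write_screen_fastq <- function(counts, library, path) {
  prefix <- attr(library, "constant_prefix")
  spacer <- setNames(library$spacer, library$guide_id)
  ids <- rep(names(counts), counts)
  seqs <- paste0(prefix, spacer[ids])
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n", qual),
             con)
  invisible(path)
}

#' Simulate a gene-effect matrix with correlated blocks
#'
#' Gaussian factor model: genes in a block with target correlation `r`
#' share a per-cell-line factor, `x = sqrt(r) * F + sqrt(1 - r) * eps`;
#' independent noise with sd `noise_sd` is added on top (attenuating the
#' realized correlation to `r / (1 + noise_sd^2)`); all other genes are
#' independent standard normals.
#'
#' @param n_genes Number of genes.
#' @param n_lines Number of cell lines.
#' @param block_spec List of blocks, each `list(genes = <ids or count>,
#'   r = <target correlation in (-1, 1)>)`. Numeric `genes` takes the
#'   first unassigned ids.
#' @param noise_sd Extra noise sd (default 0).
#' @param seed Integer seed.
#' @return Numeric matrix genes x cell lines, rownames `g1..gN`.
#' @export
simulate_effect_matrix <- function(n_genes, n_lines, block_spec = list(),
                                   noise_sd = 0, seed = 1L) {
  set.seed(seed)
  ids <- paste0("g", seq_len(n_genes))
  m <- matrix(rnorm(n_genes * n_lines), n_genes, n_lines,
              dimnames = list(ids, paste0("line", seq_len(n_lines))))
  unassigned <- ids
  for (b in block_spec) {
    if (abs(b$r) >= 1) validation_error("target correlation must be in (-1,1)")
    members <- if (is.numeric(b$genes)) {
      picked <- unassigned[seq_len(b$genes)]
      picked
    } else b$genes
    unassigned <- setdiff(unassigned, members)
    if (b$r < 0 && length(members) > 2)
      validation_error("negative target correlation only for pairs")
    f <- rnorm(n_lines)
    for (i in seq_along(members)) {
      load <- if (b$r < 0 && i == 2) -sqrt(abs(b$r)) else sqrt(abs(b$r))
      m[members[i], ] <- load * f + sqrt(1 - abs(b$r)) * rnorm(n_lines)
    }
  }
  if (noise_sd > 0)
    m <- m + matrix(rnorm(n_genes * n_lines, sd = noise_sd),
                    n_genes, n_lines)
  m
}

#' Serialize / read ground truth as JSON
#'
#' @param truth A `ground_truth` list.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$gene_classes <- as.list(x$gene_classes)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gene_classes <- unlist(x$gene_classes)
  structure(x, class = "ground_truth")
}
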