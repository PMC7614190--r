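# Build an rpm_table-like matrix directly.
rpm_mat <- function(values, samples = "s1") {
  m <- matrix(values, ncol = length(samples),
              dimnames = list(names(values), samples))
  structure(m, conditions = setNames(rep("c", length(samples)), samples))
}

test_that("coverage filter is inclusive at the threshold and two-sided", {
  kmt <- rpm_mat(c(a = 1.2, b = 1.2, c = 1.0, d = 0.9))
  k4 <- rpm_mat(c(a = 3.0, b = 0.5, c = 1.0, d = 5.0))
  got <- filter_covered_peaks(kmt, k4, min_rpm = 1)
  expect_equal(got, c("a", "c"))  # b fails K4, d fails KMT2A; c at boundary
  expect_error(filter_covered_peaks(kmt[0, , drop = FALSE], k4),
               class = "bivalentia_validation_error")
})

test_that("peak change classification: thresholds, identity and swap", {
  ctrl <- rpm_mat(c(a = 3.0, b = 0.2, c = 1.0))
  ko <- rpm_mat(c(a = 0.5, b = 1.6, c = 1.5))
  ch <- classify_peak_changes(ctrl, ko, c("a", "b", "c"))
  expect_equal(ch$category, c("reduced", "increased", "unchanged"))
  # identity: ctrl vs ctrl all unchanged
  same <- classify_peak_changes(ctrl, ctrl, c("a", "b", "c"))
  expect_true(all(same$category == "unchanged"))
  # swap exchanges reduced <-> increased exactly
  sw <- classify_peak_changes(ko, ctrl, c("a", "b", "c"))
  map <- c(reduced = "increased", increased = "reduced",
           unchanged = "unchanged")
  expect_equal(unname(map[ch$category]), sw$category)
  expect_equal(ch$delta, -sw$delta)
  # boundary |delta| exactly at threshold counts as changed
  b1 <- classify_peak_changes(rpm_mat(c(x = 2)), rpm_mat(c(x = 3)), "x")
  expect_equal(b1$category, "increased")
  expect_error(classify_peak_changes(ctrl, ko, c("a", "zz")),
               class = "bivalentia_validation_error")
})

test_that("raising delta_rpm never shrinks the unchanged set", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 30
    ids <- paste0("p", 1:n)
    ctrl <- rpm_mat(setNames(rexp(n, 1 / 5), ids))
    ko <- rpm_mat(setNames(rexp(n, 1 / 5), ids))
    lo <- classify_peak_changes(ctrl, ko, ids, delta_rpm = 0.5)
    hi <- classify_peak_changes(ctrl, ko, ids, delta_rpm = 2)
    expect_true(all(lo$peak_id[lo$category == "unchanged"] %in%
                      hi$peak_id[hi$category == "unchanged"]))
    # partition
    expect_equal(sort(lo$peak_id), sort(ids))
  }
})

test_that("gene rollup matches exhaustive enumeration of the decision rule", {
  # one gene, windows capture every peak; enumerate all category/delta
  # combinations for up to 3 peaks
  genes <- read_gene_table(write_tsv_file(data.frame(
    gene_id = "g", name = "g", chrom = "chr1", start = 5000L, end = 9000L,
    strand = "+")))
  cats <- c("increased", "reduced", "unchanged")
  deltas <- list(increased = c(1.2, 2.0), reduced = c(-1.2, -2.0),
                 unchanged = c(0.3))
  combos <- expand.grid(a = cats, b = cats, c = cats,
                        stringsAsFactors = FALSE)
  set.seed(3)
  for (i in seq_len(nrow(combos))) {
    cc <- unlist(combos[i, ])
    dd <- vapply(cc, function(ct) sample(deltas[[ct]], 1), numeric(1))
    pk <- peak_set(data.frame(
      peak_id = c("p1", "p2", "p3"), chrom = "chr1",
      start = c(4000L, 5000L, 6000L), end = c(4500L, 5500L, 6500L),
      stringsAsFactors = FALSE), "KMT2A", merge = FALSE)
    ch <- structure(data.frame(peak_id = c("p1", "p2", "p3"),
                               delta = unname(dd), category = unname(cc),
                               stringsAsFactors = FALSE),
                    class = c("peak_changes", "data.frame"))
    got <- rollup_to_genes(ch, genes, pk)
    expect_equal(got$category, oracle_rollup(cc, dd),
                 info = paste(cc, collapse = ","))
  }
  # spec's worked case: +1.2 vs -2.0 -> reduced
  ch <- structure(data.frame(peak_id = c("p1", "p2"),
                             delta = c(1.2, -2.0),
                             category = c("increased", "reduced"),
                             stringsAsFactors = FALSE),
                  class = c("peak_changes", "data.frame"))
  pk <- peak_set(data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                            start = c(4000L, 5000L), end = c(4500L, 5500L),
                            stringsAsFactors = FALSE), "KMT2A",
                 merge = FALSE)
  expect_equal(rollup_to_genes(ch, genes, pk)$category, "reduced")
  # no covered peak in window -> not_covered
  far <- read_gene_table(write_tsv_file(data.frame(
    gene_id = "g", name = "g", chrom = "chr9", start = 5000L, end = 9000L,
    strand = "+")))
  expect_equal(rollup_to_genes(ch, far, pk)$category, "not_covered")
})

test_that("group composition counts and fractions", {
  gc <- structure(data.frame(
    gene_id = c("A", "B", "C", "D"),
    category = c("increased", "increased", "increased", "reduced"),
    stringsAsFactors = FALSE), class = c("gene_changes", "data.frame"))
  calls <- structure(data.frame(
    gene_id = c("A", "B", "C", "D"),
    state = c("bivalent", "bivalent", "k4_only", "k4_only"),
    stringsAsFactors = FALSE), class = c("bivalency_calls", "data.frame"))
  comp <- group_composition(gc, calls)
  inc <- comp[comp$group == "increased", ]
  expect_equal(inc$n_genes, 3)
  expect_equal(inc$fraction_bivalent, 2 / 3)
  # no empty groups emitted
  expect_false("not_covered" %in% comp$group)
})

test_that("mark shift summary recovers per-category medians", {
  gc <- structure(data.frame(gene_id = paste0("g", 1:6),
                             category = rep(c("increased", "reduced"),
                                            each = 3),
                             stringsAsFactors = FALSE),
                  class = c("gene_changes", "data.frame"))
  lfc <- list(H3K4me3 = setNames(c(1, 1, 1, -2, -2, -2), paste0("g", 1:6)))
  s <- mark_shift_summary(gc, lfc)
  expect_equal(s$median[s$group == "increased"], 1)
  expect_equal(s$median[s$group == "reduced"], -2)
  expect_error(mark_shift_summary(gc, list(a = lfc[[1]],
                                           b = lfc[[1]][1:3])),
               class = "bivalentia_validation_error")
})

test_that("reduced group has higher baseline Menin than increased group", {
  g <- make_genome(n_genes = 400, seed = 5)
  ctrl <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e6,
                             seed = 51)
  ko <- simulate_mark_data(g$genes, g$truth, "knockout", depth = 1e6,
                           seed = 52)
  cov <- filter_covered_peaks(cbind(ctrl$rpm$KMT2A, ko$rpm$KMT2A),
                              cbind(ctrl$rpm$H3K4me3, ko$rpm$H3K4me3))
  ch <- classify_peak_changes(ctrl$rpm$KMT2A, ko$rpm$KMT2A, cov)
  gcat <- rollup_to_genes(ch, g$genes, ctrl$universe$KMT2A)
  menin <- rowMeans(ctrl$rpm$Menin)
  baseline <- function(cat) {
    ids <- paste0(gcat$gene_id[gcat$category == cat], "_pk")
    v <- menin[ids]            # genes without a Menin peak have 0 signal
    v[is.na(v)] <- 0
    mean(v)
  }
  expect_gt(baseline("reduced"), baseline("increased"))
})
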