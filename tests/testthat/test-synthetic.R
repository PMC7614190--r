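test_that("make_genome: determinism, fractions, layout and errors", {
  a <- make_genome(n_genes = 100, seed = 7)
  b <- make_genome(n_genes = 100, seed = 7)
  expect_identical(a, b)
  c <- make_genome(n_genes = 100, seed = 8)
  expect_false(identical(a$truth$gene_classes, c$truth$gene_classes))
  # all-active world
  all_active <- make_genome(
    n_genes = 50, class_fractions = c(active = 1, bivalent = 0,
                                      repressed = 0, unmarked = 0),
    gain_fraction = 0, seed = 1)
  expect_true(all(all_active$truth$gene_classes == "active"))
  expect_error(make_genome(n_genes = 10, spacing = 1000, seed = 1),
               class = "bivalentia_validation_error")
  expect_error(make_genome(class_fractions = c(active = 0.5,
                                               bivalent = 0.2,
                                               repressed = 0.2,
                                               unmarked = 0.2)),
               "sum to 1")
  # TSS windows never overlap by construction
  w <- tss_window(a$genes)
  for (ch in unique(w$chrom)) {
    ws <- w[w$chrom == ch, ]
    ws <- ws[order(ws$start), ]
    if (nrow(ws) > 1)
      expect_true(all(ws$start[-1] >= ws$end[-nrow(ws)]))
  }
  # designed redistribution sets respect their source classes
  cls <- a$truth$gene_classes
  expect_true(all(cls[a$truth$redistributed_loss] == "active"))
  expect_true(all(cls[a$truth$redistributed_gain] %in%
                    c("bivalent", "repressed")))
})

test_that("simulate_mark_data is deterministic and condition-aware", {
  g <- make_genome(n_genes = 60, seed = 3)
  s1 <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e5,
                           seed = 4)
  s2 <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e5,
                           seed = 4)
  expect_identical(s1, s2)
  expect_error(simulate_mark_data(g$genes, g$truth, "control",
                                  depth = 100),
               class = "bivalentia_validation_error")
  # unmarked genes carry no peaks in any assay
  unmarked <- names(g$truth$gene_classes)[g$truth$gene_classes == "unmarked"]
  for (assay in names(s1$peaks))
    expect_length(intersect(paste0(unmarked, "_pk"),
                            s1$peaks[[assay]]$peak_id), 0)
})

test_that("null knockout (all fold-effects 1) is distributionally control", {
  g <- make_genome(n_genes = 80, seed = 21)
  null_eff <- list(kmt2a_loss_fold = 1, kmt2a_gain_fold = 1,
                   k4_gain_fold = 1, k27_gain_fold = 1,
                   suz12_gain_fold = 1, kmt2a_poised_rpm = 3,
                   k4_acquired_rpm = 0)
  ps <- vapply(1:10, function(s) {
    ctrl <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e5,
                               seed = s, effects = null_eff)
    ko <- simulate_mark_data(g$genes, g$truth, "knockout", depth = 1e5,
                             seed = s + 100, effects = null_eff)
    suppressWarnings(wilcox.test(as.numeric(ctrl$rpm$KMT2A),
                                 as.numeric(ko$rpm$KMT2A))$p.value)
  }, numeric(1))
  expect_gt(min(ps), 0.01)
})

test_that("mean counts track the configured class means (LLN check)", {
  g <- make_genome(n_genes = 400, seed = 9)
  sim <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e6,
                            seed = 10, n_replicates = 2)
  active_nongain <- setdiff(
    names(g$truth$gene_classes)[g$truth$gene_classes == "active"],
    g$truth$redistributed_gain)
  k4 <- rowMeans(sim$rpm$H3K4me3)[paste0(active_nongain, "_pk")]
  # configured active-class H3K4me3 mean is 30 RPM; mean over ~160 peaks
  # with NB noise should land within 3 standard errors
  se <- sqrt((30 + 0.05 * 30^2) / (2 * length(k4)))
  expect_lt(abs(mean(k4) - 30), 3 * se)
})

test_that("planted gene_lfc at active genes recovers the 4-fold loss", {
  g <- make_genome(n_genes = 200, seed = 33, loss_fraction = 1)
  ctrl <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e5,
                             seed = 34)
  ko <- simulate_mark_data(g$genes, g$truth, "knockout", depth = 1e5,
                           seed = 35)
  sig_c <- gene_signal(ctrl$rpm$KMT2A, ctrl$universe$KMT2A, g$genes)
  sig_k <- gene_signal(ko$rpm$KMT2A, ko$universe$KMT2A, g$genes)
  lfc <- gene_lfc(sig_k, sig_c)
  active <- names(g$truth$gene_classes)[g$truth$gene_classes == "active"]
  expect_lt(median(unclass(lfc)[active]), -1)
})

test_that("fragments realize counts and pass the fragment counter", {
  g <- make_genome(n_genes = 30, seed = 12)
  sim <- simulate_mark_data(g$genes, g$truth, "control", depth = 1e4,
                            seed = 13, n_replicates = 1)
  sc <- sim$counts$H3K4me3[[1]]
  frags <- fragments_from_counts(sc, sim$universe$H3K4me3, seed = 14)
  expect_equal(nrow(frags), sc$library_size)
  redone <- count_fragments_in_peaks(frags, sim$universe$H3K4me3,
                                     sc$library_size)
  expect_equal(redone$counts, sc$counts)
})

test_that("screen simulation: determinism and null exchangeability", {
  g <- make_genome(n_genes = 40, seed = 15)
  s1 <- simulate_screen(g$truth, depth = 1e5, n_control_guides = 20,
                        seed = 16)
  s2 <- simulate_screen(g$truth, depth = 1e5, n_control_guides = 20,
                        seed = 16)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$library, s2$library)
  expect_error(simulate_screen(g$truth, enrichment_fold = 0.5),
               class = "bivalentia_validation_error")
  expect_warning(simulate_screen(g$truth, depth = 100, seed = 1),
                 "underpowered")
})

test_that("truth JSON round-trips through write_truth/read_truth", {
  g <- make_genome(n_genes = 25, seed = 18)
  f <- tempfile(fileext = ".json")
  write_truth(g$truth, f)
  back <- read_truth(f)
  expect_equal(back$gene_classes, g$truth$gene_classes)
  expect_equal(back$redistributed_gain, g$truth$redistributed_gain)
  expect_equal(back$planted_repressors, g$truth$planted_repressors)
})

test_that("effect matrix generator hits target correlations and limits", {
  m <- simulate_effect_matrix(20, 500,
                              block_spec = list(list(genes = 5, r = 0.9)),
                              seed = 44)
  rs <- cor(t(m[paste0("g", 1:5), ]))
  offdiag <- rs[upper.tri(rs)]
  expect_true(all(abs(offdiag - 0.9) < 0.05))
  # heavy noise kills correlation
  m2 <- simulate_effect_matrix(10, 500,
                               block_spec = list(list(genes = 5, r = 0.9)),
                               noise_sd = 20, seed = 44)
  rs2 <- cor(t(m2[paste0("g", 1:5), ]))
  expect_lt(max(abs(rs2[upper.tri(rs2)])), 0.2)
  expect_identical(simulate_effect_matrix(10, 20, seed = 5),
                   simulate_effect_matrix(10, 20, seed = 5))
})
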