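# small configuration used across generator tests
small_cfg <- function(seed = 3, ...) {
  truth_config(seed = seed, n_genes = 60,
               chrom_sizes = c(chr1 = 3e6, chr2 = 3e6, chrX = 1e6), ...)
}

test_that("generator outputs are byte-identical across reruns", {
  cfg <- small_cfg()
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
})

test_that("synthetic genes fit their chromosomes and never overlap", {
  cfg <- small_cfg(seed = 4)
  genome <- simulate_genome(cfg)
  g <- genome$gm$genes
  expect_true(all(g$start >= 1))
  expect_true(all(g$end <= genome$chrom_sizes[g$chrom]))
  for (chrom in unique(g$chrom)) {
    sub <- g[g$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
  }
  # exons inside gene bodies; sex chromosome populated
  ex <- genome$gm$exons
  gi <- match(ex$gene_id, g$gene_id)
  expect_true(all(start(ex) >= g$start[gi] & end(ex) <= g$end[gi]))
  expect_true(any(g$chrom == "chrX"))
  # zero genes is a valid annotation
  empty <- simulate_genome(truth_config(seed = 1, n_genes = 0))
  expect_equal(nrow(empty$gm$genes), 0)
})

test_that("planted gene-body methylation closes the loop with the classifier", {
  cfg <- small_cfg(seed = 5)
  genome <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, genome)
  peaks <- simulate_peaks_and_reads(cfg, genome, truth)
  cov_ctrl <- combine_replicate_coverage(
    gene_body_coverage(peaks$k79_reads$ctrl$rep1, genome$gm),
    gene_body_coverage(peaks$k79_reads$ctrl$rep2, genome$gm))
  gb_ctrl <- classify_gb_k79(cov_ctrl$read_count,
                             cov_ctrl$fraction_covered)
  expect_equal(gb_ctrl, truth$genes$gb_pos)
  cov_ko <- combine_replicate_coverage(
    gene_body_coverage(peaks$k79_reads$ko$rep1, genome$gm),
    gene_body_coverage(peaks$k79_reads$ko$rep2, genome$gm))
  gb_ko <- classify_gb_k79(cov_ko$read_count, cov_ko$fraction_covered)
  expect_false(any(gb_ko))
})

test_that("planted REs carry the promised differential-signal structure", {
  cfg <- small_cfg(seed = 6)
  genome <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, genome)
  peaks <- simulate_peaks_and_reads(cfg, genome, truth)
  res <- truth$res
  gr <- GRanges(res$chrom, IRanges(res$start, res$end))
  f79 <- differential_overlap_fraction(gr, peaks$diff_k79)
  k79_types <- res$type %in% c("k79_activating", "k79_silencing")
  expect_true(all(f79[k79_types] >= 0.10))
  # plain REs may graze a gene-body differential region but the planted
  # flag logic must recover the planted K79-REs
  flags <- flag_res(gr, peaks$diff_k79, peaks$diff_k27_up,
                    peaks$diff_k27_down)
  expect_true(all(flags$is_k79_re[k79_types]))
  # differential K27 intervals lie inside peak space
  expect_true(all(overlapsAny(peaks$diff_k27_up, peaks$k27_peaks_ko)))
  expect_true(all(overlapsAny(peaks$diff_k27_down,
                              peaks$k27_peaks_ctrl)))
  # knockout-only REs appear in the knockout peaks only
  ko_only <- res$ko_only
  expect_false(any(res$re_id[ko_only] %in% peaks$k27_peaks_ctrl$name))
  expect_true(all(res$re_id[ko_only] %in% peaks$k27_peaks_ko$name))
})

test_that("Hi-C generator is symmetric with boosted planted loops", {
  cfg <- small_cfg(seed = 7)
  genome <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, genome)
  hic <- simulate_hic(cfg, genome, truth)
  for (cm in hic) {
    expect_true(Matrix::isSymmetric(cm$counts))
  }
  expect_false("chrX" %in% names(hic))

  # Monte-Carlo check of the loop boost at one planted pair: the mean
  # count approaches boost * mu0 / (d+1)^decay
  res <- truth$res
  looped <- res[res$type == "k79_activating", ][1, ]
  g <- genome$gm$genes
  tssb <- (g$tss[match(looped$gene_id, g$gene_id)] - 1) %/%
    cfg$resolution
  enhb <- ((looped$start - 1 + looped$end) %/% 2) %/% cfg$resolution
  d <- abs(enhb - tssb)
  mu_expected <- cfg$loop_boost * cfg$hic_mu0 / (d + 1)^cfg$hic_decay
  vals <- vapply(1:60, function(k) {
    h <- simulate_hic(truth_config(seed = k + 100, n_genes = 60,
                                   chrom_sizes = cfg$chrom_sizes),
                      genome, truth)
    h[[looped$chrom]]$counts[enhb + 1, tssb + 1]
  }, numeric(1))
  se <- sqrt(mu_expected / 60)
  expect_lt(abs(mean(vals) - mu_expected), 4 * se)
})

test_that("expression generator powers planted classes and controls nulls", {
  cfg <- truth_config(seed = 8, n_genes = 200,
                      chrom_sizes = c(chr1 = 8e6, chr2 = 8e6))
  genome <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, genome)
  expr <- assign_de_status(simulate_expression(cfg, genome, truth))
  cls <- truth$genes$class
  down_called <- expr$de_status == "down"
  strong <- cls == "gb_re_down"
  expect_gt(mean(down_called[strong]), 0.9)
  null_de <- expr$de_status[cls == "none"] %in% c("down", "up")
  expect_lt(mean(null_de), 0.1)
})

test_that("motif generator plants recoverable sites", {
  cfg <- small_cfg(seed = 9)
  genome <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, genome)
  seqs <- simulate_re_sequences(cfg, truth)
  expect_equal(length(seqs$seqs), nrow(truth$res))
  expect_equal(unname(Biostrings::width(seqs$seqs)),
               truth$res$end - truth$res$start + 1L)
  sil <- truth$res$type == "k79_silencing"
  act <- truth$res$type == "k79_activating"
  res <- motif_enrichment(seqs$pwms, as.character(seqs$seqs[act]),
                          as.character(seqs$seqs[sil]))
  best <- res$tf[order(res$p_adj_silencing)][1]
  expect_equal(best, seqs$planted_tf)
})
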