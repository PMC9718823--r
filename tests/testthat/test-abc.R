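test_that("candidate windows are 5 Mb, midpoint-based, half-open", {
  gene <- list(gene_id = "g", chrom = "chr1", tss = 10000001L)
  enh <- enh_granges(c(7399901L, 7499901L, 12499801L, 12499901L),
                     rep(200L, 4), rep(1, 4))
  # midpoints (0-based): 7400000, 7500000, 12499900, 12500000
  keep <- candidate_enhancers(gene, enh, window = 5e6)
  mid0 <- (start(keep) - 1 + end(keep)) %/% 2
  expect_equal(mid0, c(7500000, 12499900)) # left edge in, right edge out

  gx <- list(gene_id = "gx", chrom = "chrX", tss = 1000L)
  expect_warning(none <- candidate_enhancers(gx, enh), "excluded")
  expect_length(none, 0)
})

test_that("gene-specific activity follows the contact-share formula", {
  # enhancer contacts only this gene
  expect_equal(gene_specific_activity(5, 4, c(4)), 5)
  # contacts split evenly with one other gene
  expect_equal(gene_specific_activity(10, 2, c(2, 2)), 5)
  # all contacts zero
  expect_equal(gene_specific_activity(3, 0, c(0, 0)), 0)
  expect_error(gene_specific_activity(3, 1, c(2, 2)), "must be among")
})

test_that("per-gene score normalization", {
  expect_equal(abc_normalize(c(10, 20)), c(1 / 3, 2 / 3))
  expect_equal(abc_normalize(c(7)), 1)
  expect_equal(abc_normalize(c(0, 0)), c(0, 0))
})

test_that("hand-worked two-enhancer fixture gives scores 1/3 and 2/3", {
  # genes g and h in adjacent bins; enhancer e1 (A=10) contacts both
  # with C=2; enhancer e2 (A=5) contacts only g with C=4
  gm <- abc_gene_models(c(g = 100001L, h = 200001L), glen = 5000L)
  # TSS bins (0-based, 5 kb): g -> 20, h -> 40
  enh <- enh_granges(c(300001L, 400001L), c(200L, 200L), c(10, 5))
  # enhancer midpoint bins: e1 -> 60, e2 -> 80
  cm <- stub_contacts(list(c(60, 20, 2), c(60, 40, 2), c(80, 20, 4)),
                      n_bins = 100)
  res <- abc_interactions(gm, enh, list(chr1 = cm))
  g_rows <- res[res$gene_id == "g", ]
  g_rows <- g_rows[order(g_rows$start), ]
  # Eq. 2: A_e1,g = 10 * 2/(2+2) = 5 ; A_e2,g = 5 * 4/4 = 5
  expect_equal(g_rows$gene_specific_activity, c(5, 5))
  # Eq. 1: weights 10 and 20 -> scores 1/3, 2/3
  expect_equal(g_rows$abc_score, c(1 / 3, 2 / 3))
  # h only reachable via e1 -> score 1
  h_rows <- res[res$gene_id == "h", ]
  expect_equal(h_rows$abc_score[h_rows$contact > 0], 1)
})

test_that("vectorized scores match the two-loop brute-force oracle", {
  set.seed(21)
  n_genes <- 6; n_enh <- 12; n_bins <- 400
  tss <- sort(sample(seq(60001L, 1800001L, by = 20000L), n_genes))
  names(tss) <- sprintf("g%d", seq_len(n_genes))
  gm <- abc_gene_models(tss, glen = 8000L)
  es <- sort(sample(seq(10001L, 1950001L, by = 7001L), n_enh))
  enh <- enh_granges(es, rep(300L, n_enh), rlnorm(n_enh))

  m <- matrix(0, n_bins, n_bins)
  set.seed(22)
  vals <- matrix(rpois(n_bins * n_bins, 0.8), n_bins)
  m <- (vals + t(vals)) / 2
  cm <- contact_matrix_from_dense(m, "chr1", 5000)
  cm$balanced <- cm$counts
  cm$scaling <- rep(1, n_bins)

  res <- abc_interactions(gm, enh, list(chr1 = cm), window = 1e6)

  mid0 <- (start(enh) - 1 + end(enh)) %/% 2
  e_df <- data.frame(id = interval_id(enh),
                     activity = enh$signal_value,
                     bin = mid0 %/% 5000)
  g_df <- data.frame(id = names(tss), bin = (tss - 1) %/% 5000)
  in_window <- outer(seq_len(n_enh), seq_len(n_genes),
                     Vectorize(function(e, g) {
                       mid0[e] >= tss[g] - 1 - 5e5 &&
                         mid0[e] < tss[g] - 1 + 5e5
                     }))
  want <- oracle_abc(e_df, g_df,
                     function(a, b) m[a + 1, b + 1], in_window)
  for (r in seq_len(nrow(res))) {
    expect_equal(res$abc_score[r],
                 want[res$re_id[r], res$gene_id[r]])
  }
  expect_equal(nrow(res), sum(in_window))
})

test_that("scores are normalized per gene and scale-invariant", {
  set.seed(33)
  tss <- setNames(sort(sample(seq(60001L, 900001L, by = 30000L), 5)),
                  sprintf("g%d", 1:5))
  gm <- abc_gene_models(tss, glen = 6000L)
  enh <- enh_granges(sort(sample(seq(5001L, 950001L, by = 9001L), 15)),
                     rep(400L, 15), rlnorm(15))
  v <- matrix(rpois(200 * 200, 0.5), 200)
  m <- v + t(v)
  mk <- function(mat, act_scale = 1) {
    cm <- contact_matrix_from_dense(mat, "chr1", 5000)
    cm$balanced <- cm$counts
    cm$scaling <- rep(1, 200)
    e2 <- enh
    e2$signal_value <- enh$signal_value * act_scale
    abc_interactions(gm, e2, list(chr1 = cm), window = 1e6)
  }
  res <- mk(m)
  # per-gene sums are 1 whenever any candidate has positive contact
  sums <- tapply(res$abc_score, res$gene_id, sum)
  has_contact <- tapply(res$contact, res$gene_id, function(x) any(x > 0))
  expect_true(all(abs(sums[has_contact] - 1) < 1e-9))
  # doubling activities or contacts leaves scores unchanged
  expect_equal(mk(m, act_scale = 2)$abc_score, res$abc_score,
               tolerance = 1e-12)
  expect_equal(mk(2 * m)$abc_score, res$abc_score, tolerance = 1e-12)
})

test_that("interaction filtering keeps the 0.02 boundary inclusive", {
  df <- data.frame(abc_score = c(0.02, 0.0199, 0.5, 0))
  kept <- filter_interactions(df)
  expect_equal(kept$abc_score, c(0.02, 0.5))
  expect_equal(nrow(filter_interactions(df[0, , drop = FALSE])), 0)
})

test_that("sex-chromosome genes are excluded from scoring", {
  lines <- c(gtf_line("chrX", "gene", 100001L, 110000L, "+", "gx"),
             gtf_line("chrX", "exon", 100001L, 110000L, "+", "gx"),
             gtf_line("chr1", "gene", 100001L, 110000L, "+", "ga"),
             gtf_line("chr1", "exon", 100001L, 110000L, "+", "ga"))
  gm <- read_gtf(toy_gtf(lines))
  enh <- suppressWarnings(c(enh_granges(120001L, 200L, 3, "chr1"),
                            enh_granges(120001L, 200L, 3, "chrX")))
  cm <- stub_contacts(list(c(20, 24, 2)), n_bins = 60)
  expect_warning(res <- abc_interactions(gm, enh, list(chr1 = cm)),
                 "excluded")
  expect_true(all(res$gene_id == "ga"))
})
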