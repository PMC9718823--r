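test_that("differential overlap fraction uses the union of peaks", {
  re <- GRanges("chr1", IRanges(1001, 2000)) # 1000 bp
  # exactly 10% covered
  expect_equal(differential_overlap_fraction(
    re, GRanges("chr1", IRanges(1001, 1100))), 0.10)
  # overlapping diff peaks: union not sum
  two <- GRanges("chr1", c(IRanges(1001, 1100), IRanges(1051, 1150)))
  expect_equal(differential_overlap_fraction(re, two), 0.15)
  # no peaks
  expect_equal(differential_overlap_fraction(re, GRanges()), 0)
  # invariant to splitting peaks into abutting fragments
  whole <- GRanges("chr1", IRanges(1201, 1400))
  split2 <- GRanges("chr1", c(IRanges(1201, 1300), IRanges(1301, 1400)))
  expect_equal(differential_overlap_fraction(re, whole),
               differential_overlap_fraction(re, split2))
})

test_that("RE flagging applies the 10% rule with down-tie-break", {
  res <- GRanges("chr1", IRanges(c(1001, 3001, 5001, 7001),
                                 c(2000, 4000, 6000, 8000)))
  diff_k79 <- GRanges("chr1", IRanges(1001, 1500)) # 50% of RE1
  diff_up <- GRanges("chr1", c(IRanges(3001, 3100),  # 10% of RE2
                               IRanges(7001, 7200))) # 20% of RE4
  diff_dn <- GRanges("chr1", IRanges(7001, 7200))    # 20% of RE4 (tie)
  flags <- flag_res(res, diff_k79, diff_up, diff_dn)
  expect_equal(flags$is_k79_re, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags$k27_diff, c("none", "up", "none", "down"))
})

test_that("differential-K27 mapping follows the control-first rule", {
  # 4-gene toy: RE1 linked to A,B in ctrl; RE2 only in ko linked to C;
  # RE3 in both conditions but linked to D only in ko
  re_flags <- data.frame(
    re_id = c("chr1:1-100", "chr1:201-300", "chr1:401-500"),
    chrom = "chr1", start = c(1L, 201L, 401L),
    end = c(100L, 300L, 500L),
    is_k79_re = FALSE,
    k27_diff = c("down", "up", "up"),
    overlaps_promoter = FALSE, stringsAsFactors = FALSE)
  ctrl <- data.frame(re_id = c("chr1:1-100", "chr1:1-100",
                               "chr1:401-500"),
                     gene_id = c("A", "B", "E"),
                     stringsAsFactors = FALSE)
  ko <- data.frame(re_id = c("chr1:201-300", "chr1:401-500"),
                   gene_id = c("C", "D"), stringsAsFactors = FALSE)
  map <- map_diff_k27_to_genes(re_flags, ctrl, ko)
  expect_setequal(map$gene_id, c("A", "B", "C", "E"))
  expect_false("D" %in% map$gene_id) # ctrl-linked RE: ko-only link ignored
  expect_equal(map$n_diff_k27_res[map$gene_id == "A"], 1L)
})

test_that("gene categorization counts sum per DE direction", {
  profiles <- data.frame(
    gene_id = sprintf("g%d", 1:8),
    de_status = c("down", "down", "down", "up", "up", "unchanged",
                  "not_expressed", "down"),
    log2fc = c(-1, -2, -1.5, 1, 2, 0, 0, -0.8),
    gb_k79 = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    gb_fraction = c(0.8, 0.5, 0, 0, 0, 0.4, 0, 0.9),
    n_k79_res = c(3L, 0L, 2L, 1L, 0L, 0L, 0L, 2L),
    n_diff_k27_res = c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  profiles$category <- paste0(
    "GB", ifelse(profiles$gb_k79, "+", "-"),
    "RE", ifelse(profiles$n_k79_res > 0, "+", "-"),
    "diffK27", ifelse(profiles$n_diff_k27_res > 0, "+", "-"))
  up <- categorize_genes(profiles)
  expect_equal(sum(up$n[up$de_status == "down"]), 4)
  expect_equal(sum(up$n[up$de_status == "up"]), 2)
  expect_equal(sum(up$percent[up$de_status == "down"]), 100)
  expect_equal(sum(up$percent[up$de_status == "up"]), 100)
  # planted categories recovered
  expect_equal(up$n[up$de_status == "down" &
                      up$category == "GB+RE+diffK27+"], 1)
  g2 <- categorize_genes(profiles, include_diff_k27 = FALSE)
  expect_equal(g2$n[g2$de_status == "down" & g2$category == "GB+RE+"], 2)
})

test_that("KS statistic matches the ECDF-grid oracle, p is asymptotic", {
  expect_equal(ks_two_sample(c(1, 2), c(1, 2))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)

  # all sample-size configurations with total n <= 8, values in {1..6}
  set.seed(17)
  for (na in 1:6) {
    for (nb in 1:(8 - na)) {
      if (nb < 1) next
      for (rep in 1:20) {
        x <- sample(1:6, na, replace = TRUE)
        y <- sample(1:6, nb, replace = TRUE)
        got <- ks_two_sample(x, y)
        expect_equal(got$statistic, oracle_ks_d(x, y))
        # invariance under common monotone transform
        got2 <- ks_two_sample(exp(x), exp(y))
        expect_equal(got2$statistic, got$statistic)
        expect_true(got$statistic >= 0 && got$statistic <= 1)
      }
    }
  }

  # asymptotic p agrees with the reference implementation on
  # continuous data
  set.seed(18)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  got <- ks_two_sample(x, y)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-8)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("stratified analysis bins half-open and detects planted shifts", {
  set.seed(8)
  n <- 420
  prof <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    de_status = "unchanged",
    log2fc = rnorm(n, 0, 0.3),
    gb_k79 = rep(c(TRUE, FALSE), length.out = n),
    gb_fraction = runif(n),
    n_k79_res = sample(0:8, n, replace = TRUE),
    n_diff_k27_res = 0L,
    category = "GB-RE-diffK27-", stringsAsFactors = FALSE)
  # plant a -0.5 shift in the >=6-RE stratum
  shift <- prof$n_k79_res >= 6
  prof$log2fc[shift] <- prof$log2fc[shift] - 0.5
  out <- stratified_cdf_analysis(prof)
  row <- out$ks[out$ks$grouping == "k79_re_count" &
                  out$ks$stratum_a == "k79_re_0" &
                  out$ks$stratum_b == "k79_re_ge_6", ]
  expect_lt(row$p_value, 0.01)

  # fraction boundary: exactly 1/3 goes to the middle stratum
  prof2 <- prof[1:12, ]
  prof2$gb_fraction <- c(1 / 3, rep(0.1, 5), rep(0.9, 6))
  out2 <- suppressWarnings(stratified_cdf_analysis(prof2))
  expect_equal(sum(names(out2$strata) == "gb_frac_1_3_to_2_3"), 1)
  expect_length(out2$strata[["gb_frac_1_3_to_2_3"]], 1)

  # same-distribution strata: D stays small
  null_row <- out$ks[out$ks$grouping == "k79_re_count" &
                       out$ks$stratum_a == "k79_re_0" &
                       out$ks$stratum_b == "k79_re_1_5", ]
  expect_lt(null_row$D, 0.35)
})

test_that("odds-ratio reconstruction from marginal counts", {
  res <- diff_peak_overlap_odds(2017, 337, 0.69, 0.99)
  expect_equal(sum(res$table[, "k27_up"]), 2017)
  expect_equal(sum(res$table[, "k27_down"]), 337)
  expect_equal(signif(res$odds_ratio, 1), 0.004)
})
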