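# in-code fixtures shared across test files

# write a small GTF and parse it back; coordinates below are 1-based
# closed (GTF convention)
toy_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start, end, strand, gene_id) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
          chrom, type, start, end, strand, gene_id)
}

# a 3-gene toy annotation on one 10 kb chromosome used by the feature-map
# tests: a + gene, a - gene, and a gene overlapping the first
toy_three_gene_models <- function() {
  lines <- c(
    gtf_line("chrT", "gene", 1001, 3000, "+", "gA"),
    gtf_line("chrT", "exon", 1001, 1400, "+", "gA"),
    gtf_line("chrT", "UTR", 1001, 1100, "+", "gA"),
    gtf_line("chrT", "exon", 2001, 2400, "+", "gA"),
    gtf_line("chrT", "gene", 5001, 7000, "-", "gB"),
    gtf_line("chrT", "exon", 5001, 5400, "-", "gB"),
    gtf_line("chrT", "exon", 6601, 7000, "-", "gB"),
    gtf_line("chrT", "UTR", 6901, 7000, "-", "gB"),
    gtf_line("chrT", "gene", 2201, 4000, "+", "gC"),
    gtf_line("chrT", "exon", 2201, 2600, "+", "gC"),
    gtf_line("chrT", "exon", 3801, 4000, "+", "gC"))
  read_gtf(toy_gtf(lines))
}

toy_chrom_sizes <- c(chrT = 10000L)

# small dense symmetric positive matrix for balancing tests
random_symmetric_matrix <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.1, 2), n, n)
  (a + t(a)) / 2
}

# gene models with explicit TSS positions on one chromosome
abc_gene_models <- function(tss_positions, chrom = "chr1",
                            glen = 10000L) {
  lines <- unlist(lapply(seq_along(tss_positions), function(i) {
    id <- names(tss_positions)[i]
    s <- tss_positions[[i]]
    c(gtf_line(chrom, "gene", s, s + glen - 1L, "+", id),
      gtf_line(chrom, "exon", s, s + glen - 1L, "+", id))
  }))
  read_gtf(toy_gtf(lines))
}

enh_granges <- function(starts, widths, signal, chrom = "chr1") {
  GRanges(chrom, IRanges(starts, starts + widths - 1L),
          signal_value = signal)
}

# balanced matrix stub with prescribed contact values (0-based bins)
stub_contacts <- function(entries, n_bins, chrom = "chr1", res = 5000) {
  m <- matrix(0, n_bins, n_bins)
  for (e in entries) {
    m[e[1] + 1, e[2] + 1] <- e[3]
    m[e[2] + 1, e[1] + 1] <- e[3]
  }
  cm <- contact_matrix_from_dense(m, chrom, res)
  cm$balanced <- cm$counts
  cm$scaling <- rep(1, n_bins)
  cm
}
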