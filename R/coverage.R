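#' Per-gene read coverage of the gene body
#'
#' For each gene, counts the reads (intervals) overlapping its gene body
#' by at least 1 bp and the fraction of gene-body bases with non-zero
#' coverage.
#'
#' @param reads `GRanges` of read intervals (one condition, one replicate,
#'   or a pooled set).
#' @param gm a `gene_models` object.
#' @return data.frame with `gene_id`, `read_count`, `fraction_covered`.
#' @export
gene_body_coverage <- function(reads, gm) {
  stopifnot(inherits(gm, "gene_models"))
  bodies <- gene_bodies(gm)
  if (any(width(bodies) == 0)) {
    stop("zero-length gene body for: ",
         paste(bodies$gene_id[width(bodies) == 0], collapse = ", "))
  }
  reads <- unstrand(reads)
  counts <- countOverlaps(bodies, reads, ignore.strand = TRUE)
  red <- reduce(reads)
  ov <- findOverlaps(bodies, red, ignore.strand = TRUE)
  covered <- numeric(length(bodies))
  if (length(ov) > 0) {
    w <- as.numeric(width(pintersect(bodies[queryHits(ov)],
                                     red[subjectHits(ov)])))
    agg <- rowsum(w, queryHits(ov))
    covered[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(gene_id = bodies$gene_id,
             read_count = as.integer(counts),
             fraction_covered = covered / as.numeric(width(bodies)),
             stringsAsFactors = FALSE)
}

#' Combine gene-body coverage across replicates
#'
#' Read counts are summed over replicates and the covered fraction is the
#' mean over replicates.
#'
#' @param ... data.frames from [gene_body_coverage()], one per replicate,
#'   with identical gene order.
#' @return data.frame with `gene_id`, `read_count` (sum),
#'   `fraction_covered` (mean).
#' @export
combine_replicate_coverage <- function(...) {
  reps <- list(...)
  stopifnot(length(reps) >= 1)
  ids <- reps[[1]]$gene_id
  for (r in reps) stopifnot(identical(r$gene_id, ids))
  data.frame(
    gene_id = ids,
    read_count = as.integer(Reduce(`+`, lapply(reps, `[[`, "read_count"))),
    fraction_covered = Reduce(`+`, lapply(reps, `[[`, "fraction_covered")) /
      length(reps),
    stringsAsFactors = FALSE)
}

#' Classify genes as gene-body methylated
#'
#' A gene carries gene-body H3K79me2 when its body has at least
#' `min_reads` overlapping reads and at least `min_fraction` of its bases
#' covered, both thresholds inclusive.
#'
#' @param read_count integer vector of gene-body read counts.
#' @param fraction_covered numeric vector of covered fractions in `[0,1]`.
#' @param min_reads read-count threshold (default 50).
#' @param min_fraction covered-fraction threshold (default 0.2).
#' @return logical vector.
#' @export
classify_gb_k79 <- function(read_count, fraction_covered,
                            min_reads = 50, min_fraction = 0.2) {
  read_count >= min_reads & fraction_covered >= min_fraction
}

#' Metagene profile over scaled gene bodies
#'
#' Averages a per-base signal over genes after linearly rescaling each
#' gene body to `body` bp, with unscaled flanks of `flank` bp on either
#' side, oriented 5'->3' (minus-strand genes are reversed). Genes with
#' zero total signal over the profiled region are skipped, as are genes
#' whose body is shorter than one bin (with a warning).
#'
#' @param signal a per-base signal: an `RleList` (e.g. from
#'   [GenomicRanges::coverage()]) or a named list of numeric vectors, one
#'   per chromosome.
#' @param gm a `gene_models` object.
#' @param flank flank length in bp (default 2000).
#' @param body scaled body length in bp (default 5000).
#' @param bin bin size in bp (default 20).
#' @return data.frame with `bin` (index), `position` (bin center relative
#'   to the scaled TSS at 0), `region` (upstream/body/downstream) and
#'   `mean_signal`; attribute `n_genes` gives the number of genes
#'   averaged.
#' @export
metagene_profile <- function(signal, gm, flank = 2000, body = 5000,
                             bin = 20) {
  stopifnot(inherits(gm, "gene_models"), nrow(gm$genes) >= 1)
  stopifnot(flank %% bin == 0, body %% bin == 0)
  g <- gm$genes
  n_flank_bins <- flank %/% bin
  n_body_bins <- body %/% bin
  n_bins <- 2L * n_flank_bins + n_body_bins

  get_base <- function(chrom, from, to) {
    # per-base values with zero-padding outside the chromosome
    v <- numeric(to - from + 1)
    track <- signal[[chrom]]
    if (is.null(track)) return(v)
    len <- length(track)
    lo <- max(from, 1L); hi <- min(to, len)
    if (lo <= hi) {
      seg <- track[lo:hi]
      if (inherits(seg, "Rle")) seg <- as.numeric(seg)
      v[(lo - from + 1):(hi - from + 1)] <- seg
    }
    v
  }

  bin_means <- function(v, n_out) {
    # mean of v over n_out equal-width (in original coordinates) bins
    idx <- ceiling(seq_along(v) / (length(v) / n_out))
    as.numeric(rowsum(v, idx)[, 1] / tabulate(idx, nbins = n_out))
  }

  acc <- matrix(0, nrow = 0, ncol = n_bins)
  skipped_short <- 0L
  for (i in seq_len(nrow(g))) {
    glen <- g$end[i] - g$start[i] + 1L
    if (glen < bin) { skipped_short <- skipped_short + 1L; next }
    up <- get_base(g$chrom[i], g$start[i] - flank, g$start[i] - 1L)
    bd <- get_base(g$chrom[i], g$start[i], g$end[i])
    dn <- get_base(g$chrom[i], g$end[i] + 1L, g$end[i] + flank)
    if (g$strand[i] == "-") {
      tmp <- rev(up); up <- rev(dn); dn <- tmp; bd <- rev(bd)
    }
    if (sum(up) + sum(bd) + sum(dn) == 0) next
    prof <- c(bin_means(up, n_flank_bins),
              bin_means(bd, n_body_bins),
              bin_means(dn, n_flank_bins))
    acc <- rbind(acc, prof)
  }
  if (skipped_short > 0) {
    warning(skipped_short, " gene(s) shorter than one bin skipped")
  }
  mean_signal <- if (nrow(acc) > 0) colMeans(acc) else rep(NA_real_, n_bins)
  out <- data.frame(
    bin = seq_len(n_bins),
    position = (seq_len(n_bins) - 0.5) * bin - flank,
    region = rep(c("upstream", "body", "downstream"),
                 c(n_flank_bins, n_body_bins, n_flank_bins)),
    mean_signal = mean_signal,
    stringsAsFactors = FALSE)
  attr(out, "n_genes") <- nrow(acc)
  out
}
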