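#' Candidate enhancers for one gene
#'
#' Candidate enhancers of a gene are the H3K27ac peaks whose midpoint
#' falls in a window (default 5 Mb) centered on the gene's most-5' TSS,
#' half-open on the right: `[tss - w/2, tss + w/2)`. Genes on the sex
#' chromosomes have no candidates and return an empty set with a warning.
#'
#' @param gene one row of `gene_models$genes` (or any list with `chrom`,
#'   `tss`).
#' @param enhancers `GRanges` of peaks with a `signal_value` column.
#' @param window window width in bp (default 5e6).
#' @param exclude_chroms chromosome names excluded from the analysis.
#' @return the subset of `enhancers` that are candidates for the gene.
#' @export
candidate_enhancers <- function(gene, enhancers, window = 5e6,
                                exclude_chroms = c("chrX", "chrY", "X", "Y")) {
  if (gene$chrom %in% exclude_chroms) {
    warning("gene ", gene$gene_id %||% "?", " on excluded chromosome ",
            gene$chrom, "; no candidates")
    return(enhancers[integer(0)])
  }
  mid0 <- (start(enhancers) - 1 + end(enhancers)) %/% 2
  tss0 <- gene$tss - 1
  keep <- as.character(seqnames(enhancers)) == gene$chrom &
    mid0 >= tss0 - window / 2 & mid0 < tss0 + window / 2
  enhancers[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-specific activity of an enhancer
#'
#' The activity of an enhancer toward one gene is its peak signal scaled
#' by the share of the enhancer's Hi-C contacts going to that gene among
#' all its candidate target genes:
#' `A_eg = A_e * C_eg / sum_j C_ej`. When the enhancer has zero contact
#' to every candidate target, the activity is 0.
#'
#' @param activity `A_e`, the enhancer's H3K27ac signal.
#' @param contact_to_gene `C_eg`, contact to the gene of interest.
#' @param contacts_all_targets vector of contacts from the enhancer to all
#'   its candidate target genes (must include `contact_to_gene`).
#' @return `A_eg`.
#' @export
gene_specific_activity <- function(activity, contact_to_gene,
                                   contacts_all_targets) {
  if (!any(abs(contacts_all_targets - contact_to_gene) < 1e-12)) {
    stop("the gene's contact must be among the enhancer's target contacts")
  }
  s <- sum(contacts_all_targets)
  if (s == 0) return(0)
  activity * contact_to_gene / s
}

#' Normalize per-gene interaction weights to adapted ABC scores
#'
#' Given the weights `A_eg * C_eg` of all candidate interactions of one
#' gene, returns each interaction's relative contribution (weights divided
#' by their sum). A zero denominator yields all-zero scores.
#'
#' @param weights numeric vector of `A_eg * C_eg` per candidate.
#' @return numeric vector of scores in `[0,1]`.
#' @export
abc_normalize <- function(weights) {
  s <- sum(weights)
  if (s == 0) return(rep(0, length(weights)))
  weights / s
}

#' Score all candidate enhancer-gene pairs with the adapted ABC model
#'
#' For every autosomal gene, every H3K27ac peak whose midpoint lies in a
#' 5 Mb window centered on the gene's most-5' TSS is scored:
#' contact `C_eg` is the balanced Hi-C frequency between the peak-midpoint
#' bin and the TSS bin; the gene-specific activity is
#' `A_eg = A_e * C_eg / sum_j C_ej` over all candidate target genes `j`
#' of the enhancer; and the adapted score is the normalized contribution
#' `A_eg * C_eg / sum_i A_ig * C_ig` over all candidates `i` of the gene.
#' Promoter-overlapping peaks are scored like any other candidate and
#' flagged.
#'
#' @param gm a `gene_models` object.
#' @param enhancers `GRanges` of H3K27ac peaks with `signal_value`.
#' @param contacts named list of balanced `contact_matrix` objects, one
#'   per chromosome.
#' @param window window width in bp (default 5e6).
#' @param exclude_chroms chromosomes dropped from the analysis (sex
#'   chromosomes by default).
#' @return data.frame with one row per candidate pair: `re_id`, `chrom`,
#'   `start`, `end`, `gene_id`, `activity` (`A_e`), `contact` (`C_eg`),
#'   `gene_specific_activity` (`A_eg`), `abc_score`,
#'   `overlaps_promoter`, `distance` (midpoint to TSS, bp).
#' @export
abc_interactions <- function(gm, enhancers, contacts, window = 5e6,
                             exclude_chroms = c("chrX", "chrY", "X", "Y")) {
  stopifnot(inherits(gm, "gene_models"))
  genes <- gm$genes
  excluded <- genes$chrom %in% exclude_chroms
  if (any(excluded)) {
    warning(sum(excluded),
            " gene(s) on excluded chromosome(s) dropped from ABC scoring")
  }
  genes <- genes[!excluded, , drop = FALSE]
  promoters <- gene_promoters(gm)
  enh_prom <- overlapsAny(enhancers, promoters, ignore.strand = TRUE)

  pieces <- list()
  for (chrom in intersect(unique(genes$chrom),
                          unique(as.character(seqnames(enhancers))))) {
    cm <- contacts[[chrom]]
    if (is.null(cm)) {
      warning("no contact matrix for ", chrom, "; chromosome skipped")
      next
    }
    gsub_idx <- which(genes$chrom == chrom)
    esub_idx <- which(as.character(seqnames(enhancers)) == chrom)
    if (length(gsub_idx) == 0 || length(esub_idx) == 0) next
    esub <- enhancers[esub_idx]
    mid0 <- (start(esub) - 1 + end(esub)) %/% 2
    tss0 <- genes$tss[gsub_idx] - 1

    # pair genes with enhancers whose midpoint is in [tss-w/2, tss+w/2)
    win <- IRanges(tss0 - window / 2 + 1, tss0 + window / 2)
    pts <- IRanges(mid0 + 1, mid0 + 1)
    ov <- findOverlaps(pts, win)
    if (length(ov) == 0) next
    ei <- queryHits(ov)   # index into esub
    gi <- subjectHits(ov) # index into gsub_idx
    C <- contact(cm, mid0[ei], tss0[gi])

    # A_eg: share of the enhancer's contacts over its target genes G_e
    csum_e <- rowsum(C, ei)
    csum <- as.numeric(csum_e[match(as.character(ei), rownames(csum_e)), 1])
    A_e <- esub$signal_value[ei]
    A_eg <- ifelse(csum > 0, A_e * C / csum, 0)

    # adapted ABC score: weight normalized within each gene's candidates
    wgt <- A_eg * C
    wsum_g <- rowsum(wgt, gi)
    wsum <- as.numeric(wsum_g[match(as.character(gi), rownames(wsum_g)), 1])
    score <- ifelse(wsum > 0, wgt / wsum, 0)

    pieces[[chrom]] <- data.frame(
      re_id = interval_id(esub)[ei],
      chrom = chrom,
      start = start(esub)[ei],
      end = end(esub)[ei],
      gene_id = genes$gene_id[gsub_idx][gi],
      activity = A_e,
      contact = C,
      gene_specific_activity = A_eg,
      abc_score = score,
      overlaps_promoter = enh_prom[esub_idx][ei],
      distance = abs(mid0[ei] - tss0[gi]),
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) {
    return(data.frame(re_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), activity = numeric(),
                      contact = numeric(),
                      gene_specific_activity = numeric(),
                      abc_score = numeric(), overlaps_promoter = logical(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Keep interactions at or above the adapted ABC score threshold
#'
#' @param interactions data.frame from [abc_interactions()].
#' @param threshold minimum score, inclusive (default 0.02).
#' @return filtered data.frame.
#' @export
filter_interactions <- function(interactions, threshold = 0.02) {
  interactions[interactions$abc_score >= threshold, , drop = FALSE]
}
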