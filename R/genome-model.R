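#' Read a GENCODE-style GTF into a gene model set
#'
#' Parses gene, exon and UTR records and derives, per gene, the gene body
#' (the span from the most 5' to the most 3' annotated coordinate), the
#' most-5' TSS in gene orientation, a 400 bp promoter centered on that TSS,
#' and the total length of merged exons. Transcript isoforms are collapsed
#' to the gene level.
#'
#' @param path path to a GTF file (1-based inclusive coordinates, GENCODE
#'   dialect; `gene_id` attribute required).
#' @return an object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{data.frame with `gene_id`, `chrom`, `strand`, `start`,
#'       `end` (gene body, 1-based closed), `tss`, `promoter_start`,
#'       `promoter_end`, `exon_length_sum`}
#'     \item{exons}{`GRanges` of exon records with a `gene_id` column}
#'     \item{utrs}{`GRanges` of UTR records with a `gene_id` column}
#'   }
#' Genes with no exon record are skipped with a warning.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$type) || is.null(gr$gene_id)) {
    stop("GTF lacks 'type' or 'gene_id' attributes: ", path)
  }
  exons <- gr[gr$type == "exon"]
  utrs <- gr[gr$type %in% c("UTR", "five_prime_utr", "three_prime_utr")]
  gene_rec <- gr[gr$type == "gene"]

  ids <- unique(c(as.character(gene_rec$gene_id), as.character(exons$gene_id)))
  no_exon <- setdiff(ids, unique(as.character(exons$gene_id)))
  if (length(no_exon) > 0) {
    warning("skipping ", length(no_exon), " gene(s) with no exon record: ",
            paste(utils::head(no_exon, 5), collapse = ", "))
    ids <- setdiff(ids, no_exon)
  }
  if (length(ids) == 0) {
    return(.new_gene_models(
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 tss = integer(), promoter_start = integer(),
                 promoter_end = integer(), exon_length_sum = integer(),
                 stringsAsFactors = FALSE),
      GRanges(), GRanges()))
  }

  ex_by_gene <- split(exons, factor(as.character(exons$gene_id), levels = ids))
  span_start <- vapply(ex_by_gene, function(g) min(start(g)), integer(1))
  span_end <- vapply(ex_by_gene, function(g) max(end(g)), integer(1))
  chrom <- vapply(ex_by_gene, function(g) as.character(seqnames(g))[1], character(1))
  strand_chr <- vapply(ex_by_gene, function(g) as.character(strand(g))[1], character(1))
  elen <- vapply(ex_by_gene, function(g) sum(width(reduce(ranges(g)))), integer(1))

  # if explicit gene records exist, the gene body is their span
  if (length(gene_rec) > 0) {
    gidx <- match(ids, as.character(gene_rec$gene_id))
    has <- !is.na(gidx)
    span_start[has] <- start(gene_rec)[gidx[has]]
    span_end[has] <- end(gene_rec)[gidx[has]]
  }

  tss <- ifelse(strand_chr == "-", span_end, span_start)
  genes <- data.frame(
    gene_id = ids, chrom = chrom, strand = strand_chr,
    start = as.integer(span_start), end = as.integer(span_end),
    tss = as.integer(tss),
    promoter_start = as.integer(tss - PROMOTER_HALF_WIDTH),
    promoter_end = as.integer(tss + PROMOTER_HALF_WIDTH - 1L),
    exon_length_sum = as.integer(elen),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  keep_ex <- as.character(exons$gene_id) %in% ids
  keep_ut <- as.character(utrs$gene_id) %in% ids
  .new_gene_models(genes,
                   granges_with_gene(exons[keep_ex]),
                   granges_with_gene(utrs[keep_ut]))
}

granges_with_gene <- function(gr) {
  out <- granges(gr)
  out$gene_id <- as.character(gr$gene_id)
  out
}

.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1]]
    stop("malformed GTF line ", bad, " in ", path, " (fewer than 9 fields)")
  }
  invisible(TRUE)
}

.new_gene_models <- function(genes, exons, utrs) {
  structure(list(genes = genes, exons = exons, utrs = utrs),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      length(x$exons), "exon records on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a gene model set back to GTF
#'
#' Emits gene, exon and UTR records with coordinates identical to the
#' parsed input, so `read_gtf(write_gtf(x))` round-trips exactly.
#'
#' @param gm a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes
  lines <- character(0)
  if (nrow(g) > 0) {
    lines <- sprintf("%s\tk79re\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                     g$chrom, g$start, g$end, g$strand, g$gene_id)
  }
  for (what in c("exons", "utrs")) {
    gr <- gm[[what]]
    if (length(gr) == 0) next
    type <- if (what == "exons") "exon" else "UTR"
    lines <- c(lines, sprintf(
      "%s\tk79re\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      as.character(seqnames(gr)), type, start(gr), end(gr),
      as.character(strand(gr)), gr$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Gene bodies as a GRanges
#' @param gm a `gene_models` object.
#' @return `GRanges` with one range per gene (`gene_id` column).
#' @export
gene_bodies <- function(gm) {
  g <- gm$genes
  gr <- GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand)
  gr$gene_id <- g$gene_id
  gr
}

#' Promoters (400 bp centered on the most-5' TSS) as a GRanges
#' @param gm a `gene_models` object.
#' @return `GRanges` with one range per gene (`gene_id` column).
#' @export
gene_promoters <- function(gm) {
  g <- gm$genes
  gr <- GRanges(g$chrom, IRanges(g$promoter_start, g$promoter_end),
                strand = g$strand)
  gr$gene_id <- g$gene_id
  gr
}

#' Build the exclusive per-base feature annotation
#'
#' Splits each chromosome into the five mutually exclusive labels
#' promoter/TSS, UTR, exon, intron and intergenic. Every base gets exactly
#' one label; precedence is promoter > UTR > exon > intron, evaluated
#' jointly over all genes (any gene's promoter beats any gene's exon).
#' Bases inside a gene body covered by no other feature are introns; bases
#' outside all gene bodies and promoters are intergenic.
#'
#' @param gm a `gene_models` object.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @return an object of class `feature_map`: a list of `GRanges`, one per
#'   label in `FEATURE_LABELS`, plus the chromosome sizes.
#' @export
build_feature_map <- function(gm, chrom_sizes) {
  stopifnot(inherits(gm, "gene_models"), !is.null(names(chrom_sizes)))
  g <- gm$genes
  unknown <- setdiff(g$chrom, names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("genes on chromosomes missing from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  beyond <- g$end > chrom_sizes[g$chrom] | g$start < 1
  if (any(beyond)) {
    stop("gene(s) extend beyond chromosome bounds: ",
         paste(utils::head(g$gene_id[beyond], 5), collapse = ", "))
  }
  genome <- GRanges(names(chrom_sizes),
                    IRanges(1L, as.integer(chrom_sizes)))

  clip <- function(gr) {
    if (length(gr) == 0) return(GRanges())
    GenomicRanges::intersect(reduce(unstrand(gr)), genome,
                             ignore.strand = TRUE)
  }
  prom <- clip(gene_promoters(gm))
  utr <- clip(gm$utrs)
  exon <- clip(gm$exons)
  bodies <- clip(gene_bodies(gm))

  utr_x <- GenomicRanges::setdiff(utr, prom, ignore.strand = TRUE)
  exon_x <- GenomicRanges::setdiff(
    exon, GenomicRanges::union(prom, utr, ignore.strand = TRUE),
    ignore.strand = TRUE)
  covered <- reduce(c(prom, utr, exon))
  intron <- GenomicRanges::setdiff(bodies, covered, ignore.strand = TRUE)
  genic <- GenomicRanges::union(bodies, prom, ignore.strand = TRUE)
  intergenic <- GenomicRanges::setdiff(genome, genic, ignore.strand = TRUE)

  structure(list(promoter_tss = prom, utr = utr_x, exon = exon_x,
                 intron = intron, intergenic = intergenic,
                 chrom_sizes = chrom_sizes),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  w <- vapply(FEATURE_LABELS, function(l) sum(as.numeric(width(x[[l]]))),
              numeric(1))
  cat("feature_map over", sum(as.numeric(x$chrom_sizes)), "bp:\n")
  print(round(w / sum(w), 4))
  invisible(x)
}

#' Genomic-feature distribution of peak base pairs
#'
#' Assigns every base pair of every peak to its (unique) feature label and
#' returns the fraction of peak bases per label. Overlapping peaks are
#' counted per peak, mirroring a per-base tally over a peak list.
#'
#' @param peaks `GRanges` of peaks.
#' @param fmap a `feature_map`.
#' @return named numeric vector of fractions over `FEATURE_LABELS`,
#'   summing to 1.
#' @export
peak_feature_distribution <- function(peaks, fmap) {
  stopifnot(inherits(fmap, "feature_map"))
  if (length(peaks) == 0) stop("empty peak list")
  bad <- !(as.character(seqnames(peaks)) %in% names(fmap$chrom_sizes))
  if (any(bad)) {
    stop("peaks on chromosomes absent from the feature map: ",
         paste(unique(as.character(seqnames(peaks))[bad]), collapse = ", "))
  }
  peaks <- unstrand(peaks)
  total <- sum(as.numeric(width(peaks)))
  bp <- vapply(FEATURE_LABELS, function(lab) {
    gr <- fmap[[lab]]
    ov <- findOverlaps(peaks, gr, ignore.strand = TRUE)
    if (length(ov) == 0) return(0)
    sum(as.numeric(width(pintersect(peaks[queryHits(ov)],
                                    gr[subjectHits(ov)]))))
  }, numeric(1))
  bp / total
}
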