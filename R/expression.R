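#' Reads per kilobase of merged exon per million mapped reads
#'
#' @param count reads assigned to the gene.
#' @param exon_length_sum total length of the gene's merged exons (bp).
#' @param library_size total mapped reads in the library.
#' @return numeric RPKM, vectorized over its arguments.
#' @export
rpkm <- function(count, exon_length_sum, library_size) {
  if (any(exon_length_sum <= 0)) stop("exon_length_sum must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (exon_length_sum / 1000) / (library_size / 1e6)
}

#' Assign differential-expression status
#'
#' A gene is expressed when its RPKM is at least `min_rpkm` in at least
#' one condition. Expressed genes are `down` when `log2fc <= -min_lfc`
#' and `fdr <= max_fdr`, `up` when `log2fc >= min_lfc` and
#' `fdr <= max_fdr` (all thresholds inclusive), otherwise `unchanged`.
#' Records with a missing FDR are treated as unchanged, with a warning.
#'
#' @param table data.frame with `gene_id`, `rpkm_ctrl`, `rpkm_ko`,
#'   `log2fc`, `fdr`.
#' @param min_rpkm expression threshold (default 1).
#' @param min_lfc absolute log2 fold-change threshold (default 0.5).
#' @param max_fdr adjusted-p threshold (default 0.05).
#' @return the input with a `de_status` factor column added
#'   (`down`/`up`/`unchanged`/`not_expressed`).
#' @export
assign_de_status <- function(table, min_rpkm = 1, min_lfc = 0.5,
                             max_fdr = 0.05) {
  need <- c("gene_id", "rpkm_ctrl", "rpkm_ko", "log2fc", "fdr")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    stop("expression table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  expressed <- pmax(table$rpkm_ctrl, table$rpkm_ko) >= min_rpkm
  fdr <- table$fdr
  if (anyNA(fdr)) {
    warning(sum(is.na(fdr)), " record(s) with missing FDR treated as unchanged")
    fdr[is.na(fdr)] <- Inf
  }
  lfc <- table$log2fc
  status <- rep("unchanged", nrow(table))
  status[expressed & lfc <= -min_lfc & fdr <= max_fdr] <- "down"
  status[expressed & lfc >= min_lfc & fdr <= max_fdr] <- "up"
  status[!expressed] <- "not_expressed"
  table$de_status <- factor(status,
                            levels = c("down", "up", "unchanged",
                                       "not_expressed"))
  table
}

#' Expression quartiles over expressed genes
#'
#' Ranks genes by control RPKM and splits them into four equal-count
#' groups (1 = lowest expression, 4 = highest). Ties are broken by the
#' stable `gene_id` order, and group sizes differ by at most one.
#'
#' @param records data.frame of expressed genes with `gene_id` and
#'   `rpkm_ctrl`.
#' @return the input with an integer `quartile` column added.
#' @export
expression_quartiles <- function(records) {
  n <- nrow(records)
  if (n < 4) stop("need at least 4 expressed genes for quartiles")
  ord <- order(records$rpkm_ctrl, records$gene_id)
  sizes <- diff(floor(n * (0:4) / 4))
  q <- integer(n)
  q[ord] <- rep(1:4, sizes)
  records$quartile <- q
  records
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `rpkm_ctrl`, `rpkm_ko`,
#'   `log2fc`, `fdr`.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  read_tsv(path)
}
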