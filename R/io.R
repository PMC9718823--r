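#' Read a BED file of intervals
#'
#' Minimal BED3/BED6 reader. BED coordinates (0-based half-open) are
#' converted to the package-internal 1-based closed convention.
#'
#' @param path path to a BED file.
#' @return `GRanges`; a `name` column is kept when a 4th column exists.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0) return(GRanges())
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  strand_chr <- if (ncol(tab) >= 6) tab[[6]] else "*"
  strand_chr[!strand_chr %in% c("+", "-")] <- "*"
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]),
                strand = strand_chr)
  if (ncol(tab) >= 4) gr$name <- as.character(tab[[4]])
  gr
}

#' Write intervals to BED
#'
#' @param gr `GRanges` (internal 1-based closed; written as 0-based
#'   half-open BED).
#' @param path output path.
#' @param name optional character vector for the 4th column; defaults to
#'   the `name` metadata column when present.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name = NULL) {
  if (is.null(name)) {
    name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  }
  strand_chr <- as.character(strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   name, 0L, strand_chr)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MACS2 narrowPeak file
#'
#' @param path path to a narrowPeak (BED6+4) file.
#' @return `GRanges` with `name`, `signal_value` (column 7, the peak
#'   activity used by the ABC score), `p_value`, `q_value`, `summit`.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  if (file.size(path) == 0) return(GRanges(signal_value = numeric()))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 7) stop("narrowPeak needs >= 7 columns (signalValue): ", path)
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
  gr$name <- as.character(tab[[4]])
  gr$signal_value <- as.numeric(tab[[7]])
  if (ncol(tab) >= 10) {
    gr$p_value <- as.numeric(tab[[8]])
    gr$q_value <- as.numeric(tab[[9]])
    gr$summit <- as.integer(tab[[10]])
  }
  gr
}

#' Write peaks in narrowPeak format
#' @param gr `GRanges` with a `signal_value` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(gr, path) {
  n <- length(gr)
  nm <- if (!is.null(gr$name)) gr$name else sprintf("peak_%d", seq_len(n))
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr), nm,
                   0L, ".", gr$signal_value, -1, -1, -1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#' @param path path to a TSV with chromosome name and length.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Write chromosome sizes
#' @param sizes named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Stable interval identifier ("chrom:start-end", 1-based closed)
#' @param gr `GRanges`.
#' @return character vector of keys.
#' @export
interval_id <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
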