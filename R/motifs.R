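#' Build a position weight matrix from a count matrix
#'
#' Adds a pseudocount to each cell and normalizes columns to
#' probabilities.
#'
#' @param counts 4 x W numeric matrix with rows A, C, G, T.
#' @param name transcription-factor name.
#' @param pseudocount added to every count before normalization
#'   (default 1).
#' @param background background base frequencies (default uniform).
#' @return an object of class `trap_pwm`: list with `name`, `prob`
#'   (4 x W column-stochastic matrix), `width`, `background`.
#' @export
pwm_from_counts <- function(counts, name, pseudocount = 1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  rownames(counts) <- c("A", "C", "G", "T")
  prob <- sweep(counts + pseudocount, 2,
                colSums(counts + pseudocount), "/")
  structure(list(name = name, prob = prob, width = ncol(prob),
                 background = background),
            class = "trap_pwm")
}

#' @export
print.trap_pwm <- function(x, ...) {
  cat("trap_pwm", x$name, "width", x$width, "consensus",
      paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = ""),
      "\n")
  invisible(x)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `>identifier name` header followed by
#' four rows `A [ counts ]` ... `T [ counts ]` (brackets optional).
#'
#' @param path path to a JASPAR PFM file.
#' @param pseudocount,background passed to [pwm_from_counts()].
#' @return named list of `trap_pwm` objects (named by TF name, falling
#'   back to the matrix identifier).
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("JASPAR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) stop("no PFM headers ('>') found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    from <- heads[h] + 1
    to <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    block <- lines[from:to]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 4) stop("PFM block with fewer than 4 rows in ", path)
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("ragged PFM block in ", path)
    }
    counts <- do.call(rbind, rows)
    hdr <- sub("^>\\s*", "", lines[heads[h]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    nm <- if (length(parts) >= 2) parts[2] else parts[1]
    out[[nm]] <- pwm_from_counts(counts, nm, pseudocount, background)
  }
  out
}

#' Write PWMs in JASPAR count format
#' @param pwms list of `trap_pwm` objects or 4 x W count matrices (named).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- character(0)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    m <- if (inherits(p, "trap_pwm")) round(p$prob * 100) else p
    lines <- c(lines, paste0(">", nm, " ", nm),
               vapply(1:4, function(r) {
                 paste0(c("A", "C", "G", "T")[r], " [ ",
                        paste(m[r, ], collapse = " "), " ]")
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' TRAP affinity of a sequence for a transcription factor
#'
#' Biophysical TRAP model: for every window `i` of PWM width `W` on both
#' strands, the mismatch energy is
#' `E_i = (1/lambda) * sum_j ln(p_max,j / p_base_j,j)` and the binding
#' probability is `P_i = R0 exp(-E_i) / (1 + R0 exp(-E_i))`; the affinity
#' is the sum of `P_i` over all windows. Windows containing `N`
#' contribute 0. Defaults are the published TRAP parameters
#' (`lambda = 0.7`, `ln R0 = 0.584 W - 5.66`).
#'
#' @param pwm a `trap_pwm`.
#' @param seq DNA sequence (character or `DNAString`), alphabet `ACGTN`.
#' @param lambda energy scale (default 0.7).
#' @param ln_r0 log of R0; default `0.584 * W - 5.66`.
#' @return numeric affinity (>= 0). Sequences shorter than the motif
#'   return 0 with a warning.
#' @export
trap_affinity <- function(pwm, seq, lambda = 0.7, ln_r0 = NULL) {
  stopifnot(inherits(pwm, "trap_pwm"))
  seq <- toupper(as.character(seq))
  W <- pwm$width
  if (is.null(ln_r0)) ln_r0 <- 0.584 * W - 5.66
  L <- nchar(seq)
  if (L < W) {
    warning("sequence shorter than motif width; affinity = 0")
    return(0)
  }
  r0 <- exp(ln_r0)
  fwd <- .trap_strand_sum(pwm$prob, seq, lambda, r0)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq)))
  rev <- .trap_strand_sum(pwm$prob, rc, lambda, r0)
  fwd + rev
}

.trap_strand_sum <- function(prob, seq, lambda, r0) {
  W <- ncol(prob)
  base_idx <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T"))
  n_win <- length(base_idx) - W + 1
  pmaxcol <- apply(prob, 2, max)
  logterm <- log(sweep(1 / prob, 2, pmaxcol, "*")) # 4 x W
  esum <- numeric(n_win)
  for (j in seq_len(W)) {
    esum <- esum + logterm[cbind(base_idx[j:(j + n_win - 1)], j)]
  }
  E <- esum / lambda
  z <- r0 * exp(-E)
  P <- z / (1 + z)
  P[is.na(P)] <- 0 # windows containing N
  sum(P)
}

#' TRAP affinities of many sequences for many TFs
#'
#' @param pwms named list of `trap_pwm` objects.
#' @param seqs `DNAStringSet` or character vector of sequences.
#' @param ... passed to [trap_affinity()].
#' @return numeric matrix, sequences x TFs.
#' @export
trap_affinities <- function(pwms, seqs, ...) {
  seqs <- as.character(seqs)
  out <- matrix(0, nrow = length(seqs), ncol = length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  for (k in seq_along(pwms)) {
    out[, k] <- vapply(seqs, trap_affinity, numeric(1), pwm = pwms[[k]],
                       ...)
  }
  out
}

#' Keep PWMs of expressed transcription factors
#'
#' Retains a motif when its TF resolves to a gene with RPKM at least
#' `min_rpkm` in either condition (inclusive); unresolvable TFs are
#' dropped with a warning.
#'
#' @param pwms named list of `trap_pwm` objects.
#' @param expr expression data.frame with `gene_id`, `rpkm_ctrl`,
#'   `rpkm_ko`.
#' @param tf_to_gene optional named character vector mapping TF names to
#'   gene ids; by default TF names are used as gene ids directly.
#' @param min_rpkm expression threshold (default 1).
#' @return filtered list of `trap_pwm` objects.
#' @export
filter_expressed_tfs <- function(pwms, expr, tf_to_gene = NULL,
                                 min_rpkm = 1) {
  genes <- if (is.null(tf_to_gene)) names(pwms) else
    as.character(tf_to_gene[names(pwms)])
  idx <- match(genes, expr$gene_id)
  unresolved <- is.na(idx)
  if (any(unresolved)) {
    warning("dropping ", sum(unresolved),
            " TF(s) not resolvable to an expressed-gene record: ",
            paste(utils::head(names(pwms)[unresolved], 5), collapse = ", "))
  }
  keep <- !unresolved &
    pmax(expr$rpkm_ctrl[idx], expr$rpkm_ko[idx]) >= min_rpkm
  keep[is.na(keep)] <- FALSE
  pwms[keep]
}

#' One-tailed Mann-Whitney test
#'
#' Tests whether sample `a` is stochastically greater than sample `b`
#' (rank-sum U with midrank ties). The p-value is exact (enumeration)
#' when `length(a) + length(b) <= 12` and there are no ties, and a
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `U` and `p.value`.
#' @export
mann_whitney_one_tailed <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1) {
    return(list(U = length(a) * length(b) / 2, p.value = 1))
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b) <= 12) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "greater", exact = use_exact, correct = TRUE,
    conf.level = 0.975))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Motif-affinity enrichment between two RE groups
#'
#' Computes TRAP affinities of every (expressed) TF over the activating
#' and silencing RE sequence groups, tests enrichment in each direction
#' with the one-tailed Mann-Whitney test, and BH-adjusts the p-values of
#' both direction analyses as a single family.
#'
#' @param pwms named list of `trap_pwm` objects.
#' @param seqs_activating,seqs_silencing sequences of the two RE groups
#'   (`DNAStringSet` or character).
#' @param expr optional expression table; when given, PWMs are first
#'   filtered with [filter_expressed_tfs()].
#' @param tf_to_gene optional TF-to-gene map for the expression filter.
#' @param alpha significance threshold on the adjusted p (default 0.05,
#'   inclusive).
#' @return data.frame with one row per TF: `tf`, `median_activating`,
#'   `median_silencing`, `u_activating`, `p_activating`,
#'   `p_adj_activating` (enrichment in activating REs), the silencing
#'   counterparts, `direction` and `significant`.
#' @export
motif_enrichment <- function(pwms, seqs_activating, seqs_silencing,
                             expr = NULL, tf_to_gene = NULL,
                             alpha = 0.05) {
  if (!is.null(expr)) {
    pwms <- filter_expressed_tfs(pwms, expr, tf_to_gene = tf_to_gene)
  }
  if (length(pwms) == 0) stop("no PWMs left to test")
  aff_a <- trap_affinities(pwms, seqs_activating)
  aff_s <- trap_affinities(pwms, seqs_silencing)
  res <- lapply(seq_along(pwms), function(k) {
    act <- mann_whitney_one_tailed(aff_a[, k], aff_s[, k])
    sil <- mann_whitney_one_tailed(aff_s[, k], aff_a[, k])
    data.frame(tf = names(pwms)[k],
               median_activating = stats::median(aff_a[, k]),
               median_silencing = stats::median(aff_s[, k]),
               u_activating = act$U, p_activating = act$p.value,
               u_silencing = sil$U, p_silencing = sil$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # both direction analyses feed one BH family
  adj <- bh_adjust(c(out$p_activating, out$p_silencing))
  out$p_adj_activating <- adj[seq_len(nrow(out))]
  out$p_adj_silencing <- adj[nrow(out) + seq_len(nrow(out))]
  out$direction <- ifelse(out$p_adj_activating <= out$p_adj_silencing,
                          "activating", "silencing")
  out$significant <- pmin(out$p_adj_activating, out$p_adj_silencing) <= alpha
  out
}
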