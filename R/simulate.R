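#' Configuration for the synthetic chromatin dataset
#'
#' Bundles every parameter of the planted-truth generator: a small
#' multi-chromosome genome, planted gene classes with their expression
#' effects, distance-decaying Hi-C contacts with boosted
#' enhancer-promoter loops, condition-specific peaks and reads, and
#' motif-seeded regulatory-element sequences. All outputs are pure
#' functions of this configuration (including its seed).
#'
#' @param seed integer seed.
#' @param n_genes total number of genes (default 300).
#' @param chrom_sizes named vector of chromosome lengths; the default
#'   (two 10 Mb autosomes plus a 5 Mb chrX) exercises the autosome-only
#'   ABC rule.
#' @param resolution Hi-C bin size in bp (default 5000).
#' @param class_props proportions of planted gene classes among autosomal
#'   genes: `gb_re_down` (gene-body methylated, K79-RE linked,
#'   downregulated), `gb_only_down`, `silencing_re_up` (upregulated via
#'   silencing K79-REs, no gene-body mark), `none`.
#' @param effects list of `c(mean, sd)` log2 fold-change effects per
#'   class.
#' @param gb_unaffected_frac fraction of `none`-class autosomal genes
#'   that carry gene-body H3K79me2 without being modulated
#'   (epigenetically compensated genes).
#' @param hic_mu0 expected diagonal contact count.
#' @param hic_decay distance-decay exponent of expected contacts.
#' @param loop_boost contact multiplier at planted RE-promoter bin pairs.
#' @param peak_signal_meanlog,peak_signal_sdlog lognormal parameters of
#'   H3K27ac peak signal values.
#' @param n_plain_res range of plain (non-K79) REs per gene, including
#'   the promoter RE.
#' @param n_k79_res range of activating K79-REs per `gb_re_down` gene.
#' @param n_silencing_res range of silencing K79-REs per
#'   `silencing_re_up` gene.
#' @param re_width RE width in bp.
#' @param n_ko_only_res number of extra REs present only in the knockout
#'   (each differentially acetylated), exercising the knockout-only
#'   mapping rule.
#' @param motif_consensus consensus of the planted silencing motif.
#' @param n_motif_sites planted motif copies per silencing-RE sequence.
#' @param n_decoy_pwms number of random decoy PWMs.
#' @param n_reps RNA-seq replicates per condition.
#' @param library_size mapped reads per RNA-seq library.
#' @param dispersion negative-binomial dispersion of gene counts.
#' @param rpkm_meanlog,rpkm_sdlog lognormal parameters of baseline
#'   control RPKM.
#' @return a list of class `truth_config`.
#' @export
truth_config <- function(seed = 0,
                         n_genes = 300,
                         chrom_sizes = c(chr1 = 10e6, chr2 = 10e6,
                                         chrX = 5e6),
                         resolution = 5000,
                         class_props = c(gb_re_down = 0.12,
                                         gb_only_down = 0.08,
                                         silencing_re_up = 0.10,
                                         none = 0.70),
                         effects = list(gb_re_down = c(-1.5, 0.3),
                                        gb_only_down = c(-0.7, 0.3),
                                        silencing_re_up = c(1.0, 0.3),
                                        none = c(0, 0.15)),
                         gb_unaffected_frac = 0.2,
                         hic_mu0 = 5, hic_decay = 1.2, loop_boost = 5,
                         peak_signal_meanlog = 1, peak_signal_sdlog = 0.5,
                         n_plain_res = 2:4, n_k79_res = 1:8,
                         n_silencing_res = 1:3,
                         re_width = 500, n_ko_only_res = 8,
                         motif_consensus = "TGACGTCATC",
                         n_motif_sites = 5, n_decoy_pwms = 19,
                         n_reps = 3, library_size = 2e7,
                         dispersion = 0.01,
                         rpkm_meanlog = 2, rpkm_sdlog = 1) {
  if (abs(sum(class_props) - 1) > 1e-8) {
    stop("class_props must sum to 1")
  }
  stopifnot(hic_mu0 > 0, hic_decay > 0, loop_boost >= 1, re_width > 0,
            all(chrom_sizes %% resolution == 0))
  cfg <- as.list(environment())
  class(cfg) <- "truth_config"
  cfg
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

.autosomes <- function(chrom_sizes) {
  names(chrom_sizes)[!grepl("[XY]$", names(chrom_sizes))]
}

#' Generate the synthetic genome annotation
#'
#' Places non-overlapping genes with lognormal lengths (median about
#' 20 kb, minimum 10 kb), 1-10 exons each, mixed strands, and 200 bp
#' terminal UTRs, deterministically from the configuration seed.
#'
#' @param cfg a `truth_config`.
#' @return list with `gm` (a `gene_models`) and `chrom_sizes`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  .with_seed(cfg$seed + 101L, {
    sizes <- cfg$chrom_sizes
    n_per <- round(cfg$n_genes * sizes / sum(sizes))
    margin <- 50000L
    gene_rows <- list()
    exon_rows <- list()
    utr_rows <- list()
    gid <- 0L
    for (chrom in names(sizes)) {
      n <- n_per[[chrom]]
      if (n == 0) next
      len <- pmin(pmax(round(rlnorm(n, log(20000), 0.6)), 10000L),
                  200000L)
      free <- sizes[[chrom]] - 2L * margin - sum(len)
      if (free < n + 1) {
        stop("genes do not fit on ", chrom,
             "; use a larger genome or fewer genes")
      }
      gaps <- as.integer(stats::rmultinom(1, free, rep(1, n + 1))[, 1])
      starts <- margin + cumsum(gaps[seq_len(n)]) +
        c(0L, cumsum(len))[seq_len(n)]
      ends <- starts + len - 1L
      strand_chr <- sample(c("+", "-"), n, replace = TRUE)
      for (i in seq_len(n)) {
        gid <- gid + 1L
        id <- sprintf("gene_%04d", gid)
        gene_rows[[gid]] <- data.frame(
          gene_id = id, chrom = chrom, strand = strand_chr[i],
          start = starts[i], end = ends[i], stringsAsFactors = FALSE)
        n_ex <- sample(1:10, 1)
        if (n_ex == 1) {
          ex_s <- starts[i]; ex_e <- ends[i]
        } else {
          cuts <- sort(sample(seq_len(len[i] - 1L), 2L * n_ex - 2L))
          bounds <- c(0L, cuts, len[i])
          seg_s <- starts[i] + bounds[-length(bounds)]
          seg_e <- starts[i] + bounds[-1] - 1L
          odd <- seq(1, 2L * n_ex - 1L, by = 2)
          ex_s <- seg_s[odd]; ex_e <- seg_e[odd]
        }
        exon_rows[[gid]] <- data.frame(
          gene_id = id, chrom = chrom, strand = strand_chr[i],
          start = ex_s, end = ex_e, stringsAsFactors = FALSE)
        utr_rows[[gid]] <- data.frame(
          gene_id = id, chrom = chrom, strand = strand_chr[i],
          start = c(ex_s[1], max(ex_s[length(ex_s)], ends[i] - 199L)),
          end = c(min(ex_e[1], starts[i] + 199L), ends[i]),
          stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, gene_rows)
    exdf <- do.call(rbind, exon_rows)
    utdf <- do.call(rbind, utr_rows)
    utdf <- utdf[utdf$start <= utdf$end, , drop = FALSE]
    exons <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                     strand = exdf$strand)
    exons$gene_id <- exdf$gene_id
    utrs <- GRanges(utdf$chrom, IRanges(utdf$start, utdf$end),
                    strand = utdf$strand)
    utrs$gene_id <- utdf$gene_id

    elen <- vapply(split(ranges(exons), exons$gene_id),
                   function(r) sum(width(reduce(r))), integer(1))
    tss <- ifelse(genes$strand == "-", genes$end, genes$start)
    gm <- .new_gene_models(
      data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                 strand = genes$strand, start = genes$start,
                 end = genes$end, tss = tss,
                 promoter_start = as.integer(tss - PROMOTER_HALF_WIDTH),
                 promoter_end = as.integer(tss + PROMOTER_HALF_WIDTH - 1L),
                 exon_length_sum = as.integer(elen[genes$gene_id]),
                 stringsAsFactors = FALSE),
      exons, utrs)
    list(gm = gm, chrom_sizes = sizes)
  })
}

#' Assign planted gene classes and regulatory elements
#'
#' Samples gene classes among autosomal genes (sex-chromosome genes are
#' always `none`), draws per-gene true log2 fold-changes and gene-body
#' coverage fractions, and places the planted regulatory elements: a
#' promoter RE plus distal plain REs for every gene, activating K79-REs
#' for `gb_re_down` genes, silencing K79-REs for `silencing_re_up`
#' genes, and a few knockout-only differential REs.
#'
#' @param cfg a `truth_config`.
#' @param genome output of [simulate_genome()].
#' @return list with `genes` (gene_id, class, true_log2fc, gb_pos,
#'   gb_fraction) and `res` (re_id, chrom, start, end, gene_id, type,
#'   diff_k27, ko_only).
#' @export
simulate_truth <- function(cfg, genome) {
  .with_seed(cfg$seed + 202L, {
    g <- genome$gm$genes
    auto <- .autosomes(genome$chrom_sizes)
    is_auto <- g$chrom %in% auto
    cls <- rep("none", nrow(g))
    auto_idx <- which(is_auto)
    n_auto <- length(auto_idx)
    counts <- round(cfg$class_props[c("gb_re_down", "gb_only_down",
                                      "silencing_re_up")] * n_auto)
    pick <- sample(auto_idx)
    cls[pick[seq_len(counts[1])]] <- "gb_re_down"
    cls[pick[counts[1] + seq_len(counts[2])]] <- "gb_only_down"
    cls[pick[counts[1] + counts[2] + seq_len(counts[3])]] <-
      "silencing_re_up"

    eff <- t(vapply(cls, function(k) cfg$effects[[k]], numeric(2)))
    true_lfc <- rnorm(nrow(g), eff[, 1], eff[, 2])
    gb_pos <- cls %in% c("gb_re_down", "gb_only_down")
    # a share of unmodulated genes also carries the gene-body mark
    comp <- is_auto & cls == "none" &
      runif(nrow(g)) < cfg$gb_unaffected_frac
    gb_pos <- gb_pos | comp
    gb_fraction <- ifelse(gb_pos, runif(nrow(g), 0.26, 0.95), 0)

    half <- cfg$re_width %/% 2
    make_res <- function(i, offsets, type, p_diff_up, p_diff_down) {
      side <- sample(c(-1, 1), length(offsets), replace = TRUE)
      center <- g$tss[i] + side * offsets
      u <- runif(length(offsets))
      diff <- rep("none", length(offsets))
      diff[u < p_diff_up] <- "up"
      diff[u >= p_diff_up & u < p_diff_up + p_diff_down] <- "down"
      data.frame(chrom = g$chrom[i],
                 start = as.integer(center - half),
                 end = as.integer(center + half - 1L),
                 gene_id = g$gene_id[i], type = type, diff_k27 = diff,
                 ko_only = FALSE, stringsAsFactors = FALSE)
    }
    res_rows <- list()
    for (i in seq_len(nrow(g))) {
      # every gene gets its promoter RE plus distal plain REs
      n_plain <- sample(cfg$n_plain_res, 1)
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        chrom = g$chrom[i], start = as.integer(g$tss[i] - half),
        end = as.integer(g$tss[i] + half - 1L), gene_id = g$gene_id[i],
        type = "plain", diff_k27 = "none", ko_only = FALSE,
        stringsAsFactors = FALSE)
      if (n_plain > 1) {
        off <- sample(seq(5500L, 49500L, by = 2000L), n_plain - 1L)
        res_rows[[length(res_rows) + 1L]] <-
          make_res(i, off, "plain", 0, 0)
      }
      if (cls[i] == "gb_re_down") {
        n_re <- sample(cfg$n_k79_res, 1)
        off <- sample(seq(5000L, 24000L, by = 1000L), n_re)
        res_rows[[length(res_rows) + 1L]] <-
          make_res(i, off, "k79_activating", 0, 0.2)
      }
      if (cls[i] == "silencing_re_up") {
        n_re <- sample(cfg$n_silencing_res, 1)
        off <- sample(seq(5000L, 24000L, by = 1000L), n_re)
        res_rows[[length(res_rows) + 1L]] <-
          make_res(i, off, "k79_silencing", 0.4, 0)
      }
    }
    # knockout-only differential REs on random autosomal genes
    ko_idx <- sample(auto_idx, min(cfg$n_ko_only_res, n_auto))
    for (i in ko_idx) {
      row <- make_res(i, sample(seq(26000L, 40000L, by = 2000L), 1),
                      "plain", 1, 0)
      row$ko_only <- TRUE
      res_rows[[length(res_rows) + 1L]] <- row
    }
    res <- do.call(rbind, res_rows)
    res$re_id <- sprintf("%s:%d-%d", res$chrom, res$start, res$end)
    res <- res[!duplicated(res$re_id), , drop = FALSE]
    rownames(res) <- NULL
    list(genes = data.frame(gene_id = g$gene_id, class = cls,
                            true_log2fc = true_lfc, gb_pos = gb_pos,
                            gb_fraction = gb_fraction,
                            stringsAsFactors = FALSE),
         res = res)
  })
}

#' Generate condition-specific peaks, reads and differential-peak calls
#'
#' Gene-body-methylated genes receive tiled H3K79me2 reads over the
#' planted fraction of their bodies in control (at least 50 reads per
#' replicate) and only background reads in the knockout; every planted RE
#' gets an H3K27ac peak in both conditions; K79-REs are half-covered by
#' differential H3K79me2 intervals; planted differential-H3K27ac REs are
#' half-covered by the corresponding directional intervals.
#'
#' @param cfg a `truth_config`.
#' @param genome output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @return list with `k27_peaks_ctrl`, `k27_peaks_ko` (`GRanges` with
#'   `signal_value`), `k79_reads` (nested list condition -> replicate
#'   `GRanges`), `k79_peaks_ctrl`, `k79_peaks_ko`, `diff_k79`,
#'   `diff_k27_up`, `diff_k27_down` (`GRanges`).
#' @export
simulate_peaks_and_reads <- function(cfg, genome, truth) {
  .with_seed(cfg$seed + 303L, {
    g <- genome$gm$genes
    tg <- truth$genes
    res <- truth$res

    read_len <- 100L
    gb_reads <- function(rep_offset) {
      rows <- list()
      for (i in seq_len(nrow(g))) {
        if (tg$gb_pos[i]) {
          span <- round(tg$gb_fraction[i] * (g$end[i] - g$start[i] + 1L))
          starts <- seq(g$start[i] + rep_offset,
                        g$start[i] + span - read_len, by = 50L)
        } else {
          starts <- g$start[i] +
            sort(sample(seq_len(max(g$end[i] - g$start[i] - read_len,
                                    1L)), 5L))
        }
        rows[[i]] <- data.frame(chrom = g$chrom[i], start = starts,
                                end = starts + read_len - 1L,
                                stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      GRanges(df$chrom, IRanges(df$start, df$end))
    }
    ko_reads <- function() {
      rows <- list()
      for (i in seq_len(nrow(g))) {
        n <- if (tg$gb_pos[i]) 3L else 5L
        starts <- g$start[i] +
          sort(sample(seq_len(max(g$end[i] - g$start[i] - read_len, 1L)),
                      n))
        rows[[i]] <- data.frame(chrom = g$chrom[i], start = starts,
                                end = starts + read_len - 1L,
                                stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      GRanges(df$chrom, IRanges(df$start, df$end))
    }
    k79_reads <- list(
      ctrl = list(rep1 = gb_reads(0L), rep2 = gb_reads(25L)),
      ko = list(rep1 = ko_reads(), rep2 = ko_reads()))

    gb_idx <- which(tg$gb_pos)
    gb_span_end <- g$start[gb_idx] +
      round(tg$gb_fraction[gb_idx] * (g$end[gb_idx] - g$start[gb_idx] + 1L)) - 1L
    k79_peaks_ctrl <- GRanges(g$chrom[gb_idx],
                              IRanges(g$start[gb_idx], gb_span_end))
    k79_peaks_ko <- GRanges()

    # differential H3K79me2: lost gene-body signal + half of each K79-RE
    k79_re <- res[res$type %in% c("k79_activating", "k79_silencing"), ,
                  drop = FALSE]
    re_half <- GRanges(k79_re$chrom,
                       IRanges(k79_re$start,
                               k79_re$start +
                                 (k79_re$end - k79_re$start + 1L) %/% 2 - 1L))
    diff_k79 <- c(granges(k79_peaks_ctrl), re_half)
    diff_k79$name <- rep("down", length(diff_k79))

    half_cover <- function(sub) {
      if (nrow(sub) == 0) return(GRanges())
      GRanges(sub$chrom,
              IRanges(sub$start,
                      sub$start + (sub$end - sub$start + 1L) %/% 2 - 1L))
    }
    diff_k27_up <- half_cover(res[res$diff_k27 == "up", , drop = FALSE])
    diff_k27_down <- half_cover(res[res$diff_k27 == "down", , drop = FALSE])

    signal <- rlnorm(nrow(res), cfg$peak_signal_meanlog,
                     cfg$peak_signal_sdlog)
    mk_peaks <- function(keep, fold) {
      sub <- res[keep, , drop = FALSE]
      gr <- GRanges(sub$chrom, IRanges(sub$start, sub$end))
      gr$name <- sub$re_id
      gr$signal_value <- signal[keep] * fold[keep]
      gr
    }
    fold_ko <- ifelse(res$diff_k27 == "up", 2,
                      ifelse(res$diff_k27 == "down", 0.5, 1))
    k27_peaks_ctrl <- mk_peaks(!res$ko_only, rep(1, nrow(res)))
    k27_peaks_ko <- mk_peaks(rep(TRUE, nrow(res)), fold_ko)

    list(k27_peaks_ctrl = k27_peaks_ctrl, k27_peaks_ko = k27_peaks_ko,
         k79_reads = k79_reads, k79_peaks_ctrl = k79_peaks_ctrl,
         k79_peaks_ko = k79_peaks_ko, diff_k79 = diff_k79,
         diff_k27_up = diff_k27_up, diff_k27_down = diff_k27_down)
  })
}

#' Generate binned Hi-C contact matrices with planted loops
#'
#' Contacts between bins at distance `d` are Poisson with mean
#' `mu0 * (d+1)^-decay`; bin pairs joining a planted RE to its target
#' gene's TSS receive a `loop_boost`-fold boosted mean. Matrices are
#' generated for autosomes only (the downstream ABC analysis excludes
#' sex chromosomes).
#'
#' @param cfg a `truth_config`.
#' @param genome output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @return named list of raw-count `contact_matrix` objects.
#' @export
simulate_hic <- function(cfg, genome, truth) {
  .with_seed(cfg$seed + 404L, {
    res <- truth$res
    g <- genome$gm$genes
    out <- list()
    for (chrom in .autosomes(genome$chrom_sizes)) {
      n <- genome$chrom_sizes[[chrom]] %/% cfg$resolution
      ii <- list(); jj <- list(); xx <- list()
      for (d in 0:(n - 1L)) {
        mu <- cfg$hic_mu0 / (d + 1)^cfg$hic_decay
        cnt <- rpois(n - d, mu)
        nz <- which(cnt > 0)
        if (length(nz) > 0) {
          ii[[length(ii) + 1L]] <- nz
          jj[[length(jj) + 1L]] <- nz + d
          xx[[length(xx) + 1L]] <- cnt[nz]
        }
      }
      # boosted loops between planted REs and their target promoters
      looped <- res[res$chrom == chrom &
                      (res$type != "plain" | res$ko_only), , drop = FALSE]
      if (nrow(looped) > 0) {
        mid0 <- (looped$start - 1L + looped$end) %/% 2
        be <- mid0 %/% cfg$resolution + 1L
        bg <- (g$tss[match(looped$gene_id, g$gene_id)] - 1L) %/%
          cfg$resolution + 1L
        d <- abs(be - bg)
        extra <- rpois(nrow(looped),
                       (cfg$loop_boost - 1) * cfg$hic_mu0 /
                         (d + 1)^cfg$hic_decay)
        keep <- extra > 0
        if (any(keep)) {
          ii[[length(ii) + 1L]] <- pmin(be, bg)[keep]
          jj[[length(jj) + 1L]] <- pmax(be, bg)[keep]
          xx[[length(xx) + 1L]] <- extra[keep]
        }
      }
      i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
      off <- i != j
      counts <- Matrix::sparseMatrix(
        i = c(i, j[off]), j = c(j, i[off]), x = c(x, x[off]),
        dims = c(n, n))
      out[[chrom]] <- .new_contact_matrix(chrom, cfg$resolution, n,
                                          counts)
    }
    out
  })
}

#' Generate the differential-expression table
#'
#' Simulates replicate RNA-seq counts per condition (negative binomial
#' around the class-planted fold change), then performs its own simple
#' differential test (Welch t on log2 counts, BH adjustment) so the
#' analysis pipeline stays a consumer of an upstream DE table.
#'
#' @param cfg a `truth_config`.
#' @param genome output of [simulate_genome()].
#' @param truth output of [simulate_truth()].
#' @return data.frame with `gene_id`, `rpkm_ctrl`, `rpkm_ko`, `log2fc`,
#'   `fdr`.
#' @export
simulate_expression <- function(cfg, genome, truth) {
  .with_seed(cfg$seed + 505L, {
    g <- genome$gm$genes
    n <- nrow(g)
    base_rpkm <- rlnorm(n, cfg$rpkm_meanlog, cfg$rpkm_sdlog)
    scale <- (g$exon_length_sum / 1000) * (cfg$library_size / 1e6)
    mu_ctrl <- base_rpkm * scale
    mu_ko <- mu_ctrl * 2^truth$genes$true_log2fc
    r <- cfg$n_reps
    counts_ctrl <- matrix(rnbinom(n * r, mu = rep(mu_ctrl, r),
                                  size = 1 / cfg$dispersion), ncol = r)
    counts_ko <- matrix(rnbinom(n * r, mu = rep(mu_ko, r),
                                size = 1 / cfg$dispersion), ncol = r)
    lc <- log2(counts_ctrl + 1)
    lk <- log2(counts_ko + 1)
    m1 <- rowMeans(lc); m2 <- rowMeans(lk)
    v1 <- apply(lc, 1, stats::var); v2 <- apply(lk, 1, stats::var)
    # moderated test: under a common NB dispersion the log-scale variance
    # is shared across well-expressed genes, so the per-gene variance is
    # shrunk to the genome-wide mean (emulating dispersion shrinkage in
    # standard DE tools); residual degrees of freedom are then large and
    # a normal reference applies
    v_pool <- mean(c(v1, v2), na.rm = TRUE)
    se <- sqrt(2 * v_pool / r)
    zstat <- (m2 - m1) / se
    pval <- 2 * stats::pnorm(-abs(zstat))
    pval[!is.finite(pval)] <- 1
    data.frame(
      gene_id = g$gene_id,
      rpkm_ctrl = rowMeans(counts_ctrl) / scale,
      rpkm_ko = rowMeans(counts_ko) / scale,
      log2fc = log2((rowMeans(counts_ko) + 0.5) /
                      (rowMeans(counts_ctrl) + 0.5)),
      fdr = stats::p.adjust(pval, method = "BH"),
      stringsAsFactors = FALSE)
  })
}

#' Generate RE sequences and the PWM set
#'
#' Every RE gets a random sequence of its own length; silencing K79-REs
#' additionally receive planted copies of the silencing-motif consensus
#' at random non-overlapping positions and strands. The PWM set contains
#' the planted motif plus random decoys, all named by gene ids of
#' well-expressed genes so the expressed-TF filter can resolve them.
#'
#' @param cfg a `truth_config`.
#' @param truth output of [simulate_truth()].
#' @param expr optional expression table used to pick expressed gene ids
#'   as TF names; defaults to arbitrary gene ids.
#' @return list with `seqs` (`DNAStringSet` named by `re_id`), `pwms`
#'   (named list of `trap_pwm`), `planted_tf` (name of the planted
#'   silencing-motif TF).
#' @export
simulate_re_sequences <- function(cfg, truth, expr = NULL) {
  .with_seed(cfg$seed + 606L, {
    res <- truth$res
    bases <- c("A", "C", "G", "T")
    widths <- res$end - res$start + 1L
    seqs <- vapply(widths, function(w) {
      paste(sample(bases, w, replace = TRUE), collapse = "")
    }, character(1))
    motif <- toupper(cfg$motif_consensus)
    wm <- nchar(motif)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(motif)))
    sil <- which(res$type == "k79_silencing")
    for (i in sil) {
      w <- widths[i]
      slot_w <- wm + 5L
      n_slots <- w %/% slot_w
      k <- min(cfg$n_motif_sites, n_slots)
      if (k == 0) next
      slots <- sample(n_slots, k)
      s <- seqs[i]
      for (sl in slots) {
        at <- (sl - 1L) * slot_w + 1L
        ins <- if (runif(1) < 0.5) motif else rc
        substr(s, at, at + wm - 1L) <- ins
      }
      seqs[i] <- s
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- res$re_id

    # planted PWM: strongly consensus-biased counts
    idx <- match(strsplit(motif, "")[[1]], bases)
    planted_counts <- matrix(5, nrow = 4, ncol = wm)
    planted_counts[cbind(idx, seq_len(wm))] <- 85
    tf_pool <- if (!is.null(expr)) {
      expr$gene_id[pmax(expr$rpkm_ctrl, expr$rpkm_ko) >= 2]
    } else {
      unique(truth$genes$gene_id)
    }
    tf_names <- sample(tf_pool, cfg$n_decoy_pwms + 1L)
    pwms <- list()
    pwms[[tf_names[1]]] <- pwm_from_counts(planted_counts, tf_names[1])
    for (k in seq_len(cfg$n_decoy_pwms)) {
      wd <- sample(8:12, 1)
      cm <- vapply(seq_len(wd), function(j) {
        as.numeric(stats::rmultinom(1, 100, runif(4) + 0.1)[, 1])
      }, numeric(4))
      pwms[[tf_names[k + 1]]] <- pwm_from_counts(cm, tf_names[k + 1])
    }
    list(seqs = dna, pwms = pwms, planted_tf = tf_names[1])
  })
}

#' Generate the full synthetic dataset on disk
#'
#' Runs every generator stage and writes the complete set of pipeline
#' inputs (GTF, chromosome sizes, narrowPeak and BED files, Hi-C triplet
#' dumps, DE table, RE FASTA, JASPAR PWMs) plus the ground-truth tables,
#' all deterministically from the configuration.
#'
#' @param cfg a `truth_config`.
#' @param dir output directory (created if needed).
#' @return list with `paths` (named list of file paths), `truth`,
#'   `planted_tf`, `cfg`, and the in-memory `genome`.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "hic"), showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  truth <- simulate_truth(cfg, genome)
  peaks <- simulate_peaks_and_reads(cfg, genome, truth)
  hic <- simulate_hic(cfg, genome, truth)
  expr <- simulate_expression(cfg, genome, truth)
  seqs <- simulate_re_sequences(cfg, truth, expr)

  p <- list(
    gtf = file.path(dir, "genes.gtf"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    k27_peaks_ctrl = file.path(dir, "k27_ctrl.narrowPeak"),
    k27_peaks_ko = file.path(dir, "k27_ko.narrowPeak"),
    k79_reads_ctrl = c(file.path(dir, "k79_ctrl_rep1.bed"),
                       file.path(dir, "k79_ctrl_rep2.bed")),
    k79_reads_ko = c(file.path(dir, "k79_ko_rep1.bed"),
                     file.path(dir, "k79_ko_rep2.bed")),
    diff_k79 = file.path(dir, "diff_k79.bed"),
    diff_k27_up = file.path(dir, "diff_k27_up.bed"),
    diff_k27_down = file.path(dir, "diff_k27_down.bed"),
    hic_dir = file.path(dir, "hic"),
    de_table = file.path(dir, "expression.tsv"),
    re_fasta = file.path(dir, "re_sequences.fasta"),
    pwms = file.path(dir, "pwms.jaspar"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_res = file.path(dir, "truth_res.tsv"))

  write_gtf(genome$gm, p$gtf)
  write_chrom_sizes(genome$chrom_sizes, p$chrom_sizes)
  write_narrowpeak(peaks$k27_peaks_ctrl, p$k27_peaks_ctrl)
  write_narrowpeak(peaks$k27_peaks_ko, p$k27_peaks_ko)
  write_bed(peaks$k79_reads$ctrl$rep1, p$k79_reads_ctrl[1])
  write_bed(peaks$k79_reads$ctrl$rep2, p$k79_reads_ctrl[2])
  write_bed(peaks$k79_reads$ko$rep1, p$k79_reads_ko[1])
  write_bed(peaks$k79_reads$ko$rep2, p$k79_reads_ko[2])
  write_bed(peaks$diff_k79, p$diff_k79)
  write_bed(peaks$diff_k27_up, p$diff_k27_up)
  write_bed(peaks$diff_k27_down, p$diff_k27_down)
  for (chrom in names(hic)) {
    write_contact_triplets(hic[[chrom]],
                           file.path(p$hic_dir, paste0(chrom, ".txt")))
  }
  write_tsv(expr, p$de_table)
  Biostrings::writeXStringSet(seqs$seqs, p$re_fasta)
  write_jaspar(seqs$pwms, p$pwms)
  write_tsv(truth$genes, p$truth_genes)
  write_tsv(truth$res, p$truth_res)

  list(paths = p, truth = truth, planted_tf = seqs$planted_tf,
       cfg = cfg, genome = genome)
}
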