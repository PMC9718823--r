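#' Fraction of a regulatory element covered by differential signal
#'
#' Computes, per RE, the fraction of its length overlapped by the union
#' of a set of differential ChIP-seq peaks.
#'
#' @param re `GRanges` of regulatory elements.
#' @param diff_peaks `GRanges` of differential peaks.
#' @return numeric vector in `[0,1]`, one value per RE.
#' @export
differential_overlap_fraction <- function(re, diff_peaks) {
  if (length(re) > 0 && any(width(re) == 0)) {
    stop("zero-length regulatory element")
  }
  out <- numeric(length(re))
  if (length(re) == 0 || length(diff_peaks) == 0) return(out)
  red <- reduce(unstrand(diff_peaks))
  ov <- findOverlaps(unstrand(re), red, ignore.strand = TRUE)
  if (length(ov) > 0) {
    w <- as.numeric(width(pintersect(unstrand(re)[queryHits(ov)],
                                     red[subjectHits(ov)])))
    agg <- rowsum(w, queryHits(ov))
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out / as.numeric(width(re))
}

#' Flag regulatory elements by differential ChIP-seq overlap
#'
#' An RE is a K79-RE when at least `min_overlap` (default 10%) of its
#' length is covered by differential H3K79me2 signal; it is differential
#' for H3K27ac (up or down) by the same rule. An RE covered by both
#' up- and down-regulated H3K27ac signal is labeled by the larger covered
#' fraction, with ties going to `down`.
#'
#' @param res `GRanges` of ABC-surviving H3K27ac peaks.
#' @param diff_k79 `GRanges` of differential H3K79me2 peaks.
#' @param diff_k27_up,diff_k27_down `GRanges` of differential H3K27ac
#'   peaks by direction.
#' @param promoters optional `GRanges` of promoters for the
#'   promoter-overlap flag.
#' @param min_overlap covered-fraction threshold, inclusive (default 0.10).
#' @return data.frame with `re_id`, `chrom`, `start`, `end`, `is_k79_re`,
#'   `k27_diff` (`none`/`up`/`down`), `overlaps_promoter`.
#' @export
flag_res <- function(res, diff_k79, diff_k27_up = GRanges(),
                     diff_k27_down = GRanges(), promoters = NULL,
                     min_overlap = 0.10) {
  f79 <- differential_overlap_fraction(res, diff_k79)
  fup <- differential_overlap_fraction(res, diff_k27_up)
  fdn <- differential_overlap_fraction(res, diff_k27_down)
  k27 <- rep("none", length(res))
  up_hit <- fup >= min_overlap
  dn_hit <- fdn >= min_overlap
  k27[up_hit & fup > fdn] <- "up"
  k27[dn_hit & fdn >= fup] <- "down"
  op <- if (is.null(promoters)) rep(NA, length(res)) else
    overlapsAny(res, promoters, ignore.strand = TRUE)
  data.frame(re_id = interval_id(res),
             chrom = as.character(seqnames(res)),
             start = start(res), end = end(res),
             is_k79_re = f79 >= min_overlap,
             k27_diff = k27,
             overlaps_promoter = op,
             stringsAsFactors = FALSE)
}

#' Map differential-H3K27ac REs to genes
#'
#' An RE with a significant H3K27ac change is accounted to every gene it
#' interacts with in the control regulatory map. REs with no control
#' interaction at all (present only in the knockout map) are accounted to
#' the genes they interact with in the knockout. An RE interacting in
#' both conditions contributes only through its control links.
#'
#' @param re_flags data.frame from [flag_res()] (the `k27_diff` column
#'   selects the differential REs).
#' @param interactions_ctrl,interactions_ko filtered interaction tables
#'   (see [filter_interactions()]) for the two conditions.
#' @return data.frame with `gene_id`, `n_diff_k27_res` (distinct
#'   differential REs accounted to the gene) and
#'   `diff_k27_directions` (comma-separated directions involved).
#' @export
map_diff_k27_to_genes <- function(re_flags, interactions_ctrl,
                                  interactions_ko) {
  diff_res <- re_flags[re_flags$k27_diff != "none", , drop = FALSE]
  if (nrow(diff_res) == 0) {
    return(data.frame(gene_id = character(), n_diff_k27_res = integer(),
                      diff_k27_directions = character(),
                      stringsAsFactors = FALSE))
  }
  ctrl_ids <- unique(interactions_ctrl$re_id)
  pairs <- list()
  for (i in seq_len(nrow(diff_res))) {
    rid <- diff_res$re_id[i]
    genes <- if (rid %in% ctrl_ids) {
      interactions_ctrl$gene_id[interactions_ctrl$re_id == rid]
    } else {
      interactions_ko$gene_id[interactions_ko$re_id == rid]
    }
    if (length(genes) > 0) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = unique(genes), re_id = rid,
        direction = diff_res$k27_diff[i], stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(gene_id = character(), n_diff_k27_res = integer(),
                      diff_k27_directions = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, pairs)
  agg_n <- tapply(tab$re_id, tab$gene_id, function(x) length(unique(x)))
  agg_d <- tapply(tab$direction, tab$gene_id,
                  function(x) paste(sort(unique(x)), collapse = ","))
  data.frame(gene_id = names(agg_n),
             n_diff_k27_res = as.integer(agg_n),
             diff_k27_directions = as.character(agg_d),
             stringsAsFactors = FALSE)
}

#' Assemble per-gene regulatory profiles
#'
#' Joins, per gene, the DE call, the gene-body H3K79me2 flag, the number
#' of distinct K79-REs linked in the control regulatory map, and the
#' number of linked differential-H3K27ac REs, and derives the UpSet
#' category label.
#'
#' @param expr data.frame with `gene_id`, `log2fc` and `de_status` (from
#'   [assign_de_status()]).
#' @param coverage data.frame with `gene_id`, `read_count`,
#'   `fraction_covered` and logical `gb_k79`.
#' @param interactions_ctrl filtered control interaction table.
#' @param re_flags data.frame from [flag_res()].
#' @param diff_k27_map data.frame from [map_diff_k27_to_genes()].
#' @return data.frame with one row per gene in `expr`: `gene_id`,
#'   `de_status`, `log2fc`, `gb_k79`, `gb_fraction`, `n_k79_res`,
#'   `n_diff_k27_res`, `category`.
#' @export
build_gene_profiles <- function(expr, coverage, interactions_ctrl,
                                re_flags, diff_k27_map = NULL) {
  k79_ids <- re_flags$re_id[re_flags$is_k79_re]
  ik <- interactions_ctrl[interactions_ctrl$re_id %in% k79_ids, ,
                          drop = FALSE]
  n_k79 <- tapply(ik$re_id, ik$gene_id, function(x) length(unique(x)))

  prof <- data.frame(gene_id = expr$gene_id,
                     de_status = as.character(expr$de_status),
                     log2fc = expr$log2fc,
                     stringsAsFactors = FALSE)
  ci <- match(prof$gene_id, coverage$gene_id)
  prof$gb_k79 <- ifelse(is.na(ci), FALSE, coverage$gb_k79[ci])
  prof$gb_fraction <- ifelse(is.na(ci), 0, coverage$fraction_covered[ci])
  prof$n_k79_res <- as.integer(n_k79[prof$gene_id])
  prof$n_k79_res[is.na(prof$n_k79_res)] <- 0L
  if (!is.null(diff_k27_map) && nrow(diff_k27_map) > 0) {
    di <- match(prof$gene_id, diff_k27_map$gene_id)
    prof$n_diff_k27_res <- ifelse(is.na(di), 0L,
                                  diff_k27_map$n_diff_k27_res[di])
  } else {
    prof$n_diff_k27_res <- 0L
  }
  prof$category <- paste0("GB", ifelse(prof$gb_k79, "+", "-"),
                          "RE", ifelse(prof$n_k79_res > 0, "+", "-"),
                          "diffK27",
                          ifelse(prof$n_diff_k27_res > 0, "+", "-"))
  prof
}

#' UpSet-style categorization of differentially expressed genes
#'
#' Counts DE genes per regulatory category (gene-body H3K79me2 x K79-RE
#' linkage, optionally x differential-H3K27ac linkage) within each DE
#' direction, with percentages per direction summing to 100.
#'
#' @param profiles data.frame from [build_gene_profiles()].
#' @param include_diff_k27 include the differential-H3K27ac axis in the
#'   category label (default `TRUE`).
#' @return data.frame with `de_status`, `category`, `n`, `percent`.
#' @export
categorize_genes <- function(profiles, include_diff_k27 = TRUE) {
  de <- profiles[profiles$de_status %in% c("down", "up"), , drop = FALSE]
  cat_lab <- if (include_diff_k27) de$category else
    sub("diffK27[+-]$", "", de$category)
  if (nrow(de) == 0) {
    return(data.frame(de_status = character(), category = character(),
                      n = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(table(de_status = de$de_status, category = cat_lab),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "n"
  totals <- tapply(tab$n, tab$de_status, sum)
  tab$percent <- 100 * tab$n / as.numeric(totals[tab$de_status])
  rownames(tab) <- NULL
  tab[order(tab$de_status, -tab$n), , drop = FALSE]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the KS statistic `D = sup |ECDF_x - ECDF_y|` and a two-sided
#' p-value from the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_x n_y / (n_x + n_y)) * D`.
#'
#' @param x,y numeric samples (each of size >= 1).
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be non-empty")
  grid <- sort(unique(c(x, y)))
  Fx <- findInterval(grid, sort(x)) / n
  Fy <- findInterval(grid, sort(y)) / m
  D <- max(abs(Fx - Fy))
  lambda <- sqrt(n * m / (n + m)) * D
  p <- if (lambda == 0) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(statistic = D, p.value = p)
}

#' Stratified cumulative log2 fold-change analysis
#'
#' Splits genes into strata by (i) gene-body H3K79me2 covered fraction
#' (`<1/3`, `[1/3, 2/3)`, `>=2/3`), (ii) number of linked K79-REs
#' (`0`, `1-5`, `>=6`), and (iii), among gene-body-methylated genes,
#' presence of at least one K79-RE, and compares the log2 fold-change
#' distributions of each pair of strata within a grouping with the
#' two-tailed KS test. Strata with fewer than 2 genes are skipped with a
#' warning.
#'
#' @param profiles data.frame from [build_gene_profiles()]; only genes
#'   with `de_status != "not_expressed"` enter the analysis.
#' @return list with `strata` (named list of per-stratum log2fc vectors)
#'   and `ks` (data.frame: `grouping`, `stratum_a`, `stratum_b`, `n_a`,
#'   `n_b`, `D`, `p_value`).
#' @export
stratified_cdf_analysis <- function(profiles) {
  p <- profiles[profiles$de_status != "not_expressed" &
                  !is.na(profiles$log2fc), , drop = FALSE]
  gb_bins <- cut(p$gb_fraction, c(-Inf, 1 / 3, 2 / 3, Inf), right = FALSE,
                 labels = c("gb_frac_lt_1_3", "gb_frac_1_3_to_2_3",
                            "gb_frac_ge_2_3"))
  re_bins <- cut(p$n_k79_res, c(-Inf, 0.5, 5.5, Inf),
                 labels = c("k79_re_0", "k79_re_1_5", "k79_re_ge_6"))
  groupings <- list(
    gb_fraction = split(p$log2fc, gb_bins),
    k79_re_count = split(p$log2fc, re_bins),
    gb_pos_by_re = split(p$log2fc[p$gb_k79],
                         ifelse(p$n_k79_res[p$gb_k79] > 0,
                                "gb_pos_with_k79_re", "gb_pos_no_k79_re")))
  rows <- list()
  strata <- list()
  for (gname in names(groupings)) {
    gl <- groupings[[gname]]
    strata[names(gl)] <- gl
    small <- names(gl)[lengths(gl) < 2]
    if (length(small) > 0) {
      warning("stratum too small for KS (", paste(small, collapse = ", "),
              ") in grouping ", gname)
    }
    ok <- names(gl)[lengths(gl) >= 2]
    if (length(ok) < 2) next
    cmb <- utils::combn(ok, 2)
    for (ci in seq_len(ncol(cmb))) {
      a <- cmb[1, ci]; b <- cmb[2, ci]
      ks <- ks_two_sample(gl[[a]], gl[[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        grouping = gname, stratum_a = a, stratum_b = b,
        n_a = length(gl[[a]]), n_b = length(gl[[b]]),
        D = ks$statistic, p_value = ks$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(strata = strata,
       ks = if (length(rows) > 0) do.call(rbind, rows) else
         data.frame(grouping = character(), stratum_a = character(),
                    stratum_b = character(), n_a = integer(),
                    n_b = integer(), D = numeric(), p_value = numeric(),
                    stringsAsFactors = FALSE))
}

#' Odds ratio of differential-peak overlap from marginal counts
#'
#' Reconstructs the 2x2 table of (direction of differential H3K27ac
#' change) x (overlap with a differential H3K79me2 peak) from the peak
#' counts and overlap fractions, and returns the odds ratio of overlap
#' for upregulated versus downregulated peaks.
#'
#' @param n_up,n_down numbers of up- and downregulated differential
#'   H3K27ac peaks.
#' @param frac_down_overlap fraction of downregulated peaks overlapping a
#'   differential H3K79me2 peak.
#' @param frac_up_nonoverlap fraction of upregulated peaks not
#'   overlapping one.
#' @return list with `table` (2x2 integer matrix) and `odds_ratio`.
#' @export
diff_peak_overlap_odds <- function(n_up, n_down, frac_down_overlap,
                                   frac_up_nonoverlap) {
  up_non <- round(n_up * frac_up_nonoverlap)
  up_ov <- n_up - up_non
  down_ov <- round(n_down * frac_down_overlap)
  down_non <- n_down - down_ov
  tab <- matrix(c(up_ov, up_non, down_ov, down_non), nrow = 2,
                dimnames = list(c("overlap", "no_overlap"),
                                c("k27_up", "k27_down")))
  list(table = tab,
       odds_ratio = (up_ov * down_non) / (up_non * down_ov))
}
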