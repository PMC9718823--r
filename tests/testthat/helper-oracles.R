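# independent brute-force oracles; each recomputes a quantity by direct
# enumeration, never through the implementation under test

# per-base feature label with explicit precedence over every base
oracle_feature_labels <- function(gm, chrom_sizes) {
  labels <- list()
  for (chrom in names(chrom_sizes)) {
    lab <- rep("intergenic", chrom_sizes[[chrom]])
    g <- gm$genes[gm$genes$chrom == chrom, , drop = FALSE]
    on_chrom <- function(gr) gr[as.character(seqnames(gr)) == chrom]
    for (i in seq_len(nrow(g))) {
      lab[g$start[i]:g$end[i]] <- "intron"
    }
    ex <- on_chrom(gm$exons)
    for (i in seq_along(ex)) lab[start(ex)[i]:end(ex)[i]] <- "exon"
    ut <- on_chrom(gm$utrs)
    for (i in seq_along(ut)) lab[start(ut)[i]:end(ut)[i]] <- "utr"
    for (i in seq_len(nrow(g))) {
      s <- max(1, g$promoter_start[i])
      e <- min(chrom_sizes[[chrom]], g$promoter_end[i])
      lab[s:e] <- "promoter_tss"
    }
    labels[[chrom]] <- lab
  }
  labels
}

# re-derive intron/exon conflicts across overlapping genes: precedence
# must hold jointly, so exon of any gene beats intron of any other
oracle_feature_labels_joint <- function(gm, chrom_sizes) {
  labels <- list()
  for (chrom in names(chrom_sizes)) {
    n <- chrom_sizes[[chrom]]
    rank <- rep(5L, n) # 1 promoter, 2 utr, 3 exon, 4 intron, 5 intergenic
    g <- gm$genes[gm$genes$chrom == chrom, , drop = FALSE]
    mark <- function(s, e, r) {
      s <- max(1, s); e <- min(n, e)
      if (s <= e) {
        idx <- s:e
        rank[idx] <<- pmin(rank[idx], r)
      }
    }
    for (i in seq_len(nrow(g))) mark(g$start[i], g$end[i], 4L)
    ex <- gm$exons[as.character(seqnames(gm$exons)) == chrom]
    for (i in seq_along(ex)) mark(start(ex)[i], end(ex)[i], 3L)
    ut <- gm$utrs[as.character(seqnames(gm$utrs)) == chrom]
    for (i in seq_along(ut)) mark(start(ut)[i], end(ut)[i], 2L)
    for (i in seq_len(nrow(g))) {
      mark(g$promoter_start[i], g$promoter_end[i], 1L)
    }
    labels[[chrom]] <- c("promoter_tss", "utr", "exon", "intron",
                         "intergenic")[rank]
  }
  labels
}

# per-base union coverage of a gene body
oracle_body_coverage <- function(reads, body_start, body_end) {
  covered <- rep(FALSE, body_end - body_start + 1)
  count <- 0L
  for (i in seq_along(reads$start)) {
    s <- reads$start[i]; e <- reads$end[i]
    if (e >= body_start && s <= body_end) {
      count <- count + 1L
      lo <- max(s, body_start) - body_start + 1
      hi <- min(e, body_end) - body_start + 1
      covered[lo:hi] <- TRUE
    }
  }
  list(count = count, fraction = mean(covered))
}

# symmetric Sinkhorn iteration run to very high precision
oracle_sinkhorn <- function(A, tol = 1e-10, max_iter = 2e5) {
  x <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    r <- as.numeric(A %*% x)
    x <- sqrt(x / r)
    s <- x * as.numeric(A %*% x)
    if (max(abs(s - 1)) < tol) break
  }
  x
}

# two-loop ABC scoring over explicit enhancer/gene lists
# enhancers: data.frame(id, activity, bin); genes: data.frame(id, bin);
# contact_fn(bin_a, bin_b) -> frequency; in_window[e, g] logical matrix
oracle_abc <- function(enhancers, genes, contact_fn, in_window) {
  scores <- matrix(0, nrow(enhancers), nrow(genes),
                   dimnames = list(enhancers$id, genes$id))
  a_eg <- matrix(0, nrow(enhancers), nrow(genes))
  for (e in seq_len(nrow(enhancers))) {
    targets <- which(in_window[e, ])
    csum <- sum(vapply(targets, function(g) {
      contact_fn(enhancers$bin[e], genes$bin[g])
    }, numeric(1)))
    for (g in targets) {
      c_eg <- contact_fn(enhancers$bin[e], genes$bin[g])
      a_eg[e, g] <- if (csum > 0) enhancers$activity[e] * c_eg / csum else 0
    }
  }
  for (g in seq_len(nrow(genes))) {
    cands <- which(in_window[, g])
    denom <- sum(vapply(cands, function(e) {
      a_eg[e, g] * contact_fn(enhancers$bin[e], genes$bin[g])
    }, numeric(1)))
    for (e in cands) {
      w <- a_eg[e, g] * contact_fn(enhancers$bin[e], genes$bin[g])
      scores[e, g] <- if (denom > 0) w / denom else 0
    }
  }
  scores
}

# exact one-tailed Mann-Whitney p by enumeration of all label splits
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(av, bv) {
    sum(vapply(av, function(x) {
      sum(x > bv) + 0.5 * sum(x == bv)
    }, numeric(1)))
  }
  u_obs <- u_of(a, b)
  splits <- utils::combn(length(pooled), na)
  us <- apply(splits, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs, p = mean(us >= u_obs - 1e-9))
}

# KS D by brute-force evaluation of both ECDFs on a fine grid
oracle_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}

# TRAP affinity by direct per-window evaluation on both strands
oracle_trap <- function(prob, seq, lambda = 0.7, ln_r0 = NULL) {
  W <- ncol(prob)
  if (is.null(ln_r0)) ln_r0 <- 0.584 * W - 5.66
  r0 <- exp(ln_r0)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  one_strand <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n_win <- length(ch) - W + 1
    if (n_win < 1) return(0)
    tot <- 0
    for (i in seq_len(n_win)) {
      win <- ch[i:(i + W - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      E <- 0
      for (j in seq_len(W)) {
        E <- E + log(max(prob[, j]) / prob[win[j], j])
      }
      E <- E / lambda
      tot <- tot + r0 * exp(-E) / (1 + r0 * exp(-E))
    }
    tot
  }
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  one_strand(seq) + one_strand(rc)
}
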