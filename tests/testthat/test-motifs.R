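uniform_pwm <- function(W, name = "uni") {
  pwm_from_counts(matrix(1, 4, W), name, pseudocount = 0)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("PWM construction pseudocounts and normalizes columns", {
  counts <- matrix(c(8, 0, 0, 0,
                     0, 8, 0, 0), nrow = 4)
  p <- pwm_from_counts(counts, "tf")
  expect_equal(colSums(p$prob), c(1, 1))
  expect_true(all(p$prob > 0))
  expect_equal(unname(p$prob[1, 1]), 9 / 12)
})

test_that("JASPAR reading round-trips written PWM sets", {
  pwms <- list(tf_a = matrix(c(8, 1, 1, 0), 4, 3),
               tf_b = matrix(5, 4, 6))
  path <- tempfile()
  write_jaspar(pwms, path)
  got <- read_jaspar(path)
  expect_setequal(names(got), c("tf_a", "tf_b"))
  expect_equal(got$tf_a$width, 3)
  expect_equal(got$tf_b$width, 6)
  expect_equal(colSums(got$tf_a$prob), rep(1, 3))
})

test_that("TRAP affinity: uniform-PWM closed form and direct oracle", {
  W <- 6
  pwm <- uniform_pwm(W)
  L <- 50
  seq <- random_seq(L, 1)
  r0 <- exp(0.584 * W - 5.66)
  want <- 2 * (L - W + 1) * r0 / (1 + r0)
  expect_equal(trap_affinity(pwm, seq), want, tolerance = 1e-12)

  # sharp PWM with one consensus hit: direct per-window oracle
  counts <- matrix(1, 4, 8)
  consensus <- c(1, 3, 2, 4, 1, 1, 3, 2) # ACGT indices
  counts[cbind(consensus, 1:8)] <- 96
  pwm2 <- pwm_from_counts(counts, "sharp")
  hit <- paste(c("A", "C", "G", "T")[consensus], collapse = "")
  seq2 <- paste0(substr(random_seq(30, 2), 1, 30), hit,
                 substr(random_seq(30, 3), 1, 30))
  expect_equal(trap_affinity(pwm2, seq2),
               unname(oracle_trap(pwm2$prob, seq2)), tolerance = 1e-10)
  # the planted hit dominates the affinity
  expect_gt(trap_affinity(pwm2, seq2),
            0.9 * trap_affinity(pwm2, hit))
})

test_that("TRAP affinity is strand-symmetric and handles N and short input", {
  pwm <- pwm_from_counts(matrix(c(9, 1, 1, 1), 4, 5), "tf")
  s <- random_seq(40, 4)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s)))
  expect_equal(trap_affinity(pwm, s), trap_affinity(pwm, rc),
               tolerance = 1e-12)
  # N windows contribute zero
  with_n <- paste0(substr(s, 1, 10), "NNNNN", substr(s, 16, 40))
  expect_lt(trap_affinity(pwm, with_n), trap_affinity(pwm, s) + 1e-12)
  expect_warning(zero <- trap_affinity(pwm, "ACG"), "shorter")
  expect_equal(zero, 0)
})

test_that("affinity is additive over concatenation up to boundary windows", {
  pwm <- uniform_pwm(5)
  a <- random_seq(30, 5)
  b <- random_seq(25, 6)
  whole <- trap_affinity(pwm, paste0(a, b))
  parts <- trap_affinity(pwm, a) + trap_affinity(pwm, b)
  r0 <- exp(0.584 * 5 - 5.66)
  # exactly W-1 = 4 extra windows per strand for the uniform PWM
  expect_equal(whole - parts, 2 * 4 * r0 / (1 + r0), tolerance = 1e-12)
})

test_that("expressed-TF filter keeps RPKM >= 1 inclusive", {
  pwms <- list(tf1 = uniform_pwm(4, "tf1"), tf2 = uniform_pwm(4, "tf2"),
               tf3 = uniform_pwm(4, "tf3"))
  expr <- data.frame(gene_id = c("tf1", "tf2"),
                     rpkm_ctrl = c(1.0, 0.3), rpkm_ko = c(0.2, 0.9))
  expect_warning(kept <- filter_expressed_tfs(pwms, expr),
                 "not resolvable")
  expect_equal(names(kept), "tf1")
})

test_that("Mann-Whitney matches exact enumeration for all n <= 5", {
  expect_equal(mann_whitney_one_tailed(c(3, 4), c(1, 2)),
               list(U = 4, p.value = 1 / 6), tolerance = 1e-12)
  got_rev <- mann_whitney_one_tailed(c(1, 2), c(3, 4))
  want_rev <- oracle_mw_exact(c(1, 2), c(3, 4))
  expect_equal(got_rev$p.value, want_rev$p, tolerance = 1e-12)

  set.seed(23)
  for (na in 1:5) {
    for (nb in 1:5) {
      for (rep in 1:8) {
        # continuous draws avoid ties so the exact path is exercised
        a <- round(rnorm(na), 6)
        b <- round(rnorm(nb), 6)
        got <- mann_whitney_one_tailed(a, b)
        want <- oracle_mw_exact(a, b)
        expect_equal(unname(got$U), want$U)
        expect_equal(got$p.value, want$p, tolerance = 1e-12)
      }
    }
  }
  # identical samples
  expect_gte(mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3))$p.value,
             0.5)
  expect_equal(mann_whitney_one_tailed(c(2, 2), c(2, 2))$p.value, 1)
})

test_that("BH adjustment follows the step-up rule and keeps 0.05 inclusive", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_true(bh_adjust(0.05) <= 0.05)
  p <- c(0.001, 0.04, 0.2, 0.8)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("planted motif is recovered by the enrichment analysis", {
  set.seed(31)
  motif <- "TGACGTCATC"
  counts <- matrix(5, 4, nchar(motif))
  idx <- match(strsplit(motif, "")[[1]], c("A", "C", "G", "T"))
  counts[cbind(idx, seq_len(nchar(motif)))] <- 85
  pwms <- list(planted = pwm_from_counts(counts, "planted"))
  for (k in 1:5) {
    cm <- vapply(1:9, function(j) as.numeric(rmultinom(1, 100,
                                                       runif(4) + 0.1)),
                 numeric(4))
    pwms[[paste0("decoy", k)]] <- pwm_from_counts(cm, paste0("decoy", k))
  }
  mk_group <- function(n, plant) {
    vapply(seq_len(n), function(i) {
      s <- random_seq(300, 1000 + plant * 100 + i)
      if (plant) {
        for (at in c(11, 61, 111, 161, 211)) {
          substr(s, at, at + nchar(motif) - 1) <- motif
        }
      }
      s
    }, character(1))
  }
  act <- mk_group(15, FALSE)
  sil <- mk_group(15, TRUE)
  res <- motif_enrichment(pwms, act, sil)
  best <- res$tf[order(res$p_adj_silencing)][1]
  expect_equal(best, "planted")
  expect_true(res$significant[res$tf == "planted"])
  expect_equal(res$direction[res$tf == "planted"], "silencing")
})
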