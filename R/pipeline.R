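#' Assemble a pipeline configuration
#'
#' Collects the input paths and analysis parameters of the integrative
#' pipeline. Defaults reproduce the reference settings: 5 Mb candidate
#' window, 5 kb Hi-C bins, adapted ABC score threshold 0.02, gene-body
#' thresholds of 50 reads and 20% coverage, the 10% differential-overlap
#' rule, and the RPKM/log2FC/FDR expression filters.
#'
#' @param gtf,chrom_sizes,de_table single input paths.
#' @param k79_reads_ctrl,k79_reads_ko character vectors of replicate
#'   read BED paths.
#' @param k27_peaks_ctrl,k27_peaks_ko narrowPeak paths per condition.
#' @param diff_k79,diff_k27_up,diff_k27_down differential-peak BED paths.
#' @param hic_dir directory containing one `<chrom>.txt` triplet dump
#'   per autosome.
#' @param pwms,re_fasta optional motif-analysis inputs (JASPAR PFMs and
#'   RE sequences named by `re_id`).
#' @param window,resolution,abc_threshold,gb_min_reads,gb_min_fraction
#'   core analysis parameters.
#' @param diff_overlap minimum differential-signal overlap fraction.
#' @param de_min_rpkm,de_min_lfc,de_max_fdr expression-filter thresholds.
#' @param motif_alpha adjusted-p threshold for motif significance.
#' @param prenormalized treat Hi-C dumps as already balanced.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, chrom_sizes, k79_reads_ctrl,
                            k79_reads_ko, k27_peaks_ctrl, k27_peaks_ko,
                            diff_k79, diff_k27_up, diff_k27_down,
                            hic_dir, de_table, pwms = NULL,
                            re_fasta = NULL,
                            window = 5e6, resolution = 5000,
                            abc_threshold = 0.02, gb_min_reads = 50,
                            gb_min_fraction = 0.2, diff_overlap = 0.10,
                            de_min_rpkm = 1, de_min_lfc = 0.5,
                            de_max_fdr = 0.05, motif_alpha = 0.05,
                            prenormalized = FALSE, seed = 0) {
  cfg <- as.list(environment())
  if (window %% resolution != 0) {
    warning("window is not a multiple of the Hi-C resolution")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.check_inputs <- function(config) {
  fields <- c("gtf", "chrom_sizes", "k79_reads_ctrl", "k79_reads_ko",
              "k27_peaks_ctrl", "k27_peaks_ko", "diff_k79",
              "diff_k27_up", "diff_k27_down", "hic_dir", "de_table")
  for (f in fields) {
    paths <- config[[f]]
    if (is.null(paths)) stop("pipeline config field missing: ", f)
    for (pp in paths) {
      if (!file.exists(pp)) {
        stop("input for field '", f, "' not found: ", pp)
      }
    }
  }
  for (f in c("pwms", "re_fasta")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("input for field '", f, "' not found: ", config[[f]])
    }
  }
  invisible(TRUE)
}

#' Run the integrative H3K79me2 pipeline
#'
#' Executes every stage in order: genomic feature distribution of the
#' differential H3K79me2 peaks, per-gene gene-body coverage and
#' classification, Hi-C loading and Knight-Ruiz balancing, adapted ABC
#' interaction scoring per condition, K79-RE and differential-H3K27ac RE
#' flagging, per-gene regulatory profiles and UpSet categorization,
#' stratified cumulative log2FC comparisons with KS tests, and (when
#' motif inputs are given) TRAP motif enrichment. Each stage writes one
#' TSV into `out_dir`; a JSON manifest records parameters and input
#' checksums. On failure a `FAILED` marker is left beside the partial
#' outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir report directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (`profiles`, `interactions_ctrl`, `interactions_ko`, `re_flags`,
#'   `upset`, `ks`, `motifs`, `coverage`, `feature_distribution`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  .check_inputs(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  result <- tryCatch(
    .run_pipeline_stages(config, out_dir),
    error = function(e) {
      writeLines(conditionMessage(e), failed_marker)
      stop(e)
    })
  invisible(result)
}

.run_pipeline_stages <- function(config, out_dir) {
  tsv <- function(name) file.path(out_dir, name)

  message("[1/8] annotation and feature distribution")
  gm <- read_gtf(config$gtf)
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  fmap <- build_feature_map(gm, chrom_sizes)
  diff_k79 <- read_bed(config$diff_k79)
  fd <- peak_feature_distribution(diff_k79, fmap)
  write_tsv(data.frame(feature = names(fd), fraction = as.numeric(fd)),
            tsv("feature_distribution.tsv"))

  message("[2/8] gene-body H3K79me2 coverage (",
          length(config$k79_reads_ctrl), " ctrl replicate(s))")
  cov_reps <- lapply(config$k79_reads_ctrl,
                     function(p) gene_body_coverage(read_bed(p), gm))
  coverage <- do.call(combine_replicate_coverage, cov_reps)
  coverage$gb_k79 <- classify_gb_k79(coverage$read_count,
                                     coverage$fraction_covered,
                                     config$gb_min_reads,
                                     config$gb_min_fraction)
  cov_ko_reps <- lapply(config$k79_reads_ko,
                        function(p) gene_body_coverage(read_bed(p), gm))
  cov_ko <- do.call(combine_replicate_coverage, cov_ko_reps)
  coverage$read_count_ko <- cov_ko$read_count
  coverage$fraction_covered_ko <- cov_ko$fraction_covered
  write_tsv(coverage, tsv("gene_body_coverage.tsv"))

  message("[3/8] Hi-C loading and balancing")
  autosomes <- .autosomes(chrom_sizes)
  contacts <- list()
  hic_summary <- list()
  for (chrom in intersect(autosomes, unique(gm$genes$chrom))) {
    path <- file.path(config$hic_dir, paste0(chrom, ".txt"))
    if (!file.exists(path)) {
      stop("Hi-C triplet file for ", chrom, " not found in field ",
           "'hic_dir': ", path)
    }
    cm <- load_contact_triplets(path, chrom, config$resolution,
                                n_bins = chrom_sizes[[chrom]] %/%
                                  config$resolution)
    if (config$prenormalized) {
      cm$balanced <- cm$counts
      cm$scaling <- rep(1, cm$n_bins)
    } else {
      cm <- kr_balance(cm)
    }
    keep <- setdiff(seq_len(cm$n_bins), cm$masked_bins + 1L)
    rs <- Matrix::rowSums(cm$balanced)[keep]
    hic_summary[[chrom]] <- data.frame(
      chrom = chrom, n_bins = cm$n_bins,
      masked_bins = length(cm$masked_bins),
      rowsum_cv = stats::sd(rs) / mean(rs), stringsAsFactors = FALSE)
    contacts[[chrom]] <- cm
  }
  write_tsv(do.call(rbind, hic_summary), tsv("hic_summary.tsv"))

  message("[4/8] adapted ABC interaction scoring")
  k27_ctrl <- read_narrowpeak(config$k27_peaks_ctrl)
  k27_ko <- read_narrowpeak(config$k27_peaks_ko)
  all_ctrl <- abc_interactions(gm, k27_ctrl, contacts,
                               window = config$window)
  all_ko <- abc_interactions(gm, k27_ko, contacts,
                             window = config$window)
  interactions_ctrl <- filter_interactions(all_ctrl,
                                           config$abc_threshold)
  interactions_ko <- filter_interactions(all_ko, config$abc_threshold)
  write_tsv(interactions_ctrl, tsv("interactions_ctrl.tsv"))
  write_tsv(interactions_ko, tsv("interactions_ko.tsv"))
  message("      ", nrow(interactions_ctrl), " ctrl / ",
          nrow(interactions_ko), " ko interactions kept (score >= ",
          config$abc_threshold, ")")

  message("[5/8] regulatory-element flagging")
  re_ids <- unique(c(interactions_ctrl$re_id, interactions_ko$re_id))
  re_tab <- unique(rbind(
    interactions_ctrl[c("re_id", "chrom", "start", "end")],
    interactions_ko[c("re_id", "chrom", "start", "end")]))
  re_gr <- GRanges(re_tab$chrom, IRanges(re_tab$start, re_tab$end))
  re_flags <- flag_res(re_gr, diff_k79,
                       read_bed(config$diff_k27_up),
                       read_bed(config$diff_k27_down),
                       promoters = gene_promoters(gm),
                       min_overlap = config$diff_overlap)
  write_tsv(re_flags, tsv("re_flags.tsv"))
  message("      ", sum(re_flags$is_k79_re), " K79-REs of ",
          nrow(re_flags), " ABC-selected REs")

  message("[6/8] gene profiles and categorization")
  expr <- assign_de_status(read_expression_table(config$de_table),
                           min_rpkm = config$de_min_rpkm,
                           min_lfc = config$de_min_lfc,
                           max_fdr = config$de_max_fdr)
  diff_map <- map_diff_k27_to_genes(re_flags, interactions_ctrl,
                                    interactions_ko)
  profiles <- build_gene_profiles(expr, coverage, interactions_ctrl,
                                  re_flags, diff_map)
  write_tsv(profiles, tsv("gene_profiles.tsv"))
  upset <- categorize_genes(profiles, include_diff_k27 = TRUE)
  write_tsv(upset, tsv("upset_categories.tsv"))
  upset2 <- categorize_genes(profiles, include_diff_k27 = FALSE)
  write_tsv(upset2, tsv("upset_categories_gb_re.tsv"))

  message("[7/8] stratified cumulative log2FC analysis")
  strat <- stratified_cdf_analysis(profiles)
  write_tsv(strat$ks, tsv("stratified_ks.tsv"))

  motifs <- NULL
  if (!is.null(config$pwms) && !is.null(config$re_fasta)) {
    message("[8/8] motif-affinity enrichment")
    motifs <- .pipeline_motifs(config, profiles, interactions_ctrl,
                               re_flags, expr)
    if (!is.null(motifs)) write_tsv(motifs, tsv("motif_enrichment.tsv"))
  } else {
    message("[8/8] motif analysis skipped (no PWM/FASTA inputs)")
  }

  manifest <- list(
    parameters = config[c("window", "resolution", "abc_threshold",
                          "gb_min_reads", "gb_min_fraction",
                          "diff_overlap", "de_min_rpkm", "de_min_lfc",
                          "de_max_fdr", "motif_alpha", "prenormalized",
                          "seed")],
    inputs = lapply(
      config[c("gtf", "chrom_sizes", "k79_reads_ctrl", "k79_reads_ko",
               "k27_peaks_ctrl", "k27_peaks_ko", "diff_k79",
               "diff_k27_up", "diff_k27_down", "de_table")],
      function(p) as.list(tools::md5sum(p))),
    n_genes = nrow(gm$genes),
    n_interactions_ctrl = nrow(interactions_ctrl),
    n_interactions_ko = nrow(interactions_ko),
    n_k79_res = sum(re_flags$is_k79_re))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(profiles = profiles, interactions_ctrl = interactions_ctrl,
       interactions_ko = interactions_ko, re_flags = re_flags,
       upset = upset, ks = strat$ks, strata = strat$strata,
       motifs = motifs, coverage = coverage, feature_distribution = fd,
       expr = expr, contacts = contacts)
}

# activating K79-REs: linked in ctrl to downregulated, gene-body
# methylated genes; silencing K79-REs: linked to upregulated genes
# without the gene-body mark
.pipeline_motifs <- function(config, profiles, interactions_ctrl,
                             re_flags, expr) {
  k79_ids <- re_flags$re_id[re_flags$is_k79_re]
  down_genes <- profiles$gene_id[profiles$de_status == "down" &
                                   profiles$gb_k79]
  up_genes <- profiles$gene_id[profiles$de_status == "up" &
                                 !profiles$gb_k79]
  act_ids <- unique(interactions_ctrl$re_id[
    interactions_ctrl$re_id %in% k79_ids &
      interactions_ctrl$gene_id %in% down_genes])
  sil_ids <- unique(interactions_ctrl$re_id[
    interactions_ctrl$re_id %in% k79_ids &
      interactions_ctrl$gene_id %in% up_genes])
  # an RE serving both groups is ambiguous for the contrast; drop it
  both <- intersect(act_ids, sil_ids)
  act_ids <- setdiff(act_ids, both)
  sil_ids <- setdiff(sil_ids, both)
  if (length(act_ids) == 0 || length(sil_ids) == 0) {
    message("      one RE group empty; motif enrichment skipped")
    return(NULL)
  }
  seqs <- Biostrings::readDNAStringSet(config$re_fasta)
  miss <- setdiff(c(act_ids, sil_ids), names(seqs))
  if (length(miss) > 0) {
    warning(length(miss), " RE(s) without a sequence skipped")
    act_ids <- setdiff(act_ids, miss)
    sil_ids <- setdiff(sil_ids, miss)
  }
  pwms <- read_jaspar(config$pwms)
  motif_enrichment(pwms, seqs[act_ids], seqs[sil_ids], expr = expr,
                   alpha = config$motif_alpha)
}

#' Simulate a dataset and run the pipeline end to end
#'
#' Generates the synthetic dataset, runs the full pipeline on its files,
#' and scores recovery of the planted truth: a confusion matrix of
#' planted versus recovered gene classes, the adjusted-p rank of the
#' planted silencing motif, and the KS comparison between the
#' many-K79-RE and no-K79-RE strata.
#'
#' @param cfg a `truth_config`.
#' @param out_dir working directory; data go to `out_dir/data`, the
#'   report to `out_dir/report`.
#' @return list with `accuracy`, `confusion` (table), `motif_rank`,
#'   `ks_high_re_p`, plus the `pipeline` result, `truth` and paths.
#' @export
simulate_and_run <- function(cfg, out_dir) {
  sim <- simulate_dataset(cfg, file.path(out_dir, "data"))
  p <- sim$paths
  config <- pipeline_config(
    gtf = p$gtf, chrom_sizes = p$chrom_sizes,
    k79_reads_ctrl = p$k79_reads_ctrl, k79_reads_ko = p$k79_reads_ko,
    k27_peaks_ctrl = p$k27_peaks_ctrl, k27_peaks_ko = p$k27_peaks_ko,
    diff_k79 = p$diff_k79, diff_k27_up = p$diff_k27_up,
    diff_k27_down = p$diff_k27_down, hic_dir = p$hic_dir,
    de_table = p$de_table, pwms = p$pwms, re_fasta = p$re_fasta,
    seed = cfg$seed)
  res <- suppressWarnings(run_pipeline(config,
                                       file.path(out_dir, "report")))

  recovered <- recovered_class(res$profiles)
  planted <- sim$truth$genes$class[match(res$profiles$gene_id,
                                         sim$truth$genes$gene_id)]
  confusion <- table(planted = planted, recovered = recovered)
  accuracy <- mean(planted == recovered)

  motif_rank <- NA_integer_
  if (!is.null(res$motifs)) {
    ord <- order(res$motifs$p_adj_silencing, res$motifs$p_silencing)
    motif_rank <- match(sim$planted_tf, res$motifs$tf[ord])
  }
  ks_row <- res$ks[res$ks$grouping == "k79_re_count" &
                     res$ks$stratum_a == "k79_re_0" &
                     res$ks$stratum_b == "k79_re_ge_6", , drop = FALSE]
  ks_high_re_p <- if (nrow(ks_row) == 1) ks_row$p_value else NA_real_

  metrics <- list(accuracy = accuracy, motif_rank = motif_rank,
                  ks_high_re_p = ks_high_re_p,
                  planted_tf = sim$planted_tf)
  jsonlite::write_json(metrics,
                       file.path(out_dir, "report",
                                 "truth_recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  c(metrics,
    list(confusion = confusion, pipeline = res, truth = sim$truth,
         paths = p))
}

#' Recovered regulatory class of each gene
#'
#' Maps a gene's pipeline profile onto the planted-class vocabulary of
#' the generator: downregulated gene-body-methylated genes with/without
#' K79-REs, upregulated unmethylated genes with K79-REs, unaffected
#' genes, and `other` for configurations outside those classes.
#'
#' @param profiles data.frame from [build_gene_profiles()].
#' @return character vector of class labels.
#' @export
recovered_class <- function(profiles) {
  out <- rep("other", nrow(profiles))
  out[profiles$de_status %in% c("unchanged", "not_expressed")] <- "none"
  down <- profiles$de_status == "down"
  up <- profiles$de_status == "up"
  out[down & profiles$gb_k79 & profiles$n_k79_res > 0] <- "gb_re_down"
  out[down & profiles$gb_k79 & profiles$n_k79_res == 0] <-
    "gb_only_down"
  out[up & !profiles$gb_k79 & profiles$n_k79_res > 0] <-
    "silencing_re_up"
  out
}
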