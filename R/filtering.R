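#' Filtering configuration
#'
#' Thresholds for the two filtering pipelines. All comparisons against "< T" thresholds are strict,
#' so a value exactly equal to a threshold survives.
#'
#' @param haploid_het_fraction Probe removed when any of its SNPs is
#'   heterozygous in more than this fraction of megagametophytes (0.05).
#' @param site_quality_min Minimum site quality (pilot pipeline; the VCF
#'   QUAL column stands in for the provider's proprietary score).
#' @param mean_depth_min_80K,mean_depth_min_49K Minimum mean read depth per
#'   SNP across all individuals (5 and 10).
#' @param indiv_depth_min Per-data-point minimum depth (10).
#' @param pop_allele_ratio_bounds Bounds on the population-average
#'   alt/(ref+alt) read ratio (pilot pipeline).
#' @param indiv_allele_ratio_min Within-individual minor-read ratio below
#'   which a data point is set missing (0.1).
#' @param alt_allele_true_depth Individual read depth above which an extra
#'   (2nd/3rd) alternate allele marks a true triallelic SNP (10); extra
#'   alleles never exceeding this depth are dropped and the SNP reclassified
#'   biallelic. Depth exactly equal to the threshold is treated as drop
#'   (neither "< 10" nor "> 10" covers it; the conservative reading).
#' @param maf_min Minimum minor allele frequency retained (0.03), computed
#'   over `maf_reference_samples`.
#' @param maf_reference_samples Sample ids of the unrelated reference
#'   cohort; `NULL` means samples with role `unrelated` or `parent`.
#' @param min_het_reads Reads per allele required before a haploid depth
#'   vector counts as heterozygous (2; avoids single-read artifacts).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(haploid_het_fraction = 0.05,
                          site_quality_min = 10,
                          mean_depth_min_80K = 5,
                          mean_depth_min_49K = 10,
                          indiv_depth_min = 10L,
                          pop_allele_ratio_bounds = c(0.1, 0.9),
                          indiv_allele_ratio_min = 0.1,
                          alt_allele_true_depth = 10L,
                          maf_min = 0.03,
                          maf_reference_samples = NULL,
                          min_het_reads = 2L) {
  stopifnot(maf_min > 0, maf_min < 0.5,
            pop_allele_ratio_bounds[1] < pop_allele_ratio_bounds[2])
  structure(as.list(environment()), class = "filter_config")
}

# alleles "present" at a site: depth >= 1 in at least one sample
observed_allele_counts <- function(vt) {
  K <- dim(vt$ad)[3]
  n_all <- 1L + lengths(vt$sites$alt)
  obs <- matrix(FALSE, n_sites(vt), K)
  for (k in seq_len(K)) {
    obs[, k] <- rowSums(vt$ad[, , k, drop = FALSE][, , 1, drop = FALSE] >= 1L) > 0
  }
  obs & outer(n_all, seq_len(K), ">=")
}

# fraction of megagametophytes whose depth vector looks heterozygous
# (>= 2 alleles each with >= min_reads reads), per site
haploid_het_fraction_by_site <- function(vt, sheet, min_reads = 2L) {
  megs <- sheet$sample_id[sheet$role == "megagametophyte"]
  megs <- intersect(megs, vt$samples)
  if (length(megs) == 0) return(NULL)
  j <- match(megs, vt$samples)
  K <- dim(vt$ad)[3]
  n_sup <- matrix(0L, n_sites(vt), length(j))
  for (k in seq_len(K)) {
    n_sup <- n_sup + (vt$ad[, j, k, drop = FALSE][, , 1] >= min_reads)
  }
  if (is.null(dim(n_sup))) n_sup <- matrix(n_sup, n_sites(vt), length(j))
  rowSums(n_sup >= 2L) / length(megs)
}

report_row <- function(vt, stage, n_data_points = NA_integer_) {
  tibble(stage = stage,
         n_genes = dplyr::n_distinct(vt$sites$gene_id),
         n_probes = dplyr::n_distinct(vt$sites$probe_id),
         n_snps = n_sites(vt),
         n_data_points = as.integer(n_data_points))
}

#' Pilot (80K-style) SNP filtering pipeline
#'
#' Applies, in order: (1) removal of whole probes whose SNPs are
#' heterozygous in more than `haploid_het_fraction` of megagametophytes;
#' (2) removal of SNPs with site quality below `site_quality_min`;
#' (3) removal of SNPs with mean read depth below `mean_depth_min_80K`;
#' (4) removal of SNPs with more than two observed alleles; (5) removal of
#' SNPs whose population-average alt/(ref+alt) read ratio falls outside
#' `pop_allele_ratio_bounds` (mean over individuals with informative depth).
#'
#' @param vt A [variant_table()].
#' @param sheet A [sample_sheet()].
#' @param cfg A [filter_config()].
#' @return A list of class `filter_result`: `vt` (surviving sites),
#'   `report` (per-stage gene/probe/SNP counts), `log` (per-stage messages).
#' @export
filter_pilot_80k <- function(vt, sheet, cfg = filter_config()) {
  stopifnot(inherits(vt, "variant_table"))
  log <- character(0)
  report <- report_row(vt, "None")

  hf <- haploid_het_fraction_by_site(vt, sheet, cfg$min_het_reads)
  if (is.null(hf)) {
    warn("no megagametophytes in sheet; polymorphic-haploid stage skipped")
    log <- c(log, "Polymorphic haploids: skipped (no megagametophytes)")
  } else {
    bad_probes <- unique(vt$sites$probe_id[hf > cfg$haploid_het_fraction])
    keep <- !(vt$sites$probe_id %in% bad_probes)
    log <- c(log, sprintf("Polymorphic haploids: removed %d probes (%d SNPs)",
                          length(bad_probes), sum(!keep)))
    vt <- subset_sites(vt, which(keep))
  }
  report <- bind_rows(report, report_row(vt, "Polymorphic haploids"))

  keep <- vt$sites$qual >= cfg$site_quality_min
  log <- c(log, sprintf("Quality: removed %d SNPs with Q < %g",
                        sum(!keep), cfg$site_quality_min))
  vt <- subset_sites(vt, which(keep))
  report <- bind_rows(report, report_row(vt, "Quality"))

  keep <- rowMeans(total_depth(vt)) >= cfg$mean_depth_min_80K
  log <- c(log, sprintf("Read depth per SNP: removed %d SNPs with mean depth < %g",
                        sum(!keep), cfg$mean_depth_min_80K))
  vt <- subset_sites(vt, which(keep))
  report <- bind_rows(report, report_row(vt, "Read depth per SNP"))

  keep <- rowSums(observed_allele_counts(vt)) <= 2L
  log <- c(log, sprintf("Biallelic: removed %d SNPs with > 2 alleles", sum(!keep)))
  vt <- subset_sites(vt, which(keep))
  report <- bind_rows(report, report_row(vt, "Biallelic"))

  ref_d <- vt$ad[, , 1, drop = FALSE][, , 1]
  alt_d <- vt$ad[, , 2, drop = FALSE][, , 1]
  if (is.null(dim(ref_d))) {
    ref_d <- matrix(ref_d, n_sites(vt)); alt_d <- matrix(alt_d, n_sites(vt))
  }
  tot <- ref_d + alt_d
  ratio <- ifelse(tot > 0, alt_d / tot, NA_real_)
  mean_ratio <- rowMeans(ratio, na.rm = TRUE)
  keep <- !is.na(mean_ratio) &
    mean_ratio >= cfg$pop_allele_ratio_bounds[1] &
    mean_ratio <= cfg$pop_allele_ratio_bounds[2]
  log <- c(log, sprintf("Allele ratio: removed %d SNPs with mean alt ratio outside [%g, %g]",
                        sum(!keep), cfg$pop_allele_ratio_bounds[1],
                        cfg$pop_allele_ratio_bounds[2]))
  vt <- subset_sites(vt, which(keep))
  report <- bind_rows(report, report_row(vt, "Allele ratio"))

  structure(list(vt = vt, report = report, log = log, pipeline = "pilot80K"),
            class = "filter_result")
}

#' Final (49K-style) SNP filtering pipeline
#'
#' Applies, in order: (1) removal of SNPs whose mean read depth across all
#' individuals is below `mean_depth_min_49K`; (2) per SNP, extra (2nd/3rd)
#' alternate alleles whose read depth never exceeds `alt_allele_true_depth`
#' in any individual are dropped and the SNP reclassified biallelic, while
#' SNPs with an extra allele above that depth are true triallelics and move
#' to a separate table; (3) individual data points with depth below
#' `indiv_depth_min` are set missing; (4) individual data points whose
#' within-individual minor-read ratio is positive but below
#' `indiv_allele_ratio_min` are set missing; (5) removal of probes
#' heterozygous in more than `haploid_het_fraction` of megagametophytes;
#' (6) removal of SNPs monomorphic across all non-missing calls in all
#' samples; (7) retention of SNPs with MAF at least `maf_min` in the
#' reference cohort.
#'
#' Stages (3) and (4) change data points, not site counts, so the report
#' tracks both the site counts and the number of callable data points.
#'
#' @inheritParams filter_pilot_80k
#' @return A list of class `filter_result`: `vt` (surviving sites),
#'   `genotypes` (a [genotype_matrix()] with the per-point stages applied),
#'   `triallelic` (the separated true-triallelic [variant_table()], or
#'   `NULL`), `report`, `log`.
#' @export
filter_final_49k <- function(vt, sheet, cfg = filter_config()) {
  stopifnot(inherits(vt, "variant_table"))
  log <- character(0)
  dp <- total_depth(vt)
  report <- report_row(vt, "None", n_data_points = sum(dp >= 1L))

  keep <- rowMeans(dp) >= cfg$mean_depth_min_49K
  log <- c(log, sprintf("Read depth per SNP: removed %d SNPs with mean depth < %g",
                        sum(!keep), cfg$mean_depth_min_49K))
  vt <- subset_sites(vt, which(keep))
  report <- bind_rows(report,
                      report_row(vt, "Read depth per SNP", sum(total_depth(vt) >= 1L)))

  # extra alternate alleles: drop (shallow) or route to the triallelic table
  K <- dim(vt$ad)[3]
  tri_vt <- NULL
  if (K > 2L) {
    n_all <- 1L + lengths(vt$sites$alt)
    max_extra <- matrix(0L, n_sites(vt), K - 2L)
    for (k in 3:K) {
      d <- vt$ad[, , k, drop = FALSE][, , 1, drop = FALSE]
      d <- matrix(d, n_sites(vt))
      d[n_all < k, ] <- 0L
      max_extra[, k - 2L] <- apply(d, 1, max)
    }
    is_true_tri <- apply(max_extra > cfg$alt_allele_true_depth, 1, any)
    has_extra <- n_all > 2L
    to_drop <- has_extra & !is_true_tri
    if (any(is_true_tri)) tri_vt <- subset_sites(vt, which(is_true_tri))
    log <- c(log, sprintf(
      "Biallelic: %d SNPs moved to triallelic table; extra alleles dropped from %d SNPs (depth <= %d, reclassified biallelic)",
      sum(is_true_tri), sum(to_drop), cfg$alt_allele_true_depth))
    vt <- subset_sites(vt, which(!is_true_tri))
    # reclassify: truncate allele lists and zero extra-allele depths
    vt$sites$alt <- lapply(vt$sites$alt, function(a) a[1])
    vt$ad <- vt$ad[, , 1:2, drop = FALSE]
  } else {
    log <- c(log, "Biallelic: no sites list extra alternate alleles")
  }
  report <- bind_rows(report,
                      report_row(vt, "Biallelic", sum(total_depth(vt) >= 1L)))

  # per-data-point stages, applied through the calling rules
  parts <- call_components(vt, sheet)
  gm <- call_genotypes(vt, sheet, min_depth = cfg$indiv_depth_min,
                       min_allele_ratio = cfg$indiv_allele_ratio_min,
                       low_ratio_action = "missing")
  n_low_dp <- sum(parts$dp < cfg$indiv_depth_min & parts$dp >= 1L)
  pts_after_dp <- sum(parts$dp >= cfg$indiv_depth_min)
  log <- c(log, sprintf("Read depth per individual: %d data points set missing (depth < %d)",
                        n_low_dp, cfg$indiv_depth_min))
  report <- bind_rows(report,
                      report_row(vt, "Read depth per individual", pts_after_dp))

  n_ratio <- pts_after_dp - sum(!is_missing(gm))
  log <- c(log, sprintf("Allele ratio: %d data points set missing (minor ratio in (0, %g))",
                        n_ratio, cfg$indiv_allele_ratio_min))
  report <- bind_rows(report,
                      report_row(vt, "Allele ratio", sum(!is_missing(gm))))

  hf <- haploid_het_fraction_by_site(vt, sheet, cfg$min_het_reads)
  if (is.null(hf)) {
    warn("no megagametophytes in sheet; polymorphic-haploid stage skipped")
    log <- c(log, "Polymorphic haploids: skipped (no megagametophytes)")
  } else {
    bad_probes <- unique(vt$sites$probe_id[hf > cfg$haploid_het_fraction])
    keep <- !(vt$sites$probe_id %in% bad_probes)
    log <- c(log, sprintf("Polymorphic haploids: removed %d probes (%d SNPs)",
                          length(bad_probes), sum(!keep)))
    vt <- subset_sites(vt, which(keep))
    gm <- subset_genotypes(gm, vt$sites$site_id)
  }
  report <- bind_rows(report,
                      report_row(vt, "Polymorphic haploids", sum(!is_missing(gm))))

  # monomorphic over all non-missing calls in all samples, haploids included
  d <- gt_dosage(gm)
  pl <- matrix(gm$ploidy, nrow(d), ncol(d), byrow = TRUE)
  pl[is.na(d)] <- 0L
  alt_n <- rowSums(d, na.rm = TRUE)
  tot_n <- rowSums(pl)
  keep <- alt_n > 0 & alt_n < tot_n
  log <- c(log, sprintf("Monomorphic markers: removed %d SNPs", sum(!keep)))
  vt <- subset_sites(vt, which(keep))
  gm <- subset_genotypes(gm, vt$sites$site_id)
  report <- bind_rows(report,
                      report_row(vt, "Monomorphic markers", sum(!is_missing(gm))))

  ref_cohort <- cfg$maf_reference_samples %||%
    sheet$sample_id[sheet$role %in% c("unrelated", "parent")]
  ref_cohort <- intersect(ref_cohort, gm$samples)
  if (length(ref_cohort) == 0) abort("MAF reference cohort is empty")
  maf <- site_maf(gm, ref_cohort)$maf
  keep <- !is.na(maf) & maf >= cfg$maf_min
  log <- c(log, sprintf("MAF: removed %d SNPs with MAF < %g in %d reference samples",
                        sum(!keep), cfg$maf_min, length(ref_cohort)))
  vt <- subset_sites(vt, which(keep))
  gm <- subset_genotypes(gm, vt$sites$site_id)
  report <- bind_rows(report,
                      report_row(vt, sprintf("MAF >= %g", cfg$maf_min),
                                 sum(!is_missing(gm))))

  structure(list(vt = vt, genotypes = gm, triallelic = tri_vt,
                 report = report, log = log, pipeline = "final49K"),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> pipeline: ", x$pipeline, "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @rdname filter_pilot_80k
#' @param x A `filter_result`.
#' @param ... Unused.
#' @export
tidy.filter_result <- function(x, ...) x$report

#' @rdname filter_pilot_80k
#' @export
glance.filter_result <- function(x, ...) {
  tibble(pipeline = x$pipeline,
         n_stages = nrow(x$report) - 1L,
         snps_in = x$report$n_snps[1],
         snps_out = x$report$n_snps[nrow(x$report)],
         genes_out = x$report$n_genes[nrow(x$report)],
         probes_out = x$report$n_probes[nrow(x$report)])
}

#' Write a filter report as tab-separated text
#' @param result A `filter_result`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @export
write_filter_report <- function(result, path, seed = NULL) {
  write_tsv_report(result$report, path, seed,
                   extra = paste0("pipeline: ", result$pipeline))
}
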