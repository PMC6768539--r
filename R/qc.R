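#' Quality-control report
#'
#' Computes the evaluation metrics used to assess a GBS SNP panel:
#' call rate per sample and per SNP, per-site mean read depth, the
#' SNPs-per-probe histogram, the MAF spectrum over a reference cohort,
#' per-probe haploid (megagametophyte) heterozygosity, replicate-pair
#' concordance, and the binned missingness-versus-depth relationship.
#'
#' @param gm A [genotype_matrix()].
#' @param vt The matching [variant_table()] (same sites).
#' @param sheet A [sample_sheet()].
#' @param maf_cohort Sample ids for the MAF spectrum (default: roles
#'   `unrelated` and `parent`).
#' @param depth_bins Breaks (in X coverage) for the missingness-vs-depth
#'   curve.
#' @return A list of class `qc_report` with tibbles `sample_stats`,
#'   `site_stats`, `snps_per_probe`, `maf`, `haploid_het`,
#'   `replicate_concordance`, `missingness_vs_depth`.
#' @export
qc_report <- function(gm, vt, sheet, maf_cohort = NULL,
                      depth_bins = c(0, 5, 10, 15, 20, 30, 40, 60, Inf)) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(vt, "variant_table"))
  if (!identical(gm$sites$site_id, vt$sites$site_id)) {
    abort("`gm` and `vt` must describe the same sites in the same order")
  }
  dp <- total_depth(vt)
  miss <- is_missing(gm)

  sample_stats <- tibble(sample_id = gm$samples,
                         call_rate = unname(1 - colMeans(miss)),
                         mean_depth = unname(colMeans(dp)))
  site_stats <- tibble(site_id = gm$sites$site_id,
                       call_rate = unname(1 - rowMeans(miss)),
                       mean_depth = unname(rowMeans(dp)))

  snps_per_probe <- vt$sites %>%
    count(.data$probe_id, name = "n_snps") %>%
    count(.data$n_snps, name = "n_probes") %>%
    arrange(.data$n_snps)

  cohort <- maf_cohort %||%
    intersect(sheet$sample_id[sheet$role %in% c("unrelated", "parent")], gm$samples)
  maf <- if (length(cohort) > 0) site_maf(gm, cohort) else
    tibble(site_id = character(0), n_alleles = integer(0),
           alt_freq = double(0), maf = double(0))

  hf <- haploid_het_fraction_by_site(vt, sheet)
  haploid_het <- if (is.null(hf)) {
    tibble(probe_id = character(0), het_fraction = double(0))
  } else {
    tibble(probe_id = vt$sites$probe_id, het_fraction = hf) %>%
      group_by(.data$probe_id) %>%
      summarise(het_fraction = max(.data$het_fraction), .groups = "drop")
  }

  replicate_concordance <- replicate_concordance(gm, sheet)

  bin <- cut(sample_stats$mean_depth, depth_bins, right = FALSE)
  missingness_vs_depth <- tibble(depth_bin = bin,
                                 missing = 1 - sample_stats$call_rate) %>%
    group_by(.data$depth_bin) %>%
    summarise(mean_missing = mean(.data$missing), n_samples = n(),
              .groups = "drop")

  structure(list(sample_stats = sample_stats, site_stats = site_stats,
                 snps_per_probe = snps_per_probe, maf = maf,
                 haploid_het = haploid_het,
                 replicate_concordance = replicate_concordance,
                 missingness_vs_depth = missingness_vs_depth),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  mean sample call rate: ", round(mean(x$sample_stats$call_rate), 3), "\n")
  cat("  mean SNPs per probe:   ",
      round(sum(x$snps_per_probe$n_snps * x$snps_per_probe$n_probes) /
              sum(x$snps_per_probe$n_probes), 2), "\n")
  if (nrow(x$replicate_concordance) > 0) {
    cat("  replicate concordance: ",
        paste(round(range(x$replicate_concordance$concordance), 3),
              collapse = "-"), "\n")
  }
  invisible(x)
}

#' Tidy a qc_report component
#' @param x A `qc_report`.
#' @param which Component name (default `"sample_stats"`).
#' @param ... Unused.
#' @export
tidy.qc_report <- function(x, which = "sample_stats", ...) {
  if (!which %in% names(x)) abort(paste0("unknown qc component: ", which))
  x[[which]]
}

#' Concordance between technical replicate pairs
#'
#' For every pair of samples sharing a `replicate_group`, the proportion of
#' sites where both calls are non-missing and the genotypes (unordered
#' allele multisets) are equal.
#'
#' @param gm A [genotype_matrix()].
#' @param sheet A [sample_sheet()].
#' @return A tibble: `sample_a`, `sample_b`, `replicate_group`, `n_shared`,
#'   `n_equal`, `concordance`.
#' @export
replicate_concordance <- function(gm, sheet) {
  grp <- sheet[!is.na(sheet$replicate_group) &
                 sheet$sample_id %in% gm$samples, c("sample_id", "replicate_group")]
  out <- list()
  for (g in unique(grp$replicate_group)) {
    ids <- grp$sample_id[grp$replicate_group == g]
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    for (p in seq_len(ncol(cmb))) {
      a <- cmb[1, p]; b <- cmb[2, p]
      ia <- match(a, gm$samples); ib <- match(b, gm$samples)
      ok <- !is.na(gm$a1[, ia]) & !is.na(gm$a1[, ib])
      eq <- ok & gm$a1[, ia] == gm$a1[, ib] &
        (is.na(gm$a2[, ia]) == is.na(gm$a2[, ib])) &
        (is.na(gm$a2[, ia]) | gm$a2[, ia] == gm$a2[, ib])
      eq[is.na(eq)] <- FALSE
      out[[length(out) + 1]] <- tibble(
        sample_a = a, sample_b = b, replicate_group = g,
        n_shared = sum(ok), n_equal = sum(eq),
        concordance = ifelse(sum(ok) > 0, sum(eq) / sum(ok), NA_real_))
    }
  }
  if (length(out) == 0) {
    return(tibble(sample_a = character(0), sample_b = character(0),
                  replicate_group = character(0), n_shared = integer(0),
                  n_equal = integer(0), concordance = double(0)))
  }
  bind_rows(out)
}

#' Mendelian consistency in trios and duos
#'
#' For every declared trio (offspring with both parents genotyped) the
#' number of sites where the offspring genotype is not producible from one
#' gamete of each parent; for every duo (megagametophyte and its mother)
#' the number of sites where the haploid allele is absent from the mother's
#' genotype. Sites with any missing genotype are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param sheet A [sample_sheet()].
#' @return A tibble: `unit` (trio/duo), `sample_id`, `mother_id`,
#'   `father_id`, `n_informative`, `n_inconsistent`.
#' @export
mendelian_check <- function(gm, sheet) {
  out <- list()
  trio_rows <- sheet[sheet$role == "offspring" &
                       !is.na(sheet$mother_id) & !is.na(sheet$father_id) &
                       sheet$sample_id %in% gm$samples, ]
  for (r in seq_len(nrow(trio_rows))) {
    off <- trio_rows$sample_id[r]
    mo <- trio_rows$mother_id[r]; fa <- trio_rows$father_id[r]
    if (!mo %in% gm$samples || !fa %in% gm$samples) next
    res <- trio_exclusions(gm, off, mo, fa, gm$sites$site_id)
    out[[length(out) + 1]] <- tibble(
      unit = "trio", sample_id = off, mother_id = mo, father_id = fa,
      n_informative = res$n_comparable, n_inconsistent = res$n_exclusions)
  }
  duo_rows <- sheet[sheet$role == "megagametophyte" &
                      sheet$sample_id %in% gm$samples, ]
  for (r in seq_len(nrow(duo_rows))) {
    meg <- duo_rows$sample_id[r]; mo <- duo_rows$mother_id[r]
    if (is.na(mo) || !mo %in% gm$samples) next
    im <- match(meg, gm$samples); imo <- match(mo, gm$samples)
    ok <- !is.na(gm$a1[, im]) & !is.na(gm$a1[, imo])
    bad <- ok & gm$a1[, im] != gm$a1[, imo] & gm$a1[, im] != gm$a2[, imo]
    bad[is.na(bad)] <- FALSE
    out[[length(out) + 1]] <- tibble(
      unit = "duo", sample_id = meg, mother_id = mo, father_id = NA_character_,
      n_informative = sum(ok), n_inconsistent = sum(bad))
  }
  if (length(out) == 0) abort("sheet declares no trios or duos present in the matrix")
  bind_rows(out)
}
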