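#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against Hardy-Weinberg proportions at the allele frequency estimated
#' from the same counts, without continuity correction. One degree of
#' freedom: three genotype classes minus one minus the one estimated
#' parameter. Monomorphic input admits no test and is returned flagged
#' with statistic 0 and p-value 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorised).
#' @return A tibble: `statistic`, `df`, `p_value`, `monomorphic`.
#' @export
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) abort("total genotype count must be >= 1")
  p <- (n_Aa + 2 * n_aa) / (2 * n)
  mono <- p == 0 | p == 1
  e_AA <- n * (1 - p)^2
  e_Aa <- n * 2 * p * (1 - p)
  e_aa <- n * p^2
  stat <- ifelse(mono, 0,
                 (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa)
  pv <- ifelse(mono, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  tibble(statistic = stat, df = 1L, p_value = pv, monomorphic = mono)
}

#' Squared genotypic correlation between two SNPs
#'
#' The square of the Pearson correlation between allele-dosage vectors
#' (0/1/2), computed over pairwise-complete individuals — the composite
#' linkage-disequilibrium measure used for panel pruning. If either vector
#' has zero variance over the complete pairs the correlation is undefined;
#' the pair is treated as unlinked and 0 is returned with a warning.
#'
#' @param snp_a,snp_b Numeric dosage vectors of equal length (`NA` allowed).
#' @return A single value in `[0, 1]`.
#' @export
genotypic_r2 <- function(snp_a, snp_b) {
  stopifnot(length(snp_a) == length(snp_b))
  ok <- !is.na(snp_a) & !is.na(snp_b)
  if (sum(ok) < 2) abort("need >= 2 pairwise-complete individuals")
  if (stats::var(snp_a[ok]) == 0 || stats::var(snp_b[ok]) == 0) {
    warn("zero dosage variance; r^2 undefined, pair treated as unlinked")
    return(0)
  }
  cor(snp_a[ok], snp_b[ok])^2
}

#' Marker selection criteria for pedigree reconstruction
#'
#' @param call_rate_min Minimum per-SNP call rate over the reference cohort
#'   (exclusive bound: rate must exceed it; default 0.75).
#' @param maf_range Inclusive MAF window (default 0.35-0.5).
#' @param hwe_p_min SNPs are kept when the HWE p-value exceeds this
#'   (default 0.10).
#' @param ld_r2_max Maximum pairwise squared genotypic correlation among
#'   retained SNPs (exclusive; default 0.02).
#' @param reference_cohort Sample ids over which call rate, MAF, HWE and LD
#'   are computed; `NULL` means roles `unrelated` + `parent`.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(call_rate_min = 0.75,
                               maf_range = c(0.35, 0.5),
                               hwe_p_min = 0.10,
                               ld_r2_max = 0.02,
                               reference_cohort = NULL) {
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2])
  structure(as.list(environment()), class = "selection_criteria")
}

#' Per-SNP selection diagnostics
#'
#' Computes, over the reference cohort, each SNP's call rate, MAF, HWE
#' statistic and p-value, and the pass/fail flags for the three marginal
#' criteria (LD pruning is pairwise and applied in
#' [select_pedigree_snps()]).
#'
#' @param gm A [genotype_matrix()] of biallelic sites.
#' @param criteria A [selection_criteria()].
#' @param sheet Optional [sample_sheet()], used to resolve the default
#'   reference cohort.
#' @return A tibble with one row per site.
#' @export
snp_criteria <- function(gm, criteria = selection_criteria(), sheet = NULL) {
  cohort <- criteria$reference_cohort
  if (is.null(cohort)) {
    if (is.null(sheet)) abort("supply `sheet` or criteria$reference_cohort")
    cohort <- sheet$sample_id[sheet$role %in% c("unrelated", "parent")]
  }
  cohort <- intersect(cohort, gm$samples)
  if (length(cohort) == 0) abort("reference cohort is empty")
  d <- gt_dosage(gm, cohort)
  cr <- rowMeans(!is.na(d))
  maf <- site_maf(gm, cohort)$maf
  n0 <- rowSums(d == 0, na.rm = TRUE)
  n1 <- rowSums(d == 1, na.rm = TRUE)
  n2 <- rowSums(d == 2, na.rm = TRUE)
  hwe <- hwe_chisq(pmax(n0, 0L), n1, n2)
  hwe$p_value[n0 + n1 + n2 == 0] <- NA_real_
  tibble(site_id = gm$sites$site_id,
         call_rate = cr, maf = maf,
         hwe_statistic = hwe$statistic, hwe_p = hwe$p_value,
         pass_call_rate = cr > criteria$call_rate_min,
         pass_maf = !is.na(maf) & maf >= criteria$maf_range[1] &
           maf <= criteria$maf_range[2],
         pass_hwe = !is.na(hwe$p_value) & hwe$p_value > criteria$hwe_p_min)
}

#' Select pedigree-reconstruction SNPs
#'
#' Applies the four selection criteria in order: call rate above the
#' threshold, MAF within the window, HWE p-value above the threshold, then
#' greedy LD pruning so that every retained pair of SNPs has squared
#' genotypic correlation below `ld_r2_max`. Pruning iterates candidates in
#' descending call-rate order (ties by site order) and discards any SNP
#' whose r-squared against an already-kept SNP reaches the bound, which is
#' deterministic and favours complete data.
#'
#' Call rate, MAF and HWE are computed over the reference cohort; the
#' pairwise r-squared is computed over *all* diploid samples in the matrix.
#' At a cohort of ~135 an `r^2 < 0.02` bound lies inside the null sampling
#' distribution of r-squared between unlinked SNPs (about 10% of unlinked
#' pairs exceed it), so pruning on the cohort alone would saturate the pool
#' far below its real size; the full sample set separates true composite LD
#' from sampling noise at that threshold.
#'
#' @inheritParams snp_criteria
#' @return A tibble (the candidate pool, in kept order): `site_id`,
#'   `call_rate`, `maf`, `hwe_p`.
#' @export
select_pedigree_snps <- function(gm, criteria = selection_criteria(),
                                 sheet = NULL) {
  diag <- snp_criteria(gm, criteria, sheet)
  pass <- diag$pass_call_rate & diag$pass_maf & diag$pass_hwe
  if (!any(pass)) {
    warn("no SNPs meet the marginal criteria; empty pool")
    return(diag[0, c("site_id", "call_rate", "maf", "hwe_p")])
  }
  cand <- diag[pass, ]
  cand <- cand[order(-cand$call_rate, match(cand$site_id, diag$site_id)), ]
  ld_cohort <- gm$samples[gm$ploidy == 2L]
  d <- gt_dosage(subset_genotypes(gm, cand$site_id), ld_cohort)
  # r^2 over pairwise-complete pairs for all candidates at once
  r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[is.na(r2)] <- 0  # undefined pairs treated as unlinked
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    keep[i] <- all(r2[i, keep] < criteria$ld_r2_max)
  }
  out <- cand[keep, c("site_id", "call_rate", "maf", "hwe_p")]
  out
}

#' Draw random SNP panels from a candidate pool
#'
#' Each panel is an independent uniform without-replacement draw of
#' `panel_size` site ids from the pool (panels may overlap each other).
#'
#' @param pool Character vector of site ids, or a tibble with a `site_id`
#'   column (e.g. the output of [select_pedigree_snps()]).
#' @param n_panels Number of panels.
#' @param panel_size SNPs per panel.
#' @param seed Integer seed for reproducible draws.
#' @return A tibble: `panel` (label), `idx` (1-based position within the
#'   panel; truncation keeps the first `k`), `site_id`.
#' @export
random_panels <- function(pool, n_panels = 60L, panel_size = 110L, seed = 1L) {
  if (is.data.frame(pool)) pool <- pool$site_id
  if (anyDuplicated(pool)) abort("pool contains duplicate site ids")
  if (panel_size > length(pool)) {
    abort(sprintf("panel_size (%d) exceeds pool size (%d)",
                  panel_size, length(pool)))
  }
  set.seed(seed)
  width <- nchar(as.character(n_panels))
  bind_rows(lapply(seq_len(n_panels), function(i) {
    tibble(panel = sprintf(paste0("panel_%0", width, "d"), i),
           idx = seq_len(panel_size),
           site_id = sample(pool, panel_size, replace = FALSE))
  }))
}

#' Truncate panels to nested prefix sub-panels
#'
#' Reduction keeps the first `k` SNPs of each panel's stored order, so the
#' sub-panels are nested by construction.
#'
#' @param panels A panels tibble from [random_panels()] (columns `panel`,
#'   `idx`, `site_id`).
#' @param sizes Integer vector of truncation sizes.
#' @return A tibble: `panel`, `size`, `idx`, `site_id`.
#' @export
truncate_panels <- function(panels, sizes) {
  stopifnot(all(c("panel", "idx", "site_id") %in% names(panels)))
  max_size <- min(tapply(panels$idx, panels$panel, max))
  if (any(sizes > max_size)) {
    abort(sprintf("size %d exceeds panel size %d", max(sizes), max_size))
  }
  bind_rows(lapply(sort(sizes, decreasing = TRUE), function(k) {
    x <- panels[panels$idx <= k, ]
    x$size <- as.integer(k)
    x[, c("panel", "size", "idx", "site_id")]
  }))
}
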