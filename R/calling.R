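#' Call genotypes from per-allele read depths
#'
#' Converts a [variant_table()] into a [genotype_matrix()] by applying the
#' depth-threshold and allele-ratio rules used in the 49K-style pipeline:
#'
#' * a data point is MISSING when its total read depth is below `min_depth`;
#' * a haploid (megagametophyte) sample is called as the single allele with
#'   the highest depth (lowest allele index wins ties);
#' * a diploid sample is called heterozygous for its two deepest alleles
#'   when the minor-read ratio (lesser of the two top depths over their sum)
#'   is at least `min_allele_ratio`; otherwise the minor reads are treated
#'   as sequencing error and the call is demoted to homozygous for the major
#'   allele (`low_ratio_action = "demote"`, the default used during calling)
#'   or the data point is set MISSING (`low_ratio_action = "missing"`, the
#'   behaviour the final pipeline's allele-ratio filter stage uses).
#'
#' A depth exactly equal to `min_depth` survives (the thresholds are strict
#' `<` comparisons, as the pipeline states them).
#'
#' @param vt A `variant_table`.
#' @param sheet A [sample_sheet()]; its ploidy column decides haploid vs
#'   diploid calling and is authoritative.
#' @param min_depth Minimum total depth for a call (default 10).
#' @param min_allele_ratio Minimum within-individual minor-read ratio for a
#'   heterozygous call, in `[0, 0.5)` (default 0.1).
#' @param low_ratio_action `"demote"` or `"missing"` (see above).
#' @return A `genotype_matrix` over the same sites and samples.
#' @export
call_genotypes <- function(vt, sheet, min_depth = 10L, min_allele_ratio = 0.1,
                           low_ratio_action = c("demote", "missing")) {
  stopifnot(inherits(vt, "variant_table"), min_depth >= 1,
            min_allele_ratio >= 0, min_allele_ratio < 0.5)
  low_ratio_action <- match.arg(low_ratio_action)
  parts <- call_components(vt, sheet)
  a1 <- parts$top1
  a2 <- matrix(NA_integer_, nrow(a1), ncol(a1))
  dip <- matrix(parts$ploidy == 2L, nrow = nrow(a1), ncol = ncol(a1), byrow = TRUE)
  het_ok <- parts$ratio >= min_allele_ratio & parts$d2 > 0L
  a2[dip & het_ok] <- parts$top2[dip & het_ok]
  hom <- dip & !het_ok
  if (low_ratio_action == "missing") {
    # a suppressed minor observation invalidates the point entirely
    kill <- hom & parts$d2 > 0L
    a1[kill] <- NA_integer_
    hom <- hom & !kill
  }
  a2[hom] <- a1[hom]  # homozygous for the major allele
  # low-depth points are missing
  low_dp <- parts$dp < min_depth
  a1[low_dp] <- NA_integer_
  a2[is.na(a1)] <- NA_integer_
  genotype_matrix(vt$sites, vt$samples, a1, a2,
                  setNames(parts$ploidy, vt$samples))
}

# Shared internals for calling and for the per-data-point filter stages:
# top two alleles by depth, their depths, total depth and minor ratio.
call_components <- function(vt, sheet) {
  stopifnot(inherits(vt, "variant_table"))
  unknown <- setdiff(vt$samples, sheet$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("sample(s) not in sheet: ", paste(unknown, collapse = ", ")))
  }
  ploidy <- unname(ploidy_of(sheet, vt$samples))
  nS <- n_sites(vt); nI <- n_samples(vt); K <- dim(vt$ad)[3]
  n_alleles <- 1L + lengths(vt$sites$alt)
  flat <- matrix(vt$ad, nrow = nS * nI, ncol = K)
  # mask depth slots beyond each site's allele list so they can't win argmax
  for (k in seq_len(K)) {
    bad <- n_alleles < k
    if (any(bad)) flat[rep(bad, times = nI), k] <- -1L
  }
  top1 <- max.col(flat, ties.method = "first") - 1L
  d1 <- flat[cbind(seq_len(nS * nI), top1 + 1L)]
  flat2 <- flat
  flat2[cbind(seq_len(nS * nI), top1 + 1L)] <- -1L
  top2 <- max.col(flat2, ties.method = "first") - 1L
  d2 <- flat2[cbind(seq_len(nS * nI), top2 + 1L)]
  d2[d2 < 0L] <- 0L
  dp <- matrix(pmax(flat, 0L) %*% rep(1L, K), nS, nI)
  d1m <- matrix(d1, nS, nI); d2m <- matrix(d2, nS, nI)
  ratio <- ifelse(d1m + d2m > 0, d2m / (d1m + d2m), 0)
  top1m <- matrix(top1, nS, nI); top2m <- matrix(as.integer(top2), nS, nI)
  top2m[d2m == 0L] <- NA_integer_
  # degenerate: zero depth everywhere -> missing
  top1m[d1m <= 0L] <- NA_integer_
  list(top1 = top1m, top2 = top2m, d1 = d1m, d2 = d2m, dp = dp,
       ratio = ratio, ploidy = ploidy)
}
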