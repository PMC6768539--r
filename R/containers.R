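#' Construct a variant table
#'
#' A `variant_table` holds the pre-call state of an exome-capture GBS
#' experiment: one record per SNP site (alleles, probe and gene of origin,
#' site quality) together with the per-sample, per-allele read depths that
#' all downstream filtering and genotype calling operate on.
#'
#' Internally the depths live in an integer array of dimension
#' `n_sites x n_samples x max_alleles`; sites with fewer alleles than the
#' array's third extent carry zeros in the unused slots. Use
#' [as_tibble.variant_table()] for a long, tidy view.
#'
#' @param sites A data frame with columns `site_id`, `probe_id`, `gene_id`,
#'   `chrom`, `pos` (1-based), `ref` (single reference allele), `alt`
#'   (list column of character vectors, one or more alternate alleles) and
#'   `qual` (non-negative site quality; the VCF QUAL column stands in for
#'   the genotyping provider's proprietary quality score).
#' @param samples Character vector of sample identifiers, in column order
#'   of `ad`.
#' @param ad Integer array `n_sites x n_samples x max_alleles` of per-allele
#'   read depths (allele slot 1 = ref, slot 2 = first alt, ...).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, samples, ad) {
  sites <- as_tibble(sites)
  required <- c("site_id", "probe_id", "gene_id", "chrom", "pos", "ref", "alt", "qual")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("`sites` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.list(sites$alt)) sites$alt <- as.list(sites$alt)
  if (any(lengths(sites$alt) < 1)) abort("every site needs at least one alternate allele")
  if (any(sites$pos < 1)) abort("positions are 1-based; `pos` must be >= 1")
  if (anyDuplicated(sites$site_id)) abort("duplicate site_id in `sites`")
  if (anyDuplicated(samples)) abort("duplicate sample ids")
  ad <- as_ad_array(ad, nrow(sites), length(samples))
  if (nrow(sites) > 0 && dim(ad)[3] < max(1L + lengths(sites$alt))) {
    abort("`ad` third dimension smaller than the largest allele count")
  }
  dimnames(ad) <- list(sites$site_id, samples, NULL)
  structure(list(sites = sites, samples = samples, ad = ad),
            class = "variant_table")
}

as_ad_array <- function(ad, n_sites, n_samples) {
  if (!is.array(ad) || length(dim(ad)) != 3) abort("`ad` must be a 3-d array")
  if (dim(ad)[1] != n_sites || dim(ad)[2] != n_samples) {
    abort("`ad` dimensions do not match sites/samples")
  }
  storage.mode(ad) <- "integer"
  if (any(ad < 0, na.rm = TRUE)) abort("read depths must be non-negative")
  ad[is.na(ad)] <- 0L
  ad
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (max ", dim(x$ad)[3], " alleles)\n", sep = "")
  print(head(x$sites, 5))
  invisible(x)
}

#' Number of sites / samples in a container
#' @param x A `variant_table` or `genotype_matrix`.
#' @return An integer count.
#' @export
n_sites <- function(x) UseMethod("n_sites")
#' @export
n_sites.variant_table <- function(x) nrow(x$sites)
#' @export
n_sites.genotype_matrix <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) UseMethod("n_samples")
#' @export
n_samples.variant_table <- function(x) length(x$samples)
#' @export
n_samples.genotype_matrix <- function(x) length(x$samples)

#' Total read depth matrix
#'
#' Sums per-allele depths into an `n_sites x n_samples` total-depth (DP)
#' matrix.
#'
#' @param vt A `variant_table`.
#' @return Integer matrix with site rows and sample columns.
#' @export
total_depth <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  dp <- vt$ad[, , 1, drop = FALSE][, , 1]
  if (dim(vt$ad)[3] > 1) {
    for (k in 2:dim(vt$ad)[3]) dp <- dp + vt$ad[, , k, drop = FALSE][, , 1]
  }
  if (is.null(dim(dp))) {
    dp <- matrix(dp, nrow = n_sites(vt), ncol = n_samples(vt),
                 dimnames = list(vt$sites$site_id, vt$samples))
  }
  dp
}

#' Subset a variant table
#'
#' @param vt A `variant_table`.
#' @param sites Character vector of site ids (or logical/integer index) to keep.
#' @param samples Optional sample ids to keep.
#' @return A `variant_table` restricted to the requested sites/samples.
#' @export
subset_sites <- function(vt, sites, samples = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (is.character(sites)) {
    idx <- match(sites, vt$sites$site_id)
    if (anyNA(idx)) abort("unknown site_id in `sites`")
  } else {
    idx <- seq_len(n_sites(vt))[sites]
  }
  sidx <- seq_along(vt$samples)
  if (!is.null(samples)) {
    sidx <- match(samples, vt$samples)
    if (anyNA(sidx)) abort("unknown sample id in `samples`")
  }
  variant_table(vt$sites[idx, , drop = FALSE], vt$samples[sidx],
                vt$ad[idx, sidx, , drop = FALSE])
}

#' Tidy long view of a variant table
#'
#' @param x A `variant_table`.
#' @param ... Unused.
#' @return A tibble with one row per site x sample: `site_id`, `sample_id`,
#'   `dp` (total depth) and `ad` (list column of per-allele depths, ref
#'   first, trimmed to the site's allele count).
#' @export
as_tibble.variant_table <- function(x, ...) {
  n_all <- 1L + lengths(x$sites$alt)
  long <- tidyr::expand_grid(site_id = x$sites$site_id, sample_id = x$samples)
  i <- match(long$site_id, x$sites$site_id)
  j <- match(long$sample_id, x$samples)
  ad_list <- lapply(seq_len(nrow(long)), function(r) x$ad[i[r], j[r], seq_len(n_all[i[r]])])
  long$ad <- ad_list
  long$dp <- vapply(ad_list, sum, integer(1))
  long
}

# ---------------------------------------------------------------------------

#' Validate and construct a sample sheet
#'
#' The sample sheet annotates every genotyped sample with its ploidy
#' (1 = haploid megagametophyte, 2 = diploid), its role in the study design,
#' its full-sib family and declared parents, and its replicate group (ramets
#' of one clone share a group).
#'
#' @param x A data frame with columns `sample_id`, `ploidy`, `role`
#'   (one of parent, offspring, unrelated, megagametophyte, replicate),
#'   `family_id`, `mother_id`, `father_id`, `replicate_group` (the last four
#'   may be `NA`).
#' @return A validated tibble (class `sample_sheet`).
#' @export
sample_sheet <- function(x) {
  x <- as_tibble(x)
  required <- c("sample_id", "ploidy", "role", "family_id", "mother_id",
                "father_id", "replicate_group")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x$ploidy <- as.integer(x$ploidy)
  roles <- c("parent", "offspring", "unrelated", "megagametophyte", "replicate")
  if (!all(x$role %in% roles)) {
    abort(paste0("unknown role(s): ", paste(setdiff(unique(x$role), roles), collapse = ", ")))
  }
  if (!all(x$ploidy %in% 1:2)) abort("ploidy must be 1 or 2")
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in sheet")
  meg <- x$role == "megagametophyte"
  if (any(x$ploidy[meg] != 1L)) abort("megagametophytes must have ploidy 1")
  if (any(is.na(x$mother_id[meg]))) abort("megagametophytes must carry a mother_id")
  if (any(!meg & x$ploidy == 1L)) abort("ploidy-1 samples must have role megagametophyte")
  off <- x$role == "offspring" & !is.na(x$family_id)
  if (any(is.na(x$mother_id[off]) | is.na(x$father_id[off]))) {
    abort("offspring with a family_id must declare both parents")
  }
  class(x) <- c("sample_sheet", class(x))
  x
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("<sample_sheet> ", nrow(x), " samples: ",
      paste(names(table(x$role)), table(x$role), sep = "=", collapse = ", "),
      "\n", sep = "")
  NextMethod()
}

ploidy_of <- function(sheet, samples) {
  p <- sheet$ploidy[match(samples, sheet$sample_id)]
  if (anyNA(p)) {
    abort(paste0("sample(s) not in sheet: ",
                 paste(samples[is.na(p)], collapse = ", ")))
  }
  setNames(p, samples)
}

# ---------------------------------------------------------------------------

#' Construct a genotype matrix
#'
#' Called genotypes for every sample at every site. Genotypes are unordered
#' allele multisets (phase is never represented): a diploid call is a pair of
#' allele indices (0 = ref), stored sorted; a haploid call is a single
#' allele. Missing calls carry `NA`.
#'
#' @param sites Site metadata tibble (as in [variant_table()]; `qual` optional).
#' @param samples Character vector of sample ids.
#' @param a1,a2 Integer matrices (`n_sites x n_samples`) of allele indices
#'   with `a1 <= a2`; for haploid samples `a2` is `NA` everywhere; a missing
#'   call has `a1` `NA`.
#' @param ploidy Named integer vector (1 or 2) per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, a1, a2, ploidy) {
  sites <- as_tibble(sites)
  stopifnot(is.matrix(a1), is.matrix(a2),
            nrow(a1) == nrow(sites), ncol(a1) == length(samples),
            all(dim(a1) == dim(a2)))
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  ploidy <- as.integer(ploidy[samples])
  if (anyNA(ploidy)) abort("`ploidy` must name every sample")
  hap <- ploidy == 1L
  if (any(!is.na(a2[, hap, drop = FALSE]))) abort("haploid samples cannot carry two alleles")
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(sites$site_id, samples)
  structure(list(sites = sites, samples = samples, a1 = a1, a2 = a2,
                 ploidy = setNames(ploidy, samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (", sum(x$ploidy == 1L), " haploid)\n", sep = "")
  cat("overall call rate: ",
      round(mean(!is.na(x$a1)), 3), "\n", sep = "")
  invisible(x)
}

#' Missingness indicator
#' @param gm A `genotype_matrix`.
#' @return Logical matrix, `TRUE` where the call is missing.
#' @export
is_missing <- function(gm) is.na(gm$a1)

#' Alternate-allele dosage matrix
#'
#' For biallelic analysis: counts of the first alternate allele (index 1)
#' per call. Diploids give 0/1/2, haploids 0/1, missing calls `NA`. Calls
#' involving allele indices above 1 (true multiallelic genotypes) are
#' returned as `NA` and a warning is raised, since dosage is only defined
#' for biallelic data.
#'
#' @param gm A `genotype_matrix`.
#' @param samples Optional subset of sample ids (default all).
#' @return Numeric matrix `n_sites x n_samples`.
#' @export
gt_dosage <- function(gm, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- if (is.null(samples)) seq_along(gm$samples) else match(samples, gm$samples)
  if (anyNA(j)) abort("unknown sample id in `samples`")
  a1 <- gm$a1[, j, drop = FALSE]; a2 <- gm$a2[, j, drop = FALSE]
  multi <- (!is.na(a1) & a1 > 1L) | (!is.na(a2) & a2 > 1L)
  d <- (a1 == 1L) + ifelse(is.na(a2), 0L, a2 == 1L)
  hap <- gm$ploidy[j] == 1L
  # haploid dosage is the single allele (0/1)
  if (any(multi)) {
    warn("multiallelic genotypes set to NA in dosage matrix")
    d[multi] <- NA_real_
  }
  dimnames(d) <- list(gm$sites$site_id, gm$samples[j])
  d
}

#' Subset a genotype matrix to a panel and/or samples
#' @param gm A `genotype_matrix`.
#' @param sites Site ids to keep (order preserved as given).
#' @param samples Optional sample ids to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  i <- if (is.null(sites)) seq_len(nrow(gm$sites)) else match(sites, gm$sites$site_id)
  if (anyNA(i)) abort("unknown site_id in `sites`")
  j <- if (is.null(samples)) seq_along(gm$samples) else match(samples, gm$samples)
  if (anyNA(j)) abort("unknown sample id in `samples`")
  genotype_matrix(gm$sites[i, , drop = FALSE], gm$samples[j],
                  gm$a1[i, j, drop = FALSE], gm$a2[i, j, drop = FALSE],
                  gm$ploidy[j])
}

#' Tidy long view of genotype calls
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return A tibble: `site_id`, `sample_id`, `ploidy`, `a1`, `a2` (allele
#'   indices, `NA` = missing), `genotype` (label such as `"0/1"`, `"1"`, or
#'   `NA`).
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  long <- tidyr::expand_grid(site_id = x$sites$site_id, sample_id = x$samples)
  i <- match(long$site_id, x$sites$site_id)
  j <- match(long$sample_id, x$samples)
  idx <- cbind(i, j)
  long$ploidy <- x$ploidy[j]
  long$a1 <- x$a1[idx]
  long$a2 <- x$a2[idx]
  long$genotype <- ifelse(is.na(long$a1), NA_character_,
                          ifelse(long$ploidy == 1L, as.character(long$a1),
                                 paste0(long$a1, "/", long$a2)))
  long
}

#' Per-sample and per-site call rates
#'
#' @param gm A `genotype_matrix`.
#' @param margin `"sample"` or `"site"`.
#' @param samples Optional cohort restriction (per-site rates only count
#'   these samples).
#' @return A tibble with id and `call_rate` in `[0, 1]`.
#' @export
call_rates <- function(gm, margin = c("sample", "site"), samples = NULL) {
  margin <- match.arg(margin)
  miss <- is_missing(gm)
  if (!is.null(samples)) {
    j <- match(samples, gm$samples)
    if (anyNA(j)) abort("unknown sample id in `samples`")
    miss <- miss[, j, drop = FALSE]
    ids <- gm$samples[j]
  } else ids <- gm$samples
  if (margin == "sample") {
    tibble(sample_id = ids, call_rate = unname(1 - colMeans(miss)))
  } else {
    tibble(site_id = gm$sites$site_id, call_rate = unname(1 - rowMeans(miss)))
  }
}

#' Minor allele frequency per site over a cohort
#'
#' Allele counts are ploidy-aware: a diploid call contributes two alleles, a
#' haploid call one. Frequencies are computed from non-missing calls only;
#' the MAF is `min(f, 1 - f)` of the first alternate allele. Sites with no
#' called alleles in the cohort get `NA`.
#'
#' @param gm A `genotype_matrix` (biallelic sites).
#' @param samples Cohort of sample ids (default: all samples).
#' @return A tibble: `site_id`, `n_alleles` (called allele count), `alt_freq`,
#'   `maf`.
#' @export
site_maf <- function(gm, samples = NULL) {
  d <- gt_dosage(gm, samples)
  j <- if (is.null(samples)) seq_along(gm$samples) else match(samples, gm$samples)
  pl <- matrix(gm$ploidy[j], nrow = nrow(d), ncol = ncol(d), byrow = TRUE)
  pl[is.na(d)] <- 0L
  n_all <- unname(rowSums(pl))
  alt <- unname(rowSums(d, na.rm = TRUE))
  f <- ifelse(n_all > 0, alt / n_all, NA_real_)
  tibble(site_id = gm$sites$site_id, n_alleles = as.integer(n_all),
         alt_freq = f, maf = pmin(f, 1 - f))
}
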