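#' Read a VCF with per-sample allele depths into a variant table
#'
#' Parses a VCF 4.x file (plain or gzipped) whose FORMAT carries `AD`
#' (per-allele read depths, ref first). The INFO keys `PROBE` and `GENE`,
#' when present, populate the probe/gene mapping; otherwise each site gets
#' its own probe and gene id. The VCF `QUAL` column is used as the site
#' quality score. Every VCF sample column must appear in the sheet.
#'
#' @param path Path to the VCF file.
#' @param sheet A [sample_sheet()] covering all VCF samples.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, sheet) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, sheet$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("VCF sample(s) not in sheet: ", paste(unknown, collapse = ", ")))
  }
  n <- nrow(fix)
  if (n == 0) abort("VCF contains no data lines")
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) abort(paste0("malformed POS at VCF data line ", which(is.na(pos))[1]))
  alt <- strsplit(fix$ALT, ",", fixed = TRUE)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0
  info_field <- function(key, default) {
    hit <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]+"), fix$INFO))
    out <- rep(NA_character_, n)
    has <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    out[has] <- sub(paste0(".*", key, "="), "", hit)
    ifelse(is.na(out), default, out)
  }
  site_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, ":", pos), fix$ID)
  sites <- tibble(
    site_id = site_id,
    probe_id = info_field("PROBE", paste0("probe_", site_id)),
    gene_id = info_field("GENE", paste0("gene_", site_id)),
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = alt, qual = qual)
  adm <- vcfR::extract.gt(v, element = "AD")
  if (is.null(adm)) abort("VCF has no AD FORMAT field")
  K <- max(1L + lengths(alt))
  ad <- array(0L, dim = c(n, length(samples), K))
  for (j in seq_along(samples)) {
    parts <- strsplit(ifelse(is.na(adm[, j]), "", adm[, j]), ",", fixed = TRUE)
    for (i in seq_len(n)) {
      d <- suppressWarnings(as.integer(parts[[i]]))
      d <- d[!is.na(d)]
      if (length(d) > 0) ad[i, j, seq_along(d)] <- d
      # absent AD entries stay as zero-depth (flagged by dp == 0)
    }
  }
  variant_table(sites, samples, ad)
}

#' Write a variant table as a VCF
#'
#' Emits VCF 4.2 with `AD:DP` per-sample fields and `PROBE`/`GENE` INFO
#' keys, sites sorted by (chrom, pos). Triallelic sites list their
#' alternates comma-separated in ALT.
#'
#' @param vt A [variant_table()].
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  if (n_sites(vt) == 0) abort("variant table is empty")
  ord <- order(vt$sites$chrom, vt$sites$pos)
  s <- vt$sites[ord, ]
  n_all <- 1L + lengths(s$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radpanel",
    "##INFO=<ID=PROBE,Number=1,Type=String,Description=\"Capture probe id\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene model id\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Per-allele read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t"))
  gt_cols <- vapply(seq_len(nrow(s)), function(r) {
    i <- ord[r]
    ads <- sapply(seq_len(n_all[r]), function(kk) vt$ad[i, , kk])
    if (is.null(dim(ads))) ads <- matrix(ads, nrow = length(vt$samples))
    paste0(apply(ads, 1, paste, collapse = ","), ":", rowSums(ads))
  }, character(length(vt$samples)))
  if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = length(vt$samples))
  lines <- vapply(seq_len(nrow(s)), function(r) {
    paste(c(s$chrom[r], s$pos[r], s$site_id[r], s$ref[r],
            paste(s$alt[[r]], collapse = ","),
            format(s$qual[r], trim = TRUE),
            ".",
            paste0("PROBE=", s$probe_id[r], ";GENE=", s$gene_id[r]),
            "AD:DP", gt_cols[, r]), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Tab-separated text with a header line
#' (`sample_id ploidy role family_id mother_id father_id replicate_group`);
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return [read_sample_sheet()] returns a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = c(sample_id = "character", ploidy = "integer",
                                 role = "character", family_id = "character",
                                 mother_id = "character",
                                 father_id = "character",
                                 replicate_group = "character"))
  sample_sheet(x)
}

#' @rdname read_sample_sheet
#' @param sheet A [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a SNP panel
#'
#' A single panel is stored as one site id per line (`#` comments allowed).
#'
#' @param path File path.
#' @return [read_panel()] returns a character vector of site ids.
#' @export
read_panel <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!grepl("^#", x) & nzchar(trimws(x))])
  if (anyDuplicated(x)) abort("panel contains duplicate site ids")
  x
}

#' @rdname read_panel
#' @param panel Character vector of site ids.
#' @param label Optional label written as a comment.
#' @export
write_panel <- function(panel, path, label = NULL) {
  hdr <- if (is.null(label)) character(0) else paste0("# panel: ", label)
  writeLines(c(hdr, panel), path)
  invisible(path)
}

# tab-separated output with a seed-recording comment header
write_tsv_report <- function(x, path, seed = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(extra)) writeLines(paste0("# ", extra), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write truth genotypes for external checking
#'
#' Emits the true genotypes of a `truth_set` as long tab-separated text
#' (`sample_id`, `site_id`, `a1`, `a2`) plus a per-site table with the true
#' alternate-allele frequency and paralog flags.
#'
#' @param truth A `truth_set`.
#' @param dir Output directory.
#' @param seed Seed recorded in the file headers.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- truth$sites
  sites$alt <- vapply(sites$alt, paste, character(1), collapse = ",")
  p1 <- file.path(dir, "truth_sites.tsv")
  write_tsv_report(sites, p1, seed)
  gt <- tibble(
    site_id = rep(rownames(truth$a1), times = ncol(truth$a1)),
    sample_id = rep(colnames(truth$a1), each = nrow(truth$a1)),
    a1 = as.vector(truth$a1), a2 = as.vector(truth$a2))
  p2 <- file.path(dir, "truth_genotypes.tsv")
  write_tsv_report(gt, p2, seed)
  invisible(c(p1, p2))
}
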