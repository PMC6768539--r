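# Fixtures are built in code; nothing is read from disk.

# A hand-built variant table: 3 biallelic sites, 2 diploids + 1 megagametophyte.
tiny_sheet <- function() {
  sample_sheet(tibble::tibble(
    sample_id = c("d1", "d2", "m1"),
    ploidy = c(2L, 2L, 1L),
    role = c("unrelated", "unrelated", "megagametophyte"),
    family_id = NA_character_,
    mother_id = c(NA, NA, "d1"),
    father_id = NA_character_,
    replicate_group = NA_character_))
}

tiny_vt <- function(ad = NULL) {
  sites <- tibble::tibble(
    site_id = c("s1", "s2", "s3"),
    probe_id = c("p1", "p1", "p2"),
    gene_id = c("g1", "g1", "g2"),
    chrom = c("c1", "c1", "c2"),
    pos = c(100L, 200L, 50L),
    ref = c("A", "C", "G"),
    alt = list("T", "G", "A"),
    qual = c(50, 60, 70))
  if (is.null(ad)) {
    ad <- array(0L, dim = c(3, 3, 2))
    ad[1, , ] <- rbind(c(30L, 28L), c(5L, 3L), c(20L, 0L))
    ad[2, , ] <- rbind(c(58L, 2L), c(0L, 40L), c(0L, 15L))
    ad[3, , ] <- rbind(c(12L, 12L), c(25L, 0L), c(9L, 0L))
  }
  variant_table(sites, c("d1", "d2", "m1"), ad)
}

# Genotype matrix built directly from dosages (biallelic, all diploid).
gm_from_dosage <- function(D, sample_ids = NULL, ploidy = NULL) {
  n <- ncol(D); S <- nrow(D)
  sample_ids <- sample_ids %||% sprintf("i%02d", seq_len(n))
  sites <- tibble::tibble(
    site_id = sprintf("s%03d", seq_len(S)), probe_id = sprintf("p%03d", seq_len(S)),
    gene_id = sprintf("g%03d", seq_len(S)), chrom = "c1", pos = seq_len(S),
    ref = "A", alt = replicate(S, "T", simplify = FALSE), qual = 50)
  ploidy <- ploidy %||% stats::setNames(rep(2L, n), sample_ids)
  hap <- ploidy[sample_ids] == 1L
  a1 <- ifelse(D == 2, 1L, 0L); a1[is.na(D)] <- NA_integer_
  a2 <- ifelse(D >= 1, 1L, 0L); a2[is.na(D)] <- NA_integer_
  # haploid dosage is the single allele itself
  a1[, hap] <- D[, hap]
  a2[, hap] <- NA_integer_
  genotype_matrix(sites, sample_ids, a1, a2, ploidy)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Cached simulations shared across test files (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Clean high-MAF study for parentage / clone tests: no error, no paralogs.
clean_study <- function() {
  cached("clean_study", {
    cfg <- sim_config(
      n_sites = 400L, n_unrelated = 60L, n_megagametophytes = 10L,
      families = list(list(mother = 1L, father = 2L, n_offspring = 25L),
                      list(mother = 3L, father = 4L, n_offspring = 25L)),
      maf_distribution = list(kind = "uniform", lo = 0.35, hi = 0.5),
      substitution_error = 0, paralog_probe_fraction = 0,
      triallelic_artifact_rate = 0, seed = 4001L)
    sim <- simulate_study(cfg)
    # truth-faithful calls: depth floor 1 and no ratio demotion, so the only
    # possible miscalls are heterozygotes whose minor allele was never read
    gm <- call_genotypes(sim$vt, sim$sheet, min_depth = 1L,
                         min_allele_ratio = 0)
    c(sim, list(gm = gm, cfg = cfg))
  })
}

# Default-condition study (error, paralogs, rare-variant MAF spectrum).
noisy_study <- function() {
  cached("noisy_study", {
    cfg <- sim_config(n_sites = 600L, n_unrelated = 60L,
                      n_megagametophytes = 40L,
                      families = list(list(mother = 1L, father = 2L, n_offspring = 15L)),
                      seed = 4002L)
    sim <- simulate_study(cfg)
    c(sim, list(cfg = cfg))
  })
}
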