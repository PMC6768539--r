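#' Simulation configuration
#'
#' Defaults emulate the study design the package's analyses assume: 135
#' putatively unrelated diploid founders, two full-sib mapping families (82
#' and 93 offspring), one haploid megagametophyte from each of 104 founders,
#' ramet (technical replicate) copies of the four family parents,
#' negative-binomial read depth around 60X, sequencing substitution error of
#' 0.2%, a rare-variant-skewed MAF spectrum (~94% of sites below MAF 0.03)
#' and a small fraction of paralog co-capture probes that make haploids look
#' heterozygous. `n_sites` defaults to a desk-scale 2000.
#'
#' @param n_unrelated Number of unrelated diploid founders.
#' @param families List of `list(mother=, father=, n_offspring=)`; parents are
#'   indices into the founders (or founder sample ids).
#' @param n_megagametophytes Number of founders (taken in order) contributing
#'   one haploid megagametophyte each.
#' @param replicate_copies Named integer vector: extra ramet copies to render
#'   per sample; `NULL` gives 2 extra copies of every family parent.
#' @param n_sites Number of biallelic SNP sites to simulate.
#' @param maf_distribution `list(kind = "beta", shape1, shape2)` (MAF =
#'   `0.5 * Beta(shape1, shape2)`) or `list(kind = "uniform", lo, hi)`.
#' @param mean_depth Mean of the negative-binomial read depth per data point.
#' @param depth_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param substitution_error Per-read probability of substitution to another
#'   listed allele, in `[0, 0.01]`.
#' @param paralog_probe_fraction Fraction of probes co-capturing a duplicated
#'   latent locus.
#' @param triallelic_artifact_rate Fraction of sites listing a spurious third
#'   allele reachable by sequencing error.
#' @param snps_per_probe_mean Mean of the (geometric-like) SNPs-per-probe
#'   distribution.
#' @param probes_per_gene_mean Mean probes per gene model.
#' @param seed Integer seed making the whole study reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_unrelated = 135L,
                       families = list(
                         list(mother = 1L, father = 2L, n_offspring = 82L),
                         list(mother = 3L, father = 4L, n_offspring = 93L)),
                       n_megagametophytes = 104L,
                       replicate_copies = NULL,
                       n_sites = 2000L,
                       maf_distribution = list(kind = "beta", shape1 = 0.05, shape2 = 3),
                       mean_depth = 60,
                       depth_dispersion = 5,
                       substitution_error = 0.002,
                       paralog_probe_fraction = 0.05,
                       triallelic_artifact_rate = 0.02,
                       snps_per_probe_mean = 1.34,
                       probes_per_gene_mean = 1.54,
                       seed = 1L) {
  cfg <- list(n_unrelated = as.integer(n_unrelated), families = families,
              n_megagametophytes = as.integer(n_megagametophytes),
              replicate_copies = replicate_copies,
              n_sites = as.integer(n_sites),
              maf_distribution = maf_distribution,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              substitution_error = substitution_error,
              paralog_probe_fraction = paralog_probe_fraction,
              triallelic_artifact_rate = triallelic_artifact_rate,
              snps_per_probe_mean = snps_per_probe_mean,
              probes_per_gene_mean = probes_per_gene_mean,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_sites < 0) abort("n_sites must be >= 0")
  if (cfg$n_unrelated < 2) abort("need at least 2 founders")
  if (cfg$substitution_error < 0 || cfg$substitution_error > 0.01) {
    abort("substitution_error must be in [0, 0.01]")
  }
  for (nm in c("paralog_probe_fraction", "triallelic_artifact_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) abort(paste(nm, "must be in [0, 1]"))
  }
  if (cfg$mean_depth <= 0 || cfg$depth_dispersion <= 0) {
    abort("mean_depth and depth_dispersion must be positive")
  }
  md <- cfg$maf_distribution
  if (!md$kind %in% c("beta", "uniform")) abort("maf_distribution kind must be beta or uniform")
  if (md$kind == "uniform" &&
      (md$lo > md$hi || md$lo < 0 || md$hi > 0.5)) {
    abort("uniform maf bounds must satisfy 0 <= lo <= hi <= 0.5")
  }
  if (md$kind == "beta" && (md$shape1 <= 0 || md$shape2 <= 0)) {
    abort("beta maf shapes must be positive")
  }
  invisible(cfg)
}

draw_maf <- function(n, md) {
  switch(md$kind,
         uniform = runif(n, md$lo, md$hi),
         beta = 0.5 * rbeta(n, md$shape1, md$shape2))
}

NUCS <- c("A", "C", "G", "T")

#' Simulate unrelated founders under Hardy-Weinberg proportions
#'
#' Draws a per-site alternate-allele frequency from the configured MAF
#' spectrum, lays sites out on probes and gene models, flags paralog
#' co-capture probes, and draws founder genotypes independently across
#' sites and individuals under Hardy-Weinberg proportions.
#'
#' @param cfg A [sim_config()]. The caller controls the RNG: this function
#'   does not reseed (use [simulate_study()] for a fully seeded run).
#' @return A `truth_set`: list with `sites` (site metadata plus `p_alt`,
#'   paralog flags and latent paralog genotype), `a1`/`a2` true-genotype
#'   matrices (sites x individuals), and a [sample_sheet()].
#' @export
simulate_founders <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_unrelated; S <- cfg$n_sites
  if (S < 1) abort("n_sites must be >= 1")
  p <- draw_maf(S, cfg$maf_distribution)
  # probe / gene layout: geometric-like SNPs per probe, probes per gene
  sites <- layout_sites(S, cfg)
  sites$p_alt <- p
  # paralog probes: a duplicated latent locus with one fixed genotype
  probes <- unique(sites$probe_id)
  para_probes <- probes[runif(length(probes)) < cfg$paralog_probe_fraction]
  sites$paralog <- sites$probe_id %in% para_probes
  lat1 <- ifelse(sites$paralog, as.integer(runif(S) < p), NA_integer_)
  lat2 <- ifelse(sites$paralog, as.integer(runif(S) < p), NA_integer_)
  sites$paralog_a1 <- pmin(lat1, lat2)
  sites$paralog_a2 <- pmax(lat1, lat2)
  ids <- sprintf("U%03d", seq_len(n))
  g1 <- matrix(as.integer(runif(S * n) < p), S, n)
  g2 <- matrix(as.integer(runif(S * n) < p), S, n)
  a1 <- pmin(g1, g2); a2 <- pmax(g1, g2)
  dimnames(a1) <- dimnames(a2) <- list(sites$site_id, ids)
  sheet <- sample_sheet(tibble(
    sample_id = ids, ploidy = 2L, role = "unrelated",
    family_id = NA_character_, mother_id = NA_character_,
    father_id = NA_character_, replicate_group = NA_character_))
  structure(list(sites = sites, a1 = a1, a2 = a2, sheet = sheet),
            class = "truth_set")
}

layout_sites <- function(S, cfg) {
  # SNPs per probe ~ 1 + geometric, mean snps_per_probe_mean
  p_probe <- 1 / cfg$snps_per_probe_mean
  sizes <- integer(0)
  while (sum(sizes) < S) {
    sizes <- c(sizes, 1L + stats::rgeom(max(64L, S %/% 2L), p_probe))
  }
  probe_of <- rep(seq_along(sizes), times = sizes)[seq_len(S)]
  n_probes <- max(probe_of)
  p_gene <- 1 / cfg$probes_per_gene_mean
  gsizes <- integer(0)
  while (sum(gsizes) < n_probes) {
    gsizes <- c(gsizes, 1L + stats::rgeom(max(64L, n_probes %/% 2L), p_gene))
  }
  gene_of_probe <- rep(seq_along(gsizes), times = gsizes)[seq_len(n_probes)]
  ref <- sample(NUCS, S, replace = TRUE)
  alt1 <- map_chr(ref, function(r) sample(setdiff(NUCS, r), 1))
  tri <- runif(S) < cfg$triallelic_artifact_rate
  alt <- lapply(seq_len(S), function(i) {
    if (tri[i]) c(alt1[i], sample(setdiff(NUCS, c(ref[i], alt1[i])), 1)) else alt1[i]
  })
  tibble(
    site_id = sprintf("S%05d", seq_len(S)),
    probe_id = sprintf("P%05d", probe_of),
    gene_id = sprintf("G%05d", gene_of_probe[probe_of]),
    chrom = sprintf("scaffold%02d", 1L + (probe_of - 1L) %% 12L),
    pos = 1000L * probe_of + stats::ave(seq_len(S), probe_of, FUN = seq_along),
    ref = ref, alt = alt,
    qual = round(runif(S, 20, 2000), 1))
}

#' Extend a truth set with a full-sib family
#'
#' Each offspring receives one uniformly chosen allele from each parent,
#' independently per site (Mendelian segregation, unlinked sites).
#'
#' @param truth A `truth_set`.
#' @param mother,father Sample ids of the (diploid) parents.
#' @param n_offspring Number of offspring.
#' @param family_id Family label (default derived from the parents).
#' @return The extended `truth_set`.
#' @export
simulate_family <- function(truth, mother, father, n_offspring,
                            family_id = NULL) {
  stopifnot(inherits(truth, "truth_set"), n_offspring >= 0)
  for (pid in c(mother, father)) {
    if (!pid %in% colnames(truth$a1)) abort(paste0("unknown parent: ", pid))
  }
  family_id <- family_id %||% paste0("F_", mother, "_", father)
  if (n_offspring == 0) return(truth)
  S <- nrow(truth$sites)
  ids <- sprintf("%s_O%03d", family_id, seq_len(n_offspring))
  gam <- function(pid) {
    pick <- matrix(runif(S * n_offspring) < 0.5, S, n_offspring)
    ifelse(pick, truth$a1[, pid], truth$a2[, pid])
  }
  g1 <- gam(mother); g2 <- gam(father)
  a1 <- pmin(g1, g2); a2 <- pmax(g1, g2)
  colnames(a1) <- colnames(a2) <- ids
  truth$a1 <- cbind(truth$a1, a1)
  truth$a2 <- cbind(truth$a2, a2)
  add <- tibble(sample_id = ids, ploidy = 2L, role = "offspring",
                family_id = family_id, mother_id = mother, father_id = father,
                replicate_group = NA_character_)
  truth$sheet <- sample_sheet(bind_rows(as_tibble(truth$sheet), add))
  # parents become role "parent"
  truth$sheet$role[truth$sheet$sample_id %in% c(mother, father)] <- "parent"
  truth
}

#' Extend a truth set with a haploid megagametophyte
#'
#' The megagametophyte carries one uniformly chosen maternal allele per site
#' (a single maternal gamete, the haploid seed tissue of conifers).
#'
#' @param truth A `truth_set`.
#' @param mother Sample id of the mother.
#' @param id Sample id for the new haploid sample (default `meg_<mother>`).
#' @return The extended `truth_set`.
#' @export
simulate_megagametophyte <- function(truth, mother, id = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!mother %in% colnames(truth$a1)) abort(paste0("unknown mother: ", mother))
  id <- id %||% paste0("meg_", mother)
  S <- nrow(truth$sites)
  pick <- runif(S) < 0.5
  a1 <- matrix(ifelse(pick, truth$a1[, mother], truth$a2[, mother]), ncol = 1)
  a2 <- matrix(NA_integer_, S, 1)
  colnames(a1) <- colnames(a2) <- id
  truth$a1 <- cbind(truth$a1, a1)
  truth$a2 <- cbind(truth$a2, a2)
  add <- tibble(sample_id = id, ploidy = 1L, role = "megagametophyte",
                family_id = NA_character_, mother_id = mother,
                father_id = NA_character_, replicate_group = NA_character_)
  truth$sheet <- sample_sheet(bind_rows(as_tibble(truth$sheet), add))
  truth
}

#' Extend a truth set with ramet (replicate) copies of a sample
#'
#' Ramets share the source sample's true genotype exactly; only read depth
#' and sequencing error are re-rendered per copy. The source sample and its
#' copies share a `replicate_group`.
#'
#' @param truth A `truth_set`.
#' @param sample_id Sample to copy.
#' @param n_copies Number of extra copies.
#' @return The extended `truth_set`.
#' @export
simulate_replicates <- function(truth, sample_id, n_copies) {
  stopifnot(inherits(truth, "truth_set"), n_copies >= 0)
  if (!sample_id %in% colnames(truth$a1)) abort(paste0("unknown sample: ", sample_id))
  if (n_copies == 0) return(truth)
  ids <- sprintf("%s_rep%d", sample_id, seq_len(n_copies))
  a1 <- truth$a1[, rep(sample_id, n_copies), drop = FALSE]
  a2 <- truth$a2[, rep(sample_id, n_copies), drop = FALSE]
  colnames(a1) <- colnames(a2) <- ids
  truth$a1 <- cbind(truth$a1, a1)
  truth$a2 <- cbind(truth$a2, a2)
  src <- truth$sheet[truth$sheet$sample_id == sample_id, ]
  grp <- sample_id  # tibble() resolves bare `sample_id` to its own column
  add <- tibble(sample_id = ids, ploidy = src$ploidy, role = "replicate",
                family_id = src$family_id, mother_id = src$mother_id,
                father_id = src$father_id, replicate_group = grp)
  sheet <- as_tibble(truth$sheet)
  sheet$replicate_group[sheet$sample_id == sample_id] <- sample_id
  truth$sheet <- sample_sheet(bind_rows(sheet, add))
  truth
}

#' Render read depths from a truth set
#'
#' Per sample and site, total depth is negative binomial
#' (`mu = mean_depth`, `size = depth_dispersion`); each read is drawn from
#' the true genotype's alleles (uniformly for heterozygotes) and substituted
#' to a uniformly chosen other listed allele with probability
#' `substitution_error`. For sites on paralog-flagged probes, the duplicated
#' latent locus contributes half of the read mass, producing the
#' pseudo-heterozygous haploid signal the filtering pipelines target.
#'
#' @param truth A `truth_set`.
#' @param cfg A [sim_config()].
#' @return A list: `vt` ([variant_table()]), `sheet` ([sample_sheet()]).
#' @export
render_reads <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"))
  validate_sim_config(cfg)
  S <- nrow(truth$sites); N <- ncol(truth$a1)
  if (S == 0 || N == 0) abort("truth set is empty")
  n_alleles <- 1L + lengths(truth$sites$alt)
  K <- max(n_alleles)
  hap <- truth$sheet$ploidy[match(colnames(truth$a1), truth$sheet$sample_id)] == 1L
  # true allele fractions per (site, sample) over allele slots 0..K-1
  frac <- array(0, dim = c(S, N, K))
  for (k in 0:(K - 1)) {
    f <- (truth$a1 == k) + ifelse(is.na(truth$a2), 0L, truth$a2 == k)
    f <- sweep(f, 2, ifelse(hap, 1L, 2L), "/")
    frac[, , k + 1] <- f
  }
  # paralog probes: latent locus contributes half of the read mass
  para <- which(truth$sites$paralog)
  if (length(para) > 0) {
    for (k in 0:(K - 1)) {
      latf <- ((truth$sites$paralog_a1[para] == k) +
                 (truth$sites$paralog_a2[para] == k)) / 2
      frac[para, , k + 1] <- 0.5 * frac[para, , k + 1] +
        0.5 * matrix(latf, length(para), N)
    }
  }
  # substitution error to a uniformly chosen other *listed* allele
  e <- cfg$substitution_error
  if (e > 0) {
    A <- matrix(n_alleles, S, N)
    q <- array(0, dim = c(S, N, K))
    for (k in seq_len(K)) {
      other <- matrix(0, S, N)
      for (j in seq_len(K)) if (j != k) other <- other + frac[, , j]
      qk <- frac[, , k] * (1 - e) + e * other / pmax(A - 1, 1)
      qk[matrix(n_alleles, S, N) < k] <- 0
      q[, , k] <- qk
    }
    frac <- q
  }
  dp <- matrix(rnbinom(S * N, size = cfg$depth_dispersion, mu = cfg$mean_depth), S, N)
  ad <- array(0L, dim = c(S, N, K))
  remaining <- dp
  pleft <- matrix(1, S, N)
  for (k in seq_len(K - 1)) {
    pk <- frac[, , k] / pmax(pleft, 1e-12)
    pk <- pmin(pmax(pk, 0), 1)
    ck <- rbinom(S * N, size = as.vector(remaining), prob = as.vector(pk))
    ck <- matrix(ck, S, N)
    ck[remaining == 0L] <- 0L
    ad[, , k] <- ck
    remaining <- remaining - ck
    pleft <- pleft - frac[, , k]
  }
  last <- remaining
  last[matrix(n_alleles, S, N) < K] <- 0L  # no mass on absent allele slots
  ad[, , K] <- last
  vt <- variant_table(truth$sites[, c("site_id", "probe_id", "gene_id",
                                      "chrom", "pos", "ref", "alt", "qual")],
                      colnames(truth$a1), ad)
  list(vt = vt, sheet = truth$sheet)
}

#' Simulate a complete study
#'
#' Seeds the RNG from `cfg$seed`, simulates founders, the configured
#' full-sib families, megagametophytes and replicate copies, renders read
#' depths, and returns truth plus rendered data.
#'
#' @param cfg A [sim_config()].
#' @return A list with `truth` (`truth_set`), `vt` ([variant_table()]) and
#'   `sheet` ([sample_sheet()]).
#' @export
simulate_study <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  truth <- simulate_founders(cfg)
  founders <- colnames(truth$a1)
  fam_parents <- character(0)
  for (i in seq_along(cfg$families)) {
    fam <- cfg$families[[i]]
    mo <- if (is.numeric(fam$mother)) founders[fam$mother] else fam$mother
    fa <- if (is.numeric(fam$father)) founders[fam$father] else fam$father
    truth <- simulate_family(truth, mo, fa, fam$n_offspring,
                             family_id = paste0("FAM", i))
    fam_parents <- c(fam_parents, mo, fa)
  }
  n_meg <- min(cfg$n_megagametophytes, cfg$n_unrelated)
  for (m in founders[seq_len(n_meg)]) {
    truth <- simulate_megagametophyte(truth, m)
  }
  reps <- cfg$replicate_copies
  if (is.null(reps)) reps <- setNames(rep(2L, length(unique(fam_parents))),
                                      unique(fam_parents))
  for (s in names(reps)) truth <- simulate_replicates(truth, s, reps[[s]])
  rendered <- render_reads(truth, cfg)
  list(truth = truth, vt = rendered$vt, sheet = rendered$sheet)
}

#' Perturb called genotypes with error and missingness
#'
#' Utility for robustness experiments: each non-missing call is replaced,
#' independently, with probability `error_rate` by a different genotype
#' (uniform over the other two biallelic genotypes for diploids, the other
#' allele for haploids), and set missing with probability `missing_rate`.
#'
#' @param gm A `genotype_matrix` (biallelic).
#' @param error_rate Per-call genotype error probability.
#' @param missing_rate Per-call missingness probability.
#' @return A perturbed `genotype_matrix`.
#' @export
perturb_genotypes <- function(gm, error_rate = 0, missing_rate = 0) {
  stopifnot(inherits(gm, "genotype_matrix"),
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  a1 <- gm$a1; a2 <- gm$a2
  called <- !is.na(a1)
  dip <- matrix(gm$ploidy == 2L, nrow(a1), ncol(a1), byrow = TRUE)
  if (error_rate > 0) {
    err <- called & matrix(runif(length(a1)) < error_rate, nrow(a1))
    # diploid: dosage moved to one of the other two genotypes, uniformly
    di <- which(err & dip)
    if (length(di) > 0) {
      d <- a1[di] + a2[di]
      shift <- ifelse(runif(length(di)) < 0.5, 1L, 2L)
      nd <- (d + shift) %% 3L
      a1[di] <- ifelse(nd == 2L, 1L, 0L)
      a2[di] <- ifelse(nd == 0L, 0L, 1L)
    }
    hi <- which(err & !dip)
    if (length(hi) > 0) a1[hi] <- 1L - a1[hi]
  }
  if (missing_rate > 0) {
    drop <- called & matrix(runif(length(a1)) < missing_rate, nrow(a1))
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  a2[is.na(a1)] <- NA_integer_
  a2[!dip] <- NA_integer_
  genotype_matrix(gm$sites, gm$samples, a1, a2, gm$ploidy)
}
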