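test_that("founder frequencies follow the configured MAF spectrum", {
  cfg <- sim_config(n_unrelated = 135L, n_sites = 10000L,
                    maf_distribution = list(kind = "uniform", lo = 0.5, hi = 0.5),
                    seed = 101L)
  set.seed(cfg$seed)
  truth <- simulate_founders(cfg)
  expect_true(all(truth$sites$p_alt == 0.5))
  # mean observed founder MAF within 3 SE of 0.425 under uniform(0.35, 0.5)
  cfg2 <- sim_config(n_unrelated = 135L, n_sites = 10000L,
                     maf_distribution = list(kind = "uniform", lo = 0.35, hi = 0.5),
                     seed = 102L)
  set.seed(cfg2$seed)
  truth2 <- simulate_founders(cfg2)
  obs <- (colSums(t(truth2$a1) ) + colSums(t(truth2$a2))) / (2 * 135)
  obs_maf <- pmin(obs, 1 - obs)
  # var of one site's observed MAF ~ var(U) + E[p(1-p)]/(2n); bound loosely
  se <- sqrt((0.15^2 / 12 + 0.25 / 270) / 10000)
  expect_lt(abs(mean(obs_maf) - 0.425), 3 * se + 0.003)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_sites = 150L, n_unrelated = 12L, n_megagametophytes = 4L,
                    families = list(list(mother = 1L, father = 2L, n_offspring = 6L)),
                    seed = 77L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$a1, s2$truth$a1)
  expect_identical(s1$vt$ad, s2$vt$ad)
  expect_identical(s1$sheet, s2$sheet)
})

test_that("offspring and megagametophytes obey Mendelian constraints", {
  sim <- clean_study()
  truth <- sim$truth
  sheet <- truth$sheet
  offs <- sheet$sample_id[sheet$role == "offspring"]
  for (o in offs[1:5]) {
    mo <- sheet$mother_id[sheet$sample_id == o]
    fa <- sheet$father_id[sheet$sample_id == o]
    from_mo <- truth$a1[, o] == truth$a1[, mo] | truth$a1[, o] == truth$a2[, mo] |
      truth$a2[, o] == truth$a1[, mo] | truth$a2[, o] == truth$a2[, mo]
    expect_true(all(from_mo))
    rm(fa)
  }
  megs <- sheet$sample_id[sheet$role == "megagametophyte"]
  for (m in megs) {
    mo <- sheet$mother_id[sheet$sample_id == m]
    ok <- truth$a1[, m] == truth$a1[, mo] | truth$a1[, m] == truth$a2[, mo]
    expect_true(all(ok))
  }
  # het x het family segregates ~1:2:1
  cfg <- sim_config(n_sites = 1L, n_unrelated = 2L, n_megagametophytes = 0L,
                    families = list(), seed = 55L,
                    maf_distribution = list(kind = "uniform", lo = 0.5, hi = 0.5))
  set.seed(55)
  tr <- simulate_founders(cfg)
  tr$a1[1, ] <- 0L; tr$a2[1, ] <- 1L  # force both parents heterozygous
  tr <- simulate_family(tr, "U001", "U002", 10000L)
  d <- tr$a1[1, -(1:2)] + tr$a2[1, -(1:2)]
  p_hat <- table(factor(d, levels = 0:2)) / 10000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(p_hat - c(.25, .5, .25)) < 3 * se))
})

test_that("megagametophytes sample maternal gametes uniformly", {
  cfg <- sim_config(n_sites = 1L, n_unrelated = 2L, families = list(),
                    n_megagametophytes = 0L, seed = 56L,
                    maf_distribution = list(kind = "uniform", lo = 0.5, hi = 0.5))
  set.seed(56)
  tr <- simulate_founders(cfg)
  tr$a1[1, "U001"] <- 0L; tr$a2[1, "U001"] <- 1L
  for (i in 1:1000) tr <- simulate_megagametophyte(tr, "U001", sprintf("mg%04d", i))
  alleles <- tr$a1[1, grepl("^mg", colnames(tr$a1))]
  expect_lt(abs(mean(alleles) - 0.5), 3 * sqrt(0.25 / 1000))
  expect_error(simulate_megagametophyte(tr, "nobody"), "unknown mother")
})

test_that("rendered depths follow the negative-binomial model", {
  sim <- noisy_study()
  dp <- total_depth(sim$vt)
  mu <- sim$cfg$mean_depth; size <- sim$cfg$depth_dispersion
  n <- length(dp)
  se <- sqrt((mu + mu^2 / size) / n)
  expect_lt(abs(mean(dp) - mu), 3 * se)
})

test_that("error-free haploid depth vectors have a single non-zero entry", {
  sim <- clean_study()  # substitution_error 0, paralogs 0
  hap <- sim$sheet$sample_id[sim$sheet$ploidy == 1L]
  j <- match(hap, sim$vt$samples)
  ad <- sim$vt$ad[, j, , drop = FALSE]
  n_nonzero <- (ad[, , 1, drop = FALSE] > 0) + (ad[, , 2, drop = FALSE] > 0)
  covered <- (ad[, , 1, drop = FALSE] + ad[, , 2, drop = FALSE]) > 0
  expect_true(all(n_nonzero[covered] == 1L))
})

test_that("substitution error produces the expected alternate reads", {
  # homozygous-ref truth, error 0.002, deep coverage: E[alt reads] = e * depth
  cfg <- sim_config(n_sites = 200L, n_unrelated = 5L, families = list(),
                    n_megagametophytes = 0L, mean_depth = 1000,
                    depth_dispersion = 1e6, substitution_error = 0.002,
                    paralog_probe_fraction = 0, triallelic_artifact_rate = 0,
                    maf_distribution = list(kind = "uniform", lo = 0.01, hi = 0.01),
                    seed = 58L)
  set.seed(58)
  truth <- simulate_founders(cfg)
  truth$a1[] <- 0L; truth$a2[] <- 0L  # force hom-ref
  rnd <- render_reads(truth, cfg)
  dp <- total_depth(rnd$vt)
  alt <- rnd$vt$ad[, , 2]
  rate <- sum(alt) / sum(dp)
  se <- sqrt(0.002 * 0.998 / sum(dp))
  expect_lt(abs(rate - 0.002), 3 * se)
})

test_that("calling on clean rendered data recovers the truth where covered", {
  sim <- clean_study()
  gm <- call_genotypes(sim$vt, sim$sheet, min_depth = 1L,
                       min_allele_ratio = 0)
  covered <- total_depth(sim$vt) > 0
  # a heterozygote whose minor allele drew zero reads is unrecoverable from
  # read data by construction; everything else must be recovered exactly
  het <- !is.na(sim$truth$a2) & sim$truth$a1 != sim$truth$a2
  minor_unseen <- het & (sim$vt$ad[, , 1] == 0L | sim$vt$ad[, , 2] == 0L)
  same <- (gm$a1 == sim$truth$a1 | (is.na(gm$a1) & is.na(sim$truth$a1))) &
    (gm$a2 == sim$truth$a2 | (is.na(gm$a2) & is.na(sim$truth$a2)))
  expect_true(all(same[covered & !minor_unseen]))
  expect_lt(mean(minor_unseen[covered]), 1e-3)
})

test_that("missingness decreases with mean depth", {
  miss_at <- function(mu) {
    cfg <- sim_config(n_sites = 300L, n_unrelated = 20L, families = list(),
                      n_megagametophytes = 0L, mean_depth = mu, seed = 59L)
    sim <- simulate_study(cfg)
    mean(is_missing(call_genotypes(sim$vt, sim$sheet, min_depth = 10L)))
  }
  m <- vapply(c(5, 15, 30, 60), miss_at, numeric(1))
  expect_true(all(diff(m) <= 0))
  # largely invariant above ~20X, severe below 10X
  expect_gt(m[1], 0.3)
  expect_lt(m[4], 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sites = -1), "n_sites")
  expect_error(sim_config(substitution_error = 0.5), "substitution_error")
  expect_error(sim_config(maf_distribution = list(kind = "uniform", lo = .4, hi = .2)),
               "bounds")
  expect_error(simulate_family(clean_study()$truth, "ghost", "U001", 2L),
               "unknown parent")
})
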