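# Independent oracle: brute-force enumeration of the 2 x 2 ordered gamete
# pairings at a biallelic locus.
brute_force_offspring <- function(p1, p2) {
  out <- list()
  for (i in 1:2) for (j in 1:2) out <- c(out, list(sort(c(p1[i], p2[j]))))
  unique(out)
}

all_biallelic_genotypes <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))

test_that("compatible genotype sets match brute-force gamete enumeration", {
  for (g1 in all_biallelic_genotypes) {
    for (g2 in all_biallelic_genotypes) {
      expect_setequal(
        lapply(compatible_offspring_genotypes(g1, g2), paste, collapse = "/"),
        lapply(brute_force_offspring(g1, g2), paste, collapse = "/"))
    }
  }
  # het x het realises the maximum of 4 ordered combinations (3 genotypes)
  n_ordered <- vapply(all_biallelic_genotypes, function(g1) {
    max(vapply(all_biallelic_genotypes, function(g2) {
      combos <- expand.grid(a = g1, b = g2)
      nrow(unique(combos))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(max(n_ordered), 4)
  expect_length(compatible_offspring_genotypes(c(0L, 1L), c(0L, 1L)), 3L)
  expect_equal(compatible_offspring_genotypes(c(0L, 0L), c(1L, 1L)), list(c(0L, 1L)))
  # missing parents are non-informative
  expect_length(compatible_offspring_genotypes(NULL, c(0L, 1L)), 0L)
})

test_that("trio exclusions count incompatible, non-missing panel SNPs", {
  # site1: off aa vs AA x Aa -> exclusion; site2: off missing -> skipped;
  # site3: compatible
  D <- rbind(c(0, 1, 2), c(1, 1, NA), c(1, 2, 2))
  gm <- gm_from_dosage(D, c("mo", "fa", "off"))
  res <- trio_exclusions(gm, "off", "mo", "fa", gm$sites$site_id)
  expect_equal(res$n_comparable, 2L)
  expect_equal(res$n_exclusions, 1L)
  expect_error(trio_exclusions(gm, "off", "mo", "ghost", gm$sites$site_id),
               "unknown sample")
})

test_that("the matrix engine agrees with per-trio counting on noisy data", {
  set.seed(17)
  n_cand <- 8L; S <- 40L
  D <- matrix(rbinom(n_cand * S, 2, runif(S, 0.2, 0.5)), S, n_cand)
  D[matrix(runif(length(D)) < 0.15, S)] <- NA
  o <- rbinom(S, 2, 0.4); o[runif(S) < 0.1] <- NA
  ids <- c(sprintf("c%02d", seq_len(n_cand)), "off")
  gm <- gm_from_dosage(cbind(D, o), ids)
  panel <- gm$sites$site_id
  fast <- assign_parents(gm, "off", ids[1:n_cand], panel)
  for (r in sample(nrow(fast), 10)) {
    slow <- trio_exclusions(gm, "off", fast$parent1[r], fast$parent2[r], panel)
    expect_equal(fast$n_exclusions[r], slow$n_exclusions)
    expect_equal(fast$n_comparable[r], slow$n_comparable)
  }
})

test_that("true parents are uniquely minimal with zero exclusions when clean", {
  sim <- clean_study()
  sheet <- sim$sheet
  cand <- sheet$sample_id[sheet$role %in% c("parent", "unrelated")]
  offs <- sheet$sample_id[sheet$role == "offspring"][c(1, 30)]
  panel <- sim$gm$sites$site_id[1:110]
  for (o in offs) {
    res <- assign_parents(sim$gm, o, cand, panel)
    best <- res[res$is_minimal, ]
    expect_equal(nrow(best), 1L)
    expect_equal(best$n_exclusions, 0L)
    declared <- sort(c(sheet$mother_id[sheet$sample_id == o],
                       sheet$father_id[sheet$sample_id == o]))
    expect_equal(sort(c(best$parent1, best$parent2)), declared)
    expect_gt(best$margin, 0)
  }
  # excluding the true parents forces exclusions onto the minimal pair
  res2 <- assign_parents(sim$gm, offs[1],
                         setdiff(cand, c("U001", "U002", "U003", "U004")), panel)
  expect_gt(min(res2$n_exclusions), 0L)
})

test_that("identical candidate genotypes produce a reported tie", {
  D <- rbind(c(0, 0, 1, 1), c(1, 1, 2, 1), c(2, 2, 0, 1), c(1, 1, 0, 0))
  gm <- gm_from_dosage(D, c("twin1", "twin2", "other", "off"))
  res <- assign_parents(gm, "off", c("twin1", "twin2", "other"), gm$sites$site_id)
  mins <- res[res$is_minimal, ]
  # (twin1, other) and (twin2, other) tie exactly
  expect_gte(nrow(mins), 2L)
  expect_equal(mins$margin, rep(0, nrow(mins)))
})

test_that("exclusion counts are non-decreasing in prefix panel size", {
  sim <- clean_study()
  gmp <- perturb_genotypes(sim$gm, error_rate = 0.05, missing_rate = 0.1)
  panel <- sim$gm$sites$site_id[1:110]
  off <- sim$sheet$sample_id[sim$sheet$role == "offspring"][1]
  counts <- vapply(c(30, 60, 90, 110), function(k) {
    trio_exclusions(gmp, off, "U001", "U002", panel[1:k])$n_exclusions
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("reduction experiment tallies assignments against the pedigree", {
  sim <- clean_study()
  pool <- sim$gm$sites$site_id
  panels <- random_panels(pool, n_panels = 3, panel_size = 110, seed = 12)
  res <- reduction_experiment(sim$gm, sim$sheet, panels,
                              sizes = c(50, 80, 110))
  expect_equal(nrow(res), 9L)
  # error-free: every offspring correctly assigned at every size
  expect_true(all(res$accuracy == 1))
  expect_true(all(res$n_false == 0L))
  expect_true(all(res$n_dropped == 0L))
  # heavy missingness in one offspring shrinks its comparable count and can
  # drop it below the floor
  gmp <- sim$gm
  off1 <- sim$sheet$sample_id[sim$sheet$role == "offspring"][1]
  gmp$a1[seq(1, 400, by = 2), off1] <- NA_integer_
  gmp$a2[is.na(gmp$a1)] <- NA_integer_
  res2 <- reduction_experiment(gmp, sim$sheet, panels[panels$panel == "panel_1", ],
                               sizes = 110, min_comparable_frac = 0.6)
  expect_equal(res2$n_dropped, 1L)
})

test_that("assignment accuracy degrades as panels shrink under noise", {
  sim <- clean_study()
  gmp <- perturb_genotypes(sim$gm, error_rate = 0.05, missing_rate = 0.1)
  panels <- random_panels(sim$gm$sites$site_id, n_panels = 6, panel_size = 110,
                          seed = 21)
  res <- reduction_experiment(gmp, sim$sheet, panels, sizes = c(50, 110))
  acc <- tapply(res$accuracy, res$size, mean)
  expect_lte(acc[["50"]], acc[["110"]])
})
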