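#' Offspring genotypes compatible with a candidate parent pair
#'
#' Enumerates the unordered allele pairs formed by one gamete from each
#' parent. A heterozygous-by-heterozygous cross realises the maximum of
#' four ordered gamete combinations (three distinct genotypes).
#'
#' @param p1,p2 Diploid genotypes as integer vectors of length 2 (allele
#'   indices), or `NULL`/`NA` for missing.
#' @return A list of sorted length-2 integer vectors (possibly empty when a
#'   parent genotype is missing — a non-informative site).
#' @export
compatible_offspring_genotypes <- function(p1, p2) {
  if (is.null(p1) || is.null(p2) || anyNA(p1) || anyNA(p2)) return(list())
  stopifnot(length(p1) == 2, length(p2) == 2)
  out <- list()
  for (g1 in p1) for (g2 in p2) {
    g <- sort(c(g1, g2))
    if (!any(vapply(out, identical, logical(1), y = g))) out <- c(out, list(g))
  }
  out
}

#' Exclusion count for one trio
#'
#' For each panel SNP with all three genotypes non-missing, the SNP is an
#' exclusion when the offspring genotype is not among the combinations
#' possible from the candidate parents' gametes. SNPs with any missing
#' genotype are skipped and do not count as comparable.
#'
#' @param gm A [genotype_matrix()].
#' @param offspring,parent1,parent2 Sample ids (all diploid).
#' @param panel Character vector of site ids (a panel), in panel order.
#' @return A one-row tibble: `offspring`, `parent1`, `parent2`,
#'   `n_comparable`, `n_exclusions`.
#' @export
trio_exclusions <- function(gm, offspring, parent1, parent2, panel) {
  ids <- c(offspring, parent1, parent2)
  j <- match(ids, gm$samples)
  if (anyNA(j)) abort(paste0("unknown sample(s): ", paste(ids[is.na(j)], collapse = ", ")))
  if (any(gm$ploidy[j] != 2L)) abort("trio members must be diploid")
  i <- match(panel, gm$sites$site_id)
  if (anyNA(i)) abort("panel contains site ids absent from the matrix")
  n_comp <- 0L; n_excl <- 0L
  for (s in i) {
    go <- c(gm$a1[s, j[1]], gm$a2[s, j[1]])
    g1 <- c(gm$a1[s, j[2]], gm$a2[s, j[2]])
    g2 <- c(gm$a1[s, j[3]], gm$a2[s, j[3]])
    if (anyNA(go) || anyNA(g1) || anyNA(g2)) next
    n_comp <- n_comp + 1L
    compat <- compatible_offspring_genotypes(g1, g2)
    go <- sort(go)
    if (!any(vapply(compat, identical, logical(1), y = go))) {
      n_excl <- n_excl + 1L
    }
  }
  tibble(offspring = offspring, parent1 = parent1, parent2 = parent2,
         n_comparable = n_comp, n_exclusions = n_excl)
}

# --- vectorised exclusion engine -------------------------------------------
# Gamete-possibility indicators from a candidates x sites dosage matrix:
# a parent with dosage 0/1 can transmit the ref allele, 1/2 the alt allele.
gamete_indicators <- function(D) {
  M <- (!is.na(D)) * 1
  D0 <- D; D0[is.na(D0)] <- -1
  list(M = M,
       can0 = (D0 >= 0 & D0 <= 1) * 1,
       can1 = (D0 >= 1) * 1,
       het = (D0 == 1) * 1)
}

# Exclusion and comparable-count matrices over all candidate pairs for one
# offspring dosage vector, per nested prefix size. `ind` comes from
# gamete_indicators() on a candidates x panel-sites dosage matrix whose
# columns follow panel order; `sizes` must be increasing.
pair_exclusions_nested <- function(ind, o, sizes) {
  n <- nrow(ind$M)
  comp <- matrix(0, n, n); compat <- matrix(0, n, n)
  res <- vector("list", length(sizes))
  lo <- 1L
  for (si in seq_along(sizes)) {
    cols <- seq.int(lo, sizes[si])
    lo <- sizes[si] + 1L
    b0 <- cols[!is.na(o[cols]) & o[cols] == 0]
    b1 <- cols[!is.na(o[cols]) & o[cols] == 1]
    b2 <- cols[!is.na(o[cols]) & o[cols] == 2]
    ball <- c(b0, b1, b2)
    comp <- comp + tcrossprod(ind$M[, ball, drop = FALSE])
    compat <- compat +
      tcrossprod(ind$can0[, b0, drop = FALSE]) +
      tcrossprod(ind$can1[, b2, drop = FALSE]) +
      tcrossprod(ind$can0[, b1, drop = FALSE], ind$can1[, b1, drop = FALSE]) +
      tcrossprod(ind$can1[, b1, drop = FALSE], ind$can0[, b1, drop = FALSE]) -
      tcrossprod(ind$het[, b1, drop = FALSE])
    res[[si]] <- list(excl = comp - compat, comp = comp)
  }
  res
}

#' Rank all candidate parent pairs for one offspring
#'
#' Evaluates every unordered pair of candidates (plus self-pairs when
#' `allow_self`) by exclusion count over the panel and reports them sorted
#' by exclusions. Ties for the minimum are reported (`is_minimal` on every
#' tied pair), never silently broken. `margin` is the runner-up exclusion
#' count minus the pair's own (positive only for a uniquely minimal pair).
#'
#' @param gm A [genotype_matrix()] of biallelic sites.
#' @param offspring Offspring sample id (diploid).
#' @param candidates Character vector of candidate parent ids (diploid).
#' @param panel Character vector of site ids in panel order.
#' @param allow_self Consider self-pairs (one candidate providing both
#'   gametes)? Default `FALSE`.
#' @return A tibble sorted by `n_exclusions`: `offspring`, `parent1`,
#'   `parent2`, `n_exclusions`, `n_comparable`, `is_minimal`, `margin`.
#' @export
assign_parents <- function(gm, offspring, candidates, panel,
                           allow_self = FALSE) {
  if (length(candidates) < 2 && !(allow_self && length(candidates) >= 1)) {
    abort("need >= 2 candidates (or >= 1 with allow_self)")
  }
  j <- match(c(offspring, candidates), gm$samples)
  if (anyNA(j)) abort("unknown sample id among offspring/candidates")
  if (any(gm$ploidy[j] != 2L)) abort("offspring and candidates must be diploid")
  sub <- subset_genotypes(gm, panel)
  D <- t(gt_dosage(sub, candidates))        # candidates x sites
  o <- gt_dosage(sub, offspring)[, 1]
  ind <- gamete_indicators(D)
  res <- pair_exclusions_nested(ind, o, length(panel))[[1]]
  n <- length(candidates)
  pairs <- which(upper.tri(res$excl, diag = allow_self), arr.ind = TRUE)
  out <- tibble(offspring = offspring,
                parent1 = candidates[pairs[, 1]],
                parent2 = candidates[pairs[, 2]],
                n_exclusions = as.integer(round(res$excl[pairs])),
                n_comparable = as.integer(round(res$comp[pairs])))
  out <- out[order(out$n_exclusions, -out$n_comparable), ]
  mn <- min(out$n_exclusions)
  runner <- if (sum(out$n_exclusions == mn) > 1) mn else
    min(out$n_exclusions[out$n_exclusions > mn], Inf)
  out$is_minimal <- out$n_exclusions == mn
  out$margin <- as.numeric(runner) - out$n_exclusions
  out
}

#' Panel-reduction parentage experiment
#'
#' For every panel and every nested truncation size (the first `k` SNPs of
#' the panel order), assigns each offspring to its minimal-exclusion
#' candidate pair and tallies assignments against the sheet's declared
#' pedigree. An offspring is dropped at a given size when its own
#' non-missing calls over those SNPs fall below
#' `min_comparable_frac * size`; a tie for the minimum is `ambiguous`; a
#' unique minimal pair equal to the declared parents is a `true` trio,
#' anything else `false`.
#'
#' @param gm A [genotype_matrix()] of biallelic sites.
#' @param sheet A [sample_sheet()] declaring offspring and their parents.
#' @param panels A panels tibble from [random_panels()].
#' @param sizes Truncation sizes (default: the full panel only).
#' @param candidates Candidate parent ids; default all diploid samples with
#'   role `parent` or `unrelated`.
#' @param offspring Offspring ids; default all sheet offspring with both
#'   declared parents among the candidates.
#' @param min_comparable_frac Comparable-SNP floor as a fraction of the
#'   panel size (default 0.5).
#' @param allow_self Consider self-pairs (default `FALSE`).
#' @return A tibble: `panel`, `size`, `n_offspring`, `n_true`, `n_false`,
#'   `n_ambiguous`, `n_dropped`, `accuracy` (true / assigned).
#' @export
reduction_experiment <- function(gm, sheet, panels, sizes = NULL,
                                 candidates = NULL, offspring = NULL,
                                 min_comparable_frac = 0.5,
                                 allow_self = FALSE) {
  candidates <- candidates %||%
    sheet$sample_id[sheet$role %in% c("parent", "unrelated") & sheet$ploidy == 2L]
  candidates <- intersect(candidates, gm$samples)
  offspring <- offspring %||% {
    off <- sheet[sheet$role == "offspring" & sheet$sample_id %in% gm$samples, ]
    off$sample_id[off$mother_id %in% candidates & off$father_id %in% candidates]
  }
  if (length(offspring) == 0) abort("no offspring with both parents among candidates")
  declared <- sheet[match(offspring, sheet$sample_id), c("mother_id", "father_id")]
  panel_labels <- unique(panels$panel)
  full_size <- max(panels$idx)
  sizes <- sort(as.integer(sizes %||% full_size))
  if (max(sizes) > full_size) abort("truncation size exceeds panel size")
  n_cand <- length(candidates)
  rows <- list()
  for (pl in panel_labels) {
    psites <- panels$site_id[panels$panel == pl][order(panels$idx[panels$panel == pl])]
    sub <- subset_genotypes(gm, psites[seq_len(max(sizes))])
    D <- t(gt_dosage(sub, candidates))
    O <- gt_dosage(sub, offspring)          # sites x offspring
    ind <- gamete_indicators(D)
    tally <- array(0L, dim = c(length(sizes), 4),
                   dimnames = list(NULL, c("true", "false", "ambiguous", "dropped")))
    for (oi in seq_along(offspring)) {
      o <- O[, oi]
      nested <- pair_exclusions_nested(ind, o, sizes)
      mo <- declared$mother_id[oi]; fa <- declared$father_id[oi]
      ti <- match(mo, candidates); tj <- match(fa, candidates)
      for (si in seq_along(sizes)) {
        k <- sizes[si]
        if (sum(!is.na(o[seq_len(k)])) < min_comparable_frac * k) {
          tally[si, "dropped"] <- tally[si, "dropped"] + 1L
          next
        }
        E <- nested[[si]]$excl
        vals <- E[upper.tri(E, diag = allow_self)]
        mn <- min(vals)
        n_min <- sum(vals <= mn + 1e-9)
        if (n_min > 1) {
          tally[si, "ambiguous"] <- tally[si, "ambiguous"] + 1L
        } else if (abs(E[min(ti, tj), max(ti, tj)] - mn) < 1e-9) {
          tally[si, "true"] <- tally[si, "true"] + 1L
        } else {
          tally[si, "false"] <- tally[si, "false"] + 1L
        }
      }
    }
    for (si in seq_along(sizes)) {
      assigned <- sum(tally[si, c("true", "false", "ambiguous")])
      rows[[length(rows) + 1]] <- tibble(
        panel = pl, size = sizes[si], n_offspring = length(offspring),
        n_true = unname(tally[si, "true"]), n_false = unname(tally[si, "false"]),
        n_ambiguous = unname(tally[si, "ambiguous"]),
        n_dropped = unname(tally[si, "dropped"]),
        accuracy = unname(ifelse(assigned > 0, tally[si, "true"] / assigned,
                                 NA_real_)))
    }
  }
  bind_rows(rows)
}
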