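#' Default comparable-SNP floor for a panel size
#'
#' The comparability rule requires at least 80 of 110 SNP comparisons; for
#' other panel sizes the floor scales proportionally (rounded).
#'
#' @param panel_size Number of SNPs in the panel.
#' @return An integer floor.
#' @export
default_min_comparable <- function(panel_size) {
  as.integer(round(80 / 110 * panel_size))
}

#' Pairwise genotype mismatch between two samples
#'
#' A SNP is comparable when both genotypes are non-missing; it is a
#' mismatch when the genotypes (unordered allele multisets) differ — a
#' heterozygote against either homozygote counts as one mismatch, with no
#' allele-sharing partial credit. The pair is flagged `included` only when
#' enough SNPs were comparable.
#'
#' @param gm A [genotype_matrix()].
#' @param a,b Sample ids (diploid).
#' @param panel Character vector of site ids.
#' @param min_comparable Comparable-SNP floor; default
#'   [default_min_comparable()] of the panel size.
#' @return A one-row tibble: `sample_a`, `sample_b`, `n_comparable`,
#'   `n_mismatch`, `pct_mismatch`, `included`.
#' @export
pairwise_mismatch <- function(gm, a, b, panel,
                              min_comparable = default_min_comparable(length(panel))) {
  j <- match(c(a, b), gm$samples)
  if (anyNA(j)) abort("unknown sample id")
  i <- match(panel, gm$sites$site_id)
  if (anyNA(i)) abort("panel contains site ids absent from the matrix")
  a1a <- gm$a1[i, j[1]]; a2a <- gm$a2[i, j[1]]
  a1b <- gm$a1[i, j[2]]; a2b <- gm$a2[i, j[2]]
  ok <- !is.na(a1a) & !is.na(a1b)
  eq <- a1a == a1b &
    (is.na(a2a) & is.na(a2b) | (!is.na(a2a) & !is.na(a2b) & a2a == a2b))
  mism <- ok & !eq
  n_comp <- sum(ok); n_mis <- sum(mism, na.rm = TRUE)
  tibble(sample_a = a, sample_b = b,
         n_comparable = n_comp, n_mismatch = n_mis,
         pct_mismatch = ifelse(n_comp > 0, 100 * n_mis / n_comp, NA_real_),
         included = n_comp >= min_comparable)
}

#' Relationship class of a sample pair
#'
#' Classifies a pair by the sample sheet: `ramet` (same replicate group),
#' `full-sib` (offspring of the same family), `parent-offspring` (one is a
#' declared parent of the other), `unrelated` (both in the unrelated role
#' set); anything else is `other` and excluded from the printed profiles.
#'
#' @param sheet A [sample_sheet()].
#' @param a,b Sample ids.
#' @return A single string.
#' @export
relationship_of <- function(sheet, a, b) {
  ra <- sheet[match(a, sheet$sample_id), ]
  rb <- sheet[match(b, sheet$sample_id), ]
  if (anyNA(c(ra$sample_id, rb$sample_id))) abort("sample not in sheet")
  if (!is.na(ra$replicate_group) && !is.na(rb$replicate_group) &&
      ra$replicate_group == rb$replicate_group) return("ramet")
  if (ra$role %in% c("offspring") && rb$role %in% c("offspring") &&
      !is.na(ra$family_id) && !is.na(rb$family_id) &&
      ra$family_id == rb$family_id) return("full-sib")
  po <- function(x, y) {
    !is.na(y$mother_id) && x$sample_id == y$mother_id ||
      !is.na(y$father_id) && x$sample_id == y$father_id
  }
  if (po(ra, rb) || po(rb, ra)) return("parent-offspring")
  if (ra$role == "unrelated" && rb$role == "unrelated") return("unrelated")
  "other"
}

# all classified pairs, computed with indicator-matrix products
pair_mismatch_table <- function(gm, sheet, panel,
                                min_comparable = default_min_comparable(length(panel))) {
  sheet <- sheet[sheet$sample_id %in% gm$samples & sheet$ploidy == 2L, ]
  pairs <- classified_pairs(sheet)
  if (nrow(pairs) == 0) {
    return(tibble(sample_a = character(0), sample_b = character(0),
                  relationship = character(0), n_comparable = integer(0),
                  n_mismatch = integer(0), pct_mismatch = double(0),
                  included = logical(0)))
  }
  ids <- union(pairs$sample_a, pairs$sample_b)
  sub <- subset_genotypes(gm, panel, ids)
  D <- gt_dosage(sub)                      # sites x ids
  M <- (!is.na(D)) * 1
  agree <- matrix(0, length(ids), length(ids))
  for (k in 0:2) agree <- agree + crossprod((!is.na(D) & D == k) * 1)
  comp <- crossprod(M)
  ia <- match(pairs$sample_a, ids); ib <- match(pairs$sample_b, ids)
  n_comp <- comp[cbind(ia, ib)]
  n_mis <- n_comp - agree[cbind(ia, ib)]
  tibble(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
         relationship = pairs$relationship,
         n_comparable = as.integer(round(n_comp)),
         n_mismatch = as.integer(round(n_mis)),
         pct_mismatch = ifelse(n_comp > 0, 100 * n_mis / n_comp, NA_real_),
         included = n_comp >= min_comparable)
}

# enumerate the pairs belonging to the four printed relationship classes
classified_pairs <- function(sheet) {
  out <- list()
  add <- function(a, b, rel) {
    if (length(a) > 0) out[[length(out) + 1]] <<-
        tibble(sample_a = a, sample_b = b, relationship = rel)
  }
  pair_up <- function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    list(a = cmb[1, ], b = cmb[2, ])
  }
  for (g in unique(stats::na.omit(sheet$replicate_group))) {
    p <- pair_up(sheet$sample_id[!is.na(sheet$replicate_group) &
                                   sheet$replicate_group == g])
    if (!is.null(p)) add(p$a, p$b, "ramet")
  }
  offs <- sheet[sheet$role == "offspring" & !is.na(sheet$family_id), ]
  for (f in unique(offs$family_id)) {
    p <- pair_up(offs$sample_id[offs$family_id == f])
    if (!is.null(p)) add(p$a, p$b, "full-sib")
  }
  for (r in seq_len(nrow(offs))) {
    for (par in stats::na.omit(c(offs$mother_id[r], offs$father_id[r]))) {
      if (par %in% sheet$sample_id) add(par, offs$sample_id[r], "parent-offspring")
    }
  }
  p <- pair_up(sheet$sample_id[sheet$role == "unrelated"])
  if (!is.null(p)) add(p$a, p$b, "unrelated")
  if (length(out) == 0) return(tibble(sample_a = character(0),
                                      sample_b = character(0),
                                      relationship = character(0)))
  bind_rows(out)
}

#' Mismatch profiles per relationship class
#'
#' Computes the pairwise mismatch percentage for every pair in the four
#' relationship classes (ramet, full-sib, parent-offspring, unrelated) over
#' a panel, and summarises the included pairs per class. Classes with no
#' included pairs are reported empty, not an error.
#'
#' @inheritParams pairwise_mismatch
#' @param sheet A [sample_sheet()].
#' @param pairs Optionally, a precomputed pair table from the same panel.
#' @return A tibble: `relationship`, `n_pairs`, `min_pct`, `max_pct`,
#'   `mean_pct`.
#' @export
class_profiles <- function(gm, sheet, panel,
                           min_comparable = default_min_comparable(length(panel)),
                           pairs = NULL) {
  pairs <- pairs %||% pair_mismatch_table(gm, sheet, panel, min_comparable)
  classes <- c("ramet", "full-sib", "parent-offspring", "unrelated")
  bind_rows(lapply(classes, function(cl) {
    x <- pairs[pairs$relationship == cl & pairs$included, ]
    tibble(relationship = cl, n_pairs = nrow(x),
           min_pct = if (nrow(x)) min(x$pct_mismatch) else NA_real_,
           max_pct = if (nrow(x)) max(x$pct_mismatch) else NA_real_,
           mean_pct = if (nrow(x)) mean(x$pct_mismatch) else NA_real_)
  }))
}

#' Rank SNP panels by the ramet / full-sib discrimination gap
#'
#' For each panel the gap statistic is the minimum full-sib mismatch
#' percentage minus the maximum ramet mismatch percentage; a larger gap
#' separates clones from their closest relatives more safely. Gaps against
#' the parent-offspring and unrelated classes are reported alongside.
#' Panels are returned sorted by descending full-sib gap (ties keep label
#' order).
#'
#' @param gm A [genotype_matrix()].
#' @param sheet A [sample_sheet()].
#' @param panels A panels tibble from [random_panels()].
#' @param min_comparable Comparable floor; `NULL` scales 80/110 with each
#'   panel's size.
#' @return A tibble: `panel`, `ramet_max`, `fullsib_min`,
#'   `parent_offspring_min`, `unrelated_min`, `gap_fullsib`,
#'   `gap_parent_offspring`, `gap_unrelated`.
#' @export
rank_panels_by_gap <- function(gm, sheet, panels, min_comparable = NULL) {
  labels <- unique(panels$panel)
  if (length(labels) == 0) abort("no panels supplied")
  rows <- lapply(labels, function(pl) {
    psites <- panels$site_id[panels$panel == pl][order(panels$idx[panels$panel == pl])]
    mc <- min_comparable %||% default_min_comparable(length(psites))
    prof <- class_profiles(gm, sheet, psites, mc)
    g <- function(cl, what) prof[[what]][prof$relationship == cl]
    rmax <- g("ramet", "max_pct")
    tibble(panel = pl,
           ramet_max = rmax,
           fullsib_min = g("full-sib", "min_pct"),
           parent_offspring_min = g("parent-offspring", "min_pct"),
           unrelated_min = g("unrelated", "min_pct"),
           gap_fullsib = fullsib_min - rmax,
           gap_parent_offspring = parent_offspring_min - rmax,
           gap_unrelated = unrelated_min - rmax)
  })
  out <- bind_rows(rows)
  out[order(-out$gap_fullsib, match(out$panel, labels)), ]
}
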