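# Correlation engine and the ITA / adjusted-ITA statistic.
#
# ITA (isomiR targeting activity) of an isomiR in a sample group is the
# number of its predicted targets whose expression is significantly
# anti-correlated with the isomiR (Spearman rho < -0.3, BH FDR < 0.05).
# The background ITA is the anti-correlated fraction among the isomiR's
# non-targets scaled by the number of predicted targets, and adjusted ITA
# is their difference:
#   adjusted ITA = m_tar - n_tar * m_nontar / n_nontar.
# Significance is a one-sided Fisher exact test on the 2x2 table
# [[m_tar, n_tar - m_tar], [m_nontar, n_nontar - m_nontar]] (alternative:
# the anti-correlated fraction is greater among targets), BH-adjusted
# across isomiRs within a group.

#' Spearman correlation (mid-rank, t-approximation p-value)
#'
#' `spearman()` handles a single pair of vectors; `spearman_matrix()`
#' computes all correlations between the rows of two matrices over shared
#' sample columns (ranks are computed once per row, Pearson correlation of
#' mid-ranks via cross products). Ties receive average ranks. Two-sided
#' p-values come from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' A constant vector has no defined rank correlation: the corresponding
#' entries are `NA` and callers exclude them with a logged count.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `spearman()`: list with `rho` and `p`. `spearman_matrix()`: list
#'   with matrices `rho` and `p` of dimension `nrow(X)` by `nrow(Y)`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) .stop_invalid("x and y must have equal length")
  res <- spearman_matrix(matrix(x, nrow = 1), matrix(y, nrow = 1))
  list(rho = res$rho[1, 1], p = res$p[1, 1])
}

#' @param X,Y numeric matrices (features in rows, shared samples in
#'   columns).
#' @rdname spearman
#' @export
spearman_matrix <- function(X, Y) {
  if (ncol(X) != ncol(Y)) .stop_invalid("X and Y must share sample columns")
  n <- ncol(X)
  if (n < 3L) .stop_invalid("need at least 3 samples")
  rank_rows <- function(M) t(apply(M, 1L, rank))
  scale_rows <- function(R) {
    R <- R - rowMeans(R)
    nrm <- sqrt(rowSums(R^2))
    zero <- nrm == 0          # constant input: rank variance is zero
    nrm[zero] <- 1
    R <- R / nrm
    R[zero, ] <- NA_real_
    R
  }
  Rx <- scale_rows(rank_rows(X))
  Ry <- scale_rows(rank_rows(Y))
  rho <- tcrossprod(Rx, Ry)
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  perfect <- which(abs(rho) == 1)
  tstat[perfect] <- Inf * sign(rho[perfect])
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  dimnames(rho) <- dimnames(p) <- list(rownames(X), rownames(Y))
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH: order p-values ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` clipped at 1, and map back to the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Count significantly anti-correlated records
#'
#' Strict thresholds on both axes: `rho < rho_max` and `fdr < fdr_max`.
#' `NA` entries (excluded correlations) never count.
#'
#' @param rho,fdr numeric vectors (parallel).
#' @param rho_max correlation threshold (default -0.3).
#' @param fdr_max FDR threshold (default 0.05).
#' @return integer count.
#' @export
count_anticorrelated <- function(rho, fdr, rho_max = -0.3, fdr_max = 0.05) {
  sum(rho < rho_max & fdr < fdr_max, na.rm = TRUE)
}

#' Adjusted isomiR targeting activity
#'
#' `m_tar - n_tar * m_nontar / n_nontar`: the observed number of
#' anti-correlated predicted targets minus the number expected under the
#' non-target (negative control) anti-correlation rate. Zero background
#' gives `m_tar`; equal anti-correlation fractions give exactly 0; a
#' background fraction above `m_tar / n_tar` gives a negative value (the
#' hub-transcription-factor situation: one real target but a large
#' transitively anti-correlated background).
#'
#' @param m_tar,n_tar anti-correlated and total predicted targets.
#' @param m_nontar,n_nontar anti-correlated and total non-targets
#'   (`n_nontar >= 1`).
#' @return numeric (vectorized).
#' @export
adjusted_ita <- function(m_tar, n_tar, m_nontar, n_nontar) {
  if (any(n_nontar == 0)) .stop_invalid("n_nontar = 0: no background estimable")
  if (any(n_tar < 1)) .stop_invalid("n_tar must be >= 1")
  if (any(m_tar < 0 | m_tar > n_tar | m_nontar < 0 | m_nontar > n_nontar)) {
    .stop_invalid("need 0 <= m <= n in both rows")
  }
  m_tar - n_tar * m_nontar / n_nontar
}

#' One-sided Fisher exact test for target anti-correlation enrichment
#'
#' Hypergeometric tail probability of observing at least `m_tar`
#' anti-correlated transcripts among the `n_tar` targets, given
#' `m_tar + m_nontar` anti-correlated transcripts among `n_tar + n_nontar`
#' in total (alternative: the anti-correlated fraction is greater among
#' targets than non-targets). `m_tar = 0` gives exactly 1.
#'
#' @inheritParams adjusted_ita
#' @return p-value (vectorized).
#' @export
fisher_one_sided <- function(m_tar, n_tar, m_nontar, n_nontar) {
  if (any(c(m_tar, n_tar - m_tar, m_nontar, n_nontar - m_nontar) < 0)) {
    .stop_invalid("negative cell in the 2x2 table")
  }
  K <- m_tar + m_nontar
  N <- n_tar + n_nontar
  stats::phyper(m_tar - 1, K, N - K, n_tar, lower.tail = FALSE)
}

#' Signed log transform
#'
#' `sgn(y) * log2(|y| + 1)`: embeds positive and negative adjusted-ITA
#' values on a symmetric logarithmic scale (odd function, fixes 0).
#'
#' @param y numeric vector.
#' @return transformed values.
#' @examples
#' signed_log(c(-3, -1, 0, 1, 3))  # -2 -1  0  1  2
#' @export
signed_log <- function(y) {
  sign(y) * log2(abs(y) + 1)
}

# Normalize a sample-group input (data frame or named vector) to a named
# character vector sample_id -> group.
.group_map <- function(sample_groups) {
  if (is.data.frame(sample_groups)) {
    stats::setNames(as.character(sample_groups$group),
                    as.character(sample_groups$sample_id))
  } else {
    stopifnot(!is.null(names(sample_groups)))
    stats::setNames(as.character(sample_groups), names(sample_groups))
  }
}

# Per-isomiR target transcript sets by stratum. Stratum membership is at
# pair granularity: a pair with several site types/regions appears in every
# matching stratum (and once in "pooled").
.strata_sets <- function(sites, strata) {
  switch(strata,
    pooled = list(pooled = unique(sites$transcript_id)),
    seed_type = lapply(split(sites$transcript_id, sites$seed_type), unique),
    region = lapply(split(sites$transcript_id, sites$region), unique),
    seed_type_region = lapply(
      split(sites$transcript_id, paste(sites$seed_type, sites$region, sep = ":")),
      unique
    ),
    .stop_invalid("unknown strata: ", strata)
  )
}

#' Compute per-group ITA profiles
#'
#' For every sample group: Spearman-correlates each analyzed isomiR with
#' all of its predicted target and non-target transcripts, BH-adjusts the
#' correlation p-values jointly over the group's full correlation family
#' (targets and non-targets together, so the significance threshold is the
#' same on both sides of the statistic), counts anti-correlated transcripts
#' per stratum, and emits one ITA record per (isomiR, stratum) with the
#' one-sided Fisher exact p-value. Fisher p-values are then BH-adjusted
#' across isomiRs within each (group, stratum) family; "active" isomiRs
#' are those with `fisher_fdr < 0.05`.
#'
#' @param iso_expr,mrna_expr log2(x+1)-scale normalized expression matrices
#'   (features by samples).
#' @param sample_groups data frame (`sample_id`, `group`) or named vector.
#' @param interactions site-level interaction table (see
#'   [read_rna22_table()], [scan_target_sites()]).
#' @param nontargets named list: isomiR id -> character vector of
#'   non-target transcript ids (see [compose_nontarget_set()]).
#' @param strata one of `"pooled"`, `"seed_type"`, `"region"`,
#'   `"seed_type_region"`.
#' @param rho_max,fdr_max strict thresholds defining significant
#'   anti-correlation (defaults -0.3 and 0.05).
#' @param min_group_size groups with fewer samples are skipped with a
#'   warning.
#' @param groups optional subset of group labels to analyze.
#' @return list with `correlations` (data frame `group`, `isomir`,
#'   `transcript_id`, `role`, `rho`, `p`, `fdr`) and `ita` (data frame with
#'   columns `isomir`, `group`, `stratum`, `n_tar`, `m_tar`, `n_nontar`,
#'   `m_nontar`, `ita`, `background_ita`, `adjusted_ita`,
#'   `adjusted_ita_signed_log`, `fisher_p`, `fisher_fdr`).
#' @export
compute_ita_profile <- function(iso_expr, mrna_expr, sample_groups,
                                interactions, nontargets,
                                strata = c("pooled", "seed_type", "region",
                                           "seed_type_region"),
                                rho_max = -0.3, fdr_max = 0.05,
                                min_group_size = 3L, groups = NULL) {
  strata <- match.arg(strata)
  map <- .group_map(sample_groups)
  samples <- intersect(intersect(colnames(iso_expr), colnames(mrna_expr)), names(map))
  if (length(samples) == 0L) .stop_invalid("no samples shared by both matrices and the group map")
  map <- map[samples]
  group_levels <- if (is.null(groups)) unique(map) else groups
  if (!all(group_levels %in% map)) {
    .stop_invalid("requested group(s) absent from the sample map: ",
                  paste(setdiff(group_levels, map), collapse = ", "))
  }

  isos <- intersect(rownames(iso_expr), names(nontargets))
  isos <- intersect(isos, unique(interactions$isomir))
  if (length(isos) == 0L) .stop_invalid("no isomiR has expression, targets and non-targets")
  sites_by_iso <- split(interactions[c("transcript_id", "seed_type", "region")],
                        interactions$isomir)
  tar_by_iso <- lapply(sites_by_iso[isos], function(s) {
    intersect(unique(s$transcript_id), rownames(mrna_expr))
  })
  non_by_iso <- lapply(nontargets[isos], function(s) intersect(s, rownames(mrna_expr)))

  cor_out <- list()
  ita_out <- list()
  n_constant <- 0L
  for (g in group_levels) {
    cols <- samples[map == g]
    if (length(cols) < max(min_group_size, 3L)) {
      warning("group ", g, " has ", length(cols),
              " samples (< minimum group size); skipped", call. = FALSE)
      next
    }
    needed <- sort(unique(c(unlist(tar_by_iso, use.names = FALSE),
                            unlist(non_by_iso, use.names = FALSE))))
    cm <- spearman_matrix(iso_expr[isos, cols, drop = FALSE],
                          mrna_expr[needed, cols, drop = FALSE])
    pair_iso <- rep(isos, times = lengths(tar_by_iso) + lengths(non_by_iso))
    pair_t <- unlist(mapply(c, tar_by_iso, non_by_iso, SIMPLIFY = FALSE),
                     use.names = FALSE)
    pair_role <- unlist(mapply(
      function(t, nt) c(rep("target", length(t)), rep("nontarget", length(nt))),
      tar_by_iso, non_by_iso, SIMPLIFY = FALSE
    ), use.names = FALSE)
    idx <- cbind(match(pair_iso, isos), match(pair_t, needed))
    fam <- data.frame(
      group = g, isomir = pair_iso, transcript_id = pair_t, role = pair_role,
      rho = cm$rho[idx], p = cm$p[idx], stringsAsFactors = FALSE
    )
    n_constant <- n_constant + sum(is.na(fam$rho))
    fam$fdr <- bh_adjust(fam$p)
    cor_out[[g]] <- fam

    recs <- list()
    for (iso in isos) {
      rows_t <- fam[fam$isomir == iso & fam$role == "target", , drop = FALSE]
      rows_n <- fam[fam$isomir == iso & fam$role == "nontarget", , drop = FALSE]
      rows_t <- rows_t[!is.na(rows_t$rho), , drop = FALSE]
      rows_n <- rows_n[!is.na(rows_n$rho), , drop = FALSE]
      n_nontar <- nrow(rows_n)
      if (n_nontar == 0L) next
      m_nontar <- count_anticorrelated(rows_n$rho, rows_n$fdr, rho_max, fdr_max)
      strata_sets <- .strata_sets(sites_by_iso[[iso]], strata)
      for (st in names(strata_sets)) {
        st_t <- strata_sets[[st]]
        sel <- rows_t[rows_t$transcript_id %in% st_t, , drop = FALSE]
        n_tar <- nrow(sel)
        if (n_tar == 0L) next
        m_tar <- count_anticorrelated(sel$rho, sel$fdr, rho_max, fdr_max)
        adj <- adjusted_ita(m_tar, n_tar, m_nontar, n_nontar)
        recs[[length(recs) + 1L]] <- data.frame(
          isomir = iso, group = g, stratum = st,
          n_tar = n_tar, m_tar = m_tar,
          n_nontar = n_nontar, m_nontar = m_nontar,
          ita = m_tar,
          background_ita = n_tar * m_nontar / n_nontar,
          adjusted_ita = adj,
          adjusted_ita_signed_log = signed_log(adj),
          fisher_p = fisher_one_sided(m_tar, n_tar, m_nontar, n_nontar),
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(recs) == 0L) next
    gi <- do.call(rbind, recs)
    gi$fisher_fdr <- stats::ave(gi$fisher_p, gi$stratum, FUN = bh_adjust)
    ita_out[[g]] <- gi
  }
  if (n_constant > 0L) {
    message(n_constant, " correlation(s) excluded (constant expression vector)")
  }
  if (length(ita_out) == 0L) .stop_invalid("no group could be analyzed")
  correlations <- do.call(rbind, cor_out)
  ita <- do.call(rbind, ita_out)
  rownames(correlations) <- rownames(ita) <- NULL
  list(correlations = correlations, ita = ita)
}

#' Active isomiR sets and their overlaps across groups
#'
#' An isomiR is active in a group when its Fisher FDR is below `fdr_max`.
#' Reports per-group active sets plus all intersection-region sizes and
#' pairwise Jaccard indices (via [compare_sets()]).
#'
#' @param ita ITA record table from [compute_ita_profile()].
#' @param fdr_max activity threshold on `fisher_fdr` (default 0.05).
#' @param stratum which stratum to report on (default `"pooled"`).
#' @return list with `active` (named list of isomiR id vectors per group),
#'   `jaccard` and `regions` (see [compare_sets()]).
#' @export
report_active_sets <- function(ita, fdr_max = 0.05, stratum = "pooled") {
  tab <- ita[ita$stratum == stratum, , drop = FALSE]
  if (nrow(tab) == 0L) .stop_invalid("no ITA records for stratum ", stratum)
  groups <- unique(tab$group)
  if (length(groups) < 2L) .stop_invalid("need at least 2 groups to compare")
  active <- lapply(stats::setNames(groups, groups), function(g) {
    sort(tab$isomir[tab$group == g & tab$fisher_fdr < fdr_max])
  })
  c(list(active = active), compare_sets(active))
}
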