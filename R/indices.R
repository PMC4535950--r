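#' @title Consensus index reports
#' @description Every index function returns an `index_report`: the
#'   per-item values (empty for the two kappas, which are defined jointly
#'   over all items) and the study-wide summary — the unweighted mean of the
#'   per-item values, or the kappa itself.
#' @param index index abbreviation.
#' @param per_item numeric vector of per-item values (may be length 0).
#' @param study_wide single study-wide value.
#' @return a list of class `"index_report"`.
#' @keywords internal
index_report <- function(index, per_item, study_wide) {
  structure(list(index = index, per_item = per_item, study_wide = study_wide),
            class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("<index_report> %s: study-wide %.4f", x$index, x$study_wide))
  if (length(x$per_item))
    cat(sprintf(" (%d item%s)", length(x$per_item),
                if (length(x$per_item) == 1L) "" else "s"))
  cat("\n")
  invisible(x)
}

# q x n matrix of rating counts: entry (j, i) = number of experts giving
# rating j to item i (the r_ij of the kappa formulas).
rating_counts <- function(m) {
  q <- scale_of(m)
  vapply(seq_len(ncol(m)), function(i) tabulate(m[, i], nbins = q),
         integer(q))
}

#' De Moivre unanimity index
#'
#' Per item, 1 if all experts gave the identical score and 0 otherwise;
#' study-wide, the proportion of unanimous items.
#'
#' @param m a [rating_matrix()] (or plain integer matrix on a 1-10 scale).
#' @return an `index_report`.
#' @export
index_de_moivre <- function(m) {
  m <- as_rating_matrix(m)
  ci <- as.numeric(apply(m, 2L, function(x) all(x == x[1L])))
  index_report("DM", ci, mean(ci))
}

#' Pairwise agreement
#'
#' Per item, the proportion of unordered expert pairs giving identical
#' scores among all `r(r-1)/2` pairs.
#'
#' @inheritParams index_de_moivre
#' @return an `index_report`.
#' @export
index_pwa <- function(m) {
  m <- as_rating_matrix(m)
  r <- nrow(m)
  cnt <- rating_counts(m)
  ai <- colSums(cnt * (cnt - 1L)) / (r * (r - 1L))
  index_report("PWA", ai, mean(ai))
}

# pair-agreement mass of a set of disjoint intervals for one item
cluster_pair_fraction <- function(ratings, lows, highs, r) {
  mcounts <- vapply(seq_along(lows), function(j)
    sum(ratings >= lows[j] & ratings <= highs[j]), integer(1))
  sum(mcounts * (mcounts - 1)) / (r * (r - 1))
}

check_disjoint <- function(lows, highs, what = "clusters") {
  if (length(lows) < 2L) return(invisible(TRUE))
  o <- order(lows)
  if (any(lows[o][-1L] <= highs[o][-length(o)]))
    stop(sprintf("overlapping %s: intervals must be disjoint", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Clustered pairwise agreement
#'
#' Like [index_pwa()] but two experts "agree" on an item when their scores
#' fall in the same consensus cluster; scores outside every cluster
#' contribute nothing.  Per item: `sum_j m_j (m_j - 1) / (r (r - 1))` over
#' the item's clusters, `m_j` the cluster's member count.
#'
#' @inheritParams index_de_moivre
#' @param cluster_sets a list with one [identify_clusters()] result per
#'   item; if `NULL`, clusters are identified from `m` itself with `params`.
#' @param params [clustering_params()] used when `cluster_sets` is `NULL`.
#' @return an `index_report`.
#' @export
index_cpwa <- function(m, cluster_sets = NULL, params = clustering_params()) {
  m <- as_rating_matrix(m)
  r <- nrow(m)
  cluster_sets <- resolve_cluster_sets(m, cluster_sets, params)
  aci <- vapply(seq_len(ncol(m)), function(i) {
    cl <- cluster_sets[[i]]$clusters
    if (length(cl) == 0L) return(0)
    lows <- vapply(cl, `[[`, integer(1), "low")
    highs <- vapply(cl, `[[`, integer(1), "high")
    check_disjoint(lows, highs)
    cluster_pair_fraction(m[, i], lows, highs, r)
  }, numeric(1))
  index_report("CPWA", aci, mean(aci))
}

#' Extreme rating groups
#'
#' The two fixed scale intervals treated as the only clusters by
#' [index_xcpwa()]: by default the bottom three and top three points of a
#' 1-10 scale.
#'
#' @param lower inclusive `c(low, high)` of the lower extreme group.
#' @param upper inclusive `c(low, high)` of the upper extreme group.
#' @param scale_max rating-scale upper end.
#' @return a list of class `"extreme_groups"`.
#' @export
extreme_groups <- function(lower = c(1L, 3L), upper = c(8L, 10L),
                           scale_max = 10L) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 2L || length(upper) != 2L ||
      lower[1L] > lower[2L] || upper[1L] > upper[2L])
    stop("groups must be inclusive intervals c(low, high)", call. = FALSE)
  if (lower[1L] < 1L || upper[2L] > scale_max)
    stop("groups must lie within the rating scale", call. = FALSE)
  if (lower[2L] >= upper[1L])
    stop("extreme groups must not overlap", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "extreme_groups")
}

#' Extremities clustered pairwise agreement
#'
#' Pair-counting agreement restricted to two fixed extreme intervals of the
#' scale (default 1-3 and 8-10): measures whether the panel polarises
#' toward the ends of the scale.
#'
#' @inheritParams index_de_moivre
#' @param groups an [extreme_groups()].
#' @return an `index_report`.
#' @export
index_xcpwa <- function(m, groups = NULL) {
  m <- as_rating_matrix(m)
  if (is.null(groups)) groups <- default_extreme_groups(scale_of(m))
  r <- nrow(m)
  lows <- c(groups$lower[1L], groups$upper[1L])
  highs <- c(groups$lower[2L], groups$upper[2L])
  acxi <- vapply(seq_len(ncol(m)), function(i)
    cluster_pair_fraction(m[, i], lows, highs, r), numeric(1))
  index_report("XCPWA", acxi, mean(acxi))
}

# Default extremes scale with the rating scale: bottom three and top three
# points on the standard 1-10 scale, shrunk proportionally for short scales.
default_extreme_groups <- function(scale_max) {
  w <- max(1L, min(3L, scale_max %/% 3L))
  extreme_groups(c(1L, w), c(scale_max - w + 1L, scale_max), scale_max)
}

# Observed agreement P and Fleiss chance agreement P_e for a count matrix.
kappa_components <- function(m) {
  r <- nrow(m); n <- ncol(m)
  cnt <- rating_counts(m)
  P <- (sum(cnt^2) - n * r) / (n * r * (r - 1))
  pj <- rowSums(cnt) / (n * r)
  list(P = P, Pe_k = sum(pj^2))
}

chance_corrected <- function(P, Pe) {
  # Perfect agreement scores 1 even when chance agreement is also perfect
  # (all experts give one identical rating everywhere), where the ratio is 0/0.
  if (P >= 1 - 1e-12) return(1)
  (P - Pe) / (1 - Pe)
}

#' Fleiss' kappa
#'
#' Chance-corrected multi-rater agreement computed jointly over all items:
#' `KF = (P - P_e) / (1 - P_e)`, where `P` is the observed proportion of
#' agreeing expert pairs and `P_e` the agreement expected if every expert
#' rated at random following the pooled rating marginals.  No per-item
#' values are reported: the formula aggregates over items by construction.
#'
#' @inheritParams index_de_moivre
#' @return an `index_report` (with empty `per_item`).
#' @export
index_fleiss_kappa <- function(m) {
  m <- as_rating_matrix(m)
  kc <- kappa_components(m)
  index_report("KF", numeric(0), chance_corrected(kc$P, kc$Pe_k))
}

#' Conger's kappa
#'
#' Like [index_fleiss_kappa()] but chance agreement uses per-expert rating
#' marginals: `P_e,C = P_e,k - sum_j s_j^2 / (r - 1)` where `s_j^2` is the
#' between-expert variance of the proportion of items each expert rated
#' `j`.  Since `P_e,C <= P_e,k`, Conger's kappa is never below Fleiss' on
#' the same matrix (when `P < 1`).
#'
#' @inheritParams index_de_moivre
#' @return an `index_report` (with empty `per_item`).
#' @export
index_conger_kappa <- function(m) {
  m <- as_rating_matrix(m)
  r <- nrow(m); n <- ncol(m); q <- scale_of(m)
  kc <- kappa_components(m)
  njk <- vapply(seq_len(r), function(k) tabulate(m[k, ], nbins = q),
                integer(q))
  s2 <- (r * rowSums(njk^2) - rowSums(njk)^2) / (n^2 * r^2)
  Pe_C <- kc$Pe_k - sum(s2) / (r - 1)
  index_report("KC", numeric(0), chance_corrected(kc$P, Pe_C))
}

#' Mode index
#'
#' Per item, the proportion of experts who chose the most popular score.
#' Ties between modal scores are broken toward the lower score when the
#' mode itself is reported; the proportion is unaffected.
#'
#' @inheritParams index_de_moivre
#' @return an `index_report`.
#' @export
index_mode <- function(m) {
  m <- as_rating_matrix(m)
  cnt <- rating_counts(m)
  si <- apply(cnt, 2L, max) / nrow(m)
  index_report("M", si, mean(si))
}

#' Clustered mode index
#'
#' Per item, the proportion of experts whose score fell in the most
#' populous consensus cluster.  Always at least as large as the plain
#' [index_mode()] value, since the modal cluster contains the modal score.
#'
#' @inheritParams index_cpwa
#' @return an `index_report`.
#' @export
index_clustered_mode <- function(m, cluster_sets = NULL,
                                 params = clustering_params()) {
  m <- as_rating_matrix(m)
  r <- nrow(m)
  cluster_sets <- resolve_cluster_sets(m, cluster_sets, params)
  csi <- vapply(seq_len(ncol(m)), function(i) {
    cl <- cluster_sets[[i]]$clusters
    if (length(cl) == 0L) return(0)
    max(vapply(cl, `[[`, integer(1), "member_count")) / r
  }, numeric(1))
  index_report("CM", csi, mean(csi))
}

#' Interquartile range index
#'
#' Per item, `q75 - q25` of the ratings, using linear interpolation between
#' order statistics at rank `1 + (r - 1) m / 100` (R's quantile type 7).
#' Lower is more consensual: 0 means at least the central half of the panel
#' coincides.  Values run from 0 to `scale_max - 1`.
#'
#' @inheritParams index_de_moivre
#' @return an `index_report`.
#' @export
index_iqr <- function(m) {
  m <- as_rating_matrix(m)
  iq <- vapply(seq_len(ncol(m)), function(i) {
    qs <- quantile(as.numeric(m[, i]), c(0.25, 0.75), type = 7, names = FALSE)
    qs[2L] - qs[1L]
  }, numeric(1))
  index_report("IQR", iq, mean(iq))
}

#' IQR consensus predicate
#'
#' The conventional dichotomous reading of the IQR index: an item reaches
#' consensus when its interquartile range does not exceed a threshold
#' (default 1 scale point).
#'
#' @param report an `index_report` from [index_iqr()] (or a rating matrix,
#'   which is passed through [index_iqr()] first).
#' @param threshold maximum IQR still counted as consensus.
#' @return logical vector, one flag per item.
#' @export
iqr_consensus <- function(report, threshold = 1.0) {
  if (!inherits(report, "index_report")) report <- index_iqr(report)
  if (report$index != "IQR") stop("`report` must be an IQR report", call. = FALSE)
  report$per_item <= threshold + 1e-12
}

resolve_cluster_sets <- function(m, cluster_sets, params) {
  if (is.null(cluster_sets)) {
    q <- scale_of(m)
    cluster_sets <- lapply(seq_len(ncol(m)), function(i)
      identify_clusters(m[, i], params, q))
  }
  if (length(cluster_sets) != ncol(m))
    stop("need exactly one cluster set per item", call. = FALSE)
  cluster_sets
}

#' All nine consensus indices at once
#'
#' Computes the full battery — DM, PWA, CPWA, XCPWA, KF, KC, M, CM, IQR —
#' on one rating matrix.  Cluster-based indices (CPWA, CM) share a single
#' set of per-item clusters, identified from the matrix itself unless
#' supplied.
#'
#' @inheritParams index_cpwa
#' @param groups [extreme_groups()] for XCPWA; default scales with the
#'   rating scale.
#' @return a named list of `index_report`s of class `"index_report_set"`,
#'   with the identified `cluster_sets` attached as an attribute.
#' @examples
#' reports <- consensus_indices(make_fixture("bimodal-9v3"))
#' study_wide_values(reports)
#' @export
consensus_indices <- function(m, cluster_sets = NULL,
                              params = clustering_params(), groups = NULL) {
  m <- as_rating_matrix(m)
  cluster_sets <- resolve_cluster_sets(m, cluster_sets, params)
  reports <- list(
    DM = index_de_moivre(m),
    PWA = index_pwa(m),
    CPWA = index_cpwa(m, cluster_sets),
    XCPWA = index_xcpwa(m, groups),
    KF = index_fleiss_kappa(m),
    KC = index_conger_kappa(m),
    M = index_mode(m),
    CM = index_clustered_mode(m, cluster_sets),
    IQR = index_iqr(m)
  )
  structure(reports, class = "index_report_set", cluster_sets = cluster_sets)
}

#' Study-wide values of a report set
#'
#' @param reports an `"index_report_set"` from [consensus_indices()].
#' @return named numeric vector of the nine study-wide values, in the
#'   canonical order DM, PWA, CPWA, XCPWA, KF, KC, M, CM, IQR.
#' @export
study_wide_values <- function(reports) {
  vapply(reports[INDEX_NAMES], `[[`, numeric(1), "study_wide")
}

#' @export
print.index_report_set <- function(x, ...) {
  sw <- study_wide_values(x)
  cat("<index_report_set> study-wide values:\n")
  print(round(sw, 4))
  invisible(x)
}
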