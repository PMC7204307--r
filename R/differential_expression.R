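#' Define a two-group contrast
#'
#' @param group_a,group_b disjoint character vectors of sample ids; each
#'   group needs at least 3 samples for the permutation test.
#' @param label_a,label_b display labels (e.g. "M1", "M0-NM").
#' @return A list of class `group_contrast`.
#' @export
group_contrast <- function(group_a, group_b, label_a = "A",
                           label_b = "B") {
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b))) {
    stopf("groups must be disjoint")
  }
  if (anyDuplicated(group_a) || anyDuplicated(group_b)) {
    stopf("duplicate sample ids within a group")
  }
  structure(list(group_a = group_a, group_b = group_b,
                 label_a = label_a, label_b = label_b),
            class = "group_contrast")
}

# Welch t statistics for all genes at once given a 0/1 group-A indicator
# matrix (samples x permutations). Returns a genes x permutations matrix.
welch_t_matrix <- function(x, ind_a, n_a, n_b) {
  sum_a <- x %*% ind_a
  sum_b <- rowSums(x) - sum_a
  sumsq_a <- (x^2) %*% ind_a
  sumsq_b <- rowSums(x^2) - sumsq_a
  mean_a <- sum_a / n_a
  mean_b <- sum_b / n_b
  var_a <- (sumsq_a - n_a * mean_a^2) / (n_a - 1)
  var_b <- (sumsq_b - n_b * mean_b^2) / (n_b - 1)
  se <- sqrt(pmax(var_a / n_a + var_b / n_b, 1e-300))
  (mean_a - mean_b) / se
}

# empirical two-tailed p of each observed statistic against a pooled null
# sample: p = (1 + #{|null| >= |obs|}) / (N_null + 1)
empirical_two_tailed_p <- function(obs, null_values) {
  null_abs <- sort(abs(null_values))
  n <- length(null_abs)
  cnt_ge <- n - findInterval(abs(obs), null_abs, left.open = TRUE)
  (1 + cnt_ge) / (n + 1)
}

#' Permutation-based integrative differential expression test
#'
#' For every gene two statistics are computed between the groups of the
#' contrast: a Welch t statistic and a log2 median-ratio. Empirical null
#' distributions for both are built from `n_perm` random label
#' permutations, pooled across genes for stable tail estimates; each
#' observed statistic is converted to a two-tailed empirical p-value
#' (with the +1 correction so p is never 0), the two are combined by a
#' Stouffer-style signed-z sum whose null distribution is itself taken
#' from the permutations (the two statistics are dependent, so the
#' combination is permutation-calibrated rather than referred to a
#' normal), and the combined p-values are BH-adjusted. A gene is
#' flagged `is_deg`
#' when `q < fdr_threshold` and its linear fold change is at least
#' `fc_threshold`.
#'
#' @param expr normalized log2 expression matrix, genes x samples.
#' @param contrast a [group_contrast()]; both groups need >= 3 samples.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed; results are deterministic given it.
#' @param fdr_threshold,fc_threshold the DEG thresholds (defaults:
#'   q < 0.05 and linear fold change >= 1.5).
#' @return A data.frame of class `deg_table`: `gene`, `log2_fc` (A over
#'   B, difference of group means on the log2 scale), `t_stat`,
#'   `median_ratio` (log2), `p_t`, `p_median`, `p_combined`, `q`,
#'   `direction` (+1/-1), `is_deg`; thresholds stored as attributes.
#' @export
integrative_deg_test <- function(expr, contrast, n_perm = 1000L,
                                 seed = 1L, fdr_threshold = 0.05,
                                 fc_threshold = 1.5) {
  stopifnot(inherits(contrast, "group_contrast"))
  n_perm <- check_count(n_perm, "n_perm", min = 1)
  if (n_perm < 100) {
    warning("n_perm < 100 gives coarse empirical p-values", call. = FALSE)
  }
  expr <- as.matrix(expr)
  a <- contrast$group_a
  b <- contrast$group_b
  if (!all(c(a, b) %in% colnames(expr))) {
    stopf("contrast samples missing from expression matrix")
  }
  if (length(a) < 3 || length(b) < 3) {
    stopf("each group needs at least 3 samples")
  }
  x <- expr[, c(a, b), drop = FALSE]
  n_a <- length(a)
  n_b <- length(b)
  n <- n_a + n_b
  g <- nrow(x)

  obs_ind <- matrix(0, n, 1)
  obs_ind[seq_len(n_a), 1] <- 1
  t_obs <- as.vector(welch_t_matrix(x, obs_ind, n_a, n_b))
  med_obs <- row_medians(x[, seq_len(n_a), drop = FALSE]) -
    row_medians(x[, n_a + seq_len(n_b), drop = FALSE])

  # Null construction is canonicalized so that swapping the two groups
  # yields the exact same pooled null (and hence identical p-values):
  # samples are put in a fixed lexicographic order and the smaller group
  # size is the one drawn; its complement plays the other group.
  ord <- order(colnames(x))
  xs <- x[, ord, drop = FALSE]
  k_small <- min(n_a, n_b)
  a_is_small <- n_a <= n_b
  perm <- with_seed(seed, {
    ind <- matrix(0, n, n_perm)
    med_null <- matrix(0, g, n_perm)
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n, k_small)
      idx_a <- if (a_is_small) idx else setdiff(seq_len(n), idx)
      ind[idx_a, p] <- 1
      med_null[, p] <- row_medians(xs[, idx_a, drop = FALSE]) -
        row_medians(xs[, -idx_a, drop = FALSE])
    }
    list(t_null = welch_t_matrix(xs, ind, n_a, n_b), med_null = med_null)
  })

  p_t <- empirical_two_tailed_p(t_obs, perm$t_null)
  p_med <- empirical_two_tailed_p(med_obs, perm$med_null)

  log2_fc <- rowMeans(x[, seq_len(n_a), drop = FALSE]) -
    rowMeans(x[, n_a + seq_len(n_b), drop = FALSE])
  direction <- ifelse(log2_fc >= 0, 1L, -1L)

  # Stouffer-combined signed z of the two statistics. The two statistics
  # are strongly dependent (both measure a location shift), so the
  # combined z is calibrated against its own permutation null: the same
  # z-combination applied to every permuted statistic pair. This keeps
  # the combined p uniform under the null whatever the dependence.
  zify <- function(p, stat) {
    qnorm(pmin(p / 2, 0.5), lower.tail = FALSE) *
      ifelse(stat == 0, 0, sign(stat))
  }
  z_comb <- (zify(p_t, t_obs) + zify(p_med, med_obs)) / sqrt(2)
  p_t_null <- empirical_two_tailed_p(perm$t_null, perm$t_null)
  p_med_null <- empirical_two_tailed_p(perm$med_null, perm$med_null)
  z_comb_null <- (zify(p_t_null, perm$t_null) +
                    zify(p_med_null, perm$med_null)) / sqrt(2)
  p_comb <- empirical_two_tailed_p(z_comb, z_comb_null)

  q <- bh_fdr(p_comb)
  is_deg <- q < fdr_threshold & abs(log2_fc) >= log2(fc_threshold)

  out <- data.frame(gene = rownames(x), log2_fc = log2_fc,
                    t_stat = t_obs, median_ratio = med_obs,
                    p_t = p_t, p_median = p_med, p_combined = p_comb,
                    q = q, direction = direction, is_deg = is_deg,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "contrast") <- paste(contrast$label_a, "vs",
                                 contrast$label_b)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment; elementwise `q >= p` after monotonization and
#' `q <= 1`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stopf("p-values must be finite and in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

deg_set <- function(tbl) tbl$gene[tbl$is_deg]

#' Intersect DEG sets across cohorts
#'
#' Computes all Venn region counts over the cohorts' DEG sets and the
#' "shared" gene list: genes in the focal cohort's DEG set that are also
#' a DEG in at least one other cohort.
#'
#' @param deg_tables named list of >= 2 [integrative_deg_test()] tables
#'   (or data.frames with `gene` and `is_deg` columns).
#' @param focal name or index of the focal cohort (default: first).
#' @return A list of class `intersection_result`: `sets` (the DEG sets),
#'   `region_counts` (named by membership pattern, e.g. "A&B"),
#'   `shared_genes`, `focal`.
#' @export
intersect_degs <- function(deg_tables, focal = 1L) {
  if (length(deg_tables) < 2) stopf("need at least 2 DEG tables")
  if (is.null(names(deg_tables))) {
    names(deg_tables) <- paste0("cohort", seq_along(deg_tables))
  }
  sets <- lapply(deg_tables, deg_set)
  nm <- names(sets)
  focal_name <- if (is.numeric(focal)) nm[focal] else focal
  if (!focal_name %in% nm) stopf("unknown focal cohort")
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  region_counts <- table(pattern)
  # all 2^k - 1 regions reported, zero-filled
  k <- length(nm)
  all_patterns <- unlist(lapply(seq_len(k), function(m) {
    combn(nm, m, FUN = paste, collapse = "&")
  }))
  counts <- setNames(rep(0L, length(all_patterns)), all_patterns)
  counts[names(region_counts)] <- as.integer(region_counts)
  in_focal <- member[, focal_name]
  in_other <- rowSums(member[, setdiff(nm, focal_name), drop = FALSE]) > 0
  shared <- all_genes[in_focal & in_other]
  structure(list(sets = sets, region_counts = counts,
                 shared_genes = shared, focal = focal_name),
            class = "intersection_result")
}

#' Cross-cohort directional concordance of shared DEGs
#'
#' A shared gene is concordant when its fold-change sign agrees across
#' all cohorts in which it is a DEG.
#'
#' @param result an [intersect_degs()] result.
#' @param deg_tables the same named list of DEG tables.
#' @return A list: `fraction` (NA when no genes are shared),
#'   `n_concordant`, `n_shared`, `flags` (named logical per shared gene).
#' @export
directional_concordance <- function(result, deg_tables) {
  stopifnot(inherits(result, "intersection_result"))
  shared <- result$shared_genes
  if (length(shared) == 0) {
    return(list(fraction = NA_real_, n_concordant = 0L, n_shared = 0L,
                flags = logical(0)))
  }
  flags <- vapply(shared, function(g) {
    signs <- unlist(lapply(deg_tables, function(tbl) {
      row <- tbl[tbl$gene == g & tbl$is_deg, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      if (is.null(row$direction)) stopf("missing direction for gene %s", g)
      row$direction
    }))
    length(unique(signs)) == 1L
  }, logical(1))
  list(fraction = mean(flags), n_concordant = sum(flags),
       n_shared = length(shared), flags = flags)
}

#' Pearson correlation of log2 fold changes between two DEG tables
#'
#' @param table_a,table_b [integrative_deg_test()] tables.
#' @param gene_subset optional gene ids to restrict to (default: all
#'   genes common to both tables).
#' @return Pearson r (NA with a warning when either fold-change vector is
#'   constant).
#' @export
deg_fc_correlation <- function(table_a, table_b, gene_subset = NULL) {
  common <- intersect(table_a$gene, table_b$gene)
  if (!is.null(gene_subset)) common <- intersect(common, gene_subset)
  if (length(common) < 3) stopf("need at least 3 common genes")
  fa <- table_a$log2_fc[match(common, table_a$gene)]
  fb <- table_b$log2_fc[match(common, table_b$gene)]
  if (sd(fa) == 0 || sd(fb) == 0) {
    warning("constant fold-change vector; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(fa, fb)
}
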