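#' Signal-to-noise gene ranking for a two-group contrast
#'
#' The per-gene metric is `(meanA - meanB) / (sdA + sdB)` with each group
#' standard deviation floored at `max(sd, sd_floor_frac * |mean|, eps)`,
#' the canonical Signal2Noise definition. Genes are sorted in descending
#' metric order; ties are broken by gene id (lexicographic) so the
#' ranking is strictly ordered and deterministic.
#'
#' @param expr normalized log2 expression matrix, genes x samples.
#' @param contrast a [group_contrast()]; both groups need >= 3 samples.
#' @param sd_floor_frac fraction of |mean| used as the sd floor.
#' @param eps absolute lower bound on the sd.
#' @return A data.frame of class `ranked_list`: `gene`, `metric`, sorted
#'   descending; the contrast label is stored as an attribute.
#' @export
signal2noise_ranking <- function(expr, contrast, sd_floor_frac = 0.2,
                                 eps = 1e-8) {
  stopifnot(inherits(contrast, "group_contrast"))
  expr <- as.matrix(expr)
  a <- contrast$group_a
  b <- contrast$group_b
  if (length(a) < 3 || length(b) < 3) {
    stopf("each group needs at least 3 samples")
  }
  if (!all(c(a, b) %in% colnames(expr))) {
    stopf("contrast samples missing from expression matrix")
  }
  xa <- expr[, a, drop = FALSE]
  xb <- expr[, b, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  sda <- apply(xa, 1, sd)
  sdb <- apply(xb, 1, sd)
  sda <- pmax(sda, sd_floor_frac * abs(ma), eps)
  sdb <- pmax(sdb, sd_floor_frac * abs(mb), eps)
  metric <- (ma - mb) / (sda + sdb)
  if (any(!is.finite(metric))) stopf("non-finite ranking metric")
  ord <- order(-metric, rownames(expr))
  out <- data.frame(gene = rownames(expr)[ord], metric = metric[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- paste(contrast$label_a, "vs",
                                 contrast$label_b)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Core running-sum walk. hit_pos: positions (ranks) of set members.
# weight 0 is the classical equal-weight Kolmogorov-Smirnov form.
running_sum_core <- function(metric, hit_pos, weight) {
  n <- length(metric)
  k <- length(hit_pos)
  incr <- numeric(n)
  if (weight == 0) {
    incr[hit_pos] <- 1 / k
  } else {
    w <- abs(metric[hit_pos])^weight
    total <- sum(w)
    if (total == 0) {
      incr[hit_pos] <- 1 / k  # degenerate all-zero metric: equal weights
    } else {
      incr[hit_pos] <- w / total
    }
  }
  miss <- rep(-1 / (n - k), n)
  miss[hit_pos] <- 0
  cumsum(incr + miss)
}

es_from_running <- function(running) {
  i <- which.max(abs(running))
  list(es = running[i], peak = i)
}

#' Enrichment score of a gene set on a ranked list
#'
#' Walks the ranked list accumulating a running sum: each gene-set hit
#' adds `|metric|^weight / sum(|metric|^weight over hits)` (with
#' `weight = 0`, simply `1/k` — the classical Kolmogorov-Smirnov
#' statistic) and each miss subtracts `1/(N-k)`. The enrichment score is
#' the signed maximum deviation of the running sum from zero (first such
#' position on ties).
#'
#' @param ranked a [signal2noise_ranking()] result (or a data.frame with
#'   `gene` and `metric`, sorted).
#' @param geneset a [gene_signature()] or character vector of gene ids;
#'   its intersection with the ranked list must be non-empty and proper.
#' @param weight hit-weight exponent; 0 (default) = classical KS, 1 =
#'   the weighted variant common in GSEA software.
#' @return A list of class `enrichment_result`: `es`, `running`
#'   (running-sum vector), `peak` (its arg-max-deviation rank),
#'   `hit_ranks`, `geneset_name`, `n_hits`, `weight`.
#' @examples
#' rl <- structure(data.frame(gene = c("a", "b", "c", "d"),
#'                            metric = c(3, 2, 1, 0)),
#'                 class = c("ranked_list", "data.frame"))
#' enrichment_score(rl, c("a"))$es  # 1 at the top of the list
#' @export
enrichment_score <- function(ranked, geneset, weight = 0) {
  genes <- if (inherits(geneset, "gene_signature")) geneset$genes else
    as.character(geneset)
  gname <- if (inherits(geneset, "gene_signature")) geneset$name else
    "geneset"
  check_number(weight, "weight", min = 0)
  hit_pos <- which(ranked$gene %in% genes)
  n <- nrow(ranked)
  if (length(hit_pos) == 0) stopf("gene set does not intersect the list")
  if (length(hit_pos) == n) {
    stopf("gene set covers the entire ranked list")
  }
  running <- running_sum_core(ranked$metric, hit_pos, weight)
  peak <- es_from_running(running)
  structure(list(es = peak$es, running = running, peak = peak$peak,
                 hit_ranks = hit_pos, geneset_name = gname,
                 n_hits = length(hit_pos), weight = weight),
            class = "enrichment_result")
}

#' Permutation p-value from random gene sets
#'
#' Builds the null distribution of the enrichment score from `n_perm`
#' uniformly drawn random gene sets of the same size as the observed
#' intersection, and reports
#' `p = (1 + #\{|ES_null| >= |ES_obs|\}) / (n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of random gene sets (>= 100 recommended).
#' @param seed integer seed; deterministic given it.
#' @return An `enrichment_result` with added `p`, `n_perm`, `null_es`
#'   and `seed` fields.
#' @export
random_geneset_pvalue <- function(ranked, geneset, n_perm = 1000L,
                                  weight = 0, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 1)
  if (n_perm < 100) {
    warning("n_perm < 100 gives coarse p-values", call. = FALSE)
  }
  res <- enrichment_score(ranked, geneset, weight)
  n <- nrow(ranked)
  k <- res$n_hits
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort(sample.int(n, k))
      r <- running_sum_core(ranked$metric, pos, weight)
      r[which.max(abs(r))]
    }, numeric(1))
  })
  res$p <- (1 + sum(abs(null_es) >= abs(res$es))) / (n_perm + 1)
  res$n_perm <- n_perm
  res$null_es <- null_es
  res$seed <- seed
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$geneset_name, ": ES = ",
      formatC(x$es, digits = 3, format = "f"),
      " (", x$n_hits, " hits)", sep = "")
  if (!is.null(x$p)) {
    cat(", p = ", formatC(x$p, digits = 4, format = "g"),
        " (", x$n_perm, " permutations)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive enrichment score: the gene-set members ranked at or
#' before the running-sum peak, in rank order. For a negative score: the
#' members at or after the running-sum minimum.
#'
#' @param result an [enrichment_score()] / [random_geneset_pvalue()]
#'   result.
#' @param ranked the ranked list the result was computed on.
#' @return Character vector of leading-edge gene ids (empty, with a
#'   warning, when ES = 0).
#' @export
leading_edge <- function(result, ranked) {
  stopifnot(inherits(result, "enrichment_result"))
  if (result$es == 0) {
    warning("ES is 0; leading edge undefined", call. = FALSE)
    return(character(0))
  }
  hits <- result$hit_ranks
  keep <- if (result$es > 0) hits[hits <= result$peak] else
    hits[hits >= result$peak]
  ranked$gene[keep]
}

#' Distill a compact signature from a leading edge
#'
#' Takes the top `k_max` leading-edge genes, intersects them with a
#' curated annotation mask (an external input, e.g. known mitosis
#' regulators) and returns the result in rank order as a new signature.
#'
#' @param leading_edge ordered character vector of leading-edge genes.
#' @param annotation_mask character vector of annotated gene ids.
#' @param k_max how many leading-edge genes to consider.
#' @param name name of the distilled signature.
#' @return A [gene_signature()].
#' @export
distill_signature <- function(leading_edge, annotation_mask,
                              k_max = length(leading_edge),
                              name = "distilled") {
  k_max <- check_count(k_max, "k_max", min = 1)
  top <- head(leading_edge, k_max)
  keep <- top[top %in% annotation_mask]
  if (length(keep) == 0) {
    stopf(paste("no leading-edge gene within the annotation mask;",
                "consider a larger k_max"))
  }
  gene_signature(name, keep)
}
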