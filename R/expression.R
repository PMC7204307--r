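#' Filter genes with insufficient raw counts
#'
#' Genes are dropped when they fail to reach `min_total` raw reads across
#' all libraries. By default "across all the libraries" is read as the
#' summed count over the cohort (`per_library = FALSE`); set
#' `per_library = TRUE` to instead require at least `min_total` in every
#' single library.
#'
#' @param raw integer count matrix, genes x samples.
#' @param min_total minimum raw read count.
#' @param per_library apply the threshold per library instead of to the
#'   cohort sum.
#' @return The filtered count matrix (sample set unchanged).
#' @export
filter_low_counts <- function(raw, min_total = 2, per_library = FALSE) {
  raw <- as.matrix(raw)
  if (nrow(raw) == 0 || ncol(raw) == 0) stopf("empty count matrix")
  if (any(raw < 0) || any(raw != round(raw))) {
    stopf("raw counts must be non-negative integers")
  }
  check_flag(per_library, "per_library")
  keep <- if (per_library) {
    apply(raw >= min_total, 1, all)
  } else {
    rowSums(raw) >= min_total
  }
  raw[keep, , drop = FALSE]
}

#' TMM normalization of a count matrix
#'
#' Computes trimmed-mean-of-M-values scaling factors (doubly trimmed by
#' log-ratio and absolute expression, precision-weighted, against a
#' reference library chosen as the one whose upper-quartile count fraction
#' is closest to the cohort mean) and returns the log2 matrix of counts
#' per million of the factor-adjusted library size. The factors are
#' rescaled so their geometric mean is 1.
#'
#' @param raw filtered count matrix, genes x samples; every library must
#'   have a positive total.
#' @param trim_logratio,trim_abs trim proportions for the M (log-ratio)
#'   and A (absolute expression) dimensions.
#' @param ref_sample optional reference column name or index.
#' @param prior_count pseudocount for the log2 transform.
#' @return A list of class `tmm_normalized`: `log2` (normalized matrix),
#'   `norm_factors` (named), `lib_sizes`, `effective_lib_sizes`
#'   (`lib_sizes * norm_factors`).
#' @export
tmm_normalize <- function(raw, trim_logratio = 0.30, trim_abs = 0.05,
                          ref_sample = NULL, prior_count = 0.5) {
  raw <- as.matrix(raw)
  if (any(colSums(raw) <= 0)) stopf("library with zero total count")
  ref_col <- if (is.null(ref_sample)) NULL else {
    if (is.character(ref_sample)) match(ref_sample, colnames(raw)) else
      as.integer(ref_sample)
  }
  y <- edgeR::DGEList(counts = raw)
  y <- edgeR::calcNormFactors(y, method = "TMM",
                              refColumn = ref_col,
                              logratioTrim = trim_logratio,
                              sumTrim = trim_abs)
  nf <- setNames(y$samples$norm.factors, colnames(raw))
  lib <- setNames(y$samples$lib.size, colnames(raw))
  log2m <- edgeR::cpm(y, log = TRUE, prior.count = prior_count)
  structure(
    list(log2 = log2m, norm_factors = nf, lib_sizes = lib,
         effective_lib_sizes = lib * nf),
    class = "tmm_normalized"
  )
}

#' Define a gene signature
#'
#' @param name signature name.
#' @param genes character vector of member gene ids (unique, non-empty).
#' @param directions optional numeric vector of +1/-1 expected directions
#'   per member (default all +1).
#' @return A list of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, directions = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0) stopf("signature must be non-empty")
  if (anyDuplicated(genes)) stopf("signature members must be unique")
  if (is.null(directions)) directions <- rep(1, length(genes))
  if (length(directions) != length(genes) ||
      !all(directions %in% c(-1, 1))) {
    stopf("`directions` must be +1/-1, one per member")
  }
  structure(list(name = name, genes = genes,
                 directions = setNames(directions, genes)),
            class = "gene_signature")
}

#' Single-sample signature activation by the Z-score method
#'
#' Each signature gene present in the matrix is standardized to zero mean
#' and unit variance across samples; a sample's activation score is the
#' (direction-signed) sum of its member z-values divided by `sqrt(k)`
#' (Stouffer combination, the default) or the plain mean of z-values
#' (`combine = "mean"`). Under the default the score vector has mean ~0
#' on the standardization cohort itself and a random gene set on null
#' data is asymptotically standard normal.
#'
#' @param expr normalized (log2) expression matrix, genes x samples.
#' @param signature a [gene_signature()].
#' @param combine `"stouffer"` (sum of z / sqrt(k)) or `"mean"`.
#' @return Named numeric vector of per-sample scores, with attributes
#'   `signature`, `n_members_used` and `combine`.
#' @export
signature_zscore <- function(expr, signature,
                             combine = c("stouffer", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(signature, "gene_signature"))
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stopf("need at least 2 samples")
  present <- intersect(signature$genes, rownames(expr))
  missing <- setdiff(signature$genes, present)
  if (length(missing)) {
    message(length(missing), " signature gene(s) absent from matrix, ",
            "skipped: ", paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  if (length(present) == 0) stopf("no signature members present")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  zerovar <- sds == 0 | !is.finite(sds)
  if (any(zerovar)) {
    warning("excluding zero-variance signature gene(s): ",
            paste(head(present[zerovar], 5), collapse = ", "),
            call. = FALSE)
    present <- present[!zerovar]
    if (length(present) == 0) stopf("no usable signature members")
    sub <- expr[present, , drop = FALSE]
    sds <- sds[!zerovar]
  }
  z <- (sub - rowMeans(sub)) / sds
  z <- z * signature$directions[present]
  k <- length(present)
  score <- if (combine == "stouffer") colSums(z) / sqrt(k) else
    colMeans(z)
  attr(score, "signature") <- signature$name
  attr(score, "n_members_used") <- k
  attr(score, "combine") <- combine
  score
}

#' Stratify samples by signature score
#'
#' Median method: samples strictly above the cohort median are "high",
#' the rest "low". Tertile method: samples are binned at the empirical
#' tertiles into "lowest"/"middle"/"highest" for descriptive use.
#'
#' @param scores named per-sample score vector.
#' @param method `"median"` or `"tertile"`.
#' @return A list of class `cin_status`: `labels` (named character),
#'   `threshold` (median, or the two tertile cutpoints), `method`.
#' @export
stratify_cin <- function(scores, method = c("median", "tertile")) {
  method <- match.arg(method)
  if (length(scores) < 2) stopf("need at least 2 samples")
  if (max(scores) == min(scores)) {
    stopf("scores are constant; no stratification possible")
  }
  if (method == "median") {
    thr <- median(scores)
    labels <- ifelse(scores > thr, "high", "low")
  } else {
    thr <- quantile(scores, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    labels <- cut(scores, breaks = c(-Inf, thr, Inf),
                  labels = c("lowest", "middle", "highest"),
                  right = TRUE)
    labels <- setNames(as.character(labels), names(scores))
  }
  structure(list(labels = setNames(labels, names(scores)),
                 threshold = thr, method = method),
            class = "cin_status")
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
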