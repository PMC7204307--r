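#' Fit the PCA + Gaussian-kernel SVM signature classifier
#'
#' Restricts the expression matrix to the signature genes, standardizes
#' each gene (training statistics stored), projects the samples onto the
#' top two principal components, and fits a radial (Gaussian) kernel SVM
#' on the 2-D scores. The kernel width defaults to the median heuristic
#' on the pairwise training distances in PC space.
#'
#' @param expr normalized log2 expression matrix, genes x samples.
#' @param signature a [gene_signature()]; at least 2 members must be
#'   present in the matrix.
#' @param labels factor or vector of two classes, one per sample (named,
#'   or in column order). The second factor level is the positive class.
#' @param seed integer seed (SVM fitting is deterministic here, but the
#'   seed is stored for provenance and used by any downstream
#'   resampling).
#' @param cost SVM regularization parameter.
#' @param gamma optional kernel parameter; default: `1 / (2 * h^2)` with
#'   `h` the median pairwise distance of the training PC scores.
#' @return An object of class `signature_classifier`.
#' @export
fit_pca_svm <- function(expr, signature, labels, seed = 1L, cost = 1,
                        gamma = NULL) {
  stopifnot(inherits(signature, "gene_signature"))
  expr <- as.matrix(expr)
  if (!is.factor(labels)) labels <- factor(labels)
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  if (length(labels) != ncol(expr)) {
    stopf("`labels` must have one entry per sample")
  }
  if (nlevels(droplevels(labels)) != 2) {
    stopf("`labels` must contain exactly 2 classes")
  }
  labels <- droplevels(labels)
  if (min(table(labels)) < 4) {
    stopf("each class needs at least 4 samples")
  }
  genes <- intersect(signature$genes, rownames(expr))
  if (length(genes) < 2) stopf("fewer than 2 usable signature genes")
  x <- t(expr[genes, , drop = FALSE])  # samples x genes
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  usable <- scl > 0
  if (sum(usable) < 2) stopf("fewer than 2 usable signature genes")
  genes <- genes[usable]
  x <- scale(x[, usable, drop = FALSE], center = ctr[usable],
             scale = scl[usable])
  pca <- prcomp(x, center = FALSE, scale. = FALSE, rank. = 2)
  scores <- pca$x[, 1:2, drop = FALSE]
  if (is.null(gamma)) {
    d <- as.vector(dist(scores))
    h <- median(d[d > 0])
    gamma <- if (is.finite(h) && h > 0) 1 / (2 * h^2) else 1
  }
  fit <- with_seed(seed, {
    e1071::svm(x = scores, y = labels, kernel = "radial", cost = cost,
               gamma = gamma, scale = FALSE)
  })
  # orient decision values so larger = positive class (second level)
  dv <- attr(predict(fit, scores, decision.values = TRUE),
             "decision.values")[, 1]
  pos <- levels(labels)[2]
  flip <- if (mean(dv[labels == pos]) < mean(dv[labels != pos])) -1 else 1
  structure(
    list(genes = genes, center = ctr[usable], scale = scl[usable],
         rotation = pca$rotation[, 1:2, drop = FALSE], svm = fit,
         gamma = gamma, cost = cost, flip = flip,
         levels = levels(labels), positive = pos, seed = seed),
    class = "signature_classifier"
  )
}

#' Decision scores of a fitted signature classifier
#'
#' Applies the stored per-gene standardization and 2-component projection
#' and returns continuous SVM decision values (larger = more like the
#' positive class). Signature genes absent from `expr` are imputed at
#' the training mean (i.e. standardized value 0), with a message.
#'
#' @param model a [fit_pca_svm()] classifier.
#' @param expr expression matrix, genes x samples.
#' @return Named numeric vector of decision values.
#' @export
predict_scores <- function(model, expr) {
  stopifnot(inherits(model, "signature_classifier"))
  expr <- as.matrix(expr)
  present <- intersect(model$genes, rownames(expr))
  if (length(present) == 0) stopf("all signature genes missing")
  if (length(present) < length(model$genes)) {
    message(length(model$genes) - length(present),
            " signature gene(s) missing; imputed at training mean")
  }
  z <- matrix(0, nrow = ncol(expr), ncol = length(model$genes),
              dimnames = list(colnames(expr), model$genes))
  z[, present] <- t((expr[present, , drop = FALSE] -
                       model$center[present]) / model$scale[present])
  scores <- z %*% model$rotation
  dv <- attr(predict(model$svm, scores, decision.values = TRUE),
             "decision.values")[, 1]
  setNames(model$flip * dv, colnames(expr))
}

#' @export
print.signature_classifier <- function(x, ...) {
  cat("<signature_classifier> ", length(x$genes),
      " genes -> 2 PCs -> radial SVM (gamma = ",
      formatC(x$gamma, digits = 3, format = "g"), ", cost = ", x$cost,
      "); positive class: ", x$positive, "\n", sep = "")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over the unique scores (descending), recording one
#' (FPR, TPR) point per threshold, and computes the AUC as the
#' trapezoidal area — equivalent to the Mann-Whitney pair-counting
#' statistic with half credit for ties.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels two-class labels; the second factor level is positive.
#' @return A list of class `roc_result`: `points` (data.frame `fpr`,
#'   `tpr`, `threshold`), `auc`, `positive`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) stopf("labels must contain exactly 2 classes")
  pos <- levels(labels)[2]
  y <- labels == pos
  n1 <- sum(y)
  n0 <- sum(!y)
  ord <- order(-scores)
  ys <- y[ord]
  ss <- scores[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(ss))
  tp <- tapply(ys, grp, sum)
  fp <- tapply(!ys, grp, sum)
  tpr <- c(0, cumsum(tp) / n1)
  fpr <- c(0, cumsum(fp) / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  points <- data.frame(fpr = fpr, tpr = tpr,
                       threshold = c(Inf, unique(ss)))
  structure(list(points = points, auc = auc, positive = pos),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", formatC(x$auc, digits = 3, format = "f"),
      " (positive class: ", x$positive, ", ",
      nrow(x$points) - 1, " thresholds)\n", sep = "")
  invisible(x)
}

#' Cross-validated (or resubstitution) AUC of the PCA-SVM classifier
#'
#' `scheme = "cv"` runs stratified k-fold cross-validation with all
#' preprocessing (standardization, PCA, kernel width) learned inside each
#' training fold, pooling the held-out decision values into one ROC.
#' `scheme = "resubstitution"` fits once and scores the training samples
#' themselves (optimistic; reported as such).
#'
#' @inheritParams fit_pca_svm
#' @param k number of folds.
#' @param scheme `"cv"` or `"resubstitution"`.
#' @return A `roc_result` with added `scheme` field and the pooled
#'   `scores`.
#' @export
cv_auc <- function(expr, signature, labels, k = 5L, seed = 1L,
                   scheme = c("cv", "resubstitution"), cost = 1,
                   gamma = NULL) {
  scheme <- match.arg(scheme)
  expr <- as.matrix(expr)
  if (!is.factor(labels)) labels <- factor(labels)
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  labels <- droplevels(labels)
  if (scheme == "resubstitution") {
    model <- fit_pca_svm(expr, signature, labels, seed = seed,
                         cost = cost, gamma = gamma)
    sc <- predict_scores(model, expr)
    out <- roc_auc(sc, labels)
    out$scheme <- "resubstitution"
    out$scores <- sc
    return(out)
  }
  k <- check_count(k, "k", min = 2)
  n <- ncol(expr)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  sc <- setNames(numeric(n), colnames(expr))
  for (fold in seq_len(k)) {
    test <- folds == fold
    if (nlevels(droplevels(labels[!test])) != 2) {
      stopf("fold %d lost a class; reduce k", fold)
    }
    model <- fit_pca_svm(expr[, !test, drop = FALSE], signature,
                         labels[!test], seed = derive_seed(seed, fold),
                         cost = cost, gamma = gamma)
    sc[test] <- predict_scores(model, expr[, test, drop = FALSE])
  }
  out <- roc_auc(sc, labels)
  out$scheme <- sprintf("%d-fold cv", k)
  out$scores <- sc
  out
}
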