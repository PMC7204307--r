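#' Construct a genome arm model
#'
#' A genome arm model defines the denominators of the copy-number alteration
#' scores: the catalog of chromosome arms (for the broad-CNA score) and the
#' gene catalog (for the focal-CNA score). Coordinates are 0-based
#' half-open throughout the package.
#'
#' @param arms data.frame with columns `chrom`, `arm` ("p"/"q"), `start`,
#'   `end` (0-based half-open) and optionally `arm_name`; arms must be
#'   non-overlapping within a chromosome.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   every gene must lie entirely within exactly one arm.
#'
#' @return An object of class `genome_arm_model`: a list with elements
#'   `arms`, `genes`, `total_arms` and `total_genes`.
#' @export
genome_arm_model <- function(arms, genes) {
  need <- c("chrom", "arm", "start", "end")
  if (!all(need %in% names(arms))) {
    stopf("`arms` must have columns %s", paste(need, collapse = ", "))
  }
  needg <- c("gene_id", "chrom", "start", "end")
  if (!all(needg %in% names(genes))) {
    stopf("`genes` must have columns %s", paste(needg, collapse = ", "))
  }
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (any(arms$end <= arms$start)) stopf("arm with end <= start")
  if (nrow(genes) > 0 && any(genes$end <= genes$start)) {
    stopf("gene with end <= start")
  }
  if (is.null(arms$arm_name)) {
    arms$arm_name <- paste0(sub("^chr", "", arms$chrom), arms$arm)
  }
  if (anyDuplicated(arms$arm_name)) stopf("duplicate arm names")
  if (anyDuplicated(genes$gene_id)) stopf("duplicate gene ids")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)])) {
      stopf("overlapping arms on chromosome %s", ch)
    }
  }
  # every gene must be contained in exactly one arm
  if (nrow(genes) > 0) {
    hit <- vapply(seq_len(nrow(genes)), function(i) {
      sum(arms$chrom == genes$chrom[i] &
            arms$start <= genes$start[i] &
            arms$end >= genes$end[i])
    }, integer(1))
    if (any(hit != 1L)) {
      stopf("%d gene(s) not contained in exactly one arm", sum(hit != 1L))
    }
  }
  structure(
    list(arms = arms, genes = genes,
         total_arms = nrow(arms), total_genes = nrow(genes)),
    class = "genome_arm_model"
  )
}

#' @export
print.genome_arm_model <- function(x, ...) {
  cat("<genome_arm_model> ", length(unique(x$arms$chrom)), " chromosomes, ",
      x$total_arms, " arms, ", x$total_genes, " genes\n", sep = "")
  invisible(x)
}

#' Generate a toy genome arm model
#'
#' Builds a simplified genome of `arms / 2` chromosomes, each split into a
#' p and a q arm of `arm_length_bp` base pairs, and places `n_genes` genes
#' of `gene_length_bp` uniformly at random, each entirely within one arm.
#' Placement is deterministic given `seed`.
#'
#' @param arms even integer; total number of chromosome arms (two per
#'   chromosome). The human genome as used for arm-level CNA scoring has
#'   roughly 39-46 informative arms.
#' @param arm_length_bp positive integer arm length in base pairs.
#' @param n_genes number of genes in the catalog.
#' @param gene_length_bp gene footprint in bp (must fit inside an arm).
#' @param seed integer seed controlling gene placement.
#'
#' @return A [genome_arm_model()].
#' @examples
#' gm <- generate_arm_model(arms = 4, arm_length_bp = 1e6, n_genes = 100,
#'                          seed = 1)
#' gm$total_arms
#' @export
generate_arm_model <- function(arms = 46L, arm_length_bp = 1e6,
                               n_genes = 2000L, gene_length_bp = 1000L,
                               seed = 1L) {
  arms <- check_count(arms, "arms", min = 2)
  if (arms %% 2L != 0L) stopf("`arms` must be even (two per chromosome)")
  arm_length_bp <- check_count(arm_length_bp, "arm_length_bp", min = 1)
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  gene_length_bp <- check_count(gene_length_bp, "gene_length_bp", min = 1)
  if (gene_length_bp > arm_length_bp) {
    stopf("`gene_length_bp` must not exceed `arm_length_bp`")
  }
  n_chrom <- arms %/% 2L
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = 2L))
  arm_lab <- rep(c("p", "q"), times = n_chrom)
  start <- rep(c(0, arm_length_bp), times = n_chrom)
  arm_df <- data.frame(
    chrom = chrom, arm = arm_lab,
    start = start, end = start + arm_length_bp,
    arm_name = paste0(rep(seq_len(n_chrom), each = 2L), arm_lab),
    stringsAsFactors = FALSE
  )
  genes <- with_seed(seed, {
    arm_idx <- sample.int(nrow(arm_df), n_genes, replace = TRUE)
    gstart <- arm_df$start[arm_idx] +
      floor(runif(n_genes, 0, arm_length_bp - gene_length_bp + 1))
    data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      chrom = arm_df$chrom[arm_idx],
      start = gstart, end = gstart + gene_length_bp,
      stringsAsFactors = FALSE
    )
  })
  genome_arm_model(arm_df, genes)
}

#' Read / write a genome arm model
#'
#' `read_arm_model()` reads arms from a BED-like TSV (`chrom`, `start`,
#' `end`, `arm_name`) and genes from a TSV (`gene_id`, `chrom`, `start`,
#' `end`); `write_arm_model()` writes the same two files.
#'
#' @param arm_file,gene_file paths to the arm BED-like TSV and gene TSV.
#' @param model a [genome_arm_model()].
#' @return `read_arm_model()` returns a [genome_arm_model()];
#'   `write_arm_model()` returns the paths invisibly.
#' @export
read_arm_model <- function(arm_file, gene_file) {
  a <- read.delim(arm_file, stringsAsFactors = FALSE)
  if (is.null(a$arm)) a$arm <- sub("^.*(p|q)$", "\\1", a$arm_name)
  g <- read.delim(gene_file, stringsAsFactors = FALSE)
  genome_arm_model(a, g)
}

#' @rdname read_arm_model
#' @export
write_arm_model <- function(model, arm_file, gene_file) {
  stopifnot(inherits(model, "genome_arm_model"))
  write.table(model$arms[, c("chrom", "start", "end", "arm_name", "arm")],
              arm_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(model$genes, gene_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(arm_file, gene_file))
}
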