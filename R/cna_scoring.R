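#' Read a SEG-style segment table
#'
#' Expects a TSV with columns `sample`, `chrom`, `start`, `end`, `value`
#' (a GISTIC-style log2 copy-number ratio). Coordinates are assumed
#' 0-based half-open; set `coords = "1incl"` for 1-based inclusive input,
#' which is converted on read.
#'
#' @param path file path.
#' @param coords `"0half"` (default) or `"1incl"`.
#' @return A segment data.frame.
#' @export
read_seg <- function(path, coords = c("0half", "1incl")) {
  coords <- match.arg(coords)
  seg <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "value")
  if (!all(need %in% names(seg))) {
    stopf("segment file must have columns %s", paste(need, collapse = ", "))
  }
  if (coords == "1incl") {
    seg$start <- seg$start - 1L  # end stays: [s, e] 1-based == [s-1, e) 0-based
  }
  validate_segments(seg)
  seg
}

validate_segments <- function(seg, check_value = TRUE) {
  need <- c("sample", "chrom", "start", "end")
  if (check_value) need <- c(need, "value")
  if (!all(need %in% names(seg))) {
    stopf("segment table must have columns %s", paste(need, collapse = ", "))
  }
  bad <- which(seg$end <= seg$start)
  if (length(bad)) {
    stopf("malformed segment (end <= start) at row(s) %s",
          paste(head(bad, 5), collapse = ", "))
  }
  invisible(seg)
}

#' Label copy-number segments as gain or loss
#'
#' Segments with a GISTIC-style value strictly greater than
#' `gain_threshold` are labelled "gain", strictly less than
#' `loss_threshold` "loss"; values in the closed interval between the two
#' thresholds (including the boundaries, since the rules are strict
#' inequalities) are neutral and dropped.
#'
#' @param segments segment data.frame (`sample`, `chrom`, `start`, `end`,
#'   `value`).
#' @param gain_threshold,loss_threshold thresholds on the segment value;
#'   `loss_threshold` must be below `gain_threshold`.
#' @return The altered subset of `segments` with an added `direction`
#'   column ("gain"/"loss"); order and coordinates preserved.
#' @examples
#' seg <- data.frame(sample = "s1", chrom = "chr1", start = 0,
#'                   end = 100, value = c(0.5, 0.3, -0.4))
#' threshold_segments(seg)
#' @export
threshold_segments <- function(segments, gain_threshold = 0.3,
                               loss_threshold = -0.3) {
  check_number(gain_threshold, "gain_threshold")
  check_number(loss_threshold, "loss_threshold")
  if (loss_threshold >= gain_threshold) {
    stopf("`loss_threshold` must be below `gain_threshold`")
  }
  validate_segments(segments)
  direction <- ifelse(segments$value > gain_threshold, "gain",
                      ifelse(segments$value < loss_threshold, "loss", NA))
  out <- segments[!is.na(direction), , drop = FALSE]
  out$direction <- direction[!is.na(direction)]
  rownames(out) <- NULL
  out
}

#' Split segments at chromosome-arm boundaries
#'
#' Intersects every segment with the arm intervals of the genome model so
#' that each output segment lies entirely within one arm; a segment
#' spanning the centromere is split, its value copied to both parts.
#' Total altered base pairs are conserved exactly.
#'
#' @param segments segment data.frame (optionally with `direction`).
#' @param model a [genome_arm_model()].
#' @return The arm-split segment table with added `arm_name` column.
#' @export
split_segments_by_arm <- function(segments, model) {
  stopifnot(inherits(model, "genome_arm_model"))
  validate_segments(segments, check_value = FALSE)
  if (nrow(segments) == 0) {
    out <- segments
    out$arm_name <- character(0)
    return(out)
  }
  unknown <- setdiff(unique(segments$chrom), unique(model$arms$chrom))
  if (length(unknown)) {
    stopf("segment chromosome(s) not in arm model: %s",
          paste(unknown, collapse = ", "))
  }
  seg_gr <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1L,
                              end = segments$end))
  arm_gr <- GenomicRanges::GRanges(
    seqnames = model$arms$chrom,
    ranges = IRanges::IRanges(start = model$arms$start + 1L,
                              end = model$arms$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, arm_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  covered <- tapply(
    IRanges::width(IRanges::pintersect(IRanges::ranges(seg_gr)[qh],
                                       IRanges::ranges(arm_gr)[sh])),
    qh, sum)
  widths <- segments$end - segments$start
  cov_full <- setNames(rep(0, nrow(segments)), seq_len(nrow(segments)))
  cov_full[names(covered)] <- covered
  if (any(cov_full < widths)) {
    stopf("segment(s) extend outside all arm intervals: row(s) %s",
          paste(head(which(cov_full < widths), 5), collapse = ", "))
  }
  piece <- IRanges::pintersect(IRanges::ranges(seg_gr)[qh],
                               IRanges::ranges(arm_gr)[sh])
  out <- segments[qh, , drop = FALSE]
  out$start <- IRanges::start(piece) - 1L
  out$end <- IRanges::end(piece)
  out$arm_name <- model$arms$arm_name[sh]
  rownames(out) <- NULL
  out
}

#' Call broad and focal alteration events
#'
#' For each (sample, arm, direction) the altered regions are merged
#' (union of intervals); if the merged altered length exceeds
#' `broad_fraction` of the arm (strictly — the rule is "longer than"), a
#' single broad event is emitted for that sample/arm/direction; otherwise
#' one focal event is emitted per maximal merged altered run.
#'
#' @param altered arm-split, thresholded segment table (needs columns
#'   `sample`, `chrom`, `start`, `end`, `direction`, `arm_name`).
#' @param model a [genome_arm_model()].
#' @param broad_fraction arm fraction above which a merged altered region
#'   is broad; must lie strictly inside (0, 1).
#' @return data.frame of events: `sample`, `chrom`, `arm_name`,
#'   `direction`, `breadth` ("broad"/"focal"), `span_bp`, `arm_fraction`
#'   (for focal events, the fraction of the individual run; for broad
#'   events, of the merged altered length).
#' @export
call_events <- function(altered, model, broad_fraction = 0.98) {
  stopifnot(inherits(model, "genome_arm_model"))
  check_number(broad_fraction, "broad_fraction")
  if (broad_fraction <= 0 || broad_fraction >= 1) {
    stopf("`broad_fraction` must be strictly between 0 and 1")
  }
  need <- c("sample", "chrom", "start", "end", "direction", "arm_name")
  if (!all(need %in% names(altered))) {
    stopf("`altered` must be thresholded and arm-split (columns %s)",
          paste(need, collapse = ", "))
  }
  empty <- data.frame(sample = character(), chrom = character(),
                      arm_name = character(), direction = character(),
                      breadth = character(), span_bp = double(),
                      arm_fraction = double(), stringsAsFactors = FALSE)
  if (nrow(altered) == 0) return(empty)
  arm_len <- setNames(model$arms$end - model$arms$start,
                      model$arms$arm_name)
  key <- factor(paste(altered$sample, altered$arm_name,
                      altered$direction, sep = "\r"))
  ir <- IRanges::IRanges(start = altered$start + 1L, end = altered$end)
  merged <- IRanges::reduce(S4Vectors::split(ir, key))  # per-group runs
  widths <- IRanges::width(merged)
  totals <- sum(widths)
  runs_per_group <- lengths(widths)
  first <- !duplicated(key)
  grp_order <- match(levels(key), key[first])
  meta <- altered[which(first)[grp_order], c("sample", "chrom",
                                             "arm_name", "direction")]
  alen <- arm_len[meta$arm_name]
  is_broad <- totals / alen > broad_fraction
  n_rows <- ifelse(is_broad, 1L, runs_per_group)
  rep_idx <- rep(seq_along(n_rows), n_rows)
  w_all <- unlist(widths, use.names = FALSE)  # runs in group order
  run_grp <- rep(seq_along(runs_per_group), runs_per_group)
  span <- numeric(length(rep_idx))
  span[is_broad[rep_idx]] <- totals[is_broad]
  span[!is_broad[rep_idx]] <- w_all[!is_broad[run_grp]]
  out <- data.frame(
    sample = meta$sample[rep_idx], chrom = meta$chrom[rep_idx],
    arm_name = meta$arm_name[rep_idx],
    direction = meta$direction[rep_idx],
    breadth = ifelse(is_broad, "broad", "focal")[rep_idx],
    span_bp = span,
    arm_fraction = span / alen[rep_idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$sample, match(out$arm_name, model$arms$arm_name),
            out$direction), , drop = FALSE]
}

#' Per-sample broad and focal CNA scores
#'
#' The broad-CNA score of a sample is its number of broad events divided
#' by the total number of chromosome arms; the focal-CNA score is its
#' number of focal events divided by the total number of genes in the
#' catalog. Gains and losses both count; samples listed in `samples` with
#' no events score 0.
#'
#' @param events event table from [call_events()].
#' @param model a [genome_arm_model()].
#' @param samples optional character vector of sample ids to report
#'   (default: samples present in `events`).
#' @return Named numeric vector of scores.
#' @export
broad_cna_score <- function(events, model, samples = NULL) {
  stopifnot(inherits(model, "genome_arm_model"))
  if (is.null(samples)) samples <- unique(events$sample)
  n <- table(factor(events$sample[events$breadth == "broad"],
                    levels = samples))
  as.vector(n) / model$total_arms -> score
  setNames(score, samples)
}

#' @rdname broad_cna_score
#' @export
focal_cna_score <- function(events, model, samples = NULL) {
  stopifnot(inherits(model, "genome_arm_model"))
  if (model$total_genes == 0) stopf("gene catalog is empty")
  if (is.null(samples)) samples <- unique(events$sample)
  n <- table(factor(events$sample[events$breadth == "focal"],
                    levels = samples))
  setNames(as.vector(n) / model$total_genes, samples)
}

#' Tumor mutational burden
#'
#' Nonsynonymous mutation count divided by the exome size in megabases;
#' the default denominator is the 299.029409 Mb consensus exome.
#'
#' @param nonsyn_count nonnegative mutation count (vectorized).
#' @param exome_size_mb exome size in Mb.
#' @return Mutations per megabase.
#' @examples
#' tmb_score(2990)
#' @export
tmb_score <- function(nonsyn_count, exome_size_mb = 299.029409) {
  check_number(exome_size_mb, "exome_size_mb", min = 1e-12)
  if (any(!is.finite(nonsyn_count)) || any(nonsyn_count < 0)) {
    stopf("`nonsyn_count` must be nonnegative")
  }
  nonsyn_count / exome_size_mb
}

#' Fusion score
#'
#' Ratio of the number of fusion events observed in a sample to the total
#' number of fusion types assayed.
#'
#' @param n_events nonnegative event count (vectorized).
#' @param n_fusion_types positive number of fusion types.
#' @return The ratio.
#' @export
fusion_score <- function(n_events, n_fusion_types) {
  if (any(!is.finite(n_fusion_types)) || any(n_fusion_types <= 0)) {
    stopf("`n_fusion_types` must be positive")
  }
  if (any(!is.finite(n_events)) || any(n_events < 0)) {
    stopf("`n_events` must be nonnegative")
  }
  n_events / n_fusion_types
}

#' Cohort CNA frequency profile
#'
#' Tiles the genome into `bin_bp` bins and reports, per bin, the fraction
#' of cohort samples with any gain (resp. loss) segment overlapping the
#' bin.
#'
#' @param altered thresholded segment table (with `direction`).
#' @param model a [genome_arm_model()].
#' @param bin_bp bin width in base pairs.
#' @param samples cohort sample ids (defaults to those present in
#'   `altered`); the denominator of the frequencies.
#' @return data.frame: `chrom`, `start`, `end`, `gain_freq`, `loss_freq`.
#' @export
cna_frequency_profile <- function(altered, model, bin_bp,
                                  samples = NULL) {
  stopifnot(inherits(model, "genome_arm_model"))
  bin_bp <- check_count(bin_bp, "bin_bp", min = 1)
  if (is.null(samples)) samples <- unique(altered$sample)
  if (length(samples) == 0) stopf("empty cohort")
  chroms <- unique(model$arms$chrom)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    lo <- min(model$arms$start[model$arms$chrom == ch])
    hi <- max(model$arms$end[model$arms$chrom == ch])
    s <- seq(lo, hi - 1L, by = bin_bp)
    data.frame(chrom = ch, start = s, end = pmin(s + bin_bp, hi),
               stringsAsFactors = FALSE)
  }))
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1L,
                                                    bins$end))
  freq <- function(dir) {
    sub <- altered[altered$direction == dir, , drop = FALSE]
    if (nrow(sub) == 0) return(rep(0, nrow(bins)))
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start + 1L, sub$end))
    hits <- GenomicRanges::findOverlaps(bin_gr, gr)
    pair <- unique(data.frame(bin = S4Vectors::queryHits(hits),
                              sample = sub$sample[S4Vectors::subjectHits(hits)]))
    cnt <- table(factor(pair$bin, levels = seq_len(nrow(bins))))
    as.vector(cnt) / length(samples)
  }
  bins$gain_freq <- freq("gain")
  bins$loss_freq <- freq("loss")
  bins
}

#' Assemble the per-sample genomic score panel
#'
#' Convenience wrapper running the full copy-number scoring chain
#' (threshold, arm-split, event calling, broad/focal scores) and combining
#' it with TMB, fusion score and the MSI passthrough from a per-sample
#' annotation table.
#'
#' @param segments raw SEG-style segment table.
#' @param model a [genome_arm_model()].
#' @param annotations per-sample data.frame with columns `sample`,
#'   `nonsyn_mutations`, `fusion_events`, `fusion_types_total` and
#'   optionally `msi`.
#' @param gain_threshold,loss_threshold,broad_fraction see
#'   [threshold_segments()] and [call_events()].
#' @return data.frame with one row per sample: `sample`,
#'   `broad_cna_score`, `focal_cna_score`, `tmb`, `fusion_score`, `msi`
#'   (NA when absent), plus empty `cin70_score`/`pccin_score` columns to
#'   be filled from expression.
#' @export
genomic_score_panel <- function(segments, model, annotations,
                                gain_threshold = 0.3,
                                loss_threshold = -0.3,
                                broad_fraction = 0.98) {
  need <- c("sample", "nonsyn_mutations", "fusion_events",
            "fusion_types_total")
  if (!all(need %in% names(annotations))) {
    stopf("`annotations` must have columns %s", paste(need, collapse = ", "))
  }
  samples <- annotations$sample
  alt <- threshold_segments(segments, gain_threshold, loss_threshold)
  alt <- split_segments_by_arm(alt, model)
  ev <- call_events(alt, model, broad_fraction)
  data.frame(
    sample = samples,
    broad_cna_score = as.vector(broad_cna_score(ev, model, samples)),
    focal_cna_score = as.vector(focal_cna_score(ev, model, samples)),
    tmb = tmb_score(annotations$nonsyn_mutations),
    fusion_score = fusion_score(annotations$fusion_events,
                                annotations$fusion_types_total),
    msi = if (!is.null(annotations$msi)) annotations$msi else NA_real_,
    cin70_score = NA_real_,
    pccin_score = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Pairwise Pearson correlation matrix of score columns
#'
#' @param panel a score panel data.frame (non-numeric columns such as
#'   `sample` are dropped automatically).
#' @return Symmetric correlation matrix with unit diagonal; columns that
#'   are constant (or all-NA) give NA entries with a warning, never 0.
#' @export
score_correlation_matrix <- function(panel) {
  num <- panel[vapply(panel, is.numeric, logical(1))]
  num <- num[, colSums(!is.na(num)) > 0, drop = FALSE]
  if (nrow(num) < 3) stopf("need at least 3 samples")
  const <- vapply(num, function(x) var(x, na.rm = TRUE) == 0 ||
                    !is.finite(var(x, na.rm = TRUE)), logical(1))
  if (any(const)) {
    warning("constant score column(s) reported as NA: ",
            paste(names(num)[const], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(m <- cor(as.matrix(num), use = "pairwise.complete.obs"))
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}
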