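# Independent brute-force oracles. These deliberately avoid the package's
# code paths (IRanges merging, p.adjust, cumsum tricks) so that agreement
# is evidence, not tautology.

# union length of a set of [start, end) intervals by endpoint sweep
oracle_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  total <- 0
  cur_s <- start[1]
  cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

# number of maximal merged runs of a set of [start, end) intervals
oracle_run_count <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  runs <- 1L
  cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      runs <- runs + 1L
      cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  runs
}

# Full brute-force re-derivation of gain/loss + broad/focal calls and both
# CNA scores from a raw segment table and an arm model. Direct interval
# arithmetic per (sample, arm, direction); strict inequalities throughout.
oracle_cna_scores <- function(segments, model, gain_thr = 0.3,
                              loss_thr = -0.3, broad_fraction = 0.98) {
  samples <- unique(segments$sample)
  broad <- setNames(numeric(length(samples)), samples)
  focal <- setNames(numeric(length(samples)), samples)
  n_broad <- setNames(integer(length(samples)), samples)
  n_focal <- setNames(integer(length(samples)), samples)
  arm_chrom <- model$arms$chrom
  arm_start <- model$arms$start
  arm_end <- model$arms$end
  for (s in samples) {
    in_s <- segments$sample == s
    s_chrom <- segments$chrom[in_s]
    s_start <- segments$start[in_s]
    s_end <- segments$end[in_s]
    s_value <- segments$value[in_s]
    for (ai in seq_along(arm_chrom)) {
      alen <- arm_end[ai] - arm_start[ai]
      on_arm <- s_chrom == arm_chrom[ai] & s_start < arm_end[ai] &
        s_end > arm_start[ai]
      if (!any(on_arm)) next
      for (dir in c("gain", "loss")) {
        keep <- on_arm & (if (dir == "gain") s_value > gain_thr else
          s_value < loss_thr)
        if (!any(keep)) next
        cs <- pmax(s_start[keep], arm_start[ai])
        ce <- pmin(s_end[keep], arm_end[ai])
        total <- oracle_union_length(cs, ce)
        if (total > broad_fraction * alen) {
          n_broad[s] <- n_broad[s] + 1L
        } else {
          n_focal[s] <- n_focal[s] + oracle_run_count(cs, ce)
        }
      }
    }
  }
  list(broad_score = n_broad / model$total_arms,
       focal_score = n_focal / model$total_genes,
       n_broad = n_broad, n_focal = n_focal)
}

# random raw segment table over a model's genome
random_segment_table <- function(model, n_segments, n_samples = 3) {
  arm <- model$arms[sample.int(nrow(model$arms), n_segments,
                               replace = TRUE), ]
  alen <- arm$end - arm$start
  frac <- runif(n_segments)^0.5  # favor longer segments so broads occur
  len <- pmax(1, floor(alen * frac))
  start <- arm$start + floor(runif(n_segments) * (alen - len + 1))
  data.frame(
    sample = paste0("s", sample.int(n_samples, n_segments, replace = TRUE)),
    chrom = arm$chrom,
    start = start, end = start + len,
    value = round(runif(n_segments, -1, 1), 3),
    stringsAsFactors = FALSE
  )
}

# Benjamini-Hochberg step-up by its textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  # q_(i) = min_{j >= i} m * p_(j) / j
  ps <- p[o]
  qs <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, m * ps[i] / i)
    qs[i] <- min(running_min, 1)
  }
  q[o] <- qs
  q
}

# Exhaustive max-deviation scan of the KS running sum (equal weights):
# recompute the prefix sums position by position without cumsum, track
# the signed maximum deviation.
oracle_es <- function(ranked_genes, geneset) {
  n <- length(ranked_genes)
  hits <- ranked_genes %in% geneset
  k <- sum(hits)
  stopifnot(k > 0, k < n)
  value <- 0
  best <- 0
  for (i in seq_len(n)) {
    value <- value + if (hits[i]) 1 / k else -1 / (n - k)
    if (abs(value) > abs(best)) best <- value
  }
  best
}

# all-pairs Mann-Whitney AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  labels <- factor(labels)
  pos <- levels(labels)[2]
  sp <- scores[labels == pos]
  sn <- scores[labels != pos]
  total <- 0
  for (p in sp) {
    for (q in sn) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(sp) * length(sn))
}

# small helper: planted two-group log2 expression matrix
make_two_group_matrix <- function(n_genes, n_per_group, n_deg = 0,
                                  effect = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n_genes * n, mean = 5, sd = sd), n_genes, n)
  rownames(x) <- sprintf("g%04d", seq_len(n_genes))
  colnames(x) <- sprintf("s%03d", seq_len(n))
  if (n_deg > 0) {
    x[seq_len(n_deg), seq_len(n_per_group)] <-
      x[seq_len(n_deg), seq_len(n_per_group)] + effect
  }
  list(x = x,
       contrast = cinscore::group_contrast(
         colnames(x)[seq_len(n_per_group)],
         colnames(x)[n_per_group + seq_len(n_per_group)]),
       deg_genes = rownames(x)[seq_len(n_deg)])
}
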