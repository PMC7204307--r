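#' Simulation configuration for a synthetic CIN cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: each sample carries a latent chromosomal-instability (CIN)
#' level that jointly drives (i) the per-arm probability of a broad
#' copy-number event, (ii) up-regulation of a planted signature gene set,
#' and (iii) the nonsynonymous mutation count. Stage classes follow the
#' M-stage nomenclature (M0-NM, M0-oligo, M0-poly, M1-oligo, M1-poly) with
#' higher mean CIN in M1 groups, and the latent CIN of M1 samples is a
#' two-component normal mixture so the M1 population is bimodal.
#'
#' @param n_samples_per_group integer, or named integer vector over stage
#'   classes; samples per group.
#' @param n_genes number of genes in the expression matrix and catalog.
#' @param n_signature_genes number of planted CIN-responsive genes.
#' @param cin_effect expression shift (log2 units) per unit latent CIN on
#'   the planted signature genes.
#' @param group_cin_means named numeric vector: latent CIN mean per stage
#'   class. Classes whose name starts with "M1" use the bimodal mixture.
#' @param m1_bimodal_weight fraction of M1 samples drawn from the low-CIN
#'   mixture component.
#' @param m1_low_mode_mean latent CIN mean of the low component of the M1
#'   mixture (default: the smallest non-M1 group mean).
#' @param cin_sd standard deviation of latent CIN within a component.
#' @param arms even number of chromosome arms in the toy genome.
#' @param arm_length_bp arm length in base pairs.
#' @param broad_rate_slope per-arm broad-event probability per unit latent
#'   CIN (clipped to `[0, 1]`).
#' @param focal_rate Poisson mean of the per-sample focal event count.
#' @param dispersion negative-binomial dispersion of the counts (so the
#'   count variance is `mu + dispersion * mu^2`).
#' @param mutation_base,mutation_slope nonsynonymous mutation counts are
#'   Poisson with mean `mutation_base * exp(mutation_slope * cin)`.
#' @param fusion_types_total number of distinct fusion types assayed
#'   (denominator of the fusion score); the source assay tracked three.
#' @param seed integer master seed; per-sample sub-seeds are derived from
#'   it deterministically.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_samples_per_group = 20L,
                              n_genes = 2000L,
                              n_signature_genes = 70L,
                              cin_effect = 1,
                              group_cin_means = c("M0-NM" = 0.2,
                                                  "M0-oligo" = 0.4,
                                                  "M0-poly" = 0.6,
                                                  "M1-oligo" = 0.9,
                                                  "M1-poly" = 1.2),
                              m1_bimodal_weight = 1 / 3,
                              m1_low_mode_mean = NULL,
                              cin_sd = 0.25,
                              arms = 46L,
                              arm_length_bp = 1e6,
                              broad_rate_slope = 0.3,
                              focal_rate = 3,
                              dispersion = 0.1,
                              mutation_base = 30,
                              mutation_slope = 0.5,
                              fusion_types_total = 3L,
                              seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 2)
  n_signature_genes <- check_count(n_signature_genes, "n_signature_genes",
                                   min = 1)
  if (n_signature_genes > n_genes) {
    stopf("`n_signature_genes` must not exceed `n_genes`")
  }
  check_number(cin_effect, "cin_effect", min = 0)
  check_number(m1_bimodal_weight, "m1_bimodal_weight", min = 0, max = 1)
  check_number(cin_sd, "cin_sd", min = 0)
  arms <- check_count(arms, "arms", min = 2)
  if (arms %% 2L != 0L) stopf("`arms` must be even")
  check_count(arm_length_bp, "arm_length_bp", min = 1)
  check_number(broad_rate_slope, "broad_rate_slope")
  check_number(focal_rate, "focal_rate", min = 0)
  check_number(dispersion, "dispersion", min = 1e-12)
  check_number(mutation_base, "mutation_base", min = 0)
  check_number(mutation_slope, "mutation_slope")
  fusion_types_total <- check_count(fusion_types_total,
                                    "fusion_types_total", min = 1)
  if (is.null(names(group_cin_means)) || anyDuplicated(names(group_cin_means))) {
    stopf("`group_cin_means` must be a uniquely named numeric vector")
  }
  groups <- names(group_cin_means)
  if (length(n_samples_per_group) == 1L && is.null(names(n_samples_per_group))) {
    n_samples_per_group <- setNames(rep(as.integer(n_samples_per_group),
                                        length(groups)), groups)
  }
  if (!all(groups %in% names(n_samples_per_group))) {
    stopf("`n_samples_per_group` missing stage classes: %s",
          paste(setdiff(groups, names(n_samples_per_group)), collapse = ", "))
  }
  n_samples_per_group <- n_samples_per_group[groups]
  if (any(n_samples_per_group < 1) ||
      any(n_samples_per_group != round(n_samples_per_group))) {
    stopf("all group sample sizes must be positive integers")
  }
  if (is.null(m1_low_mode_mean)) {
    non_m1 <- group_cin_means[!startsWith(groups, "M1")]
    m1_low_mode_mean <- if (length(non_m1)) min(non_m1) else
      min(group_cin_means)
  }
  structure(
    list(n_samples_per_group = as.integer(n_samples_per_group),
         n_genes = n_genes, n_signature_genes = n_signature_genes,
         cin_effect = as.double(cin_effect),
         group_cin_means = group_cin_means,
         m1_bimodal_weight = as.double(m1_bimodal_weight),
         m1_low_mode_mean = as.double(m1_low_mode_mean),
         cin_sd = as.double(cin_sd),
         arms = arms, arm_length_bp = as.integer(arm_length_bp),
         broad_rate_slope = as.double(broad_rate_slope),
         focal_rate = as.double(focal_rate),
         dispersion = as.double(dispersion),
         mutation_base = as.double(mutation_base),
         mutation_slope = as.double(mutation_slope),
         fusion_types_total = fusion_types_total,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a synthetic multi-group CIN cohort
#'
#' Draws a full cohort from a [simulation_config()]: latent CIN per sample
#' (bimodal within M1 classes), copy-number segments (broad events cover
#' 99\% of their arm and focal events at most 10\%, so class membership
#' under the 98\% rule is unambiguous), negative-binomial expression counts
#' with the planted signature genes shifted by `cin_effect * cin`, and
#' mutation/fusion counts. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#'
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `expression` (integer count matrix, genes x samples), `segments`
#'   (SEG-style data.frame: `sample`, `chrom`, `start`, `end`, `value`),
#'   `annotations` (per-sample data.frame with `sample`, `group`,
#'   `latent_cin`, `nonsyn_mutations`, `fusion_events`,
#'   `fusion_types_total`, `cin_mode` — which mixture component the
#'   latent CIN was drawn from — `msi`, `bcr`, `crpc`, `death`), `arm_model`,
#'   and `truth` (planted signature genes and their per-unit-CIN log2
#'   effect).
#' @examples
#' coh <- generate_cohort(simulation_config(
#'   n_samples_per_group = 5, n_genes = 200, n_signature_genes = 20,
#'   arms = 4, seed = 42))
#' dim(coh$expression)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stopf("`config` must be a simulation_config")
  }
  cfg <- config
  groups <- names(cfg$group_cin_means)
  model <- generate_arm_model(arms = cfg$arms,
                              arm_length_bp = cfg$arm_length_bp,
                              n_genes = cfg$n_genes,
                              seed = derive_seed(cfg$seed, 0L))

  n_total <- sum(cfg$n_samples_per_group)
  group_of <- rep(groups, times = cfg$n_samples_per_group)
  sample_id <- sprintf("S%03d", seq_len(n_total))

  # cohort-level draws: gene baselines and planted signature membership
  cohort_draws <- with_seed(derive_seed(cfg$seed, 1L), {
    list(base_log2 = runif(cfg$n_genes, 3, 8),
         sig_idx = sort(sample.int(cfg$n_genes, cfg$n_signature_genes)),
         lib_factor = exp(rnorm(n_total, 0, 0.2)))
  })
  base_log2 <- cohort_draws$base_log2
  sig_idx <- cohort_draws$sig_idx
  lib_factor <- cohort_draws$lib_factor

  arm_df <- model$arms
  n_arms <- nrow(arm_df)
  arm_len <- arm_df$end - arm_df$start

  expr <- matrix(0L, nrow = cfg$n_genes, ncol = n_total,
                 dimnames = list(model$genes$gene_id, sample_id))
  seg_list <- vector("list", n_total)
  ann <- data.frame(sample = sample_id, group = group_of,
                    latent_cin = NA_real_,
                    nonsyn_mutations = NA_integer_,
                    fusion_events = NA_integer_,
                    fusion_types_total = cfg$fusion_types_total,
                    cin_mode = NA_character_,
                    msi = NA_real_, bcr = NA_integer_,
                    crpc = NA_integer_, death = NA_integer_,
                    stringsAsFactors = FALSE)

  for (i in seq_len(n_total)) {
    g <- group_of[i]
    draws <- with_seed(derive_seed(cfg$seed, 1000L + i), {
      # latent CIN: two-component normal mixture within M1 classes
      if (startsWith(g, "M1") && runif(1) < cfg$m1_bimodal_weight) {
        mu <- cfg$m1_low_mode_mean
        low_mode <- TRUE
      } else {
        mu <- cfg$group_cin_means[[g]]
        low_mode <- FALSE
      }
      cin <- rnorm(1, mu, cfg$cin_sd)
      p_broad <- min(max(cfg$broad_rate_slope * cin, 0), 1)
      broad_arm <- which(rbinom(n_arms, 1L, p_broad) == 1L)
      broad_dir <- sample(c(1, -1), length(broad_arm), replace = TRUE)
      broad_mag <- runif(length(broad_arm), 0.35, 1)
      n_focal <- rpois(1, cfg$focal_rate)
      free_arms <- setdiff(seq_len(n_arms), broad_arm)
      n_focal <- min(n_focal, length(free_arms))
      focal_arm <- if (n_focal > 0) {
        sample(free_arms, n_focal, replace = FALSE)
      } else integer(0)
      focal_frac <- runif(n_focal, 0.01, 0.10)
      focal_dir <- sample(c(1, -1), n_focal, replace = TRUE)
      focal_mag <- runif(n_focal, 0.35, 1)
      focal_off <- runif(n_focal)
      mu_log2 <- base_log2
      mu_log2[sig_idx] <- mu_log2[sig_idx] + cfg$cin_effect * cin
      counts <- rnbinom(cfg$n_genes,
                        mu = (2^mu_log2) * lib_factor[i],
                        size = 1 / cfg$dispersion)
      nonsyn <- rpois(1, cfg$mutation_base * exp(cfg$mutation_slope * cin))
      fus <- rpois(1, max(0.2, 1 + cin))
      msi <- runif(1, 0, 0.4)  # MANTIS-like passthrough, unrelated to CIN
      risk <- 1 / (1 + exp(-(cin - 1)))
      flags <- rbinom(3, 1, risk)
      list(cin = cin, low_mode = low_mode,
           broad_arm = broad_arm, broad_dir = broad_dir,
           broad_mag = broad_mag,
           focal_arm = focal_arm, focal_frac = focal_frac,
           focal_dir = focal_dir, focal_mag = focal_mag,
           focal_off = focal_off,
           counts = counts, nonsyn = nonsyn, fus = fus, msi = msi,
           flags = flags)
    })

    # broad segments cover 99% of the arm, centered
    segs <- NULL
    if (length(draws$broad_arm)) {
      a <- draws$broad_arm
      pad <- floor(arm_len[a] * 0.005)
      segs <- data.frame(
        sample = sample_id[i], chrom = arm_df$chrom[a],
        start = arm_df$start[a] + pad,
        end = arm_df$start[a] + pad + ceiling(arm_len[a] * 0.99),
        value = draws$broad_dir * draws$broad_mag,
        stringsAsFactors = FALSE
      )
    }
    if (length(draws$focal_arm)) {
      a <- draws$focal_arm
      flen <- pmax(1, floor(arm_len[a] * draws$focal_frac))
      fstart <- arm_df$start[a] +
        floor(draws$focal_off * (arm_len[a] - flen))
      fseg <- data.frame(
        sample = sample_id[i], chrom = arm_df$chrom[a],
        start = fstart, end = fstart + flen,
        value = draws$focal_dir * draws$focal_mag,
        stringsAsFactors = FALSE
      )
      segs <- rbind(segs, fseg)
    }
    seg_list[[i]] <- segs
    expr[, i] <- as.integer(draws$counts)
    ann$latent_cin[i] <- draws$cin
    ann$cin_mode[i] <- if (draws$low_mode) "low" else "high"
    ann$nonsyn_mutations[i] <- draws$nonsyn
    ann$fusion_events[i] <- draws$fus
    ann$msi[i] <- draws$msi
    ann$bcr[i] <- draws$flags[1]
    ann$crpc[i] <- draws$flags[2]
    ann$death[i] <- draws$flags[3]
  }

  segments <- do.call(rbind, seg_list[!vapply(seg_list, is.null, logical(1))])
  if (is.null(segments)) {
    segments <- data.frame(sample = character(), chrom = character(),
                           start = integer(), end = integer(),
                           value = double(), stringsAsFactors = FALSE)
  }
  rownames(segments) <- NULL

  truth <- data.frame(gene_id = model$genes$gene_id[sig_idx],
                      log2_effect_per_unit_cin = cfg$cin_effect,
                      stringsAsFactors = FALSE)

  structure(
    list(expression = expr, segments = segments, annotations = ann,
         arm_model = model, truth = truth, config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", ncol(x$expression), " samples, ",
      nrow(x$expression), " genes, ", nrow(x$segments),
      " CNA segments\n", sep = "")
  print(table(x$annotations$group))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the count matrix (TSV, gene rows x sample columns), segments
#' (SEG-style TSV, 0-based half-open), annotations, arm model (BED-like
#' TSV plus gene catalog TSV) and the planted-truth table into `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The output paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  counts <- data.frame(gene_id = rownames(cohort$expression),
                       cohort$expression, check.names = FALSE)
  write.table(counts, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$segments, p("segments.seg"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$annotations, p("annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_arm_model(cohort$arm_model, p("arms.bed.tsv"), p("genes.tsv"))
  write.table(cohort$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(vapply(c("counts.tsv", "segments.seg", "annotations.tsv",
                     "arms.bed.tsv", "genes.tsv", "truth.tsv"), p,
                   character(1)))
}
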