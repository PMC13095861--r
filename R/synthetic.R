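# Synthetic study generator: genotypes under HWE with planted joint sources,
# state-switching ICN time courses whose windowed connectivity clusters into
# K planted states, covariates, and a recoverable ground truth.

#' Define a synthetic study design
#'
#' Collects the dimensions and effect parameters of a synthetic
#' genotype + dFNC study. All downstream generators are deterministic
#' functions of this design (every random draw flows from `seed` through
#' a counter-based substream per subject).
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs.
#' @param n_icns number of intrinsic connectivity networks.
#' @param n_timepoints fMRI time points per subject.
#' @param tr_seconds repetition time in seconds.
#' @param k_states number of planted connectivity states (>= 2).
#' @param n_components number of planted joint sources (< n_subjects).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param snr planted-signal variance / noise variance per feature for the
#'   continuous joint data and the genotype liability.
#' @param dwell_mean mean dwell time of a state visit, in TRs.
#' @param effect_components component indices receiving a case-control
#'   loading shift.
#' @param effect_size standardized mean loading difference (cases - controls).
#' @param seed integer master seed.
#' @return object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_subjects = 200, n_snps = 300, n_icns = 10,
                             n_timepoints = 400, tr_seconds = 0.735,
                             k_states = 4, n_components = 5,
                             maf_range = c(0.05, 0.5), snr = 2,
                             dwell_mean = 50, effect_components = integer(0),
                             effect_size = 0, seed = 1) {
  if (k_states < 2) stop("k_states must be >= 2")
  if (n_components >= n_subjects) stop("n_components must be < n_subjects")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (length(effect_components) && any(effect_components > n_components))
    stop("all effect_components must be <= n_components")
  if (snr <= 0 || dwell_mean <= 0 || tr_seconds <= 0)
    stop("snr, dwell_mean and tr_seconds must be positive")
  structure(list(
    n_subjects = n_subjects, n_snps = n_snps, n_icns = n_icns,
    n_timepoints = n_timepoints, tr_seconds = tr_seconds,
    k_states = k_states, n_components = n_components,
    maf_range = maf_range, snr = snr, dwell_mean = dwell_mean,
    effect_components = as.integer(effect_components),
    effect_size = effect_size, seed = as.integer(seed),
    n_pairs = n_fnc_pairs(n_icns)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic dynamic-fusion design\n")
  cat(sprintf("  %d subjects, %d SNPs, %d ICNs (%d pairs), %d time points (TR %.3f s)\n",
              x$n_subjects, x$n_snps, x$n_icns, x$n_pairs, x$n_timepoints,
              x$tr_seconds))
  cat(sprintf("  %d planted states (mean dwell %d TRs), %d joint components, SNR %.2f\n",
              x$k_states, x$dwell_mean, x$n_components, x$snr))
  if (length(x$effect_components))
    cat(sprintf("  case-control shift %.2f SD on component(s) %s\n",
                x$effect_size, paste(x$effect_components, collapse = ", ")))
  invisible(x)
}

# Laplace draws: difference of exponentials has density (1/2) exp(-|x|),
# variance 2; scaled to unit variance. Positive excess kurtosis (3), the
# super-Gaussian family Infomax extracts.
rlaplace_unit <- function(n) (rexp(n) - rexp(n)) / sqrt(2)

#' Generate the planted ground truth for a design
#'
#' Draws super-Gaussian joint sources (sparse Laplace rows over the
#' concatenated SNP + connectivity-pair feature space), Gaussian subject
#' loadings with the designed case-control shift, factor-structured state
#' centroid correlation patterns, and per-subject Markov state sequences.
#'
#' @param design a [synthetic_design()].
#' @param template optional `ground_truth` of a previously generated cohort
#'   (same n_snps, n_icns, k_states, n_components): its sources and state
#'   centroids are reused so the new cohort samples fresh subjects from the
#'   same population, as an independent validation cohort does.
#' @return object of class `ground_truth` with elements `sources`
#'   (n_components x (n_snps + n_pairs)), `loadings`
#'   (n_subjects x n_components), `state_centroids` (k_states x n_pairs,
#'   correlation units), `state_sequence` (list of integer vectors),
#'   `diagnosis` (0 control / 1 case), `snp_active` (logical, SNPs carrying
#'   any planted weight) and bookkeeping ids.
#' @export
generate_ground_truth <- function(design, template = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  d <- design
  subj_ids <- sprintf("S%04d", seq_len(d$n_subjects))
  snp_ids <- if (d$n_snps > 0) sprintf("rs%06d", seq_len(d$n_snps)) else character(0)

  if (!is.null(template)) {
    td <- template$design
    if (td$n_snps != d$n_snps || td$n_icns != d$n_icns ||
        td$k_states != d$k_states || td$n_components != d$n_components)
      stop("template ground truth has incompatible dimensions")
  }
  truth <- with_substream(d$seed, 0L, {
    if (is.null(template)) {
      # Sparse Laplace sources: zeroed entries sharpen the peak (excess
      # kurtosis 6/p - 3 > 0), and all-zero columns give genuinely null SNPs.
      src_snp <- matrix(rlaplace_unit(d$n_components * d$n_snps) *
                          rbinom(d$n_components * d$n_snps, 1, 0.3),
                        d$n_components, d$n_snps)
      src_dfnc <- matrix(rlaplace_unit(d$n_components * d$n_pairs) *
                           rbinom(d$n_components * d$n_pairs, 1, 0.5),
                         d$n_components, d$n_pairs)
      sources <- cbind(src_snp, src_dfnc)
      # Two-factor structured correlation per state; factor scale 1.3 gives
      # typical |r| around 0.3-0.5, well separated between states relative
      # to windowed-estimation noise.
      centroids <- matrix(0, d$k_states, d$n_pairs)
      for (k in seq_len(d$k_states)) {
        B <- matrix(1.3 * rnorm(d$n_icns * 2), d$n_icns, 2)
        S <- tcrossprod(B) + diag(d$n_icns)
        centroids[k, ] <- matrix_to_pairs(stats::cov2cor(S))
      }
    } else {
      sources <- template$sources
      src_snp <- sources[, seq_len(d$n_snps), drop = FALSE]
      centroids <- template$state_centroids
    }

    loadings <- matrix(rnorm(d$n_subjects * d$n_components),
                       d$n_subjects, d$n_components)
    diagnosis <- rep(c(0L, 1L), length.out = d$n_subjects)
    if (length(d$effect_components) && d$effect_size != 0)
      loadings[diagnosis == 1L, d$effect_components] <-
        loadings[diagnosis == 1L, d$effect_components] + d$effect_size

    list(sources = sources, loadings = loadings, diagnosis = diagnosis,
         state_centroids = centroids,
         snp_active = colSums(abs(src_snp)) > 0)
  })

  # Markov state sequences per subject: stay probability 1 - 1/dwell_mean,
  # uniform off-diagonal transitions, uniform initial state.
  p_stay <- max(0, 1 - 1 / d$dwell_mean)
  truth$state_sequence <- lapply(seq_len(d$n_subjects), function(i) {
    with_substream(d$seed, i, {
      s <- integer(d$n_timepoints)
      s[1] <- sample.int(d$k_states, 1)
      if (d$n_timepoints > 1) {
        u <- runif(d$n_timepoints - 1)
        jump <- sample.int(d$k_states - 1, d$n_timepoints - 1, replace = TRUE)
        for (t in 2:d$n_timepoints) {
          if (u[t - 1] < p_stay) s[t] <- s[t - 1]
          else s[t] <- ((s[t - 1] - 1 + jump[t - 1]) %% d$k_states) + 1
        }
      }
      s
    })
  })
  truth$subject_ids <- subj_ids
  truth$snp_ids <- snp_ids
  truth$design <- d
  class(truth) <- "ground_truth"
  truth
}

#' Generate a genotype dosage matrix with planted joint structure
#'
#' Builds a continuous liability `loadings %*% sources_snp + noise` (noise
#' variance set by the design SNR) and discretizes each SNP by per-SNP
#' quantile cuts at the Hardy-Weinberg genotype proportions `(1-maf)^2` and
#' `(1-maf)^2 + 2 maf (1-maf)` of its liability distribution, so the minor
#' allele frequency is preserved by construction while the planted
#' loading-dosage correlation survives discretization.
#'
#' @param design a [synthetic_design()].
#' @param truth matching [generate_ground_truth()] output.
#' @return object of class `genotype_matrix`: list with `dosage`
#'   (subjects x SNPs, values 0/1/2 counting minor alleles), `subject_ids`,
#'   `snp_ids`, `maf` (target frequencies) and `alleles`.
#' @export
generate_genotypes <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"), inherits(truth, "ground_truth"))
  d <- design
  n <- d$n_subjects
  if (d$n_snps == 0) {
    return(structure(list(
      dosage = matrix(integer(0), n, 0, dimnames = list(truth$subject_ids, NULL)),
      subject_ids = truth$subject_ids, snp_ids = character(0),
      maf = numeric(0), alleles = data.frame()), class = "genotype_matrix"))
  }
  signal <- truth$loadings %*% truth$sources[, seq_len(d$n_snps), drop = FALSE]
  # Block-level noise scale: null SNPs stay purely stochastic.
  sig_var <- mean(apply(signal, 2, var))
  noise_sd <- sqrt(max(sig_var, .Machine$double.eps) / d$snr)
  out <- with_substream(d$seed, 1048576L, {
    liability <- signal + matrix(rnorm(n * d$n_snps, sd = noise_sd), n, d$n_snps)
    maf <- runif(d$n_snps, d$maf_range[1], d$maf_range[2])
    dosage <- matrix(0L, n, d$n_snps,
                     dimnames = list(truth$subject_ids, truth$snp_ids))
    for (j in seq_len(d$n_snps)) {
      p0 <- (1 - maf[j])^2
      p1 <- 2 * maf[j] * (1 - maf[j])
      cuts <- quantile(liability[, j], c(p0, p0 + p1), names = FALSE, type = 7)
      dosage[, j] <- (liability[, j] > cuts[1]) + (liability[, j] > cuts[2])
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, d$n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    list(dosage = dosage, maf = maf,
         alleles = data.frame(snp = truth$snp_ids, major = ref, minor = alt))
  })
  structure(list(dosage = out$dosage, subject_ids = truth$subject_ids,
                 snp_ids = truth$snp_ids, maf = out$maf, alleles = out$alleles),
            class = "genotype_matrix")
}

# Per-pair standard deviation (correlation units) of the subject-specific
# sa-dFNC perturbation added to the state centroids. A generator convention
# (see the methods vignette), not a design dial.
.dfnc_perturbation_sd <- 0.08

#' Generate state-switching ICN time courses
#'
#' Each subject follows its planted Markov state sequence; within a state,
#' time points are drawn from a zero-mean multivariate normal whose
#' correlation matrix is that state's centroid plus a subject-specific
#' perturbation proportional to `loadings %*% sources_dfnc` (the planted
#' sa-dFNC signal), repaired to positive definiteness by eigenvalue
#' clipping and re-normalization to unit diagonal.
#'
#' @param design a [synthetic_design()].
#' @param truth matching [generate_ground_truth()] output.
#' @return named list of `n_timepoints x n_icns` matrices, one per subject.
#' @export
generate_timecourses <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"), inherits(truth, "ground_truth"))
  d <- design
  src_dfnc <- truth$sources[, d$n_snps + seq_len(d$n_pairs), drop = FALSE]
  pert <- truth$loadings %*% src_dfnc
  psd <- sqrt(mean(apply(pert, 2, var)))
  if (psd > 0) pert <- pert * (.dfnc_perturbation_sd / psd)

  tcs <- lapply(seq_len(d$n_subjects), function(i) {
    seqs <- truth$state_sequence[[i]]
    # Subject-and-state correlation matrices, repaired and factorized once.
    chols <- lapply(seq_len(d$k_states), function(k) {
      R <- pairs_to_matrix(truth$state_centroids[k, ] + pert[i, ], d$n_icns)
      R <- nearest_pd_corr(R)
      ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min < 1e-8)
        stop(sprintf("state %d: correlation matrix not repairable for subject %d", k, i))
      chol(R)
    })
    with_substream(d$seed, 524288L + i, {
      Z <- matrix(rnorm(d$n_timepoints * d$n_icns), d$n_timepoints, d$n_icns)
      tc <- matrix(0, d$n_timepoints, d$n_icns)
      for (k in unique(seqs)) {
        rows <- which(seqs == k)
        tc[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[k]]
      }
      colnames(tc) <- sprintf("ICN%02d", seq_len(d$n_icns))
      tc
    })
  })
  names(tcs) <- truth$subject_ids
  tcs
}

#' Continuous joint data matrix implied by the planted model
#'
#' Returns `X = loadings %*% sources + noise` with per-block noise variance
#' set so the block-average signal-to-noise ratio equals the design SNR.
#' This is the latent joint matrix underlying genotype discretization and
#' time-course synthesis; source-recovery checks of the ICA engine run on it.
#'
#' @param design a [synthetic_design()].
#' @param truth matching [generate_ground_truth()] output.
#' @param noise_seed_offset substream offset for the noise draw, so several
#'   noisy replicates can be generated from one truth.
#' @return list with `X` (subjects x (n_snps + n_pairs)), `p_snp`, `p_dfnc`.
#' @export
synthetic_joint_data <- function(design, truth, noise_seed_offset = 0L) {
  stopifnot(inherits(design, "synthetic_design"), inherits(truth, "ground_truth"))
  d <- design
  signal <- truth$loadings %*% truth$sources
  blocks <- list(seq_len(d$n_snps), d$n_snps + seq_len(d$n_pairs))
  X <- with_substream(d$seed, 262144L + noise_seed_offset, {
    E <- matrix(rnorm(length(signal)), nrow(signal), ncol(signal))
    for (b in blocks) {
      if (!length(b)) next
      sv <- mean(apply(signal[, b, drop = FALSE], 2, var))
      E[, b] <- E[, b] * sqrt(max(sv, .Machine$double.eps) / d$snr)
    }
    signal + E
  })
  rownames(X) <- truth$subject_ids
  list(X = X, p_snp = d$n_snps, p_dfnc = d$n_pairs)
}

#' Generate the covariate table
#'
#' Age, sex, site, mean framewise displacement, diagnosis, seven synthetic
#' cognitive scores and two symptom scores. Cognitive and symptom scores are
#' weak linear functions of the planted loadings (plus noise) so that the
#' association stage has a recoverable signal; demographic covariates are
#' independent of the planted structure.
#'
#' @param design a [synthetic_design()].
#' @param truth matching [generate_ground_truth()] output.
#' @return data.frame keyed by `subject`.
#' @export
generate_covariates <- function(design, truth) {
  d <- design
  n <- d$n_subjects
  with_substream(d$seed, 2097152L, {
    comp <- if (length(d$effect_components)) d$effect_components[1] else 1L
    base <- truth$loadings[, comp]
    cog <- sapply(seq_len(7), function(j) 0.3 * base + rnorm(n))
    colnames(cog) <- c("cog_composite", "cog_speed", "cog_attention",
                       "cog_working_memory", "cog_verbal", "cog_visual",
                       "cog_reasoning")
    sym <- sapply(seq_len(2), function(j) -0.3 * base + rnorm(n))
    colnames(sym) <- c("panss_pos", "panss_neg")
    df <- data.frame(
      subject = truth$subject_ids,
      age = round(rnorm(n, 55, 8), 1),
      sex = sample(c(0L, 1L), n, replace = TRUE),
      site = sample(paste0("site", 1:3), n, replace = TRUE),
      mean_fd = round(exp(rnorm(n, -1.6, 0.4)), 4),
      diagnosis = truth$diagnosis)
    cbind(df, round(cog, 4), round(sym, 4))
  })
}

#' Write a complete fixture bundle to disk
#'
#' Writes the genotype table, one time-course TSV per subject, the covariate
#' table, ICN labels with functional domains, a SNP-to-gene annotation map,
#' a ground-truth archive (RDS) and a checksummed manifest.
#'
#' @param design a [synthetic_design()].
#' @param truth optional precomputed [generate_ground_truth()]; regenerated
#'   from the design when `NULL`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
write_fixture_bundle <- function(design, truth = NULL, outdir) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.null(truth)) truth <- generate_ground_truth(design)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)

  geno <- generate_genotypes(design, truth)
  gdf <- data.frame(subject = geno$subject_ids, geno$dosage,
                    check.names = FALSE, row.names = NULL)
  tsv(gdf, "genotypes.tsv")

  tcs <- generate_timecourses(design, truth)
  dir.create(file.path(outdir, "timecourses"), showWarnings = FALSE)
  for (id in names(tcs))
    write.table(round(tcs[[id]], 6), file.path(outdir, "timecourses", paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  tsv(generate_covariates(design, truth), "covariates.tsv")

  domains <- c("SC", "AUD", "SM", "VIS", "CC", "DMN", "CB")
  icns <- data.frame(index = seq_len(design$n_icns),
                     label = sprintf("ICN%02d", seq_len(design$n_icns)),
                     domain = rep(domains, length.out = design$n_icns))
  tsv(icns, "icn_labels.tsv")

  if (design$n_snps > 0) {
    ann <- with_substream(design$seed, 3145728L, {
      chr <- sort(sample(1:22, design$n_snps, replace = TRUE))
      data.frame(snp = truth$snp_ids, chromosome = chr,
                 position = as.integer(1e5 + seq_len(design$n_snps) * 937),
                 gene = sprintf("GENE%03d", ceiling(seq_len(design$n_snps) / 3)))
    })
  } else ann <- data.frame(snp = character(), chromosome = integer(),
                           position = integer(), gene = character())
  tsv(ann, "snp_annotation.tsv")

  saveRDS(truth, file.path(outdir, "ground_truth.rds"))
  writeLines(c(sprintf("n_subjects\t%d", design$n_subjects),
               sprintf("n_snps\t%d", design$n_snps),
               sprintf("n_icns\t%d", design$n_icns),
               sprintf("n_timepoints\t%d", design$n_timepoints),
               sprintf("tr_seconds\t%g", design$tr_seconds),
               sprintf("k_states\t%d", design$k_states),
               sprintf("seed\t%d", design$seed)),
             file.path(outdir, "design.tsv"))

  files <- c("genotypes.tsv", "covariates.tsv", "icn_labels.tsv",
             "snp_annotation.tsv", "ground_truth.rds", "design.tsv",
             file.path("timecourses", paste0(names(tcs), ".tsv")))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))))
  tsv(manifest, "manifest.tsv")
  invisible(manifest)
}
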