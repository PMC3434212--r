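# Synthetic bead-level cohorts and qPCR plates with known ground truth.

#' Simulation configuration
#'
#' Builds a validated configuration for [generate_cohort()] and
#' [generate_qpcr()]. Defaults emulate the study design the package targets:
#' 12 healthy controls and 18 patients sampled at baseline, of whom 12 are
#' resampled after short-term treatment; about half of the probes expressed
#' above the negative-control background; a modest number of differentially
#' expressed genes with linear fold changes between patients and controls in
#' `de_fc_range`; a dominant per-subject signature shared by a subject's
#' baseline and post-treatment samples; a minority of patients with extra
#' per-gene variance; and contamination-driven genes (haemoglobin analogues)
#' that respond deterministically to treatment.
#'
#' @param n_probes number of gene probes on the array.
#' @param n_neg_controls number of negative-control probes.
#' @param beads_per_probe beads per probe per array.
#' @param n_controls,n_patients,n_treated cohort sizes; the first `n_treated`
#'   patients contribute a paired post-treatment sample.
#' @param frac_expressed fraction of gene probes expressed above background.
#' @param n_de_genes number of genes shifted in patients relative to controls.
#' @param de_fc_range range (linear scale) of patient/control fold changes.
#' @param patient_effect_sd sd (log2) of the per-subject gene signature,
#'   identical at both timepoints of a subject.
#' @param treatment_effect_sd sd (log2) of the per-gene treatment shift.
#' @param n_heterogeneous_patients,hetero_extra_sd number of high-variance
#'   patients and the sd (log2) of their extra per-gene noise.
#' @param outlier_bead_rate fraction of beads hit by a gross multiplicative
#'   error (factor 4 or 1/4).
#' @param measurement_sd per-bead measurement noise sd (log2).
#' @param contamination_gene_ids probe ids receiving a fixed +log2(1.5)
#'   post-treatment shift; `NULL` picks the first two expressed probes.
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @param background_log2 log2 level of the negative-control background.
#' @param expressed_log2_range range of baseline log2 levels for expressed
#'   genes.
#' @param qpcr_n_targets number of differentially expressed genes carried into
#'   the simulated qPCR plate.
#' @param qpcr_replicate_sd replicate-to-replicate Ct noise sd (cycles).
#' @param qpcr_bio_sd per-sample biological Ct noise sd (cycles).
#' @param qpcr_sample_offset_sd sd of the per-sample global Ct offset
#'   (loading/pipetting), shared by all genes of a sample.
#' @param qpcr_fail_rate probability that a replicate fails amplification-curve
#'   QC (quality score drawn below 0.65).
#' @param qpcr_hk_sd_scale multiplier on the housekeeping panel's designed
#'   per-sample noise sds (set 0 for a noise-free panel).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000, n_neg_controls = 100,
                       beads_per_probe = 30, n_controls = 12,
                       n_patients = 18, n_treated = 12,
                       frac_expressed = 0.5, n_de_genes = 100,
                       de_fc_range = c(0.3, 1.7), patient_effect_sd = 0.3,
                       treatment_effect_sd = 0.1,
                       n_heterogeneous_patients = 4, hetero_extra_sd = 0.5,
                       outlier_bead_rate = 0.02, measurement_sd = 0.25,
                       contamination_gene_ids = NULL, rng_seed = 1L,
                       background_log2 = 5,
                       expressed_log2_range = c(6.5, 12),
                       qpcr_n_targets = 5, qpcr_replicate_sd = 0.15,
                       qpcr_bio_sd = 0.2, qpcr_sample_offset_sd = 0.3,
                       qpcr_fail_rate = 0.05, qpcr_hk_sd_scale = 1) {
  cfg <- list(n_probes = n_probes, n_neg_controls = n_neg_controls,
              beads_per_probe = beads_per_probe, n_controls = n_controls,
              n_patients = n_patients, n_treated = n_treated,
              frac_expressed = frac_expressed, n_de_genes = n_de_genes,
              de_fc_range = de_fc_range, patient_effect_sd = patient_effect_sd,
              treatment_effect_sd = treatment_effect_sd,
              n_heterogeneous_patients = n_heterogeneous_patients,
              hetero_extra_sd = hetero_extra_sd,
              outlier_bead_rate = outlier_bead_rate,
              measurement_sd = measurement_sd,
              contamination_gene_ids = contamination_gene_ids,
              rng_seed = as.integer(rng_seed),
              background_log2 = background_log2,
              expressed_log2_range = expressed_log2_range,
              qpcr_n_targets = qpcr_n_targets,
              qpcr_replicate_sd = qpcr_replicate_sd,
              qpcr_bio_sd = qpcr_bio_sd,
              qpcr_sample_offset_sd = qpcr_sample_offset_sd,
              qpcr_fail_rate = qpcr_fail_rate,
              qpcr_hk_sd_scale = qpcr_hk_sd_scale)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", what,
                          call. = FALSE)
  }
  pos_count <- function(x) length(x) == 1 && is.finite(x) && x >= 1 &&
    x == round(x)
  count0 <- function(x) length(x) == 1 && is.finite(x) && x >= 0 &&
    x == round(x)
  chk(pos_count(cfg$n_probes), "n_probes", "must be a positive count")
  chk(pos_count(cfg$n_neg_controls), "n_neg_controls",
      "must be a positive count")
  chk(pos_count(cfg$beads_per_probe), "beads_per_probe",
      "must be a positive count")
  chk(count0(cfg$n_controls), "n_controls", "must be a nonnegative count")
  chk(count0(cfg$n_patients), "n_patients", "must be a nonnegative count")
  chk(count0(cfg$n_treated), "n_treated", "must be a nonnegative count")
  chk(cfg$n_treated <= cfg$n_patients, "n_treated",
      "must not exceed n_patients")
  chk(length(cfg$frac_expressed) == 1 && cfg$frac_expressed > 0 &&
        cfg$frac_expressed <= 1, "frac_expressed", "must be in (0, 1]")
  chk(count0(cfg$n_de_genes), "n_de_genes", "must be a nonnegative count")
  chk(cfg$n_de_genes <= cfg$n_probes, "n_de_genes",
      "must not exceed n_probes")
  chk(length(cfg$de_fc_range) == 2 && all(cfg$de_fc_range > 0) &&
        cfg$de_fc_range[1] <= cfg$de_fc_range[2], "de_fc_range",
      "must be an increasing pair of positive ratios")
  for (f in c("patient_effect_sd", "treatment_effect_sd", "hetero_extra_sd",
              "qpcr_replicate_sd", "qpcr_bio_sd", "qpcr_sample_offset_sd")) {
    chk(length(cfg[[f]]) == 1 && is.finite(cfg[[f]]) && cfg[[f]] >= 0, f,
        "must be a nonnegative sd")
  }
  chk(count0(cfg$n_heterogeneous_patients) &&
        cfg$n_heterogeneous_patients <= cfg$n_patients,
      "n_heterogeneous_patients", "must be a count <= n_patients")
  chk(length(cfg$outlier_bead_rate) == 1 && cfg$outlier_bead_rate >= 0 &&
        cfg$outlier_bead_rate < 1, "outlier_bead_rate",
      "must be a fraction in [0, 1)")
  chk(length(cfg$measurement_sd) == 1 && cfg$measurement_sd > 0,
      "measurement_sd", "must be a positive sd")
  chk(length(cfg$qpcr_fail_rate) == 1 && cfg$qpcr_fail_rate >= 0 &&
        cfg$qpcr_fail_rate <= 1, "qpcr_fail_rate", "must be in [0, 1]")
  chk(length(cfg$qpcr_hk_sd_scale) == 1 && cfg$qpcr_hk_sd_scale >= 0,
      "qpcr_hk_sd_scale", "must be a nonnegative multiplier")
  invisible(cfg)
}

#' Bead-level array container
#'
#' One sample's raw bead-level intensities grouped by probe. `beads` may be a
#' named list of per-probe intensity vectors (arbitrary bead counts) or, when
#' every probe carries the same number of beads, a numeric matrix with one
#' column per probe (column names are probe ids).
#'
#' @param sample_id sample identifier.
#' @param beads named list of positive numeric vectors, or a numeric matrix
#'   with probe ids as column names.
#' @param negative_control_ids probe ids of the negative controls; must be a
#'   subset of the probes present.
#' @return an object of class `bead_array`.
#' @export
bead_array <- function(sample_id, beads, negative_control_ids) {
  if (is.matrix(beads)) {
    if (is.null(colnames(beads))) stop("bead matrix must have probe ids as ",
                                       "column names")
    ids <- colnames(beads)
  } else if (is.list(beads)) {
    if (is.null(names(beads))) stop("bead list must be named by probe id")
    if (any(lengths(beads) < 1)) stop("every probe needs at least one bead")
    ids <- names(beads)
  } else stop("beads must be a named list or a matrix")
  if (anyDuplicated(ids)) stop("duplicated probe ids in bead data")
  missing_nc <- setdiff(negative_control_ids, ids)
  if (length(missing_nc)) {
    stop("negative-control ids absent from bead data: ",
         paste(utils::head(missing_nc, 5), collapse = ", "))
  }
  structure(list(sample_id = sample_id, beads = beads,
                 negative_control_ids = negative_control_ids),
            class = "bead_array")
}

#' @export
print.bead_array <- function(x, ...) {
  n <- if (is.matrix(x$beads)) ncol(x$beads) else length(x$beads)
  nb <- if (is.matrix(x$beads)) nrow(x$beads) * ncol(x$beads) else
    sum(lengths(x$beads))
  cat("bead_array '", x$sample_id, "': ", n, " probes (",
      length(x$negative_control_ids), " negative controls), ", nb,
      " beads\n", sep = "")
  invisible(x)
}

probe_ids <- function(ba) {
  if (is.matrix(ba$beads)) colnames(ba$beads) else names(ba$beads)
}

# sub-seeds drawn from the master stream keep per-sample generation
# reproducible and independent of how many samples precede it
draw_subseeds <- function(n) sample.int(2147483646L, n)

#' Generate a synthetic bead-level cohort
#'
#' Simulates one bead array per sample under a log-normal intensity model:
#' each gene has a baseline log2 level (expressed genes high, non-expressed
#' genes at the negative-control background), differentially expressed genes
#' carry a patient-group shift, every subject has a gene-wise random signature
#' shared by both timepoints, treated samples receive a per-gene treatment
#' shift (deterministic +log2(1.5) for contamination genes), heterogeneous
#' patients get extra per-gene noise, and bead intensities are
#' `2^(level + noise)` with a fraction of beads hit by a gross x4 or x1/4
#' error. Negative-control probes are drawn from the background distribution.
#'
#' @param config a [sim_config()].
#' @return a list with components `arrays` (list of [bead_array()]), `meta`
#'   (sample metadata data frame with columns sample_id, subject_id, group,
#'   timepoint, treated, crp) and `truth` (ground-truth list: `de_gene_ids`,
#'   `true_log2_fc`, `heterogeneous_patient_ids`, `expressed_gene_ids`,
#'   `treatment_responsive_ids`).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$rng_seed)

  gene_ids <- sprintf("P%05d", seq_len(cfg$n_probes))
  neg_ids <- sprintf("NEG%04d", seq_len(cfg$n_neg_controls))
  n_expr <- max(1L, round(cfg$frac_expressed * cfg$n_probes))
  expressed <- gene_ids[seq_len(n_expr)]

  mu <- rep(cfg$background_log2, cfg$n_probes)
  names(mu) <- gene_ids
  mu[expressed] <- stats::runif(n_expr, cfg$expressed_log2_range[1],
                                cfg$expressed_log2_range[2])

  contam <- cfg$contamination_gene_ids
  if (is.null(contam)) contam <- utils::head(expressed, 2)
  contam <- intersect(contam, gene_ids)

  de_pool <- setdiff(expressed, contam)
  n_de <- min(cfg$n_de_genes, length(de_pool))
  de_genes <- sort(sample(de_pool, n_de))
  true_fc <- rep(1, cfg$n_probes)
  names(true_fc) <- gene_ids
  if (n_de > 0) {
    true_fc[de_genes] <- stats::runif(n_de, cfg$de_fc_range[1],
                                      cfg$de_fc_range[2])
  }
  de_shift <- log2(true_fc)

  control_subj <- sprintf("C%02d", seq_len(cfg$n_controls))
  patient_subj <- sprintf("S%02d", seq_len(cfg$n_patients))
  treated_subj <- utils::head(patient_subj, cfg$n_treated)
  hetero_subj <- sort(sample(patient_subj,
                             cfg$n_heterogeneous_patients))

  meta <- data.frame(
    sample_id = c(paste0(control_subj, "_b"), paste0(patient_subj, "_b"),
                  paste0(treated_subj, "_p", recycle0 = TRUE)),
    subject_id = c(control_subj, patient_subj, treated_subj),
    group = c(rep("control", cfg$n_controls),
              rep("patient", cfg$n_patients + cfg$n_treated)),
    timepoint = c(rep("baseline", cfg$n_controls + cfg$n_patients),
                  rep("post", cfg$n_treated)),
    treated = c(rep(0L, cfg$n_controls),
                as.integer(patient_subj %in% treated_subj),
                rep(1L, cfg$n_treated)),
    stringsAsFactors = FALSE
  )
  crp_by_subj <- stats::setNames(
    c(rep(NA_real_, cfg$n_controls),
      round(stats::rlnorm(cfg$n_patients, log(4), 1.1), 1)),
    c(control_subj, patient_subj))
  meta$crp <- unname(crp_by_subj[meta$subject_id])

  subjects <- c(control_subj, patient_subj)
  sig <- matrix(stats::rnorm(cfg$n_probes * length(subjects), 0,
                             cfg$patient_effect_sd),
                cfg$n_probes, length(subjects),
                dimnames = list(gene_ids, subjects))
  treat_shift <- matrix(stats::rnorm(cfg$n_probes * cfg$n_treated, 0,
                                     cfg$treatment_effect_sd),
                        cfg$n_probes, max(cfg$n_treated, 1),
                        dimnames = list(gene_ids,
                                        utils::head(treated_subj,
                                                    max(cfg$n_treated, 1))))
  if (length(contam) && cfg$n_treated > 0) {
    treat_shift[contam, ] <- log2(1.5)
  }

  sub_seeds <- draw_subseeds(nrow(meta))
  n_total <- cfg$n_probes + cfg$n_neg_controls
  all_ids <- c(gene_ids, neg_ids)

  arrays <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    set.seed(sub_seeds[i])
    subj <- meta$subject_id[i]
    lev <- mu + sig[, subj]
    if (meta$group[i] == "patient") lev <- lev + de_shift
    if (meta$timepoint[i] == "post") lev <- lev + treat_shift[, subj]
    if (subj %in% hetero_subj) {
      lev <- lev + stats::rnorm(cfg$n_probes, 0, cfg$hetero_extra_sd)
    }
    lev_all <- c(lev, rep(cfg$background_log2, cfg$n_neg_controls))
    k <- cfg$beads_per_probe
    noise <- stats::rnorm(k * n_total, 0, cfg$measurement_sd)
    intens <- 2^(rep(lev_all, each = k) + noise)
    if (cfg$outlier_bead_rate > 0) {
      out <- stats::runif(k * n_total) < cfg$outlier_bead_rate
      n_out <- sum(out)
      if (n_out) intens[out] <- intens[out] * sample(c(4, 0.25), n_out,
                                                     replace = TRUE)
    }
    bm <- matrix(intens, nrow = k, dimnames = list(NULL, all_ids))
    arrays[[i]] <- bead_array(meta$sample_id[i], bm, neg_ids)
  }
  names(arrays) <- meta$sample_id

  truth <- list(de_gene_ids = de_genes,
                true_log2_fc = de_shift,
                heterogeneous_patient_ids = hetero_subj,
                expressed_gene_ids = expressed,
                treatment_responsive_ids = contam)
  list(arrays = arrays, meta = meta, truth = truth)
}

#' Generate a synthetic qPCR plate
#'
#' Simulates triplicate Ct values for a panel of target genes (taken from the
#' cohort's differentially expressed genes) plus four housekeeping candidates
#' (GAPDH, RN18S, ACTB, RPL13A). Ct values follow
#' `Ct = base - log2(relative expression) + sample offset + noise`; GAPDH is
#' designed most stable (smallest extra per-sample variation, no group shift),
#' RN18S carries a patient-group shift, ACTB and RPL13A carry larger
#' per-sample noise. Quality scores are drawn so that a configurable fraction
#' of replicates falls below the 0.65 amplification-quality threshold.
#'
#' @param config a [sim_config()].
#' @param cohort output of [generate_cohort()]; its `truth` supplies the
#'   target genes and fold changes and its `meta` the samples and groups.
#' @return an object of class `qpcr_study`: a data frame with columns
#'   sample_id, gene, replicate, ct, quality, plus attributes
#'   `housekeeping_candidates`, `designed_stable`, `targets` and `meta`.
#' @export
generate_qpcr <- function(config, cohort) {
  validate_sim_config(config)
  cfg <- config
  meta <- cohort$meta
  truth <- cohort$truth
  set.seed(cfg$rng_seed + 7L)

  hk <- c("GAPDH", "RN18S", "ACTB", "RPL13A")
  hk_extra_sd <- c(GAPDH = 0.05, RN18S = 0.3, ACTB = 0.35,
                   RPL13A = 0.4) * cfg$qpcr_hk_sd_scale
  hk_group_shift <- c(GAPDH = 0, RN18S = 0, ACTB = 0, RPL13A = 0)
  targets <- utils::head(truth$de_gene_ids, cfg$qpcr_n_targets)
  genes <- c(targets, hk)

  base_ct <- stats::setNames(stats::runif(length(genes), 20, 28), genes)
  offset <- stats::setNames(
    stats::rnorm(nrow(meta), 0, cfg$qpcr_sample_offset_sd), meta$sample_id)

  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    is_pat <- meta$group == "patient"
    if (g %in% targets) {
      x <- ifelse(is_pat, truth$true_log2_fc[g], 0) +
        stats::rnorm(nrow(meta), 0, cfg$qpcr_bio_sd)
    } else {
      x <- stats::rnorm(nrow(meta), 0, hk_extra_sd[[g]]) -
        ifelse(is_pat, hk_group_shift[[g]], 0)
    }
    ct_mean <- base_ct[[g]] - x + offset
    rep_ct <- rep(ct_mean, each = 3) +
      stats::rnorm(3 * nrow(meta), 0, cfg$qpcr_replicate_sd)
    fails <- stats::runif(3 * nrow(meta)) < cfg$qpcr_fail_rate
    quality <- ifelse(fails, stats::runif(3 * nrow(meta), 0, 0.649),
                      stats::runif(3 * nrow(meta), 0.65, 1))
    rows[[gi]] <- data.frame(
      sample_id = rep(meta$sample_id, each = 3),
      gene = g, replicate = rep(1:3, nrow(meta)),
      ct = rep_ct, quality = quality, stringsAsFactors = FALSE)
  }
  study <- do.call(rbind, rows)
  structure(study, class = c("qpcr_study", "data.frame"),
            housekeeping_candidates = hk, designed_stable = "GAPDH",
            targets = targets, meta = meta)
}
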