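# Shared fixtures built in code.

# brute-force oracle for the bead outlier rule: filter directly by the
# definition, independent of the implementation's code path
oracle_mad_filter <- function(x, k = 2) {
  med <- median(x)
  mad0 <- median(abs(x - med))
  keep <- x >= med - k * mad0 & x <= med + k * mad0
  list(retained = x[keep], removed = x[!keep])
}

# minimal expr_matrix wrapper around a plain values matrix
make_em <- function(values, meta = NULL, scale = "log2-quantile",
                    group_active = NULL, assessed = rownames(values)) {
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(values),
                       subject_id = colnames(values),
                       group = "patient", timepoint = "baseline",
                       treated = 0L, crp = NA_real_,
                       stringsAsFactors = FALSE)
  }
  structure(list(values = values, scale = scale, presence = NULL,
                 group_active = group_active, assessed = assessed,
                 sample_meta = meta, groups = cohort_groups(meta),
                 probe_calls = NULL),
            class = "expr_matrix")
}

# small cohort for smoke-level pipeline tests; dots override the defaults
tiny_config <- function(seed = 7, ...) {
  args <- utils::modifyList(list(n_probes = 200, n_neg_controls = 30,
                                 beads_per_probe = 8, rng_seed = seed),
                            list(...))
  do.call(sim_config, args)
}

# run preprocessing + normalization on a cohort in one step
normalized_matrix <- function(cohort, ...) {
  em <- suppressMessages(build_expression_matrix(cohort$arrays,
                                                 cohort$meta, ...))
  suppressMessages(log2_quantile_normalize(em))
}

# 20-gene differential-expression fixture with hand-computable grid counts
grid_fixture <- function() {
  data.frame(
    gene_id = sprintf("g%02d", 1:20),
    p_value = c(0.20, 0.049, 0.04, 0.05, 0.009, 0.04, 0.0009, 0.00009,
                0.00009, 0.0009, 0.009, 0.049, 0.30, 0.60, 0.0099,
                0.00001, 0.0001, 0.049, 0.02, 0.70),
    fold_change = c(1.00, 1.36, 1.35, 1.40, 0.73, 0.74, 1.21, 1.09,
                    1.11, 0.81, 1.10, 0.70, 2.00, 0.50, 1.25,
                    0.90, 0.91, 1.00, 1.50, 1.20),
    stringsAsFactors = FALSE)
}
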