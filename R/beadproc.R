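# Bead-level preprocessing: outlier removal, probe summarization, detection
# calls against negative controls, group-level activity calls.

#' Remove bead outliers by the median +/- k * MAD rule
#'
#' A bead is retained when its intensity lies inside
#' `[median - k * MAD, median + k * MAD]` (inclusive), where MAD is the
#' unscaled median absolute deviation from the median (no 1.4826 consistency
#' factor). When MAD is 0 the rule applied literally retains only beads equal
#' to the median (`mad_zero_policy = "strict"`, with a warning);
#' `"retain_all"` keeps every bead instead.
#'
#' @param intensities numeric vector of positive bead intensities.
#' @param mad_multiplier the `k` in the rule; default 2.
#' @param mad_zero_policy `"strict"` or `"retain_all"`; behaviour when the
#'   MAD is exactly 0.
#' @return list with components `retained` and `removed`.
#' @export
remove_bead_outliers <- function(intensities, mad_multiplier = 2,
                                 mad_zero_policy = c("strict", "retain_all")) {
  mad_zero_policy <- match.arg(mad_zero_policy)
  if (length(intensities) < 1) stop("at least one bead intensity required")
  med <- stats::median(intensities)
  mad0 <- stats::median(abs(intensities - med))
  if (mad0 == 0 && any(intensities != med)) {
    if (mad_zero_policy == "retain_all") {
      return(list(retained = intensities, removed = numeric(0)))
    }
    warning("MAD is 0; strict rule retains only beads equal to the median",
            call. = FALSE)
  }
  lo <- med - mad_multiplier * mad0
  hi <- med + mad_multiplier * mad0
  keep <- intensities >= lo & intensities <= hi
  list(retained = intensities[keep], removed = intensities[!keep])
}

#' Summarize a probe's retained beads
#'
#' @param retained numeric vector of retained bead intensities.
#' @return arithmetic mean intensity; `NA` (with a message) when no beads
#'   survived outlier removal, in which case the probe is excluded from the
#'   detection call for that array.
#' @export
summarize_probe <- function(retained) {
  if (length(retained) == 0) {
    message("probe has no retained beads; flagged missing for this array")
    return(NA_real_)
  }
  mean(retained)
}

# one-sided Welch t-test (greater), vectorized over probes
welch_greater <- function(mx, vx, nx, my, vy, ny) {
  p <- rep(NA_real_, length(mx))
  degenerate <- vx == 0 & vy == 0
  se2 <- vx / nx + vy / ny
  ok <- !degenerate & is.finite(se2) & se2 > 0
  tt <- (mx[ok] - my) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((vx[ok] / nx[ok])^2 / (nx[ok] - 1) +
                       (vy / ny)^2 / (ny - 1))
  p[ok] <- stats::pt(tt, df, lower.tail = FALSE)
  p[degenerate] <- ifelse(mx[degenerate] > my, 0, 1)
  p
}

#' Detection call for one probe against negative controls
#'
#' One-sided two-sample Welch t-test of the probe's retained bead intensities
#' against the pooled negative-control bead intensities of the same array
#' (alternative: probe mean greater). The probe is called present when
#' `p < alpha`. When both samples have zero variance and equal means the
#' detection p-value is 1 and the probe absent.
#'
#' @param probe_beads_retained numeric vector (>= 2 values).
#' @param negcontrol_values numeric vector (>= 2 values).
#' @param alpha detection significance level; default 0.05.
#' @return list with `detection_p` and `present`.
#' @export
detection_call <- function(probe_beads_retained, negcontrol_values,
                           alpha = 0.05) {
  if (length(probe_beads_retained) < 2 || length(negcontrol_values) < 2) {
    stop("detection_call needs >= 2 values in each sample")
  }
  p <- welch_greater(mean(probe_beads_retained),
                     stats::var(probe_beads_retained),
                     length(probe_beads_retained),
                     mean(negcontrol_values), stats::var(negcontrol_values),
                     length(negcontrol_values))
  list(detection_p = p, present = is.finite(p) && p < alpha)
}

#' Group-size-dependent presence threshold
#'
#' Returns the minimum number of present samples for a probe to be called
#' transcriptionally active in a group of size `n`. Group sizes 12 and 18 use
#' the published thresholds 8 and 13; any other size falls back to the
#' smallest `k` for which a one-sided Z-test of the observed proportion
#' against 0.5 (no continuity correction) gives p < 0.05. A value of `n + 1`
#' means activity cannot be reached at that group size.
#'
#' @param n group size (>= 1).
#' @return integer threshold.
#' @export
presence_threshold <- function(n) {
  if (n < 1) stop("group size must be >= 1")
  lookup <- c(`12` = 8L, `18` = 13L)
  key <- as.character(n)
  if (key %in% names(lookup)) return(lookup[[key]])
  k <- seq_len(n)
  z <- (k / n - 0.5) / sqrt(0.25 / n)
  p <- stats::pnorm(z, lower.tail = FALSE)
  hit <- which(p < 0.05)
  if (length(hit)) as.integer(hit[1]) else n + 1L
}

#' Group-level transcriptional-activity call
#'
#' @param presence_flags logical vector: per-sample presence of one probe in
#'   one group.
#' @return `TRUE` when the number of present samples reaches
#'   [presence_threshold()] for the group size.
#' @export
group_presence <- function(presence_flags) {
  n <- length(presence_flags)
  sum(presence_flags, na.rm = TRUE) >= presence_threshold(n)
}

# per-column medians of a matrix via a single order() pass
col_medians <- function(x) {
  k <- nrow(x)
  s <- matrix(x[order(col(x), x)], nrow = k)
  (s[floor((k + 1) / 2), ] + s[ceiling((k + 1) / 2), ]) / 2
}

# vectorized per-probe preprocessing of a uniform bead matrix
process_bead_matrix <- function(bm, mad_multiplier, mad_zero_policy) {
  k <- nrow(bm)
  med <- col_medians(bm)
  mad0 <- col_medians(abs(sweep(bm, 2, med)))
  lo <- med - mad_multiplier * mad0
  hi <- med + mad_multiplier * mad0
  keep <- sweep(bm, 2, lo, ">=") & sweep(bm, 2, hi, "<=")
  if (mad_zero_policy == "retain_all") {
    zero_mad <- mad0 == 0
    if (any(zero_mad)) keep[, zero_mad] <- TRUE
  }
  n_ret <- colSums(keep)
  s1 <- colSums(bm * keep)
  s2 <- colSums(bm^2 * keep)
  mean_ret <- ifelse(n_ret > 0, s1 / n_ret, NA_real_)
  var_ret <- ifelse(n_ret > 1, pmax(0, (s2 - n_ret * mean_ret^2) /
                                      (n_ret - 1)), NA_real_)
  list(mean = mean_ret, var = var_ret, n_retained = n_ret,
       n_removed = k - n_ret, keep = keep)
}

#' Preprocess one bead array
#'
#' Applies bead outlier removal probe by probe, summarizes retained beads as
#' the probe mean, and calls detection of each gene probe against the pooled
#' (outlier-filtered) negative-control beads of the same array.
#'
#' @param ba a [bead_array()].
#' @param mad_multiplier,mad_zero_policy passed to [remove_bead_outliers()].
#' @param alpha detection significance level.
#' @return data frame of probe calls: probe_id, mean_intensity,
#'   n_beads_retained, n_beads_removed, detection_p, present (gene probes
#'   only; negative controls feed the detection reference).
#' @export
process_array <- function(ba, mad_multiplier = 2, alpha = 0.05,
                          mad_zero_policy = c("strict", "retain_all")) {
  mad_zero_policy <- match.arg(mad_zero_policy)
  stopifnot(inherits(ba, "bead_array"))
  ids <- probe_ids(ba)
  is_neg <- ids %in% ba$negative_control_ids

  if (is.matrix(ba$beads)) {
    res <- process_bead_matrix(ba$beads, mad_multiplier, mad_zero_policy)
    neg_vals <- ba$beads[, is_neg, drop = FALSE]
    neg_keep <- res$keep[, is_neg, drop = FALSE]
    neg_pool <- neg_vals[neg_keep]
  } else {
    filt <- lapply(ba$beads, function(b) {
      suppressWarnings(remove_bead_outliers(b, mad_multiplier,
                                            mad_zero_policy))
    })
    ret <- lapply(filt, `[[`, "retained")
    res <- list(mean = vapply(ret, function(r) {
      if (length(r)) mean(r) else NA_real_
    }, 0),
    var = vapply(ret, function(r) {
      if (length(r) > 1) stats::var(r) else NA_real_
    }, 0),
    n_retained = lengths(ret),
    n_removed = lengths(ba$beads) - lengths(ret))
    neg_pool <- unlist(ret[is_neg], use.names = FALSE)
  }

  if (length(neg_pool) < 2) stop("fewer than 2 retained negative-control ",
                                 "beads on array ", ba$sample_id)
  my <- mean(neg_pool)
  vy <- stats::var(neg_pool)
  ny <- length(neg_pool)

  gene <- !is_neg
  p <- rep(NA_real_, sum(gene))
  ok <- res$n_retained[gene] >= 2
  vx <- res$var[gene]
  vx[is.na(vx)] <- 0
  p[ok] <- welch_greater(res$mean[gene][ok], vx[ok],
                         res$n_retained[gene][ok], my, vy, ny)
  data.frame(probe_id = ids[gene],
             mean_intensity = res$mean[gene],
             n_beads_retained = res$n_retained[gene],
             n_beads_removed = res$n_removed[gene],
             detection_p = p,
             present = !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Derive the standard comparison groups from sample metadata
#'
#' @param meta sample metadata (as produced by [generate_cohort()]).
#' @return named list of sample-id vectors: `control.baseline`,
#'   `patient.baseline`, and when post-treatment samples exist, `treated.pre`
#'   (baseline samples of treated subjects) and `treated.post`.
#' @export
cohort_groups <- function(meta) {
  g <- list()
  cb <- meta$sample_id[meta$group == "control" & meta$timepoint == "baseline"]
  pb <- meta$sample_id[meta$group == "patient" & meta$timepoint == "baseline"]
  if (length(cb)) g$control.baseline <- cb
  if (length(pb)) g$patient.baseline <- pb
  post <- meta[meta$timepoint == "post", , drop = FALSE]
  if (nrow(post)) {
    g$treated.post <- post$sample_id
    pre <- meta[meta$timepoint == "baseline" &
                  meta$subject_id %in% post$subject_id, , drop = FALSE]
    g$treated.pre <- pre$sample_id[match(post$subject_id, pre$subject_id)]
  }
  g
}

#' Assemble an expression matrix from preprocessed bead arrays
#'
#' Runs [process_array()] on every array, assembles the probe-mean matrix and
#' presence mask, and applies the group activity rule ([group_presence()]) to
#' each comparison group. The assessed probe set is the union of probes active
#' in at least one group. Probes whose beads were all removed on an array are
#' imputed at that array's minimum summarized intensity (logged).
#'
#' @param arrays list of [bead_array()] sharing one probe universe.
#' @param meta sample metadata with a `sample_id` column covering the arrays.
#' @param groups named list of sample-id vectors defining the comparison
#'   groups; default [cohort_groups()] of `meta`.
#' @param mad_multiplier,alpha,mad_zero_policy preprocessing parameters.
#' @return an object of class `expr_matrix`: list with `values` (probes x
#'   samples), `scale` (`"raw"`), `presence`, `group_active`, `assessed`,
#'   `sample_meta` and `probe_calls`.
#' @export
build_expression_matrix <- function(arrays, meta, groups = NULL,
                                    mad_multiplier = 2, alpha = 0.05,
                                    mad_zero_policy = "strict") {
  stopifnot(length(arrays) >= 1)
  ids0 <- sort(setdiff(probe_ids(arrays[[1]]),
                       arrays[[1]]$negative_control_ids))
  for (ba in arrays[-1]) {
    ids <- setdiff(probe_ids(ba), ba$negative_control_ids)
    bad <- c(setdiff(ids0, ids), setdiff(ids, ids0))
    if (length(bad)) {
      stop("probe universe mismatch on array ", ba$sample_id, ": ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "")
    }
  }
  sample_ids <- unname(vapply(arrays, `[[`, "", "sample_id"))
  if (!all(sample_ids %in% meta$sample_id)) {
    stop("metadata missing samples: ",
         paste(setdiff(sample_ids, meta$sample_id), collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]

  calls <- lapply(arrays, process_array, mad_multiplier = mad_multiplier,
                  alpha = alpha, mad_zero_policy = mad_zero_policy)
  values <- matrix(NA_real_, length(ids0), length(arrays),
                   dimnames = list(ids0, sample_ids))
  presence <- matrix(FALSE, length(ids0), length(arrays),
                     dimnames = list(ids0, sample_ids))
  for (j in seq_along(calls)) {
    pc <- calls[[j]]
    idx <- match(pc$probe_id, ids0)
    values[idx, j] <- pc$mean_intensity
    presence[idx, j] <- pc$present
    miss <- is.na(values[, j])
    if (any(miss)) {
      message(sum(miss), " probe(s) with no retained beads on ",
              sample_ids[j], "; imputed at array minimum")
      values[miss, j] <- min(values[, j], na.rm = TRUE)
    }
  }

  if (is.null(groups)) groups <- cohort_groups(meta)
  group_active <- NULL
  if (length(groups)) {
    group_active <- vapply(groups, function(s) {
      apply(presence[, s, drop = FALSE], 1, group_presence)
    }, logical(nrow(presence)))
    if (is.null(dim(group_active))) {
      group_active <- matrix(group_active, ncol = length(groups),
                             dimnames = list(ids0, names(groups)))
    }
  }
  assessed <- if (is.null(group_active)) character(0) else
    rownames(group_active)[rowSums(group_active) > 0]

  structure(list(values = values, scale = "raw", presence = presence,
                 group_active = group_active, assessed = assessed,
                 sample_meta = meta, groups = groups,
                 probe_calls = stats::setNames(calls, sample_ids)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples (scale: ", x$scale, ")\n", sep = "")
  if (length(x$assessed)) {
    cat("assessed (active in >= 1 group): ", length(x$assessed),
        " probes across ", ncol(x$group_active), " group(s)\n", sep = "")
  }
  invisible(x)
}

#' Active probes over a set of comparison groups
#'
#' With `rule = "union"` (the assessed set used for differential expression)
#' a probe qualifies when active in at least one named group; with
#' `rule = "intersection"` it must be active in every named group — the
#' solidly expressed probes whose log2 values behave normally in all groups,
#' appropriate for variance comparisons such as
#' [per_sample_heterogeneity()].
#'
#' @param em an `expr_matrix`.
#' @param group_names which columns of `group_active` to combine; default all.
#' @param rule `"union"` or `"intersection"`.
#' @return character vector of probe ids.
#' @export
assessed_probes <- function(em, group_names = NULL,
                            rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  stopifnot(inherits(em, "expr_matrix"))
  ga <- em$group_active
  if (is.null(ga)) return(character(0))
  if (is.null(group_names)) group_names <- colnames(ga)
  ga <- ga[, group_names, drop = FALSE]
  need <- if (rule == "union") 1L else ncol(ga)
  rownames(ga)[rowSums(ga) >= need]
}
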