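# qPCR validation arm: replicate QC, geNorm / NormFinder reference-gene
# stability, delta-delta-Ct relative quantification.

#' QC-filter and aggregate replicate Ct values
#'
#' Drops replicates whose amplification-curve quality score falls below the
#' threshold and averages the survivors per (sample, gene). Combinations with
#' no surviving replicate are reported missing (logged) and excluded
#' downstream.
#'
#' @param study a `qpcr_study` or data frame with columns sample_id, gene,
#'   replicate, ct, quality.
#' @param quality_threshold minimum acceptable quality score; default 0.65.
#' @return data frame: sample_id, gene, ct (mean of surviving replicates),
#'   n_replicates. Attributes of the input study are carried over.
#' @export
qc_and_aggregate <- function(study, quality_threshold = 0.65) {
  keep <- study$quality >= quality_threshold
  all_combo <- unique(study[, c("sample_id", "gene")])
  ok <- study[keep, , drop = FALSE]
  if (nrow(ok)) {
    agg <- stats::aggregate(ct ~ sample_id + gene, data = ok, FUN = mean)
    cnt <- stats::aggregate(ct ~ sample_id + gene, data = ok, FUN = length)
    agg$n_replicates <- cnt$ct
  } else {
    agg <- data.frame(sample_id = character(0), gene = character(0),
                      ct = numeric(0), n_replicates = integer(0))
  }
  n_missing <- nrow(all_combo) - nrow(agg)
  if (n_missing > 0) {
    message(n_missing, " (sample, gene) combination(s) lost all replicates ",
            "to QC; marked missing")
  }
  for (a in c("housekeeping_candidates", "designed_stable", "targets",
              "meta")) {
    attr(agg, a) <- attr(study, a)
  }
  agg
}

#' Relative quantities for reference-gene stability analysis
#'
#' The geNorm input transform: per gene, `q = 2^-(Ct - min Ct)`, so the
#' best-expressed sample of each gene has quantity 1.
#'
#' @param agg aggregated Ct table from [qc_and_aggregate()].
#' @param genes genes to include; default the housekeeping candidates
#'   recorded on the study.
#' @return numeric matrix samples x genes of relative quantities (NA where
#'   missing).
#' @export
relative_quantities <- function(agg, genes = NULL) {
  if (is.null(genes)) genes <- attr(agg, "housekeeping_candidates")
  if (is.null(genes)) genes <- unique(agg$gene)
  agg <- agg[agg$gene %in% genes, , drop = FALSE]
  samples <- sort(unique(agg$sample_id))
  q <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  q[cbind(match(agg$sample_id, samples), match(agg$gene, genes))] <- agg$ct
  for (j in seq_along(genes)) {
    q[, j] <- 2^-(q[, j] - min(q[, j], na.rm = TRUE))
  }
  q
}

#' geNorm expression-stability measure M
#'
#' For each candidate reference gene j, `M_j` is the mean over the other
#' candidates k of the standard deviation across samples of
#' `log2(q_j / q_k)`. Lower M means more stable. Pairwise-complete samples
#' are used; a candidate sharing fewer than 3 complete samples with every
#' partner is excluded (logged).
#'
#' @param quantities samples x candidates matrix of positive relative
#'   quantities (e.g. [relative_quantities()]).
#' @return named numeric vector of M values (NA for excluded candidates).
#' @export
genorm_m <- function(quantities) {
  stopifnot(is.matrix(quantities), ncol(quantities) >= 2,
            nrow(quantities) >= 2)
  if (any(quantities <= 0, na.rm = TRUE)) {
    stop("relative quantities must be positive")
  }
  lq <- log2(quantities)
  k <- ncol(lq)
  m <- stats::setNames(rep(NA_real_, k), colnames(lq))
  for (j in seq_len(k)) {
    sds <- vapply(setdiff(seq_len(k), j), function(i) {
      r <- lq[, j] - lq[, i]
      r <- r[is.finite(r)]
      if (length(r) < 3) return(NA_real_)
      stats::sd(r)
    }, 0)
    if (anyNA(sds)) {
      message("candidate ", colnames(lq)[j],
              " excluded from geNorm (fewer than 3 shared samples ",
              "with some partner)")
    } else m[j] <- mean(sds)
  }
  m
}

#' Model-based (NormFinder-style) reference-gene stability
#'
#' Candidate log-quantities are centered per sample on the candidate mean
#' (removing global sample effects), then decomposed per group into an
#' intergroup bias (deviation of the candidate's group mean from its overall
#' mean) and an intragroup variance. Raw bias estimates are shrunken toward
#' zero by the model-based factor `tau^2 / (tau^2 + se^2)`, where `tau^2` is
#' the across-candidate estimate of true intergroup variance (moment
#' estimator, floored at 0) and `se^2` the sampling variance of the bias
#' estimate — so when no candidate truly differs between groups the ranking
#' reduces to intragroup variation, while a genuinely group-dependent
#' candidate keeps its bias. The stability of candidate i is the mean over
#' groups of `|shrunken bias| + sqrt(variance / n_group)`; lower is more
#' stable. With a single group the intragroup term alone is used (logged).
#'
#' @param log_quantities samples x candidates matrix of log-scale quantities
#'   (e.g. `-Ct` or `log2` relative quantities).
#' @param groups per-sample group labels (length = rows).
#' @return named numeric vector of stability values.
#' @export
normfinder_stability <- function(log_quantities, groups) {
  stopifnot(is.matrix(log_quantities),
            length(groups) == nrow(log_quantities))
  if (ncol(log_quantities) < 3) stop("need >= 3 candidates")
  y <- log_quantities - rowMeans(log_quantities)
  gl <- unique(groups)
  if (length(gl) == 1) {
    message("single group: NormFinder falls back to intragroup ",
            "variation only")
    return(apply(y, 2, stats::sd))
  }
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  gm <- vapply(gl, function(g) colMeans(y[groups == g, , drop = FALSE]),
               numeric(ncol(y)))
  gv <- vapply(gl, function(g) apply(y[groups == g, , drop = FALSE], 2,
                                     stats::var), numeric(ncol(y)))
  overall <- rowMeans(gm)
  n_g <- as.numeric(tab[gl])
  ng <- length(gl)
  d_hat <- gm - overall                       # candidates x groups
  se2 <- sweep(gv, 2, n_g, "/") * (ng - 1) / ng
  tau2 <- pmax(0, colMeans(d_hat^2) - colMeans(se2))  # per group
  tau2m <- matrix(tau2, nrow(d_hat), ng, byrow = TRUE)
  shrink <- d_hat * tau2m / (tau2m + se2)
  stab <- vapply(seq_len(ncol(y)), function(i) {
    mean(abs(shrink[i, ]) + sqrt(gv[i, ] / n_g))
  }, 0)
  stats::setNames(stab, colnames(y))
}

#' Rank candidate reference genes by both stability criteria
#'
#' Computes the geNorm M value (on relative quantities) and the
#' NormFinder-style stability (on log2 relative quantities) for every
#' housekeeping candidate and selects the geNorm winner; when the two
#' criteria disagree a warning flags the disagreement as a data-quality
#' signal (on well-behaved plates both select the same gene).
#'
#' @param agg aggregated Ct table from [qc_and_aggregate()].
#' @param groups named per-sample group labels; default taken from the
#'   study's metadata (`control` / `patient` at baseline).
#' @param candidates candidate genes; default the study's housekeeping
#'   candidates.
#' @return object of class `stability_ranking`: data frame (gene, genorm_m,
#'   normfinder_stability) plus `selected_reference`.
#' @export
stability_ranking <- function(agg, groups = NULL, candidates = NULL) {
  if (is.null(candidates)) candidates <- attr(agg, "housekeeping_candidates")
  q <- relative_quantities(agg, candidates)
  if (is.null(groups)) {
    meta <- attr(agg, "meta")
    if (is.null(meta)) stop("supply per-sample group labels")
    groups <- stats::setNames(meta$group, meta$sample_id)[rownames(q)]
  } else groups <- groups[rownames(q)]
  m <- genorm_m(q)
  complete <- stats::complete.cases(log2(q))
  nf <- normfinder_stability(log2(q[complete, , drop = FALSE]),
                             groups[complete])
  sel_g <- names(m)[which.min(m)]
  sel_n <- names(nf)[which.min(nf)]
  if (!identical(sel_g, sel_n)) {
    warning("geNorm (", sel_g, ") and NormFinder (", sel_n,
            ") disagree; selecting the geNorm winner", call. = FALSE)
  }
  structure(list(
    table = data.frame(gene = names(m), genorm_m = unname(m),
                       normfinder_stability = unname(nf[names(m)]),
                       stringsAsFactors = FALSE),
    selected_reference = sel_g, normfinder_choice = sel_n),
    class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("stability_ranking (lower = more stable):\n")
  print(x$table, row.names = FALSE)
  cat("selected reference:", x$selected_reference, "\n")
  invisible(x)
}

#' Delta-delta-Ct relative quantification
#'
#' `deltaCt(s) = Ct_target(s) - Ct_reference(s)` per sample;
#' `ddCt = mean deltaCt(group A) - mean deltaCt(reference group B)`;
#' fold change `2^-ddCt`. The group difference is tested on the deltaCt scale
#' with a two-sample Welch t-test, or a paired t-test when the two groups are
#' matched timepoints of the same subjects (`paired = TRUE`, groups aligned
#' position-wise). A result is flagged low-confidence when the target is
#' missing in more than half of either group.
#'
#' @param agg aggregated Ct table from [qc_and_aggregate()].
#' @param target target gene.
#' @param reference_gene reference (housekeeping) gene; must be measured in
#'   every included sample.
#' @param group_a,group_b_reference sample ids; fold changes express group A
#'   relative to the reference group B.
#' @param paired treat the groups as matched pairs.
#' @return object of class `ddct_result`: `delta_ct` (named per sample),
#'   `ddct`, `fold_change`, `p_value`, `low_confidence`, `test`.
#' @export
ddct <- function(agg, target, reference_gene, group_a, group_b_reference,
                 paired = FALSE) {
  get_ct <- function(gene, samples) {
    idx <- match(paste(samples, gene), paste(agg$sample_id, agg$gene))
    stats::setNames(agg$ct[idx], samples)
  }
  all_s <- c(group_a, group_b_reference)
  ref_ct <- get_ct(reference_gene, all_s)
  if (anyNA(ref_ct)) {
    stop("reference gene ", reference_gene, " not measured in sample(s): ",
         paste(names(ref_ct)[is.na(ref_ct)], collapse = ", "))
  }
  tgt_ct <- get_ct(target, all_s)
  dct <- tgt_ct - ref_ct
  da <- dct[group_a]
  db <- dct[group_b_reference]
  low_conf <- mean(is.na(da)) > 0.5 || mean(is.na(db)) > 0.5
  if (low_conf) message("target ", target, " missing in more than half of ",
                        "a group; result flagged low-confidence")
  if (paired) {
    ok <- !is.na(da) & !is.na(db)
    da_t <- da[ok]
    db_t <- db[ok]
    if (!length(da_t)) {
      return(structure(list(target = target,
                            reference_gene = reference_gene,
                            delta_ct = dct, ddct = NA_real_,
                            fold_change = NA_real_, p_value = NA_real_,
                            low_confidence = TRUE, test = "paired_t"),
                       class = "ddct_result"))
    }
    diffs <- da_t - db_t
    ddct_val <- mean(diffs)
    p <- if (stats::sd(diffs) == 0) {
      if (mean(diffs) == 0) 1 else 0
    } else stats::t.test(da_t, db_t, paired = TRUE)$p.value
    test <- "paired_t"
  } else {
    da_t <- da[!is.na(da)]
    db_t <- db[!is.na(db)]
    if (!length(da_t) || !length(db_t)) {
      return(structure(list(target = target,
                            reference_gene = reference_gene,
                            delta_ct = dct, ddct = NA_real_,
                            fold_change = NA_real_, p_value = NA_real_,
                            low_confidence = TRUE, test = "welch_t"),
                       class = "ddct_result"))
    }
    ddct_val <- mean(da_t) - mean(db_t)
    degen <- stats::sd(da_t) == 0 && stats::sd(db_t) == 0
    p <- if (degen) {
      if (ddct_val == 0) 1 else 0
    } else stats::t.test(da_t, db_t)$p.value
    test <- "welch_t"
  }
  structure(list(target = target, reference_gene = reference_gene,
                 delta_ct = dct, ddct = ddct_val,
                 fold_change = 2^(-ddct_val), p_value = p,
                 low_confidence = low_conf, test = test),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("ddct_result: ", x$target, " vs ", x$reference_gene, "\n",
      "  ddCt = ", format(x$ddct, digits = 4), ", fold change 2^-ddCt = ",
      format(x$fold_change, digits = 4), ", p = ",
      format(x$p_value, digits = 3), " (", x$test, ")",
      if (x$low_confidence) " [low confidence]", "\n", sep = "")
  invisible(x)
}
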