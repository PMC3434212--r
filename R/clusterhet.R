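# Ratio-based hierarchical clustering of pre/post samples and per-sample
# log2-ratio heterogeneity analysis.

#' Ratio matrix relative to the average baseline signal
#'
#' For every gene, the reference is the arithmetic mean of the linear-scale
#' signal over the baseline samples; each sample's ratio is its linear signal
#' divided by that reference. Log2-scale matrices are linearized (`2^value`)
#' first.
#'
#' @param em a normalized `expr_matrix` (log2 scale) or a linear matrix.
#' @param baseline_samples sample ids defining the baseline reference.
#' @param gene_subset genes to keep (e.g. the significantly modulated genes
#'   entering the heat map); default all rows.
#' @return object of class `ratio_matrix`: list with `ratios` (genes x
#'   samples) and `baseline_reference`.
#' @export
build_ratio_matrix <- function(em, baseline_samples, gene_subset = NULL) {
  if (inherits(em, "expr_matrix")) {
    lin <- if (em$scale == "raw") em$values else 2^em$values
  } else {
    lin <- em
  }
  if (!length(baseline_samples)) stop("baseline_samples must be non-empty")
  if (is.null(gene_subset)) gene_subset <- rownames(lin)
  missing_g <- setdiff(gene_subset, rownames(lin))
  if (length(missing_g)) {
    stop("gene_subset not in matrix: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  }
  lin <- lin[gene_subset, , drop = FALSE]
  ref <- rowMeans(lin[, baseline_samples, drop = FALSE])
  if (any(ref <= 0)) stop("zero or negative baseline reference")
  structure(list(ratios = lin / ref, baseline_reference = ref),
            class = "ratio_matrix")
}

# reorder an hclust merge tree so that at each merge the subtree with the
# smaller minimum label goes left, then read off the leaf order
canonical_leaf_order <- function(merge, labels) {
  n1 <- nrow(merge)
  minid <- character(n1)
  node_min <- function(j) if (j < 0) labels[-j] else minid[j]
  for (i in seq_len(n1)) {
    l <- node_min(merge[i, 1])
    r <- node_min(merge[i, 2])
    if (r < l) {
      merge[i, ] <- merge[i, 2:1]
      minid[i] <- r
    } else minid[i] <- l
  }
  flatten <- function(j) {
    if (j < 0) return(-j)
    c(flatten(merge[j, 1]), flatten(merge[j, 2]))
  }
  list(merge = merge, order = flatten(n1))
}

#' Average-linkage hierarchical clustering of sample ratio profiles
#'
#' Computes pairwise Euclidean distances between sample columns and
#' agglomerates with average linkage (UPGMA). The leaf order is made
#' deterministic (independent of input order): at every merge the subtree
#' containing the lexicographically smallest sample id is placed on the left.
#'
#' @param ratios a `ratio_matrix`, or a plain numeric matrix (features x
#'   samples).
#' @param samples optional sample ids to cluster; default all columns.
#' @return object of class `cluster_result`: `distance_matrix`, `merges`
#'   (data frame left/right/height in `stats::hclust` node convention,
#'   negative entries are leaves), `leaf_order` (sample ids), `labels`, and
#'   the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(ratios, samples = NULL) {
  m <- if (inherits(ratios, "ratio_matrix")) ratios$ratios else ratios
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 samples to cluster")
  d <- stats::dist(t(m))
  hc <- stats::hclust(d, method = "average")
  can <- canonical_leaf_order(hc$merge, hc$labels)
  hc$merge <- can$merge
  hc$order <- can$order
  structure(list(distance_matrix = as.matrix(d),
                 merges = data.frame(left = hc$merge[, 1],
                                     right = hc$merge[, 2],
                                     height = hc$height),
                 leaf_order = hc$labels[hc$order],
                 labels = hc$labels, hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(x$labels), " samples, average linkage on ",
      "Euclidean distance\nleaf order: ",
      paste(x$leaf_order, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Plot the dendrogram of a cluster result
#'
#' @param x a `cluster_result`.
#' @param ... passed to [plot.hclust()].
#' @export
plot.cluster_result <- function(x, ...) {
  plot(x$hclust, ...)
}

#' Pre/post leaf-adjacency score
#'
#' Fraction of subjects whose baseline and post-treatment samples occupy
#' adjacent positions in the dendrogram's leaf order — the strict reading of
#' "each treated patient clusters next to their own baseline profile".
#'
#' @param result a `cluster_result`.
#' @param pairs data frame with columns `subject_id`, `pre`, `post` (sample
#'   ids), or a named list `subject -> c(pre, post)`.
#' @return list of class `adjacency_report`: `per_subject` (named logical)
#'   and `adjacency_fraction`.
#' @export
adjacency_score <- function(result, pairs) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(subject_id = names(pairs),
                        pre = vapply(pairs, `[`, "", 1),
                        post = vapply(pairs, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  pos_pre <- match(pairs$pre, result$leaf_order)
  pos_post <- match(pairs$post, result$leaf_order)
  bad <- is.na(pos_pre) | is.na(pos_post)
  if (any(bad)) {
    stop("samples missing from leaf order for subject(s): ",
         paste(pairs$subject_id[bad], collapse = ", "))
  }
  adj <- abs(pos_pre - pos_post) == 1
  names(adj) <- pairs$subject_id
  structure(list(per_subject = adj, adjacency_fraction = mean(adj)),
            class = "adjacency_report")
}

#' @export
print.adjacency_report <- function(x, ...) {
  cat("adjacency_report: ", sum(x$per_subject), "/", length(x$per_subject),
      " subjects with adjacent pre/post leaves (fraction ",
      format(x$adjacency_fraction, digits = 3), ")\n", sep = "")
  invisible(x)
}

# flag rule on per-sample SDs: patient sd above mean + k * sd of control SDs
het_flag <- function(control_sds, patient_sds, flag_k) {
  thr <- mean(control_sds) + flag_k * stats::sd(control_sds)
  list(threshold = thr, flagged = names(patient_sds)[patient_sds > thr])
}

#' Per-sample log2-ratio heterogeneity analysis
#'
#' Scores each sample by the standard deviation, over the assessed genes, of
#' its log2 ratio to the per-gene control reference (the mean log2 value over
#' control samples; leave-self-out when scoring a control). A patient is
#' flagged as heterogeneous when its SD exceeds the mean plus `flag_k`
#' standard deviations of the control sample SDs.
#'
#' @param em a log2-scale `expr_matrix`.
#' @param controls,patients sample ids of the two sets (>= 3 controls).
#' @param flag_k flag multiplier; default 2.
#' @param genes gene subset; default the assessed probes (all probes when no
#'   activity mask is available).
#' @return object of class `het_report`: `sample_sd` (data frame sample_id,
#'   sd_log2_ratio, set), `control_mean`, `control_sd`, `threshold`,
#'   `flagged`.
#' @export
per_sample_heterogeneity <- function(em, controls, patients, flag_k = 2,
                                     genes = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale == "raw") stop("normalize the matrix first")
  if (length(controls) < 3) stop("need >= 3 control samples")
  if (is.null(genes)) {
    genes <- if (length(em$assessed)) em$assessed else rownames(em$values)
  }
  v <- em$values[genes, , drop = FALSE]
  ref <- rowMeans(v[, controls, drop = FALSE])
  sd_pat <- vapply(patients, function(s) stats::sd(v[, s] - ref), 0)
  sd_ctl <- vapply(controls, function(s) {
    loo <- rowMeans(v[, setdiff(controls, s), drop = FALSE])
    stats::sd(v[, s] - loo)
  }, 0)
  fl <- het_flag(sd_ctl, sd_pat, flag_k)
  structure(list(
    sample_sd = data.frame(
      sample_id = c(controls, patients),
      sd_log2_ratio = c(unname(sd_ctl), unname(sd_pat)),
      set = rep(c("control", "patient"),
                c(length(controls), length(patients))),
      stringsAsFactors = FALSE),
    control_mean = mean(sd_ctl), control_sd = stats::sd(sd_ctl),
    threshold = fl$threshold, flagged = fl$flagged, flag_k = flag_k),
    class = "het_report")
}

#' @export
print.het_report <- function(x, ...) {
  cat("het_report: ", sum(x$sample_sd$set == "patient"), " patients vs ",
      sum(x$sample_sd$set == "control"), " controls; threshold ",
      format(x$threshold, digits = 3), " (mean + ", x$flag_k,
      " sd of control SDs)\nflagged: ",
      if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
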