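# Normalization and differential expression: log2-quantile normalization,
# Bayesian-regularized (Cyber-t) unpaired test, paired t, fold changes,
# threshold-grid counting, CRP tertile contrast.

#' Cyber-t configuration
#'
#' @param window_size odd positive count: number of genes (by mean log2
#'   expression rank) whose variances form the local background estimate.
#' @param confidence weight (pseudo-observations) given to the background
#'   variance in the regularized variance.
#' @return list of class `cybert_config`.
#' @export
cybert_config <- function(window_size = 101, confidence = 10) {
  if (window_size < 1 || window_size %% 2 != 1) {
    stop("window_size must be an odd positive count")
  }
  if (confidence <= 0) stop("confidence must be > 0")
  structure(list(window_size = window_size, confidence = confidence),
            class = "cybert_config")
}

# quantile normalization with the declared tie rule: tied values receive the
# mean of the reference values their tied ranks span
quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    s <- x[o, j]
    run <- cumsum(c(TRUE, diff(s) != 0))
    out[o, j] <- stats::ave(ref, run)
  }
  out
}

#' Log2-quantile normalization
#'
#' Log2-transforms a raw expression matrix and quantile-normalizes it: each
#' sample's sorted values are replaced by the across-sample mean of values at
#' the same rank; tied values receive the mean of the reference values their
#' tied ranks span. Afterwards every sample holds the identical multiset of
#' values (exactly so in the absence of ties).
#'
#' @param em an `expr_matrix` on the raw scale with all values > 0.
#' @return the `expr_matrix` with normalized values and scale
#'   `"log2-quantile"`.
#' @export
log2_quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "raw") stop("expected an expr_matrix on the raw scale")
  bad <- which(em$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("nonpositive intensity at probe ", rownames(em$values)[bad[1, 1]],
         ", sample ", colnames(em$values)[bad[1, 2]])
  }
  em$values <- quantile_normalize(log2(em$values))
  em$scale <- "log2-quantile"
  em
}

# truncated running mean over a sorted sequence
running_mean <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  cs <- cumsum(v)
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Bayesian-regularized (Cyber-t) unpaired test
#'
#' Two-sample test on log2 expression with gene-wise variance regularized
#' toward a local background: genes are ordered by mean log2 expression, the
#' background variance `sigma0^2` of a gene is the mean pooled sample
#' variance over the `window_size` nearest genes in that order (window
#' truncated at the ends), and the regularized pooled variance is
#' `(confidence * sigma0^2 + (nA-1) sA^2 + (nB-1) sB^2) /
#'  (confidence + nA + nB - 2)`,
#' which reduces exactly to the ordinary pooled variance as
#' `confidence -> 0`. The statistic is the two-sample t with this variance;
#' two-sided p-values use `nA + nB - 2 + 2 * confidence - 2` degrees of
#' freedom. Genes whose background window has zero variance fall back to the
#' smallest positive gene variance (logged).
#'
#' @param values_a,values_b numeric matrices (genes x samples, same genes,
#'   >= 2 samples each) of log2 expression; vectors are treated as one gene.
#' @param cfg a [cybert_config()].
#' @return data frame: gene_id, fold_change (`2^(meanA - meanB)`), p_value,
#'   t_reg, mean_log2_A, mean_log2_B, test.
#' @export
cybert_unpaired <- function(values_a, values_b, cfg = cybert_config()) {
  if (is.vector(values_a)) values_a <- matrix(values_a, nrow = 1)
  if (is.vector(values_b)) values_b <- matrix(values_b, nrow = 1)
  stopifnot(nrow(values_a) == nrow(values_b))
  na <- ncol(values_a)
  nb <- ncol(values_b)
  if (na < 2 || nb < 2) stop("need >= 2 samples per group")
  g <- nrow(values_a)
  if (cfg$window_size > g) {
    stop("window_size (", cfg$window_size, ") exceeds the number of tested ",
         "genes (", g, "); lower window_size")
  }
  ids <- rownames(values_a)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(g))

  ma <- rowMeans(values_a)
  mb <- rowMeans(values_b)
  va <- rowSums((values_a - ma)^2) / (na - 1)
  vb <- rowSums((values_b - mb)^2) / (nb - 1)
  pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)

  rank_stat <- (na * ma + nb * mb) / (na + nb)
  o <- order(rank_stat)
  sigma0 <- numeric(g)
  sigma0[o] <- running_mean(pooled[o], cfg$window_size)
  if (any(sigma0 == 0)) {
    pos <- pooled[pooled > 0]
    if (length(pos)) {
      message(sum(sigma0 == 0), " gene(s) with zero background variance; ",
              "falling back to smallest positive gene variance")
      sigma0[sigma0 == 0] <- min(pos)
    }
  }

  conf <- cfg$confidence
  reg <- (conf * sigma0 + (na - 1) * va + (nb - 1) * vb) /
    (conf + na + nb - 2)
  se <- sqrt(reg * (1 / na + 1 / nb))
  t_reg <- ifelse(se > 0, (ma - mb) / se, 0)
  df <- na + nb - 2 + 2 * conf - 2
  p <- 2 * stats::pt(-abs(t_reg), df)
  data.frame(gene_id = ids, fold_change = 2^(ma - mb), p_value = p,
             t_reg = t_reg, mean_log2_A = ma, mean_log2_B = mb,
             test = "cybert_unpaired", stringsAsFactors = FALSE)
}

#' Paired t-test per gene
#'
#' Standard paired t on per-subject differences (post - pre), two-sided.
#' Zero-variance differences yield p = 1 when the mean difference is 0 and
#' p = 0 otherwise (logged as degenerate).
#'
#' @param values_pre,values_post numeric matrices (genes x subjects, columns
#'   matched by subject); vectors are treated as one gene.
#' @return data frame: gene_id, fold_change (`2^(mean post - mean pre)`),
#'   p_value, t, mean_log2_A (post), mean_log2_B (pre), test.
#' @export
paired_t <- function(values_pre, values_post) {
  if (is.vector(values_pre)) values_pre <- matrix(values_pre, nrow = 1)
  if (is.vector(values_post)) values_post <- matrix(values_post, nrow = 1)
  stopifnot(dim(values_pre)[2] == dim(values_post)[2],
            nrow(values_pre) == nrow(values_post))
  n <- ncol(values_pre)
  if (n < 2) stop("need >= 2 matched pairs")
  d <- values_post - values_pre
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1))
  tt <- ifelse(sdd > 0, md / (sdd / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(-abs(tt), n - 1)
  degen <- sdd == 0
  if (any(degen)) {
    message(sum(degen), " gene(s) with zero-variance differences ",
            "(degenerate paired test)")
    p[degen] <- ifelse(md[degen] == 0, 1, 0)
    tt[degen] <- ifelse(md[degen] == 0, 0, Inf * sign(md[degen]))
  }
  ids <- rownames(values_pre)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(values_pre)))
  data.frame(gene_id = ids,
             fold_change = 2^(rowMeans(values_post) - rowMeans(values_pre)),
             p_value = p, t = tt,
             mean_log2_A = rowMeans(values_post),
             mean_log2_B = rowMeans(values_pre),
             test = "paired_t", stringsAsFactors = FALSE)
}

#' Linear fold change from group mean log2 values
#'
#' @param mean_log2_a,mean_log2_b group means on the log2 scale.
#' @return `2^(mean_log2_a - mean_log2_b)`.
#' @export
fold_change <- function(mean_log2_a, mean_log2_b) {
  2^(mean_log2_a - mean_log2_b)
}

#' Append a Benjamini-Hochberg FDR column
#'
#' Optional: the primary outputs deliberately carry no multiple-testing
#' correction (matching the small-cohort design the pipeline targets).
#'
#' @param de a differential-expression table with a `p_value` column.
#' @return the table with an `fdr` column.
#' @export
add_fdr <- function(de) {
  de$fdr <- stats::p.adjust(de$p_value, method = "BH")
  de
}

#' Threshold-grid counts of differentially expressed genes
#'
#' Counts genes in the seven cells of the significance/fold-change grid, with
#' strict inequalities throughout: p<0.05, p<0.01, p<0.001, p<0.0001,
#' p<0.05 & FC<0.74 or >1.35, p<0.001 & FC<0.82 or >1.2, and
#' p<0.0001 & FC<0.91 or >1.1.
#'
#' @param de data frame with `p_value` and `fold_change` columns.
#' @return named integer vector of class `threshold_grid`.
#' @export
threshold_count_table <- function(de) {
  p <- de$p_value
  fc <- de$fold_change
  cells <- c(
    "p<0.05" = sum(p < 0.05),
    "p<0.01" = sum(p < 0.01),
    "p<0.001" = sum(p < 0.001),
    "p<0.0001" = sum(p < 0.0001),
    "p<0.05 & FC<0.74 or >1.35" = sum(p < 0.05 & (fc < 0.74 | fc > 1.35)),
    "p<0.001 & FC<0.82 or >1.2" = sum(p < 0.001 & (fc < 0.82 | fc > 1.2)),
    "p<0.0001 & FC<0.91 or >1.1" = sum(p < 0.0001 & (fc < 0.91 | fc > 1.1)))
  structure(as.integer(cells), names = names(cells),
            class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat("threshold_grid (strict inequalities):\n")
  for (i in seq_along(x)) cat(sprintf("  %-28s %d\n", names(x)[i], x[i]))
  invisible(x)
}

#' Cyber-t contrast between two sample sets of an expression matrix
#'
#' @param em a normalized (`log2-quantile`) `expr_matrix`.
#' @param samples_a,samples_b sample ids of the two groups (A vs B;
#'   fold changes are A/B).
#' @param genes gene subset; default the assessed probes of the groups'
#'   activity columns (all assessed probes when `NULL`).
#' @param cfg a [cybert_config()]; the window is capped at the largest odd
#'   number of tested genes when fewer genes than `window_size` are tested.
#' @return a differential-expression data frame (see [cybert_unpaired()]).
#' @export
cybert_contrast <- function(em, samples_a, samples_b, genes = NULL,
                            cfg = cybert_config()) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale == "raw") stop("normalize the matrix first")
  if (is.null(genes)) genes <- em$assessed
  if (!length(genes)) stop("no assessed genes to test")
  w <- min(cfg$window_size, length(genes))
  if (w %% 2 == 0) w <- w - 1
  cfg <- cybert_config(w, cfg$confidence)
  cybert_unpaired(em$values[genes, samples_a, drop = FALSE],
                  em$values[genes, samples_b, drop = FALSE], cfg)
}

#' Paired pre/post contrast of an expression matrix
#'
#' @param em a normalized `expr_matrix`.
#' @param pre_samples,post_samples sample ids matched position-wise by
#'   subject.
#' @param genes gene subset; default the probes active before and/or after
#'   treatment (union of the `treated.pre` and `treated.post` activity
#'   columns when present, else all assessed probes).
#' @return a differential-expression data frame (see [paired_t()]).
#' @export
paired_contrast <- function(em, pre_samples, post_samples, genes = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale == "raw") stop("normalize the matrix first")
  if (is.null(genes)) {
    gn <- intersect(c("treated.pre", "treated.post"),
                    colnames(em$group_active))
    genes <- if (length(gn)) assessed_probes(em, gn) else em$assessed
  }
  if (!length(genes)) stop("no assessed genes to test")
  paired_t(em$values[genes, pre_samples, drop = FALSE],
           em$values[genes, post_samples, drop = FALSE])
}

#' CRP tertile contrast against controls
#'
#' Sorts baseline patients by CRP level (ties broken by sample id), splits
#' them into tertiles of size `floor(n/3)` (logged when n is not divisible by
#' 3), and tests the lowest and highest tertiles each against all baseline
#' controls with the Cyber-t test on the assessed gene set; the middle
#' tertile is left out.
#'
#' @param em a normalized `expr_matrix` whose `sample_meta` carries `group`,
#'   `timepoint` and `crp`.
#' @param cfg a [cybert_config()].
#' @param genes gene subset; default the baseline assessed set.
#' @return list with `grid_low`, `grid_high` ([threshold_count_table()] of
#'   each contrast), the two DE tables `de_low`, `de_high`, and the tertile
#'   sample ids.
#' @export
crp_tertile_contrast <- function(em, cfg = cybert_config(), genes = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  meta <- em$sample_meta
  pat <- meta[meta$group == "patient" & meta$timepoint == "baseline", ,
              drop = FALSE]
  ctl <- meta$sample_id[meta$group == "control" &
                          meta$timepoint == "baseline"]
  if (anyNA(pat$crp)) {
    stop("missing CRP for samples: ",
         paste(pat$sample_id[is.na(pat$crp)], collapse = ", "))
  }
  n <- nrow(pat)
  size <- floor(n / 3)
  if (size < 2) stop("too few patients for tertiles")
  if (n %% 3 != 0) message("patient count ", n, " not divisible by 3; ",
                           "tertile size ", size)
  o <- order(pat$crp, pat$sample_id)
  low <- pat$sample_id[o][seq_len(size)]
  high <- pat$sample_id[o][seq(n - size + 1, n)]
  if (is.null(genes)) {
    gn <- intersect(c("control.baseline", "patient.baseline"),
                    colnames(em$group_active))
    genes <- if (length(gn)) assessed_probes(em, gn) else em$assessed
  }
  de_low <- cybert_contrast(em, low, ctl, genes, cfg)
  de_high <- cybert_contrast(em, high, ctl, genes, cfg)
  list(grid_low = threshold_count_table(de_low),
       grid_high = threshold_count_table(de_high),
       de_low = de_low, de_high = de_high,
       tertile_low = low, tertile_high = high)
}
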