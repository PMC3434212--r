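make_study <- function(df) {
  structure(df, class = c("qpcr_study", "data.frame"))
}

test_that("replicate QC drops low-quality curves and averages the rest", {
  st <- make_study(data.frame(
    sample_id = "s1", gene = "IL8", replicate = 1:3,
    ct = c(20.0, 20.2, 20.4), quality = c(0.9, 0.9, 0.9),
    stringsAsFactors = FALSE))
  agg <- qc_and_aggregate(st)
  expect_equal(agg$ct, 20.2)
  expect_equal(agg$n_replicates, 3L)

  st$quality <- c(0.9, 0.5, 0.9)
  agg <- qc_and_aggregate(st)
  expect_equal(agg$ct, 20.2)
  expect_equal(agg$n_replicates, 2L)

  st$quality <- c(0.3, 0.3, 0.3)
  expect_message(agg <- qc_and_aggregate(st), "lost all replicates")
  expect_equal(nrow(agg), 0)

  # boundary: quality exactly at the threshold is kept
  st$quality <- c(0.65, 0.2, 0.2)
  agg <- qc_and_aggregate(st)
  expect_equal(agg$ct, 20.0)
})

test_that("a gene losing every replicate is unmeasurable downstream", {
  df <- expand.grid(sample_id = paste0("s", 1:6), gene = c("IL8", "GAPDH"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  df$ct <- 25 + rnorm(nrow(df), 0, 0.01)
  df$quality <- ifelse(df$gene == "IL8", 0.2, 0.9)
  agg <- suppressMessages(qc_and_aggregate(make_study(df)))
  r <- suppressMessages(ddct(agg, "IL8", "GAPDH", paste0("s", 1:3),
                             paste0("s", 4:6)))
  expect_true(r$low_confidence)
  expect_true(is.na(r$fold_change))
})

test_that("geNorm M is zero for proportional candidates", {
  # q_j = c * q_k across samples: constant log-ratio, sd 0
  q <- cbind(a = c(1, 2, 4), b = c(2, 4, 8))
  m <- genorm_m(q)
  expect_equal(unname(m), c(0, 0))

  # a candidate perturbed by independent noise has the largest M
  set.seed(71)
  wins <- 0
  for (s in 1:20) {
    base <- 2^rnorm(10, 0, 1)
    q <- cbind(a = base, b = base * 2^rnorm(10, 0, 0.05),
               c = base * 2^rnorm(10, 0, 0.8))
    wins <- wins + (names(which.max(genorm_m(q))) == "c")
  }
  expect_gte(wins, 19)

  expect_error(genorm_m(cbind(a = c(1, -1), b = c(1, 2))), "positive")
})

test_that("NormFinder ranks a sample-mean tracker best, a shifted gene worst", {
  set.seed(73)
  n <- 20
  grp <- rep(c("A", "B"), each = 10)
  x <- matrix(rnorm(n * 3, 0, 0.4), n, 3,
              dimnames = list(NULL, c("hk1", "hk2", "hk3")))
  # candidate tracking the per-sample candidate mean exactly: stability ~ 0
  x <- cbind(x, tracker = rowMeans(x) * 4 - rowSums(x))
  # tracker satisfies: tracker = rowmean of all four candidates
  expect_equal(rowMeans(x), x[, "tracker"], tolerance = 1e-12)
  st <- normfinder_stability(x, grp)
  expect_equal(names(which.min(st)), "tracker")
  expect_lt(st["tracker"], 1e-9)

  # planted one-cycle group shift: largest stability
  y <- matrix(rnorm(n * 4, 0, 0.3), n, 4,
              dimnames = list(NULL, paste0("hk", 1:4)))
  y[grp == "B", 2] <- y[grp == "B", 2] + 1
  st2 <- normfinder_stability(y, grp)
  expect_equal(names(which.max(st2)), "hk2")

  # permutation invariance
  perm <- sample(n)
  st3 <- normfinder_stability(y[perm, ], grp[perm])
  expect_equal(st2, st3, tolerance = 1e-12)

  # single group falls back to intragroup-only variation
  expect_message(st4 <- normfinder_stability(y, rep("A", n)),
                 "single group")
  expect_length(st4, 4)
})

test_that("stability measures are invariant to consistent global Ct shifts", {
  set.seed(79)
  n <- 16
  grp <- rep(c("A", "B"), each = 8)
  ct <- matrix(rnorm(n * 4, 25, 0.5), n, 4,
               dimnames = list(NULL, paste0("hk", 1:4)))
  q1 <- apply(ct, 2, function(col) 2^-(col - min(col)))
  ct2 <- ct + 3  # same shift for every candidate and sample
  q2 <- apply(ct2, 2, function(col) 2^-(col - min(col)))
  expect_equal(genorm_m(q1), genorm_m(q2), tolerance = 1e-12)
  expect_equal(normfinder_stability(log2(q1), grp),
               normfinder_stability(log2(q2), grp), tolerance = 1e-12)
})

test_that("ddct matches the hand-worked example and identities", {
  agg <- data.frame(
    sample_id = rep(paste0("s", 1:6), 2),
    gene = rep(c("IL8", "GAPDH"), each = 6),
    ct = c(25 + c(5.0, 5.2, 5.4, 6.0, 6.2, 6.4), rep(25, 6)),
    n_replicates = 3L, stringsAsFactors = FALSE)
  r <- ddct(agg, "IL8", "GAPDH", paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(r$ddct, -1)
  expect_equal(r$fold_change, 2)
  expect_equal(r$p_value, t.test(c(5.0, 5.2, 5.4),
                                 c(6.0, 6.2, 6.4))$p.value,
               tolerance = 1e-12)
  expect_equal(r$p_value, 0.003602, tolerance = 1e-3)

  # reciprocality under group swap
  r2 <- ddct(agg, "IL8", "GAPDH", paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(r$fold_change * r2$fold_change, 1)

  # identical delta-Ct distributions: ddCt 0, fold 1
  agg2 <- agg
  agg2$ct[1:6] <- 30
  r3 <- ddct(agg2, "IL8", "GAPDH", paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(r3$fold_change, 1)
  expect_equal(r3$p_value, 1)

  # missing reference is an error naming the samples
  agg3 <- agg[agg$gene == "IL8" | agg$sample_id != "s2", ]
  expect_error(ddct(agg3, "IL8", "GAPDH", paste0("s", 1:3),
                    paste0("s", 4:6)), "s2")
})

test_that("paired ddct aligns matched samples", {
  agg <- data.frame(
    sample_id = rep(paste0("s", 1:6), 2),
    gene = rep(c("IL8", "GAPDH"), each = 6),
    ct = c(24, 24.5, 25, 23.2, 23.6, 24.4, rep(20, 6)),
    n_replicates = 3L, stringsAsFactors = FALSE)
  # groups aligned position-wise: (s1,s4), (s2,s5), (s3,s6)
  r <- ddct(agg, "IL8", "GAPDH", paste0("s", 4:6), paste0("s", 1:3),
            paired = TRUE)
  diffs <- c(23.2 - 24, 23.6 - 24.5, 24.4 - 25)
  expect_equal(r$ddct, mean(diffs))
  expect_equal(r$p_value, t.test(diffs)$p.value, tolerance = 1e-12)
  expect_equal(r$test, "paired_t")
})

test_that("both criteria select the designed reference on simulated plates", {
  cfg <- tiny_config(seed = 83)
  co <- generate_cohort(cfg)
  st <- generate_qpcr(cfg, co)
  agg <- suppressMessages(qc_and_aggregate(st))
  base <- attr(st, "meta")
  base <- base[base$timepoint == "baseline", ]
  agg_b <- agg[agg$sample_id %in% base$sample_id, ]
  for (a in c("housekeeping_candidates", "designed_stable", "targets")) {
    attr(agg_b, a) <- attr(st, a)
  }
  attr(agg_b, "meta") <- base
  sr <- suppressWarnings(stability_ranking(agg_b))
  expect_equal(sr$selected_reference, attr(st, "designed_stable"))
  expect_s3_class(sr, "stability_ranking")
  expect_named(sr$table, c("gene", "genorm_m", "normfinder_stability"))
})

test_that("array and qPCR fold changes are sign-concordant for planted genes", {
  set.seed(89)
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_probes = 300, n_neg_controls = 40,
                      beads_per_probe = 8, n_de_genes = 20,
                      de_fc_range = c(0.4, 2.5), rng_seed = 400 + s)
    co <- generate_cohort(cfg)
    em <- normalized_matrix(co)
    de <- suppressMessages(cybert_contrast(
      em, em$groups$patient.baseline, em$groups$control.baseline,
      cfg = cybert_config(51, 10)))
    st <- generate_qpcr(cfg, co)
    agg <- suppressMessages(qc_and_aggregate(st))
    m <- co$meta
    for (g in attr(st, "targets")) {
      if (!g %in% de$gene_id) next
      r <- ddct(agg, g, "GAPDH",
                m$sample_id[m$group == "patient" & m$timepoint == "baseline"],
                m$sample_id[m$group == "control"])
      arr_fc <- de$fold_change[de$gene_id == g]
      total <- total + 1
      hits <- hits + ((arr_fc > 1) == (r$fold_change > 1))
    }
  }
  expect_gte(hits / total, 0.9)
})
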