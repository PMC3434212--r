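test_that("log2-quantile normalization matches worked examples", {
  # one sample: pure log2 transform
  v <- matrix(c(2, 8, 32), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  em <- make_em(v, scale = "raw")
  out <- log2_quantile_normalize(em)
  expect_equal(unname(out$values[, 1]), c(1, 3, 5))
  expect_equal(out$scale, "log2-quantile")

  # two samples with aligned log2 ranks: rank-wise means (1.5, 2.5, 3.5)
  v <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
  rownames(v) <- paste0("g", 1:3)
  out <- log2_quantile_normalize(make_em(v, scale = "raw"))
  expect_equal(unname(out$values[, "s1"]), c(1.5, 2.5, 3.5))
  expect_equal(unname(out$values[, "s2"]), c(1.5, 2.5, 3.5))

  expect_error(log2_quantile_normalize(make_em(cbind(s1 = c(1, -2)),
                                               scale = "raw")),
               "nonpositive")
})

test_that("normalized samples share one value multiset; ties span ranks", {
  set.seed(17)
  for (i in 1:25) {
    v <- matrix(2^rnorm(40 * 4, 8, 2), 40, 4,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:4)))
    out <- log2_quantile_normalize(make_em(v, scale = "raw"))
    ref <- unname(sort(out$values[, 1]))
    for (j in 2:4) expect_equal(unname(sort(out$values[, j])), ref)
    # rank order preserved within each sample
    for (j in 1:4) expect_equal(order(out$values[, j]), order(v[, j]))
  }

  # agreement with the limma implementation on tie-free data
  skip_if_not_installed("limma")
  set.seed(18)
  v <- matrix(2^rnorm(200 * 5, 8, 1.5), 200, 5)
  mine <- log2_quantile_normalize(
    make_em(`dimnames<-`(v, list(sprintf("g%03d", 1:200),
                                 paste0("s", 1:5))), scale = "raw"))
  ref <- limma::normalizeQuantiles(log2(v))
  expect_equal(unname(mine$values), unname(ref), tolerance = 1e-10)

  # tie rule: tied values receive the mean of the spanned reference values
  v <- cbind(s1 = c(2, 2, 8), s2 = c(2, 4, 8))
  rownames(v) <- paste0("g", 1:3)
  out <- log2_quantile_normalize(make_em(v, scale = "raw"))
  # log2 matrices: s1 = (1,1,3), s2 = (1,2,3); ref = (1, 1.5, 3)
  expect_equal(unname(out$values[, "s1"]), c(1.25, 1.25, 3))
  expect_equal(unname(out$values[, "s2"]), c(1, 1.5, 3))
})

test_that("Cyber-t reduces to the pooled t-test in the zero-confidence limit", {
  set.seed(23)
  g <- 300
  a <- matrix(rnorm(g * 6, 8, 1), g, 6,
              dimnames = list(sprintf("g%03d", 1:g), NULL))
  b <- matrix(rnorm(g * 8, 8, 1), g, 8,
              dimnames = list(sprintf("g%03d", 1:g), NULL))
  de <- cybert_unpaired(a, b, cybert_config(101, 1e-9))
  # ordinary pooled two-sample t, computed independently
  tt <- sapply(seq_len(g), function(i) {
    na <- 6; nb <- 8
    sp2 <- ((na - 1) * var(a[i, ]) + (nb - 1) * var(b[i, ])) / (na + nb - 2)
    (mean(a[i, ]) - mean(b[i, ])) / sqrt(sp2 * (1 / na + 1 / nb))
  })
  expect_lt(max(abs(de$t_reg - tt)), 1e-6)
})

test_that("Cyber-t input validation and degenerate genes behave", {
  a <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  b <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(cybert_unpaired(a, b, cybert_config(7, 10)), "window_size")
  expect_error(cybert_config(4, 10), "odd")
  expect_error(cybert_config(5, 0), "confidence")

  # a constant gene among noisy neighbours: t_reg = 0 on zero mean diff
  a[3, ] <- 5
  b[3, ] <- 5
  de <- cybert_unpaired(a, b, cybert_config(5, 10))
  expect_equal(de$t_reg[3], 0)
  expect_equal(de$p_value[3], 1)
})

test_that("paired t matches the hand-computed example and degenerate rules", {
  # diffs (1,1,2,2): mean 1.5, sd 0.57735, t = 5.196, p ~ 0.0138
  de <- paired_t(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(de$t, 5.196152, tolerance = 1e-6)
  expect_equal(de$p_value, 0.0138, tolerance = 1e-2)
  expect_equal(de$p_value, t.test(c(2, 3, 5, 6), c(1, 2, 3, 4),
                                  paired = TRUE)$p.value, tolerance = 1e-10)

  # post == pre: t = 0, p = 1
  de <- suppressMessages(paired_t(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(de$t, 0)
  expect_equal(de$p_value, 1)

  # constant nonzero differences: degenerate, p = 0
  de <- suppressMessages(paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  expect_equal(de$p_value, 0)
})

test_that("fold change follows the log2 convention and is reciprocal", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(6, 5), 2)
  expect_equal(fold_change(5, 6.75), 0.2973018, tolerance = 1e-6)
  set.seed(29)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(fold_change(a, b) * fold_change(b, a), rep(1, 50))
})

test_that("threshold grid reproduces hand-computed counts", {
  de <- grid_fixture()
  g <- threshold_count_table(de)
  expect_equal(unname(g[1:4]), c(15L, 9L, 6L, 3L))
  expect_equal(unname(g[5:7]), c(4L, 2L, 2L))
  # strict boundaries: p = 0.05 exactly counts nowhere
  g1 <- threshold_count_table(data.frame(p_value = 0.05, fold_change = 1.4))
  expect_true(all(g1 == 0))
  g0 <- threshold_count_table(data.frame(p_value = numeric(0),
                                         fold_change = numeric(0)))
  expect_true(all(g0 == 0))
  # single gene p = 0.04, FC = 1.4
  g2 <- threshold_count_table(data.frame(p_value = 0.04, fold_change = 1.4))
  expect_equal(unname(g2), c(1L, 0L, 0L, 0L, 1L, 0L, 0L))
  # pure-p column is non-increasing for random tables
  set.seed(3)
  for (i in 1:20) {
    gg <- threshold_count_table(data.frame(p_value = runif(100)^2,
                                           fold_change = 2^rnorm(100)))
    expect_true(all(diff(gg[1:4]) <= 0))
  }
})

test_that("BH column is available but optional", {
  de <- grid_fixture()
  de2 <- add_fdr(de)
  expect_equal(de2$fdr, p.adjust(de$p_value, "BH"))
  expect_false("fdr" %in% names(de))
})

test_that("CRP tertiles split 18 patients into 6/6/6 and test vs controls", {
  set.seed(37)
  n_g <- 60
  ids <- sprintf("g%02d", 1:n_g)
  ctl <- paste0("C", 1:12); pat <- paste0("S", 1:18)
  v <- matrix(rnorm(n_g * 30, 8, 1), n_g, 30,
              dimnames = list(ids, c(ctl, pat)))
  meta <- data.frame(sample_id = c(ctl, pat),
                     subject_id = c(ctl, pat),
                     group = rep(c("control", "patient"), c(12, 18)),
                     timepoint = "baseline", treated = 0L,
                     crp = c(rep(NA, 12), seq(1, 52, length.out = 18)),
                     stringsAsFactors = FALSE)
  em <- make_em(v, meta)
  res <- crp_tertile_contrast(em, cybert_config(21, 10))
  expect_length(res$tertile_low, 6)
  expect_length(res$tertile_high, 6)
  expect_equal(res$tertile_low, paste0("S", 1:6))
  expect_equal(res$tertile_high, paste0("S", 13:18))
  expect_s3_class(res$grid_low, "threshold_grid")

  meta$crp[13] <- NA
  expect_error(crp_tertile_contrast(make_em(v, meta)), "missing CRP")
})

test_that("a CRP-linked signal yields more high-tertile DE than low", {
  set.seed(43)
  wins <- 0
  for (s in 1:20) {
    n_g <- 80
    ids <- sprintf("g%02d", 1:n_g)
    ctl <- paste0("C", 1:12); pat <- paste0("S", 1:18)
    v <- matrix(rnorm(n_g * 30, 8, 0.5), n_g, 30,
                dimnames = list(ids, c(ctl, pat)))
    crp <- seq(1, 52, length.out = 18)
    # plant a shift on 15 genes in the 6 highest-CRP patients only
    high <- paste0("S", 13:18)
    v[1:15, high] <- v[1:15, high] + 1
    meta <- data.frame(sample_id = c(ctl, pat), subject_id = c(ctl, pat),
                       group = rep(c("control", "patient"), c(12, 18)),
                       timepoint = "baseline", treated = 0L,
                       crp = c(rep(NA, 12), crp), stringsAsFactors = FALSE)
    res <- crp_tertile_contrast(make_em(v, meta), cybert_config(21, 10))
    wins <- wins + (res$grid_high[["p<0.05"]] > res$grid_low[["p<0.05"]])
  }
  expect_gte(wins, 18)
})

test_that("Cyber-t recovers planted effects well above the null rate", {
  set.seed(47)
  n_g <- 600; n_de <- 60
  a <- matrix(rnorm(n_g * 18, 8, sqrt(0.5^2 + 0.3^2)), n_g, 18,
              dimnames = list(sprintf("g%03d", 1:n_g), NULL))
  b <- matrix(rnorm(n_g * 12, 8, sqrt(0.5^2 + 0.3^2)), n_g, 12,
              dimnames = list(sprintf("g%03d", 1:n_g), NULL))
  a[1:n_de, ] <- a[1:n_de, ] + 0.6 * sample(c(-1, 1), n_de, TRUE)
  de <- cybert_unpaired(a, b, cybert_config(101, 10))
  sens <- mean(de$p_value[1:n_de] < 0.05)
  fpr <- mean(de$p_value[-(1:n_de)] < 0.05)
  expect_gte(sens, 5 * max(fpr, 0.01))
})
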