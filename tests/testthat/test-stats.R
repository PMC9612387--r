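# minimal feature table with controllable paired differences
pair_table <- function(tumor, mirrored, feature = "featA",
                       kind = "TTP", phenotype = "isometabolic") {
  n <- length(tumor)
  df <- rbind(
    data.frame(patient_id = sprintf("P%03d", 1:n), phenotype = phenotype,
               voi_label = "tumor", image_kind = kind, n_degenerate = 0L,
               x = tumor),
    data.frame(patient_id = sprintf("P%03d", 1:n), phenotype = phenotype,
               voi_label = "mirrored", image_kind = kind, n_degenerate = 0L,
               x = mirrored))
  names(df)[names(df) == "x"] <- feature
  df
}

test_that("exact two-sided p for ten all-positive unit differences is 2/1024", {
  set.seed(1)
  mir <- rnorm(10)
  tb <- pair_table(mir + 1, mir)
  r <- paired_wilcoxon(tb, "TTP", "all")
  expect_equal(r$p_value, 2 / 1024)
  expect_equal(r$direction, 1)
  expect_equal(r$n_pairs, 10L)
  # oracle: enumerate all 2^10 sign assignments of the rank sum
  ranks <- 1:10
  all_sums <- vapply(0:(2^10 - 1), function(b) {
    sum(ranks[bitwAnd(b, 2^(0:9)) > 0])
  }, numeric(1))
  v_obs <- sum(ranks)
  p_exact <- 2 * mean(all_sums >= v_obs)
  expect_equal(r$p_value, p_exact)
})

test_that("the exact signed-rank p agrees with the reference implementation when ranks are untied", {
  set.seed(17)
  for (i in 1:5) {
    mir <- rnorm(12)
    tum <- mir + rnorm(12, 0.4, 0.6)
    r <- paired_wilcoxon(pair_table(tum, mir), "TTP", "all")
    ref <- stats::wilcox.test(tum, mir, paired = TRUE, exact = TRUE)
    expect_equal(r$p_value, ref$p.value)
    expect_equal(r$statistic, unname(ref$statistic))
  }
})

test_that("all-zero differences are flagged degenerate without a p-value", {
  x <- rnorm(8)
  r <- paired_wilcoxon(pair_table(x, x), "TTP", "all", min_pairs = 5)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_equal(r$direction, 0)
})

test_that("label swap preserves p-values and flips directions; row order is irrelevant", {
  set.seed(2)
  mir <- rnorm(12)
  tum <- mir + rnorm(12, 0.8, 0.3)
  tb <- pair_table(tum, mir)
  r <- paired_wilcoxon(tb, "TTP", "all")
  swapped <- tb
  swapped$voi_label <- ifelse(tb$voi_label == "tumor", "mirrored", "tumor")
  rs <- paired_wilcoxon(swapped, "TTP", "all")
  expect_equal(rs$p_value, r$p_value)
  expect_equal(rs$direction, -r$direction)
  shuffled <- tb[sample(nrow(tb)), ]
  expect_equal(paired_wilcoxon(shuffled, "TTP", "all")$p_value, r$p_value)
})

test_that("the census counts strictly below alpha and reports percentages", {
  # build 93 features: k of them shifted, rest null
  set.seed(3)
  n <- 20
  base <- data.frame(patient_id = rep(sprintf("P%03d", 1:n), 2),
                     phenotype = "isometabolic",
                     voi_label = rep(c("tumor", "mirrored"), each = n),
                     image_kind = "TTP", n_degenerate = 0L)
  for (k in 1:93) {
    shift <- if (k <= 64) 2 else 0
    base[[sprintf("f%02d", k)]] <- rnorm(2 * n) +
      rep(c(shift, 0), each = n)
  }
  for (kind in c("TBR_5_15", "TBR_20_40")) {
    b2 <- base; b2$image_kind <- kind
    base <- rbind(base, b2)
  }
  cen <- significance_census(base, subgroups = "all")
  row_ttp <- cen$census[cen$census$image_kind == "TTP", ]
  expect_gte(row_ttp$n_significant, 64L)
  expect_equal(cen$census$n_features, rep(93L, 3))
  expect_equal(row_ttp$percent, round(100 * row_ttp$n_significant / 93))
  expect_equal(round(100 * 64 / 93), 69)
})

test_that("boundary p-values are not counted as significant", {
  # direct check of the strict < rule used by the census
  p <- c(0.049, 0.05, 0.051)
  expect_equal(sum(p < 0.05), 1L)
  set.seed(4)
  tb <- pair_table(rnorm(6), rnorm(6))
  expect_error(paired_wilcoxon(tb, "TTP", "all", min_pairs = 10), "pairs")
})
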