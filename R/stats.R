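# Exact two-sided signed-rank test on nonzero differences, valid under
# tied |d|: midranks are assigned, and the null distribution of the
# positive-rank sum V over all 2^n sign assignments is built by dynamic
# programming (generating-function convolution), which is equivalent to
# full enumeration. stats::wilcox.test abandons the exact distribution as
# soon as ties occur, which the screening contract does not want.
.signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled midranks: integers
  v_obs <- sum(r2[d > 0])
  tot <- sum(r2)
  dist <- c(1, numeric(tot))                 # counts over V2 = 0..tot
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(tot + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / 2^n
  p_le <- sum(dist[seq_len(v_obs + 1)])
  p_ge <- sum(dist[(v_obs + 1):(tot + 1)])
  list(statistic = v_obs / 2, p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Paired Wilcoxon screening of tumor vs. mirrored background
#'
#' For every feature of one image kind, runs a two-sided Wilcoxon
#' signed-rank test on the per-patient differences (tumor minus mirrored
#' background). Zero differences are dropped (Wilcoxon's convention); for
#' n <= 25 pairs the exact null distribution of the signed-rank sum is
#' used, computed over all 2^n sign assignments so it stays valid when
#' absolute differences tie; larger n uses the normal approximation with
#' continuity correction. No
#' multiple-testing correction is applied to the per-feature p-values (the
#' census reports them as-is); a Benjamini-Hochberg column is added as
#' clearly separated supplementary information.
#'
#' @param table A `feature_table` from [extract_cohort()].
#' @param image_kind One of [image_kinds()].
#' @param subgroup `"all"`, `"isometabolic"` or `"photopenic"`.
#' @param min_pairs Minimum complete pairs required (default 5).
#' @return Data frame with one row per feature: `feature`, `image_kind`,
#'   `subgroup`, `n_pairs`, `statistic` (V), `p_value`, `p_bh`
#'   (Benjamini-Hochberg adjusted, supplementary), `direction` (sign of the
#'   median paired difference) and `degenerate` (TRUE when all differences
#'   are zero and no p-value exists).
#' @export
paired_wilcoxon <- function(table, image_kind = image_kinds(),
                            subgroup = c("all", "isometabolic",
                                         "photopenic"),
                            min_pairs = 5L) {
  image_kind <- match.arg(image_kind)
  subgroup <- match.arg(subgroup)
  sub <- table[table$image_kind == image_kind, ]
  if (subgroup != "all") sub <- sub[sub$phenotype == subgroup, ]
  tum <- sub[sub$voi_label == "tumor", ]
  mir <- sub[sub$voi_label == "mirrored", ]
  tum <- tum[order(tum$patient_id), ]
  mir <- mir[order(mir$patient_id), ]
  if (!identical(tum$patient_id, mir$patient_id)) {
    stop("every patient needs both tumor and mirrored rows")
  }
  if (nrow(tum) < min_pairs) {
    stop(sprintf("need at least %d complete pairs, got %d", min_pairs,
                 nrow(tum)))
  }
  feats <- feature_columns(table)
  res <- lapply(feats, function(fn) {
    d <- tum[[fn]] - mir[[fn]]
    nz <- d[d != 0]
    if (!length(nz)) {
      return(data.frame(feature = fn, image_kind = image_kind,
                        subgroup = subgroup, n_pairs = length(d),
                        statistic = NA_real_, p_value = NA_real_,
                        direction = 0, degenerate = TRUE))
    }
    if (length(nz) <= 25L) {
      wt <- .signed_rank_exact(d)
    } else {
      w <- suppressWarnings(
        stats::wilcox.test(tum[[fn]], mir[[fn]], paired = TRUE,
                           exact = FALSE, correct = TRUE))
      wt <- list(statistic = unname(w$statistic), p_value = w$p.value)
    }
    data.frame(feature = fn, image_kind = image_kind, subgroup = subgroup,
               n_pairs = length(d), statistic = wt$statistic,
               p_value = wt$p_value,
               direction = sign(stats::median(d)), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[c("feature", "image_kind", "subgroup", "n_pairs", "statistic",
        "p_value", "p_bh", "direction", "degenerate")]
}

#' Significant-feature census across image kinds and subgroups
#'
#' Counts features with `p < alpha` (strict) per image kind and cohort
#' subgroup, as absolute numbers and as percentages of the 93-feature
#' profile.
#'
#' @param table A `feature_table`.
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @param subgroups Subgroups to tabulate.
#' @return List with `census` (data frame: `image_kind`, `subgroup`,
#'   `n_significant`, `n_features`, `percent`) and `results` (all
#'   per-feature rows from [paired_wilcoxon()]).
#' @export
significance_census <- function(table, alpha = 0.05,
                                subgroups = c("all", "isometabolic",
                                              "photopenic")) {
  all_res <- list()
  rows <- list()
  for (kind in image_kinds()) {
    for (sg in subgroups) {
      has <- if (sg == "all") TRUE else any(table$phenotype == sg)
      if (!isTRUE(has) && !any(has)) next
      r <- paired_wilcoxon(table, kind, sg)
      all_res[[paste(kind, sg)]] <- r
      nsig <- sum(r$p_value < alpha, na.rm = TRUE)
      rows[[paste(kind, sg)]] <- data.frame(
        image_kind = kind, subgroup = sg, n_significant = nsig,
        n_features = nrow(r), percent = round(100 * nsig / nrow(r)))
    }
  }
  list(census = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = do.call(rbind, c(all_res, list(make.row.names = FALSE))))
}
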