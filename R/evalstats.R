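check_labels <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors differ in length: ", length(truth), " vs ", length(pred))
  if (length(truth) == 0L) stop("empty label vectors")
}

#' Clustering accuracy metrics
#'
#' Three permutation-invariant comparisons of a predicted partition with
#' the ground truth, all computed from the joint contingency table:
#'
#' * `adjusted_rand_index()` — the chance-corrected pair-counting index
#'   (Hubert–Arabie form), in \[-1, 1\], 1 iff the partitions are identical.
#' * `normalized_mutual_information()` — mutual information normalized by
#'   the arithmetic mean of the two marginal entropies, in \[0, 1\].
#' * `homogeneity()` — 1 - H(truth | pred) / H(truth), in \[0, 1\]; equals 1
#'   exactly when every predicted cluster contains members of a single
#'   ground-truth class. Defined as 1 when H(truth) = 0 (single-class
#'   truth, degenerate but total).
#'
#' @param truth,pred Equal-length label vectors (any atomic type; label
#'   identities are irrelevant).
#' @return A single numeric value.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1: same partition
#' homogeneity(c(0, 0, 1, 1), rep(1, 4))              # 0: one big cluster
#' @export
adjusted_rand_index <- function(truth, pred) {
  check_labels(truth, pred)
  as.numeric(mclust::adjustedRandIndex(truth, pred))
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @rdname adjusted_rand_index
#' @export
normalized_mutual_information <- function(truth, pred) {
  check_labels(truth, pred)
  tab <- table(truth, pred)
  n <- sum(tab)
  ht <- entropy_nats(rowSums(tab))
  hp <- entropy_nats(colSums(tab))
  if (ht == 0 && hp == 0) return(1)
  pij <- tab / n
  pi_ <- rowSums(tab) / n
  p_j <- colSums(tab) / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  mi / ((ht + hp) / 2)
}

#' @rdname adjusted_rand_index
#' @export
homogeneity <- function(truth, pred) {
  check_labels(truth, pred)
  tab <- table(truth, pred)
  n <- sum(tab)
  ht <- entropy_nats(rowSums(tab))
  if (ht == 0) return(1)
  # H(truth | pred) = sum_j p(j) H(truth | pred = j)
  hcond <- sum(apply(tab, 2L, function(col) {
    nj <- sum(col)
    if (nj == 0) 0 else nj / n * entropy_nats(col)
  }))
  1 - hcond / ht
}

#' Paired run-wise deltas between two arms
#'
#' The unit of the paired benchmarking design: for each (sample, run) key
#' present in both arms, delta = value_dw - value_ori. Sample-level
#' summaries average the run-wise deltas within each sample.
#'
#' @param ori,dw Data frames with columns `sample_id`, `run_id`, `value`
#'   (and optionally `metric`); the two arms must contain identical
#'   (sample_id, run_id\[, metric\]) key sets.
#' @return A `paired_run_table` data frame with columns `sample_id`,
#'   `run_id` (and `metric` if supplied), `value_ori`, `value_dw`, `delta`.
#' @export
paired_deltas <- function(ori, dw) {
  keys <- intersect(c("sample_id", "run_id", "metric"), names(ori))
  if (!all(c("sample_id", "run_id") %in% keys))
    stop("arm tables need sample_id and run_id columns")
  if (!all(keys %in% names(dw)))
    stop("the two arms have different key columns")
  if (!"value" %in% names(ori) || !"value" %in% names(dw))
    stop("arm tables need a value column")
  mk <- function(df) do.call(paste, c(df[keys], sep = "\r"))
  ko <- mk(ori); kd <- mk(dw)
  if (anyDuplicated(ko) || anyDuplicated(kd))
    stop("duplicate (sample, run) keys within an arm")
  if (!setequal(ko, kd) || length(ko) != length(kd))
    stop("unmatched (sample, run) keys between arms")
  dw <- dw[match(ko, kd), , drop = FALSE]
  out <- ori[keys]
  out$value_ori <- ori$value
  out$value_dw <- dw$value
  out$delta <- out$value_dw - out$value_ori
  class(out) <- c("paired_run_table", "data.frame")
  out
}

#' @rdname paired_deltas
#' @param table A `paired_run_table`.
#' @return `sample_mean_deltas` returns one row per sample (x metric) with
#'   the mean run-wise delta.
#' @export
sample_mean_deltas <- function(table) {
  keys <- intersect(c("sample_id", "metric"), names(table))
  agg <- stats::aggregate(table["delta"], by = table[keys], FUN = mean)
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

#' Paired Wilcoxon signed-rank test on deltas
#'
#' Two-sided signed-rank test of the run-wise (or sample-mean) deltas
#' against a zero-shift null. Zero differences are discarded before
#' ranking (classic treatment); if all deltas are zero the test is
#' degenerate and p = 1 is returned with a flag rather than an error,
#' matching "ns" reporting. The exact null distribution is used for
#' n <= 25 without ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param deltas Numeric vector of paired differences.
#' @return List with `stat` (V, sum of positive ranks), `p_value`, `n_used`
#'   (pairs remaining after zero removal), `exact` and `degenerate` flags.
#' @export
wilcoxon_signed_rank <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 1L) stop("need at least one delta")
  nz <- deltas[deltas != 0]
  if (length(nz) == 0L)
    return(list(stat = 0, p_value = 1, n_used = 0L, exact = TRUE,
                degenerate = TRUE))
  ties <- anyDuplicated(abs(nz)) > 0L
  use_exact <- length(nz) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(stat = unname(wt$statistic), p_value = min(wt$p.value, 1),
       n_used = length(nz), exact = use_exact, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; the significance set at any threshold equals
#' the textbook BH rejection set, adjusted values are elementwise >= raw
#' and capped at 1, and input order is preserved.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Cliff's delta effect size
#'
#' Nonparametric effect size over all n x m cross pairs of the two arms:
#' delta = (#\{x > y\} - #\{x < y\}) / (n m), in \[-1, 1\]. Positive values
#' mean the first arm tends to exceed the second. Magnitude labels follow
#' the conventional |delta| thresholds 0.147 / 0.33 / 0.474.
#'
#' @param values_dw,values_ori Nonempty numeric vectors.
#' @return List with `delta` and `effect_label` (one of negligible, small,
#'   medium, large).
#' @export
cliffs_delta <- function(values_dw, values_ori) {
  x <- as.numeric(values_dw); y <- as.numeric(values_ori)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty")
  cmp <- outer(x, y, "-")
  delta <- (sum(cmp > 0) - sum(cmp < 0)) / (length(x) * length(y))
  list(delta = delta, effect_label = cliffs_label(delta))
}

cliffs_label <- function(delta) {
  a <- abs(delta)
  if (a < 0.147) "negligible" else if (a < 0.33) "small"
  else if (a < 0.474) "medium" else "large"
}

significance_stars <- function(fdr) {
  ifelse(fdr < 1e-4, "****",
  ifelse(fdr < 1e-3, "***",
  ifelse(fdr < 1e-2, "**",
  ifelse(fdr < 0.05, "*", "ns"))))
}

#' Paired benchmark report
#'
#' Full benchmarking analysis of a paired run table, at two levels:
#'
#' * sample level — for each (sample, metric), a Wilcoxon signed-rank test
#'   over that sample's R run-wise deltas, plus mean delta and Cliff's
#'   delta over the sample's runs;
#' * dataset level — for each metric, a Wilcoxon test over the per-sample
#'   mean deltas pooled across samples, plus Cliff's delta over all
#'   run-level values of the two arms.
#'
#' BH correction is applied separately within each analysis family (all
#' sample x metric tests together; all dataset x metric tests together),
#' and significance stars are attached at FDR 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param table A `paired_run_table` from [paired_deltas()].
#' @return A `benchmark_report`: list of two data frames, `sample_level`
#'   and `dataset_level`.
#' @export
benchmark_report <- function(table) {
  stopifnot(inherits(table, "data.frame"),
            all(c("sample_id", "value_ori", "value_dw", "delta") %in% names(table)))
  if (!"metric" %in% names(table)) table$metric <- "metric"
  split_keys <- interaction(table$sample_id, table$metric, drop = TRUE)
  samp <- do.call(rbind, lapply(split(table, split_keys), function(df) {
    w <- wilcoxon_signed_rank(df$delta)
    cd <- cliffs_delta(df$value_dw, df$value_ori)
    data.frame(sample_id = df$sample_id[1], metric = df$metric[1],
               n_runs = nrow(df), mean_delta = mean(df$delta),
               wilcoxon_stat = w$stat, p_value = w$p_value,
               cliffs_delta = cd$delta, effect_label = cd$effect_label)
  }))
  samp <- samp[order(samp$metric, samp$sample_id), , drop = FALSE]
  samp$fdr <- benjamini_hochberg(samp$p_value)
  samp$significant <- samp$fdr < 0.05
  samp$stars <- significance_stars(samp$fdr)
  rownames(samp) <- NULL

  ds <- do.call(rbind, lapply(split(table, table$metric), function(df) {
    sm <- sample_mean_deltas(df)
    w <- wilcoxon_signed_rank(sm$delta)
    cd <- cliffs_delta(df$value_dw, df$value_ori)
    data.frame(metric = df$metric[1], n_samples = nrow(sm),
               mean_delta = mean(sm$delta),
               wilcoxon_stat = w$stat, p_value = w$p_value,
               cliffs_delta = cd$delta, effect_label = cd$effect_label)
  }))
  ds$fdr <- benjamini_hochberg(ds$p_value)
  ds$significant <- ds$fdr < 0.05
  ds$stars <- significance_stars(ds$fdr)
  rownames(ds) <- NULL
  structure(list(sample_level = samp, dataset_level = ds),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Paired benchmark report\n\nDataset level:\n")
  print(x$dataset_level, digits = 4)
  cat("\nSample level (first rows):\n")
  print(utils::head(x$sample_level, 10), digits = 4)
  invisible(x)
}

#' Evaluate pipeline runs against ground truth
#'
#' Convenience: scores every run (column) of a label matrix against the
#' ground-truth domains with all three metrics, in the long format the
#' paired-delta machinery consumes.
#'
#' @param labels N x R integer label matrix (one column per run).
#' @param truth Ground-truth label vector of length N.
#' @param sample_id Identifier recorded in the output rows.
#' @return Data frame with columns `sample_id`, `run_id`, `metric`, `value`.
#' @export
score_runs <- function(labels, truth, sample_id = "sample_1") {
  labels <- as.matrix(labels)
  metrics <- list(ARI = adjusted_rand_index,
                  NMI = normalized_mutual_information,
                  Homogeneity = homogeneity)
  do.call(rbind, lapply(seq_len(ncol(labels)), function(r) {
    data.frame(sample_id = sample_id, run_id = r,
               metric = names(metrics),
               value = vapply(metrics, function(f) f(truth, labels[, r]),
                              numeric(1)),
               row.names = NULL)
  }))
}
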