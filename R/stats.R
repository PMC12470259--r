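# Statistical validation protocol: paired two-sided t-tests on per-subject
# metric scores at alpha = 0.05, t-distribution 95% confidence intervals,
# and subject-level k-fold cross-validation splits. No multiple-testing
# correction is applied (raw p-values are reported).

#' Paired t-test on per-subject scores
#'
#' Two-sided paired t-test comparing two models' per-subject metric scores
#' (e.g. Dice), paired by subject. Degenerate inputs (zero variance of the
#' differences) are signalled with a warning and handled in closed form:
#' identical lists give t = 0, p = 1; a constant nonzero difference gives
#' infinite t and p = 0.
#'
#' @param scores_a,scores_b Numeric vectors of equal length (>= 3), one
#'   score per subject, paired by position.
#' @param alpha Significance level used for the `significant` flag.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_diff`, `alpha`,
#'   `significant`.
#' @export
paired_t_test <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must have equal length", call. = FALSE)
  }
  n <- length(scores_a)
  if (n < 3L) stop("need at least 3 paired subjects", call. = FALSE)
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    warning("zero variance of paired differences; degenerate t-test")
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- stats::t.test(scores_a, scores_b, paired = TRUE)
    t <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(t = t, df = n - 1L, p_value = p, mean_diff = mean(d),
                 alpha = alpha, significant = p < alpha)
}

#' t-distribution confidence interval for a metric
#'
#' @param scores Numeric vector of per-subject scores (length >= 2).
#' @param level Confidence level; default 0.95.
#' @return One-row tibble: `mean`, `lower`, `upper`, `level`, `n`.
#' @export
confidence_interval <- function(scores, level = 0.95) {
  n <- length(scores)
  if (n < 2L) {
    stop("need at least 2 observations for a confidence interval",
         call. = FALSE)
  }
  m <- mean(scores)
  half <- qt(1 - (1 - level) / 2, df = n - 1L) * sd(scores) / sqrt(n)
  tibble::tibble(mean = m, lower = m - half, upper = m + half,
                 level = level, n = n)
}

#' Subject-level k-fold split
#'
#' Partitions subjects (never slices) into k validation folds of
#' near-equal size after a seeded shuffle, so every subject appears in
#' exactly one validation fold and slices of one brain can never leak
#' across the split.
#'
#' @param subject_ids Character or integer vector of distinct subject ids.
#' @param k Number of folds (>= 2); default 5.
#' @param seed Integer seed for the shuffle.
#' @return List of `k` elements, each `list(train_ids, val_ids)`.
#' @export
kfold_split <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) {
    stop(sprintf("only %d distinct subjects for %d folds", n, k),
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shuffled <- sample(subject_ids)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    list(train_ids = shuffled[fold_of != f], val_ids = shuffled[fold_of == f])
  })
}
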