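#' ROC analysis of CTC counts as a cancer/healthy classifier
#'
#' The AUC is computed by the rank (Mann-Whitney) statistic — the
#' probability that a randomly chosen cancer sample scores above a randomly
#' chosen healthy sample, counting ties as 1/2 — which handles tied integer
#' counts exactly. Operating points are evaluated at half-integer cutoffs
#' between observed scores with the strict rule "count > cutoff is
#' positive"; higher counts indicate cancer.
#'
#' @param samples data frame with columns `group` (values `"cancer"` /
#'   `"healthy"`) and the count column named by `score`.
#' @param score which count column to use (default `"ctc_count"`).
#' @return a `ctc_roc` list: `auc`, `operating_points` (data frame of
#'   `cutoff`, `sensitivity`, `specificity`), `youden_optimal_cutoff`.
#' @export
#' @examples
#' d <- data.frame(group = rep(c("cancer", "healthy"), c(4, 3)),
#'                 ctc_count = c(5, 8, 2, 7, 0, 1, 2))
#' roc_curve(d)$auc
roc_curve <- function(samples, score = "ctc_count") {
  stopifnot(score %in% names(samples), "group" %in% names(samples))
  x <- samples[[score]]
  g <- samples$group
  cancer <- x[g == "cancer"]
  healthy <- x[g == "healthy"]
  if (!length(cancer) || !length(healthy))
    stop("both the cancer and the healthy group must be non-empty")
  n1 <- length(cancer); n0 <- length(healthy)
  r <- rank(c(cancer, healthy)) # midranks: ties count 1/2
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  u <- sort(unique(x))
  cutoffs <- c(min(u) - 0.5, (u[-length(u)] + u[-1]) / 2, max(u) + 0.5)
  ops <- do.call(rbind, lapply(cutoffs, function(cut) {
    ss <- sens_spec_at_cutoff(samples, cut, score)
    data.frame(cutoff = cut, sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]])
  }))
  youden <- ops$cutoff[which.max(ops$sensitivity + ops$specificity - 1)]
  structure(list(auc = auc, operating_points = ops,
                 youden_optimal_cutoff = youden, score = score),
            class = "ctc_roc")
}

#' @export
print.ctc_roc <- function(x, ...) {
  cat(sprintf("ROC on %s: AUC = %.3f, Youden-optimal cutoff = %g\n",
              x$score, x$auc, x$youden_optimal_cutoff))
  invisible(x)
}

#' Sensitivity and specificity at a count cutoff
#'
#' Predicts cancer when `count > cutoff` (strict, matching half-integer
#' cutoffs on integer counts). Sensitivity is evaluated on the cancer
#' group, specificity on the healthy group.
#'
#' @inheritParams roc_curve
#' @param cutoff decision threshold.
#' @return named numeric vector `c(sensitivity=, specificity=)`.
#' @export
sens_spec_at_cutoff <- function(samples, cutoff, score = "ctc_count") {
  x <- samples[[score]]
  g <- samples$group
  cancer <- x[g == "cancer"]
  healthy <- x[g == "healthy"]
  c(sensitivity = mean(cancer > cutoff),
    specificity = mean(healthy <= cutoff))
}

#' Inter-run reproducibility of CTC counts
#'
#' Per-subject replicate mean, sample standard deviation (n - 1
#' denominator) and coefficient of variation `CV% = 100 * SD / mean`. When
#' the mean is zero the CV is undefined and flagged rather than reported.
#'
#' @param replicates long-format data frame with columns `subject_id` and
#'   `count`, at least two replicates per subject.
#' @return data frame with `subject_id`, `n`, `mean`, `sd`, `cv_percent`,
#'   `cv_defined`.
#' @export
#' @examples
#' reproducibility_cv(data.frame(subject_id = c("a", "a"), count = c(4, 6)))
reproducibility_cv <- function(replicates) {
  stopifnot(all(c("subject_id", "count") %in% names(replicates)))
  out <- do.call(rbind, lapply(split(replicates, replicates$subject_id),
    function(d) {
      if (nrow(d) < 2)
        stop("subject ", d$subject_id[1], " has fewer than 2 replicates")
      m <- mean(d$count); s <- stats::sd(d$count)
      data.frame(subject_id = d$subject_id[1], n = nrow(d), mean = m, sd = s,
                 cv_percent = if (m > 0) 100 * s / m else NA_real_,
                 cv_defined = m > 0)
    }))
  rownames(out) <- NULL
  out
}

#' Percent reduction of CTC count under treatment
#'
#' `100 * (pre - post) / pre`, the per-patient treatment-response measure.
#'
#' @param pre_count CTC count before treatment (> 0).
#' @param post_count CTC count after treatment.
#' @return percentage reduction (can be negative if the count rose).
#' @export
#' @examples
#' percent_reduction(40, 7) # 82.5
percent_reduction <- function(pre_count, post_count) {
  if (any(pre_count <= 0)) stop("pre_count must be positive")
  100 * (pre_count - post_count) / pre_count
}

#' Read a CTC count table from CSV
#'
#' Expected header: `subject_id,group,ctc_count,dual_positive_count,total_count`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_count_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "ctc_count")
  if (!all(need %in% names(d)))
    stop("count CSV must have columns: ", paste(need, collapse = ", "))
  d
}
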