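#' Configuration of the purity-adjusted somatic caller
#'
#' The caller tests tumor variant enrichment over the matched normal with a
#' one-tailed Fisher's exact test and applies a variant-frequency threshold
#' scaled by tumor purity: in a CTC microfluidic output the tumor cells sit
#' in a hematopoietic background, so a clonal variant is expected at VF of
#' roughly `purity` (homozygous) rather than the bulk-tumor 20%. The
#' effective minimum VF is `base_min_vf * purity`, floored at 1e-4. A
#' germline guard rejects loci whose normal-sample VF exceeds
#' `max_normal_vf`, so that sheer coverage cannot make a germline site
#' "somatic".
#'
#' @param base_min_vf minimum VF before purity scaling (default 0.20).
#' @param purity tumor (CTC) purity in `(0, 1]`, typically from
#'   [enumerate_cells()].
#' @param somatic_p_threshold significance threshold (default 0.05).
#' @param max_normal_vf maximum VF tolerated in the normal (default 0.01).
#' @param min_vf_floor lower bound of the effective VF threshold.
#' @return a `call_config` list.
#' @export
call_config <- function(base_min_vf = 0.20, purity = 1,
                        somatic_p_threshold = 0.05, max_normal_vf = 0.01,
                        min_vf_floor = 1e-4) {
  stopifnot(base_min_vf >= 0, base_min_vf <= 1,
            somatic_p_threshold > 0, somatic_p_threshold <= 1,
            max_normal_vf >= 0, max_normal_vf <= 1, min_vf_floor >= 0)
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  structure(list(base_min_vf = base_min_vf, purity = purity,
                 somatic_p_threshold = somatic_p_threshold,
                 max_normal_vf = max_normal_vf, min_vf_floor = min_vf_floor),
            class = "call_config")
}

#' One-tailed Fisher's exact p for tumor variant enrichment
#'
#' Compares reference- and variant-supporting read counts between the
#' tumor (CTC output) and normal (WBC) samples. Conditioning on the table
#' margins, the tumor variant count is hypergeometric; the p-value is the
#' exact upper tail `P(X >= var_t)`, computed in log space and stable for
#' coverages up to about 1e6.
#'
#' @param ref_t,var_t tumor reference/variant read counts.
#' @param ref_n,var_n normal reference/variant read counts.
#' @param log if `TRUE` return `log(p)`, which stays finite where the
#'   p-value itself underflows double precision at extreme enrichment.
#' @return p-value in `[0, 1]` (or its log).
#' @export
#' @examples
#' fisher_somatic_p(900, 100, 1000, 0) # strongly enriched
fisher_somatic_p <- function(ref_t, var_t, ref_n, var_n, log = FALSE) {
  counts <- c(ref_t, var_t, ref_n, var_n)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ref_t + var_t == 0 || ref_n + var_n == 0)
    stop("each sample must have coverage > 0")
  m <- var_t + var_n        # variant reads overall
  n <- ref_t + ref_n        # reference reads overall
  k <- ref_t + var_t        # tumor sample size
  if (var_t == 0) return(if (log) 0 else 1)
  stats::phyper(var_t - 1, m, n, k, lower.tail = FALSE, log.p = log)
}

#' Purity-adjusted minimum variant frequency
#'
#' @param config a [call_config()].
#' @return `max(base_min_vf * purity, min_vf_floor)`.
#' @export
effective_min_vf <- function(config) {
  stopifnot(inherits(config, "call_config"))
  max(config$base_min_vf * config$purity, config$min_vf_floor)
}

#' Call one locus somatic or not
#'
#' A locus is called iff the one-tailed Fisher p is below
#' `somatic_p_threshold`, the tumor VF reaches the purity-adjusted
#' threshold, and the normal VF stays at or below the germline guard.
#'
#' @param pair a `pileup_pair` (or any list with `tumor_ref`, `tumor_var`,
#'   `normal_ref`, `normal_var`).
#' @param config a [call_config()].
#' @return a `somatic_call` list: `somatic_p`, `vf_tumor`, `vf_normal`,
#'   `called`, plus `locus` and `truth` when present on the pair.
#' @export
call_somatic <- function(pair, config) {
  stopifnot(inherits(config, "call_config"))
  p <- fisher_somatic_p(pair$tumor_ref, pair$tumor_var,
                        pair$normal_ref, pair$normal_var)
  vf_t <- pair$tumor_var / (pair$tumor_ref + pair$tumor_var)
  vf_n <- pair$normal_var / (pair$normal_ref + pair$normal_var)
  called <- p < config$somatic_p_threshold &&
    vf_t >= effective_min_vf(config) &&
    vf_n <= config$max_normal_vf
  structure(list(somatic_p = p, vf_tumor = vf_t, vf_normal = vf_n,
                 called = called, locus = pair$locus,
                 truth = pair$truth %||% NA),
            class = "somatic_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call somatic variants on a pileup table
#'
#' @param pileups data frame with columns `tumor_ref`, `tumor_var`,
#'   `normal_ref`, `normal_var` (extra columns carried through).
#' @param config a [call_config()].
#' @return the input with `somatic_p`, `vf_tumor`, `vf_normal`, `called`
#'   columns appended.
#' @export
call_somatic_table <- function(pileups, config) {
  stopifnot(inherits(config, "call_config"))
  p <- mapply(fisher_somatic_p, pileups$tumor_ref, pileups$tumor_var,
              pileups$normal_ref, pileups$normal_var)
  vf_t <- pileups$tumor_var / (pileups$tumor_ref + pileups$tumor_var)
  vf_n <- pileups$normal_var / (pileups$normal_ref + pileups$normal_var)
  pileups$somatic_p <- p
  pileups$vf_tumor <- vf_t
  pileups$vf_normal <- vf_n
  pileups$called <- p < config$somatic_p_threshold &
    vf_t >= effective_min_vf(config) & vf_n <= config$max_normal_vf
  pileups
}

#' Consensus somatic calls across technical replicates
#'
#' A locus enters the consensus iff it is called — with somatic p below
#' the threshold — in every replicate (the duplicate rule generalized to
#' k >= 2). Per-replicate p-values are retained.
#'
#' @param replicate_calls list (length >= 2) of per-replicate call tables,
#'   each a data frame with a shared `locus_id` column plus `somatic_p`
#'   and `called`.
#' @return data frame of consensus loci with per-replicate p-value columns
#'   `somatic_p_rep1`, `somatic_p_rep2`, ... and `consensus = TRUE`.
#' @export
consensus_calls <- function(replicate_calls) {
  if (length(replicate_calls) < 2)
    stop("consensus requires at least 2 technical replicates")
  for (d in replicate_calls)
    stopifnot(all(c("locus_id", "somatic_p", "called") %in% names(d)))
  called_sets <- lapply(replicate_calls,
                        function(d) d$locus_id[d$called])
  consensus_ids <- Reduce(intersect, called_sets)
  base <- replicate_calls[[1]]
  out <- base[base$locus_id %in% consensus_ids,
              setdiff(names(base), c("somatic_p", "called")), drop = FALSE]
  for (i in seq_along(replicate_calls)) {
    d <- replicate_calls[[i]]
    out[[paste0("somatic_p_rep", i)]] <-
      d$somatic_p[match(out$locus_id, d$locus_id)]
  }
  out$consensus <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Evaluate calls against a truth set
#'
#' @param called logical vector of calls per locus.
#' @param truth logical vector, same length: variant truly present.
#' @return an `eval_metrics` list: `tp`, `fp`, `fn`, `ppv`, `fdr`,
#'   `sensitivity`, and `ppv_defined` (FALSE when there are no calls, in
#'   which case PPV and FDR are `NA`, not 0).
#' @export
evaluate_calls <- function(called, truth) {
  stopifnot(length(called) == length(truth))
  tp <- sum(called & truth)
  fp <- sum(called & !truth)
  fn <- sum(!called & truth)
  n_call <- tp + fp
  structure(list(tp = tp, fp = fp, fn = fn,
                 ppv = if (n_call > 0) tp / n_call else NA_real_,
                 fdr = if (n_call > 0) fp / n_call else NA_real_,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 ppv_defined = n_call > 0),
            class = "eval_metrics")
}

#' Linearity of detected versus expected variant frequency
#'
#' Ordinary least squares of detected on expected VF over a dilution
#' series; a well-behaved assay gives a slope near 1 and R-squared near 1.
#'
#' @param expected,detected numeric vectors (>= 3 points, >= 2 distinct
#'   expected values).
#' @return a `linearity_fit` list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_linearity <- function(expected, detected) {
  stopifnot(length(expected) == length(detected))
  if (length(expected) < 3) stop("need at least 3 points")
  if (length(unique(expected)) < 2)
    stop("expected VFs are degenerate (all equal)")
  fit <- stats::lm(detected ~ expected)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((detected - mean(detected))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 n = length(expected)),
            class = "linearity_fit")
}

#' Dilution-series linearity benchmark
#'
#' Simulates a spike-in dilution series and fits detected ~ expected VF.
#'
#' @param vfs expected VF levels (default the published non-zero series
#'   0.08%, 0.8%, 2.68%, 8%).
#' @param n number of points (default 10).
#' @param coverage,error_rate simulator settings.
#' @param seed master seed.
#' @return list with `series` (data frame) and `fit` (a `linearity_fit`),
#'   plus the simulator settings as metadata.
#' @export
benchmark_linearity <- function(vfs = c(0.0008, 0.008, 0.0268, 0.08),
                                n = 10, coverage = 4e5, error_rate = 1e-4,
                                seed = 1L) {
  series <- simulate_dilution_series(vfs, n, coverage, error_rate, seed)
  fit <- fit_linearity(series$expected_vf, series$detected_vf)
  list(series = series, fit = fit,
       metadata = list(coverage = coverage, error_rate = error_rate,
                       seed = seed))
}

#' Replicate-consensus benchmark at low variant frequency
#'
#' Simulates `n_samples` tumor/normal sample pairs, each carrying one true
#' variant at `vf` among a panel of wild-type decoy loci, in `reps`
#' technical replicates. Calls each replicate with the purity-adjusted
#' Fisher caller (purity taken as the spike fraction), forms the consensus
#' across replicates, and evaluates single-replicate versus consensus
#' PPV/FDR/sensitivity against the known truth.
#'
#' @param n_samples number of simulated samples (default 5).
#' @param vf true variant frequency (default 0.008, i.e. 0.8%).
#' @param coverage,error_rate simulator settings.
#' @param reps number of technical replicates (default 2).
#' @param n_decoys wild-type loci per sample in addition to the true one.
#' @param seed master seed.
#' @param config optional [call_config()]; default uses `purity = vf`
#'   (homozygous spike).
#' @return list with `single` and `consensus` (`eval_metrics`), and the
#'   per-locus call tables.
#' @export
benchmark_consensus <- function(n_samples = 5, vf = 0.008, coverage = 4e5,
                                error_rate = 1e-4, reps = 2, n_decoys = 20,
                                seed = 1L, config = NULL) {
  stopifnot(reps >= 1)
  if (is.null(config)) config <- call_config(purity = max(vf, 1e-4))
  loci <- panel_loci()
  rep_tables <- vector("list", reps)
  truth_all <- NULL
  for (s in seq_len(n_samples)) {
    truth <- c(TRUE, rep(FALSE, n_decoys))
    for (r in seq_len(reps)) {
      rows <- lapply(seq_along(truth), function(j) {
        pair <- withr::with_seed(
          sub_seed(seed, ((s - 1) * reps + r) * 100003 + j),
          draw_pair(if (truth[j]) vf else 0, as.integer(coverage),
                    error_rate, truth[j]))
        data.frame(locus_id = sprintf("s%d_locus%02d", s, j),
                   gene = loci[[((j - 1) %% length(loci)) + 1]]$gene,
                   sample = s, tumor_ref = pair$tumor_ref,
                   tumor_var = pair$tumor_var, normal_ref = pair$normal_ref,
                   normal_var = pair$normal_var, truth = truth[j])
      })
      tab <- call_somatic_table(do.call(rbind, rows), config)
      rep_tables[[r]] <- rbind(rep_tables[[r]], tab)
    }
    truth_all <- c(truth_all, truth)
  }
  single <- rep_tables[[1]]
  single_metrics <- evaluate_calls(single$called, single$truth)
  if (reps >= 2) {
    cons <- consensus_calls(rep_tables)
    cons_called <- single$locus_id %in% cons$locus_id
    cons_metrics <- evaluate_calls(cons_called, single$truth)
  } else {
    cons <- NULL
    cons_metrics <- single_metrics
  }
  list(single = single_metrics, consensus = cons_metrics,
       replicate_tables = rep_tables, consensus_table = cons,
       metadata = list(n_samples = n_samples, vf = vf, coverage = coverage,
                       error_rate = error_rate, reps = reps,
                       n_decoys = n_decoys, seed = seed,
                       effective_min_vf = effective_min_vf(config)))
}

#' Write somatic calls as a minimal VCF 4.2 file
#'
#' INFO fields: `SOMATIC_P`, `VF_T`, `VF_N`, `CONSENSUS`.
#'
#' @param calls data frame with `locus_id` (used as ID), optional `chrom`,
#'   `pos`, `ref`, `alt` columns, `somatic_p`, `vf_tumor`, `vf_normal`,
#'   and optionally `consensus`.
#' @param path output path.
#' @param sample_names character vector recorded in the header.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(calls, path, sample_names = c("TUMOR", "NORMAL")) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write VCF to ", path))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ctcflow",
    "##INFO=<ID=SOMATIC_P,Number=1,Type=Float,Description=\"One-tailed Fisher exact somatic p-value\">",
    "##INFO=<ID=VF_T,Number=1,Type=Float,Description=\"Tumor variant frequency\">",
    "##INFO=<ID=VF_N,Number=1,Type=Float,Description=\"Normal variant frequency\">",
    "##INFO=<ID=CONSENSUS,Number=0,Type=Flag,Description=\"Called in all technical replicates\">",
    paste0("##samples=", paste(sample_names, collapse = ",")),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0) {
    chrom <- calls$chrom %||% rep(".", nrow(calls))
    pos <- calls$pos %||% seq_len(nrow(calls))
    ref <- calls$ref %||% rep("N", nrow(calls))
    alt <- calls$alt %||% rep("N", nrow(calls))
    cons <- if (!is.null(calls$consensus)) calls$consensus
            else rep(FALSE, nrow(calls))
    info <- sprintf("SOMATIC_P=%.6g;VF_T=%.6g;VF_N=%.6g%s",
                    calls$somatic_p, calls$vf_tumor, calls$vf_normal,
                    ifelse(cons, ";CONSENSUS", ""))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                       chrom, as.integer(pos), calls$locus_id, ref, alt,
                       info), con)
  }
  invisible(path)
}
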