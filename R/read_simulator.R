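#' Panel locus description
#'
#' @param gene gene symbol (e.g. `"EGFR"`).
#' @param label position/variant label (e.g. `"L861Q"`).
#' @param ref,alt single-nucleotide reference and variant alleles.
#' @param zygosity `"hom"` or `"het"` in the spiked tumor DNA.
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(gene = "EGFR", label = "L861Q", ref = "T", alt = "A",
                       zygosity = c("hom", "het")) {
  zygosity <- match.arg(zygosity)
  stopifnot(ref %in% DNA_BASES, alt %in% DNA_BASES, ref != alt)
  structure(list(gene = gene, label = label, ref = ref, alt = alt,
                 zygosity = zygosity), class = "locus_spec")
}

#' Default six-gene panel used by the benchmarks
#'
#' One representative single-nucleotide variant per gene (NRAS, ESR1, EGFR,
#' KRAS, BRAF, TP53).
#'
#' @return list of [locus_spec()] objects.
#' @export
panel_loci <- function() {
  list(locus_spec("NRAS", "Q61R", "T", "C"),
       locus_spec("ESR1", "S559A", "T", "G"),
       locus_spec("EGFR", "L861Q", "T", "A"),
       locus_spec("KRAS", "G12D", "G", "A"),
       locus_spec("BRAF", "V600E", "T", "A"),
       locus_spec("TP53", "A364S", "G", "T"))
}

#' Tumor/normal mixture description for pileup simulation
#'
#' Emulates a microfluidic CTC output: tumor DNA at `tumor_fraction` in a
#' hematopoietic (wild-type) background, sequenced to `coverage` reads per
#' locus with a per-base substitution error rate toward the specific
#' variant allele.
#'
#' @param tumor_fraction spike/CTC purity in `[0, 1]`.
#' @param coverage reads per locus per sample (default 4e5, the magnitude
#'   of the clinical amplicon coverages).
#' @param error_rate probability of a sequencing error producing the
#'   specific alt allele (default 1e-4, post-filter Illumina-like).
#' @param seed optional integer seed.
#' @return a `mixture_spec` list.
#' @export
mixture_spec <- function(tumor_fraction, coverage = 4e5, error_rate = 1e-4,
                         seed = NULL) {
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1, coverage > 0,
            error_rate >= 0, error_rate < 0.25)
  structure(list(tumor_fraction = tumor_fraction,
                 coverage = as.integer(coverage),
                 error_rate = error_rate, seed = seed),
            class = "mixture_spec")
}

#' Expected variant frequency of a spiked mixture
#'
#' A homozygous variant contributes one alt allele per tumor genome copy,
#' so the expected VF equals the tumor fraction; a heterozygous variant
#' contributes half.
#'
#' @param tumor_fraction spike fraction in `[0, 1]`.
#' @param zygosity `"hom"` or `"het"`.
#' @return expected variant frequency.
#' @export
#' @examples
#' expected_vf(0.08, "hom") # 0.08
#' expected_vf(0.16, "het") # 0.08
expected_vf <- function(tumor_fraction, zygosity = c("hom", "het")) {
  zygosity <- match.arg(zygosity)
  if (zygosity == "hom") tumor_fraction else tumor_fraction / 2
}

draw_pair <- function(vf, coverage, error_rate, truth) {
  # errors arise on the non-variant template fraction
  p_t <- vf + error_rate * (1 - vf)
  var_t <- stats::rbinom(1, coverage, p_t)
  var_n <- stats::rbinom(1, coverage, error_rate)
  list(tumor_ref = coverage - var_t, tumor_var = var_t,
       normal_ref = coverage - var_n, normal_var = var_n,
       truth = truth)
}

#' Simulate tumor/normal pileup counts at one locus
#'
#' Tumor variant reads are Binomial(`coverage`, expected VF plus error on
#' the remaining templates); matched-normal variant reads are
#' Binomial(`coverage`, `error_rate`). The truth flag records whether the
#' variant is genuinely present in the tumor mixture.
#'
#' @param locus a [locus_spec()].
#' @param mix a [mixture_spec()].
#' @return a `pileup_pair` list with `tumor_ref`, `tumor_var`,
#'   `normal_ref`, `normal_var`, `truth`, `locus`, `expected_vf`.
#' @export
simulate_pileup <- function(locus, mix) {
  stopifnot(inherits(locus, "locus_spec"), inherits(mix, "mixture_spec"))
  vf <- expected_vf(mix$tumor_fraction, locus$zygosity)
  draw <- function() draw_pair(vf, mix$coverage, mix$error_rate,
                               truth = mix$tumor_fraction > 0)
  pair <- if (is.null(mix$seed)) draw() else withr::with_seed(mix$seed, draw())
  structure(c(pair, list(locus = locus, expected_vf = vf)),
            class = "pileup_pair")
}

#' Simulate a spike-in dilution series
#'
#' Draws independent tumor/normal pileups at the requested expected-VF
#' levels, cycling through the levels until `n` points are produced —
#' the in-silico analogue of spiking mutant cell-line DNA into a
#' wild-type background at known fractions. Default levels are the
#' published series 0%, 0.08%, 0.8%, 2.68%, 8%.
#'
#' @param vfs expected variant frequencies (fractions).
#' @param n total number of points (default 10).
#' @param coverage,error_rate see [mixture_spec()].
#' @param seed master seed; each point gets a deterministic sub-seed.
#' @return data frame with one row per point: `expected_vf`, pileup counts,
#'   `detected_vf = tumor_var / coverage`, `truth`.
#' @export
simulate_dilution_series <- function(vfs = c(0, 0.0008, 0.008, 0.0268, 0.08),
                                     n = 10, coverage = 4e5,
                                     error_rate = 1e-4, seed = 1L) {
  stopifnot(all(vfs >= 0), n >= 1)
  levels <- rep_len(vfs, n)
  rows <- lapply(seq_len(n), function(i) {
    pair <- withr::with_seed(sub_seed(seed, i),
      draw_pair(levels[i], as.integer(coverage), error_rate, levels[i] > 0))
    data.frame(point = i, expected_vf = levels[i],
               tumor_ref = pair$tumor_ref, tumor_var = pair$tumor_var,
               normal_ref = pair$normal_ref, normal_var = pair$normal_var,
               detected_vf = pair$tumor_var / (pair$tumor_ref + pair$tumor_var),
               truth = pair$truth)
  })
  do.call(rbind, rows)
}

# deterministic sub-seed derivation, kept below 2^31
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629)
}

#' Simulate technical replicates of one locus
#'
#' `k` independent pileup pairs sharing the same truth flag; sub-seeds are
#' derived deterministically from the master seed so the whole series is
#' reproducible.
#'
#' @param k number of technical replicates (>= 1).
#' @param locus a [locus_spec()].
#' @param mix a [mixture_spec()]; its `seed` is the master seed (required).
#' @return list of `k` `pileup_pair` objects.
#' @export
simulate_replicates <- function(k, locus, mix) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(inherits(mix, "mixture_spec"))
  if (is.null(mix$seed)) stop("mixture_spec seed is required for replicates")
  lapply(seq_len(k), function(i) {
    m <- mix
    # replicate 1 reproduces the single-pileup draw exactly
    m$seed <- if (i == 1) mix$seed else sub_seed(mix$seed, i)
    simulate_pileup(locus, m)
  })
}

#' Write a pileup table as CSV
#'
#' @param pileups data frame (e.g. from [simulate_dilution_series()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pileup_csv <- function(pileups, path) {
  utils::write.csv(pileups, path, row.names = FALSE)
  invisible(path)
}
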