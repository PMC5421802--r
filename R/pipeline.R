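#' End-to-end run configuration
#'
#' Bundles the sub-configurations of every stage: synthetic image fixture,
#' gating, read simulator, and somatic caller. All sub-configs are
#' validated up front, before any stage runs.
#'
#' @param fixture a [fixture_config()].
#' @param gates a [gate_config()] (intensity thresholds may be `NA` when
#'   `calibrate` is `TRUE`).
#' @param calibrate logical; derive intensity gates from synthetic
#'   control measurements generated alongside the fixture.
#' @param vf true variant frequency for the sequencing stage; `NULL`
#'   (default) uses the measured CTC purity, the expected VF of a clonal
#'   homozygous variant carried by the tumor fraction.
#' @param coverage,error_rate read simulator settings.
#' @param reps technical replicates for consensus calling.
#' @param n_decoys wild-type panel loci per sample.
#' @param seed master seed governing every stage.
#' @param out_dir output directory for artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(fixture = fixture_config(seed = 1L),
                       gates = gate_config(ck_epcam_positive_threshold = 500,
                                           cd45_positive_threshold = 500),
                       calibrate = FALSE,
                       vf = NULL, coverage = 4e5, error_rate = 1e-4,
                       reps = 2, n_decoys = 20, seed = 1L,
                       out_dir = tempfile("ctcflow_run_")) {
  stopifnot(inherits(fixture, "fixture_config"),
            inherits(gates, "gate_config"),
            is.null(vf) || (vf >= 0 && vf <= 1), coverage > 0, reps >= 1)
  structure(list(fixture = fixture, gates = gates, calibrate = calibrate,
                 vf = vf, coverage = coverage, error_rate = error_rate,
                 reps = reps, n_decoys = n_decoys, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full workflow: image -> enumeration -> purity -> calling
#'
#' Generates the synthetic three-channel image, runs the enumeration
#' pipeline, estimates CTC purity, feeds the purity into the somatic
#' caller configuration, simulates tumor/normal pileups at the configured
#' variant frequency in technical replicates, calls consensus somatic
#' mutations, and writes a JSON run report. If a stage fails (e.g. purity
#' undefined because no cells were detected), later stages are skipped
#' with an explicit reason in the report.
#'
#' @param config a [run_config()].
#' @return the run report (also written to `report.json` in `out_dir`):
#'   a list with per-stage status, metrics and artifact paths.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(), artifacts = list())

  # stage 1: synthetic images
  fx <- generate_fixture(config$fixture)
  paths <- write_fixture(fx, file.path(config$out_dir, "images"))
  report$stages$simulate_images <- list(status = "ok",
                                        n_cells = nrow(fx$ground_truth))
  report$artifacts$images <- as.character(paths)

  # stage 2: enumeration and purity
  gates <- config$gates
  if (config$calibrate) {
    iso <- data.frame(mean_ck_epcam = rep(config$fixture$background_level, 50),
                      mean_cd45 = rep(config$fixture$background_level, 50))
    pos <- data.frame(mean_ck_epcam = rep(1500, 50), mean_cd45 = rep(50, 50))
    gates <- calibrate_gates(pos, iso, gates$calibration_k, gates)
  }
  enum <- count_ctcs(fx$dna, fx$ck_epcam, fx$cd45,
                     pixel_size = config$fixture$pixel_size, gates = gates)
  meas_path <- file.path(config$out_dir, "measurements.csv")
  write_measurements(enum$records, meas_path)
  report$artifacts$measurements <- meas_path
  res <- enum$result
  report$stages$enumeration <- list(
    status = "ok", counts = as.list(res$counts),
    total_cells = res$total_cells,
    ctc_purity = if (res$purity_defined) res$ctc_purity else NA,
    purity_defined = res$purity_defined,
    eccentricity_max = gates$eccentricity_max)

  # stage 3: purity-adjusted somatic calling on simulated reads
  if (!res$purity_defined || is.na(res$ctc_purity) || res$ctc_purity <= 0) {
    report$stages$somatic_calling <- list(
      status = "skipped",
      reason = "CTC purity undefined or zero; no tumor signal to call")
  } else {
    cfg <- call_config(purity = res$ctc_purity)
    vf <- if (is.null(config$vf)) res$ctc_purity else config$vf
    bench <- benchmark_consensus(
      n_samples = 1, vf = vf, coverage = config$coverage,
      error_rate = config$error_rate, reps = config$reps,
      n_decoys = config$n_decoys, seed = config$seed, config = cfg)
    tab <- bench$replicate_tables[[1]]
    tab$consensus <- tab$locus_id %in% bench$consensus_table$locus_id
    vcf_path <- file.path(config$out_dir, "calls.vcf")
    write_vcf(tab[tab$called, , drop = FALSE], vcf_path)
    report$artifacts$vcf <- vcf_path
    report$stages$somatic_calling <- list(
      status = "ok", purity_used = res$ctc_purity, simulated_vf = vf,
      effective_min_vf = effective_min_vf(cfg),
      consensus_calls = nrow(bench$consensus_table),
      sensitivity = bench$consensus$sensitivity)
  }

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  report$artifacts$report <- report_path
  report
}
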