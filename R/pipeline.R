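# End-to-end convenience wrappers: files in, predictions and concordance
# out.  These exercise the same readers a user would call, so a cohort
# written with write_cohort() and analysed with run_pipeline() round-trips
# through the on-disk formats.

#' Run the full inference pipeline from files
#'
#' Reads phased genotypes, the depth track and (optionally) serology;
#' calls RHD zygosity and C/c state from depth ratios, glycophorin
#' structural alleles from the windowed HMM, then predicts all 24 antigens
#' and, when serology is supplied, summarizes concordance.
#'
#' @param vcf_path phased VCF restricted to the blood-group loci.
#' @param depth_path per-window depth TSV.
#' @param serology_path serology grade TSV, or `NULL`.
#' @param panel a [bg_panel()].
#' @param p1_predictor passed to [infer_p1()].
#' @param cc_method passed to [rh_cnv_call()].
#' @return list with `predictions`, `rh`, `structural`, `haplotypes`, and
#'   `concordance` (when serology was supplied).
#' @export
run_pipeline <- function(vcf_path, depth_path, serology_path = NULL,
                         panel = bg_panel(), p1_predictor = "consensus",
                         cc_method = "modified") {
  h <- read_phased_genotypes(vcf_path, panel)
  depth <- read_depth(depth_path)
  rh <- rh_cnv_call(depth, panel, method = cc_method)
  structural <- glycophorin_calls(depth, panel)
  pred <- predict_all(h, rh, structural, panel, p1_predictor = p1_predictor)
  out <- list(predictions = pred, rh = rh, structural = structural,
              haplotypes = h)
  if (!is.null(serology_path)) {
    serology <- read_serology(serology_path, panel)
    out$concordance <- summarize_concordance(pred, serology, panel)
    out$serology <- serology
  }
  out
}

#' Run the pipeline on an in-memory cohort via its on-disk formats
#'
#' Writes the cohort to `dir` and analyses the written files, so the
#' result reflects exactly what an external user of the formats would
#' compute.
#'
#' @param cohort a `bg_cohort`.
#' @param dir directory for the intermediate files (a fresh temporary
#'   directory by default).
#' @param ... passed to [run_pipeline()].
#' @return as [run_pipeline()].
#' @export
run_cohort_pipeline <- function(cohort,
                                dir = tempfile("bg_cohort_"), ...) {
  paths <- write_cohort(cohort, dir)
  run_pipeline(paths["vcf"], paths["depth"], paths["serology"], ...)
}
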