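# RHD zygosity and C/c antigen state from depth ratios at the paralogous
# RHD/RHCE locus pair.
#
# The RHCE*C haplotype carries RHD-like sequence across exon 2, so its
# exon-2 reads align to RHD exon 2 instead of RHCE exon 2.  C/c state is
# therefore read from depth depletion at RHCE exon 2.  Two methods are
# implemented: the paralog-aware ("modified") method compares RHCE exon-2
# depth with per-copy RHD exon-2 depth and is used whenever RHD is present;
# the whole-gene ("legacy") method compares RHCE exon-2 depth with the
# RHCE locus mean and is the fallback for RHD-null samples.
#
# All ratios are scaled so that their ideal values are per-copy: the RHD
# zygosity ratio is RHD depth over haploid RHCE depth (expected 0, 1, 2 for
# null, hemizygous, homozygous) and the modified C/c ratio is RHCE exon-2
# depth over per-copy RHD exon-2 depth (expected 2, ~0.67, 0 for c/c, C/c,
# C/C with two RHD copies).  Band boundaries sit in configuration and
# values falling in the gaps between bands yield an explicit no-call
# rather than being rounded into the nearest band.

#' Classification thresholds for the Rh copy-number methods
#'
#' @param rhd_null,rhd_hemi,rhd_hom inclusive \[lo, hi\] bands for the RHD
#'   zygosity ratio.
#' @param cc_present bands for the modified C/c ratio when RHD is present
#'   at two copies: list of `Cneg` (lower bound, inclusive), `both`
#'   (inclusive range), `cneg` (upper bound, exclusive).
#' @param cc_hemi bands when RHD is hemizygous (lower bound exclusive for
#'   `Cneg` per the published boundaries).
#' @param cc_null bands for the legacy exon-2 / locus ratio used for
#'   RHD-null samples.
#' @return list of class `rh_thresholds`.
#' @export
rh_thresholds <- function(
    rhd_null = c(0, 0.5), rhd_hemi = c(0.6, 1.5), rhd_hom = c(1.6, 2.5),
    cc_present = list(Cneg = 1.5, both = c(0.5, 1.4), cneg = 0.5),
    cc_hemi = list(Cneg = 0.67, both = c(0.1, 0.66), cneg = 0.1),
    cc_null = list(Cneg = 0.75, both = c(0.25, 0.74), cneg = 0.25)) {
  structure(list(rhd_null = rhd_null, rhd_hemi = rhd_hemi, rhd_hom = rhd_hom,
                 cc_present = cc_present, cc_hemi = cc_hemi,
                 cc_null = cc_null),
            class = "rh_thresholds")
}

#' RHD zygosity from locus depth
#'
#' The ratio of RHD locus depth to haploid RHCE locus depth (RHCE carries
#' two copies in everyone) is banded into null / hemizygous / homozygous.
#' Values in the gaps between bands are an explicit no-call.
#'
#' @param rhd_depth mean MAPQ-filtered depth across the RHD locus.
#' @param rhce_depth mean depth across the RHCE locus.
#' @param thresholds an [rh_thresholds()].
#' @return list with `zygosity` (`"null"`, `"hemizygous"`, `"homozygous"`,
#'   `"no-call"`) and `ratio`.
#' @export
rhd_zygosity <- function(rhd_depth, rhce_depth, thresholds = rh_thresholds()) {
  if (is.na(rhce_depth) || rhce_depth <= 0) {
    stop("RHCE locus depth is zero; sample fails depth QC", call. = FALSE)
  }
  ratio <- rhd_depth / (rhce_depth / 2)
  t <- thresholds
  zyg <- if (ratio >= t$rhd_null[1] && ratio <= t$rhd_null[2]) "null"
    else if (ratio >= t$rhd_hemi[1] && ratio <= t$rhd_hemi[2]) "hemizygous"
    else if (ratio >= t$rhd_hom[1] && ratio <= t$rhd_hom[2]) "homozygous"
    else "no-call"
  list(zygosity = zyg, ratio = ratio)
}

.cc_classify <- function(ratio, bands, upper_inclusive) {
  if (is.na(ratio)) return("no-call")
  if (upper_inclusive) {
    if (ratio >= bands$Cneg) return("C-c+")
  } else {
    if (ratio > bands$Cneg) return("C-c+")
  }
  if (ratio >= bands$both[1] && ratio <= bands$both[2]) return("C+c+")
  if (ratio < bands$cneg) return("C+c-")
  "no-call"
}

#' C/c antigen state by the paralog-aware exon-2 method
#'
#' For samples carrying RHD, compares RHCE exon-2 depth to per-copy RHD
#' exon-2 depth.  A C-carrying haplotype contributes no reads at RHCE exon
#' 2 (they sit on RHD exon 2), so the ratio drops from ~2 (c/c) through
#' ~0.67 (C/c) to ~0 (C/C) in two-copy RHD samples.
#'
#' @param rhce_ex2_depth mean depth over the RHCE exon-2 tract.
#' @param rhd_ex2_depth mean depth over the RHD exon-2 tract.
#' @param zygosity `"homozygous"` or `"hemizygous"` (from [rhd_zygosity()]).
#' @param thresholds an [rh_thresholds()].
#' @return list with `phenotype` (`"C+c-"`, `"C+c+"`, `"C-c+"`,
#'   `"no-call"`) and the per-copy `ratio` used.
#' @export
infer_Cc_modified <- function(rhce_ex2_depth, rhd_ex2_depth, zygosity,
                              thresholds = rh_thresholds()) {
  if (!zygosity %in% c("homozygous", "hemizygous")) {
    stop("modified C/c method requires RHD to be present ",
         "(zygosity homozygous or hemizygous); use infer_Cc_legacy for ",
         "RHD-null samples", call. = FALSE)
  }
  if (is.na(rhd_ex2_depth) || rhd_ex2_depth <= 0) {
    stop("RHD exon-2 depth is zero despite RHD being called present",
         call. = FALSE)
  }
  copies <- if (zygosity == "homozygous") 2 else 1
  ratio <- rhce_ex2_depth / (rhd_ex2_depth / copies)
  bands <- if (zygosity == "homozygous") thresholds$cc_present
           else thresholds$cc_hemi
  list(phenotype = .cc_classify(ratio, bands,
                                upper_inclusive = zygosity == "homozygous"),
       ratio = ratio)
}

#' C/c antigen state by the whole-gene (legacy) method
#'
#' Compares RHCE exon-2 depth to the RHCE locus mean.  Each C haplotype
#' removes half of the exon-2 depth, so the expected ratio is 1, 0.5, 0 for
#' c/c, C/c, C/C.  This method ignores RHD entirely and is the route for
#' RHD-null samples, where there is no RHD exon 2 to compare against.
#'
#' @param rhce_ex2_depth mean depth over the RHCE exon-2 tract.
#' @param rhce_locus_depth mean depth over the whole RHCE locus.
#' @param thresholds an [rh_thresholds()].
#' @return list with `phenotype` and `ratio`.
#' @export
infer_Cc_legacy <- function(rhce_ex2_depth, rhce_locus_depth,
                            thresholds = rh_thresholds()) {
  if (is.na(rhce_locus_depth) || rhce_locus_depth <= 0) {
    stop("RHCE locus depth is zero; sample fails depth QC", call. = FALSE)
  }
  ratio <- rhce_ex2_depth / rhce_locus_depth
  list(phenotype = .cc_classify(ratio, thresholds$cc_null,
                                upper_inclusive = TRUE),
       ratio = ratio)
}

#' Per-sample Rh copy-number calls from a depth track
#'
#' Runs [rhd_zygosity()] for every sample, then the modified C/c method for
#' RHD-present samples and the legacy method for RHD-null samples.
#'
#' @param depth a `bg_depth` track covering the RHD/RHCE region.
#' @param panel a [bg_panel()] (supplies locus and exon-2 tract intervals).
#' @param thresholds an [rh_thresholds()].
#' @param method `"modified"` (zygosity-aware, legacy only for RHD-null) or
#'   `"legacy"` (whole-gene method for every sample).
#' @return data frame with one row per sample: sample, zygosity, rhd_ratio,
#'   cc_phenotype, cc_ratio, method.
#' @export
rh_cnv_call <- function(depth, panel, thresholds = rh_thresholds(),
                        method = c("modified", "legacy")) {
  method <- match.arg(method)
  reg <- panel$regions
  get_reg <- function(n) reg[reg$name == n, , drop = FALSE]
  rhd <- get_reg("rhd_locus"); rhce <- get_reg("rhce_locus")
  rhd_ex2 <- get_reg("rhd_ex2"); rhce_ex2 <- get_reg("rhce_ex2")

  # locus means exclude the exon-2 tract, i.e. "the rest of the gene":
  # the tract's depth moves with C-conversion mismapping and would
  # otherwise leak genotype signal into the zygosity denominator
  mean_excluding <- function(s, locus, tract) {
    w1 <- tract$start - locus$start
    w2 <- locus$end - tract$end
    m1 <- if (w1 > 0) depth_mean(depth, s, locus$chrom, locus$start,
                                 tract$start) else 0
    m2 <- if (w2 > 0) depth_mean(depth, s, locus$chrom, tract$end,
                                 locus$end) else 0
    (m1 * max(w1, 0) + m2 * max(w2, 0)) / (max(w1, 0) + max(w2, 0))
  }
  samples <- unique(depth$sample)
  out <- lapply(samples, function(s) {
    d_rhd <- mean_excluding(s, rhd, rhd_ex2)
    d_rhce <- mean_excluding(s, rhce, rhce_ex2)
    d_rhd_ex2 <- depth_mean(depth, s, rhd_ex2$chrom, rhd_ex2$start, rhd_ex2$end)
    d_rhce_ex2 <- depth_mean(depth, s, rhce_ex2$chrom, rhce_ex2$start,
                             rhce_ex2$end)
    zyg <- rhd_zygosity(d_rhd, d_rhce, thresholds)
    if (method == "legacy" || zyg$zygosity %in% c("null", "no-call")) {
      cc <- infer_Cc_legacy(d_rhce_ex2, d_rhce, thresholds)
      used <- "legacy"
    } else {
      cc <- infer_Cc_modified(d_rhce_ex2, d_rhd_ex2, zyg$zygosity, thresholds)
      used <- "modified"
    }
    data.frame(sample = s, zygosity = zyg$zygosity, rhd_ratio = zyg$ratio,
               cc_phenotype = cc$phenotype, cc_ratio = cc$ratio,
               method = used)
  })
  do.call(rbind, out)
}
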