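# Serology-vs-prediction concordance statistics and discordance triage.
#
# Serology is treated as truth.  Antigen accuracy is the percent of donors
# whose expression of that antigen is correctly predicted; system accuracy
# requires every tested antigen of the system to match; weak-positive
# predictions count as positive; no-calls count as incorrect.
# Discordances are enumerated one per sample-subsystem, with M/N and S/s
# counted separately within MNS.

.subsystems <- function(panel) {
  subs <- list()
  for (sys in names(panel$systems)) {
    if (sys == "MNS") {
      subs[["MNS (M/N)"]] <- list(system = "MNS", antigens = c("M", "N"))
      subs[["MNS (S/s)"]] <- list(system = "MNS", antigens = c("S", "s"))
    } else {
      subs[[sys]] <- list(system = sys, antigens = panel$systems[[sys]])
    }
  }
  subs
}

.match_matrix <- function(pred, serology) {
  pp <- prediction_positive(pred)
  sp <- serology_positive(serology)
  samples <- intersect(rownames(pp), rownames(sp))
  antigens <- intersect(colnames(pp), colnames(sp))
  if (length(samples) == 0) {
    stop("no overlapping samples between predictions and serology",
         call. = FALSE)
  }
  pp <- pp[samples, antigens, drop = FALSE]
  sp <- sp[samples, antigens, drop = FALSE]
  ok <- pp == sp
  ok[is.na(ok)] <- FALSE     # no-calls are counted incorrect
  list(ok = ok, pred = pp, sero = sp, samples = samples)
}

#' Per-antigen prediction accuracy
#'
#' @param pred a `bg_predictions` data frame.
#' @param serology a `bg_serology` grade matrix.
#' @param antigen antigen name.
#' @return percentage in \[0, 100\].
#' @export
antigen_accuracy <- function(pred, serology, antigen) {
  m <- .match_matrix(pred, serology)
  if (!antigen %in% colnames(m$ok)) {
    stop("antigen not present on both sides: ", antigen, call. = FALSE)
  }
  100 * mean(m$ok[, antigen])
}

#' Per-system prediction accuracy
#'
#' A donor counts correct only if every tested antigen of the system
#' matches serology.
#'
#' @param pred a `bg_predictions` data frame.
#' @param serology a `bg_serology` grade matrix.
#' @param system system name.
#' @param panel a [bg_panel()].
#' @return percentage in \[0, 100\].
#' @export
system_accuracy <- function(pred, serology, system, panel = bg_panel()) {
  antigens <- antigens_of(system, panel)
  m <- .match_matrix(pred, serology)
  antigens <- intersect(antigens, colnames(m$ok))
  if (length(antigens) == 0) {
    stop("no tested antigens for system ", system, call. = FALSE)
  }
  100 * mean(apply(m$ok[, antigens, drop = FALSE], 1, all))
}

#' Full concordance report
#'
#' Per-antigen and per-system accuracies, their unweighted average (to one
#' decimal), and the enumerated discordances, one row per sample-subsystem
#' (M/N and S/s counted separately within MNS).  Direction is
#' false-negative when the genotype predicted no expression but serology
#' was positive, false-positive for the reverse.
#'
#' @param pred a `bg_predictions` data frame.
#' @param serology a `bg_serology` grade matrix.
#' @param panel a [bg_panel()].
#' @return list of class `bg_concordance`: `n`, `antigen_accuracy` (named
#'   vector), `system_accuracy` (named vector), `average_accuracy`,
#'   `discordances` (data frame).
#' @export
summarize_concordance <- function(pred, serology, panel = bg_panel()) {
  m <- .match_matrix(pred, serology)
  antigens <- colnames(m$ok)
  ag_acc <- setNames(100 * colMeans(m$ok), antigens)
  sys_acc <- setNames(
    vapply(names(panel$systems), function(sys)
      system_accuracy(pred, serology, sys, panel), 0),
    names(panel$systems))
  if (any(is.na(sys_acc))) stop("missing system accuracy", call. = FALSE)

  disc <- list()
  for (lbl in names(.subsystems(panel))) {
    sub <- .subsystems(panel)[[lbl]]
    ags <- intersect(sub$antigens, antigens)
    if (length(ags) == 0) next
    bad <- which(!apply(m$ok[, ags, drop = FALSE], 1, all))
    for (i in bad) {
      s <- m$samples[i]
      mism <- ags[!m$ok[i, ags]]
      sero_ph <- paste0(ags, ifelse(m$sero[i, ags], "+", "-"), collapse = "")
      pred_ph <- paste0(ags, ifelse(is.na(m$pred[i, ags]), "?",
                                    ifelse(m$pred[i, ags], "+", "-")),
                        collapse = "")
      dir_per <- ifelse(is.na(m$pred[i, mism]) | !m$pred[i, mism],
                        "false-negative", "false-positive")
      direction <- if (length(unique(dir_per)) == 1) dir_per[1] else "mixed"
      disc[[length(disc) + 1]] <- data.frame(
        sample = s, subsystem = lbl, system = sub$system,
        serology = sero_ph, predicted = pred_ph,
        antigens = paste(mism, collapse = ","), direction = direction)
    }
  }
  disc <- if (length(disc) > 0) do.call(rbind, disc)
          else data.frame(sample = character(0), subsystem = character(0),
                          system = character(0), serology = character(0),
                          predicted = character(0), antigens = character(0),
                          direction = character(0))
  structure(list(
    n = length(m$samples),
    antigen_accuracy = ag_acc,
    system_accuracy = sys_acc,
    average_accuracy = round(mean(sys_acc), 1),
    discordances = disc), class = "bg_concordance")
}

#' @export
print.bg_concordance <- function(x, ...) {
  cat("<bg_concordance> n =", x$n, "\n")
  cat("  average system accuracy:", x$average_accuracy, "%\n")
  cat("  system accuracies:\n")
  print(round(x$system_accuracy))
  cat("  discordances:", nrow(x$discordances), "in",
      length(unique(x$discordances$sample)), "donors\n")
  invisible(x)
}

.severity_rank <- c(nonsense = 1, frameshift = 2, missense = 3,
                    "splice-region" = 4, "regulatory-overlap" = 5)

.load_extdata_tsv <- function(name) {
  read.table(system.file("extdata", name, package = "bloodgroupr"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Triage a discordant sample for rare candidate variants
#'
#' Scans the full cohort VCF for variants carried by the discordant sample
#' within the gene bodies of the implicated system or within supplied
#' regulatory intervals (e.g. transcription-factor binding-site BEDs),
#' keeping those with cohort allele count at or below the ceiling.  Panel
#' variants (the predictors themselves) are excluded.  Candidates get a
#' rule-based consequence class from the shipped transcript annotation:
#' CDS indels whose length change is not a multiple of three are
#' frameshift, CDS SNVs missense, variants within 8 bp of a CDS edge
#' splice-region, and variants inside a supplied interval
#' regulatory-overlap.  Gene-body variants with none of these predicted
#' effects are not candidates.  Output is ordered by consequence severity,
#' then allele count.
#'
#' @param sample the discordant sample id.
#' @param system the implicated blood group system.
#' @param vcf_path full cohort VCF.
#' @param panel a [bg_panel()].
#' @param tfbs_beds named character vector of BED paths with candidate
#'   regulatory intervals (names label the region source).
#' @param ac_ceiling maximum cohort alternate-allele count (default 2).
#' @return data frame: sample, id, chrom, pos, ref, alt, ac, region,
#'   consequence.
#' @export
triage_discordance <- function(sample, system, vcf_path, panel,
                               tfbs_beds = character(0), ac_ceiling = 2) {
  genes <- .load_extdata_tsv("gene_regions.tsv")
  genes <- genes[genes$system == system, , drop = FALSE]
  cds <- .load_extdata_tsv("cds_regions.tsv")

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  fixed <- as.data.frame(fx, stringsAsFactors = FALSE)
  fixed$POS <- as.integer(fixed$POS)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!sample %in% colnames(gt)) {
    stop("sample absent from VCF: ", sample, call. = FALSE)
  }

  beds <- lapply(tfbs_beds, read_bed)
  in_gene <- rep(FALSE, nrow(fixed))
  for (i in seq_len(nrow(genes))) {
    in_gene <- in_gene | (fixed$CHROM == genes$chrom[i] &
                          fixed$POS > genes$start[i] &
                          fixed$POS <= genes$end[i])
  }
  if (!any(in_gene) && length(beds) == 0) {
    stop("VCF has no coverage of the ", system, " gene regions",
         call. = FALSE)
  }
  bed_hit <- rep(NA_character_, nrow(fixed))
  for (nm in names(beds)) {
    b <- beds[[nm]]
    for (i in seq_len(nrow(b))) {
      hit <- fixed$CHROM == b$chrom[i] & fixed$POS > b$start[i] &
             fixed$POS <= b$end[i]
      bed_hit[hit & is.na(bed_hit)] <-
        if (!is.na(b$name[i])) b$name[i] else nm
    }
  }

  alt_count <- function(g) {
    a <- unlist(strsplit(g, "[/|]"))
    sum(a == "1", na.rm = TRUE)
  }
  ac <- apply(gt, 1, function(row) sum(vapply(row, alt_count, 0L)))
  carried <- vapply(gt[, sample], alt_count, 0L) > 0

  panel_keys <- vapply(seq_len(nrow(panel$variants)), function(i)
    .variant_key(panel$variants$chrom[i], panel$variants$pos[i],
                 panel$variants$ref[i], panel$variants$alt[i]), "")
  keys <- vapply(seq_len(nrow(fixed)), function(i)
    .variant_key(fixed$CHROM[i], fixed$POS[i], fixed$REF[i], fixed$ALT[i]),
    "")

  keep <- carried & ac > 0 & ac <= ac_ceiling & (in_gene | !is.na(bed_hit)) &
          !(keys %in% panel_keys)
  if (!any(keep)) {
    return(data.frame(sample = character(0), id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), ac = integer(0),
                      region = character(0), consequence = character(0)))
  }
  idx <- which(keep)
  consequence <- region <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (!is.na(bed_hit[i])) {
      consequence[j] <- "regulatory-overlap"
      region[j] <- bed_hit[i]
      next
    }
    g <- genes[fixed$CHROM[i] == genes$chrom &
               fixed$POS[i] > genes$start & fixed$POS[i] <= genes$end, ]
    region[j] <- if (nrow(g) > 0) g$gene[1] else "gene body"
    cds_g <- cds[cds$gene %in% g$gene, , drop = FALSE]
    in_cds <- FALSE; near_cds <- FALSE
    for (k in seq_len(nrow(cds_g))) {
      if (fixed$POS[i] > cds_g$start[k] && fixed$POS[i] <= cds_g$end[k]) {
        in_cds <- TRUE
      } else if (fixed$POS[i] > cds_g$start[k] - 8 &&
                 fixed$POS[i] <= cds_g$end[k] + 8) {
        near_cds <- TRUE
      }
    }
    is_indel <- nchar(fixed$REF[i]) != nchar(fixed$ALT[i])
    consequence[j] <- if (in_cds && is_indel &&
                          (abs(nchar(fixed$REF[i]) - nchar(fixed$ALT[i])) %% 3
                           != 0)) "frameshift"
      else if (in_cds) "missense"
      else if (near_cds) "splice-region"
      else NA_character_
  }
  ok <- !is.na(consequence)
  out <- data.frame(
    sample = sample,
    id = fixed$ID[idx][ok], chrom = fixed$CHROM[idx][ok],
    pos = fixed$POS[idx][ok], ref = fixed$REF[idx][ok],
    alt = fixed$ALT[idx][ok], ac = ac[idx][ok],
    region = region[ok], consequence = consequence[ok])
  out <- out[order(.severity_rank[out$consequence], out$ac, out$pos), ]
  rownames(out) <- NULL
  out
}
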