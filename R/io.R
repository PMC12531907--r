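# Readers and writers: phased VCF genotypes at panel sites, per-window depth
# tracks, serology grade tables (one row per donor, one column per antigen)
# and BED interval sets.  Coordinate conventions: VCF positions are 1-based
# inclusive; BED and depth windows are 0-based half-open.

#' Read phased genotypes at panel sites from a VCF
#'
#' Resolves every SNV/indel panel site for every sample into an ordered
#' haplotype pair.  Indel representations are normalized (common
#' leading/trailing bases trimmed, position adjusted) before matching, so
#' equivalent encodings of the same deletion match regardless of VCF
#' dialect.  Panel sites absent from the VCF are assumed homozygous
#' reference (the joint-calling convention of omitting invariant rows) and
#' flagged; set `missing_as` to `"no-call"` to treat them as missing
#' instead.
#'
#' Unphased heterozygotes at multi-variant systems are resolved to the most
#' frequent known haplotype configuration (e.g. ABO c.261del in trans to
#' the B-defining variants; FUT3 c.202T>C and c.314C>T on opposite
#' haplotypes) and a warning is recorded in the `notes` attribute.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param panel a [bg_panel()].
#' @param missing_as `"hom-ref"` (default) or `"no-call"` for panel sites
#'   absent from the VCF.
#' @return a `bg_haplotypes` object: list with character matrices `hap1`,
#'   `hap2` (values `"ref"`/`"alt"`/`NA`, rows = panel variant ids, columns
#'   = samples), logical matrix `phased`, `samples`, and a data frame
#'   `notes` of per-site flags.
#' @export
read_phased_genotypes <- function(vcf_path, panel,
                                  missing_as = c("hom-ref", "no-call")) {
  missing_as <- match.arg(missing_as)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fixed <- vcfR::getFIX(vcf)
  if (is.null(dim(fixed))) fixed <- matrix(fixed, nrow = 1,
                                           dimnames = list(NULL, names(fixed)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field", call. = FALSE)
  samples <- colnames(gt_raw)

  vcf_key <- vapply(seq_len(nrow(fixed)), function(i) {
    .variant_key(fixed[i, "CHROM"], as.integer(fixed[i, "POS"]),
                 fixed[i, "REF"], fixed[i, "ALT"])
  }, "")

  snv <- panel$variants[panel$variants$class != "structural-tag", ]
  hap1 <- hap2 <- matrix(NA_character_, nrow = nrow(snv), ncol = length(samples),
                         dimnames = list(snv$id, samples))
  phased <- matrix(TRUE, nrow = nrow(snv), ncol = length(samples),
                   dimnames = list(snv$id, samples))
  notes <- list()

  for (i in seq_len(nrow(snv))) {
    key <- .variant_key(snv$chrom[i], snv$pos[i], snv$ref[i], snv$alt[i])
    row <- match(key, vcf_key)
    if (is.na(row)) {
      if (missing_as == "hom-ref") {
        hap1[i, ] <- "ref"; hap2[i, ] <- "ref"
        notes[[length(notes) + 1]] <- data.frame(
          variant = snv$id[i], sample = NA_character_,
          note = "assumed hom-ref (site absent from VCF)")
      }
      next
    }
    g <- gt_raw[row, ]
    sep_phased <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[/|]")
    a1 <- vapply(parts, function(p) p[1] %||% ".", "")
    a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else ".", "")
    hap1[i, ] <- .gt_allele(a1)
    hap2[i, ] <- .gt_allele(a2)
    phased[i, ] <- sep_phased | (a1 == a2)
  }

  out <- structure(list(hap1 = hap1, hap2 = hap2, phased = phased,
                        samples = samples,
                        notes = do.call(rbind, notes)),
                   class = "bg_haplotypes")
  .resolve_unphased(out, panel)
}

.gt_allele <- function(a) {
  ifelse(a == "0", "ref", ifelse(a == "1", "alt", NA_character_))
}

# normalize an allele pair: trim shared trailing bases, then shared leading
# bases (advancing pos), so left/right-shifted indel encodings match
.variant_key <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

# Most-frequent-configuration resolution for unphased multi-site
# heterozygotes.  Each rule lists sites whose alt alleles ride together
# (cis) or apart (trans) on the commonest haplotypes.
.phase_rules <- list(
  list(sites = c("rs8176746", "rs8176747"), mode = "cis"),
  list(sites = c("rs8176719", "rs8176746"), mode = "cis"),
  list(sites = c("rs7682260", "rs7687256", "rs7658293"), mode = "cis"),
  list(sites = c("rs5751348", "rs8138197", "rs2143918"), mode = "cis"),
  list(sites = c("rs12075", "rs2814778"), mode = "cis"),
  list(sites = c("rs812936", "rs778986"), mode = "trans"),
  list(sites = c("rs28362459", "rs3894326"), mode = "trans")
)

.resolve_unphased <- function(h, panel) {
  for (s in h$samples) {
    het <- !is.na(h$hap1[, s]) & h$hap1[, s] != h$hap2[, s] & !h$phased[, s]
    if (!any(het)) next
    for (rule in .phase_rules) {
      sites <- intersect(rule$sites, rownames(h$hap1))
      hs <- sites[het[sites]]
      if (length(hs) < 2) next
      anchor <- hs[1]
      # orient anchor alt onto hap1, then place the rest per rule
      h$hap1[anchor, s] <- "alt"; h$hap2[anchor, s] <- "ref"
      for (v in hs[-1]) {
        if (rule$mode == "cis") {
          h$hap1[v, s] <- "alt"; h$hap2[v, s] <- "ref"
        } else {
          h$hap1[v, s] <- "ref"; h$hap2[v, s] <- "alt"
        }
      }
      h$notes <- rbind(h$notes, data.frame(
        variant = paste(hs, collapse = "+"), sample = s,
        note = paste0("unphased heterozygotes resolved to most frequent ",
                      rule$mode, " configuration")))
    }
  }
  h
}

#' Read a serology grade table
#'
#' One row per donor, one column per antigen; entries are reaction grades
#' 0-4 where 0 is a negative reaction (clear red-cell button) and 1-4 are
#' positive.
#'
#' @param path TSV path; first column `sample`, remaining columns antigens.
#' @param panel a [bg_panel()]; used to validate antigen names.
#' @return integer matrix (samples x antigens) of grades with class
#'   `bg_serology`.
#' @export
read_serology <- function(path, panel) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "sample") {
    stop("serology table must have 'sample' as its first column",
         call. = FALSE)
  }
  antigens <- unlist(panel$systems)
  unknown <- setdiff(names(df)[-1], antigens)
  if (length(unknown) > 0) {
    stop("unknown antigen column(s) in serology table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  bad <- which(is.na(m) | m < 0L | m > 4L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("serology grade outside 0-4 at sample ",
         rownames(m)[bad[1, 1]], ", antigen ", colnames(m)[bad[1, 2]],
         call. = FALSE)
  }
  structure(m, class = c("bg_serology", class(m)))
}

#' Positivity from serology grades
#'
#' @param serology a `bg_serology` matrix of grades.
#' @return logical matrix; grade >= 1 is positive.
#' @export
serology_positive <- function(serology) {
  unclass(serology) >= 1L
}

#' Read a per-window depth track
#'
#' @param path TSV with columns sample, chrom, start, end, depth
#'   (0-based half-open windows, mean MAPQ-filtered depth per window).
#' @return data frame of class `bg_depth`, sorted by sample, chrom, start.
#' @export
read_depth <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "start", "end", "depth")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("depth track missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$sample, df$chrom, df$start), required]
  if (any(df$depth < 0)) stop("negative depth in track", call. = FALSE)
  by_sc <- split(df, list(df$sample, df$chrom), drop = TRUE)
  for (grp in by_sc) {
    if (nrow(grp) > 1 && any(grp$start[-1] < grp$end[-nrow(grp)])) {
      stop("overlapping depth windows for sample ", grp$sample[1],
           " on ", grp$chrom[1], call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("bg_depth", "data.frame"))
}

#' Mean depth over an interval
#'
#' Overlap-weighted mean of window depths across `[start, end)` for one
#' sample.  Positions not covered by any window count as zero depth, so an
#' empty region yields 0, not `NA`.
#'
#' @param depth a `bg_depth` track.
#' @param sample sample id.
#' @param chrom chromosome.
#' @param start,end 0-based half-open interval.
#' @return numeric mean depth.
#' @export
depth_mean <- function(depth, sample, chrom, start, end) {
  stopifnot(end > start)
  d <- depth[depth$sample == sample & depth$chrom == chrom &
             depth$end > start & depth$start < end, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  ov <- pmin(d$end, end) - pmax(d$start, start)
  sum(d$depth * ov) / (end - start)
}

#' Compute a windowed depth track from a BAM file
#'
#' Counts reads with mapping quality above `min_mapq` and converts to mean
#' per-base depth in fixed windows.  This is the optional alignment-backed
#' route; the primary interface is a precomputed depth TSV.
#'
#' @param bam_path indexed BAM.
#' @param sample sample id to record in the track.
#' @param chrom,start,end region to tile (0-based half-open).
#' @param window window size in bp.
#' @param min_mapq exclusive MAPQ threshold; reads must have MAPQ > this.
#' @return a `bg_depth` data frame.
#' @export
depth_from_bam <- function(bam_path, sample, chrom, start, end,
                           window = 500L, min_mapq = 20L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("depth_from_bam requires the Rsamtools package", call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("pos", "qwidth", "mapq"),
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end)))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  keep <- !is.na(res$mapq) & res$mapq > min_mapq
  pos <- res$pos[keep]; w <- res$qwidth[keep]
  starts <- seq(start, end - 1L, by = window)
  ends <- pmin(starts + window, end)
  cov <- numeric(length(starts))
  for (j in seq_along(pos)) {
    r1 <- pos[j] - 1L; r2 <- r1 + w[j]   # read interval, 0-based half-open
    ov <- pmin(ends, r2) - pmax(starts, r1)
    cov <- cov + pmax(ov, 0)
  }
  structure(data.frame(sample = sample, chrom = chrom, start = starts,
                       end = ends, depth = cov / (ends - starts)),
            class = c("bg_depth", "data.frame"))
}

#' Read a BED interval file (BED3 plus optional name column)
#'
#' @param path BED path (0-based half-open intervals).
#' @return data frame with chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name" else df$name <- NA_character_
  df[, c("chrom", "start", "end", "name")]
}

#' Write a minimal phased VCF
#'
#' @param variants data frame with id, chrom, pos, ref, alt (rows in output
#'   order).
#' @param gt character matrix of genotypes (`"0|1"` etc.), rows matching
#'   `variants`, columns = samples.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, gt, path) {
  stopifnot(nrow(variants) == nrow(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bloodgroupr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")), con)
  ord <- order(variants$chrom, variants$pos)
  body <- vapply(ord, function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write a serology grade table
#' @param serology `bg_serology` matrix or plain integer matrix.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_serology <- function(serology, path) {
  df <- data.frame(sample = rownames(serology),
                   unclass(serology)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a depth track
#' @param depth `bg_depth` data frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_depth <- function(depth, path) {
  write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
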