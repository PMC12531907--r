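#' @importFrom utils read.table write.table
#' @importFrom stats setNames rnbinom
NULL

# Ordered antigen panel: nine systems, 24 antigens.  The order is the
# conventional serology-panel order (ABO, Rh, Kell, Kidd, Duffy, Lewis,
# Lutheran, MNS, P1) and is relied on throughout for stable output.
.bg_systems <- list(
  ABO      = c("A", "B"),
  Rh       = c("D", "C", "c", "E", "e"),
  Kell     = c("K", "k", "Kpa", "Kpb"),
  Kidd     = c("Jka", "Jkb"),
  Duffy    = c("Fya", "Fyb"),
  Lewis    = c("Lea", "Leb"),
  Lutheran = c("Lua", "Lub"),
  MNS      = c("M", "N", "S", "s"),
  P1       = c("P1")
)

.bg_antithetical <- list(
  c("K", "k"), c("Kpa", "Kpb"), c("Jka", "Jkb"), c("Lua", "Lub"),
  c("S", "s"), c("C", "c"), c("E", "e")
)

#' Load a blood group variant panel
#'
#' Reads the variant panel, named-allele definitions and region annotation
#' that drive phenotype inference.  The builtin panel covers 24 antigens in
#' nine blood group systems, with one row per genetic change (SNV, indel or
#' structural tag).  Structural alleles (RHD deletion, RHCE exon-2
#' conversion, GYPB deletion, Dantu) are represented as structural tags and
#' are resolved by the copy-number modules, not from VCF genotypes.
#'
#' @param variants_path path to a variants TSV (id, system, chrom, pos, ref,
#'   alt, cdna, protein, class); `NULL` for the builtin panel.
#' @param alleles_path path to an allele-definition TSV (allele, system,
#'   requires, effects); `NULL` for the builtin.
#' @param regions_path path to a region TSV (name, chrom, start, end, role);
#'   `NULL` for the builtin.
#' @return An object of class `bg_panel`: a list with `variants`,
#'   `alleles`, `regions` data frames, the ordered `systems` list and
#'   `antithetical` pairs.
#' @export
#' @examples
#' panel <- bg_panel()
#' nrow(panel$variants)
bg_panel <- function(variants_path = NULL, alleles_path = NULL,
                     regions_path = NULL) {
  variants_path <- variants_path %||%
    system.file("extdata", "panel_variants.tsv", package = "bloodgroupr")
  alleles_path <- alleles_path %||%
    system.file("extdata", "panel_alleles.tsv", package = "bloodgroupr")
  regions_path <- regions_path %||%
    system.file("extdata", "panel_regions.tsv", package = "bloodgroupr")

  variants <- .read_panel_tsv(variants_path, "variants",
    c("id", "system", "chrom", "pos", "ref", "alt", "cdna", "protein", "class"))
  alleles <- .read_panel_tsv(alleles_path, "alleles",
    c("allele", "system", "requires", "effects"))
  regions <- .read_panel_tsv(regions_path, "regions",
    c("name", "chrom", "start", "end", "role"))

  variants$pos <- as.integer(variants$pos)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)

  .validate_panel(variants, alleles)

  structure(list(
    variants = variants,
    alleles = alleles,
    regions = regions,
    systems = .bg_systems,
    antithetical = .bg_antithetical
  ), class = "bg_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_panel_tsv <- function(path, what, required_cols) {
  if (!file.exists(path)) {
    stop("panel ", what, " file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", quote = "",
               colClasses = "character", comment.char = ""),
    error = function(e) {
      stop("malformed panel ", what, " file (", conditionMessage(e), ")",
           call. = FALSE)
    })
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("panel ", what, " file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("panel ", what, " file is empty: ", path, call. = FALSE)
  }
  df
}

.validate_panel <- function(variants, alleles) {
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant id(s) in panel: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(variants$pos <= 0)) stop("variant pos must be positive", call. = FALSE)
  if (any(variants$ref == variants$alt)) {
    stop("variant ref and alt must differ", call. = FALSE)
  }
  bad_sys <- setdiff(unique(variants$system), names(.bg_systems))
  if (length(bad_sys) > 0) {
    stop("unknown system(s) in variant panel: ",
         paste(bad_sys, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(alleles))) {
    req <- .parse_requires(alleles$requires[i])
    unknown <- setdiff(names(req), variants$id)
    if (length(unknown) > 0) {
      stop("allele ", alleles$allele[i], " references unknown variant(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    eff <- .parse_effects(alleles$effects[i])
    sys_ag <- .bg_systems[[alleles$system[i]]]
    if (is.null(sys_ag)) {
      stop("allele ", alleles$allele[i], " has unknown system ",
           alleles$system[i], call. = FALSE)
    }
    bad_ag <- setdiff(names(eff), sys_ag)
    if (length(bad_ag) > 0) {
      stop("allele ", alleles$allele[i], " affects antigen(s) outside its ",
           "system: ", paste(bad_ag, collapse = ", "), call. = FALSE)
    }
  }
  # every antigen must be reachable through at least one allele effect
  all_eff <- unlist(lapply(alleles$effects, function(e) names(.parse_effects(e))))
  orphan <- setdiff(unlist(.bg_systems), all_eff)
  if (length(orphan) > 0) {
    stop("antigen(s) not referenced by any allele definition: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# "rs1=alt;rs2=ref" -> named character vector
.parse_requires <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

.parse_effects <- .parse_requires

#' Write a panel back to TSV files
#'
#' Re-emits the variants and alleles tables in the same column order and
#' format the loader reads, so that a load/write cycle is lossless.
#'
#' @param panel a `bg_panel` object.
#' @param variants_path,alleles_path output paths.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, variants_path, alleles_path) {
  stopifnot(inherits(panel, "bg_panel"))
  write.table(panel$variants, variants_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(panel$alleles, alleles_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(variants_path, alleles_path))
}

#' Ordered antigens of a blood group system
#'
#' @param system system name, e.g. `"Kidd"`.
#' @param panel a `bg_panel` (defaults to the builtin).
#' @return character vector of antigen names in panel order.
#' @export
#' @examples
#' antigens_of("Kidd")
antigens_of <- function(system, panel = NULL) {
  systems <- if (is.null(panel)) .bg_systems else panel$systems
  if (!system %in% names(systems)) {
    stop("unknown blood group system: ", system, call. = FALSE)
  }
  systems[[system]]
}

#' Alternate-allele frequency of a panel variant
#'
#' Computes alt-allele count over called haplotypes from a genotype matrix
#' (rows = variants, columns = samples, entries like `"0|1"`, `"0/0"`, or
#' `"."` for missing).
#'
#' @param gt genotype matrix with rownames containing the variant id.
#' @param variant_id panel variant id (e.g. an rsID).
#' @return frequency in \[0, 1\].
#' @export
allele_frequency <- function(gt, variant_id) {
  if (!variant_id %in% rownames(gt)) {
    stop("variant not present in genotype matrix: ", variant_id,
         call. = FALSE)
  }
  g <- gt[variant_id, ]
  alleles <- unlist(strsplit(g, "[/|]"))
  alleles <- alleles[alleles %in% c("0", "1")]
  if (length(alleles) == 0) {
    stop("no called genotypes at ", variant_id, call. = FALSE)
  }
  sum(alleles == "1") / length(alleles)
}

#' @export
print.bg_panel <- function(x, ...) {
  cat("<bg_panel> ", nrow(x$variants), " variants, ",
      nrow(x$alleles), " named alleles, ",
      length(unlist(x$systems)), " antigens in ",
      length(x$systems), " systems\n", sep = "")
  invisible(x)
}
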