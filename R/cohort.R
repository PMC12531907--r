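# Synthetic cohort generator.
#
# Cohorts are built at the haplotype level: for each blood group system a
# haplotype class is drawn per chromosome under Hardy-Weinberg (independent
# draws at the configured haplotype frequencies), cis-linkage is encoded in
# the class definitions themselves (e.g. the ABO B class carries both
# B-defining variants; the Duffy GATA promoter variant rides on Fyb
# haplotypes), and genotypes, depth tracks and serology all derive from the
# same truth.
#
# Depth model: each haplotype contributes half the diploid mean depth.
# RHCE*C haplotypes carry RHD-like exon-2 sequence, so a fraction `mismap`
# (default 1) of their exon-2-tract reads is reassigned to RHD exon 2.  A
# second, background fraction `cross_mismap` (default 0) of RHD-origin
# exon-2 reads lands on RHCE exon 2, emulating bidirectional paralog
# cross-mapping.  Window noise is negative-binomial at the read-count
# level with size 60, giving a coefficient of variation of ~0.15 for a
# 1600-bp window at 16x.

.default_hap_freqs <- function() {
  list(
    abo  = c(O = 0.79, A = 0.115, B = 0.095),
    rhd  = c(norm = 0.7724, del = 0.19, pseudo = 0.0376),
    cc   = c(c = 0.54, C = 0.46),
    ee   = c(e = 0.865, E = 0.12, Ew = 0.015),
    kell = c(k = 0.965, K = 0.035),
    kpa  = c(b = 0.99, a = 0.01),
    jk   = c(a = 0.64, b = 0.36),
    fy   = c(A = 0.045, Bx = 0.065, Bg = 0.87, BgW = 0.015, BgF = 0.005),
    fut3 = c(N1 = 0.48, N2 = 0.01, A202 = 0.13, A202G = 0.115,
             B314 = 0.2, B314A = 0.055, WT = 0.01),
    fut2 = c(Se = 0.595, se = 0.405),
    lu   = c(b = 0.985, a = 0.015),
    gypa = c(N = 0.36, M = 0.64),
    gypb = c(s = 0.57, S = 0.40, del = 0.015, He = 0.01, Dantu = 0.005),
    p1   = c(P1 = 0.575, P2 = 0.41, P2b = 0.015)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the analysis assumes: 16x mean
#' depth, complete mismapping of RHCE*C exon-2 reads onto RHD exon 2, and
#' haplotype frequencies matching the published cohort's allele
#' frequencies with the documented cis-linkage (B-defining ABO variants in
#' cis; Duffy GATA in cis with Fyb; FUT3 c.202T>C and c.314C>T largely on
#' opposite haplotypes except on the null haplotype that carries both).
#'
#' @param n number of samples.
#' @param seed RNG seed; every random draw is derived from it.
#' @param hap_freqs named list of per-system haplotype class frequencies
#'   (each summing to 1).
#' @param mean_depth diploid mean depth.
#' @param mismap fraction of RHCE*C exon-2-tract reads reassigned to RHD
#'   exon 2.
#' @param cross_mismap background fraction of RHD-origin exon-2 reads
#'   landing on RHCE exon 2.
#' @param nb_size negative-binomial size for window read counts; `Inf` (or
#'   `noise = FALSE`) for noise-free depth.
#' @param noise logical; FALSE yields exact expected depth in every window.
#' @param depth_tracks logical; FALSE skips depth-track generation (useful
#'   for large genotype-only cohorts).
#' @param rh_window,gyp_window depth window sizes (bp) for the Rh region
#'   and the glycophorin region.
#' @param discordances list of injection specs, see [inject_discordance()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n = 100, seed = 1, hap_freqs = .default_hap_freqs(),
                          mean_depth = 16, mismap = 1.0, cross_mismap = 0,
                          nb_size = 60, noise = TRUE, depth_tracks = TRUE,
                          rh_window = 500L, gyp_window = 1600L,
                          discordances = list()) {
  for (sys in names(hap_freqs)) {
    f <- hap_freqs[[sys]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop("haplotype frequencies for ", sys, " must be in [0,1] and sum ",
           "to 1", call. = FALSE)
    }
  }
  structure(list(n = n, seed = seed, hap_freqs = hap_freqs,
                 mean_depth = mean_depth, mismap = mismap,
                 cross_mismap = cross_mismap, nb_size = nb_size,
                 noise = noise, depth_tracks = depth_tracks,
                 rh_window = as.integer(rh_window),
                 gyp_window = as.integer(gyp_window),
                 discordances = discordances),
            class = "cohort_config")
}

# one haplotype-class draw per system per chromosome
.draw_haps <- function(config) {
  n <- config$n
  samples <- sprintf("S%04d", seq_len(n))
  truth <- data.frame(sample = samples)
  for (sys in names(config$hap_freqs)) {
    f <- config$hap_freqs[[sys]]
    for (k in 1:2) {
      truth[[paste0(sys, k)]] <-
        sample(names(f), n, replace = TRUE, prob = f)
    }
  }
  truth
}

# map haplotype classes to per-haplotype 0/1 at each panel variant
.hap_variant_map <- list(
  rs8176719   = function(t, k) as.integer(t[[paste0("abo", k)]] != "O"),
  rs8176746   = function(t, k) as.integer(t[[paste0("abo", k)]] == "B"),
  rs8176747   = function(t, k) as.integer(t[[paste0("abo", k)]] == "B"),
  rs748783394 = function(t, k) as.integer(t[[paste0("rhd", k)]] == "pseudo"),
  rs609320    = function(t, k)
    as.integer(t[[paste0("ee", k)]] %in% c("E", "EEw")),
  rs141398055 = function(t, k)
    as.integer(t[[paste0("ee", k)]] %in% c("Ew", "EEw")),
  rs8176058   = function(t, k) as.integer(t[[paste0("kell", k)]] == "K"),
  rs8176059   = function(t, k) as.integer(t[[paste0("kpa", k)]] == "a"),
  rs1058396   = function(t, k) as.integer(t[[paste0("jk", k)]] == "b"),
  rs12075     = function(t, k) as.integer(t[[paste0("fy", k)]] != "A"),
  rs2814778   = function(t, k)
    as.integer(t[[paste0("fy", k)]] %in% c("Bg", "BgW", "BgF")),
  rs34599082  = function(t, k) as.integer(t[[paste0("fy", k)]] == "BgW"),
  rs773692057 = function(t, k) as.integer(t[[paste0("fy", k)]] == "BgF"),
  rs601338    = function(t, k) as.integer(t[[paste0("fut2", k)]] == "se"),
  rs28362459  = function(t, k)
    as.integer(t[[paste0("fut3", k)]] %in% c("N2", "A202G")),
  rs812936    = function(t, k)
    as.integer(t[[paste0("fut3", k)]] %in% c("N1", "A202", "A202G")),
  rs778986    = function(t, k)
    as.integer(t[[paste0("fut3", k)]] %in% c("N1", "B314", "B314A")),
  rs3894326   = function(t, k)
    as.integer(t[[paste0("fut3", k)]] %in% c("N2", "B314A")),
  rs28399653  = function(t, k) as.integer(t[[paste0("lu", k)]] == "a"),
  rs7682260   = function(t, k) as.integer(t[[paste0("gypa", k)]] == "M"),
  rs7687256   = function(t, k) as.integer(t[[paste0("gypa", k)]] == "M"),
  rs7658293   = function(t, k) as.integer(t[[paste0("gypa", k)]] == "M"),
  rs7683365   = function(t, k) as.integer(t[[paste0("gypb", k)]] == "S"),
  rs139511876 = function(t, k) as.integer(t[[paste0("gypb", k)]] == "He"),
  rs5751348   = function(t, k) as.integer(t[[paste0("p1", k)]] == "P2"),
  rs8138197   = function(t, k)
    as.integer(t[[paste0("p1", k)]] %in% c("P2", "P2b")),
  rs2143918   = function(t, k)
    as.integer(t[[paste0("p1", k)]] %in% c("P2", "P2b")),
  rs66781836  = function(t, k)
    as.integer(t[[paste0("p1", k)]] %in% c("P2", "P2b"))
)

# phased genotype matrix (variants x samples) of "a|b" strings
.truth_to_gt <- function(truth, panel) {
  snv <- panel$variants[panel$variants$class != "structural-tag", ]
  gt <- matrix("0|0", nrow(snv), nrow(truth),
               dimnames = list(snv$id, truth$sample))
  del1 <- truth$gypb1 == "del"; del2 <- truth$gypb2 == "del"
  for (v in snv$id) {
    f <- .hap_variant_map[[v]]
    if (is.null(f)) next
    a1 <- f(truth, 1); a2 <- f(truth, 2)
    if (v %in% c("rs7683365", "rs139511876")) {
      # a deleted GYPB haplotype leaves the site hemizygous; short-read
      # callers report the remaining haplotype's allele as homozygous
      a1[del1] <- a2[del1]
      a2[del2] <- a1[del2]
    }
    gt[v, ] <- paste0(a1, "|", a2)
  }
  gt
}

# truth phenotype states (positive / weak-positive / negative) per antigen
.truth_phenotype <- function(truth) {
  n <- nrow(truth)
  st <- function(pos, weak = rep(FALSE, n)) {
    ifelse(pos, "positive", ifelse(weak, "weak-positive", "negative"))
  }
  both <- function(col) cbind(truth[[paste0(col, 1)]],
                              truth[[paste0(col, 2)]])
  any_is <- function(col, vals) {
    m <- both(col)
    m[, 1] %in% vals | m[, 2] %in% vals
  }
  count_is <- function(col, vals) {
    m <- both(col)
    (m[, 1] %in% vals) + (m[, 2] %in% vals)
  }

  rhd_copies <- 2 - count_is("rhd", "del")
  functional <- rhd_copies - count_is("rhd", "pseudo")

  fut3_null_hap <- function(k) truth[[paste0("fut3", k)]] %in% c("N1", "N2")
  active <- !(fut3_null_hap(1) & fut3_null_hap(2))
  secretor <- any_is("fut2", "Se")

  m <- cbind(
    A = st(any_is("abo", "A")),
    B = st(any_is("abo", "B")),
    D = st(functional >= 1),
    C = st(any_is("cc", "C")),
    c = st(any_is("cc", "c")),
    E = st(any_is("ee", c("E", "EEw")), any_is("ee", "Ew")),
    e = st(any_is("ee", "e")),
    K = st(any_is("kell", "K")),
    k = st(any_is("kell", "k")),
    Kpa = st(any_is("kpa", "a")),
    Kpb = st(any_is("kpa", "b")),
    Jka = st(any_is("jk", "a")),
    Jkb = st(any_is("jk", "b")),
    Fya = st(any_is("fy", "A")),
    Fyb = st(any_is("fy", "Bx")),
    Lea = st(active & !secretor),
    Leb = st(active & secretor),
    Lua = st(any_is("lu", "a")),
    Lub = st(any_is("lu", "b")),
    M = st(any_is("gypa", "M")),
    N = st(any_is("gypa", "N")),
    S = st(any_is("gypb", "S")),
    s = st(any_is("gypb", "s"), any_is("gypb", "Dantu")),
    P1 = st(any_is("p1", "P1"))
  )
  rownames(m) <- truth$sample
  m
}

# expected (noise-free) depth for every window of every sample
.truth_depth <- function(truth, panel, config) {
  reg <- panel$regions
  r <- function(nm) reg[reg$name == nm, ]
  rhd <- r("rhd_locus"); rhce <- r("rhce_locus")
  rhd_ex2 <- r("rhd_ex2"); rhce_ex2 <- r("rhce_ex2")
  gyp <- r("gyp_region")
  del_span <- r("gypb_del_span"); dantu_t <- r("dantu_template")

  hap_depth <- config$mean_depth / 2
  f <- config$mismap; g <- config$cross_mismap

  rh_starts <- seq(25272000L, 25431000L - config$rh_window,
                   by = config$rh_window)
  gyp_starts <- seq(gyp$start, gyp$end - config$gyp_window,
                    by = config$gyp_window)

  overlaps <- function(starts, ends, iv) ends > iv$start & starts < iv$end

  n <- nrow(truth)
  rhd_copies <- (truth$rhd1 != "del") + (truth$rhd2 != "del")
  c_haps <- (truth$cc1 == "C") + (truth$cc2 == "C")
  gypb_del <- (truth$gypb1 == "del") + (truth$gypb2 == "del")
  dantu <- (truth$gypb1 == "Dantu") + (truth$gypb2 == "Dantu")

  rh_ends <- rh_starts + config$rh_window
  in_rhd <- overlaps(rh_starts, rh_ends, rhd)
  in_rhce <- overlaps(rh_starts, rh_ends, rhce)
  in_rhd_ex2 <- overlaps(rh_starts, rh_ends, rhd_ex2)
  in_rhce_ex2 <- overlaps(rh_starts, rh_ends, rhce_ex2)
  gyp_ends <- gyp_starts + config$gyp_window
  in_del <- overlaps(gyp_starts, gyp_ends, del_span)
  in_dantu <- overlaps(gyp_starts, gyp_ends, dantu_t)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    rh_depth <- rep(config$mean_depth, length(rh_starts))
    rh_depth[in_rhd] <- hap_depth * rhd_copies[i]
    rh_depth[in_rhd_ex2] <- hap_depth * rhd_copies[i] * (1 - g) +
      hap_depth * f * c_haps[i]
    rh_depth[in_rhce] <- config$mean_depth
    rh_depth[in_rhce_ex2] <- hap_depth * (2 - c_haps[i]) +
      hap_depth * c_haps[i] * (1 - f) + hap_depth * rhd_copies[i] * g

    cn <- rep(2, length(gyp_starts))
    cn[in_del] <- cn[in_del] - gypb_del[i]
    cn[in_dantu] <- cn[in_dantu] + dantu[i]
    gyp_depth <- hap_depth * cn

    out[[i]] <- data.frame(
      sample = truth$sample[i],
      chrom = c(rep(rhd$chrom, length(rh_starts)),
                rep(gyp$chrom, length(gyp_starts))),
      start = c(rh_starts, gyp_starts),
      end = c(rh_ends, gyp_ends),
      depth = c(rh_depth, gyp_depth))
  }
  do.call(rbind, out)
}

.add_depth_noise <- function(depth, config) {
  if (!config$noise || !is.finite(config$nb_size)) return(depth)
  w <- depth$end - depth$start
  mu_reads <- depth$depth * w / 150
  reads <- rnbinom(length(mu_reads), mu = mu_reads, size = config$nb_size)
  depth$depth <- reads * 150 / w
  depth
}

# serology grades from truth phenotype: 0 for negative, 1 for
# weak-positive, 2-4 for positive (deterministic cycle over cells)
.serology_from_phenotype <- function(phen) {
  n <- nrow(phen); k <- ncol(phen)
  idx <- outer(seq_len(n), seq_len(k), `+`)
  grades <- matrix(0L, n, k, dimnames = dimnames(phen))
  grades[phen == "weak-positive"] <- 1L
  grades[phen == "positive"] <- 2L + (idx[phen == "positive"] %% 3L)
  structure(grades, class = c("bg_serology", "matrix", "array"))
}

#' Sample a synthetic cohort
#'
#' Draws haplotypes per system under Hardy-Weinberg at the configured
#' class frequencies, derives phased genotypes, expected depth with
#' negative-binomial window noise, true phenotypes, and serology grades
#' (0 negative, 1 weak, 2-4 positive).  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list of class `bg_cohort`: `truth` (haplotype classes),
#'   `phenotype` (truth state matrix), `gt` (phased genotype matrix),
#'   `variants` (VCF rows incl. planted extras), `depth` (`bg_depth` or
#'   `NULL`), `serology` (`bg_serology`), `discordances` (labels of
#'   injected events), `config`.
#' @export
sample_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  panel <- bg_panel()
  truth <- .draw_haps(config)
  gt <- .truth_to_gt(truth, panel)
  phen <- .truth_phenotype(truth)
  depth <- NULL
  if (config$depth_tracks) {
    depth <- .add_depth_noise(.truth_depth(truth, panel, config), config)
    depth <- structure(depth, class = c("bg_depth", "data.frame"))
  }
  serology <- .serology_from_phenotype(phen)
  snv <- panel$variants[panel$variants$class != "structural-tag",
                        c("id", "chrom", "pos", "ref", "alt")]
  cohort <- structure(list(
    truth = truth, phenotype = phen, gt = gt, variants = snv,
    depth = depth, serology = serology,
    discordances = data.frame(sample = character(0), mechanism = character(0),
                              antigen = character(0)),
    config = config), class = "bg_cohort")
  for (spec in config$discordances) {
    cohort <- inject_discordance(cohort, spec)
  }
  cohort
}

#' Inject a discordance event into a cohort
#'
#' Supported mechanisms:
#' \describe{
#'   \item{genotype-miscall}{flip the VCF genotype at one site
#'     (`variant`, `gt`), serology keeps following the truth.}
#'   \item{antigen-silencing}{set serology for `antigen` to grade 0
#'     despite predicted expression.}
#'   \item{weak-expression}{set serology for `antigen` to grade 0 for a
#'     sample whose predicted expression is weak (below assay
#'     sensitivity).}
#'   \item{serology-positive}{set serology for `antigen` to a positive
#'     grade (`grade`, default 2) despite no predicted expression --
#'     an unexplained reaction.}
#'   \item{novel-variant}{change serology for `antigen` (`to` grade) and
#'     plant a private variant row (`variant` list with id, chrom, pos,
#'     ref, alt, and `carriers`).}
#' }
#'
#' @param cohort a `bg_cohort`.
#' @param spec list with `mechanism`, `sample`, and mechanism-specific
#'   fields.
#' @return the modified cohort; injected events are recorded in
#'   `cohort$discordances`.
#' @export
inject_discordance <- function(cohort, spec) {
  mech <- spec$mechanism
  s <- spec$sample
  if (!s %in% rownames(cohort$serology) && mech != "novel-variant") {
    stop("unknown sample in discordance spec: ", s, call. = FALSE)
  }
  if (mech == "genotype-miscall") {
    cohort$gt[spec$variant, s] <- spec$gt
  } else if (mech %in% c("antigen-silencing", "weak-expression")) {
    cohort$serology[s, spec$antigen] <- 0L
  } else if (mech == "serology-positive") {
    cohort$serology[s, spec$antigen] <- as.integer(spec$grade %||% 2L)
  } else if (mech == "novel-variant") {
    if (!is.null(spec$antigen)) {
      cohort$serology[s, spec$antigen] <- as.integer(spec$to)
    }
    vs <- spec$variants %||% list(spec$variant)
    for (v in vs) {
      if (is.null(v) || v$id %in% rownames(cohort$gt)) next
      cohort$variants <- rbind(cohort$variants,
        data.frame(id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref,
                   alt = v$alt))
      row <- setNames(rep("0|0", ncol(cohort$gt)), colnames(cohort$gt))
      row[v$carriers] <- "0|1"
      cohort$gt <- rbind(cohort$gt, matrix(row, 1,
        dimnames = list(v$id, colnames(cohort$gt))))
    }
  } else {
    stop("unknown discordance mechanism: ", mech, call. = FALSE)
  }
  cohort$discordances <- rbind(cohort$discordances, data.frame(
    sample = s, mechanism = mech,
    antigen = spec$antigen %||% NA_character_))
  cohort
}

#' Write a cohort's VCF, depth track and serology table to a directory
#'
#' @param cohort a `bg_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             depth = file.path(dir, "depth.tsv"),
             serology = file.path(dir, "serology.tsv"),
             truth = file.path(dir, "truth_haplotypes.tsv"),
             phenotype = file.path(dir, "truth_phenotype.tsv"))
  write_vcf(cohort$variants, cohort$gt[cohort$variants$id, , drop = FALSE],
            paths["vcf"])
  if (!is.null(cohort$depth)) write_depth(cohort$depth, paths["depth"])
  write_serology(cohort$serology, paths["serology"])
  write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = rownames(cohort$phenotype),
                         cohort$phenotype, check.names = FALSE),
              paths["phenotype"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
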