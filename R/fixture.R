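# Deterministic 100-donor cohort reproducing the published study's
# discordance structure.  Serology antigen-positive counts equal the
# published antigen frequency table by construction, every enumerated
# discordance is encoded with its printed genotypes, and the panel allele
# counts match the published allele frequencies wherever those are
# integral over 200 haplotypes.  Depth tracks are noise-free (exact
# expected coverage under the truth copy numbers), making the whole object
# argument-free and byte-stable.

# assign class pairs to sample indices; `spec` is a list of
# list(idx, hap1, hap2); remaining samples get the default pair
.assign_pairs <- function(n, default, spec) {
  h1 <- rep(default[1], n); h2 <- rep(default[2], n)
  for (s in spec) {
    h1[s$idx] <- s$hap[1]; h2[s$idx] <- s$hap[2]
  }
  cbind(h1, h2)
}

.fixture_truth <- function() {
  n <- 100
  ids <- paste0("18263X", seq_len(n))
  ids[76] <- "18273X76"

  truth <- data.frame(sample = ids)
  add <- function(name, m) {
    truth[[paste0(name, 1)]] <<- m[, 1]
    truth[[paste0(name, 2)]] <<- m[, 2]
  }

  add("abo", .assign_pairs(n, c("O", "O"), list(
    list(idx = 1:22, hap = c("A", "O")),
    list(idx = 23:24, hap = c("B", "B")),
    list(idx = 25:36, hap = c("B", "O")),
    list(idx = 37:38, hap = c("A", "B")),
    list(idx = 61, hap = c("B", "O")))))   # true B/O; VCF miscalled 0/0

  add("rhd", .assign_pairs(n, c("norm", "norm"), list(
    list(idx = 1:6, hap = c("del", "del")),
    list(idx = 7:8, hap = c("del", "pseudo")),
    list(idx = 9:32, hap = c("del", "norm")),
    list(idx = 33:38, hap = c("pseudo", "norm")))))

  add("cc", .assign_pairs(n, c("c", "c"), list(
    list(idx = 1:29, hap = c("C", "C")),
    list(idx = 30:69, hap = c("C", "c")))))

  add("ee", .assign_pairs(n, c("e", "e"), list(
    list(idx = 1:2, hap = c("E", "E")),
    list(idx = 3:20, hap = c("E", "e")),
    list(idx = 21:22, hap = c("EEw", "e")),
    list(idx = 23, hap = c("Ew", "e")))))

  add("kell", .assign_pairs(n, c("k", "k"),
    list(list(idx = 1:7, hap = c("K", "k")))))
  add("kpa", .assign_pairs(n, c("b", "b"),
    list(list(idx = 8:9, hap = c("a", "b")))))
  add("jk", .assign_pairs(n, c("a", "a"), list(
    list(idx = 45:84, hap = c("a", "b")),
    list(idx = 85:100, hap = c("b", "b")))))

  add("fy", .assign_pairs(n, c("Bg", "Bg"), list(
    list(idx = 1:2, hap = c("A", "A")),
    list(idx = 3:6, hap = c("A", "Bg")),
    list(idx = 7, hap = c("A", "Bx")),
    list(idx = 8:13, hap = c("Bx", "Bx")),
    list(idx = 14:16, hap = c("BgW", "Bg")),
    list(idx = 17, hap = c("BgF", "Bg")))))

  # Lewis: 17 FUT3-null donors, donor 9 is the weak-secretor discordance
  # (one null haplotype in trans to a fully wild-type FUT3 haplotype)
  fut3 <- .assign_pairs(n, c("WT", "WT"), list(
    list(idx = c(1:8, 10:17), hap = c("N1", "N1")),
    list(idx = 18, hap = c("N1", "N2")),
    list(idx = 9, hap = c("WT", "N1"))))
  # active haplotype slots: carriers 19..81 (one null hap each), pure
  # active 82..100; slot order is fixed so the fill is reproducible
  slots <- list()
  for (i in 19:81) { fut3[i, 2] <- if (i == 81) "N2" else "N1"
                     slots[[length(slots) + 1]] <- c(i, 1) }
  for (i in 82:100) { slots[[length(slots) + 1]] <- c(i, 1)
                      slots[[length(slots) + 1]] <- c(i, 2) }
  slots <- slots[-length(slots)]          # sample 100 hap2 stays WT
  fill <- c(rep("A202G", 23), rep("A202", 26), rep("B314A", 11),
            rep("B314", 40))
  stopifnot(length(fill) == length(slots))
  for (j in seq_along(slots)) fut3[slots[[j]][1], slots[[j]][2]] <- fill[j]
  add("fut3", fut3)

  add("fut2", .assign_pairs(n, c("Se", "Se"), list(
    list(idx = c(1:3, 19:32), hap = c("se", "se")),
    list(idx = c(4:8, 9:11, 33:71), hap = c("Se", "se")))))

  add("lu", .assign_pairs(n, c("b", "b"),
    list(list(idx = 1:3, hap = c("a", "b")))))

  mn_homref <- c(1:6, 34, 49, 50, 76, 88)
  mn_homalt <- c(32, setdiff(7:51, c(mn_homref, 32, 49, 50))[1:41])
  add("gypa", .assign_pairs(n, c("M", "N"), list(
    list(idx = mn_homref, hap = c("N", "N")),
    list(idx = mn_homalt, hap = c("M", "M")))))

  add("gypb", .assign_pairs(n, c("s", "s"), list(
    list(idx = c(1:9, 15:21, 86), hap = c("S", "S")),
    list(idx = 10, hap = c("S", "del")),
    list(idx = 11:12, hap = c("s", "del")),
    list(idx = 13, hap = c("S", "He")),
    list(idx = 14, hap = c("s", "He")),
    list(idx = 22:64, hap = c("S", "s")),
    list(idx = 66, hap = c("S", "Dantu")))))

  add("p1", .assign_pairs(n, c("P1", "P1"), list(
    list(idx = 1:20, hap = c("P2", "P2")),
    list(idx = c(21:61, 75), hap = c("P1", "P2")),
    list(idx = 62:64, hap = c("P1", "P2b")))))

  truth
}

.fixture_discordances <- function(ids) {
  x <- function(i) ids[i]
  c(
    list(list(mechanism = "genotype-miscall", sample = x(61),
              variant = "rs8176719", gt = "0/0", antigen = "B")),
    list(list(mechanism = "novel-variant", sample = x(9), antigen = "Lea",
              to = 1,
              variant = list(id = "rs373779096", chrom = "chr19",
                             pos = 48703959L, ref = "G", alt = "T",
                             carriers = x(9)))),
    list(list(mechanism = "novel-variant", sample = x(34), antigen = "Lub",
              to = 0,
              variants = list(
                list(id = "rs533045163", chrom = "chr11", pos = 47380161L,
                     ref = "T", alt = "A", carriers = x(34)),
                list(id = "rs184739796", chrom = "chr11", pos = 47380162L,
                     ref = "C", alt = "T", carriers = x(34))))),
    list(list(mechanism = "novel-variant", sample = x(75), antigen = "P1",
              to = 0,
              variant = list(id = "chr22_42721266_A_C", chrom = "chr22",
                             pos = 42721266L, ref = "A", alt = "C",
                             carriers = c(x(75), x(3))))),
    lapply(c(34, 49, 50, 76, 88), function(i)
      list(mechanism = "serology-positive", sample = x(i), antigen = "M",
           grade = 2)),
    list(list(mechanism = "serology-positive", sample = x(32),
              antigen = "N", grade = 1)),
    list(list(mechanism = "serology-positive", sample = x(86),
              antigen = "s", grade = 1)),
    list(list(mechanism = "weak-expression", sample = x(66), antigen = "s"))
  )
}

#' The deterministic published-cohort fixture
#'
#' A 100-donor cohort whose serology antigen-positive counts equal the
#' published antigen frequency column, whose 12 discordance events (in 11
#' donors) are encoded with their printed genotypes, and whose panel
#' allele counts match the published allele frequencies wherever those are
#' integral over 200 haplotypes (e.g. 7 K alleles, 3 GYPB deletions, 1
#' Dantu).  Includes the triage-plantable private variants: a FUT2
#' missense (allele count 1) in the Lewis-discordant donor, two adjacent
#' SNVs in a GATA1 binding site (allele count 1) in the Lutheran-discordant
#' donor, and a 5' variant in a STAT1 binding site (allele count 2) shared
#' by the P1-discordant donor and one concordant donor.  Depth tracks are
#' noise-free, so the object is fully deterministic and argument-free.
#'
#' @return a `bg_cohort` (see [sample_cohort()]).
#' @export
published_fixture <- function() {
  truth <- .fixture_truth()
  panel <- bg_panel()
  config <- cohort_config(n = 100, seed = 0, noise = FALSE)
  gt <- .truth_to_gt(truth, panel)
  phen <- .truth_phenotype(truth)
  depth <- structure(.truth_depth(truth, panel, config),
                     class = c("bg_depth", "data.frame"))
  serology <- .serology_from_phenotype(phen)
  snv <- panel$variants[panel$variants$class != "structural-tag",
                        c("id", "chrom", "pos", "ref", "alt")]
  cohort <- structure(list(
    truth = truth, phenotype = phen, gt = gt, variants = snv,
    depth = depth, serology = serology,
    discordances = data.frame(sample = character(0), mechanism = character(0),
                              antigen = character(0)),
    config = config), class = "bg_cohort")
  for (spec in .fixture_discordances(truth$sample)) {
    cohort <- inject_discordance(cohort, spec)
  }
  cohort
}
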