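panel <- bg_panel()

# small constructed predictions/serology pair for formula checks
toy_pred <- function(states) {
  # states: named list sample -> c(Jka = ..., Jkb = ...)
  rows <- do.call(rbind, lapply(names(states), function(s)
    data.frame(sample = s, system = "Kidd",
               antigen = names(states[[s]]), state = states[[s]],
               provenance = "toy")))
  class(rows) <- c("bg_predictions", "data.frame")
  rows
}

toy_sero <- function(grades) {
  m <- do.call(rbind, grades)
  rownames(m) <- names(grades)
  structure(m, class = c("bg_serology", "matrix", "array"))
}

test_that("antigen accuracy is percent correct with no-calls incorrect", {
  pred <- toy_pred(list(
    s1 = c(Jka = "positive", Jkb = "negative"),
    s2 = c(Jka = "weak-positive", Jkb = "positive"),
    s3 = c(Jka = "no-call", Jkb = "positive"),
    s4 = c(Jka = "negative", Jkb = "positive")))
  sero <- toy_sero(list(s1 = c(Jka = 3L, Jkb = 0L),
                        s2 = c(Jka = 1L, Jkb = 2L),
                        s3 = c(Jka = 4L, Jkb = 2L),
                        s4 = c(Jka = 0L, Jkb = 3L)))
  expect_equal(antigen_accuracy(pred, sero, "Jka"), 75)  # no-call wrong
  expect_equal(antigen_accuracy(pred, sero, "Jkb"), 100)
  expect_equal(system_accuracy(pred, sero, "Kidd", panel), 75)
})

test_that("negating predictions complements accuracy", {
  fx <- fixture_cohort()
  res <- fixture_pipeline()
  acc <- antigen_accuracy(res$predictions, fx$serology, "M")
  flipped <- res$predictions
  flipped$state <- ifelse(flipped$state %in% c("positive", "weak-positive"),
                          "negative", ifelse(flipped$state == "negative",
                                             "positive", flipped$state))
  expect_equal(antigen_accuracy(flipped, fx$serology, "M"), 100 - acc)
})

test_that("system accuracy never exceeds its antigens' accuracies", {
  fx <- fixture_cohort()
  res <- fixture_pipeline()
  rep <- res$concordance
  for (sys in names(panel$systems)) {
    ags <- antigens_of(sys, panel)
    expect_lte(rep$system_accuracy[[sys]],
               min(rep$antigen_accuracy[ags]) + 1e-9)
  }
  # a single-antigen system equals its antigen accuracy
  expect_equal(rep$system_accuracy[["P1"]], rep$antigen_accuracy[["P1"]])
})

test_that("average accuracy is the rounded mean of system accuracies", {
  res <- fixture_pipeline()
  rep <- res$concordance
  expect_equal(rep$average_accuracy,
               round(mean(rep$system_accuracy), 1))
  # the fixture's exact decomposition
  expect_equal(round(mean(c(99, 100, 100, 100, 100, 99, 99, 92, 99)), 1),
               98.7)
})

test_that("a concordant cohort reports 100 everywhere", {
  co <- sample_cohort(cohort_config(n = 30, seed = 9, noise = FALSE))
  res <- run_cohort_pipeline(co)
  expect_equal(unname(res$concordance$system_accuracy),
               rep(100, 9))
  expect_equal(res$concordance$average_accuracy, 100)
  expect_equal(nrow(res$concordance$discordances), 0)
})

test_that("discordance enumeration counts sample-subsystem events once", {
  res <- fixture_pipeline()
  disc <- res$concordance$discordances
  # each discordance appears in exactly one subsystem list
  expect_false(anyDuplicated(paste(disc$sample, disc$subsystem)) > 0)
  expect_lte(length(unique(disc$sample)), nrow(disc))
  # directions split as published: nine false negatives, three false
  # positives
  expect_equal(sum(disc$direction == "false-negative"), 9)
  expect_equal(sum(disc$direction == "false-positive"), 3)
})

test_that("triage recovers the planted private variants", {
  fx <- fixture_cohort()
  d <- withr::local_tempdir()
  paths <- write_cohort(fx, d)
  gata <- system.file("extdata", "tfbs_gata1.bed", package = "bloodgroupr")
  stat <- system.file("extdata", "tfbs_stat1.bed", package = "bloodgroupr")

  lew <- triage_discordance("18263X9", "Lewis", paths["vcf"], panel)
  expect_true("rs373779096" %in% lew$id)
  expect_equal(lew$ac[lew$id == "rs373779096"], 1)
  expect_equal(lew$consequence[lew$id == "rs373779096"], "missense")

  lut <- triage_discordance("18263X34", "Lutheran", paths["vcf"], panel,
                            tfbs_beds = c(GATA1 = gata))
  expect_true(all(c("rs533045163", "rs184739796") %in% lut$id))
  expect_true(all(lut$consequence[lut$id %in%
    c("rs533045163", "rs184739796")] == "regulatory-overlap"))

  p1 <- triage_discordance("18263X75", "P1", paths["vcf"], panel,
                           tfbs_beds = c(STAT1 = stat))
  expect_true("chr22_42721266_A_C" %in% p1$id)
  expect_equal(p1$ac[p1$id == "chr22_42721266_A_C"], 2)

  # a concordant sample with no qualifying rare variants
  none <- triage_discordance("18263X40", "Lewis", paths["vcf"], panel)
  expect_equal(nrow(none), 0)
})

test_that("triage output equals a brute-force region scan", {
  fx <- fixture_cohort()
  d <- withr::local_tempdir()
  paths <- write_cohort(fx, d)
  gata <- system.file("extdata", "tfbs_gata1.bed", package = "bloodgroupr")
  got <- triage_discordance("18263X34", "Lutheran", paths["vcf"], panel,
                            tfbs_beds = c(GATA1 = gata))

  # brute force: parse the VCF text directly
  lines <- readLines(paths["vcf"])
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[max(which(startsWith(lines, "#")))], "\t")[[1]]
  fields <- strsplit(body, "\t")
  sample_i <- which(header == "18263X34")
  genes <- read.table(system.file("extdata", "gene_regions.tsv",
                                  package = "bloodgroupr"),
                      header = TRUE, sep = "\t")
  genes <- genes[genes$system == "Lutheran", ]
  bed <- read_bed(gata)
  expected <- character(0)
  for (f in fields) {
    chrom <- f[1]; pos <- as.integer(f[2]); id <- f[3]
    gts <- f[10:length(f)]
    acount <- sum(unlist(strsplit(gts, "[/|]")) == "1")
    carried <- sum(unlist(strsplit(f[sample_i], "[/|]")) == "1") > 0
    in_gene <- any(chrom == genes$chrom & pos > genes$start &
                   pos <= genes$end)
    in_bed <- any(chrom == bed$chrom & pos > bed$start & pos <= bed$end)
    if (carried && acount <= 2 &&
        (in_gene || in_bed) && !grepl("^rs28399653$", id)) {
      expected <- c(expected, id)
    }
  }
  # panel predictor sites are excluded by design; brute force above
  # excludes the Lutheran panel site the same way
  expect_setequal(got$id, setdiff(expected, "rs28399653"))
})

test_that("triage errors when the VCF lacks the region entirely", {
  d <- withr::local_tempdir()
  v <- data.frame(id = "x", chrom = "chrZ", pos = 10L, ref = "A", alt = "T")
  gt <- matrix("0|1", 1, 1, dimnames = list("x", "s1"))
  p <- file.path(d, "x.vcf")
  write_vcf(v, gt, p)
  expect_error(triage_discordance("s1", "Lewis", p, panel),
               "no coverage")
})
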