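test_that("identical seed and config give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(sample_cohort(cohort_config(n = 20, seed = 11)), d1)
  p2 <- write_cohort(sample_cohort(cohort_config(n = 20, seed = 11)), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
  p3 <- write_cohort(sample_cohort(cohort_config(n = 20, seed = 12)),
                     withr::local_tempdir())
  expect_false(identical(readLines(p1[["vcf"]]), readLines(p3[["vcf"]])))
})

test_that("allele and phenotype frequencies recover under Hardy-Weinberg", {
  co <- sample_cohort(cohort_config(n = 10000, seed = 1,
                                    depth_tracks = FALSE))
  # K-positive fraction within 3 binomial SD of 1-(1-q)^2 at q = 0.035
  p_exp <- 1 - (1 - 0.035)^2
  k_pos <- mean(co$phenotype[, "K"] == "positive")
  expect_lt(abs(k_pos - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
  # alt-allele frequencies converge on the configured values
  af_targets <- c(rs8176058 = 0.035, rs1058396 = 0.36, rs2814778 = 0.89,
                  rs601338 = 0.405, rs609320 = 0.12)
  for (v in names(af_targets)) {
    q <- af_targets[[v]]
    se <- sqrt(q * (1 - q) / 20000)
    expect_lt(abs(allele_frequency(co$gt, v) - q), 4 * se, label = v)
  }
})

test_that("structural haplotypes shape the depth track as expected", {
  co <- sample_cohort(cohort_config(n = 100, seed = 3, noise = FALSE))
  panel <- bg_panel()
  reg <- panel$regions
  rhd <- reg[reg$name == "rhd_locus", ]
  null_s <- co$truth$sample[co$truth$rhd1 == "del" & co$truth$rhd2 == "del"]
  ex2_d0 <- reg[reg$name == "rhd_ex2", ]
  if (length(null_s) > 0) {
    # outside the exon-2 tract the deleted locus is read-free; the tract
    # itself can still collect mismapped RHCE*C reads
    expect_equal(depth_mean(co$depth, null_s[1], rhd$chrom,
                            rhd$start, ex2_d0$start), 0)
    expect_equal(depth_mean(co$depth, null_s[1], rhd$chrom,
                            ex2_d0$end, rhd$end), 0)
  }
  # one RHCE*C haplotype with RHD present: exon-2 ratio in the C+c+ band
  cc_het <- co$truth$sample[
    (co$truth$cc1 == "C") + (co$truth$cc2 == "C") == 1 &
    co$truth$rhd1 == "norm" & co$truth$rhd2 == "norm"]
  ex2_ce <- reg[reg$name == "rhce_ex2", ]
  ex2_d <- reg[reg$name == "rhd_ex2", ]
  s <- cc_het[1]
  ratio <- depth_mean(co$depth, s, ex2_ce$chrom, ex2_ce$start, ex2_ce$end) /
    (depth_mean(co$depth, s, ex2_d$chrom, ex2_d$start, ex2_d$end) / 2)
  expect_gte(ratio, 0.5)
  expect_lte(ratio, 1.4)
})

test_that("injection mechanisms modify exactly what they claim", {
  base <- cohort_config(n = 10, seed = 21, noise = FALSE)
  co <- sample_cohort(base)
  # empty spec: byte-identical outputs
  co2 <- sample_cohort(base)
  expect_identical(co$gt, co2$gt)
  expect_identical(co$serology, co2$serology)

  s <- co$truth$sample[1]
  m1 <- inject_discordance(co, list(mechanism = "genotype-miscall",
                                    sample = s, variant = "rs8176719",
                                    gt = "0/0", antigen = "B"))
  expect_equal(m1$gt["rs8176719", s], "0/0")
  expect_identical(m1$serology, co$serology)

  m2 <- inject_discordance(co, list(mechanism = "antigen-silencing",
                                    sample = s, antigen = "Lub"))
  expect_equal(unname(m2$serology[s, "Lub"]), 0L)
  same <- m2$serology; same[s, "Lub"] <- co$serology[s, "Lub"]
  expect_identical(unclass(same), unclass(co$serology))

  expect_error(inject_discordance(co, list(mechanism = "teleport",
                                           sample = s)),
               "unknown discordance mechanism")
})

test_that("a genotype miscall makes the pipeline predict O against B serology", {
  co <- sample_cohort(cohort_config(n = 10, seed = 33, noise = FALSE))
  # force a B/O donor, then miscall the O-site genotype
  bo <- co$truth$sample[co$truth$abo1 == "B" | co$truth$abo2 == "B"]
  s <- if (length(bo) > 0) bo[1] else {
    co$truth$abo1[1] <- "B"; co$truth$abo2[1] <- "O"
    co$gt <- bloodgroupr:::.truth_to_gt(co$truth, bg_panel())
    co$phenotype <- bloodgroupr:::.truth_phenotype(co$truth)
    co$serology <- bloodgroupr:::.serology_from_phenotype(co$phenotype)
    co$truth$sample[1]
  }
  co <- inject_discordance(co, list(mechanism = "genotype-miscall",
                                    sample = s, variant = "rs8176719",
                                    gt = "0/0", antigen = "B"))
  res <- run_cohort_pipeline(co)
  pred_b <- res$predictions[res$predictions$sample == s &
                            res$predictions$antigen == "B", "state"]
  expect_equal(pred_b, "negative")
  expect_gte(co$serology[s, "B"], 1L)
})

test_that("fixture marginals match the published cohort", {
  fx <- fixture_cohort()
  pos_counts <- colSums(serology_positive(fx$serology))
  published <- c(A = 24, B = 17, D = 92, C = 69, c = 71, E = 23, e = 98,
                 K = 7, k = 100, Kpa = 2, Kpb = 100, Jka = 84, Jkb = 56,
                 Fya = 7, Fyb = 7, Lea = 15, Leb = 69, Lua = 3, Lub = 99,
                 M = 94, N = 59, S = 63, s = 81, P1 = 79)
  expect_equal(pos_counts[names(published)], published)
  # integral allele counts over 200 haplotypes
  expect_equal(allele_frequency(fx$gt, "rs8176058"), 0.035)   # 7 K alleles
  expect_equal(allele_frequency(fx$gt, "rs8176059"), 0.01)
  expect_equal(allele_frequency(fx$gt, "rs28399653"), 0.015)
  expect_equal(allele_frequency(fx$gt, "rs141398055"), 0.015)
  expect_equal(allele_frequency(fx$gt, "rs139511876"), 0.01)
  expect_equal(allele_frequency(fx$gt, "rs34599082"), 0.015)
  expect_equal(allele_frequency(fx$gt, "rs773692057"), 0.005)
  expect_equal(allele_frequency(fx$gt, "rs3894326"), 0.065)
  expect_equal(allele_frequency(fx$gt, "rs8176719"), 0.21)
  expect_equal(allele_frequency(fx$gt, "rs8176746"), 0.095)
  # three GYPB deletion haplotypes and one Dantu
  expect_equal(sum(fx$truth$gypb1 == "del") + sum(fx$truth$gypb2 == "del"),
               3)
  expect_equal(sum(fx$truth$gypb1 == "Dantu") +
               sum(fx$truth$gypb2 == "Dantu"), 1)
})

test_that("the fixture's discordant donors carry their printed genotypes", {
  fx <- fixture_cohort()
  g <- fx$gt
  expect_equal(unname(g["rs8176719", "18263X61"]), "0/0")
  expect_equal(unname(g["rs8176746", "18263X61"]), "1|0")
  expect_equal(unname(g["rs8176747", "18263X61"]), "1|0")
  expect_equal(unname(g["rs601338", "18263X9"]), "0|1")
  expect_equal(unname(g["rs28362459", "18263X9"]), "0|0")
  expect_equal(unname(g["rs812936", "18263X9"]), "0|1")
  expect_equal(unname(g["rs778986", "18263X9"]), "0|1")
  expect_equal(unname(g["rs28399653", "18263X34"]), "0|0")
  for (s in c("18263X34", "18263X49", "18263X50", "18273X76", "18263X88")) {
    expect_equal(unname(g["rs7682260", s]), "0|0")
    expect_equal(unname(g["rs7687256", s]), "0|0")
    expect_equal(unname(g["rs7658293", s]), "0|0")
  }
  expect_equal(unname(g["rs7682260", "18263X32"]), "1|1")
  expect_setequal(strsplit(g["rs7683365", "18263X66"], "\\|")[[1]],
                  c("0", "1"))
  expect_equal(unname(g["rs7683365", "18263X86"]), "1|1")
  for (v in c("rs5751348", "rs8138197", "rs2143918")) {
    expect_setequal(strsplit(g[v, "18263X75"], "\\|")[[1]], c("0", "1"))
  }
})
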