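test_that("ABO haplotype rules reproduce the phase-sensitive cases", {
  # functional haplotype with both B variants in trans to O -> B
  h <- make_haps(rs8176719 = c("ref", "alt"),
                 rs8176746 = c("ref", "alt"),
                 rs8176747 = c("ref", "alt"))
  expect_equal(attr(infer_abo(h, "s1"), "phenotype"), "B")
  # B variants in cis with the O frameshift -> the other haplotype is A
  h2 <- make_haps(rs8176719 = c("ref", "alt"),
                  rs8176746 = c("alt", "ref"),
                  rs8176747 = c("alt", "ref"))
  expect_equal(attr(infer_abo(h2, "s1"), "phenotype"), "A")
  # both haplotypes carry the O allele
  h3 <- make_haps()
  expect_equal(attr(infer_abo(h3, "s1"), "phenotype"), "O")
  expect_equal(call_state(infer_abo(h3, "s1"), "A"), "negative")
  # missing genotype -> no-call
  h4 <- make_haps(rs8176719 = c(NA, NA))
  expect_equal(call_state(infer_abo(h4, "s1"), "B"), "no-call")
})

test_that("D antigen integrates zygosity and the pseudogene allele", {
  h <- make_haps()
  expect_equal(infer_rh_d("homozygous", h, "s1")$state, "positive")
  expect_equal(infer_rh_d("null", h, "s1")$state, "negative")
  hp <- make_haps(rs748783394 = c("alt", "ref"))
  expect_equal(infer_rh_d("hemizygous", hp, "s1")$state, "negative")
  expect_equal(infer_rh_d("homozygous", hp, "s1")$state, "positive")
  hpp <- make_haps(rs748783394 = c("alt", "alt"))
  expect_equal(infer_rh_d("hemizygous", hpp, "s1")$state, "no-call")
  expect_equal(infer_rh_d("no-call", h, "s1")$state, "no-call")
})

test_that("C/c is copied from the depth call; E/e follow RHCE genotypes", {
  h <- make_haps(rs609320 = c("ref", "alt"))
  calls <- infer_rh_CcEe("C+c+", h, "s1")
  st <- vapply(calls, `[[`, "", "state")
  names(st) <- vapply(calls, `[[`, "", "antigen")
  expect_equal(unname(st[c("C", "c", "E", "e")]),
               c("positive", "positive", "positive", "positive"))
  hE <- make_haps(rs609320 = c("alt", "alt"))
  calls <- infer_rh_CcEe("C-c+", hE, "s1")
  expect_equal(call_state(calls, "E"), "positive")
  expect_equal(call_state(calls, "e"), "negative")
  # weak E allele alone gives weak-positive E, e stays positive
  hW <- make_haps(rs141398055 = c("alt", "ref"))
  calls <- infer_rh_CcEe("C+c+", hW, "s1")
  expect_equal(call_state(calls, "E"), "weak-positive")
  expect_equal(call_state(calls, "e"), "positive")
  # CNV no-call propagates to C/c only
  calls <- infer_rh_CcEe("no-call", h, "s1")
  expect_equal(call_state(calls, "C"), "no-call")
  expect_equal(call_state(calls, "e"), "positive")
})

test_that("antithetical SNV pairs: het both-positive, hom one-sided", {
  h_het <- make_haps(rs1058396 = c("ref", "alt"))
  calls <- infer_antithetical(h_het, "s1", "rs1058396", "Jka", "Jkb",
                              "JK*01", "JK*02")
  expect_equal(call_state(calls, "Jka"), "positive")
  expect_equal(call_state(calls, "Jkb"), "positive")
  h_ref <- make_haps()
  calls <- infer_antithetical(h_ref, "s1", "rs8176058", "k", "K",
                              "KEL*02", "KEL*01.01")
  expect_equal(call_state(calls, "K"), "negative")
  expect_equal(call_state(calls, "k"), "positive")
  calls <- infer_antithetical(h_ref, "s1", "rs28399653", "Lub", "Lua",
                              "LU*02", "LU*01")
  expect_equal(call_state(calls, "Lua"), "negative")
  expect_equal(call_state(calls, "Lub"), "positive")
  h_na <- make_haps(rs8176058 = c(NA, NA))
  calls <- infer_antithetical(h_na, "s1", "rs8176058", "k", "K",
                              "KEL*02", "KEL*01.01")
  expect_equal(call_state(calls, "K"), "no-call")
})

test_that("Duffy cis-silencing and weak alleles resolve per haplotype", {
  # both haplotypes Fyb with GATA in cis -> Fy(a-b-)
  h <- make_haps(rs12075 = c("alt", "alt"), rs2814778 = c("alt", "alt"))
  calls <- infer_duffy(h, "s1")
  expect_equal(call_state(calls, "Fya"), "negative")
  expect_equal(call_state(calls, "Fyb"), "negative")
  # Fya expressed, Fyb silenced in cis -> Fy(a+b-)
  h2 <- make_haps(rs12075 = c("ref", "alt"), rs2814778 = c("ref", "alt"))
  calls <- infer_duffy(h2, "s1")
  expect_equal(call_state(calls, "Fya"), "positive")
  expect_equal(call_state(calls, "Fyb"), "negative")
  # weak allele on an expressed Fyb haplotype -> weak-positive
  h3 <- make_haps(rs12075 = c("ref", "alt"), rs34599082 = c("ref", "alt"))
  calls <- infer_duffy(h3, "s1")
  expect_equal(call_state(calls, "Fyb"), "weak-positive")
  # frameshift nulls the haplotype entirely
  h4 <- make_haps(rs12075 = c("ref", "alt"), rs773692057 = c("ref", "alt"))
  calls <- infer_duffy(h4, "s1")
  expect_equal(call_state(calls, "Fyb"), "negative")
})

test_that("Lewis phenotype follows FUT3 nulls and secretor status", {
  # one null FUT3 haplotype in trans to wild type, secretor het -> Le(a-b+)
  h <- make_haps(rs601338 = c("ref", "alt"),
                 rs812936 = c("ref", "alt"), rs778986 = c("ref", "alt"))
  calls <- infer_lewis(h, "s1")
  expect_equal(call_state(calls, "Lea"), "negative")
  expect_equal(call_state(calls, "Leb"), "positive")
  # both FUT3 haplotypes null -> Le(a-b-)
  h2 <- make_haps(rs812936 = c("alt", "alt"), rs778986 = c("alt", "alt"))
  calls <- infer_lewis(h2, "s1")
  expect_equal(call_state(calls, "Lea"), "negative")
  expect_equal(call_state(calls, "Leb"), "negative")
  # the 202/314 alts in trans leave both haplotypes active
  h3 <- make_haps(rs812936 = c("alt", "ref"), rs778986 = c("ref", "alt"),
                  rs601338 = c("alt", "alt"))
  calls <- infer_lewis(h3, "s1")
  expect_equal(call_state(calls, "Lea"), "positive")
  expect_equal(call_state(calls, "Leb"), "negative")
  # the 59/1067 cis combination also nulls
  h4 <- make_haps(rs28362459 = c("alt", "alt"), rs3894326 = c("alt", "alt"))
  expect_equal(call_state(infer_lewis(h4, "s1"), "Lea"), "negative")
  h5 <- make_haps(rs601338 = c(NA, NA))
  expect_equal(call_state(infer_lewis(h5, "s1"), "Leb"), "no-call")
})

test_that("MNS rules: fixed M/N orientation, structural S/s overrides", {
  h <- make_haps()
  calls <- infer_mns(h, "s1")
  expect_equal(call_state(calls, "M"), "negative")
  expect_equal(call_state(calls, "N"), "positive")
  hM <- make_haps(rs7682260 = c("alt", "alt"), rs7687256 = c("alt", "alt"),
                  rs7658293 = c("alt", "alt"))
  calls <- infer_mns(hM, "s1")
  expect_equal(call_state(calls, "M"), "positive")
  expect_equal(call_state(calls, "N"), "negative")
  # S/s from c.143; Dantu haplotype expresses s weakly
  hS <- make_haps(rs7683365 = c("alt", "ref"))
  calls <- infer_mns(hS, "s1", structural = "Dantu_het")
  expect_equal(call_state(calls, "S"), "positive")
  expect_equal(call_state(calls, "s"), "weak-positive")
  # Henshaw silences its haplotype; remaining S haplotype expresses
  hHe <- make_haps(rs7683365 = c("alt", "ref"),
                   rs139511876 = c("ref", "alt"))
  calls <- infer_mns(hHe, "s1")
  expect_equal(call_state(calls, "S"), "positive")
  expect_equal(call_state(calls, "s"), "negative")
  # deletion het leaves the remaining haplotype only
  hDel <- make_haps(rs7683365 = c("alt", "alt"))
  calls <- infer_mns(hDel, "s1", structural = "GYPB_del_het")
  expect_equal(call_state(calls, "S"), "positive")
  expect_equal(call_state(calls, "s"), "negative")
  calls <- infer_mns(h, "s1", structural = "GYPB_del_hom")
  expect_equal(call_state(calls, "S"), "negative")
  expect_equal(call_state(calls, "s"), "negative")
  calls <- infer_mns(h, "s1", structural = "complex")
  expect_equal(call_state(calls, "S"), "no-call")
})

test_that("S-s- requires silencing alleles on both haplotypes", {
  combos <- expand.grid(a = c("ref", "alt"), b = c("ref", "alt"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    h <- make_haps(rs7683365 = c(combos$a[i], combos$b[i]))
    calls <- infer_mns(h, "s1")
    st <- c(call_state(calls, "S"), call_state(calls, "s"))
    expect_false(all(st == "negative"))
  }
})

test_that("P1 consensus and alternative predictors behave as configured", {
  h_het <- make_haps(rs5751348 = c("ref", "alt"),
                     rs8138197 = c("ref", "alt"),
                     rs2143918 = c("ref", "alt"))
  expect_equal(infer_p1(h_het, "s1")$state, "positive")
  h_p2 <- make_haps(rs5751348 = c("alt", "alt"),
                    rs8138197 = c("alt", "alt"),
                    rs2143918 = c("alt", "alt"))
  expect_equal(infer_p1(h_p2, "s1")$state, "negative")
  # the alternative single-site predictor runs independently
  h_mix <- make_haps(rs5751348 = c("alt", "alt"),
                     rs8138197 = c("alt", "alt"),
                     rs2143918 = c("alt", "alt"),
                     rs66781836 = c("ref", "alt"))
  expect_equal(infer_p1(h_mix, "s1", predictor = "rs66781836")$state,
               "positive")
  expect_equal(infer_p1(h_mix, "s1")$state, "negative")
})

test_that("predict_all emits 24 ordered calls and sensible defaults", {
  fx <- fixture_cohort()
  res <- fixture_pipeline()
  pred <- res$predictions
  expect_equal(nrow(pred), 24 * 100)
  one <- pred[pred$sample == "18263X100", ]
  expect_equal(one$antigen, unlist(bg_panel()$systems, use.names = FALSE))
  # a sample with no variant alleles anywhere: ref-orientation defaults
  h0 <- make_haps()
  rh0 <- data.frame(sample = "s1", zygosity = "homozygous", rhd_ratio = 2,
                    cc_phenotype = "C-c+", cc_ratio = 2, method = "modified")
  st0 <- data.frame(sample = "s1", call = "none")
  p0 <- predict_all(h0, rh0, st0, bg_panel())
  st <- setNames(p0$state, p0$antigen)
  expect_equal(nrow(p0), 24)
  expect_equal(unname(st["K"]), "negative")
  expect_equal(unname(st["k"]), "positive")
  expect_equal(unname(st["Jka"]), "positive")
  expect_equal(unname(st["Jkb"]), "negative")
  expect_equal(unname(st["D"]), "positive")
  expect_equal(unname(st["Fya"]), "positive")
  expect_equal(unname(st["Leb"]), "positive")
  expect_equal(unname(st["P1"]), "positive")
  # the Lutheran-discordant donor is predicted Lu(a-b+)
  x34 <- pred[pred$sample == "18263X34", ]
  st34 <- setNames(x34$state, x34$antigen)
  expect_equal(unname(st34["Lua"]), "negative")
  expect_equal(unname(st34["Lub"]), "positive")
})

test_that("swapping haplotype labels never changes any antigen call", {
  fx <- fixture_cohort()
  res <- fixture_pipeline()
  h <- res$haplotypes
  swapped <- h
  swapped$hap1 <- h$hap2
  swapped$hap2 <- h$hap1
  pred1 <- predict_all(h, res$rh, res$structural, bg_panel())
  pred2 <- predict_all(swapped, res$rh, res$structural, bg_panel())
  expect_equal(pred1$state, pred2$state)
})
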