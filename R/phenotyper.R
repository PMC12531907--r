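# Rule engine: phased genotypes + Rh copy-number calls + glycophorin
# structural calls -> 24 antigen calls per sample.
#
# Calls carry provenance (the named allele or rule that fired).  States are
# "positive", "weak-positive", "negative", "no-call"; weak-positive counts
# as positive downstream.  No-calls are propagated, never silently
# converted.

.hap <- function(h, variant, sample, which_hap) {
  m <- if (which_hap == 1) h$hap1 else h$hap2
  if (!variant %in% rownames(m)) return(NA_character_)
  m[variant, sample]
}

.hap_is <- function(h, variant, sample, which_hap, allele) {
  a <- .hap(h, variant, sample, which_hap)
  !is.na(a) & a == allele
}

.call <- function(antigen, state, provenance) {
  list(antigen = antigen, state = state, provenance = provenance)
}

.nocall <- function(antigens, why) {
  lapply(antigens, .call, state = "no-call", provenance = why)
}

#' ABO phenotype from phased genotypes
#'
#' Per haplotype: the O-defining frameshift first (a haplotype without the
#' functional allele at c.261 is O regardless of downstream variants), then
#' the two B-defining missense variants in cis define B, anything else A.
#' The reference genome carries the O allele at c.261, so "ref" at
#' rs8176719 is the non-functional state.
#'
#' @param h a `bg_haplotypes` object.
#' @param sample sample id.
#' @return list of two antigen calls (A, B); attribute `phenotype` one of
#'   A/B/AB/O, attribute `alleles` the per-haplotype allele names.
#' @export
infer_abo <- function(h, sample) {
  sites <- c("rs8176719", "rs8176746", "rs8176747")
  g <- vapply(1:2, function(i)
    vapply(sites, function(v) .hap(h, v, sample, i), ""), character(3))
  if (any(is.na(g))) {
    out <- .nocall(c("A", "B"), "missing ABO genotype")
    attr(out, "phenotype") <- "no-call"
    return(out)
  }
  hap_allele <- vapply(1:2, function(i) {
    if (g["rs8176719", i] == "ref") "ABO*O.01.01"
    else if (g["rs8176746", i] == "alt" && g["rs8176747", i] == "alt") "ABO*B.01"
    else "ABO*A1.01"
  }, "")
  a_pos <- any(hap_allele == "ABO*A1.01")
  b_pos <- any(hap_allele == "ABO*B.01")
  pheno <- if (a_pos && b_pos) "AB" else if (a_pos) "A"
           else if (b_pos) "B" else "O"
  prov <- paste(hap_allele, collapse = "/")
  out <- list(.call("A", if (a_pos) "positive" else "negative", prov),
              .call("B", if (b_pos) "positive" else "negative", prov))
  attr(out, "phenotype") <- pheno
  attr(out, "alleles") <- hap_allele
  out
}

#' D antigen from RHD zygosity and the pseudogene insertion
#'
#' Functional RHD copies = gene copies (from depth zygosity) minus
#' pseudogene allele count (the 37-bp exon-4 insertion of RHD*08N.01,
#' which truncates the protein while leaving the gene in place).  D+ iff
#' at least one functional copy remains.
#'
#' @param zygosity from [rhd_zygosity()].
#' @param h,sample haplotypes and sample id (for rs748783394).
#' @return one antigen call for D.
#' @export
infer_rh_d <- function(zygosity, h, sample) {
  if (zygosity == "no-call") {
    return(.call("D", "no-call", "RHD zygosity no-call"))
  }
  copies <- c(null = 0, hemizygous = 1, homozygous = 2)[[zygosity]]
  pseudo <- sum(vapply(1:2, function(i)
    .hap_is(h, "rs748783394", sample, i, "alt"), TRUE))
  functional <- copies - pseudo
  if (functional < 0) {
    return(.call("D", "no-call",
                 "pseudogene allele count exceeds RHD gene copies"))
  }
  prov <- if (copies == 0) "RHD*01N.01/RHD*01N.01"
          else if (functional == 0) "RHD*08N.01"
          else "RHD*01"
  .call("D", if (functional >= 1) "positive" else "negative", prov)
}

#' C, c, E, e antigens from the Rh copy-number call and RHCE genotypes
#'
#' C/c is copied from the depth-ratio call.  E is expressed by c.676C
#' (full) or by the weak allele c.602C (weak-positive); e is expressed by
#' any haplotype carrying neither.
#'
#' @param cc_phenotype `"C+c-"`, `"C+c+"`, `"C-c+"` or `"no-call"` from
#'   [rh_cnv_call()].
#' @param h,sample haplotypes and sample id.
#' @return list of four antigen calls (C, c, E, e).
#' @export
infer_rh_CcEe <- function(cc_phenotype, h, sample) {
  if (cc_phenotype == "no-call") {
    cc <- .nocall(c("C", "c"), "Rh depth-ratio no-call")
  } else {
    c_pos <- substr(cc_phenotype, 2, 2) == "+"
    small_c_pos <- substr(cc_phenotype, 4, 4) == "+"
    cc <- list(
      .call("C", if (c_pos) "positive" else "negative", "RHCE exon-2 ratio"),
      .call("c", if (small_c_pos) "positive" else "negative",
            "RHCE exon-2 ratio"))
  }
  e676 <- vapply(1:2, function(i) .hap(h, "rs609320", sample, i), "")
  e602 <- vapply(1:2, function(i) .hap(h, "rs141398055", sample, i), "")
  if (any(is.na(e676))) {
    ee <- .nocall(c("E", "e"), "missing c.676 genotype")
  } else {
    full <- e676 == "alt"
    weak <- !is.na(e602) & e602 == "alt" & !full
    e_state <- if (any(full)) "positive"
               else if (any(weak)) "weak-positive" else "negative"
    e_prov <- if (any(full)) "RHCE*cE" else if (any(weak)) "RHCE*ce.02"
              else "RHCE*ce"
    little_e <- any(!full & !weak)
    ee <- list(.call("E", e_state, e_prov),
               .call("e", if (little_e) "positive" else "negative", "RHCE*ce"))
  }
  c(cc, ee)
}

#' Antithetical antigen pair from one SNV
#'
#' Heterozygotes express both antigens; homozygotes express one and lack
#' the antithetical one.
#'
#' @param h,sample haplotypes and sample id.
#' @param variant the panel SNV.
#' @param ref_antigen,alt_antigen antigen expressed by the ref / alt allele.
#' @param ref_allele_name,alt_allele_name provenance labels.
#' @return list of two antigen calls, ordered (alt_antigen, ref_antigen) to
#'   match panel order for pairs like K/k where the alt allele defines the
#'   first-listed antigen.
#' @export
infer_antithetical <- function(h, sample, variant, ref_antigen, alt_antigen,
                               ref_allele_name, alt_allele_name) {
  g <- vapply(1:2, function(i) .hap(h, variant, sample, i), "")
  if (any(is.na(g))) {
    return(.nocall(c(alt_antigen, ref_antigen),
                   paste("missing genotype at", variant)))
  }
  alt_pos <- any(g == "alt")
  ref_pos <- any(g == "ref")
  prov <- paste(ifelse(g == "alt", alt_allele_name, ref_allele_name),
                collapse = "/")
  list(.call(alt_antigen, if (alt_pos) "positive" else "negative", prov),
       .call(ref_antigen, if (ref_pos) "positive" else "negative", prov))
}

#' Duffy antigens from phased genotypes
#'
#' Haplotype identity (Fya/Fyb) comes from rs12075; a haplotype is silent
#' on red cells when the GATA-box promoter variant rs2814778 is in cis,
#' null when the rs773692057 frameshift is in cis, and weakened by
#' rs34599082 in cis.  An antigen is positive iff at least one haplotype
#' of that identity is expressed.
#'
#' @param h,sample haplotypes and sample id.
#' @return list of two antigen calls (Fya, Fyb).
#' @export
infer_duffy <- function(h, sample) {
  sites <- c("rs12075", "rs2814778", "rs34599082", "rs773692057")
  g <- vapply(1:2, function(i)
    vapply(sites, function(v) .hap(h, v, sample, i), ""), character(4))
  if (any(is.na(g["rs12075", ]))) {
    return(.nocall(c("Fya", "Fyb"), "missing rs12075 genotype"))
  }
  res <- list(Fya = "negative", Fyb = "negative")
  prov <- list(Fya = character(0), Fyb = character(0))
  for (i in 1:2) {
    ident <- if (g["rs12075", i] == "alt") "Fyb" else "Fya"
    silent <- isTRUE(g["rs2814778", i] == "alt")
    null <- isTRUE(g["rs773692057", i] == "alt")
    weak <- isTRUE(g["rs34599082", i] == "alt")
    if (null) { prov[[ident]] <- c(prov[[ident]], "FY*01N.06"); next }
    if (silent) { prov[[ident]] <- c(prov[[ident]], "FY*02N.01"); next }
    if (weak && ident == "Fyb") {
      if (res$Fyb == "negative") res$Fyb <- "weak-positive"
      prov$Fyb <- c(prov$Fyb, "FY*02W.01")
    } else {
      res[[ident]] <- "positive"
      prov[[ident]] <- c(prov[[ident]],
                         if (ident == "Fya") "FY*01" else "FY*02")
    }
  }
  list(.call("Fya", res$Fya,
             paste(unique(c(prov$Fya, "FY rules")), collapse = ";")),
       .call("Fyb", res$Fyb,
             paste(unique(c(prov$Fyb, "FY rules")), collapse = ";")))
}

#' Lewis antigens from FUT3 and FUT2 genotypes
#'
#' A FUT3 haplotype is null iff it carries c.202T>C and c.314C>T in cis, or
#' c.59T>G and c.1067T>A in cis; FUT3 is active iff at least one haplotype
#' is non-null.  Secretor status comes from FUT2 c.461G>A (nonsense):
#' secretor iff at least one haplotype lacks the stop.  Null FUT3 gives
#' Le(a-b-); active/non-secretor Le(a+b-); active/secretor Le(a-b+).
#'
#' @param h,sample haplotypes and sample id.
#' @return list of two antigen calls (Lea, Leb).
#' @export
infer_lewis <- function(h, sample) {
  fut3 <- c("rs28362459", "rs812936", "rs778986", "rs3894326")
  g <- vapply(1:2, function(i)
    vapply(fut3, function(v) .hap(h, v, sample, i), ""), character(4))
  fut2 <- vapply(1:2, function(i) .hap(h, "rs601338", sample, i), "")
  if (any(is.na(fut2))) {
    return(.nocall(c("Lea", "Leb"), "missing FUT2 genotype"))
  }
  if (any(is.na(g))) {
    return(.nocall(c("Lea", "Leb"), "missing FUT3 genotype"))
  }
  hap_null <- vapply(1:2, function(i) {
    (g["rs812936", i] == "alt" && g["rs778986", i] == "alt") ||
      (g["rs28362459", i] == "alt" && g["rs3894326", i] == "alt")
  }, TRUE)
  active <- any(!hap_null)
  secretor <- any(fut2 == "ref")
  if (!active) {
    prov <- "LE*01N.03/LE*01N.09"
    return(list(.call("Lea", "negative", prov),
                .call("Leb", "negative", prov)))
  }
  if (secretor) {
    list(.call("Lea", "negative", "LE*01+SE*01"),
         .call("Leb", "positive", "LE*01+SE*01"))
  } else {
    list(.call("Lea", "positive", "LE*01+SE*01N.02"),
         .call("Leb", "negative", "LE*01+SE*01N.02"))
  }
}

#' MNS antigens from GYPA/GYPB genotypes and the structural call
#'
#' M/N: a GYPA haplotype is M iff it carries the alt alleles at c.59, c.71
#' and c.72 (orientation fixed so that the all-hom-ref genotype is M-N+);
#' otherwise N.  S/s: GYPB haplotype expresses S with c.143T (Met48), s
#' with c.143C (Thr48); a haplotype silenced by the Henshaw splice variant
#' or removed by the GYPB deletion expresses neither; the Dantu hybrid
#' haplotype expresses s weakly.
#'
#' @param h,sample haplotypes and sample id.
#' @param structural structural call string from [glycophorin_calls()].
#' @return list of four antigen calls (M, N, S, s).
#' @export
infer_mns <- function(h, sample, structural = "none") {
  gypa <- c("rs7682260", "rs7687256", "rs7658293")
  ga <- vapply(1:2, function(i)
    vapply(gypa, function(v) .hap(h, v, sample, i), ""), character(3))
  if (any(is.na(ga))) {
    mn <- .nocall(c("M", "N"), "missing GYPA genotype")
  } else {
    hap_m <- vapply(1:2, function(i) all(ga[, i] == "alt"), TRUE)
    prov <- paste(ifelse(hap_m, "GYPA*M", "GYPA*N"), collapse = "/")
    mn <- list(
      .call("M", if (any(hap_m)) "positive" else "negative", prov),
      .call("N", if (any(!hap_m)) "positive" else "negative", prov))
  }

  if (structural == "complex") {
    return(c(mn, .nocall(c("S", "s"), "complex glycophorin copy number")))
  }
  g143 <- vapply(1:2, function(i) .hap(h, "rs7683365", sample, i), "")
  ghe <- vapply(1:2, function(i) .hap(h, "rs139511876", sample, i), "")
  if (any(is.na(g143))) {
    return(c(mn, .nocall(c("S", "s"), "missing c.143 genotype")))
  }
  if (structural == "GYPB_del_hom") {
    return(c(mn, list(.call("S", "negative", "GYPB*05N.01/GYPB*05N.01"),
                      .call("s", "negative", "GYPB*05N.01/GYPB*05N.01"))))
  }
  # expressed haplotype types
  hap_type <- ifelse(g143 == "alt", "S", "s")
  silenced <- !is.na(ghe) & ghe == "alt"            # Henshaw in cis
  weak_s <- c(FALSE, FALSE)
  provs <- ifelse(g143 == "alt", "GYPB*S", "GYPB*s")
  provs[silenced] <- "GYP.He(P2)"
  if (structural == "GYPB_del_het") {
    # one haplotype is gone; the VCF genotype is effectively hemizygous and
    # the remaining haplotype carries the called allele
    drop <- if (!silenced[2]) 2 else 1
    silenced[drop] <- TRUE
    provs[drop] <- "GYPB*05N.01"
  }
  if (structural == "Dantu_het") {
    # the hybrid haplotype sits on the c.143C (s) side and expresses s
    # weakly; prefer marking a non-S haplotype as the hybrid
    dantu_i <- if (hap_type[2] == "s") 2 else 1
    weak_s[dantu_i] <- TRUE
    provs[dantu_i] <- "GYP.Dantu"
  }
  expressed <- !silenced & !weak_s
  s_big <- any(expressed & hap_type == "S")
  s_small_full <- any(expressed & hap_type == "s")
  s_small_state <- if (s_small_full) "positive"
    else if (any(weak_s & !silenced)) "weak-positive" else "negative"
  prov <- paste(provs, collapse = "/")
  c(mn, list(
    .call("S", if (s_big) "positive" else "negative", prov),
    .call("s", s_small_state, prov)))
}

#' P1 antigen from the associated intronic SNVs
#'
#' The default predictor is the majority consensus of the three SNVs that
#' nearly always travel together; each site votes P1-positive iff at least
#' one haplotype carries the P1-associated (reference) allele.  The
#' alternative single-site predictor rs66781836 can be selected to report
#' its accuracy separately.
#'
#' @param h,sample haplotypes and sample id.
#' @param predictor `"consensus"` or `"rs66781836"`.
#' @return one antigen call for P1.
#' @export
infer_p1 <- function(h, sample, predictor = c("consensus", "rs66781836")) {
  predictor <- match.arg(predictor)
  if (predictor == "rs66781836") {
    g <- vapply(1:2, function(i) .hap(h, "rs66781836", sample, i), "")
    if (any(is.na(g))) return(.call("P1", "no-call", "missing rs66781836"))
    return(.call("P1", if (any(g == "ref")) "positive" else "negative",
                 "rs66781836 predictor"))
  }
  sites <- c("rs5751348", "rs8138197", "rs2143918")
  votes <- vapply(sites, function(v) {
    g <- c(.hap(h, v, sample, 1), .hap(h, v, sample, 2))
    if (any(is.na(g))) return(NA)
    any(g == "ref")
  }, TRUE)
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return(.call("P1", "no-call", "no P1 sites called"))
  n_pos <- sum(votes)
  if (n_pos * 2 == length(votes)) {
    return(.call("P1", "no-call", "P1 sites discordant with no majority"))
  }
  .call("P1", if (n_pos * 2 > length(votes)) "positive" else "negative",
        if (n_pos * 2 > length(votes)) "P1PK*P1" else "P1PK*P2")
}

#' Predict all 24 antigens for every sample
#'
#' Deterministic aggregation of the per-system rules; per-antigen failures
#' become no-calls with a reason, never silent conversions.
#'
#' @param h a `bg_haplotypes` object.
#' @param rh data frame from [rh_cnv_call()].
#' @param structural data frame from [glycophorin_calls()].
#' @param panel a [bg_panel()].
#' @param p1_predictor passed to [infer_p1()].
#' @return data frame of class `bg_predictions`: sample, system, antigen,
#'   state, provenance (24 rows per sample, panel order).  ABO phenotype
#'   and per-system allele assignments attached as attribute
#'   `assignments`.
#' @export
predict_all <- function(h, rh, structural, panel,
                        p1_predictor = "consensus") {
  rows <- list()
  assignments <- list()
  for (s in h$samples) {
    rh_s <- rh[rh$sample == s, , drop = FALSE]
    zyg <- if (nrow(rh_s) == 1) rh_s$zygosity else "no-call"
    cc <- if (nrow(rh_s) == 1) rh_s$cc_phenotype else "no-call"
    st_s <- structural[structural$sample == s, , drop = FALSE]
    st <- if (nrow(st_s) == 1) st_s$call else "none"

    abo <- infer_abo(h, s)
    calls <- c(
      abo,
      list(infer_rh_d(zyg, h, s)),
      infer_rh_CcEe(cc, h, s),
      infer_antithetical(h, s, "rs8176058", "k", "K", "KEL*02", "KEL*01.01"),
      infer_antithetical(h, s, "rs8176059", "Kpb", "Kpa", "KEL*02",
                         "KEL*02.03"),
      infer_antithetical(h, s, "rs1058396", "Jka", "Jkb", "JK*01", "JK*02"),
      infer_duffy(h, s),
      infer_lewis(h, s),
      infer_antithetical(h, s, "rs28399653", "Lub", "Lua", "LU*02", "LU*01"),
      infer_mns(h, s, st),
      list(infer_p1(h, s, p1_predictor)))
    df <- data.frame(
      sample = s,
      antigen = vapply(calls, `[[`, "", "antigen"),
      state = vapply(calls, `[[`, "", "state"),
      provenance = vapply(calls, `[[`, "", "provenance"))
    rows[[s]] <- df
    assignments[[s]] <- list(abo_phenotype = attr(abo, "phenotype"),
                             abo_alleles = attr(abo, "alleles"))
  }
  out <- do.call(rbind, rows)
  # order antigens in panel order and attach system
  antigen_order <- unlist(panel$systems, use.names = FALSE)
  sys_of <- rep(names(panel$systems),
                lengths(panel$systems))[match(out$antigen, antigen_order)]
  out$system <- sys_of
  out <- out[, c("sample", "system", "antigen", "state", "provenance")]
  out <- out[order(match(out$sample, h$samples),
                   match(out$antigen, antigen_order)), ]
  rownames(out) <- NULL
  attr(out, "assignments") <- assignments
  class(out) <- c("bg_predictions", "data.frame")
  out
}

#' Positivity matrix from predictions
#'
#' @param pred a `bg_predictions` data frame.
#' @return logical matrix samples x antigens; weak-positive counts as
#'   positive; no-call is `NA`.
#' @export
prediction_positive <- function(pred) {
  samples <- unique(pred$sample)
  antigens <- unique(pred$antigen)
  m <- matrix(NA, length(samples), length(antigens),
              dimnames = list(samples, antigens))
  pos <- pred$state %in% c("positive", "weak-positive")
  neg <- pred$state == "negative"
  m[cbind(match(pred$sample, samples), match(pred$antigen, antigens))] <-
    ifelse(pos, TRUE, ifelse(neg, FALSE, NA))
  m
}
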