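# Shared test helpers: in-code haplotype construction and a lazily cached
# run of the full pipeline over the deterministic 100-donor fixture.

.cache <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.cache$fx)) .cache$fx <- published_fixture()
  .cache$fx
}

fixture_pipeline <- function() {
  if (is.null(.cache$res)) {
    .cache$res <- run_cohort_pipeline(fixture_cohort())
  }
  .cache$res
}

# build a bg_haplotypes object for one sample from named haplotype pairs,
# e.g. make_haps(rs8176719 = c("alt", "ref")); unlisted panel sites
# default to hom-ref
make_haps <- function(..., sample = "s1", phased = TRUE) {
  spec <- list(...)
  panel <- bg_panel()
  ids <- panel$variants$id[panel$variants$class != "structural-tag"]
  hap1 <- hap2 <- matrix("ref", length(ids), 1,
                         dimnames = list(ids, sample))
  ph <- matrix(TRUE, length(ids), 1, dimnames = list(ids, sample))
  for (v in names(spec)) {
    hap1[v, 1] <- spec[[v]][1]
    hap2[v, 1] <- spec[[v]][2]
    ph[v, 1] <- phased
  }
  structure(list(hap1 = hap1, hap2 = hap2, phased = ph, samples = sample,
                 notes = NULL), class = "bg_haplotypes")
}

# flat depth track helper: one sample, tiled windows at constant depth
flat_depth <- function(sample, chrom, start, end, window, depth) {
  starts <- seq(start, end - window, by = window)
  structure(data.frame(sample = sample, chrom = chrom, start = starts,
                       end = starts + window, depth = depth),
            class = c("bg_depth", "data.frame"))
}

call_state <- function(calls, antigen) {
  for (cl in calls) if (cl$antigen == antigen) return(cl$state)
  stop("no call for ", antigen)
}
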