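# Windowed-coverage copy-number segmentation over the glycophorin cluster
# (GYPE-GYPB-GYPA on chr4) and classification of the structural alleles it
# supports: the GYPB whole-gene deletion and the Dantu GYPB-GYPA hybrid
# duplication.
#
# Coverage in 1600-bp windows at high-mappability sites is normalized to
# copy units (2 = diploid) against a copy-number-stable flanking region,
# then decoded with a five-state HMM (copies 0-4) by Viterbi.  Emissions
# are Gaussian around the state copy number; 1600-bp window means at ~16x
# are close to Gaussian, and the standard deviation is estimated from the
# diploid flank with a small floor so that noise-free input stays finite.

#' HMM configuration for glycophorin copy-number decoding
#'
#' @param window window size in bp (depth-track windows must match).
#' @param states copy-number state space.
#' @param switch_prob per-window probability of switching to any one other
#'   state.
#' @param sigma emission standard deviation in copy units; `NULL` to
#'   estimate from the diploid flank of each sample.
#' @param sigma_floor lower bound applied to the (estimated) sigma.
#' @param mask_path BED of low-mappability intervals to exclude; `NULL`
#'   for the builtin mask.
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(window = 1600L, states = 0:4, switch_prob = 1e-4,
                       sigma = NULL, sigma_floor = 0.1, mask_path = NULL) {
  stopifnot(switch_prob > 0, switch_prob < 1,
            all(diff(states) > 0))
  mask_path <- mask_path %||%
    system.file("extdata", "gyp_lowmap.bed", package = "bloodgroupr")
  structure(list(window = as.integer(window), states = states,
                 switch_prob = switch_prob, sigma = sigma,
                 sigma_floor = sigma_floor, mask_path = mask_path),
            class = "hmm_config")
}

#' Normalize windowed depth to copy units
#'
#' Scales each window's depth by half the sample's diploid mean depth
#' (estimated over a copy-number-stable flank), so that diploid windows
#' have expected value 2.  Windows overlapping the low-mappability mask
#' are removed.
#'
#' @param depth a `bg_depth` track covering the glycophorin region.
#' @param sample sample id.
#' @param panel a [bg_panel()] (supplies the region and flank intervals).
#' @param config an [hmm_config()].
#' @param diploid_mean override for the diploid mean depth; `NULL` to
#'   estimate from the flank.
#' @return data frame with chrom, start, end, norm (copy units) and the
#'   diploid mean as attribute `diploid_mean`.
#' @export
normalize_windows <- function(depth, sample, panel, config = hmm_config(),
                              diploid_mean = NULL) {
  reg <- panel$regions
  gyp <- reg[reg$name == "gyp_region", ]
  flank <- reg[reg$name == "gyp_diploid_flank", ]
  d <- depth[depth$sample == sample & depth$chrom == gyp$chrom &
             depth$start >= gyp$start & depth$end <= gyp$end, , drop = FALSE]
  if (nrow(d) == 0) stop("no depth windows for sample ", sample,
                         " in the glycophorin region", call. = FALSE)
  if (is.null(diploid_mean)) {
    diploid_mean <- depth_mean(depth, sample, flank$chrom, flank$start,
                               flank$end)
  }
  if (!is.finite(diploid_mean) || diploid_mean <= 0) {
    stop("diploid mean depth must be positive for sample ", sample,
         call. = FALSE)
  }
  mask <- read_bed(config$mask_path)
  mask <- mask[mask$chrom == gyp$chrom, , drop = FALSE]
  masked <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(mask))) {
    masked <- masked | (d$end > mask$start[i] & d$start < mask$end[i])
  }
  if (all(masked)) stop("all windows masked for sample ", sample,
                        call. = FALSE)
  if (mean(masked) > 0.5) {
    warning("more than half of the windows are masked for sample ", sample)
  }
  out <- d[!masked, c("chrom", "start", "end")]
  out$norm <- d$depth[!masked] / (diploid_mean / 2)
  rownames(out) <- NULL
  attr(out, "diploid_mean") <- diploid_mean
  out
}

#' Viterbi copy-number decoding of normalized coverage
#'
#' Maximum-probability state path under Gaussian emissions centred on the
#' copy-number states and a uniform switch probability between states;
#' adjacent windows with equal decoded state are merged into segments.
#'
#' @param norm output of [normalize_windows()].
#' @param config an [hmm_config()].
#' @return list of class `cn_profile`: `windows` (with decoded `state`),
#'   `segments` (start, end, copies, n_windows), `sigma` used.
#' @export
viterbi_copy_number <- function(norm, config = hmm_config()) {
  if (nrow(norm) < 10) {
    stop("need at least 10 unmasked windows for decoding", call. = FALSE)
  }
  x <- norm$norm
  if (any(!is.finite(x))) stop("non-finite normalized coverage", call. = FALSE)
  states <- config$states
  k <- length(states)
  sigma <- config$sigma
  if (is.null(sigma)) {
    # spread of presumed-diploid windows; robust to the CNV windows via MAD
    sigma <- stats::mad(x, center = 2)
  }
  sigma <- max(sigma, config$sigma_floor)

  log_stay <- log1p(-(k - 1) * config$switch_prob)
  log_switch <- log(config$switch_prob)
  n <- length(x)
  # emission log-likelihoods, windows x states
  em <- vapply(states, function(s) stats::dnorm(x, mean = s, sd = sigma,
                                                log = TRUE),
               numeric(n))
  em <- matrix(em, nrow = n)
  v <- matrix(-Inf, n, k)
  bp <- matrix(0L, n, k)
  v[1, ] <- em[1, ] + log(1 / k)
  for (i in 2:n) {
    for (j in seq_len(k)) {
      cand <- v[i - 1, ] + ifelse(seq_len(k) == j, log_stay, log_switch)
      bp[i, j] <- which.max(cand)
      v[i, j] <- cand[bp[i, j]] + em[i, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (i in (n - 1):1) path[i] <- bp[i + 1, path[i + 1]]
  win <- norm
  win$state <- states[path]

  runs <- rle(win$state)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  segments <- data.frame(
    chrom = win$chrom[idx_start],
    start = win$start[idx_start],
    end = win$end[idx_end],
    copies = runs$values,
    n_windows = runs$lengths)
  structure(list(windows = win, segments = segments, sigma = sigma),
            class = "cn_profile")
}

#' Classify structural glycophorin alleles from a copy-number profile
#'
#' A heterozygous GYPB deletion is called when at least 80% of the
#' (unmasked) GYPB windows decode to one copy (zero copies for the
#' homozygous deletion).  Dantu is recognized by template: a segment of
#' three or more copies covering at least 60% of the GYPB-GYPA hybrid
#' template interval.  Profiles that are neither diploid nor matching a
#' template yield `"complex"`.
#'
#' @param profile a `cn_profile` from [viterbi_copy_number()].
#' @param panel a [bg_panel()] (supplies GYPB gene and Dantu template
#'   intervals).
#' @return list with `call` (one of `"none"`, `"GYPB_del_het"`,
#'   `"GYPB_del_hom"`, `"Dantu_het"`, `"complex"`) and `segments`
#'   supporting it.
#' @export
classify_structural <- function(profile, panel) {
  win <- profile$windows
  reg <- panel$regions
  gypb <- reg[reg$name == "gypb", ]
  template <- reg[reg$name == "dantu_template", ]

  in_gypb <- win$end > gypb$start & win$start < gypb$end
  in_template <- win$end > template$start & win$start < template$end

  gypb_state_frac <- function(s) {
    if (!any(in_gypb)) return(0)
    mean(win$state[in_gypb] == s)
  }
  dantu_frac <- if (any(in_template)) mean(win$state[in_template] >= 3) else 0

  support <- function(states_wanted) {
    seg <- profile$segments
    seg[seg$copies %in% states_wanted, , drop = FALSE]
  }

  call <- if (gypb_state_frac(0) >= 0.8) "GYPB_del_hom"
    else if (gypb_state_frac(1) >= 0.8) "GYPB_del_het"
    else if (dantu_frac >= 0.6) "Dantu_het"
    else if (all(win$state == 2)) "none"
    else if (mean(win$state != 2) < 0.05) "none"
    else "complex"

  seg <- switch(call,
    GYPB_del_hom = support(0), GYPB_del_het = support(1),
    Dantu_het = support(3:4),
    profile$segments[0, , drop = FALSE])
  list(call = call, segments = seg)
}

#' Structural calls for every sample in a depth track
#'
#' @param depth a `bg_depth` track covering the glycophorin region.
#' @param panel a [bg_panel()].
#' @param config an [hmm_config()].
#' @return data frame: sample, call; profiles attached as attribute
#'   `profiles` (named list).
#' @export
glycophorin_calls <- function(depth, panel, config = hmm_config()) {
  samples <- unique(depth$sample)
  profiles <- list()
  calls <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    norm <- normalize_windows(depth, s, panel, config)
    prof <- viterbi_copy_number(norm, config)
    profiles[[s]] <- prof
    calls[i] <- classify_structural(prof, panel)$call
  }
  structure(data.frame(sample = samples, call = calls),
            profiles = profiles)
}
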