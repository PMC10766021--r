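#' Synthetic slide configuration
#'
#' Parameters of the synthetic cell point pattern: tumor cells are scattered
#' in Gaussian blobs around jittered grid centers. `mixing` controls the
#' spatial colocalization of the two tumor classes: with probability
#' `1 - mixing` a blob is single-class (Ki67-positive with probability
#' `positivity`), otherwise its cells draw classes independently with
#' probability `positivity`. At `mixing = 0` blobs are fully segregated by
#' class, at `mixing = 1` classes are independent of position; the overall
#' expected positivity is `positivity` throughout.
#'
#' The defaults give blobs far smaller than the 300-px clustering threshold,
#' spaced far beyond it, so blobs and spatial clusters coincide; cell
#' densities per blob are in the range of nuclei counts in a ~100-µm tumor
#' nest at x40.
#'
#' @param n_blobs number of blobs.
#' @param cells_per_blob tumor cells per blob.
#' @param blob_sigma Gaussian scatter of cells about the blob center (px).
#' @param blob_spacing grid spacing of blob centers (px).
#' @param positivity overall Ki67-positive fraction, in `[0, 1]`.
#' @param mixing colocalization parameter in `[0, 1]` (see above).
#' @param nontumor_fraction fraction of additional nontumor cells relative
#'   to the tumor-cell count.
#' @param seed integer seed.
#' @return Named list of validated parameters.
#' @export
slide_sim_config <- function(n_blobs = 8, cells_per_blob = 60,
                             blob_sigma = 40, blob_spacing = 1500,
                             positivity = 0.5, mixing = 0.5,
                             nontumor_fraction = 0.1, seed = 1L) {
  if (n_blobs < 1 || cells_per_blob < 1)
    ki67cl_stop("config", "counts must be positive")
  for (fr in c(positivity, mixing, nontumor_fraction))
    if (fr < 0 || fr > 1) ki67cl_stop("config", "fractions must lie in [0, 1]")
  list(n_blobs = as.integer(n_blobs),
       cells_per_blob = as.integer(cells_per_blob),
       blob_sigma = blob_sigma, blob_spacing = blob_spacing,
       positivity = positivity, mixing = mixing,
       nontumor_fraction = nontumor_fraction, seed = as.integer(seed))
}

#' Simulate a synthetic slide
#'
#' Generates a [cell_table()] according to a [slide_sim_config()] and,
#' optionally, enclosing region annotations: one TUMOR rectangle around the
#' blob extent and a disjoint DCIS square seeded with its own mixed cells.
#' Deterministic under a fixed seed.
#'
#' @param config a [slide_sim_config()].
#' @param slide_id slide identifier.
#' @param with_regions also emit a [region_set()] plus DCIS cells.
#' @return list with `cells` (a [cell_table()]) and `regions` (a
#'   [region_set()] or `NULL`).
#' @export
simulate_slide <- function(config = slide_sim_config(), slide_id = "sim",
                           with_regions = FALSE) {
  with_seed(config$seed, {
    ncol_grid <- ceiling(sqrt(config$n_blobs))
    margin <- 6 * config$blob_sigma
    bi <- seq_len(config$n_blobs) - 1L
    cx <- margin + (bi %% ncol_grid) * config$blob_spacing +
      stats::runif(config$n_blobs, -0.1, 0.1) * config$blob_spacing
    cy <- margin + (bi %/% ncol_grid) * config$blob_spacing +
      stats::runif(config$n_blobs, -0.1, 0.1) * config$blob_spacing
    xs <- ys <- numeric(0); cls <- character(0)
    for (b in seq_len(config$n_blobs)) {
      n <- config$cells_per_blob
      bx <- pmax(0, stats::rnorm(n, cx[b], config$blob_sigma))
      by <- pmax(0, stats::rnorm(n, cy[b], config$blob_sigma))
      pure <- stats::runif(1) < (1 - config$mixing)
      lab <- if (pure) {
        rep(if (stats::runif(1) < config$positivity) "TUMOR_POS" else "TUMOR_NEG", n)
      } else {
        ifelse(stats::runif(n) < config$positivity, "TUMOR_POS", "TUMOR_NEG")
      }
      xs <- c(xs, bx); ys <- c(ys, by); cls <- c(cls, lab)
    }
    extent <- c(max(xs), max(ys)) + margin
    n_nt <- round(config$nontumor_fraction * length(xs))
    if (n_nt > 0) {
      xs <- c(xs, stats::runif(n_nt, 0, extent[1]))
      ys <- c(ys, stats::runif(n_nt, 0, extent[2]))
      cls <- c(cls, ifelse(stats::runif(n_nt) < config$positivity,
                           "NONTUMOR_POS", "NONTUMOR_NEG"))
    }
    regions <- NULL
    if (with_regions) {
      side <- 4 * config$blob_sigma
      d0 <- c(extent[1] + 2 * side, margin)   # DCIS square, disjoint from TUMOR
      nd <- config$cells_per_blob
      xs <- c(xs, stats::runif(nd, d0[1], d0[1] + side))
      ys <- c(ys, stats::runif(nd, d0[2], d0[2] + side))
      cls <- c(cls, ifelse(stats::runif(nd) < config$positivity,
                           "TUMOR_POS", "TUMOR_NEG"))
      rect <- function(x0, y0, x1, y1)
        rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
      regions <- region_set(list(
        list(label = "TUMOR", rings = list(rect(0, 0, extent[1], extent[2]))),
        list(label = "DCIS",
             rings = list(rect(d0[1], d0[2], d0[1] + side, d0[2] + side)))),
        slide_id = slide_id)
    }
    list(cells = cell_table(xs, ys, cls, slide_id = slide_id),
         regions = regions)
  })
}

#' Synthetic cohort configuration
#'
#' Proportional-hazards generator: patients whose slide score exceeds
#' `score_threshold` have their exponential event hazard multiplied by
#' `hazard_ratio_high`; independent exponential censoring plus an
#' administrative follow-up cap. Defaults give a median event time of about
#' 70 months in the low-risk group with roughly a third of records censored
#' within a 10-year follow-up — the shape of a long-running breast cancer
#' cohort.
#'
#' @param n_patients cohort size.
#' @param baseline_hazard events per month in the low-score group.
#' @param hazard_ratio_high hazard multiplier above the threshold.
#' @param score_threshold score defining the true high-risk group.
#' @param censoring_rate exponential dropout rate (events per month); 0
#'   disables random censoring.
#' @param follow_up_cap administrative censoring time in months (`Inf` to
#'   disable).
#' @param seed integer seed.
#' @return Named list of validated parameters.
#' @export
cohort_sim_config <- function(n_patients = 600, baseline_hazard = 0.01,
                              hazard_ratio_high = 2, score_threshold = 0.5,
                              censoring_rate = 0.005, follow_up_cap = 120,
                              seed = 1L) {
  if (baseline_hazard <= 0 || hazard_ratio_high <= 0)
    ki67cl_stop("config", "rates and hazard ratios must be positive")
  if (censoring_rate < 0) ki67cl_stop("config", "censoring_rate must be >= 0")
  list(n_patients = as.integer(n_patients), baseline_hazard = baseline_hazard,
       hazard_ratio_high = hazard_ratio_high,
       score_threshold = score_threshold, censoring_rate = censoring_rate,
       follow_up_cap = follow_up_cap, seed = as.integer(seed))
}

#' Simulate survival outcomes tied to slide scores
#'
#' @param slide_scores numeric vector of per-patient marker values; recycled
#'   or truncated to `config$n_patients` must match — an error is raised on
#'   mismatch.
#' @param config a [cohort_sim_config()].
#' @return A [survival_table()] with columns `patient_id`, `time`, `event`,
#'   `marker`, `high_true` (the generating group).
#' @export
simulate_cohort <- function(slide_scores, config = cohort_sim_config()) {
  if (length(slide_scores) != config$n_patients)
    ki67cl_stop("config", "need one slide score per patient (%d != %d)",
                length(slide_scores), config$n_patients)
  if (any(!is.finite(slide_scores)))
    ki67cl_stop("config", "slide scores must be finite")
  with_seed(config$seed, {
    high <- slide_scores > config$score_threshold
    hazard <- config$baseline_hazard *
      ifelse(high, config$hazard_ratio_high, 1)
    t_event <- stats::rexp(config$n_patients, rate = hazard)
    t_cens <- if (config$censoring_rate > 0)
      stats::rexp(config$n_patients, rate = config$censoring_rate) else Inf
    t_cens <- pmin(t_cens, config$follow_up_cap)
    survival_table(data.frame(
      patient_id = sprintf("P%04d", seq_len(config$n_patients)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      marker = slide_scores,
      high_true = high))
  })
}

#' Simulate a multi-channel probability map
#'
#' Gaussian density rendering of ground-truth dots per channel plus clipped
#' Gaussian noise; the dot lists are kept as an attribute for round-trip
#' detection tests.
#'
#' @param dots list of [dot_set()] objects (one per channel).
#' @param shape `c(height, width)` in pixels.
#' @param sigma Gaussian sigma of the density rendering (default 3).
#' @param noise_sd standard deviation of the additive noise (default 0).
#' @param seed integer seed for the noise.
#' @return A [prob_map()]; attribute `"truth"` holds the input dot sets.
#' @export
simulate_probability_map <- function(dots, shape, sigma = 3, noise_sd = 0,
                                     seed = 1L) {
  if (noise_sd < 0) ki67cl_stop("config", "noise_sd must be >= 0")
  channels <- lapply(dots, function(d) {
    g <- dots_to_density(d, shape, sigma = sigma)
    pmin(g, 1)
  })
  names(channels) <- vapply(dots, function(d) d$channel, character(1))
  if (noise_sd > 0) {
    channels <- with_seed(seed, lapply(channels, function(g) {
      pmin(pmax(g + matrix(stats::rnorm(length(g), 0, noise_sd),
                           nrow = nrow(g)), 0), 1)
    }))
  }
  pm <- prob_map(channels)
  attr(pm, "truth") <- dots
  pm
}
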