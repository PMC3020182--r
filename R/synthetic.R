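#' Simulation configuration
#'
#' Describes a synthetic control-structured experiment. The signal model is
#' additive on the log2 scale: each probeset has a deterministic baseline
#' (for polyA+ spikes, `intercept + slope * log2(concentration) -
#' position_delta * distance-from-3'`, emulating limited labeling
#' processivity), each array adds a brightness offset drawn from
#' `N(0, brightness_sd)`, and Gaussian noise with a class-specific sigma is
#' added on top. Planted anomalies then perturb selected arrays:
#' \describe{
#'   \item{labeling_failure}{collapses the polyA+ block (and only it)
#'     toward the background floor by fraction `magnitude` (1 = full
#'     collapse).}
#'   \item{brightness_shift}{adds `magnitude` log2 units to every probeset
#'     of the array (a scanning/hybridization-stage effect, visible in all
#'     classes).}
#'   \item{degradation}{subtracts `magnitude` from 5' and `magnitude/2`
#'     from middle probesets of the RNA degradation controls and
#'     `magnitude/4` from endogenous probesets (sample-stage signal loss).}
#'   \item{hybridization_failure}{subtracts `magnitude` and adds extra
#'     noise of sd `magnitude/2` to every probeset.}
#' }
#'
#' @param n_hybridizations number of arrays.
#' @param date_classes character vector of per-array date-class labels
#'   (length `n_hybridizations`).
#' @param replicate_groups per-array aliquot identifiers (re-hybridizations
#'   share one); defaults to singletons.
#' @param sigma named per-class noise sds (hybridization <= polyA <=
#'   endogenous), plus `background`.
#' @param brightness_sd sd of the per-array brightness offset (log2).
#' @param polya_slope,polya_intercept linear log-signal response to
#'   log2(concentration) of the polyA+ spikes.
#' @param position_delta log2 attenuation per position step away from 3'
#'   (3' = 0, M = 1, 5' = 2) for polyA+ and RNA degradation probesets.
#' @param hyb_levels named nominal log2 levels of the biotinylated
#'   hybridization spikes (BioB lowest, CreX highest).
#' @param rnad_levels named nominal 3'-end log2 levels of GAPDH/beta-Actin.
#' @param background_n number of non-control background probesets.
#' @param background_expressed_frac,background_expressed_mean,background_expressed_sd,background_unexpressed_mean,background_unexpressed_sd
#'   two-component mixture of per-probeset background baselines (so a 75th
#'   percentile is meaningful).
#' @param endogenous_mean,endogenous_sd distribution of per-gene endogenous
#'   baselines.
#' @param collapse_floor log2 background floor toward which a labeling
#'   failure collapses the polyA+ signal.
#' @param anomalies data.frame with columns `type`, `target` (hybridization
#'   index, 1-based), `magnitude`.
#' @param seed RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_hybridizations = 60L,
                              date_classes = NULL,
                              replicate_groups = NULL,
                              sigma = c(hybridization = 0.10, polyA = 0.18,
                                        rna_degradation = 0.22,
                                        endogenous = 0.25, background = 0.35),
                              brightness_sd = 0.15,
                              polya_slope = 1.0, polya_intercept = 2.5,
                              position_delta = 0.3,
                              hyb_levels = c(BioB = 7.5, BioC = 9.0,
                                             BioDn = 10.5, CreX = 12.0),
                              rnad_levels = c(GAPDH = 12.0, bActin = 11.5),
                              background_n = 400L,
                              background_expressed_frac = 0.6,
                              background_expressed_mean = 8.0,
                              background_expressed_sd = 1.5,
                              background_unexpressed_mean = 4.0,
                              background_unexpressed_sd = 0.8,
                              endogenous_mean = 8.0, endogenous_sd = 1.5,
                              collapse_floor = 4.5,
                              anomalies = NULL,
                              seed = 1L) {
  n <- as.integer(n_hybridizations)
  if (n < 2L) stop("need at least 2 hybridizations")
  if (is.null(date_classes)) date_classes <- rep("A", n)
  if (length(date_classes) != n) stop("date_classes must have one label per array")
  if (is.null(replicate_groups))
    replicate_groups <- sprintf("RG%03d", seq_len(n))
  if (length(replicate_groups) != n)
    stop("replicate_groups must have one entry per array")
  if (any(sigma < 0) || brightness_sd < 0) stop("sigmas must be non-negative")
  if (is.null(anomalies))
    anomalies <- data.frame(type = character(0), target = integer(0),
                            magnitude = numeric(0))
  known <- c("labeling_failure", "brightness_shift", "degradation",
             "hybridization_failure")
  if (nrow(anomalies)) {
    bad <- setdiff(anomalies$type, known)
    if (length(bad)) stop("unknown anomaly type: ", paste(bad, collapse = ", "))
    if (any(anomalies$target < 1L | anomalies$target > n))
      stop("anomaly target index outside 1..", n)
  }
  structure(list(n_hybridizations = n, date_classes = date_classes,
                 replicate_groups = replicate_groups, sigma = sigma,
                 brightness_sd = brightness_sd, polya_slope = polya_slope,
                 polya_intercept = polya_intercept,
                 position_delta = position_delta, hyb_levels = hyb_levels,
                 rnad_levels = rnad_levels,
                 background_n = as.integer(background_n),
                 background_expressed_frac = background_expressed_frac,
                 background_expressed_mean = background_expressed_mean,
                 background_expressed_sd = background_expressed_sd,
                 background_unexpressed_mean = background_unexpressed_mean,
                 background_unexpressed_sd = background_unexpressed_sd,
                 endogenous_mean = endogenous_mean,
                 endogenous_sd = endogenous_sd,
                 collapse_floor = collapse_floor,
                 anomalies = anomalies, seed = seed),
            class = "simulation_config")
}

#' Default synthetic scenario shaped like an RAE230A experiment
#'
#' A 60-array scenario with 13 date classes (A-M), the full RAE230A control
#' complement (class blocks of 18, 27, 12 and 100 probesets plus
#' background) and three planted technical problems: one labeling-failure
#' array in date class J, one bright replicate pair (an aliquot hybridized
#' twice, dates F and I, sharing a replicate group), and five degraded
#' arrays making up date class G.
#'
#' @param seed RNG seed.
#' @return a [simulation_config()].
#' @export
default_rae230a_scenario <- function(seed = 1L) {
  sizes <- c(rep(5L, 8L), rep(4L, 5L))          # A..H: 5 arrays, I..M: 4
  dates <- rep(LETTERS[1:13], times = sizes)     # 60 arrays
  reps <- sprintf("RG%03d", seq_len(60L))
  bright_pair <- c(28L, 43L)                     # date F array re-hybridized on date I
  reps[bright_pair[2L]] <- reps[bright_pair[1L]]
  degraded <- 31:35                              # all of date class G
  anomalies <- data.frame(
    type = c("labeling_failure", rep("brightness_shift", 2L),
             rep("degradation", 5L)),
    target = c(47L, bright_pair, degraded),
    magnitude = c(1.0, 1.5, 1.5, rep(2.0, 5L)))
  simulation_config(n_hybridizations = 60L, date_classes = dates,
                    replicate_groups = reps, anomalies = anomalies,
                    seed = seed)
}

#' Simulate a control-structured expression experiment
#'
#' Generates a log2 expression matrix over the RAE230A control registry
#' plus a background block, together with hybridization metadata, the
#' spike-in design and per-array truth labels. Identical seeds give
#' bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` ([expression_matrix()]), `metadata`
#'   ([hybridization_metadata()]), `design` ([spikein_design()]), `truth`
#'   (data.frame hybridization_id, anomaly, magnitude), `registry`
#'   (the [control_registry()] used).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  registry <- build_rae230a_registry()
  design <- rae230a_spikein_design()
  n <- config$n_hybridizations

  ids <- sprintf("%s%02d", config$date_classes, seq_len(n))
  pos_dist <- c("5'" = 2, "M" = 1, "3'" = 0, "none" = 0)

  # deterministic per-probeset baselines
  reg <- registry
  base <- numeric(nrow(reg))
  is_polya <- reg$class == "polyA"
  base[is_polya] <- config$polya_intercept +
    config$polya_slope * log2(design$concentrations[reg$transcript[is_polya]]) -
    config$position_delta * pos_dist[reg$position[is_polya]]
  is_hyb <- reg$class == "hybridization"
  base[is_hyb] <- config$hyb_levels[reg$transcript[is_hyb]]
  is_rnad <- reg$class == "rna_degradation"
  base[is_rnad] <- config$rnad_levels[reg$transcript[is_rnad]] -
    config$position_delta * pos_dist[reg$position[is_rnad]]
  is_endo <- reg$class == "endogenous"
  base[is_endo] <- stats::rnorm(sum(is_endo), config$endogenous_mean,
                                config$endogenous_sd)

  # background block: expressed/unexpressed mixture of per-probeset baselines
  nbg <- config$background_n
  bg_ids <- sprintf("BG_SYN_%04d_at", seq_len(nbg))
  expressed <- stats::runif(nbg) < config$background_expressed_frac
  bg_base <- ifelse(expressed,
                    stats::rnorm(nbg, config$background_expressed_mean,
                                 config$background_expressed_sd),
                    stats::rnorm(nbg, config$background_unexpressed_mean,
                                 config$background_unexpressed_sd))

  all_ids <- c(reg$probeset_id, bg_ids)
  all_base <- c(base, bg_base)
  cls <- c(reg$class, rep("background", nbg))
  sig <- config$sigma[cls]
  k <- length(all_ids)

  brightness <- stats::rnorm(n, 0, config$brightness_sd)
  X <- matrix(NA_real_, n, k, dimnames = list(ids, all_ids))
  for (h in seq_len(n))
    X[h, ] <- all_base + brightness[h] + stats::rnorm(k, 0, sig)

  truth <- data.frame(hybridization_id = ids, anomaly = "clean",
                      magnitude = 0, stringsAsFactors = FALSE)
  an <- config$anomalies
  for (i in seq_len(nrow(an))) {
    h <- an$target[i]; m <- an$magnitude[i]
    switch(an$type[i],
      labeling_failure = {
        cols <- cls == "polyA"
        X[h, cols] <- X[h, cols] - m * (X[h, cols] - config$collapse_floor)
      },
      brightness_shift = {
        X[h, ] <- X[h, ] + m
      },
      degradation = {
        p5 <- cls == "rna_degradation" & c(reg$position, rep("none", nbg)) == "5'"
        pm <- cls == "rna_degradation" & c(reg$position, rep("none", nbg)) == "M"
        X[h, p5] <- X[h, p5] - m
        X[h, pm] <- X[h, pm] - m / 2
        X[h, cls == "endogenous"] <- X[h, cls == "endogenous"] - m / 4
      },
      hybridization_failure = {
        X[h, ] <- X[h, ] - m + stats::rnorm(k, 0, m / 2)
      })
    truth$anomaly[h] <- an$type[i]
    truth$magnitude[h] <- m
  }

  metadata <- hybridization_metadata(data.frame(
    hybridization_id = ids,
    date_class = config$date_classes,
    replicate_group = config$replicate_groups,
    scan_qc = NA, stringsAsFactors = FALSE))

  list(matrix = expression_matrix(X),
       metadata = metadata, design = design, truth = truth,
       registry = registry, config = config)
}
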