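#' Simulation settings for nCounter-like count data
#'
#' Defaults emulate a two-group miRNA profiling study with a strongly
#' unbalanced design: 72 tumor lanes vs 3 osteoblast control lanes, ~600
#' endogenous probes of which roughly 519 survive background filtering, six
#' positive spike-in controls on a 4-fold geometric ladder, eight negative
#' (no-target) controls, lane-specific scale factors, negative-binomial
#' overdispersion, and a planted differential set whose absolute log2 fold
#' changes span 1 to 6.5 (2-fold to ~93-fold) with 26/70 of planted probes
#' up-regulated.
#'
#' @param n_endogenous number of endogenous miRNA probes.
#' @param n_positive number of positive-control probes.
#' @param n_negative number of negative-control probes.
#' @param group_sizes named integer vector, group label -> number of lanes;
#'   at least two groups, each of size >= 1. The first group is the "case"
#'   group that carries the planted fold changes.
#' @param lane_scale_log_sd SD of log lane scale factors (log-normal lanes).
#' @param baseline_log_mean,baseline_log_sd mean and SD of per-probe baseline
#'   abundance on the log2 scale.
#' @param dispersion negative-binomial size parameter shared by all
#'   endogenous probes; variance = mu + mu^2/dispersion. `Inf` gives Poisson
#'   counts.
#' @param de_fraction fraction of endogenous probes planted as differential.
#' @param up_fraction fraction of planted probes that are up-regulated in the
#'   case group.
#' @param absent_fraction fraction of endogenous probes with no true signal
#'   (baseline 0, background counts only); these are the probes the
#'   prevalence filter is meant to remove, emulating panel miRNAs not
#'   expressed in the profiled tissue. Absent probes are never planted as
#'   differential.
#' @param lfc_range interval of absolute log2 fold changes for planted probes;
#'   lower bound must be > 0.
#' @param background_mean,background_sd negative-control count model: counts
#'   are Gaussian draws rounded and truncated at zero. The same mean is added
#'   to every endogenous probe's expectation as non-specific background.
#' @param seed integer random seed.
#' @return a `sim_config` list of the validated settings.
#' @export
sim_config <- function(n_endogenous = 600,
                       n_positive = 6,
                       n_negative = 8,
                       group_sizes = c(OS = 72, Ob = 3),
                       lane_scale_log_sd = 0.2,
                       baseline_log_mean = 6,
                       baseline_log_sd = 2,
                       dispersion = 10,
                       de_fraction = 70 / 600,
                       up_fraction = 26 / 70,
                       absent_fraction = 0.12,
                       lfc_range = c(1, 6.5),
                       background_mean = 25,
                       background_sd = 6,
                       seed = 1L) {
  cfg <- list(n_endogenous = n_endogenous, n_positive = n_positive,
              n_negative = n_negative, group_sizes = group_sizes,
              lane_scale_log_sd = lane_scale_log_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion, de_fraction = de_fraction,
              up_fraction = up_fraction, absent_fraction = absent_fraction,
              lfc_range = lfc_range,
              background_mean = background_mean,
              background_sd = background_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_endogenous >= 1, n_positive >= 1, n_negative >= 2,
              lane_scale_log_sd >= 0, baseline_log_sd >= 0,
              dispersion > 0,
              de_fraction >= 0, de_fraction <= 1,
              up_fraction >= 0, up_fraction <= 1,
              absent_fraction >= 0, de_fraction + absent_fraction <= 1,
              length(lfc_range) == 2, lfc_range[1] > 0,
              lfc_range[2] >= lfc_range[1],
              background_mean > 0, background_sd >= 0)
    if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
      stop("`group_sizes` must be a named vector of group sample counts")
    if (length(group_sizes) < 2)
      stop("at least 2 groups are required (the contrast is undefined otherwise)")
    if (any(group_sizes < 1))
      stop("every group must have at least 1 sample")
  })
  structure(cfg, class = "sim_config")
}

# expected positive-control counts at unit lane scale: a 4-fold geometric
# ladder (nCounter spike-in convention); top chosen so the lowest rung stays
# well above zero under Poisson noise
pos_control_ladder <- function(n_positive) 32768 / 4^(seq_len(n_positive) - 1)

#' Simulate an nCounter-like count matrix with known ground truth
#'
#' Positive-control counts are Poisson around a fixed, lane-scaled 4-fold
#' geometric ladder. Negative-control counts are rounded truncated-Gaussian
#' draws from the background model, independent of group and lane scale.
#' Endogenous counts are a negative-binomial signal plus an additive
#' background draw from the same model as the negative controls, so the
#' total mean is
#' `lane_scale * baseline * 2^(case_indicator * true_log2_fc) + background_mean`
#' and a probe with no signal is distributed like a negative control.
#' The same seed gives bit-identical output; the caller's RNG state is
#' restored on exit.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts` ([ncounter_counts]), `truth` (data
#'   frame: `probe_id`, `is_de`, `true_log2_fc`, `true_baseline`) and
#'   `metadata` (data frame: `sample_id`, `group`).
#' @examples
#' sim <- simulate_ncounter(sim_config(n_endogenous = 50,
#'                                     group_sizes = c(OS = 6, Ob = 3)))
#' sim$counts
#' head(sim$truth)
#' @export
simulate_ncounter <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- unclass(config)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n_s <- length(groups)
  sample_ids <- unlist(lapply(names(cfg$group_sizes), function(g)
    sprintf("%s_%02d", g, seq_len(cfg$group_sizes[[g]]))))
  endo_ids <- sprintf("miR-%04d", seq_len(cfg$n_endogenous))
  pos_ids <- sprintf("POS_%s", LETTERS[seq_len(cfg$n_positive)])
  neg_ids <- sprintf("NEG_%02d", seq_len(cfg$n_negative))

  with_seed(cfg$seed, {
    lane_scale <- exp(stats::rnorm(n_s, 0, cfg$lane_scale_log_sd))
    baseline <- 2^stats::rnorm(cfg$n_endogenous, cfg$baseline_log_mean,
                               cfg$baseline_log_sd)
    n_absent <- round(cfg$absent_fraction * cfg$n_endogenous)
    absent_idx <- if (n_absent > 0) sample.int(cfg$n_endogenous, n_absent)
                  else integer(0)
    baseline[absent_idx] <- 0
    n_de <- round(cfg$de_fraction * cfg$n_endogenous)
    lfc <- numeric(cfg$n_endogenous)
    if (n_de > 0) {
      expressed <- setdiff(seq_len(cfg$n_endogenous), absent_idx)
      de_idx <- sample(expressed, n_de)
      n_up <- round(cfg$up_fraction * n_de)
      sign <- rep(c(1, -1), c(n_up, n_de - n_up))
      lfc[de_idx] <- sign * stats::runif(n_de, cfg$lfc_range[1], cfg$lfc_range[2])
      # a detected down-regulated miRNA must still sit above background in
      # the repressed (case) group, which holds >90% of the lanes in the
      # default design and would otherwise trip the prevalence filter; floor
      # the baseline so the repressed mean stays ~3x background, emulating
      # a signature of probes expressed above background in both groups
      down <- de_idx[lfc[de_idx] < 0]
      floor_bl <- 3 * cfg$background_mean * 2^(-lfc[down])
      baseline[down] <- pmax(baseline[down], floor_bl)
    }
    case <- as.numeric(groups == names(cfg$group_sizes)[1])

    # endogenous: NB signal around the lane-scaled baseline, plus additive
    # non-specific background drawn from the same model as the negative
    # controls, so total mean = lane_scale * baseline * 2^(case * lfc) +
    # background_mean and a signal-free probe behaves like a negative probe
    rbackground <- function(n)
      round(pmax(stats::rnorm(n, cfg$background_mean, cfg$background_sd), 0))
    mu <- outer(baseline, lane_scale) * 2^outer(lfc, case)
    signal <- if (is.finite(cfg$dispersion)) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion), nrow = nrow(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    }
    endo <- signal + matrix(rbackground(length(mu)), nrow = nrow(mu))
    pos_mu <- outer(pos_control_ladder(cfg$n_positive), lane_scale)
    pos <- matrix(stats::rpois(length(pos_mu), pos_mu), nrow = nrow(pos_mu))
    neg <- matrix(rbackground(cfg$n_negative * n_s), nrow = cfg$n_negative)

    counts <- rbind(pos, neg, endo)
    dimnames(counts) <- list(c(pos_ids, neg_ids, endo_ids), sample_ids)
    x <- ncounter_counts(counts,
                         rep(c("Positive", "Negative", "Endogenous"),
                             c(cfg$n_positive, cfg$n_negative, cfg$n_endogenous)))
    truth <- data.frame(probe_id = endo_ids,
                        is_de = lfc != 0,
                        true_log2_fc = lfc,
                        true_baseline = baseline,
                        stringsAsFactors = FALSE)
    metadata <- data.frame(sample_id = sample_ids, group = groups,
                           stringsAsFactors = FALSE)
    list(counts = x, truth = truth, metadata = metadata)
  })
}

#' Simulate qPCR Ct replicate tables with known relative quantities
#'
#' Target Ct for a sample in group g is
#' `reference_ct + calibrator_dct - log2(true_rq[g]) + noise`; reference-gene
#' Ct is `reference_ct + noise`; both in triplicate. A group with
#' `true_rq = 1` therefore has expected delta-Ct equal to `calibrator_dct`,
#' and delta-delta-Ct relative to it recovers `true_rq` exactly when
#' `ct_noise_sd = 0`.
#'
#' @param n_per_group samples per group.
#' @param true_rq named positive vector: true relative quantity per group
#'   (the intended calibrator group should have value 1).
#' @param ct_noise_sd SD (cycles) of Gaussian per-well noise, >= 0.
#' @param reference_ct expected reference-gene Ct (cycles).
#' @param calibrator_dct expected delta-Ct (target - reference, cycles) of a
#'   group with `true_rq = 1`.
#' @param target,reference assay names used in the output table.
#' @param n_replicates technical replicates per (sample, assay) well group.
#' @param seed integer random seed.
#' @return list with `ct` (replicate table: `sample_id`, `group`, `target`,
#'   `is_reference`, `replicate`, `ct`) and `true_rq`.
#' @export
simulate_qpcr <- function(n_per_group, true_rq, ct_noise_sd = 0.2,
                          reference_ct = 20, calibrator_dct = 3,
                          target = "miR-9", reference = "U6",
                          n_replicates = 3, seed = 1L) {
  stopifnot(n_per_group >= 1, ct_noise_sd >= 0, n_replicates >= 1)
  if (is.null(names(true_rq)) || any(!nzchar(names(true_rq))))
    stop("`true_rq` must be a named vector (one value per group)")
  if (any(true_rq <= 0)) stop("`true_rq` must be strictly positive")
  groups <- names(true_rq)
  with_seed(as.integer(seed), {
    rows <- lapply(groups, function(g) {
      ids <- sprintf("%s_%02d", g, seq_len(n_per_group))
      tgt_mu <- reference_ct + calibrator_dct - log2(true_rq[[g]])
      do.call(rbind, lapply(ids, function(s) {
        data.frame(
          sample_id = s, group = g,
          target = c(rep(target, n_replicates), rep(reference, n_replicates)),
          is_reference = rep(c(FALSE, TRUE), each = n_replicates),
          replicate = rep(seq_len(n_replicates), 2),
          ct = c(tgt_mu + stats::rnorm(n_replicates, 0, ct_noise_sd),
                 reference_ct + stats::rnorm(n_replicates, 0, ct_noise_sd)),
          stringsAsFactors = FALSE)
      }))
    })
    list(ct = do.call(rbind, rows), true_rq = true_rq)
  })
}

#' Write a simulated dataset to a directory
#'
#' Writes the count matrix CSV, the sample metadata TSV and the ground-truth
#' sidecar TSV (`probe_id`, `is_de`, `true_log2_fc`) so downstream results
#' can be joined to truth without re-simulation.
#'
#' @param sim result of [simulate_ncounter()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.csv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth[, c("probe_id", "is_de", "true_log2_fc")],
                     file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
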