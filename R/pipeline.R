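#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end synthetic-cohort
#' analysis, with defaults pinned to the standard analysis choices:
#' 75th-percentile amplitude criteria, 0.5-3 s spindles, 0.8-2 s slow
#' oscillations, 0.16/2 Hz SO filters, +/-2 Hz individualized spindle
#' band, 2.5 s co-occurrence window, coupling restricted to N3, 1000
#' permutations at cluster alpha 0.05.
#'
#' @param n_subjects cohort size.
#' @param target_rho target Spearman correlation between subject kappa and
#'   overnight proficiency gain.
#' @param base_config [sim_config()] template for the per-subject EEG.
#' @param coupling_stages stages used for coupling analyses (default "N3").
#' @param spectrum_stages stages entering the spectra (default N2 + N3).
#' @param win_s,step_s spectral window length and slide step (s).
#' @param percentile amplitude-criterion percentile.
#' @param cooccurrence_window co-occurrence window (s).
#' @param min_events minimum events per channel for a coupling estimate.
#' @param n_perm,cluster_alpha,alpha cluster-test settings.
#' @param nights 1 for the learning night only, 2 to add an adaptation
#'   night (enables the night-stability summary).
#' @param behavior_noise SD of the block-score noise (cascades).
#' @param kappa_range interval subject kappas are drawn from.
#' @param seed master seed; all stage seeds derive from it.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(n_subjects = 20, target_rho = 0.6,
                            base_config = sim_config(),
                            coupling_stages = "N3",
                            spectrum_stages = c("N2", "N3"),
                            win_s = 15, step_s = 1,
                            percentile = 75, cooccurrence_window = 2.5,
                            min_events = 10, n_perm = 1000,
                            cluster_alpha = 0.05, alpha = 0.05,
                            nights = 1, behavior_noise = 1.5,
                            kappa_range = c(0.5, 6), seed = 1L) {
  structure(list(n_subjects = n_subjects, target_rho = target_rho,
                 base_config = base_config,
                 coupling_stages = coupling_stages,
                 spectrum_stages = spectrum_stages,
                 win_s = win_s, step_s = step_s, percentile = percentile,
                 cooccurrence_window = cooccurrence_window,
                 min_events = min_events, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, alpha = alpha,
                 nights = nights, behavior_noise = behavior_noise,
                 kappa_range = kappa_range, seed = seed),
            class = "pipeline_config")
}

# One subject-night: simulate, spectra, individualized detection, gating,
# coupling. Returns the coupling_result (plus event counts).
analyze_subject_night <- function(cfg, pcfg, night_label) {
  sim <- generate_recording(cfg)
  rec <- znorm_signal(sim$recording)
  if (!any(sim$hypnogram$stages %in% pcfg$coupling_stages))
    stop("stage gating: no ", paste(pcfg$coupling_stages, collapse = "/"),
         " epochs in the hypnogram")
  spectra <- compute_spectra(rec, sim$hypnogram, pcfg$spectrum_stages,
                             win_s = pcfg$win_s, step_s = pcfg$step_s)
  peaks <- find_peaks(spectra)
  sp <- detect_spindles(rec, sim$hypnogram, peaks, pcfg$coupling_stages,
                        percentile = pcfg$percentile)
  so <- detect_slow_oscillations(rec, sim$hypnogram, pcfg$coupling_stages,
                                 percentile = pcfg$percentile)
  sp <- znorm_epochs(sp)
  coupled <- gate_cooccurrence(sp, so, pcfg$cooccurrence_window)
  res <- subject_coupling(coupled, min_events = pcfg$min_events,
                          night_label = night_label)
  list(coupling = res, n_spindles = nrow(sp$events),
       n_sos = nrow(so$events), n_coupled = nrow(coupled$events),
       truth = sim$truth)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains simulate -> spectra/IRASA -> individualized detection ->
#' co-occurrence gating -> coupling -> behavior parameterization ->
#' cluster statistics on a synthetic cohort whose per-subject coupling
#' concentration (kappa) drives the overnight proficiency gain. The result
#' bundle contains per-subject coupling, the fitted learning-curve table,
#' the cluster-corrected correlations of coupling strength with the
#' overnight changes in task proficiency and learning curve, an optional
#' two-night stability summary, and a provenance record sufficient to
#' re-run the analysis bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param progress print per-subject progress messages.
#' @return list of class \code{pipeline_result} with elements
#'   \code{coupling} (subject x channel matrix of coupling strength),
#'   \code{coupling_tables}, \code{behavior}, \code{fits}, \code{change},
#'   \code{cor_y1}, \code{cor_m} (cluster results), \code{stability}
#'   (per-channel adaptation/learning correlation, if \code{nights = 2}),
#'   \code{truth}, and \code{provenance}.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$n_subjects, config$kappa_range,
                            config$target_rho, config$behavior_noise,
                            seed = config$seed,
                            base_config = config$base_config)
  chans <- config$base_config$channel_labels
  nsub <- config$n_subjects
  strength <- matrix(NA_real_, nsub, length(chans),
                     dimnames = list(names(cohort$configs), chans))
  strength_adapt <- strength
  tables <- list()
  for (i in seq_len(nsub)) {
    sid <- names(cohort$configs)[i]
    if (progress) message("subject ", sid)
    night <- tryCatch(
      analyze_subject_night(cohort$configs[[i]], config, "learning"),
      error = function(e) stop("stage failure at subject ", sid, ": ",
                               conditionMessage(e)))
    res <- night$coupling
    strength[i, res$channel] <- res$coupling_strength
    tables[[sid]] <- cbind(subject = sid, as.data.frame(res))
    if (config$nights >= 2) {
      cfg2 <- cohort$configs[[i]]
      cfg2$seed <- cfg2$seed + 1L
      adapt <- analyze_subject_night(cfg2, config, "adaptation")
      strength_adapt[i, adapt$coupling$channel] <-
        adapt$coupling$coupling_strength
    }
  }

  fits <- fit_behavior_table(cohort$behavior)
  change <- overnight_change(fits, pre = 1, post = 2)
  change <- change[match(rownames(strength), change$subject), ]

  adj <- montage_adjacency(chans)
  cor_y1 <- cluster_corrected_spearman(strength, change$delta_y1, adj,
                                       config$cluster_alpha, config$n_perm,
                                       config$alpha,
                                       seed = config$seed + 101L)
  cor_m <- cluster_corrected_spearman(strength, change$delta_m, adj,
                                      config$cluster_alpha, config$n_perm,
                                      config$alpha,
                                      seed = config$seed + 202L)

  stability <- NULL
  if (config$nights >= 2) {
    stability <- data.frame(
      channel = chans,
      rho = vapply(seq_along(chans), function(j)
        stats::cor(strength[, j], strength_adapt[, j],
                   method = "spearman", use = "complete.obs"), numeric(1)))
  }

  provenance <- list(package_version = as.character(
                       utils::packageVersion("sospindle")),
                     seed = config$seed,
                     parameters = config[setdiff(names(config),
                                                 "base_config")],
                     base_config = unclass(config$base_config),
                     subject_seeds = vapply(cohort$configs, `[[`,
                                            numeric(1), "seed"))
  structure(list(coupling = strength, coupling_adaptation = strength_adapt,
                 coupling_tables = do.call(rbind, tables),
                 behavior = cohort$behavior, fits = fits, change = change,
                 cor_y1 = cor_y1, cor_m = cor_m, stability = stability,
                 truth = cohort$truth, provenance = provenance),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subject(s), %d channel(s)\n",
              nrow(x$coupling), ncol(x$coupling)))
  cat("coupling strength vs overnight proficiency change:\n")
  print(x$cor_y1)
  cat("coupling strength vs overnight learning-curve change:\n")
  print(x$cor_m)
  invisible(x)
}
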