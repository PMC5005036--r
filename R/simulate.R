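# Synthetic-data generators. Each emulates the statistical structure of
# one half of the workflow -- log-normal baseline abundances, log-linear
# fraction enrichment for a membrane subset, logistic detection dropout,
# shared/isoform-unique peptides, specific-vs-nonspecific IP binding,
# Gaussian PRM elution peaks -- with every true parameter recorded, so
# downstream stages can be tested against known ground truth. Draws come
# from one seeded generator per call; identical config => identical output.

#' Configuration for the purification-fraction simulator
#'
#' Defaults describe the emulated study conditions at desk scale: a few
#' hundred proteins over five ordered fractions, with a membrane subset
#' enriching log-linearly across the preparation.
#'
#' @param n_proteins number of singleton proteins (default 500).
#' @param frac_membrane proportion of proteins in the enriching
#'   membrane class (default 0.15).
#' @param n_fractions number of ordered purification fractions
#'   (default 5).
#' @param slope_membrane mean log10-enrichment per fraction step for
#'   membrane proteins (default 0.4 decades/step).
#' @param slope_sd SD of true slopes around their class mean
#'   (default 0.1).
#' @param base_abundance_sigma log10 SD of baseline iBAQ (default 1.2).
#' @param noise_sigma log10 SD of per-measurement multiplicative noise
#'   (default 0.2; 0 disables noise).
#' @param dropout_midpoint log10 abundance at which detection
#'   probability is 0.5 (default 4).
#' @param dropout_steepness logistic steepness of detection on log10
#'   abundance (default 1.5; 0 disables dropout, everything detected).
#' @param n_isoform_groups number of two-member isoform groups appended
#'   to the matrix (default 5).
#' @param contaminant_rate proportion of proteins flagged contaminant
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list of class `purification_sim_config`.
#' @export
purification_sim_config <- function(n_proteins = 500, frac_membrane = 0.15,
                                    n_fractions = 5, slope_membrane = 0.4,
                                    slope_sd = 0.1,
                                    base_abundance_sigma = 1.2,
                                    noise_sigma = 0.2,
                                    dropout_midpoint = 4,
                                    dropout_steepness = 1.5,
                                    n_isoform_groups = 5,
                                    contaminant_rate = 0.05, seed = 1) {
  stopifnot(n_proteins >= 1, n_fractions >= 2, n_isoform_groups >= 0)
  for (p in c(frac_membrane, contaminant_rate))
    if (p < 0 || p > 1)
      stop("proportions must lie in [0, 1]", call. = FALSE)
  if (slope_sd < 0 || base_abundance_sigma < 0 || noise_sigma < 0)
    stop("dispersions must be non-negative", call. = FALSE)
  structure(as.list(environment()), class = "purification_sim_config")
}

#' Simulate a purification-fraction iBAQ experiment
#'
#' Generates an iBAQ matrix over ordered fractions in which every
#' membrane-class protein's expected log10 iBAQ rises linearly with
#' fraction index at its own true slope, background and contaminant
#' proteins have slopes near zero, measurement noise is multiplicative
#' log-normal, and detection follows a logistic dropout on log10
#' abundance. Isoform groups are appended as single group rows (the sum
#' of their members) together with peptide evidence holding shared and
#' isoform-unique peptides, so isoform apportionment can be tested.
#'
#' @param config a [purification_sim_config()].
#' @return list with elements `quant` (iBAQ [quant_matrix()]),
#'   `evidence` ([peptide_evidence()] for the isoform groups), `design`
#'   ([study_design()] over the fractions), and `truth` (list:
#'   `proteins` data.frame with `protein_id`, `class`, `true_slope`,
#'   `parent_group`; `member_ibaq` noise-applied member-level matrix;
#'   `config`).
#' @export
simulate_purification <- function(config) {
  stopifnot(inherits(config, "purification_sim_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_proteins
    n_mem <- round(cf$frac_membrane * n)
    n_cont <- round(cf$contaminant_rate * (n - n_mem))
    class <- rep("background", n)
    if (n_mem > 0) class[seq_len(n_mem)] <- "membrane"
    if (n_cont > 0) class[n_mem + seq_len(n_cont)] <- "contaminant"
    ids <- sprintf("P%04d", seq_len(n))

    slope <- ifelse(class == "membrane",
                    stats::rnorm(n, cf$slope_membrane, cf$slope_sd),
                    stats::rnorm(n, 0, cf$slope_sd))
    base <- stats::rnorm(n, 6, cf$base_abundance_sigma)
    fr_idx <- seq_len(cf$n_fractions) - 1
    fracs <- c("S1", "P2", "M3", "P6", "S7",
               paste0("F", seq_len(max(0, cf$n_fractions - 5)) + 5))
    fracs <- fracs[seq_len(cf$n_fractions)]

    log_a <- outer(base, rep(1, cf$n_fractions)) +
      outer(slope, fr_idx)
    if (cf$noise_sigma > 0)
      log_a <- log_a + matrix(stats::rnorm(length(log_a), 0,
                                           cf$noise_sigma), n)
    detected <- if (cf$dropout_steepness > 0) {
      p <- stats::plogis(cf$dropout_steepness *
                           (log_a - cf$dropout_midpoint))
      matrix(stats::runif(length(log_a)) < p, n)
    } else matrix(TRUE, n, cf$n_fractions)
    ibaq <- 10^log_a
    ibaq[!detected] <- NA_real_
    dimnames(ibaq) <- list(ids, fracs)

    truth <- data.frame(protein_id = ids, class = class,
                        true_slope = slope,
                        parent_group = NA_character_,
                        stringsAsFactors = FALSE)

    # isoform groups: two members each, quantified as one group row
    evidence <- NULL
    member_ibaq <- NULL
    if (cf$n_isoform_groups > 0) {
      g_ids <- sprintf("GRP%02d", seq_len(cf$n_isoform_groups))
      mem_ids <- sprintf("%s.%s", rep(g_ids, each = 2), c("A", "B"))
      mem_slope <- stats::rnorm(2 * cf$n_isoform_groups, 0, cf$slope_sd)
      mem_base <- stats::rnorm(2 * cf$n_isoform_groups, 6,
                               cf$base_abundance_sigma)
      mem_log <- outer(mem_base, rep(1, cf$n_fractions)) +
        outer(mem_slope, fr_idx)
      if (cf$noise_sigma > 0)
        mem_log <- mem_log + matrix(stats::rnorm(length(mem_log), 0,
                                                 cf$noise_sigma),
                                    nrow(mem_log))
      member_ibaq <- 10^mem_log
      dimnames(member_ibaq) <- list(mem_ids, fracs)
      grp_ibaq <- rowsum(member_ibaq, rep(g_ids, each = 2))
      ibaq <- rbind(ibaq, grp_ibaq[g_ids, , drop = FALSE])
      class <- c(class, rep("background", cf$n_isoform_groups))
      truth <- rbind(truth,
                     data.frame(protein_id = mem_ids,
                                class = "background",
                                true_slope = mem_slope,
                                parent_group = rep(g_ids, each = 2),
                                stringsAsFactors = FALSE))

      # peptides: one unique peptide per member, two shared per group
      uniq_meta <- data.frame(
        peptide_id = paste0("pep_u_", mem_ids),
        sequence = paste0("UNIQ", seq_along(mem_ids)),
        parent_group = rep(g_ids, each = 2),
        unique_to = mem_ids, stringsAsFactors = FALSE)
      sh_ids <- sprintf("pep_s_%s_%d", rep(g_ids, each = 2), 1:2)
      sh_meta <- data.frame(
        peptide_id = sh_ids,
        sequence = paste0("SHAR", seq_along(sh_ids)),
        parent_group = rep(g_ids, each = 2),
        unique_to = NA_character_, stringsAsFactors = FALSE)
      uniq_int <- 0.3 * member_ibaq
      sh_int <- 0.2 * grp_ibaq[rep(g_ids, each = 2), , drop = FALSE]
      rownames(sh_int) <- sh_ids
      evidence <- peptide_evidence(rbind(uniq_meta, sh_meta),
                                   rbind(uniq_int, sh_int))
    }

    quant <- quant_matrix(ibaq,
                          contaminant = class == "contaminant",
                          scale = "ibaq")
    list(quant = quant, evidence = evidence,
         design = study_design(fraction_order = fracs),
         truth = list(proteins = truth, member_ibaq = member_ibaq,
                      config = cf))
  })
}

#' Configuration for the immunoaffinity-purification simulator
#'
#' @param bait_id protein id of the bait (must exist in the totals).
#' @param true_partners data.frame with columns `protein_id`,
#'   `capture_efficiency` in (0, 1].
#' @param n_specific_runs bait-antibody eluate runs (default 6).
#' @param n_control_runs control-IgG eluate runs (default 6).
#' @param nonspecific_rate per-run probability that a non-partner
#'   protein binds the beads nonspecifically (default 0.1; identical
#'   for control and specific runs).
#' @param eluate_noise_sigma natural-log SD of per-run multiplicative
#'   noise (default 0.3; 0 disables).
#' @param capture_gain abundance multiplier from total to eluate for
#'   specifically captured proteins (default 1e4, a bait-like
#'   enrichment).
#' @param partner_detect_prob per-run detection probability for bait
#'   and partners in specific runs (default 0.95).
#' @param seed RNG seed.
#' @return list of class `ip_sim_config`.
#' @export
ip_sim_config <- function(bait_id, true_partners,
                          n_specific_runs = 6, n_control_runs = 6,
                          nonspecific_rate = 0.1,
                          eluate_noise_sigma = 0.3,
                          capture_gain = 1e4,
                          partner_detect_prob = 0.95, seed = 1) {
  stopifnot(n_specific_runs >= 1, n_control_runs >= 0)
  true_partners <- as.data.frame(true_partners, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "capture_efficiency") %in% names(true_partners)))
    stop("`true_partners` needs columns protein_id, capture_efficiency",
         call. = FALSE)
  if (any(true_partners$capture_efficiency <= 0 |
            true_partners$capture_efficiency > 1))
    stop("capture efficiencies must lie in (0, 1]", call. = FALSE)
  if (nonspecific_rate < 0 || nonspecific_rate > 1)
    stop("`nonspecific_rate` must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "ip_sim_config")
}

#' Simulate an immunoaffinity-purification experiment
#'
#' Builds eluate runs on top of a starting-material abundance profile:
#' in specific (bait-antibody) runs the bait is captured at full
#' efficiency and each true partner at its capture efficiency, both
#' amplified by `capture_gain`; every other protein binds
#' nonspecifically with the same per-run probability and
#' abundance-proportional level in specific and control runs (the
#' premise that lets controls be subtracted computationally).
#' Per-run multiplicative log-normal noise and Bernoulli detection
#' dropout are applied.
#'
#' @param config an [ip_sim_config()].
#' @param totals a [quant_matrix()] of starting-material abundances;
#'   its columns become the `total` runs of the output.
#' @return list with `quant` (iBAQ-scale [quant_matrix()] over total +
#'   specific + control runs), `design` ([study_design()] with
#'   `ip_conditions`), `truth` (data.frame `protein_id`, `is_partner`,
#'   `capture_efficiency`).
#' @export
simulate_ip <- function(config, totals) {
  stopifnot(inherits(config, "ip_sim_config"),
            inherits(totals, "quant_matrix"))
  cf <- config
  ids <- rownames(totals$values)
  unknown <- setdiff(c(cf$bait_id, cf$true_partners$protein_id), ids)
  if (length(unknown))
    stop("bait/partner id(s) absent from totals: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  with_seed(cf$seed, {
    avail <- rowMeans(totals$values, na.rm = TRUE)
    avail[!is.finite(avail)] <- 0
    n <- length(ids)
    eff <- stats::setNames(rep(0, n), ids)
    eff[cf$bait_id] <- 1
    eff[cf$true_partners$protein_id] <- cf$true_partners$capture_efficiency
    specific_part <- avail * eff * cf$capture_gain

    spec_runs <- sprintf("IP%d", seq_len(cf$n_specific_runs))
    ctrl_runs <- if (cf$n_control_runs > 0)
      sprintf("CTRL%d", seq_len(cf$n_control_runs)) else character(0)

    # nonspecific binders are drawn from the non-captured proteins with
    # the same abundance-proportional level in specific and control
    # runs; captured proteins' nonspecific contribution is negligible
    # next to their specific capture and is not modelled
    draw_nonspecific <- function() {
      present <- eff == 0 & stats::runif(n) < cf$nonspecific_rate
      ifelse(present, avail, 0)
    }
    noise <- function(x) {
      if (cf$eluate_noise_sigma > 0)
        x * exp(stats::rnorm(length(x), 0, cf$eluate_noise_sigma))
      else x
    }
    cols <- list()
    for (r in spec_runs) {
      v <- noise(specific_part + draw_nonspecific())
      det <- eff > 0 & stats::runif(n) < cf$partner_detect_prob
      v[eff > 0 & !det] <- 0
      cols[[r]] <- v
    }
    for (r in ctrl_runs) cols[[r]] <- noise(draw_nonspecific())
    eluate <- do.call(cbind, cols)
    rownames(eluate) <- ids

    all_values <- cbind(totals$values, eluate)
    design <- study_design(ip_conditions = data.frame(
      run = c(colnames(totals$values), spec_runs, ctrl_runs),
      condition = c(rep("total", ncol(totals$values)),
                    rep("specific", length(spec_runs)),
                    rep("control", length(ctrl_runs))),
      stringsAsFactors = FALSE))
    truth <- data.frame(protein_id = ids,
                        is_partner = ids %in%
                          c(cf$bait_id, cf$true_partners$protein_id),
                        capture_efficiency = unname(eff),
                        stringsAsFactors = FALSE)
    list(quant = quant_matrix(all_values, scale = "ibaq"),
         design = design, truth = truth)
  })
}

#' Configuration for the PRM chromatogram simulator
#'
#' @param peptides list of peptide descriptions; each a list with
#'   `sequence`, `true_rt` (minutes), `fragments` (named numeric vector
#'   of relative fragment intensities summing to 1) and optionally
#'   `amplitude` (apex intensity of the summed peak; default 1e5).
#' @param peak_width_sigma Gaussian elution SD in minutes
#'   (default 0.1).
#' @param noise_floor scale of the additive non-negative noise
#'   (uniform on \[0, noise_floor\]; default 0 = noise-free).
#' @param sampling_interval time between scans, minutes (default 0.05,
#'   i.e. 3 s cycles).
#' @param ms2_event_prob_at_apex probability of a matched MS2
#'   identification event at the peak apex, decaying with the Gaussian
#'   profile off-apex (default 0.8; 0 = never identified).
#' @param run_window length-2 vector, chromatographic window in
#'   minutes (default covers all peptides with a 2-min margin).
#' @param seed RNG seed.
#' @return list of class `prm_sim_config`.
#' @export
prm_sim_config <- function(peptides, peak_width_sigma = 0.1,
                           noise_floor = 0, sampling_interval = 0.05,
                           ms2_event_prob_at_apex = 0.8,
                           run_window = NULL, seed = 1) {
  if (!length(peptides)) stop("empty peptide list", call. = FALSE)
  rts <- vapply(peptides, `[[`, numeric(1), "true_rt")
  for (p in peptides) {
    s <- sum(p$fragments)
    if (abs(s - 1) > 1e-8)
      stop("relative fragment intensities must sum to 1 (peptide ",
           p$sequence, ")", call. = FALSE)
  }
  if (is.null(run_window))
    run_window <- c(max(0, min(rts) - 2), max(rts) + 2)
  if (any(rts < run_window[1] | rts > run_window[2]))
    stop("true_rt outside the run window", call. = FALSE)
  stopifnot(peak_width_sigma > 0, sampling_interval > 0,
            noise_floor >= 0,
            ms2_event_prob_at_apex >= 0, ms2_event_prob_at_apex <= 1)
  structure(as.list(environment()), class = "prm_sim_config")
}

#' Simulate PRM fragment-ion chromatograms
#'
#' Each peptide's fragments co-elute as Gaussians sharing center
#' (`true_rt`) and width; additive noise is non-negative; matched MS2
#' identification events are sampled near the apex with
#' Gaussian-decaying probability. Analytic per-fragment areas
#' (amplitude x relative intensity x sigma x sqrt(2*pi)) are recorded
#' as ground truth.
#'
#' @param config a [prm_sim_config()].
#' @param run run id for the generated traces (default `"run1"`).
#' @return list with `traces` (data.frame `run`, `peptide`, `fragment`,
#'   `time_min`, `intensity`), `ms2` (data.frame `run`, `peptide`,
#'   `time_min`, `matched`), `truth` (data.frame `peptide`, `fragment`,
#'   `true_rt`, `true_area`, plus per-peptide totals where
#'   `fragment == "<sum>"`).
#' @export
simulate_prm <- function(config, run = "run1") {
  stopifnot(inherits(config, "prm_sim_config"))
  cf <- config
  with_seed(cf$seed, {
    grid <- seq(cf$run_window[1], cf$run_window[2],
                by = cf$sampling_interval)
    traces <- list(); ms2 <- list(); truth <- list()
    for (p in cf$peptides) {
      amp <- if (is.null(p$amplitude)) 1e5 else p$amplitude
      shape <- exp(-(grid - p$true_rt)^2 / (2 * cf$peak_width_sigma^2))
      for (f in names(p$fragments)) {
        y <- amp * p$fragments[[f]] * shape
        if (cf$noise_floor > 0)
          y <- y + stats::runif(length(y), 0, cf$noise_floor)
        traces[[length(traces) + 1]] <- data.frame(
          run = run, peptide = p$sequence, fragment = f,
          time_min = grid, intensity = y, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          peptide = p$sequence, fragment = f, true_rt = p$true_rt,
          true_area = amp * p$fragments[[f]] * cf$peak_width_sigma *
            sqrt(2 * pi), stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1]] <- data.frame(
        peptide = p$sequence, fragment = "<sum>", true_rt = p$true_rt,
        true_area = amp * cf$peak_width_sigma * sqrt(2 * pi),
        stringsAsFactors = FALSE)
      if (cf$ms2_event_prob_at_apex > 0) {
        near <- abs(grid - p$true_rt) <= 3 * cf$peak_width_sigma
        pr <- cf$ms2_event_prob_at_apex * shape[near]
        hit <- stats::runif(sum(near)) < pr
        if (any(hit))
          ms2[[length(ms2) + 1]] <- data.frame(
            run = run, peptide = p$sequence,
            time_min = grid[near][hit], matched = TRUE,
            stringsAsFactors = FALSE)
      }
    }
    ms2 <- if (length(ms2)) do.call(rbind, ms2)
           else data.frame(run = character(0), peptide = character(0),
                           time_min = numeric(0), matched = logical(0))
    list(traces = do.call(rbind, traces), ms2 = ms2,
         truth = do.call(rbind, truth))
  })
}
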