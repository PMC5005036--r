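#' Run one stage of the analysis pipeline
#'
#' Thin orchestration over the package's functions, tying the stages
#' into the two label-free workflows (fraction-enrichment profiling and
#' IP analysis) plus the targeted-PRM workflow. Each stage reads its
#' inputs, writes its result tables under `config$out_dir` and records
#' a JSON manifest (stage, parameters, seed, package version, input
#' paths and MD5 checksums of every output), so a rerun with the same
#' config produces byte-identical outputs and checksums.
#'
#' Config entries (a named list, or a path to a YAML file):
#' \describe{
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{seed}{integer seed for `simulate`.}
#'   \item{protein_table, peptide_table, design, chromatograms,
#'         ms2_events, fraction_assays}{input paths per stage.}
#'   \item{min_detected, min_specific, max_control, fdr_alpha, bait,
#'         reference_fraction, log_base, k_range, noise_floor,
#'         smooth_points, rt_tolerance_min}{thresholds with the
#'         package defaults (`min_detected` 3, `min_specific` 4,
#'         `max_control` 0, `fdr_alpha` 0.05, `rt_tolerance_min` 2.0).}
#' }
#'
#' @param config named list or YAML path.
#' @param stage one of `"simulate"`, `"enrich"`, `"cluster"`, `"ip"`,
#'   `"prm"`, `"report"`.
#' @return (invisibly) the manifest list, with element `outputs`
#'   naming every file written.
#' @export
run_pipeline <- function(config,
                         stage = c("simulate", "enrich", "cluster",
                                   "ip", "prm", "report")) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(stage,
    simulate = .stage_simulate(config, out_dir),
    enrich = .stage_enrich(config, out_dir),
    cluster = .stage_cluster(config, out_dir),
    ip = .stage_ip(config, out_dir),
    prm = .stage_prm(config, out_dir),
    report = .stage_report(config, out_dir))
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("stereoquant")),
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = as.list(tools::md5sum(unlist(outputs))))
  manifest_path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message("[", stage, "] wrote ", length(outputs), " file(s) to ", out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

.stage_simulate <- function(config, out_dir) {
  args <- config$simulate %||% list()
  if (!is.null(config$seed)) args$seed <- config$seed
  cf <- do.call(purification_sim_config, args)
  sim <- simulate_purification(cf)
  p1 <- write_protein_table(sim$quant,
                            file.path(out_dir, "protein_table.tsv"))
  p2 <- write_design(sim$design, file.path(out_dir, "design.tsv"))
  outs <- c(p1, p2)
  if (!is.null(sim$evidence))
    outs <- c(outs, write_peptide_table(
      sim$evidence, file.path(out_dir, "peptide_table.tsv")))
  outs <- c(outs, write_result_tsv(
    sim$truth$proteins, file.path(out_dir, "ground_truth.tsv")))
  outs
}

.stage_enrich <- function(config, out_dir) {
  qm <- read_protein_table(config$protein_table)
  design <- read_design(config$design)
  rib <- compute_ribaq(qm)
  slopes <- enrichment_slope(rib, design,
                             min_detected = config$min_detected %||% 3,
                             log_base = config$log_base %||% 10)
  outs <- write_result_tsv(slopes,
                           file.path(out_dir, "enrichment_slopes.tsv"))
  tm <- tm_rolling_average(slopes, rib$tm_helix,
                           window = config$tm_window %||% 50)
  c(outs, write_result_tsv(tm, file.path(out_dir, "tm_rolling.tsv")))
}

.stage_cluster <- function(config, out_dir) {
  qm <- read_protein_table(config$protein_table)
  design <- read_design(config$design)
  rib <- compute_ribaq(qm)
  lg <- rib
  lg$values <- log10(rib$values)
  lg$scale <- "log2"   # generic log scale; only shape matters below
  z <- row_standardize(lg)
  slopes <- enrichment_slope(rib, design,
                             min_detected = config$min_detected %||% 3)
  sl <- stats::setNames(slopes$slope, slopes$protein_id)
  cl <- cluster_profiles(z, k_range = config$k_range %||% 1:9,
                         slopes = sl, seed = config$seed %||% 1)
  tab <- cl$assignments
  tab$k_selected <- cl$k_selected
  tab$model <- cl$model
  c(write_result_tsv(tab, file.path(out_dir, "clusters.tsv")),
    write_result_tsv(cl$bic, file.path(out_dir, "cluster_bic.tsv")))
}

.stage_ip <- function(config, out_dir) {
  qm <- read_protein_table(config$protein_table)
  design <- read_design(config$design)
  rib <- compute_ribaq(qm)
  passing <- filter_specific(rib, design,
                             min_specific = config$min_specific %||% 4,
                             max_control = config$max_control %||% 0)
  er <- enrichment_ratio(rib, design)
  lg <- log2_median_normalize(rib)
  tt <- moderated_t_test(lg, list(ip_runs(design, "specific"),
                                  ip_runs(design, "total")))
  tt$fdr_adjusted_p <- bh_fdr(tt$p_value)
  volcano <- merge(er, tt[, c("protein_id", "t", "df", "p_value",
                              "fdr_adjusted_p")],
                   by = "protein_id", all.x = TRUE)
  volcano <- volcano[order(-volcano$log10_enrichment), ]
  outs <- c(
    write_result_tsv(data.frame(protein_id = passing),
                     file.path(out_dir, "specific_proteins.tsv")),
    write_result_tsv(volcano, file.path(out_dir, "ip_volcano.tsv")))
  if (!is.null(config$bait)) {
    st <- stoichiometry(rib, design, config$bait)
    outs <- c(outs, write_result_tsv(
      st, file.path(out_dir, "stoichiometry.tsv")))
  }
  outs
}

.stage_prm <- function(config, out_dir) {
  traces <- read_chromatograms(config$chromatograms)
  ms2 <- if (!is.null(config$ms2_events))
    read_ms2_events(config$ms2_events) else NULL
  calls <- list()
  for (r in unique(traces$run)) {
    for (pep in unique(traces$peptide[traces$run == r])) {
      tr <- traces[traces$run == r & traces$peptide == pep, ]
      ev <- if (!is.null(ms2))
        ms2[ms2$run == r & ms2$peptide == pep, ] else NULL
      pc <- qualify_peak(
        tr, ev,
        rt_tolerance = config$rt_tolerance_min %||% 2,
        noise_floor = config$noise_floor %||% 0,
        smooth_points = config$smooth_points %||% 3)
      calls[[length(calls) + 1]] <- data.frame(
        run = r, peptide = pep, accepted = pc$accepted,
        area = pc$area, rt_apex = pc$rt_apex,
        start_min = pc$boundaries[1], end_min = pc$boundaries[2],
        n_coeluting = pc$n_coeluting,
        rejection_reasons = paste(pc$rejection_reasons, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  write_result_tsv(do.call(rbind, calls),
                   file.path(out_dir, "prm_peak_areas.tsv"))
}

.stage_report <- function(config, out_dir) {
  assays <- read_fraction_assays(config$fraction_assays)
  ref <- config$reference_fraction %||% assays$fraction[1]
  rep_tab <- fraction_of_reference(assays, ref)
  outs <- write_result_tsv(rep_tab,
                           file.path(out_dir, "fraction_report.tsv"))
  if (!is.null(config$fold_from) && !is.null(config$fold_to)) {
    fold <- per_ug_fold_enrichment(assays, config$fold_from,
                                   config$fold_to)
    outs <- c(outs, write_result_tsv(
      data.frame(from = config$fold_from, to = config$fold_to,
                 fold = fold, fold_report = signif(fold, 1)),
      file.path(out_dir, "fold_enrichment.tsv")))
  }
  outs
}
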