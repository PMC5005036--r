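# Tab-delimited readers and writers for the package's exchange formats.
# All tables are plain TSV with explicit headers; blank fields mean
# "not detected". Standard search-engine protein-group exports map onto
# the protein-table columns (id, gene symbol, contaminant and TM flags,
# one intensity column per sample).

read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a protein-group quantitation table
#'
#' Expected TSV header: `protein_id`, `gene_symbol`, `contaminant`
#' (0/1), `tm_helix` (0/1), then one intensity column per sample; blank
#' cells are missing (not detected).
#'
#' @param path file path.
#' @param scale scale of the stored intensities (default `"ibaq"`).
#' @return a [quant_matrix()]; gene symbols are kept in the
#'   `gene_symbol` attribute.
#' @export
read_protein_table <- function(path, scale = "ibaq") {
  meta_cols <- c("protein_id", "gene_symbol", "contaminant", "tm_helix")
  df <- read_table_checked(path, meta_cols)
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols))
    stop(path, ": no sample intensity columns", call. = FALSE)
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup))
    stop(path, ": duplicate protein_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  v <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(v))
    stop(path, ": non-numeric intensity column(s)", call. = FALSE)
  if (any(v < 0, na.rm = TRUE))
    stop(path, ": negative intensities", call. = FALSE)
  rownames(v) <- df$protein_id
  qm <- quant_matrix(v, contaminant = df$contaminant == 1,
                     tm_helix = df$tm_helix == 1, scale = scale)
  attr(qm, "gene_symbol") <- stats::setNames(df$gene_symbol,
                                             df$protein_id)
  qm
}

#' Write a protein-group quantitation table
#'
#' @param m a [quant_matrix()].
#' @param path output TSV path.
#' @param gene_symbol optional named vector of gene symbols; defaults
#'   to the protein ids.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(m, path, gene_symbol = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  ids <- rownames(m$values)
  if (is.null(gene_symbol)) gene_symbol <- attr(m, "gene_symbol")
  if (is.null(gene_symbol)) gene_symbol <- stats::setNames(ids, ids)
  df <- data.frame(protein_id = ids,
                   gene_symbol = unname(gene_symbol[ids]),
                   contaminant = as.integer(m$contaminant),
                   tm_helix = as.integer(m$tm_helix),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a peptide-evidence table
#'
#' Expected TSV header: `peptide_id`, `sequence`, `parent_group`,
#' `unique_to` (blank = shared peptide), then one intensity column per
#' sample.
#'
#' @param path file path.
#' @return a [peptide_evidence()].
#' @export
read_peptide_table <- function(path) {
  meta_cols <- c("peptide_id", "sequence", "parent_group", "unique_to")
  df <- read_table_checked(path, meta_cols)
  sample_cols <- setdiff(names(df), meta_cols)
  inten <- as.matrix(df[, sample_cols, drop = FALSE])
  peptide_evidence(df[, meta_cols], inten)
}

#' Write a peptide-evidence table
#'
#' @param ev a [peptide_evidence()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(ev, path) {
  stopifnot(inherits(ev, "peptide_evidence"))
  df <- cbind(ev$meta, as.data.frame(ev$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a study-design table
#'
#' Expected TSV header: `sample`, `type` (one of `fraction`, `total`,
#' `control`, `specific`), `order` (fraction order, required for
#' fractions), `replicate` (optional).
#'
#' @param path file path.
#' @return a [study_design()].
#' @export
read_design <- function(path) {
  df <- read_table_checked(path, c("sample", "type"))
  fr <- df[df$type == "fraction", , drop = FALSE]
  fraction_order <- NULL
  if (nrow(fr)) {
    if (is.null(fr$order) || any(is.na(fr$order)))
      stop(path, ": fraction rows need an `order` column", call. = FALSE)
    fraction_order <- fr$sample[order(fr$order)]
  }
  ip <- df[df$type %in% c("total", "control", "specific"), , drop = FALSE]
  ip_conditions <- NULL
  if (nrow(ip))
    ip_conditions <- data.frame(run = ip$sample, condition = ip$type,
                                replicate = if (is.null(ip$replicate))
                                  seq_len(nrow(ip)) else ip$replicate,
                                stringsAsFactors = FALSE)
  study_design(fraction_order, ip_conditions)
}

#' Write a study-design table
#'
#' @param design a [study_design()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  if (!is.null(design$fractions))
    rows$fr <- data.frame(sample = design$fractions$sample,
                          type = "fraction",
                          order = design$fractions$index,
                          replicate = NA, stringsAsFactors = FALSE)
  if (!is.null(design$ip))
    rows$ip <- data.frame(sample = design$ip$run,
                          type = design$ip$condition, order = NA,
                          replicate = design$ip$replicate,
                          stringsAsFactors = FALSE)
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read long-format extracted-ion chromatograms
#'
#' Expected CSV/TSV header: `run`, `peptide`, `fragment`, `time_min`,
#' `intensity`.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return data.frame of traces.
#' @export
read_chromatograms <- function(path, sep = ",") {
  df <- read_table_checked(path, c("run", "peptide", "fragment",
                                   "time_min", "intensity"), sep = sep)
  if (any(!is.finite(df$time_min)))
    stop(path, ": non-numeric time_min values", call. = FALSE)
  if (any(df$intensity < 0, na.rm = TRUE))
    stop(path, ": negative intensities", call. = FALSE)
  df
}

#' Read MS2 identification events
#'
#' Expected CSV/TSV header: `run`, `peptide`, `time_min`, `matched`
#' (0/1 or TRUE/FALSE).
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return data.frame of events with logical `matched`.
#' @export
read_ms2_events <- function(path, sep = ",") {
  df <- read_table_checked(path, c("run", "peptide", "time_min",
                                   "matched"), sep = sep)
  df$matched <- as.logical(df$matched)
  if (any(is.na(df$matched)))
    stop(path, ": `matched` must be 0/1 or TRUE/FALSE", call. = FALSE)
  df
}

#' Read a fraction-assay table
#'
#' Expected TSV header: `fraction`, `protein_ug`, and at least one of
#' `per_ug_intensity`, `total_intensity`.
#'
#' @param path file path.
#' @return data.frame as from [fraction_assays()].
#' @export
read_fraction_assays <- function(path) {
  df <- read_table_checked(path, c("fraction", "protein_ug"))
  fraction_assays(df$fraction, df$protein_ug,
                  per_ug_intensity = df$per_ug_intensity,
                  total_intensity = df$total_intensity)
}
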