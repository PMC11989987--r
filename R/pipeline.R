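# End-to-end orchestration: read -> filter -> aggregate -> spike QC ->
# absolute abundance -> enrichment screen -> paired tests -> summaries.

#' Assemble a pipeline configuration
#'
#' @param counts,taxonomy,metadata,copy_numbers paths to the four input
#'   TSV tables.
#' @param out_dir output directory for the report bundle.
#' @param filter_threshold zOTUs with total reads `<=` this are dropped
#'   (see [filter_low_count_zotus()]).
#' @param ratio_bounds calibrator read-ratio QC interval
#'   (see [qc_samples()]).
#' @param min_pulp_cells,min_fold sporadic-enrichment screen thresholds
#'   (see [sporadic_enrichment_screen()]).
#' @param zero_policy,exact_limit,quartile_type test options
#'   (see [paired_differential()]).
#' @param top_k genera reported per sample type
#'   (see [select_top_genera()]).
#' @param spec a [spike_spec].
#' @return a `pipeline_config` (classed list).
#' @export
pipeline_config <- function(counts, taxonomy, metadata, copy_numbers,
                            out_dir, filter_threshold = 10,
                            ratio_bounds = c(0.1, 10),
                            min_pulp_cells = 20, min_fold = 20,
                            zero_policy = "discard", exact_limit = 25,
                            quartile_type = 7, top_k = 25,
                            spec = spike_spec()) {
  structure(list(counts = counts, taxonomy = taxonomy,
                 metadata = metadata, copy_numbers = copy_numbers,
                 out_dir = out_dir,
                 filter_threshold = filter_threshold,
                 ratio_bounds = ratio_bounds,
                 min_pulp_cells = min_pulp_cells, min_fold = min_fold,
                 zero_policy = zero_policy, exact_limit = exact_limit,
                 quartile_type = quartile_type, top_k = top_k,
                 spec = spec),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys match the arguments of [pipeline_config()]; the
#' spike specification may be given as a `spike` mapping with keys
#' `name_ih`, `copies_ih`, `name_ah`, `copies_ah`, `cells_spiked`.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$spike)) {
    vals$spec <- do.call(spike_spec, vals$spike)
    vals$spike <- NULL
  }
  if (!is.null(vals$ratio_bounds))
    vals$ratio_bounds <- as.numeric(vals$ratio_bounds)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

#' Run the full spike-calibrated analysis
#'
#' Executes every stage on the configured inputs and writes the report
#' bundle to `config$out_dir`: `qc_report.tsv`,
#' `abundance_species.tsv`, `abundance_genus.tsv`, `screen_hits.tsv`,
#' `differential.tsv`, `top_genera.tsv` and `run_log.txt` (parameter
#' echo plus per-stage sample and taxon counts). Any stage failure
#' aborts with the stage name, removing partial outputs. The run is
#' deterministic: identical inputs and configuration give identical
#' outputs.
#'
#' @param config a `pipeline_config`.
#' @return invisible list with every intermediate object.
#' @export
run_all <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_lines <- c("spikequant run", "parameters:",
                 sprintf("  filter_threshold: %g", config$filter_threshold),
                 sprintf("  ratio_bounds: [%g, %g]",
                         config$ratio_bounds[1], config$ratio_bounds[2]),
                 sprintf("  min_pulp_cells: %g  min_fold: %g",
                         config$min_pulp_cells, config$min_fold),
                 sprintf("  zero_policy: %s  exact_limit: %d  quartile_type: %d",
                         config$zero_policy, as.integer(config$exact_limit),
                         as.integer(config$quartile_type)),
                 sprintf("  spike: %s (x%g) / %s (x%g), %g cells each",
                         config$spec$name_ih, config$spec$copies_ih,
                         config$spec$name_ah, config$spec$copies_ah,
                         config$spec$cells_spiked))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(path, writer, obj) {
    writer(obj, path)
    written <<- c(written, path)
  }
  res <- list()
  res$counts <- stage("read", read_counts(config$counts))
  res$taxonomy <- stage("read", read_taxonomy(config$taxonomy))
  res$sheet <- stage("read", read_metadata(config$metadata))
  res$copies <- stage("read", read_copy_numbers(config$copy_numbers))
  log_lines <- c(log_lines, sprintf(
    "read: %d zOTUs, %d samples", nrow(res$counts), ncol(res$counts)))

  res$filtered <- stage("filter",
    filter_low_count_zotus(res$counts, config$filter_threshold))
  log_lines <- c(log_lines, sprintf(
    "filter: %d zOTUs retained (threshold %g)", nrow(res$filtered),
    config$filter_threshold))

  res$species <- stage("aggregate",
    aggregate_by_taxon(res$filtered, res$taxonomy, "species"))
  res$genus <- stage("aggregate",
    aggregate_by_taxon(res$filtered, res$taxonomy, "genus"))
  log_lines <- c(log_lines, sprintf(
    "aggregate: %d species, %d genera", nrow(res$species),
    nrow(res$genus)))

  res$spikes <- stage("spike_qc",
    extract_spike_counts(res$species, config$spec))
  res$qc <- stage("spike_qc",
    qc_samples(res$spikes, config$ratio_bounds))
  emit(file.path(out_dir, "qc_report.tsv"), write_qc_report, res$qc)
  retained <- res$qc$sample_id[res$qc$status == "retained"]
  log_lines <- c(log_lines, sprintf(
    "spike_qc: %d of %d samples retained", length(retained),
    nrow(res$qc)))
  if (length(retained) == 0) {
    unlink(written)
    stop("pipeline stage 'spike_qc' failed: no retained samples",
         call. = FALSE)
  }
  spikes_ok <- res$spikes[res$spikes$sample_id %in% retained, ]

  res$ab_species <- stage("abundance", estimate_absolute_abundance(
    res$species, spikes_ok, res$copies, config$spec))
  res$ab_genus <- stage("abundance", estimate_absolute_abundance(
    res$genus, spikes_ok, res$copies, config$spec))
  emit(file.path(out_dir, "abundance_species.tsv"), write_abundance,
       res$ab_species)
  emit(file.path(out_dir, "abundance_genus.tsv"), write_abundance,
       res$ab_genus)

  res$hits <- stage("screen", sporadic_enrichment_screen(
    res$ab_species, res$sheet, config$min_pulp_cells, config$min_fold))
  emit(file.path(out_dir, "screen_hits.tsv"), write_screen_hits,
       res$hits)
  log_lines <- c(log_lines, sprintf(
    "screen: %d sporadically enriched species", nrow(res$hits)))

  res$diff <- stage("test", rbind(
    cbind(rank = "species", paired_differential(
      res$ab_species, res$sheet, zero_policy = config$zero_policy,
      exact_limit = config$exact_limit,
      quartile_type = config$quartile_type)),
    cbind(rank = "genus", paired_differential(
      res$ab_genus, res$sheet, zero_policy = config$zero_policy,
      exact_limit = config$exact_limit,
      quartile_type = config$quartile_type))))
  emit(file.path(out_dir, "differential.tsv"), write_differential,
       res$diff)
  log_lines <- c(log_lines, sprintf(
    "test: %d taxon-comparison results", nrow(res$diff)))

  res$top <- stage("summary", select_top_genera(
    res$ab_genus, res$sheet, k = config$top_k))
  emit(file.path(out_dir, "top_genera.tsv"),
       function(obj, path) utils::write.table(
         obj, path, sep = "\t", quote = FALSE, row.names = FALSE),
       res$top)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(res)
}

#' Select the dominant genera per sample type
#'
#' Ranks genera within each sample type by their median cell-equivalent
#' abundance across that type's samples; genera tied at a zero median
#' are ordered by mean abundance instead, and remaining ties break
#' lexicographically. The top `k` per type are returned. With
#' `by = "sample"` the ranking is per individual sample by its own
#' abundances.
#'
#' @param ab a genus-rank `abundance_table`.
#' @param sheet a [sample_sheet].
#' @param k genera per group (default 25).
#' @param by `"type"` (default) or `"sample"`.
#' @return data.frame: `group` (sample type or sample id), `position`,
#'   `genus`, `median_ab`, `mean_ab`.
#' @export
select_top_genera <- function(ab, sheet, k = 25, by = c("type", "sample")) {
  by <- match.arg(by)
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a positive integer")
  ab <- biological_abundance(ab)
  m <- unclass(ab)
  type <- .sample_types(ab, sheet)
  groups <- if (by == "type") {
    g <- lapply(unique(type), function(tt) which(type == tt))
    names(g) <- unique(type)
    g
  } else {
    g <- lapply(seq_len(ncol(m)), identity)
    names(g) <- colnames(m)
    g
  }
  out <- lapply(names(groups), function(gn) {
    cols <- groups[[gn]]
    med <- apply(m[, cols, drop = FALSE], 1, stats::median)
    mn <- rowMeans(m[, cols, drop = FALSE])
    # median desc; zero-median (and any other) ties fall back to mean,
    # then to name
    ord <- order(-med, -mn, rownames(m))
    sel <- ord[seq_len(min(k, nrow(m)))]
    data.frame(group = gn, position = seq_along(sel),
               genus = rownames(m)[sel], median_ab = med[sel],
               mean_ab = mn[sel], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
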