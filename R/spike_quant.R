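# Calibrator detection, spike-recovery QC, and conversion of read counts
# to absolute cell-equivalent abundances.

#' Specification of the cellular spike-in calibrators
#'
#' Describes the two exogenous calibrator species added to every sample
#' before DNA extraction at a known cell count, together with their
#' genomic 16S rRNA copy numbers. Defaults match the ZymoBIOMICS
#' spike-in Control I pair: *Imtechella halotolerans* (3 copies of the
#' 16S gene per genome) and *Allobacillus halotolerans* (7 copies), each
#' spiked at 500 cells.
#'
#' @param name_ih species name of the first calibrator (Imtechella).
#' @param copies_ih genomic 16S copies of the first calibrator.
#' @param name_ah species name of the second calibrator (Allobacillus).
#' @param copies_ah genomic 16S copies of the second calibrator.
#' @param cells_spiked cells of each calibrator added per sample.
#' @return a `spike_spec` (classed list).
#' @export
spike_spec <- function(name_ih = "Imtechella halotolerans", copies_ih = 3,
                       name_ah = "Allobacillus halotolerans", copies_ah = 7,
                       cells_spiked = 500) {
  if (identical(name_ih, name_ah))
    stop("the two calibrators must be distinct species")
  if (copies_ih <= 0 || copies_ah <= 0 || cells_spiked <= 0)
    stop("copy numbers and cells_spiked must be strictly positive")
  structure(list(name_ih = name_ih, copies_ih = copies_ih,
                 name_ah = name_ah, copies_ah = copies_ah,
                 cells_spiked = cells_spiked),
            class = "spike_spec")
}

#' Extract calibrator read counts per sample
#'
#' Pulls the rows of a species-level count table matching the two
#' calibrator species. A calibrator absent from the table contributes
#' zero reads in every sample.
#'
#' @param taxa a species-rank `taxon_counts` object
#'   (see [aggregate_by_taxon()]).
#' @param spec a [spike_spec].
#' @return data.frame with columns `sample_id`, `n_ih`, `n_ah`.
#' @export
extract_spike_counts <- function(taxa, spec = spike_spec()) {
  if (!identical(attr(taxa, "rank"), "species"))
    stop("spike counts must be extracted from a species-level table")
  grab <- function(name) {
    if (name %in% rownames(taxa)) as.numeric(unclass(taxa)[name, ])
    else rep(0, ncol(taxa))
  }
  data.frame(sample_id = colnames(taxa),
             n_ih = grab(spec$name_ih),
             n_ah = grab(spec$name_ah),
             stringsAsFactors = FALSE)
}

#' Quality-control samples on calibrator recovery
#'
#' A sample is excluded when either calibrator is undetected (zero
#' reads), since the extraction or amplification evidently failed for at
#' least part of the community, or when the Allobacillus/Imtechella read
#' ratio falls outside `ratio_bounds`, indicating distorted recovery.
#' With both calibrators spiked at equal cell counts and 7 vs 3 genomic
#' 16S copies, the ideal ratio is 7/3; the default bounds span a
#' symmetric decade around unity so that grossly aberrant samples
#' (ratios in the hundreds or thousands) are flagged while ordinary
#' extraction variability is tolerated.
#'
#' @param spikes data.frame from [extract_spike_counts()].
#' @param ratio_bounds length-2 positive numeric, lower < upper; samples
#'   with `n_ah/n_ih` outside this closed interval are excluded.
#' @return a `spike_qc` data.frame: `sample_id`, `n_ih`, `n_ah`,
#'   `ratio_ah_ih` (NA when undefined), `status` (one of `retained`,
#'   `excluded_undetected`, `excluded_ratio`), `reason`.
#' @export
qc_samples <- function(spikes, ratio_bounds = c(0.1, 10)) {
  if (length(ratio_bounds) != 2 || !is.numeric(ratio_bounds) ||
      any(ratio_bounds <= 0) || ratio_bounds[1] >= ratio_bounds[2])
    stop("ratio_bounds must be two positive numbers, lower < upper")
  ratio <- ifelse(spikes$n_ih > 0 & spikes$n_ah > 0,
                  spikes$n_ah / spikes$n_ih, NA_real_)
  undet <- spikes$n_ih == 0 | spikes$n_ah == 0
  aberr <- !undet & (ratio < ratio_bounds[1] | ratio > ratio_bounds[2])
  status <- ifelse(undet, "excluded_undetected",
                   ifelse(aberr, "excluded_ratio", "retained"))
  reason <- character(nrow(spikes))
  reason[undet] <- "one or both calibrators undetected"
  reason[aberr] <- sprintf("Ah/Ih read ratio %.3g outside [%g, %g]",
                           ratio[aberr], ratio_bounds[1], ratio_bounds[2])
  reason[status == "retained"] <- "calibrators recovered"
  out <- data.frame(sample_id = spikes$sample_id,
                    n_ih = spikes$n_ih, n_ah = spikes$n_ah,
                    ratio_ah_ih = ratio, status = status, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("spike_qc", "data.frame")
  out
}

#' Look up the 16S copy number of a taxon with rank-wise fallback
#'
#' Walks the taxon's lineage from species up to domain, returning the
#' copy number of the first rank with an entry in the table; when no
#' rank matches, the table's dataset-wide default (taxon `"*"`, rank
#' `"default"`) is used. The walk skips unclassified ranks. The result
#' depends only on the table's contents, never on its row order.
#'
#' @param taxon taxon name (used in error messages).
#' @param lineage named character vector or one-row data.frame giving the
#'   7 ranks of [TAX_RANKS] for the taxon.
#' @param table a [copy_number_table].
#' @return a single positive copy number.
#' @export
lookup_copy_number <- function(taxon, lineage, table) {
  lineage <- unlist(lineage[TAX_RANKS])
  for (r in rev(TAX_RANKS)) {          # species first, then up to domain
    nm <- lineage[[r]]
    if (is.na(nm) || nm == UNCLASSIFIED) next
    hit <- table$taxon == nm & table$rank == r
    if (any(hit)) return(table$copies[hit][1])
  }
  dflt <- table$rank == "default"
  if (any(dflt)) return(table$copies[dflt][1])
  stop(sprintf("no 16S copy number found for taxon '%s' at any rank %s",
               taxon, "and no default entry provided"))
}

#' Estimate absolute abundances in cell equivalents
#'
#' Converts read counts to cell equivalents using the two spike-in
#' calibrators. For taxon X in a sample with calibrator reads
#' `N_Ih`, `N_Ah`, spiked cells `C`, calibrator copy numbers 3 and 7,
#' and taxon copy number `Copy16S_X`:
#'
#' \deqn{AB_X = \frac{1}{2}\left(\frac{N_X}{N_{Ih}} \cdot C \cdot
#'   \frac{3}{Copy16S_X} + \frac{N_X}{N_{Ah}} \cdot C \cdot
#'   \frac{7}{Copy16S_X}\right)}
#'
#' i.e. the mean of the two single-calibrator estimates. The estimator
#' assumes reads are proportional to cells times 16S copy number within
#' a sample; under that ideal each calibrator's own estimate equals `C`
#' exactly. Only samples with both calibrators detected may be processed
#' — run [qc_samples()] first and pass retained samples only.
#'
#' @param taxa a `taxon_counts` object (species or genus rank).
#' @param spikes data.frame from [extract_spike_counts()], subset to
#'   QC-retained samples; both counts must be positive everywhere.
#' @param copies a [copy_number_table].
#' @param spec a [spike_spec]. Calibrator rows use the spec's own copy
#'   numbers rather than a table lookup.
#' @return an `abundance_table`: matrix of cell equivalents (taxon x
#'   retained sample) with attributes `rank`, `lineage`, `calibrator`
#'   (logical per row) and `copy_number` (numeric per row).
#' @export
estimate_absolute_abundance <- function(taxa, spikes, copies,
                                        spec = spike_spec()) {
  if (any(spikes$n_ih <= 0) || any(spikes$n_ah <= 0))
    stop("all processed samples must have positive calibrator counts; ",
         "run qc_samples() and keep retained samples only")
  miss <- setdiff(spikes$sample_id, colnames(taxa))
  if (length(miss) > 0)
    stop(sprintf("samples absent from count table: %s",
                 paste(miss, collapse = ", ")))
  m <- unclass(taxa)[, spikes$sample_id, drop = FALSE]
  lineage <- attr(taxa, "lineage")
  role <- vapply(seq_len(nrow(m)),
                 function(i) .calibrator_role(lineage[i, ], spec),
                 character(1))
  cn <- vapply(seq_len(nrow(m)), function(i) {
    if (role[i] == "ih") return(spec$copies_ih)
    if (role[i] == "ah") return(spec$copies_ah)
    lookup_copy_number(lineage$taxon[i], lineage[i, ], copies)
  }, numeric(1))
  C <- spec$cells_spiked
  # per-sample calibrator scale factors
  s_ih <- C * spec$copies_ih / spikes$n_ih
  s_ah <- C * spec$copies_ah / spikes$n_ah
  ab <- (m %*% diag(s_ih, nrow = length(s_ih)) +
         m %*% diag(s_ah, nrow = length(s_ah))) / (2 * cn)
  dimnames(ab) <- dimnames(m)
  structure(ab, rank = attr(taxa, "rank"), lineage = lineage,
            calibrator = role != "none",
            copy_number = stats::setNames(cn, rownames(m)),
            class = c("abundance_table", "matrix", "array"))
}

# Identify whether an aggregated row is one of the calibrators. At
# species rank the species name is compared; at genus rank the genus is
# compared against the calibrator's genus (first word of its binomial),
# which is safe because the calibrators are exogenous marine/halophile
# genera absent from the communities under study.
.calibrator_role <- function(lineage_row, spec) {
  sp <- as.character(lineage_row[["species"]])
  gn <- as.character(lineage_row[["genus"]])
  if (identical(sp, spec$name_ih)) return("ih")
  if (identical(sp, spec$name_ah)) return("ah")
  if (identical(sp, UNCLASSIFIED)) {
    if (identical(gn, strsplit(spec$name_ih, " ")[[1]][1])) return("ih")
    if (identical(gn, strsplit(spec$name_ah, " ")[[1]][1])) return("ah")
  }
  "none"
}

#' Drop calibrator rows from an abundance table
#'
#' The spiked organisms are experimental controls, not community
#' members; all biological outputs (screens, tests, summaries) work on
#' the table with calibrator rows removed.
#'
#' @param ab an `abundance_table`.
#' @return the table without calibrator rows.
#' @export
biological_abundance <- function(ab) {
  keep <- !attr(ab, "calibrator")
  structure(unclass(ab)[keep, , drop = FALSE],
            rank = attr(ab, "rank"),
            lineage = attr(ab, "lineage")[keep, , drop = FALSE],
            calibrator = rep(FALSE, sum(keep)),
            copy_number = attr(ab, "copy_number")[keep],
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "%s-level abundance table: %d taxa (%d calibrator) x %d samples\n",
    attr(x, "rank"), nrow(x), sum(attr(x, "calibrator")), ncol(x)))
  invisible(x)
}

#' Write a spike QC report as TSV
#' @param qc a `spike_qc` data.frame from [qc_samples()].
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(as.data.frame(qc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an abundance table as TSV
#'
#' Columns: `taxon`, `is_calibrator`, then one column of cell
#' equivalents per retained sample.
#'
#' @param ab an `abundance_table`.
#' @param path output path.
#' @export
write_abundance <- function(ab, path) {
  df <- data.frame(taxon = rownames(ab),
                   is_calibrator = attr(ab, "calibrator"),
                   unclass(ab)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an abundance table written by [write_abundance()]
#' @param path TSV path.
#' @param rank rank label to attach (`"species"` or `"genus"`).
#' @return an `abundance_table` (without lineage information).
#' @export
read_abundance <- function(path, rank = "species") {
  df <- .read_tsv(path)
  if (!all(c("taxon", "is_calibrator") %in% colnames(df)))
    stop(sprintf("%s: expected columns 'taxon' and 'is_calibrator'", path))
  samp <- setdiff(colnames(df), c("taxon", "is_calibrator"))
  m <- as.matrix(vapply(df[samp], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, samp))
  rownames(m) <- df$taxon
  structure(m, rank = rank, lineage = NULL,
            calibrator = df$is_calibrator == "TRUE",
            copy_number = NULL,
            class = c("abundance_table", "matrix", "array"))
}
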