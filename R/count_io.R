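# Reading, validation, filtering and aggregation of zOTU count data.

#' Taxonomic ranks used throughout the package
#'
#' Seven-rank bacterial lineage, highest to lowest.
#' @export
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

#' Marker for an unassigned rank in a lineage
#' @export
UNCLASSIFIED <- "unclassified"

#' Construct a validated zOTU count table
#'
#' A zOTU (zero-radius OTU) count table holds nonnegative integer read
#' counts, one row per zOTU, one column per sample. Row and column names
#' are the zOTU and sample identifiers and must be unique.
#'
#' @param counts numeric matrix of nonnegative whole numbers, with unique
#'   rownames (zOTU ids) and unique colnames (sample ids).
#' @return a `zotu_counts` object (a classed matrix).
#' @export
zotu_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 || ncol(counts) > 0) {
    if (is.null(colnames(counts)))
      stop("count matrix must have sample ids as column names")
  }
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("count matrix must have zOTU ids as row names")
  .check_unique(rownames(counts), "zOTU id")
  .check_unique(colnames(counts), "sample id")
  .check_count_cells(counts)
  storage.mode(counts) <- "double"
  structure(counts, class = c("zotu_counts", "matrix", "array"))
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")))
  invisible(ids)
}

.check_count_cells <- function(m) {
  if (length(m) == 0) return(invisible(m))
  if (!is.numeric(m) || anyNA(m))
    stop("counts must be numeric with no missing values")
  if (any(m < 0)) stop("counts must be nonnegative")
  if (any(m != floor(m))) stop("counts must be whole numbers")
  invisible(m)
}

#' @export
print.zotu_counts <- function(x, ...) {
  cat(sprintf("zOTU count table: %d zOTUs x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

.read_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  # read.delim silently uniquifies duplicated headers; re-impose originals
  if (length(header) == ncol(df)) colnames(df) <- header
  df
}

#' Read a zOTU count table from TSV
#'
#' Expects a UTF-8 tab-separated file whose first column is headed
#' `zotu_id` and whose remaining column headers are sample ids; cells are
#' nonnegative integers. Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @return a [zotu_counts] object.
#' @export
read_counts <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 1 || colnames(df)[1] != "zotu_id")
    stop(sprintf("%s: first column must be 'zotu_id'", path))
  .check_unique(colnames(df)[-1], "sample id")
  samples <- colnames(df)[-1]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                dimnames = list(NULL, samples))
    return(zotu_counts(m))
  }
  m <- matrix(vals, nrow = nrow(df), ncol = length(samples),
              dimnames = list(df$zotu_id, samples))
  if (anyNA(m)) stop(sprintf("%s: non-numeric count cell", path))
  if (any(m != floor(m)))
    stop(sprintf("%s: non-integer count cell", path))
  zotu_counts(m)
}

#' Read a BIOM-format count table
#'
#' Maps a BIOM file onto the same contract as [read_counts()]. Requires
#' the `biomformat` package.
#'
#' @param path path to a BIOM file.
#' @return a [zotu_counts] object.
#' @export
read_counts_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  zotu_counts(m)
}

#' Write a zOTU count table as TSV
#'
#' Inverse of [read_counts()]; a write/read round trip reproduces the
#' table exactly.
#'
#' @param x a [zotu_counts] object.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(zotu_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(x) == 0)
    df <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = ncol(x) + 1)),
      c("zotu_id", colnames(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a validated taxonomy table
#'
#' One row per zOTU with a 7-rank lineage (domain through species). Each
#' entry is a taxon name, an EzBioCloud-style phylotype name (`_s` / `_g`
#' suffix), or the literal `"unclassified"`. Once a rank is unclassified,
#' every lower rank must be unclassified too.
#'
#' @param df data.frame with columns `zotu_id` and the seven ranks of
#'   [TAX_RANKS].
#' @return a `taxonomy_table` (classed data.frame).
#' @export
taxonomy_table <- function(df) {
  need <- c("zotu_id", TAX_RANKS)
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop(sprintf("taxonomy missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- df[, need, drop = FALSE]
  .check_unique(df$zotu_id, "zOTU id")
  lin <- as.matrix(df[, TAX_RANKS, drop = FALSE])
  if (anyNA(lin) || any(lin == ""))
    stop("taxonomy entries must be names or 'unclassified', not blank")
  uncls <- lin == UNCLASSIFIED
  if (nrow(lin) > 0) {
    for (i in seq_len(nrow(lin))) {
      u <- which(uncls[i, ])
      if (length(u) > 0 && any(!uncls[i, u[1]:length(TAX_RANKS)]))
        stop(sprintf(
          "zOTU %s: rank below an 'unclassified' rank carries a name",
          df$zotu_id[i]))
    }
  }
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with columns `zotu_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`.
#' @return a [taxonomy_table].
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(.read_tsv(path))
}

#' Write a taxonomy table as TSV
#' @param x a [taxonomy_table].
#' @param path output path.
#' @export
write_taxonomy <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a validated sample sheet
#'
#' Samples carry a type (`pulp`, `dentin` or `control`) and a patient id
#' linking the pulp and dentin sample of the same tooth. Reagent controls
#' may have a missing patient id. Each (patient, type) combination occurs
#' at most once.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`,
#'   `sample_type`.
#' @return a `sample_sheet` (classed data.frame).
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "patient_id", "sample_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop(sprintf("metadata missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- df[, need, drop = FALSE]
  df$patient_id[!is.na(df$patient_id) & df$patient_id == ""] <- NA
  .check_unique(df$sample_id, "sample id")
  bad <- setdiff(unique(df$sample_type), c("pulp", "dentin", "control"))
  if (length(bad) > 0)
    stop(sprintf("unknown sample_type value(s): %s",
                 paste(bad, collapse = ", ")))
  with_pat <- !is.na(df$patient_id)
  key <- paste(df$patient_id[with_pat], df$sample_type[with_pat])
  if (anyDuplicated(key))
    stop("each (patient_id, sample_type) may occur at most once")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path TSV with columns `sample_id`, `patient_id`, `sample_type`.
#' @return a [sample_sheet].
#' @export
read_metadata <- function(path) {
  df <- .read_tsv(path)
  if ("patient_id" %in% colnames(df))
    df$patient_id[df$patient_id %in% c("", "NA")] <- NA
  sample_sheet(df)
}

#' Write a sample sheet as TSV
#' @param x a [sample_sheet].
#' @param path output path.
#' @export
write_metadata <- function(x, path) {
  df <- as.data.frame(x)
  df$patient_id[is.na(df$patient_id)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a validated 16S copy-number table
#'
#' Median genomic 16S rRNA copy numbers per taxon at a given rank, used
#' to correct read counts for copy-number bias. An optional row with
#' taxon `"*"` and rank `"default"` supplies a dataset-wide fallback for
#' taxa unresolvable at any rank.
#'
#' @param df data.frame with columns `taxon`, `rank`, `copies`.
#' @return a `copy_number_table` (classed data.frame).
#' @export
copy_number_table <- function(df) {
  need <- c("taxon", "rank", "copies")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop(sprintf("copy-number table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  df <- df[, need, drop = FALSE]
  df$copies <- as.numeric(df$copies)
  if (anyNA(df$copies) || any(df$copies <= 0))
    stop("16S copy numbers must be positive")
  bad <- setdiff(unique(df$rank), c(TAX_RANKS, "default"))
  if (length(bad) > 0)
    stop(sprintf("unknown rank value(s): %s", paste(bad, collapse = ", ")))
  if (any(df$rank == "default" & df$taxon != "*"))
    stop("the default row must have taxon '*'")
  if (sum(df$rank == "default") > 1)
    stop("at most one default copy-number row allowed")
  if (anyDuplicated(paste(df$taxon, df$rank)))
    stop("at most one copy-number entry per (taxon, rank)")
  class(df) <- c("copy_number_table", "data.frame")
  df
}

#' Read a 16S copy-number table from TSV
#' @param path TSV with columns `taxon`, `rank`, `copies`.
#' @return a [copy_number_table].
#' @export
read_copy_numbers <- function(path) {
  copy_number_table(.read_tsv(path))
}

#' Write a copy-number table as TSV
#' @param x a [copy_number_table].
#' @param path output path.
#' @export
write_copy_numbers <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove low-count zOTUs
#'
#' Drops every zOTU whose total read count summed across all samples is
#' at or below `max_total`. This mirrors the common denoising-pipeline
#' convention of discarding sparsely represented sequence variants, which
#' in low-biomass data are dominated by residual errors and cross-talk.
#' The sample set is unchanged; surviving rows are untouched.
#'
#' @param x a [zotu_counts] object.
#' @param max_total nonnegative threshold; zOTUs with total `<= max_total`
#'   are removed (default 10).
#' @return a filtered [zotu_counts] object.
#' @export
filter_low_count_zotus <- function(x, max_total = 10) {
  if (!is.numeric(max_total) || length(max_total) != 1 || max_total < 0)
    stop("max_total must be a single nonnegative number")
  if (nrow(x) == 0) return(x)
  keep <- rowSums(unclass(x)) > max_total
  zotu_counts(unclass(x)[keep, , drop = FALSE])
}

#' Aggregate zOTU counts to species or genus level
#'
#' Sums the read counts of all zOTUs sharing the same taxon name at the
#' requested rank. zOTUs unclassified at that rank are pooled per lowest
#' classified ancestor under the name `"<ancestor> unclassified"` (e.g.
#' `"Atopostipes unclassified"` for zOTUs resolved to the genus
#' Atopostipes but not to a species), so pools under different ancestors
#' stay distinct. Aggregation conserves reads: per sample, the column sum
#' of the result equals the column sum of the input.
#'
#' @param counts a [zotu_counts] object.
#' @param taxonomy a [taxonomy_table] covering every zOTU in `counts`.
#' @param rank `"species"` or `"genus"`.
#' @return a `taxon_counts` object: a counts matrix (taxon x sample) with
#'   attributes `rank` and `lineage` (data.frame of taxon name plus the
#'   7-rank lineage of each row, `"unclassified"` below the aggregation
#'   resolution).
#' @export
aggregate_by_taxon <- function(counts, taxonomy, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  ri <- match(rank, TAX_RANKS)
  idx <- match(rownames(counts), taxonomy$zotu_id)
  if (anyNA(idx))
    stop(sprintf("zOTUs missing from taxonomy: %s",
                 paste(rownames(counts)[is.na(idx)][1:min(5, sum(is.na(idx)))],
                       collapse = ", ")))
  lin <- as.matrix(as.data.frame(taxonomy)[idx, TAX_RANKS, drop = FALSE])
  # truncate lineage at the aggregation rank; lower ranks are unresolved
  lin[, seq_along(TAX_RANKS) > ri] <- UNCLASSIFIED
  name_at <- lin[, ri]
  pooled <- name_at == UNCLASSIFIED
  if (any(pooled)) {
    anc <- apply(lin[pooled, seq_len(ri - 1), drop = FALSE], 1, function(v) {
      cls <- which(v != UNCLASSIFIED)
      if (length(cls) == 0) UNCLASSIFIED else v[max(cls)]
    })
    name_at[pooled] <- ifelse(anc == UNCLASSIFIED, UNCLASSIFIED,
                              paste(anc, UNCLASSIFIED))
  }
  key <- apply(cbind(lin[, seq_len(ri), drop = FALSE]), 1, paste,
               collapse = "\r")
  first <- !duplicated(key)
  ord <- key[first]                      # first-occurrence row order
  if (nrow(counts) == 0) {
    m <- matrix(numeric(0), 0, ncol(counts),
                dimnames = list(NULL, colnames(counts)))
    lineage <- data.frame(taxon = character(0))
    for (r in TAX_RANKS) lineage[[r]] <- character(0)
    return(structure(m, rank = rank, lineage = lineage,
                     class = c("taxon_counts", "matrix", "array")))
  }
  agg <- rowsum(unclass(counts), group = key, reorder = FALSE)
  agg <- agg[match(ord, rownames(agg)), , drop = FALSE]
  names_ord <- name_at[first]
  lin_ord <- lin[first, , drop = FALSE]
  if (anyDuplicated(names_ord)) names_ord <- make.unique(names_ord, sep = " #")
  rownames(agg) <- names_ord
  lineage <- data.frame(taxon = names_ord, lin_ord, row.names = NULL,
                        stringsAsFactors = FALSE)
  colnames(lineage) <- c("taxon", TAX_RANKS)
  structure(agg, rank = rank, lineage = lineage,
            class = c("taxon_counts", "matrix", "array"))
}

#' @export
print.taxon_counts <- function(x, ...) {
  cat(sprintf("%s-level count table: %d taxa x %d samples\n",
              attr(x, "rank"), nrow(x), ncol(x)))
  invisible(x)
}
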