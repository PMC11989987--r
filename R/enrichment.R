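# Sporadic-enrichment screening and paired nonparametric differential
# testing on cell-equivalent abundance tables.

#' Screen for taxa sporadically enriched in pulp samples
#'
#' A consistent group-level shift is not the only signature of interest
#' in low-biomass data: a taxon genuinely present in a tooth may appear
#' in a single pulp sample yet never in dentin or reagent controls. The
#' screen reports every taxon whose maximum abundance over pulp samples
#' reaches `min_pulp_cells` cell equivalents AND is at least `min_fold`
#' times the highest abundance observed in any dentin or control sample.
#' A taxon entirely absent from the background passes the fold condition
#' vacuously. Calibrator rows are never reported.
#'
#' @param ab an `abundance_table` restricted to QC-retained samples.
#' @param sheet a [sample_sheet] covering the table's samples.
#' @param min_pulp_cells minimum cell equivalents in at least one pulp
#'   sample (default 20).
#' @param min_fold minimum ratio of the pulp maximum to the background
#'   maximum (default 20).
#' @return data.frame of hits sorted by `max_pulp_ab` descending:
#'   `taxon`, `max_pulp_ab`, `max_background_ab`, `fold` (Inf when the
#'   background is zero), then one abundance column per sample.
#' @export
sporadic_enrichment_screen <- function(ab, sheet, min_pulp_cells = 20,
                                       min_fold = 20) {
  if (min_pulp_cells <= 0 || min_fold <= 0)
    stop("min_pulp_cells and min_fold must be positive")
  ab <- biological_abundance(ab)
  type <- .sample_types(ab, sheet)
  pulp <- colnames(ab)[type == "pulp"]
  bg <- colnames(ab)[type %in% c("dentin", "control")]
  if (length(pulp) == 0)
    stop("screen requires at least one pulp sample")
  m <- unclass(ab)
  max_pulp <- apply(m[, pulp, drop = FALSE], 1, max)
  max_bg <- if (length(bg) > 0) apply(m[, bg, drop = FALSE], 1, max)
            else rep(0, nrow(m))
  hit <- max_pulp >= min_pulp_cells & max_pulp >= min_fold * max_bg
  fold <- ifelse(max_bg > 0, max_pulp / max_bg, Inf)
  out <- data.frame(taxon = rownames(m), max_pulp_ab = max_pulp,
                    max_background_ab = max_bg, fold = fold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  out <- out[hit, , drop = FALSE]
  out <- out[order(-out$max_pulp_ab, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.sample_types <- function(ab, sheet) {
  idx <- match(colnames(ab), sheet$sample_id)
  if (anyNA(idx))
    stop(sprintf("samples missing from metadata: %s",
                 paste(colnames(ab)[is.na(idx)], collapse = ", ")))
  sheet$sample_type[idx]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired observations. Zero differences
#' are handled per `zero_policy`: `"discard"` (drop before ranking, the
#' convention of most amplicon-analysis software) or `"pratt"` (rank
#' with zeros included, then drop the zero ranks). Absolute differences
#' are ranked with midranks for ties; the statistic W is the sum of
#' ranks of positive differences. For `m <= exact_limit` informative
#' pairs the p-value comes from the exact null distribution of W over
#' all \eqn{2^m} sign assignments (computed by convolution, so ties are
#' handled exactly); beyond that a normal approximation with tie-exact
#' variance and continuity correction is used. All differences zero
#' gives p = 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param zero_policy `"discard"` or `"pratt"`.
#' @param exact_limit largest number of informative pairs for which the
#'   exact distribution is enumerated (default 25).
#' @return list with `statistic` (W), `p_value`, `n_used` (informative
#'   pairs m) and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y, zero_policy = c("discard", "pratt"),
                                 exact_limit = 25) {
  zero_policy <- match.arg(zero_policy)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 1) stop("at least one pair required")
  d <- x - y
  if (zero_policy == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  m <- length(d)
  if (m == 0)
    return(list(statistic = 0, p_value = 1, n_used = 0, method = "exact"))
  W <- sum(r[d > 0])
  if (m <= exact_limit) {
    p <- .signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)        # tie-exact: Var = sum(r_i^2)/4
    z <- W - mu
    cc <- 0.5 * sign(z)
    z <- if (sigma > 0) (z - cc) / sigma else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n_used = m, method = method)
}

# Exact two-sided p for W = sum of ranks of positive differences, given
# the (mid)ranks r. Doubling the smaller tail equals the symmetric
# |W - E[W]| tail probability because the null distribution of W is
# symmetric under flipping all signs. Ranks are doubled so midranks
# (k/2) become integers, then the subset-sum distribution is built by
# convolution.
.signed_rank_exact_p <- function(r, W) {
  s <- as.integer(round(2 * r))
  S <- sum(s)
  f <- numeric(S + 1)
  f[1] <- 1
  for (si in s) {
    shifted <- c(numeric(si), f[seq_len(S + 1 - si)])
    f <- f + shifted
  }
  total <- 2^length(s)
  w <- as.integer(round(2 * W))
  pl <- sum(f[seq_len(w + 1)]) / total
  pu <- sum(f[seq.int(w + 1, S + 1)]) / total
  min(1, 2 * min(pl, pu))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values (q-values): for sorted p-values,
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1. Monotone in p
#' and never below the raw p-value. Delegates to
#' [stats::p.adjust()][stats::p.adjust] after validating the input.
#'
#' @param p numeric vector of p-values in \[0, 1\], no missing values.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Paired differential-abundance testing between sample types
#'
#' For each taxon, tests pulp against dentin (`pulp_vs_dentin`) and pulp
#' against reagent control (`pulp_vs_control`) with the Wilcoxon
#' signed-rank test on patient-matched abundance pairs. Patients lacking
#' either member of a pair are dropped from that comparison. Taxa with
#' zero abundance in every sample of both groups are uninformative and
#' skipped. Benjamini-Hochberg correction is applied within each
#' comparison family separately. Group summaries (median, min, Q1, Q3,
#' max, over all samples of the type) accompany each result.
#'
#' @param ab an `abundance_table` restricted to QC-retained samples.
#' @param sheet a [sample_sheet].
#' @param comparisons subset of `c("pulp_vs_dentin", "pulp_vs_control")`.
#' @param zero_policy,exact_limit passed to [wilcoxon_signed_rank()].
#' @param quartile_type quantile algorithm for Q1/Q3
#'   (see [stats::quantile()]; default 7, linear interpolation).
#' @return data.frame: `taxon`, `comparison`, `other_group`, `n_pairs`,
#'   `statistic`, `p_value`, `q_value`, then `pulp_*` and `other_*`
#'   summary columns (median, min, q1, q3, max). Comparisons
#'   with fewer than 2 complete pairs are flagged `untestable = TRUE`
#'   with NA p and q.
#' @export
paired_differential <- function(ab, sheet,
                                comparisons = c("pulp_vs_dentin",
                                                "pulp_vs_control"),
                                zero_policy = "discard", exact_limit = 25,
                                quartile_type = 7) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  ab <- biological_abundance(ab)
  m <- unclass(ab)
  idx <- match(colnames(m), sheet$sample_id)
  if (anyNA(idx))
    stop("all abundance samples must appear in the metadata")
  stype <- sheet$sample_type[idx]
  patient <- sheet$patient_id[idx]
  res <- list()
  for (cmp in comparisons) {
    other <- if (cmp == "pulp_vs_dentin") "dentin" else "control"
    pulp_cols <- which(stype == "pulp")
    other_cols <- which(stype == other)
    # patient-matched pairs present on both sides
    pp <- patient[pulp_cols]; po <- patient[other_cols]
    shared <- intersect(pp[!is.na(pp)], po[!is.na(po)])
    i_pulp <- pulp_cols[match(shared, pp)]
    i_other <- other_cols[match(shared, po)]
    n_pairs <- length(shared)
    group_cols <- c(pulp_cols, other_cols)
    informative <- rowSums(m[, group_cols, drop = FALSE] > 0) > 0
    taxa <- rownames(m)[informative]
    rows <- lapply(taxa, function(tx) {
      pulp_ab <- m[tx, pulp_cols]
      other_ab <- m[tx, other_cols]
      if (n_pairs >= 2) {
        wt <- wilcoxon_signed_rank(m[tx, i_pulp], m[tx, i_other],
                                   zero_policy = zero_policy,
                                   exact_limit = exact_limit)
        stat <- wt$statistic; pv <- wt$p_value; untest <- FALSE
      } else {
        stat <- NA_real_; pv <- NA_real_; untest <- TRUE
      }
      data.frame(taxon = tx, comparison = cmp, other_group = other,
                 n_pairs = n_pairs,
                 statistic = stat, p_value = pv, untestable = untest,
                 .summary(pulp_ab, "pulp", quartile_type),
                 .summary(other_ab, "other", quartile_type),
                 stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    if (!is.null(fam)) {
      fam$q_value <- NA_real_
      ok <- !is.na(fam$p_value)
      fam$q_value[ok] <- benjamini_hochberg(fam$p_value[ok])
      res[[cmp]] <- fam
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  front <- c("taxon", "comparison", "other_group", "n_pairs",
             "statistic", "p_value", "q_value", "untestable")
  out[, c(front, setdiff(colnames(out), front)), drop = FALSE]
}

.summary <- function(v, label, quartile_type) {
  if (length(v) == 0) {
    out <- data.frame(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
    colnames(out) <- paste(label, c("median", "min", "q1", "q3", "max"),
                           sep = "_")
    return(out)
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = quartile_type, names = FALSE)
  out <- data.frame(stats::median(v), min(v), q[1], q[2], max(v))
  colnames(out) <- paste(label, c("median", "min", "q1", "q3", "max"),
                         sep = "_")
  out
}

#' Format a group summary as "median (min; Q1; Q3; max)"
#' @param median,min,q1,q3,max numeric vectors.
#' @param digits significant digits (default 3).
#' @return character vector.
#' @export
format_group_summary <- function(median, min, q1, q3, max, digits = 3) {
  f <- function(x) formatC(signif(x, digits), format = "fg", flag = "#")
  trim <- function(s) sub("\\.$", "", trimws(s))
  sprintf("%s (%s;%s;%s;%s)", trim(f(median)), trim(f(min)), trim(f(q1)),
          trim(f(q3)), trim(f(max)))
}

#' Write screen hits as TSV
#' @param hits data.frame from [sporadic_enrichment_screen()].
#' @param path output path.
#' @export
write_screen_hits <- function(hits, path) {
  hits$fold[is.infinite(hits$fold)] <- "inf"
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write differential test results as TSV
#'
#' Emits one formatted "median (min; Q1; Q3; max)" column per group in
#' addition to the numeric columns.
#'
#' @param diff data.frame from [paired_differential()].
#' @param path output path.
#' @export
write_differential <- function(diff, path) {
  for (g in c("pulp", "other")) {
    cols <- paste(g, c("median", "min", "q1", "q3", "max"), sep = "_")
    if (all(cols %in% colnames(diff)))
      diff[[paste0(g, "_summary")]] <-
        do.call(format_group_summary, unname(as.list(diff[cols])))
  }
  utils::write.table(diff, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
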