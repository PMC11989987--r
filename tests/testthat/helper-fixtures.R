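# In-code fixtures and independent oracles shared across the suite.

# ---- tiny tables ----------------------------------------------------------

tiny_counts_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("zotu_id\tS1\tS2",
               "z1\t5\t0",
               "z2\t7\t2",
               "z3\t0\t11"), path)
  path
}

lineage_row <- function(species, genus = "GenusX", family = "FamilyX",
                        order = "OrderX", class = "ClassX",
                        phylum = "PhylumX", domain = "Bacteria") {
  data.frame(domain = domain, phylum = phylum, class = class,
             order = order, family = family, genus = genus,
             species = species, stringsAsFactors = FALSE)
}

# taxonomy for a vector of zotu ids, optionally overriding ranks per zotu
make_taxonomy <- function(zotu_ids, species, genus = NULL) {
  if (is.null(genus)) genus <- vapply(strsplit(species, " "),
                                      `[`, "", 1)
  taxonomy_table(data.frame(
    zotu_id = zotu_ids,
    do.call(rbind, Map(function(s, g) lineage_row(s, genus = g),
                       species, genus)),
    row.names = NULL, stringsAsFactors = FALSE))
}

make_sheet <- function(n_patients = 3, n_controls = 2,
                       control_patients = FALSE) {
  pid <- sprintf("P%d", seq_len(n_patients))
  ctrl_pid <- if (control_patients && n_controls > 0)
    sprintf("P%d", seq_len(n_controls)) else rep(NA_character_, n_controls)
  sample_sheet(data.frame(
    sample_id = c(sprintf("pulp%d", seq_len(n_patients)),
                  sprintf("dent%d", seq_len(n_patients)),
                  if (n_controls > 0) sprintf("ctrl%d", seq_len(n_controls))),
    patient_id = c(pid, pid, ctrl_pid),
    sample_type = c(rep("pulp", n_patients), rep("dentin", n_patients),
                    rep("control", n_controls)),
    stringsAsFactors = FALSE))
}

# an abundance_table built directly (no estimator), for screen/test units
fake_ab <- function(m, rank = "species") {
  lineage <- data.frame(taxon = rownames(m),
                        do.call(rbind, lapply(rownames(m), lineage_row)),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(m, rank = rank, lineage = lineage,
            calibrator = rep(FALSE, nrow(m)),
            copy_number = stats::setNames(rep(4, nrow(m)), rownames(m)),
            class = c("abundance_table", "matrix", "array"))
}

# a species-level taxon_counts table whose reads are exactly proportional
# to cells x 16S copies: the ideal noiseless sample
ideal_species_table <- function(spec = spike_spec(), extra = NULL,
                                scale = 2) {
  taxa <- c(spec$name_ih, spec$name_ah)
  reads <- scale * spec$cells_spiked * c(spec$copies_ih, spec$copies_ah)
  genera <- c("Imtechella", "Allobacillus")
  if (!is.null(extra)) {
    taxa <- c(taxa, extra$taxon)
    reads <- c(reads, scale * extra$cells * extra$copies)
    genera <- c(genera, vapply(strsplit(extra$taxon, " "), `[`, "", 1))
  }
  counts <- zotu_counts(matrix(reads, ncol = 1,
                               dimnames = list(sprintf("z%d",
                                                       seq_along(taxa)),
                                               "S1")))
  aggregate_by_taxon(counts, make_taxonomy(rownames(counts), taxa, genera),
                     "species")
}

# ---- independent oracles --------------------------------------------------

# Signed-rank two-sided p by explicit enumeration of every sign vector.
brute_signed_rank <- function(x, y, zero_policy = "discard") {
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
  if (m == 0) return(list(W = 0, p = 1))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Wd <- as.numeric(signs %*% r)
  p <- min(1, 2 * min(mean(Wd <= W), mean(Wd >= W)))
  list(W = W, p = p)
}

# Closed-form two-pass BH step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q
}
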