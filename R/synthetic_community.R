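# Ground-truthed simulator for low-biomass spike-in amplicon datasets:
# a reagent-contaminant background shared by all sample types, sporadic
# oral taxa confined to pulp samples, calibrators at a known cell count
# with occasional dropout/distortion, and multinomial read sampling
# proportional to cells x 16S copy number.

#' Default reagent-contaminant profile
#'
#' Twelve taxa named after genera that dominate extraction-kit
#' contamination in low-biomass 16S studies (Burkholderiales members
#' prominent among them). Per-taxon cell loads are lognormal,
#' `meanlog`/`sdlog` chosen to span roughly 10-250 cells per sample at
#' the median — plausible kitome levels, not fitted to any dataset.
#' The same profile applies to pulp, dentin and control samples alike,
#' which is the defining property of reagent contamination.
#'
#' @return data.frame: `taxon`, the 7 ranks of [TAX_RANKS], `copies`
#'   (genomic 16S copies), `meanlog`, `sdlog`.
#' @export
default_contaminant_profile <- function() {
  tab <- rbind(
    c("Pelomonas saccharophila", "Pseudomonadota", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Pelomonas", 2, log(230), 0.8),
    c("Paraburkholderia fungorum", "Pseudomonadota", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", "Paraburkholderia", 5, log(150), 0.8),
    c("Cutibacterium acnes", "Actinomycetota", "Actinomycetes", "Propionibacteriales", "Propionibacteriaceae", "Cutibacterium", 3, log(60), 0.7),
    c("Ralstonia pickettii", "Pseudomonadota", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae", "Ralstonia", 4, log(40), 0.9),
    c("Acinetobacter junii", "Pseudomonadota", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Acinetobacter", 6, log(30), 0.9),
    c("Staphylococcus epidermidis", "Bacillota", "Bacilli", "Bacillales", "Staphylococcaceae", "Staphylococcus", 5, log(25), 0.8),
    c("Micrococcus luteus", "Actinomycetota", "Actinomycetes", "Micrococcales", "Micrococcaceae", "Micrococcus", 2, log(20), 0.8),
    c("Corynebacterium afermentans", "Actinomycetota", "Actinomycetes", "Corynebacteriales", "Corynebacteriaceae", "Corynebacterium", 4, log(15), 0.9),
    c("Bradyrhizobium elkanii", "Pseudomonadota", "Alphaproteobacteria", "Rhizobiales", "Bradyrhizobiaceae", "Bradyrhizobium", 1, log(12), 0.8),
    c("Sphingomonas paucimobilis", "Pseudomonadota", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae", "Sphingomonas", 2, log(10), 0.9),
    c("Methylobacterium radiotolerans", "Pseudomonadota", "Alphaproteobacteria", "Rhizobiales", "Methylobacteriaceae", "Methylobacterium", 5, log(8), 0.9),
    c("Pseudomonas poae", "Pseudomonadota", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas", 5, log(10), 0.9))
  .profile_df(tab, prevalence = NULL)
}

#' Default sporadic oral-taxon panel
#'
#' Six oral taxa present only in pulp samples, each with a per-sample
#' presence probability (`prevalence`) and a lognormal load when
#' present. Includes a Treponema entry with a high load at low
#' prevalence, emulating the occasional pulp sample dominated by a
#' genuine oral spirochete rather than by contaminants.
#'
#' @return data.frame as in [default_contaminant_profile()] plus a
#'   `prevalence` column.
#' @export
default_oral_panel <- function() {
  tab <- rbind(
    c("Treponema medium", "Spirochaetota", "Spirochaetia", "Spirochaetales", "Treponemataceae", "Treponema", 2, log(800), 1.0),
    c("Fretibacterium fastidiosum", "Synergistota", "Synergistia", "Synergistales", "Synergistaceae", "Fretibacterium", 2, log(60), 1.0),
    c("Fusobacterium nucleatum", "Fusobacteriota", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae", "Fusobacterium", 5, log(40), 0.8),
    c("Finegoldia magna", "Bacillota", "Tissierellia", "Tissierellales", "Peptoniphilaceae", "Finegoldia", 4, log(30), 0.8),
    c("Schlegelella aquatica", "Pseudomonadota", "Betaproteobacteria", "Burkholderiales", "Comamonadaceae", "Schlegelella", 2, log(25), 0.9),
    c("Atopostipes suicloacalis", "Bacillota", "Bacilli", "Lactobacillales", "Carnobacteriaceae", "Atopostipes", 4, log(15), 0.8))
  df <- .profile_df(tab, prevalence = c(0.12, 0.2, 0.25, 0.25, 0.2, 0.3))
  df
}

.profile_df <- function(tab, prevalence) {
  df <- data.frame(taxon = tab[, 1], domain = "Bacteria",
                   phylum = tab[, 2], class = tab[, 3], order = tab[, 4],
                   family = tab[, 5], genus = tab[, 6],
                   species = tab[, 1],
                   copies = as.numeric(tab[, 7]),
                   meanlog = as.numeric(tab[, 8]),
                   sdlog = as.numeric(tab[, 9]),
                   stringsAsFactors = FALSE)
  if (!is.null(prevalence)) df$prevalence <- prevalence
  df
}

.spike_profile <- function(spec) {
  data.frame(taxon = c(spec$name_ih, spec$name_ah),
             domain = "Bacteria",
             phylum = c("Bacteroidota", "Bacillota"),
             class = c("Flavobacteriia", "Bacilli"),
             order = c("Flavobacteriales", "Bacillales"),
             family = c("Flavobacteriaceae", "Bacillaceae"),
             genus = c("Imtechella", "Allobacillus"),
             species = c(spec$name_ih, spec$name_ah),
             copies = c(spec$copies_ih, spec$copies_ah),
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic low-biomass community
#'
#' Collects every parameter of the simulator. Defaults mirror the
#' archetypal study design this simulator emulates: 17 patients each
#' contributing one pulp and one dentin sample, 9 reagent controls, a
#' shared contaminant background, a sporadic oral panel confined to
#' pulp, calibrators spiked at a fixed cell count, and per-sample read
#' depths around 50,000 (negative binomial across samples).
#'
#' @param n_patients patients; each yields one pulp + one dentin sample.
#' @param n_controls reagent-control samples (no patient id).
#' @param depth_mean mean total reads per sample.
#' @param depth_dispersion negative-binomial size for the across-sample
#'   depth distribution; `Inf` gives a fixed depth.
#' @param contaminant_profile data.frame as
#'   [default_contaminant_profile()].
#' @param oral_panel data.frame as [default_oral_panel()].
#' @param spike_dropout_prob probability a sample loses one calibrator
#'   entirely (extraction failure for that organism).
#' @param spike_distortion_prob probability the Allobacillus calibrator
#'   load is multiplied by `spike_distortion_factor`, emulating the
#'   grossly aberrant read ratios occasionally seen in practice. At most
#'   one spike event occurs per sample (dropout drawn first).
#' @param spike_distortion_factor multiplicative distortion (default 100).
#' @param zotus_per_taxon zOTUs each taxon's reads are split across.
#' @param read_model `"multinomial"` (reads allocated multinomially
#'   given total depth) or `"nb"` (independent negative-binomial reads
#'   per taxon around the same expectations, for robustness checks).
#' @param nb_size per-taxon negative-binomial size when
#'   `read_model = "nb"`.
#' @param seed root seed; every random draw of the simulator flows from
#'   it.
#' @return a `simulation_config` (classed list).
#' @export
simulation_config <- function(n_patients = 17, n_controls = 9,
                              depth_mean = 5e4, depth_dispersion = 10,
                              contaminant_profile = default_contaminant_profile(),
                              oral_panel = default_oral_panel(),
                              spike_dropout_prob = 0.05,
                              spike_distortion_prob = 0.05,
                              spike_distortion_factor = 100,
                              zotus_per_taxon = 2,
                              read_model = c("multinomial", "nb"),
                              nb_size = 10,
                              seed = 1L) {
  read_model <- match.arg(read_model)
  stopifnot(n_patients >= 1, n_controls >= 0, depth_mean > 0,
            spike_dropout_prob >= 0, spike_dropout_prob <= 1,
            spike_distortion_prob >= 0, spike_distortion_prob <= 1,
            spike_distortion_factor > 0, zotus_per_taxon >= 1,
            all(contaminant_profile$sdlog >= 0),
            all(oral_panel$prevalence >= 0 & oral_panel$prevalence <= 1))
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 contaminant_profile = contaminant_profile,
                 oral_panel = oral_panel,
                 spike_dropout_prob = spike_dropout_prob,
                 spike_distortion_prob = spike_distortion_prob,
                 spike_distortion_factor = spike_distortion_factor,
                 zotus_per_taxon = zotus_per_taxon,
                 read_model = read_model, nb_size = nb_size,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate ground-truth cell loads
#'
#' Draws the true per-sample cell load of every taxon. Contaminant loads
#' are i.i.d. lognormal per taxon per sample, identical in distribution
#' across pulp, dentin and control samples. Oral-panel taxa appear only
#' in pulp samples, each with its prevalence probability and lognormal
#' load. Calibrators sit at `spec$cells_spiked` except in samples hit by
#' a dropout (one calibrator zeroed, chosen at random) or distortion
#' (Allobacillus multiplied by the distortion factor) event; events are
#' recorded in the event log. Deterministic for a fixed `config$seed`.
#'
#' @param config a [simulation_config].
#' @param spec a [spike_spec].
#' @return a `community_truth` list: `sheet` (a [sample_sheet]), `loads`
#'   (taxon x sample matrix of true cells), `taxa` (profile data.frame
#'   with lineages and copy numbers), `events` (per-sample event log),
#'   `spec`.
#' @export
simulate_truth <- function(config, spec = spike_spec()) {
  set.seed(config$seed)
  np <- config$n_patients; nc <- config$n_controls
  pid <- sprintf("P%02d", seq_len(np))
  sheet <- sample_sheet(data.frame(
    sample_id = c(sprintf("A%02d", seq_len(nc)),
                  sprintf("B%02d", seq_len(np)),
                  sprintf("C%02d", seq_len(np))),
    patient_id = c(rep(NA_character_, nc), pid, pid),
    sample_type = c(rep("control", nc), rep("dentin", np),
                    rep("pulp", np)),
    stringsAsFactors = FALSE))
  cont <- config$contaminant_profile
  oral <- config$oral_panel
  spk <- .spike_profile(spec)
  taxa <- rbind(cbind(cont, prevalence = NA_real_, role = "contaminant"),
                cbind(oral, role = "oral"),
                cbind(spk, meanlog = NA_real_, sdlog = NA_real_,
                      prevalence = NA_real_, role = "calibrator"))
  rownames(taxa) <- NULL
  ns <- nrow(sheet)
  loads <- matrix(0, nrow(taxa), ns,
                  dimnames = list(taxa$taxon, sheet$sample_id))
  is_pulp <- sheet$sample_type == "pulp"
  for (i in which(taxa$role == "contaminant"))
    loads[i, ] <- stats::rlnorm(ns, taxa$meanlog[i], taxa$sdlog[i])
  for (i in which(taxa$role == "oral")) {
    present <- is_pulp & stats::runif(ns) < taxa$prevalence[i]
    loads[i, present] <- stats::rlnorm(sum(present), taxa$meanlog[i],
                                       taxa$sdlog[i])
  }
  loads[spec$name_ih, ] <- spec$cells_spiked
  loads[spec$name_ah, ] <- spec$cells_spiked
  u <- stats::runif(ns)
  event <- rep("none", ns)
  detail <- rep("", ns)
  for (s in seq_len(ns)) {
    if (u[s] < config$spike_dropout_prob) {
      event[s] <- "dropout"
      victim <- if (stats::runif(1) < 0.5) spec$name_ih else spec$name_ah
      loads[victim, s] <- 0
      detail[s] <- victim
    } else if (u[s] < config$spike_dropout_prob +
                      config$spike_distortion_prob) {
      event[s] <- "distortion"
      loads[spec$name_ah, s] <- loads[spec$name_ah, s] *
        config$spike_distortion_factor
      detail[s] <- sprintf("%s x%g", spec$name_ah,
                           config$spike_distortion_factor)
    }
  }
  events <- data.frame(sample_id = sheet$sample_id, event = event,
                       detail = detail, stringsAsFactors = FALSE)
  structure(list(sheet = sheet, loads = loads, taxa = taxa,
                 events = events, spec = spec),
            class = "community_truth")
}

#' Simulate amplicon reads from a ground truth
#'
#' Per sample, the total read depth is drawn from the configured depth
#' distribution and allocated to taxa with probability proportional to
#' true cell load times 16S copy number — the same proportionality that
#' the downstream estimator inverts. Each taxon's reads are then split
#' uniformly at random among its `zotus_per_taxon` zOTUs, and a
#' consistent taxonomy table is emitted. Copy numbers are resolved
#' through [lookup_copy_number()] so the read model and the estimator
#' share one copy-number source.
#'
#' @param truth a `community_truth` from [simulate_truth()].
#' @param copies a [copy_number_table] covering every truth taxon.
#' @param config the same [simulation_config].
#' @return list: `counts` (a [zotu_counts]), `taxonomy` (a
#'   [taxonomy_table]).
#' @export
simulate_reads <- function(truth, copies, config) {
  # distinct stream from simulate_truth so each stage is reproducible
  # on its own; both flow from the one root seed
  set.seed((config$seed + 999983L) %% .Machine$integer.max)
  taxa <- truth$taxa
  cn <- vapply(seq_len(nrow(taxa)), function(i)
    lookup_copy_number(taxa$taxon[i], taxa[i, TAX_RANKS], copies),
    numeric(1))
  k <- config$zotus_per_taxon
  nt <- nrow(taxa)
  zotu_ids <- sprintf("zotu%04d", seq_len(nt * k))
  zotu_taxon <- rep(seq_len(nt), each = k)
  ns <- ncol(truth$loads)
  counts <- matrix(0, nt * k, ns,
                   dimnames = list(zotu_ids, colnames(truth$loads)))
  depth <- if (is.infinite(config$depth_dispersion))
    rep(round(config$depth_mean), ns)
  else
    stats::rnbinom(ns, mu = config$depth_mean,
                   size = config$depth_dispersion)
  for (s in seq_len(ns)) {
    w <- truth$loads[, s] * cn
    if (depth[s] == 0 || sum(w) == 0) next
    taxon_reads <- if (config$read_model == "multinomial")
      as.numeric(stats::rmultinom(1, depth[s], w))
    else
      stats::rnbinom(nt, mu = depth[s] * w / sum(w), size = config$nb_size)
    for (i in which(taxon_reads > 0)) {
      rows <- which(zotu_taxon == i)
      counts[rows, s] <- as.numeric(
        stats::rmultinom(1, taxon_reads[i], rep(1, k)))
    }
  }
  taxonomy <- taxonomy_table(data.frame(
    zotu_id = zotu_ids,
    as.data.frame(taxa[zotu_taxon, TAX_RANKS]),
    row.names = NULL, stringsAsFactors = FALSE))
  list(counts = zotu_counts(counts), taxonomy = taxonomy)
}

#' Build a copy-number table covering a simulated community
#'
#' Species-rank entries for every truth taxon plus a dataset-wide
#' default of 4.2 copies (a plausible bacterial median).
#'
#' @param truth a `community_truth`.
#' @param default_copies fallback copy number (default 4.2).
#' @return a [copy_number_table].
#' @export
truth_copy_numbers <- function(truth, default_copies = 4.2) {
  copy_number_table(data.frame(
    taxon = c(truth$taxa$taxon, "*"),
    rank = c(rep("species", nrow(truth$taxa)), "default"),
    copies = c(truth$taxa$copies, default_copies),
    stringsAsFactors = FALSE))
}

#' Write a complete simulated fixture to disk
#'
#' Emits every input the pipeline readers consume — `counts.tsv`,
#' `taxonomy.tsv`, `metadata.tsv`, `copy_numbers.tsv` — plus
#' `truth.tsv` (sample, taxon, true cells, event flags). Re-running
#' with the same seed reproduces the files byte for byte.
#'
#' @param truth a `community_truth`.
#' @param counts a [zotu_counts].
#' @param taxonomy a [taxonomy_table].
#' @param copies a [copy_number_table].
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of the five file paths.
#' @export
write_fixture <- function(truth, counts, taxonomy, copies, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  paths <- file.path(out_dir, c("counts.tsv", "taxonomy.tsv",
                                "metadata.tsv", "copy_numbers.tsv",
                                "truth.tsv"))
  write_counts(counts, paths[1])
  write_taxonomy(taxonomy, paths[2])
  write_metadata(truth$sheet, paths[3])
  write_copy_numbers(copies, paths[4])
  ev <- truth$events[match(colnames(truth$loads),
                           truth$events$sample_id), ]
  long <- data.frame(
    sample_id = rep(colnames(truth$loads), each = nrow(truth$loads)),
    taxon = rep(rownames(truth$loads), times = ncol(truth$loads)),
    true_cells = as.vector(truth$loads),
    event = rep(ev$event, each = nrow(truth$loads)),
    event_detail = rep(ev$detail, each = nrow(truth$loads)),
    stringsAsFactors = FALSE)
  utils::write.table(long, paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
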