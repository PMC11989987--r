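test_that("spike counts are extracted per sample, zero when a calibrator is absent", {
  spec <- spike_spec()
  tab <- ideal_species_table(spec, extra = data.frame(
    taxon = "Finegoldia magna", cells = 100, copies = 4))
  sc <- extract_spike_counts(tab, spec)
  expect_equal(sc$n_ih, 2 * 500 * 3)
  expect_equal(sc$n_ah, 2 * 500 * 7)

  no_spikes <- aggregate_by_taxon(
    zotu_counts(matrix(10, 1, 1, dimnames = list("z1", "S1"))),
    make_taxonomy("z1", "Finegoldia magna"), "species")
  sc0 <- extract_spike_counts(no_spikes, spec)
  expect_equal(sc0$n_ih, 0)
  expect_equal(sc0$n_ah, 0)

  gen <- aggregate_by_taxon(
    zotu_counts(matrix(10, 1, 1, dimnames = list("z1", "S1"))),
    make_taxonomy("z1", "Finegoldia magna"), "genus")
  expect_error(extract_spike_counts(gen, spec), "species")
})

test_that("QC labels undetected, aberrant-ratio, and retained samples", {
  spikes <- data.frame(
    sample_id = c("ok", "high", "very_high", "lost_ih", "lost_ah", "low"),
    n_ih = c(3000, 2, 1, 0, 500, 5000),
    n_ah = c(7000, 870, 2603, 500, 0, 100))
  qc <- qc_samples(spikes, ratio_bounds = c(0.1, 10))
  expect_equal(qc$status,
               c("retained", "excluded_ratio", "excluded_ratio",
                 "excluded_undetected", "excluded_undetected",
                 "excluded_ratio"))
  expect_equal(qc$ratio_ah_ih[1], 7 / 3)
  expect_equal(qc$ratio_ah_ih[2], 435)
  expect_true(is.na(qc$ratio_ah_ih[4]))
  # every sample gets exactly one status
  expect_equal(nrow(qc), nrow(spikes))
  expect_true(all(qc$status %in% c("retained", "excluded_undetected",
                                   "excluded_ratio")))

  expect_error(qc_samples(spikes, c(-1, 10)), "positive")
  expect_error(qc_samples(spikes, c(10, 2)), "lower")
})

test_that("copy-number lookup walks species to domain then default, order-independently", {
  table <- copy_number_table(data.frame(
    taxon = c("Finegoldia magna", "Atopostipes", "Carnobacteriaceae", "*"),
    rank = c("species", "genus", "family", "default"),
    copies = c(5, 4, 3.5, 4.2)))
  lin_sp <- lineage_row("Finegoldia magna", genus = "Finegoldia",
                        family = "Peptoniphilaceae")
  expect_equal(lookup_copy_number("Finegoldia magna", lin_sp, table), 5)

  lin_gen <- lineage_row("Atopostipes suicloacalis", genus = "Atopostipes",
                         family = "Carnobacteriaceae")
  expect_equal(lookup_copy_number("Atopostipes suicloacalis", lin_gen,
                                  table), 4)

  lin_fam <- lineage_row("unclassified", genus = "unclassified",
                         family = "Carnobacteriaceae")
  expect_equal(lookup_copy_number("Carnobacteriaceae unclassified",
                                  lin_fam, table), 3.5)

  lin_none <- lineage_row("Rothia amarae", genus = "Rothia",
                          family = "Micrococcaceae")
  expect_equal(lookup_copy_number("Rothia amarae", lin_none, table), 4.2)

  no_default <- copy_number_table(data.frame(
    taxon = "Finegoldia magna", rank = "species", copies = 5))
  expect_error(lookup_copy_number("Rothia amarae", lin_none, no_default),
               "Rothia amarae")

  # permuting table rows never changes any lookup
  set.seed(11)
  for (i in 1:10) {
    shuf <- copy_number_table(as.data.frame(table)[sample(nrow(table)), ])
    for (lin in list(lin_sp, lin_gen, lin_fam, lin_none))
      expect_equal(lookup_copy_number("x", lin, shuf),
                   lookup_copy_number("x", lin, table))
  }
})

test_that("estimator reproduces the hand-worked value and its basic identities", {
  spec <- spike_spec()
  # N_Ih = N_Ah = N_X = 100, Copy16S_X = 1 -> (1*500*3 + 1*500*7)/2 = 2500
  counts <- zotu_counts(matrix(c(100, 100, 100, 0), ncol = 1,
                               dimnames = list(paste0("z", 1:4), "S1")))
  tax <- make_taxonomy(paste0("z", 1:4),
                       c(spec$name_ih, spec$name_ah, "Rothia amarae",
                         "Finegoldia magna"),
                       c("Imtechella", "Allobacillus", "Rothia",
                         "Finegoldia"))
  sp <- aggregate_by_taxon(counts, tax, "species")
  copies <- copy_number_table(data.frame(
    taxon = c("Rothia amarae", "*"), rank = c("species", "default"),
    copies = c(1, 4.2)))
  spikes <- extract_spike_counts(sp, spec)
  ab <- estimate_absolute_abundance(sp, spikes, copies, spec)
  expect_equal(unclass(ab)["Rothia amarae", "S1"], 2500)
  # zero reads give exactly zero cells
  expect_equal(unclass(ab)["Finegoldia magna", "S1"], 0)
  # calibrator rows are flagged
  expect_equal(sum(attr(ab, "calibrator")), 2L)

  # linearity: doubling N_X doubles ab at fixed spike counts
  counts2 <- zotu_counts(matrix(c(100, 100, 200, 0), ncol = 1,
                                dimnames = list(paste0("z", 1:4), "S1")))
  sp2 <- aggregate_by_taxon(counts2, tax, "species")
  ab2 <- estimate_absolute_abundance(sp2, spikes, copies, spec)
  expect_equal(unclass(ab2)["Rothia amarae", "S1"], 2 * 2500)

  # QC contract: zero spike counts are refused
  bad <- data.frame(sample_id = "S1", n_ih = 0, n_ah = 100)
  expect_error(estimate_absolute_abundance(sp, bad, copies, spec),
               "qc_samples")
})

test_that("estimator equals the mean of two independently computed single-calibrator estimates", {
  spec <- spike_spec()
  set.seed(3)
  for (i in 1:20) {
    n_ih <- sample(50:5000, 1)
    n_ah <- sample(50:5000, 1)
    n_x <- sample(0:5000, 1)
    cn_x <- runif(1, 1, 12)
    counts <- zotu_counts(matrix(c(n_ih, n_ah, n_x), ncol = 1,
                                 dimnames = list(paste0("z", 1:3), "S1")))
    tax <- make_taxonomy(paste0("z", 1:3),
                         c(spec$name_ih, spec$name_ah, "Rothia amarae"),
                         c("Imtechella", "Allobacillus", "Rothia"))
    sp <- aggregate_by_taxon(counts, tax, "species")
    copies <- copy_number_table(data.frame(taxon = "Rothia amarae",
                                           rank = "species",
                                           copies = cn_x))
    ab <- estimate_absolute_abundance(sp, extract_spike_counts(sp, spec),
                                      copies, spec)
    # independent re-derivation of each single-calibrator estimate
    est_ih <- n_x / n_ih * 500 * 3 / cn_x
    est_ah <- n_x / n_ah * 500 * 7 / cn_x
    expect_equal(unclass(ab)["Rothia amarae", "S1"],
                 mean(c(est_ih, est_ah)))
  }
})

test_that("ideal proportional reads recover each calibrator at exactly the spiked amount", {
  spec <- spike_spec()
  tab <- ideal_species_table(spec, extra = data.frame(
    taxon = c("Rothia amarae", "Finegoldia magna"),
    cells = c(40, 250), copies = c(2, 4)))
  copies <- copy_number_table(data.frame(
    taxon = c("Rothia amarae", "Finegoldia magna"),
    rank = "species", copies = c(2, 4)))
  ab <- estimate_absolute_abundance(tab, extract_spike_counts(tab, spec),
                                    copies, spec)
  expect_equal(unclass(ab)[spec$name_ih, "S1"], 500, tolerance = 1e-12)
  expect_equal(unclass(ab)[spec$name_ah, "S1"], 500, tolerance = 1e-12)
  # and any other taxon is recovered exactly under ideal proportionality
  expect_equal(unclass(ab)["Rothia amarae", "S1"], 40, tolerance = 1e-12)
  expect_equal(unclass(ab)["Finegoldia magna", "S1"], 250,
               tolerance = 1e-12)
  # calibrator rows stay out of biological outputs
  expect_false(any(rownames(biological_abundance(ab)) %in%
                   c(spec$name_ih, spec$name_ah)))
})
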