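test_that("sporadic-enrichment screen applies both thresholds with vacuous zero background", {
  sheet <- make_sheet(2, 1)
  m <- rbind(
    hit_zero_bg   = c(25, 0, 1, 0, 0),   # pulp max 25 >= 20, bg max 1 -> 25 >= 20*1
    low_pulp      = c(19, 0, 0, 0, 0),   # fails the cell threshold, bg 0
    low_fold      = c(25, 0, 2, 0, 0),   # 25 < 20*2 -> fails the fold
    absent        = c(0, 0, 0, 0, 0),
    big_hit       = c(100, 40, 0, 0, 0)) # bg 0 -> fold vacuously satisfied
  colnames(m) <- sheet$sample_id
  hits <- sporadic_enrichment_screen(fake_ab(m), sheet)
  expect_equal(hits$taxon, c("big_hit", "hit_zero_bg"))  # sorted desc
  expect_equal(hits$fold, c(Inf, 25))
  expect_equal(hits$max_background_ab, c(0, 1))
  # per-sample abundances are carried along
  expect_equal(hits[hits$taxon == "big_hit", sheet$sample_id[1]], 100)

  no_pulp <- sample_sheet(data.frame(sample_id = colnames(m),
                                     patient_id = NA,
                                     sample_type = "control"))
  expect_error(sporadic_enrichment_screen(fake_ab(m), no_pulp), "pulp")
})

test_that("raising either screen threshold never adds a hit", {
  sheet <- make_sheet(3, 2)
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rexp(8 * 8, rate = 1 / 30), 8, 8)
    dimnames(m) <- list(paste0("t", 1:8), sheet$sample_id)
    base <- sporadic_enrichment_screen(fake_ab(m), sheet, 10, 5)$taxon
    stricter_cells <- sporadic_enrichment_screen(fake_ab(m), sheet,
                                                 30, 5)$taxon
    stricter_fold <- sporadic_enrichment_screen(fake_ab(m), sheet,
                                                10, 20)$taxon
    expect_true(all(stricter_cells %in% base))
    expect_true(all(stricter_fold %in% base))
  }
})

test_that("signed-rank test matches known small cases and symmetries", {
  # 5 pairs, all differences positive, no ties: p = 2/2^5
  x <- c(5, 6, 7, 8, 9); y <- c(1, 2, 3, 4, 4.5)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$method, "exact")

  # identical vectors carry no information
  expect_equal(wilcoxon_signed_rank(x, x)$p_value, 1)

  # swapping x and y preserves p and reflects W to m(m+1)/2 - W
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    f <- wilcoxon_signed_rank(a, b); g <- wilcoxon_signed_rank(b, a)
    expect_equal(f$p_value, g$p_value)
    m <- f$n_used
    expect_equal(g$statistic, m * (m + 1) / 2 - f$statistic)
  }

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("signed-rank p agrees with enumeration and with wilcox.test where comparable", {
  set.seed(13)
  for (i in 1:40) {
    m <- sample(2:10, 1)
    x <- sample(0:6, m, replace = TRUE)      # many ties and zeros
    y <- sample(0:6, m, replace = TRUE)
    for (zp in c("discard", "pratt")) {
      ours <- wilcoxon_signed_rank(x, y, zero_policy = zp)
      oracle <- brute_signed_rank(x, y, zero_policy = zp)
      expect_equal(ours$statistic, oracle$W)
      expect_equal(ours$p_value, oracle$p)
    }
  }
  # tie-free, zero-free instances match stats::wilcox.test exactly
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  # large-m normal path matches the reference approximation
  set.seed(15)
  x <- rnorm(40, 0.3); y <- rnorm(40)
  ours <- wilcoxon_signed_rank(x, y, exact_limit = 25)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "normal")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg q-values follow the step-up rule", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)),
               c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, NA)), "missing")

  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm])
    # monotone in p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("paired differential testing matches exact enumeration on a planted taxon", {
  sheet <- make_sheet(10, 3, control_patients = TRUE)
  m <- matrix(0, 3, nrow(sheet),
              dimnames = list(c("planted", "shared", "flat"),
                              sheet$sample_id))
  pulp_cols <- sheet$sample_id[sheet$sample_type == "pulp"]
  m["planted", pulp_cols] <- 50 + seq_along(pulp_cols)
  m["shared", ] <- 30                      # constant everywhere
  res <- paired_differential(fake_ab(m), sheet)

  pvd <- res[res$comparison == "pulp_vs_dentin", ]
  expect_equal(pvd$n_pairs, rep(10L, nrow(pvd)))
  # all 10 differences positive -> exact two-sided p = 2/2^10
  expect_equal(pvd$p_value[pvd$taxon == "planted"], 2 / 2^10)
  # constant taxon: all differences zero -> p = 1
  expect_equal(pvd$p_value[pvd$taxon == "shared"], 1)
  # all-zero taxon is uninformative and not reported
  expect_false("flat" %in% res$taxon)
  # group summaries of a constant column collapse to that constant
  sh <- pvd[pvd$taxon == "shared", ]
  expect_equal(unlist(sh[paste0("pulp_", c("median", "min", "q1", "q3",
                                           "max"))], use.names = FALSE),
               rep(30, 5))
  # q-values never undercut p-values, BH applied per comparison family
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
  pvc <- res[res$comparison == "pulp_vs_control", ]
  expect_equal(pvc$n_pairs, rep(3L, nrow(pvc)))
  expect_equal(pvc$q_value, bh_oracle(pvc$p_value))
})

test_that("comparisons with fewer than two complete pairs are flagged untestable", {
  sheet <- make_sheet(2, 2)                # controls have no patient ids
  m <- matrix(c(25, 10, 1, 2, 0, 0), 1, 6,
              dimnames = list("t1", sheet$sample_id))
  res <- paired_differential(fake_ab(m), sheet)
  pvc <- res[res$comparison == "pulp_vs_control", ]
  expect_true(all(pvc$untestable))
  expect_true(all(is.na(pvc$p_value)))
  expect_equal(pvc$n_pairs, rep(0L, nrow(pvc)))
})
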