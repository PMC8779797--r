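rec_for <- function(acc, gt1, gt2, loci = btr_loci()) {
  data.frame(accession = acc,
             chrom = loci$chrom, pos = loci$pos,
             ref = loci$ref, alt = loci$alt,
             gt = c(gt1, gt2), stringsAsFactors = FALSE)
}

test_that("Btr classification reads the diagnostic deletions", {
  v <- rbind(rec_for("a1", 1, 0),   # 1-bp deletion only
             rec_for("a2", 0, 0),   # wild type at both
             rec_for("a3", 0, 1),   # 11-bp deletion only
             rec_for("a4", 1, 1))
  cls <- classify_btr(v)
  expect_equal(cls$genotype,
               c("btr1Btr2", "Btr1Btr2", "Btr1btr2", "btr1btr2"))

  # locus without a covering record is unknown
  v5 <- rec_for("a5", 0, 0)[1, ]
  cls5 <- classify_btr(v5)
  expect_equal(cls5$btr1_allele, "Btr1")
  expect_equal(cls5$btr2_allele, "unknown")
  expect_equal(cls5$genotype, "unknown")

  # conflicting calls collapse to unknown with a warning
  v6 <- rbind(rec_for("a6", 1, 0), rec_for("a6", 0, 0))
  expect_warning(cls6 <- classify_btr(v6), "conflicting")
  expect_equal(cls6$btr1_allele, "unknown")
})

test_that("Btr classification is idempotent and order-independent", {
  v <- rbind(rec_for("a1", 1, 0), rec_for("a2", 0, 1))
  c1 <- classify_btr(v)
  c2 <- classify_btr(v[rev(seq_len(nrow(v))), ])
  expect_equal(c1$genotype[order(c1$accession)],
               c2$genotype[order(c2$accession)])
  # duplicated consistent records do not change the call
  c3 <- classify_btr(rbind(v, v))
  expect_equal(c3$genotype[order(c3$accession)],
               c1$genotype[order(c1$accession)])
})

test_that("classification round-trips the simulator's genotype plans", {
  cfg <- simulation_config(seed = 2)
  gr <- simulate_group_assignment(cfg)
  # mixed plan mirroring the canonical group pattern: wild all Btr1Btr2,
  # intermediate group mixed, cultivated carrying one deletion each
  plan <- data.frame(
    accession = gr$accession,
    genotype = c(rep("Btr1Btr2", 7),
                 rep(c("btr1Btr2", "Btr1btr2", "Btr1Btr2"), each = 3),
                 rep(c("btr1Btr2", "Btr1btr2"), length.out = 9)),
    stringsAsFactors = FALSE
  )
  rec <- simulate_btr_locus(cfg, plan)
  cls <- classify_btr(rec)
  expect_equal(cls$genotype[match(plan$accession, cls$accession)],
               plan$genotype)
})

test_that("haplotype grouping enumerates and labels haplotypes by frequency", {
  # 4 biallelic sites -> 16 possible haplotypes
  set.seed(81)
  calls <- rbind(
    matrix(rep(c(1, 1, 1, 1), 5), nrow = 5, byrow = TRUE),
    matrix(rep(c(2, 2, 1, 1), 3), nrow = 3, byrow = TRUE),
    matrix(rep(c(2, 2, 2, 2), 1), nrow = 1, byrow = TRUE)
  )
  g <- make_geno(calls, pos = c(10, 20, 30, 40))
  gr <- make_groups(g, c(5, 4))
  h <- haplotype_group(g, gr, "1H", c(10, 20, 30, 40))
  expect_equal(h$n_possible, 16)
  expect_equal(sum(h$table$observed), 3)
  expect_equal(h$table$haplotype[h$table$label == "hap1"], "AAAA")
  expect_equal(h$table$total[h$table$label == "hap1"], 5L)
  expect_equal(h$table$haplotype[h$table$label == "hap2"], "TTAA")
  expect_true(all(h$assignment$label[1:5] == "hap1"))

  # all accessions identical: one observed haplotype
  g1 <- make_geno(matrix(1L, nrow = 4, ncol = 3), pos = c(5, 6, 7))
  h1 <- haplotype_group(g1, make_groups(g1, 4), "1H", c(5, 6, 7))
  expect_equal(sum(h1$table$observed), 1)

  expect_error(haplotype_group(g1, make_groups(g1, 4), "1H", 99),
               "absent")
  expect_error(haplotype_group(g1, make_groups(g1, 4), "1H", c(5, 6),
                               gene_start = 0, gene_end = 5),
               "within the gene interval")

  # random matrices: per-haplotype counts match direct string grouping
  for (k in 1:10) {
    ck <- matrix(sample(1:2, 6 * 3, replace = TRUE), nrow = 6)
    gk <- make_geno(ck, pos = c(1, 2, 3))
    hk <- haplotype_group(gk, make_groups(gk, 6), "1H", 1:3)
    strings <- apply(ck, 1, function(r) paste(c("A", "T")[r], collapse = ""))
    orc <- hap_oracle(strings)
    got <- hk$table$total[hk$table$observed]
    names(got) <- hk$table$haplotype[hk$table$observed]
    expect_equal(sort(got), sort(as.integer(orc)), ignore_attr = TRUE)
    expect_equal(got[names(orc)[1]], max(orc), ignore_attr = TRUE)
    expect_lte(sum(hk$table$observed), min(6, hk$n_possible))
  }
})

test_that("haplotype-content comparison reproduces Welch's t-test", {
  acc <- sprintf("a%d", 1:8)
  gr2 <- c("X", "Y")

  # identical samples both sides
  v0 <- matrix(5, nrow = 8, ncol = 1, dimnames = list(acc, "m1"))
  m0 <- log2_transform(make_metab(v0))
  r0 <- compare_haplotype_content(m0, acc[1:4], acc[5:8], "m1")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$direction, "equal")

  # clear separation with tiny jitter
  set.seed(91)
  v1 <- matrix(c(rnorm(4, 0, 1e-3), rnorm(4, 5, 1e-3)), ncol = 1,
               dimnames = list(acc, "m1"))
  m1 <- log2_transform(make_metab(v1))
  r1 <- compare_haplotype_content(m1, acc[1:4], acc[5:8], "m1")
  expect_lt(r1$p, 1e-4)
  expect_equal(r1$direction, "B > A")

  # random instances vs the textbook computation; antisymmetry of t
  for (k in 1:10) {
    y <- rnorm(8)
    vk <- matrix(y, ncol = 1, dimnames = list(acc, "m1"))
    mk <- log2_transform(make_metab(vk))
    rk <- compare_haplotype_content(mk, acc[1:4], acc[5:8], "m1")
    orc <- welch_oracle(y[1:4], y[5:8])
    expect_equal(rk$t, orc$t)
    expect_equal(rk$p, orc$p)
    flip <- compare_haplotype_content(mk, acc[5:8], acc[1:4], "m1")
    expect_equal(flip$t, -rk$t)
  }
})

test_that("fingerprint novelty counts panel-discriminating sites", {
  # panels fixed for different alleles at 4 of 5 sites; site 5 uninformative
  calls <- rbind(
    matrix(1L, nrow = 3, ncol = 5),            # panel A
    cbind(matrix(2L, nrow = 3, ncol = 4), 1L), # panel B
    c(2L, 2L, 2L, 2L, 1L)                      # probe matches B
  )
  g <- make_geno(calls, pos = 1:5)
  nov <- haplotype_novelty(g, g$accession_ids[7],
                           panel_a = g$accession_ids[1:3],
                           panel_b = g$accession_ids[4:6])
  expect_equal(nov$n_informative, 4)
  expect_equal(nov$n_match_b_not_a, 4)
  expect_equal(nov$n_match_a_not_b, 0)
})
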