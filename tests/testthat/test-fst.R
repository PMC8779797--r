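test_that("per-SNP AMOVA Fst handles fixed and undifferentiated sites", {
  # fixed difference: all within-group pairs identical
  g <- make_geno(matrix(c(rep(1, 4), rep(2, 4)), ncol = 1))
  gr <- make_groups(g, c(4, 4))
  f <- fst_amova_per_snp(g, gr, c("G1", "G2"))
  expect_equal(f$fst, 1)

  # identical allele frequencies and counts in both groups
  g2 <- make_geno(matrix(c(1, 1, 2, 2, 1, 1, 2, 2), ncol = 1))
  f2 <- fst_amova_per_snp(g2, make_groups(g2, c(4, 4)), c("G1", "G2"))
  expect_equal(f2$fst, 0)

  # monomorphic sites are excluded before computation
  g3 <- make_geno(cbind(c(1, 1, 2, 2), rep(1L, 4)))
  f3 <- fst_amova_per_snp(g3, make_groups(g3, c(2, 2)), c("G1", "G2"))
  expect_equal(f3$site, 1L)
  g4 <- make_geno(matrix(1L, nrow = 4, ncol = 2))
  expect_error(fst_amova_per_snp(g4, make_groups(g4, c(2, 2)), c("G1", "G2")),
               "monomorphic")
})

test_that("per-SNP Fst equals the mismatch-matrix AMOVA oracle", {
  # the spec's worked case: n = 4 + 4, alt frequencies 3/4 vs 1/4
  a1 <- c(2, 2, 2, 1); a2 <- c(2, 1, 1, 1)
  g <- make_geno(matrix(c(a1, a2), ncol = 1))
  f <- fst_amova_per_snp(g, make_groups(g, c(4, 4)), c("G1", "G2"))
  orc <- amova_oracle(a1, a2)
  expect_equal(f$fst, orc$fst)
  expect_equal(f$sigma_b2, orc$sigma_b2)
  expect_equal(f$sigma_t2, orc$sigma_t2)

  set.seed(5)
  for (k in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x1 <- sample(1:3, n1, replace = TRUE)
    x2 <- sample(1:3, n2, replace = TRUE)
    if (length(unique(c(x1, x2))) < 2) next
    gk <- make_geno(matrix(c(x1, x2), ncol = 1),
                    alleles = list(c("A", "T", "G")))
    fk <- fst_amova_per_snp(gk, make_groups(gk, c(n1, n2)), c("G1", "G2"))
    expect_equal(fk$fst, amova_oracle(x1, x2)$fst)
  }
})

test_that("Fst is invariant to accession ordering and allele relabeling", {
  set.seed(9)
  calls <- matrix(sample(1:2, 10 * 20, replace = TRUE), nrow = 10)
  g <- make_geno(calls)
  gr <- make_groups(g, c(5, 5))
  f <- fst_amova_per_snp(g, gr, c("G1", "G2"))

  perm <- sample(10)
  gp <- genotype_matrix(calls[perm, ], g$sites, g$accession_ids[perm])
  fp <- fst_amova_per_snp(gp, gr, c("G1", "G2"))
  expect_equal(fp$fst, f$fst)

  # swap allele codes 1 <-> 2 at every site
  gs <- make_geno(3L - calls)
  fs <- fst_amova_per_snp(gs, gr, c("G1", "G2"))
  expect_equal(fs$fst, f$fst)
})

test_that("permutation p-values follow the add-one rule and enumeration", {
  g <- make_geno(matrix(c(rep(1, 4), rep(2, 4)), ncol = 1))
  gr <- make_groups(g, c(4, 4))
  r1 <- permutation_outlier_test(g, gr, c("G1", "G2"), n_perm = 1, seed = 1)
  expect_true(r1$perm_p %in% c(0.5, 1.0))

  # exhaustive enumeration: groups of 7 and 9 fixed for different alleles;
  # only one of the C(16,7) = 11440 label subsets reproduces Fst = 1
  gf <- make_geno(matrix(c(rep(1, 7), rep(2, 9)), ncol = 1))
  grf <- make_groups(gf, c(7, 9))
  sets <- utils::combn(16, 7, simplify = FALSE)
  rf <- permutation_outlier_test(gf, grf, c("G1", "G2"), perm_sets = sets)
  expect_equal(rf$perm_p, (1 + 1) / (length(sets) + 1))
  expect_false(rf$neutral)
  expect_equal(attr(rf, "cutoff"), 1)
})

test_that("permutation Fst matches the observed-statistic code path", {
  # identical labels must give perm Fst == observed Fst, hence p = 1
  set.seed(21)
  calls <- matrix(sample(1:2, 12 * 30, replace = TRUE), nrow = 12)
  g <- make_geno(calls)
  gr <- make_groups(g, c(6, 6))
  ident <- list(1:6)
  r <- permutation_outlier_test(g, gr, c("G1", "G2"), perm_sets = ident)
  expect_true(all(r$perm_p == 1))
})

test_that("windowed Fst averages member SNPs and omits empty windows", {
  rec <- data.frame(chrom = "1H", pos = c(10, 20), fst = c(0.2, 0.4))
  w <- windowed_fst(rec, window_bp = 100, step_bp = 100)
  expect_equal(nrow(w), 1)
  expect_equal(w$mean_fst, 0.3)

  # SNPs only in the first and third windows of the grid: middle omitted
  rec2 <- data.frame(chrom = "1H", pos = c(10, 250), fst = c(0.2, 0.6))
  w2 <- windowed_fst(rec2, window_bp = 100, step_bp = 100, chrom_lengths = c("1H" = 300))
  expect_equal(w2$start, c(0, 200))

  set.seed(3)
  pos <- sort(sample.int(2000, 120))
  fst <- runif(120)
  rec3 <- data.frame(chrom = "1H", pos = pos, fst = fst)
  w3 <- windowed_fst(rec3, window_bp = 300, step_bp = 150)
  orc <- window_mean_oracle(pos, fst, 300, 150)
  expect_equal(w3$start, orc$start)
  expect_equal(w3$mean_fst, orc$mean_fst)
  expect_equal(w3$n_snps, orc$n_snps)
  expect_error(windowed_fst(rec3, window_bp = 0), "must be > 0")
})

test_that("sweep flagging uses the interpolated top quantile with >=", {
  w <- data.frame(chrom = "1H", start = seq(0, 1900, 100),
                  end = seq(100, 2000, 100),
                  n_snps = 5, mean_fst = seq(0.01, 0.20, 0.01))
  s <- sweep_regions(w, 0.95)
  expect_equal(attr(s, "threshold"),
               as.numeric(quantile(w$mean_fst, 0.95)))
  expect_equal(which(s$is_sweep), 20L)

  weq <- data.frame(chrom = "1H", start = 0:3 * 100, end = 1:4 * 100,
                    n_snps = 2, mean_fst = rep(0.3, 4))
  expect_true(all(sweep_regions(weq)$is_sweep))
  w1 <- weq[1, ]
  expect_true(sweep_regions(w1)$is_sweep)
})

test_that("window-to-gene mapping agrees with all-pairs interval overlap", {
  ann <- data.frame(chrom = "1H", start = c(99, 399), end = c(200, 500),
                    strand = "+", gene_id = c("gene1", "gene2"))
  w <- data.frame(chrom = "1H", start = 150, end = 300)
  hit <- map_windows_to_genes(w, ann)
  expect_equal(hit$gene_id, "gene1")

  set.seed(13)
  for (k in 1:10) {
    ws <- sort(sample.int(1000, 6))
    gs <- sort(sample.int(1000, 6))
    wd <- data.frame(chrom = "1H", start = ws[c(1, 3, 5)], end = ws[c(2, 4, 6)])
    ad <- data.frame(chrom = "1H", start = gs[c(1, 3, 5)], end = gs[c(2, 4, 6)],
                     strand = "+", gene_id = paste0("g", 1:3))
    got <- map_windows_to_genes(wd, ad)
    want <- 0L
    for (i in 1:3) for (j in 1:3) {
      if (wd$start[i] < ad$end[j] && ad$start[j] < wd$end[i]) want <- want + 1L
    }
    expect_equal(nrow(got), want)
  }
})

test_that("GFF reading skips malformed records with a warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1H\tsrc\tgene\t100\t200\t.\t+\t.\tID=geneA",
    "1H\tsrc\tgene\tnotanumber\t300\t.\t+\t.\tID=geneBad",
    "1H\tsrc\tgene\t400\t350\t.\t-\t.\tID=geneInverted",
    "1H\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=tx1",
    "1H\tsrc\tgene\t500\t600\t.\t-\t.\tID=geneB;Name=b"
  ), gff)
  expect_warning(ann <- read_gene_annotation(gff), "2 malformed")
  expect_equal(ann$gene_id, c("geneA", "geneB"))
  # 1-based inclusive converted to 0-based half-open
  expect_equal(ann$start, c(99, 499))
  expect_equal(ann$end, c(200, 600))
})

test_that("multi-locus Fst tracks the island-model expectation", {
  cfg <- simulation_config(n_groups = 2, group_labels = c("A", "B"),
                           accessions_per_group = c(8, 8),
                           divergence_F = 0.2, n_snps = 4000,
                           n_chromosomes = 2, seed = 19)
  geno <- simulate_genotypes(cfg)
  gr <- attr(geno, "groups")
  f <- fst_amova_per_snp(geno, gr, c("A", "B"))
  expect_lt(abs(attr(f, "global_fst") - expected_amova_fst(0.2, 0.2, 8, 8)),
            0.02)
})
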