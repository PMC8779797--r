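#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study design the package targets: three groups of a
#' selfing crop along a domestication gradient -- wild ancestral (Wb-NE),
#' intermediate/feralized (Wb-T) and cultivated (Cb-C) -- with 7/9/9
#' accessions, SNPs drawn under a Balding-Nichols island model whose
#' per-group drift parameters produce pairwise differentiation near
#' Fst 0.14 (Wb-NE vs Wb-T) and 0.24 (Wb-T vs Cb-C) together with a
#' decreasing within-group diversity gradient, and metabolites measured in
#' three replicates per accession with known between/within-group variance
#' components.
#'
#' @param n_groups number of groups.
#' @param group_labels labels, length `n_groups`.
#' @param accessions_per_group integer vector (recycled) of accessions per
#'   group; each group needs at least 2.
#' @param n_snps total number of SNP sites.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length chromosome length in bp.
#' @param divergence_F per-group Balding-Nichols drift parameter in `[0, 1)`;
#'   scalar or length `n_groups`.
#' @param n_metabolites number of metabolites.
#' @param replicates_per_accession technical/biological replicates per
#'   accession (>= 2).
#' @param sigma_b2 between-group variance component of log2 abundance for
#'   divergent metabolites (scalar or per-metabolite after expansion).
#' @param sigma_w2 within-group (between-accession) variance component (> 0).
#' @param fraction_divergent proportion of metabolites with `sigma_b2 > 0`.
#' @param technical_var replicate-level noise variance; default 5% of
#'   `sigma_w2` (replicate noise is not separated from biological noise in
#'   typical metabolome designs, so it is kept small).
#' @param seed master random seed; all stages derive child seeds from it.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_groups = 3,
                              group_labels = c("Wb-NE", "Wb-T", "Cb-C"),
                              accessions_per_group = c(7, 9, 9),
                              n_snps = 5000,
                              n_chromosomes = 7,
                              chromosome_length = 5e6,
                              divergence_F = c(0.10, 0.18, 0.30),
                              n_metabolites = 500,
                              replicates_per_accession = 3,
                              sigma_b2 = 2,
                              sigma_w2 = 1,
                              fraction_divergent = 0.3,
                              technical_var = NULL,
                              seed = 1) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    group_labels = rep_len(as.character(group_labels), n_groups),
    accessions_per_group = rep_len(as.integer(accessions_per_group), n_groups),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    divergence_F = rep_len(as.numeric(divergence_F), n_groups),
    n_metabolites = as.integer(n_metabolites),
    replicates_per_accession = as.integer(replicates_per_accession),
    sigma_b2 = as.numeric(sigma_b2),
    sigma_w2 = as.numeric(sigma_w2),
    fraction_divergent = as.numeric(fraction_divergent),
    technical_var = if (is.null(technical_var)) 0.05 * as.numeric(sigma_w2)[1]
                    else as.numeric(technical_var),
    seed = as.integer(seed)
  )
  if (cfg$n_snps < 1) stop("n_snps must be >= 1")
  if (any(cfg$accessions_per_group < 2)) {
    stop("each group needs at least 2 accessions")
  }
  if (any(cfg$divergence_F < 0 | cfg$divergence_F >= 1)) {
    stop("divergence_F must lie in [0, 1)")
  }
  if (any(cfg$sigma_b2 < 0)) stop("sigma_b2 must be >= 0")
  if (any(cfg$sigma_w2 <= 0)) stop("sigma_w2 must be > 0")
  if (cfg$replicates_per_accession < 2) {
    stop("replicates_per_accession must be >= 2")
  }
  if (cfg$fraction_divergent < 0 || cfg$fraction_divergent > 1) {
    stop("fraction_divergent must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Group assignment implied by a simulation configuration
#'
#' @param config a [simulation_config()].
#' @return data.frame as from [group_assignment()], with accession ids of the
#'   form `<group>_01`, `<group>_02`, ...
#' @export
simulate_group_assignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tag <- gsub("[^A-Za-z0-9]", "", config$group_labels)
  acc <- unlist(mapply(function(t, n) sprintf("%s_%02d", t, seq_len(n)),
                       tag, config$accessions_per_group, SIMPLIFY = FALSE))
  group_assignment(acc, rep(config$group_labels, config$accessions_per_group))
}

#' Simulate haploid SNP genotypes under a Balding-Nichols island model
#'
#' For each SNP an ancestral allele frequency `p` is drawn uniformly on
#' `[0.05, 0.95]` (avoiding monomorphic draws, as in post-filter SNP panels);
#' each group's frequency is drawn `Beta(p(1-F)/F, (1-p)(1-F)/F)` with the
#' group's drift parameter `F` (frequency equals `p` exactly when `F = 0`);
#' accession alleles are sampled Bernoulli. Positions are drawn uniformly
#' without replacement per chromosome and sorted; there are no missing
#' genotypes.
#'
#' @param config a [simulation_config()].
#' @param groups optional group assignment (defaults to
#'   [simulate_group_assignment()]).
#' @return a [genotype_matrix()] with attributes `groups` (the assignment)
#'   and `truth` (data.frame of per-site ancestral and per-group allele
#'   frequencies).
#' @export
simulate_genotypes <- function(config, groups = simulate_group_assignment(config)) {
  stopifnot(inherits(config, "sim_config"))
  seed <- fan_seeds(config$seed, 4)[1]
  withr::with_seed(seed, {
    per_chrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chromosomes + 1)))
    chroms <- sprintf("%dH", seq_len(config$n_chromosomes))
    sites <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(k) {
      n <- per_chrom[k]
      if (n == 0) return(NULL)
      data.frame(chrom = chroms[k],
                 pos = sort(sample.int(config$chromosome_length, n)),
                 stringsAsFactors = FALSE)
    }))
    s <- nrow(sites)
    # random REF/ALT nucleotides, distinct per site
    nucs <- c("A", "C", "G", "T")
    ref <- sample(nucs, s, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
    sites$alleles <- mapply(c, ref, alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)

    p <- stats::runif(s, 0.05, 0.95)
    n_acc <- sum(config$accessions_per_group)
    calls <- matrix(1L, nrow = n_acc, ncol = s)
    freq <- matrix(NA_real_, nrow = config$n_groups, ncol = s)
    row0 <- cumsum(c(0, config$accessions_per_group))
    for (g in seq_len(config$n_groups)) {
      f <- config$divergence_F[g]
      fg <- if (f == 0) p else
        stats::rbeta(s, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      freq[g, ] <- fg
      ng <- config$accessions_per_group[g]
      alt_draw <- matrix(stats::rbinom(ng * s, 1L, rep(fg, each = ng)),
                         nrow = ng)
      calls[(row0[g] + 1):row0[g + 1], ] <- 1L + alt_draw
    }
    geno <- genotype_matrix(calls, sites, groups$accession)
    attr(geno, "groups") <- groups
    truth <- data.frame(chrom = sites$chrom, pos = sites$pos, p_ancestral = p)
    fr <- as.data.frame(t(freq))
    names(fr) <- paste0("freq_", gsub("[^A-Za-z0-9]", "", config$group_labels))
    attr(geno, "truth") <- cbind(truth, fr)
    geno
  })
}

#' Closed-form AMOVA Fst expectation under the Balding-Nichols model
#'
#' Ratio of expected among-group to expected total variance components for a
#' pair of groups with drift parameters `F1`, `F2` and sample sizes
#' `n1`, `n2` (the ancestral-frequency factor `p(1-p)` cancels). Used to
#' calibrate the generator and as an analytical oracle for the per-SNP
#' estimator.
#'
#' @param F1,F2 per-group drift parameters.
#' @param n1,n2 haploid sample sizes.
#' @return expected Fst (ratio of expectations).
#' @export
expected_amova_fst <- function(F1, F2, n1, n2) {
  N <- n1 + n2
  n0 <- (N - (n1^2 + n2^2) / N)
  ssd_w <- (n1 - 1) * (1 - F1) + (n2 - 1) * (1 - F2)
  ssd_t <- (choose2(n1) * 2 * (1 - F1) + choose2(n2) * 2 * (1 - F2) +
              2 * n1 * n2) / N
  ms_w <- ssd_w / (N - 2)
  ms_b <- ssd_t - ssd_w  # df = 1 for two groups
  sb <- (ms_b - ms_w) / n0
  sb / (sb + ms_w)
}

#' Simulate replicated metabolite abundances with known variance components
#'
#' Each metabolite `m` gets a baseline log2 abundance, a group effect and
#' accession-level noise `Normal(0, sigma_w2)`; replicates add a small
#' technical noise. Group effects are drawn Gaussian and then standardized so
#' that the realized between-group variance component equals `sigma_b2`
#' exactly, making the recorded true Qst
#' `sigma_b2 / (sigma_b2 + 2 sigma_w2)` exact for every metabolite rather
#' than an average over group-effect draws (with only 2-3 groups, raw random
#' effects would make the realized component extremely noisy).
#'
#' The first `round(fraction_divergent * n_metabolites)` metabolites are the
#' divergent ones (`sigma_b2 > 0`); the remainder have `sigma_b2 = 0`.
#'
#' @param config a [simulation_config()].
#' @param groups group assignment consistent with `config`.
#' @return a [metabolite_matrix()] on the raw (positive abundance) scale with
#'   the ground truth (per-metabolite `sigma_b2`, `sigma_w2`, `true_qst`,
#'   `divergent`) stored in its `truth` field.
#' @export
simulate_metabolites <- function(config, groups = simulate_group_assignment(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$sigma_w2 <= 0)) stop("sigma_w2 must be > 0")
  seed <- fan_seeds(config$seed, 4)[2]
  M <- config$n_metabolites
  n_div <- round(config$fraction_divergent * M)
  sb2 <- rep_len(config$sigma_b2, M)
  sb2[seq_len(M) > n_div] <- 0
  sw2 <- rep_len(config$sigma_w2, M)
  glabs <- unique(groups$group)
  g_of_acc <- match(groups$group, glabs)
  n_g <- tabulate(g_of_acc, length(glabs))
  n_acc <- nrow(groups)
  reps <- config$replicates_per_accession

  withr::with_seed(seed, {
    mu <- stats::rnorm(M, 10, 1)
    # group effects standardized to the exact between-group component:
    # the AMOVA/expected-mean-squares estimand for fixed group effects a_g is
    # sum n_g (a_g - a_bar_w)^2 / ((G - 1) n0); scale draws so it equals sb2
    G <- length(glabs)
    N <- sum(n_g)
    n0 <- (N - sum(n_g^2) / N) / (G - 1)
    alpha <- matrix(0, nrow = G, ncol = M)
    for (m in seq_len(M)) {
      if (sb2[m] == 0) next
      repeat {
        z <- stats::rnorm(G)
        zc <- z - sum(n_g * z) / N
        comp <- sum(n_g * zc^2) / ((G - 1) * n0)
        if (comp > 0) break
      }
      alpha[, m] <- zc * sqrt(sb2[m] / comp)
    }
    acc_val <- matrix(
      rep(mu, each = n_acc) +
        alpha[cbind(rep(g_of_acc, M), rep(seq_len(M), each = n_acc))] +
        stats::rnorm(n_acc * M, 0, rep(sqrt(sw2), each = n_acc)),
      nrow = n_acc, ncol = M)
    tech <- sqrt(config$technical_var)
    acc_idx <- rep(rep(seq_len(n_acc), reps), M)
    met_idx <- rep(seq_len(M), each = n_acc * reps)
    long <- data.frame(
      accession = groups$accession[acc_idx],
      replicate = rep(rep(seq_len(reps), each = n_acc), times = M),
      metabolite = sprintf("met_%04d", met_idx),
      stringsAsFactors = FALSE
    )
    log2val <- acc_val[cbind(acc_idx, met_idx)] +
      stats::rnorm(nrow(long), 0, tech)
    long$abundance <- 2^log2val
    truth <- data.frame(
      metabolite = sprintf("met_%04d", seq_len(M)),
      sigma_b2 = sb2, sigma_w2 = sw2,
      true_qst = ifelse(sb2 + sw2 == 0, NA_real_, sb2 / (sb2 + 2 * sw2)),
      divergent = sb2 > 0,
      stringsAsFactors = FALSE
    )
    metabolite_matrix(long, log2 = FALSE, truth = truth)
  })
}

#' Default diagnostic variant definitions for the Btr1/Btr2 loci
#'
#' The non-brittle (domesticated) alleles differ from the wild alleles by a
#' 1-bp deletion (REF `GC`, ALT `G`) at the Btr1 locus and an 11-bp deletion
#' (REF `GGCAACGTCTTC`, ALT `G`) at the Btr2 locus. Genomic coordinates are
#' configuration inputs; the defaults place both loci on chromosome 3H.
#'
#' @param chrom chromosome name.
#' @param pos_btr1,pos_btr2 1-based positions of the two diagnostic indels.
#' @return data.frame with columns `locus`, `chrom`, `pos`, `ref`, `alt`.
#' @export
btr_loci <- function(chrom = "3H", pos_btr1 = 1000000L, pos_btr2 = 2000000L) {
  data.frame(
    locus = c("Btr1", "Btr2"),
    chrom = chrom,
    pos = as.integer(c(pos_btr1, pos_btr2)),
    ref = c("GC", "GGCAACGTCTTC"),
    alt = c("G", "G"),
    stringsAsFactors = FALSE
  )
}

#' Plant Btr1/Btr2 deletion genotypes according to a per-accession plan
#'
#' Emits VCF-style records at the two diagnostic indel positions: accessions
#' whose plan carries a lowercase allele (`btr1` and/or `btr2`) receive the
#' corresponding deletion call.
#'
#' @param config a [simulation_config()] (only used for validation/seeding
#'   symmetry; records are deterministic given the plan).
#' @param plan data.frame with columns `accession` and `genotype`, the latter
#'   one of `"Btr1Btr2"`, `"btr1Btr2"`, `"Btr1btr2"`, `"btr1btr2"`.
#' @param loci diagnostic locus table, default [btr_loci()].
#' @return data.frame of per-accession variant records (columns `accession`,
#'   `chrom`, `pos`, `ref`, `alt`, `gt`) suitable for [classify_btr()].
#' @export
simulate_btr_locus <- function(config, plan, loci = btr_loci()) {
  stopifnot(inherits(config, "sim_config"),
            all(c("accession", "genotype") %in% names(plan)))
  valid <- c("Btr1Btr2", "btr1Btr2", "Btr1btr2", "btr1btr2")
  bad <- setdiff(plan$genotype, valid)
  if (length(bad)) stop("unknown Btr genotype label(s): ",
                        paste(unique(bad), collapse = ", "))
  has_btr1 <- grepl("^btr1", plan$genotype)
  has_btr2 <- grepl("btr2$", plan$genotype)
  rec <- function(i, del) {
    data.frame(accession = plan$accession,
               chrom = loci$chrom[i], pos = loci$pos[i],
               ref = loci$ref[i], alt = loci$alt[i],
               gt = as.integer(del), stringsAsFactors = FALSE)
  }
  rbind(rec(1, has_btr1), rec(2, has_btr2))
}

#' Copy one group's gene-pool consensus into another over an interval
#'
#' Used to plant a region of perfect genomic similarity: within the 0-based
#' half-open interval `[start, end)` on `chrom`, every accession of
#' `to_group` is set to the majority allele of `from_group` (ties resolved to
#' the lowest allele index), so the two groups' pool consensus sequences
#' become identical there.
#'
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param from_group,to_group group labels.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval bounds in bp.
#' @return the modified `geno_matrix`.
#' @export
plant_similar_region <- function(geno, groups, from_group, to_group,
                                 chrom, start, end) {
  in_iv <- geno$sites$chrom == chrom &
    (geno$sites$pos - 1) >= start & (geno$sites$pos - 1) < end
  rows_from <- group_rows(geno, groups, from_group)
  rows_to <- group_rows(geno, groups, to_group)
  for (j in which(in_iv)) {
    tab <- tabulate(geno$calls[rows_from, j],
                    nbins = length(geno$sites$alleles[[j]]))
    geno$calls[rows_to, j] <- which.max(tab)
  }
  geno
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Genotypes as VCF v4.2 (haploid GT), groups and replicate-level metabolite
#' abundances as TSV, and the metabolite ground truth as a sidecar TSV.
#'
#' @param dir output directory (created if needed).
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param metab optional [metabolite_matrix()].
#' @param btr_records optional long-format Btr variant records from
#'   [simulate_btr_locus()]; written into the VCF as indel records.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(dir, geno, groups, metab = NULL, btr_records = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             groups = file.path(dir, "groups.tsv"))
  extra <- NULL
  if (!is.null(btr_records)) {
    extra <- do.call(rbind, lapply(
      split(btr_records, paste(btr_records$chrom, btr_records$pos)),
      function(d) {
        wide <- data.frame(chrom = d$chrom[1], pos = d$pos[1],
                           ref = d$ref[1], alt = d$alt[1],
                           stringsAsFactors = FALSE)
        for (i in seq_len(nrow(d))) wide[[d$accession[i]]] <- d$gt[i]
        wide
      }))
  }
  write_vcf_genotypes(geno, paths["vcf"], extra_records = extra)
  utils::write.table(groups, paths["groups"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(metab)) {
    paths["metabolites"] <- file.path(dir, "metabolites.tsv")
    utils::write.table(metab$data, paths["metabolites"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(metab$truth)) {
      paths["metabolite_truth"] <- file.path(dir, "metabolite_truth.tsv")
      utils::write.table(metab$truth, paths["metabolite_truth"], sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  invisible(paths)
}
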