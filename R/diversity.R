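#' Nucleotide diversity of a group over the analysed SNP sites
#'
#' Mean pairwise difference per analysed site among the group's haploid
#' sequences: `pi = sum_{i<j} d_ij / (C(n,2) * L)` over the `L` sites of the
#' matrix. Normalization is per analysed SNP site (not genome length) because
#' a filtered SNP panel carries no invariant-site information.
#'
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param group group label (>= 2 accessions).
#' @return scalar pi; the per-site values are attached as attribute
#'   `per_site`.
#' @export
nucleotide_diversity <- function(geno, groups, group) {
  rows <- group_rows(geno, groups, group)
  n <- length(rows)
  if (n < 2) stop("group '", group, "' has fewer than 2 accessions")
  counts <- site_allele_counts(geno, rows)
  mism <- choose2(n) - colSums(choose2(counts))
  per_site <- mism / choose2(n)
  structure(mean(per_site), per_site = per_site)
}

#' Watterson's estimator of a group over the analysed SNP sites
#'
#' `theta_W = S / (a_n * L)` with `S` the number of sites segregating within
#' the group, `a_n = sum_{i=1}^{n-1} 1/i` the harmonic number for `n`
#' sequences, and `L` the number of analysed sites.
#'
#' @inheritParams nucleotide_diversity
#' @return scalar theta_W per analysed site.
#' @export
watterson_theta <- function(geno, groups, group) {
  rows <- group_rows(geno, groups, group)
  n <- length(rows)
  if (n < 2) stop("group '", group, "' has fewer than 2 accessions")
  counts <- site_allele_counts(geno, rows)
  S <- sum(colSums(counts > 0) >= 2)
  a_n <- sum(1 / seq_len(n - 1))
  S / (a_n * nrow(geno$sites))
}

#' Polymorphism information content from allele frequencies
#'
#' `PIC = 1 - sum_i p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`, where `p_i` are the
#' allele frequencies at a locus.
#'
#' @param freqs numeric vector of allele frequencies (non-negative, summing
#'   to 1 within `1e-9`).
#' @return scalar PIC.
#' @export
pic <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  p2 <- freqs^2
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))  # sum_{i<j} 2 p_i^2 p_j^2
}

#' Per-site and mean minor allele frequency within a group
#'
#' The frequency of the least frequent *observed* allele at each site
#' (`min(p, 1-p)` for biallelic sites); a site monomorphic within the group
#' has MAF 0.
#'
#' @inheritParams nucleotide_diversity
#' @return numeric vector of per-site MAF; the mean over sites is attached as
#'   attribute `mean`.
#' @export
minor_allele_freq <- function(geno, groups, group) {
  rows <- group_rows(geno, groups, group)
  counts <- site_allele_counts(geno, rows)
  n <- length(rows)
  maf <- apply(counts, 2, function(c) {
    obs <- c[c > 0]
    if (length(obs) < 2) 0 else min(obs) / n
  })
  structure(maf, mean = mean(maf))
}

#' Per-group genetic diversity summary
#'
#' One row per group with nucleotide diversity, Watterson's estimator, mean
#' minor allele frequency and mean polymorphism information content, all
#' computed over the full analysed site set of the matrix.
#'
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param which_groups group labels to summarize (default: all in `groups`,
#'   in order of first appearance).
#' @return data.frame with columns `group`, `n`, `pi`, `theta_w`, `maf`,
#'   `pic`.
#' @export
diversity_summary <- function(geno, groups, which_groups = unique(groups$group)) {
  rows_list <- lapply(which_groups, function(g) group_rows(geno, groups, g))
  out <- lapply(seq_along(which_groups), function(k) {
    g <- which_groups[k]
    rows <- rows_list[[k]]
    n <- length(rows)
    counts <- site_allele_counts(geno, rows)
    freqs <- counts / n
    pic_site <- apply(freqs, 2, function(f) pic(f[f > 0] / sum(f[f > 0])))
    data.frame(
      group = g, n = n,
      pi = as.numeric(nucleotide_diversity(geno, groups, g)),
      theta_w = watterson_theta(geno, groups, g),
      maf = attr(minor_allele_freq(geno, groups, g), "mean"),
      pic = mean(pic_site),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
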