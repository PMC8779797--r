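# Per-SNP AMOVA on haploid allele-mismatch distances, two groups.
#
# Variance components via the standard sums-of-squared-distances identities:
#   SSD(T) = (1/N) sum_{i<j} d_ij,  SSD(W) = sum_g (1/n_g) sum_{i<j in g} d_ij
# with d_ij the 0/1 allele mismatch, so the pairwise sums reduce to allele
# counts: sum_{i<j} d_ij = C(n,2) - sum_a C(c_a,2).
# MS(W) = SSD(W)/(N-2) estimates sigma_w^2; MS(B) = SSD(B)/(g-1) estimates
# sigma_w^2 + n0 sigma_b^2 with n0 = (N - sum n_g^2 / N)/(g-1).
# Negative sigma_b^2 estimates are truncated to 0 before forming the ratio.

# counts1/counts2: max_alleles x S allele counts for the two groups.
# Returns list(sigma_b2, sigma_w2) of length-S vectors.
amova_components <- function(counts1, counts2, n1, n2) {
  N <- n1 + n2
  n0 <- (N - (n1^2 + n2^2) / N)  # g - 1 = 1
  mism1 <- choose2(n1) - colSums(choose2(counts1))
  mism2 <- choose2(n2) - colSums(choose2(counts2))
  mism_t <- choose2(N) - colSums(choose2(counts1 + counts2))
  ssd_w <- mism1 / n1 + mism2 / n2
  ssd_t <- mism_t / N
  ms_w <- ssd_w / (N - 2)
  ms_b <- ssd_t - ssd_w
  raw <- (ms_b - ms_w) / n0
  list(sigma_b2 = pmax(0, raw), sigma_w2 = ms_w, sigma_b2_raw = raw)
}

fst_from_components <- function(sigma_b2, sigma_w2) {
  sigma_t2 <- sigma_b2 + sigma_w2
  ifelse(sigma_t2 == 0, 0, pmin(1, pmax(0, sigma_b2 / sigma_t2)))
}

#' Per-SNP fixation index between two groups by AMOVA
#'
#' One-level analysis of molecular variance on haploid allele-mismatch
#' distances per SNP: the total variance is partitioned into among-group
#' (`sigma_b2`) and within-group components via expected-mean-square
#' estimators, and `Fst = sigma_b2 / sigma_t2`. Negative component estimates
#' are truncated at 0 before the ratio; a site whose truncated total variance
#' is 0 gets Fst 0. Sites monomorphic across the two groups are excluded
#' before the computation.
#'
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param pair character vector of the two group labels.
#' @return data.frame of class `fst_records` with columns `site` (index into
#'   `geno$sites`), `chrom`, `pos`, `fst`, `sigma_b2`, `sigma_t2`.
#'   Attributes: `pair`, `n` (group sizes), `global_fst` (ratio of summed
#'   components, the weighted average reported as a stage's overall Fst) and
#'   `mean_fst` (arithmetic mean of per-SNP values).
#' @export
fst_amova_per_snp <- function(geno, groups, pair) {
  stopifnot(length(pair) == 2)
  rows1 <- group_rows(geno, groups, pair[1])
  rows2 <- group_rows(geno, groups, pair[2])
  if (length(rows1) < 2 || length(rows2) < 2) {
    stop("both groups need at least 2 accessions")
  }
  counts1 <- site_allele_counts(geno, rows1)
  counts2 <- site_allele_counts(geno, rows2)
  poly <- colSums((counts1 + counts2) > 0) >= 2
  if (!any(poly)) stop("all sites are monomorphic in this group pair")
  comp <- amova_components(counts1[, poly, drop = FALSE],
                           counts2[, poly, drop = FALSE],
                           length(rows1), length(rows2))
  out <- data.frame(
    site = which(poly),
    chrom = geno$sites$chrom[poly],
    pos = geno$sites$pos[poly],
    fst = fst_from_components(comp$sigma_b2, comp$sigma_w2),
    sigma_b2 = comp$sigma_b2,
    sigma_t2 = comp$sigma_b2 + comp$sigma_w2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fst_records", "data.frame")
  attr(out, "pair") <- pair
  attr(out, "n") <- c(length(rows1), length(rows2))
  # multi-locus (weighted) Fst: variance components summed over loci without
  # per-locus truncation, then one global ratio truncated to [0, 1]
  attr(out, "global_fst") <- min(1, max(0,
    sum(comp$sigma_b2_raw) / sum(comp$sigma_b2_raw + comp$sigma_w2)))
  attr(out, "mean_fst") <- mean(out$fst)
  out
}

#' Permutation outlier test for per-SNP Fst
#'
#' Identifies SNPs that deviate from the neutral expectation by permuting
#' accessions across the two groups. A single shared block of `n_perm` label
#' permutations is applied to every SNP (the null -- exchangeable labels --
#' is the same for all SNPs). Per SNP,
#' `perm_p = (1 + #\{Fst_perm >= Fst_obs\}) / (n_perm + 1)` (add-one rule, so
#' p is never 0) and the SNP is neutral when `perm_p >= alpha`. No
#' multiple-testing correction is applied across SNPs.
#'
#' @inheritParams fst_amova_per_snp
#' @param n_perm number of permutations (default 20000).
#' @param alpha outlier significance level (default 0.01).
#' @param seed seed for the shared permutation block.
#' @param perm_sets optional list of integer vectors, each giving the indices
#'   (into the pooled accession vector, group 1 first) assigned to group 1;
#'   overrides random permutations, e.g. for exhaustive enumeration.
#' @return the [fst_amova_per_snp()] records with additional columns
#'   `perm_p` and `neutral`. Attributes: `cutoff` (smallest observed Fst
#'   among discarded SNPs, `NA` if none discarded), `n_perm`, `alpha`.
#' @export
permutation_outlier_test <- function(geno, groups, pair, n_perm = 20000,
                                     alpha = 0.01, seed = 1,
                                     perm_sets = NULL) {
  obs <- fst_amova_per_snp(geno, groups, pair)
  rows1 <- group_rows(geno, groups, pair[1])
  rows2 <- group_rows(geno, groups, pair[2])
  rows <- c(rows1, rows2)
  n1 <- length(rows1); n2 <- length(rows2); N <- n1 + n2
  sub <- geno_subset(geno, accessions = rows, site_idx = obs$site)
  amax <- max(lengths(sub$sites$alleles))
  S <- nrow(sub$sites)
  # allele indicator matrices, N x S, one per allele index
  M_a <- lapply(seq_len(amax), function(a) (sub$calls == a) * 1)
  counts_tot <- matrix(vapply(M_a, function(m) .colSums(m, N, S), numeric(S)),
                       nrow = S)  # S x amax
  if (is.null(perm_sets)) {
    if (n_perm < 1) stop("n_perm must be >= 1")
    perm_sets <- withr::with_seed(as.integer(seed),
      replicate(n_perm, sample.int(N, n1), simplify = FALSE))
  } else {
    n_perm <- length(perm_sets)
    stopifnot(all(vapply(perm_sets, length, integer(1)) == n1))
  }
  ge <- numeric(S)
  obs_fst <- obs$fst
  chunk <- 512L
  starts <- seq(1L, n_perm, by = chunk)
  tM <- lapply(M_a, t)  # S x N
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, n_perm)
    P <- matrix(0, nrow = N, ncol = length(idx))
    for (k in seq_along(idx)) P[perm_sets[[idx[k]]], k] <- 1
    same1 <- matrix(0, nrow = S, ncol = length(idx))
    same2 <- same1
    for (a in seq_len(amax)) {
      c1 <- tM[[a]] %*% P              # S x B counts of allele a in group 1
      c2 <- counts_tot[, a] - c1
      same1 <- same1 + choose2(c1)
      same2 <- same2 + choose2(c2)
    }
    mism1 <- choose2(n1) - same1
    mism2 <- choose2(n2) - same2
    ssd_w <- mism1 / n1 + mism2 / n2
    mism_t <- choose2(N) - rowSums(choose2(counts_tot))
    ssd_t <- mism_t / N
    ms_w <- ssd_w / (N - 2)
    ms_b <- ssd_t - ssd_w
    n0 <- (N - (n1^2 + n2^2) / N)
    sb <- pmax(0, (ms_b - ms_w) / n0)
    fst_perm <- sb / (sb + ms_w)
    fst_perm[sb + ms_w == 0] <- 0
    ge <- ge + rowSums(fst_perm >= obs_fst - 1e-12)
  }
  obs$perm_p <- (1 + ge) / (n_perm + 1)
  obs$neutral <- obs$perm_p >= alpha
  attr(obs, "cutoff") <- if (any(!obs$neutral)) min(obs$fst[!obs$neutral]) else NA_real_
  attr(obs, "n_perm") <- n_perm
  attr(obs, "alpha") <- alpha
  obs
}

#' Summary Fst of the neutral SNP set
#'
#' The neutral reference used in the Qst-Fst comparison. A single "neutral
#' SNP" is underdetermined, so the reference defaults to the mean per-SNP Fst
#' over the neutral set; an arbitrary quantile is available.
#'
#' @param records output of [permutation_outlier_test()].
#' @param stat `"mean"` (default) or `"quantile"`.
#' @param q quantile level when `stat = "quantile"`.
#' @return scalar neutral Fst reference.
#' @export
neutral_fst_reference <- function(records, stat = c("mean", "quantile"), q = 0.5) {
  stat <- match.arg(stat)
  if (!"neutral" %in% names(records)) stop("records lack a 'neutral' flag")
  f <- records$fst[records$neutral]
  if (length(f) == 0) stop("no neutral SNPs")
  if (stat == "mean") mean(f) else stats::quantile(f, q, names = FALSE)
}

# Sliding-window grid: 0-based half-open [start, start + window_bp) anchored
# at 0, stepped by step_bp, covering positions up to `limit`.
window_grid <- function(limit, window_bp, step_bp) {
  if (window_bp <= 0 || step_bp <= 0) stop("window_bp and step_bp must be > 0")
  last <- max(0, step_bp * floor((limit - 1) / step_bp))
  starts <- seq(0, last, by = step_bp)
  data.frame(start = starts, end = pmin(starts + window_bp, limit))
}

#' Mean per-SNP Fst in sliding windows
#'
#' Windows are 0-based half-open `[start, start + window_bp)`, anchored at
#' position 0 of each chromosome and stepped by `step_bp`; the final partial
#' window is truncated at the chromosome end. Windows containing no SNP are
#' omitted.
#'
#' @param records an `fst_records` data.frame (with `chrom`, `pos`, `fst`).
#' @param window_bp window span in bp (default 150000).
#' @param step_bp step in bp (default 75000).
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @return data.frame of class `fst_windows` with columns `chrom`, `start`,
#'   `end`, `n_snps`, `mean_fst`.
#' @export
windowed_fst <- function(records, window_bp = 150000, step_bp = 75000,
                         chrom_lengths = NULL) {
  out <- lapply(split(records, records$chrom), function(d) {
    lim <- if (!is.null(chrom_lengths)) chrom_lengths[[d$chrom[1]]] else max(d$pos)
    grid <- window_grid(lim, window_bp, step_bp)
    p0 <- d$pos - 1  # to 0-based
    res <- lapply(seq_len(nrow(grid)), function(i) {
      inw <- p0 >= grid$start[i] & p0 < grid$end[i]
      if (!any(inw)) return(NULL)
      data.frame(chrom = d$chrom[1], start = grid$start[i], end = grid$end[i],
                 n_snps = sum(inw), mean_fst = mean(d$fst[inw]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("fst_windows", "data.frame")
  out
}

#' Flag selective-sweep windows by the top-Fst quantile
#'
#' The sweep threshold is the empirical `quantile` (default 95th percentile,
#' i.e. the top 5%) of window mean Fst, computed with linear interpolation
#' between order statistics; windows at or above the threshold are flagged.
#'
#' @param windows output of [windowed_fst()].
#' @param quantile quantile level (default 0.95).
#' @return `windows` with an `is_sweep` column; the threshold is attached as
#'   attribute `threshold`.
#' @export
sweep_regions <- function(windows, quantile = 0.95) {
  if (nrow(windows) < 1) stop("at least one window is required")
  thr <- stats::quantile(windows$mean_fst, quantile, names = FALSE, type = 7)
  windows$is_sweep <- windows$mean_fst >= thr
  attr(windows, "threshold") <- thr
  windows
}

#' Read gene features from a GFF3 file
#'
#' A light validating reader: records with the wrong number of fields,
#' non-numeric or inverted coordinates are skipped with a warning naming the
#' line, so one malformed record does not abort the scan. GFF 1-based
#' inclusive intervals are converted to the internal 0-based half-open
#' convention. The gene identifier is taken from the `ID=` (or failing that
#' `Name=`) attribute.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     strand = character(), gene_id = character(),
                     stringsAsFactors = FALSE)
  bad <- 0L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 9) { bad <- bad + 1L; next }
    if (f[3] != feature) next
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s < 1 || e < s) { bad <- bad + 1L; next }
    id <- sub(".*?(?:ID|Name)=([^;]+).*", "\\1", f[9], perl = TRUE)
    if (identical(id, f[9])) id <- paste0("feature_", i)
    keep <- rbind(keep, data.frame(chrom = f[1], start = s - 1, end = e,
                                   strand = f[7], gene_id = id,
                                   stringsAsFactors = FALSE))
  }
  if (bad > 0) warning(bad, " malformed GFF record(s) skipped")
  keep
}

#' Map windows to overlapping genes
#'
#' A gene is reported for a window iff their intervals overlap by at least
#' 1 bp on the same chromosome (computed with `GenomicRanges::findOverlaps`).
#'
#' @param windows a window data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. sweep windows.
#' @param annotation gene table from [read_gene_annotation()] (0-based
#'   half-open `start`/`end`, `gene_id`).
#' @return data.frame with one row per (window, gene) overlap: `chrom`,
#'   `start`, `end`, `gene_id`, plus `mean_fst`/`is_sweep` if present in
#'   `windows`.
#' @export
map_windows_to_genes <- function(windows, annotation) {
  if (nrow(windows) == 0 || nrow(annotation) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1, windows$end))
  g <- GenomicRanges::GRanges(annotation$chrom,
                              IRanges::IRanges(annotation$start + 1,
                                               annotation$end))
  hits <- GenomicRanges::findOverlaps(w, g)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- windows[qi, intersect(c("chrom", "start", "end", "n_snps",
                                 "mean_fst", "is_sweep"), names(windows)),
                 drop = FALSE]
  out$gene_id <- annotation$gene_id[si]
  rownames(out) <- NULL
  out
}
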