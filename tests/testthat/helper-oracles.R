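# Independent brute-force oracles used to validate the vectorised
# implementations on small instances. These deliberately use the most direct
# formulation available (pairwise loops, full mismatch matrices, explicit
# set algebra) and share no code with the package internals.

# mean pairwise difference per site over all accession pairs
pi_oracle <- function(calls) {
  n <- nrow(calls); L <- ncol(calls)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(calls[i, ] != calls[j, ])
  }
  tot / (choose(n, 2) * L)
}

# PIC by explicit double loop
pic_oracle <- function(p) {
  val <- 1 - sum(p^2)
  k <- length(p)
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) val <- val - 2 * p[i]^2 * p[j]^2
  }
  val
}

# one-level AMOVA Fst for a single SNP from the full pairwise mismatch matrix
amova_oracle <- function(alleles1, alleles2) {
  x <- c(alleles1, alleles2)
  n1 <- length(alleles1); n2 <- length(alleles2); N <- n1 + n2
  D <- outer(x, x, FUN = "!=") * 1
  ut <- upper.tri(D)
  ssd_t <- sum(D[ut]) / N
  D1 <- D[1:n1, 1:n1]; D2 <- D[(n1 + 1):N, (n1 + 1):N]
  ssd_w <- sum(D1[upper.tri(D1)]) / n1 + sum(D2[upper.tri(D2)]) / n2
  ms_w <- ssd_w / (N - 2)
  ms_b <- (ssd_t - ssd_w) / 1
  n0 <- N - (n1^2 + n2^2) / N
  sb <- max(0, (ms_b - ms_w) / n0)
  st <- sb + ms_w
  list(fst = if (st == 0) 0 else sb / st, sigma_b2 = sb, sigma_t2 = st)
}

# one-way expected-mean-squares components via stats::aov sums of squares
vc_oracle <- function(y, grp) {
  fit <- stats::aov(y ~ factor(grp))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  n_g <- table(grp)
  N <- sum(n_g)
  n0 <- (N - sum(n_g^2) / N) / (length(n_g) - 1)
  list(sigma_b2 = max(0, (ms[1] - ms[2]) / n0), sigma_w2 = ms[2])
}

# textbook Welch t statistic and p-value
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# interval-scan oracle for window means: loop over windows and SNPs
window_mean_oracle <- function(pos, fst, window_bp, step_bp, limit = max(pos)) {
  starts <- seq(0, max(0, step_bp * floor((limit - 1) / step_bp)), by = step_bp)
  out <- NULL
  for (s in starts) {
    e <- min(s + window_bp, limit)
    sel <- which(pos - 1 >= s & pos - 1 < e)
    if (length(sel) == 0) next
    out <- rbind(out, data.frame(start = s, end = e, n_snps = length(sel),
                                 mean_fst = mean(fst[sel])))
  }
  out
}

# brute-force 3-set Venn cell sizes
venn_oracle <- function(a, b, c) {
  u <- unique(c(a, b, c))
  cells <- c(
    sum(u %in% a & !(u %in% b) & !(u %in% c)),
    sum(!(u %in% a) & u %in% b & !(u %in% c)),
    sum(!(u %in% a) & !(u %in% b) & u %in% c),
    sum(u %in% a & u %in% b & !(u %in% c)),
    sum(u %in% a & !(u %in% b) & u %in% c),
    sum(!(u %in% a) & u %in% b & u %in% c),
    sum(u %in% a & u %in% b & u %in% c)
  )
  cells
}

# group haplotype strings by brute force
hap_oracle <- function(strings) sort(table(strings), decreasing = TRUE)

# a tiny hand-made genotype matrix: rows accessions, entries allele indices
make_geno <- function(calls, chrom = "1H", pos = NULL, alleles = NULL,
                      acc = NULL) {
  calls <- as.matrix(calls)
  S <- ncol(calls)
  pos <- pos %||% seq_len(S)
  alleles <- alleles %||% replicate(S, c("A", "T"), simplify = FALSE)
  acc <- acc %||% sprintf("acc%02d", seq_len(nrow(calls)))
  sites <- data.frame(chrom = rep_len(chrom, S), pos = pos,
                      stringsAsFactors = FALSE)
  sites$alleles <- alleles
  genotype_matrix(calls, sites, acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced two-group assignment for a matrix built with make_geno
make_groups <- function(geno, sizes, labels = paste0("G", seq_along(sizes))) {
  group_assignment(geno$accession_ids,
                   rep(labels, sizes))
}

# long-format metabolite data from an accessions x metabolites matrix of
# accession-level values, replicated with optional jitter
make_metab <- function(values, acc = rownames(values), reps = 3, jitter = 0) {
  met <- colnames(values) %||% sprintf("m%02d", seq_len(ncol(values)))
  long <- expand.grid(accession = acc, replicate = seq_len(reps),
                      metabolite = met, stringsAsFactors = FALSE)
  long$abundance <- 2^(values[cbind(match(long$accession, acc),
                                    match(long$metabolite, met))] +
                         if (jitter > 0) rnorm(nrow(long), 0, jitter) else 0)
  metabolite_matrix(long)
}
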