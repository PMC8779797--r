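#' Construct a replicated metabolite abundance matrix
#'
#' Long-format container of replicate-level abundances with a flag recording
#' whether values are on the raw (positive) or log2 scale.
#'
#' @param data data.frame with columns `accession`, `replicate`,
#'   `metabolite`, `abundance`.
#' @param log2 logical; `TRUE` if `abundance` is already log2-converted.
#' @param truth optional ground-truth data.frame (from the simulator).
#' @return object of class `metab_matrix`.
#' @export
metabolite_matrix <- function(data, log2 = FALSE, truth = NULL) {
  need <- c("accession", "replicate", "metabolite", "abundance")
  if (!all(need %in% names(data))) {
    stop("metabolite data needs columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(data$abundance)) stop("missing abundances are not supported")
  structure(list(data = data[, need], log2 = isTRUE(log2), truth = truth),
            class = "metab_matrix")
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat("<metab_matrix> ", length(unique(x$data$metabolite)), " metabolites x ",
      length(unique(x$data$accession)), " accessions (",
      if (x$log2) "log2" else "raw", " scale)\n", sep = "")
  invisible(x)
}

#' Read a long-format metabolite TSV
#'
#' @param path TSV with columns `accession`, `replicate`, `metabolite`,
#'   `abundance` (raw scale).
#' @return a [metabolite_matrix()] with `log2 = FALSE`.
#' @export
read_metabolite_table <- function(path) {
  metabolite_matrix(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Convert metabolite contents to log2
#'
#' All contents are log2-converted to enhance data homogeneity before
#' variance decomposition. Non-positive abundances are a domain error and the
#' offending cell is named.
#'
#' @param m a [metabolite_matrix()] on the raw scale.
#' @return the matrix with log2 abundances and the `log2` flag set.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "metab_matrix"))
  if (m$log2) stop("matrix is already log2-transformed")
  bad <- which(m$data$abundance <= 0)
  if (length(bad)) {
    b <- m$data[bad[1], ]
    stop("non-positive abundance at accession ", b$accession,
         ", metabolite ", b$metabolite, ", replicate ", b$replicate)
  }
  m$data$abundance <- log2(m$data$abundance)
  m$log2 <- TRUE
  m
}

#' Accession-mean log2 abundance matrix
#'
#' Replicates are averaged per accession; rows are accessions, columns
#' metabolites.
#'
#' @param m a log2-transformed [metabolite_matrix()].
#' @return numeric matrix accessions x metabolites.
#' @export
accession_means <- function(m) {
  stopifnot(inherits(m, "metab_matrix"))
  if (!m$log2) stop("log2-transform the matrix first (log2_transform)")
  acc <- sort(unique(m$data$accession))
  met <- sort(unique(m$data$metabolite))
  sums <- tapply(m$data$abundance,
                 list(factor(m$data$accession, acc),
                      factor(m$data$metabolite, met)),
                 mean)
  out <- matrix(as.numeric(sums), nrow = length(acc),
                dimnames = list(acc, met))
  if (anyNA(out)) stop("every accession needs at least one replicate per metabolite")
  out
}

# Standard unbalanced one-way coefficient n0 = (N - sum n_i^2 / N)/(g - 1).
n0_coefficient <- function(n_g) {
  N <- sum(n_g)
  (N - sum(n_g^2) / N) / (length(n_g) - 1)
}

#' Between- and within-group variance components per metabolite
#'
#' One-way random-effects decomposition on accession means (replicates are
#' averaged first): `sigma_w2` is the pooled within-group variance of
#' accession means (`MS_within`), and
#' `sigma_b2 = max(0, (MS_between - MS_within) / n0)` with `n0` the standard
#' unbalanced-design coefficient -- the method-of-moments solution that
#' reproduces the mixed-model answer for balanced designs without an
#' iterative fit.
#'
#' @param m a log2-transformed [metabolite_matrix()].
#' @param groups group assignment covering the accessions.
#' @param pair the two group labels to compare (each with >= 2 accessions).
#' @return data.frame with columns `metabolite`, `sigma_b2`, `sigma_w2`.
#' @export
variance_components <- function(m, groups, pair) {
  A <- accession_means(m)
  vc <- variance_components_matrix(A, groups, pair)
  data.frame(metabolite = colnames(A), sigma_b2 = vc$sigma_b2,
             sigma_w2 = vc$sigma_w2, stringsAsFactors = FALSE)
}

# Core decomposition on an accessions x metabolites matrix of means.
variance_components_matrix <- function(A, groups, pair) {
  stopifnot(length(pair) == 2)
  lab <- groups$group[match(rownames(A), groups$accession)]
  rows <- lapply(pair, function(g) which(lab == g))
  n_g <- lengths(rows)
  if (any(n_g < 2)) stop("both groups need at least 2 accessions")
  A1 <- A[rows[[1]], , drop = FALSE]
  A2 <- A[rows[[2]], , drop = FALSE]
  N <- sum(n_g)
  m1 <- colMeans(A1); m2 <- colMeans(A2)
  ov <- (n_g[1] * m1 + n_g[2] * m2) / N
  ssb <- n_g[1] * (m1 - ov)^2 + n_g[2] * (m2 - ov)^2
  ssw <- colSums((A1 - rep(m1, each = n_g[1]))^2) +
    colSums((A2 - rep(m2, each = n_g[2]))^2)
  ms_b <- ssb / 1
  ms_w <- ssw / (N - 2)
  n0 <- n0_coefficient(n_g)
  list(sigma_b2 = pmax(0, (ms_b - ms_w) / n0), sigma_w2 = ms_w)
}

#' Qst from variance components
#'
#' `Qst = sigma_b2 / (sigma_b2 + 2 sigma_w2)`; the factor 2 converts the
#' between-group component to the scale of additive genetic variance for the
#' trait analogue of Fst. Undefined (returned as `NA`) when both components
#' are 0.
#'
#' @param sigma_b2,sigma_w2 non-negative variance components (vectorised).
#' @return numeric Qst in `[0, 1]` (or `NA` where undefined).
#' @export
qst <- function(sigma_b2, sigma_w2) {
  if (any(sigma_b2 < 0, na.rm = TRUE) || any(sigma_w2 < 0, na.rm = TRUE)) {
    stop("variance components must be non-negative")
  }
  denom <- sigma_b2 + 2 * sigma_w2
  ifelse(denom == 0, NA_real_, sigma_b2 / denom)
}

#' Stratified bootstrap confidence intervals for Qst
#'
#' Accessions are resampled with replacement within each group (replicates
#' travel with their accession, i.e. resampling acts on accession means);
#' Qst is recomputed for each resample and percentile bounds are taken at
#' `(1 - level)/2` and `1 - (1 - level)/2`. Resamples with undefined Qst
#' (both components 0) are skipped and counted. One shared set of resample
#' indices is used for all metabolites in the call.
#'
#' Percentile intervals can exclude the point estimate in skewed cases, so
#' `ci_lo <= qst <= ci_hi` is not guaranteed.
#'
#' @inheritParams variance_components
#' @param metabolites metabolite ids to process (default all).
#' @param n_boot number of resamples (default 1000).
#' @param level confidence level (default 0.99).
#' @param seed resampling seed.
#' @return data.frame with columns `metabolite`, `ci_lo`, `ci_hi`,
#'   `n_undefined`.
#' @export
bootstrap_qst_ci <- function(m, groups, pair, metabolites = NULL,
                             n_boot = 1000, level = 0.99, seed = 1) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  A <- accession_means(m)
  if (!is.null(metabolites)) {
    miss <- setdiff(metabolites, colnames(A))
    if (length(miss)) stop("unknown metabolite(s): ", paste(miss, collapse = ", "))
    A <- A[, metabolites, drop = FALSE]
  }
  lab <- groups$group[match(rownames(A), groups$accession)]
  rows <- lapply(pair, function(g) which(lab == g))
  n_g <- lengths(rows)
  if (any(n_g < 2)) stop("both groups need at least 2 accessions")
  M <- ncol(A)
  qmat <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(rows[[1]][sample.int(n_g[1], n_g[1], replace = TRUE)],
               rows[[2]][sample.int(n_g[2], n_g[2], replace = TRUE)])
      Ab <- A[idx, , drop = FALSE]
      rownames(Ab) <- rownames(A)[c(rows[[1]], rows[[2]])]
      vc <- variance_components_matrix(Ab, groups, pair)
      as.numeric(qst(vc$sigma_b2, vc$sigma_w2))
    }, numeric(M))
  })
  qmat <- matrix(qmat, nrow = M)  # M x n_boot
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(qmat, 1, function(q) {
    q <- q[!is.na(q)]
    if (length(q) == 0) c(NA_real_, NA_real_) else
      stats::quantile(q, probs, names = FALSE, type = 7)
  }))
  data.frame(metabolite = colnames(A), ci_lo = ci[, 1], ci_hi = ci[, 2],
             n_undefined = rowSums(is.na(qmat)), stringsAsFactors = FALSE)
}

#' Divergence call for a metabolite's Qst interval
#'
#' A metabolite is divergent (under selection) iff its whole confidence
#' interval lies above the neutral Fst reference, i.e. `ci_lo > reference`
#' (strict: an interval touching the reference is not called).
#'
#' @param ci_lo lower CI bound(s).
#' @param reference neutral Fst reference value.
#' @return logical vector (`NA` where the CI is missing).
#' @export
call_divergent <- function(ci_lo, reference) {
  stopifnot(length(reference) == 1, !is.na(reference))
  ifelse(is.na(ci_lo), NA, ci_lo > reference)
}

#' Per-metabolite Qst scan against a neutral Fst reference
#'
#' Convenience wrapper: variance components, Qst, bootstrap CI and the
#' divergence call for every metabolite in one stage (group pair).
#'
#' @inheritParams bootstrap_qst_ci
#' @param neutral_fst neutral Fst reference (e.g. from
#'   [neutral_fst_reference()]).
#' @param stage optional stage label (default `"A vs B"` from the pair).
#' @return data.frame of per-metabolite records: `metabolite`, `sigma_b2`,
#'   `sigma_w2`, `qst`, `ci_lo`, `ci_hi`, `divergent`, `stage`.
#' @export
qst_scan <- function(m, groups, pair, neutral_fst, n_boot = 1000,
                     level = 0.99, seed = 1, stage = paste(pair, collapse = " vs ")) {
  vc <- variance_components(m, groups, pair)
  ci <- bootstrap_qst_ci(m, groups, pair, n_boot = n_boot, level = level,
                         seed = seed)
  out <- merge(vc, ci, by = "metabolite", sort = TRUE)
  out$qst <- qst(out$sigma_b2, out$sigma_w2)
  out$divergent <- call_divergent(out$ci_lo, neutral_fst)
  out$stage <- stage
  out[, c("metabolite", "sigma_b2", "sigma_w2", "qst", "ci_lo", "ci_hi",
          "divergent", "stage")]
}

#' Set algebra of divergent-metabolite calls across two stages
#'
#' @param calls_stage1,calls_stage2 character vectors of divergent metabolite
#'   ids for the two evolutionary stages.
#' @param universe all metabolite ids (or the total count) over which the
#'   common percentage is expressed.
#' @return list with `stage1_only`, `stage2_only`, `common` (id vectors) and
#'   counts `n_stage1`, `n_stage2`, `n_common`, `n_union`, `n_total`,
#'   `percent_common_of_all` (= 100 * common / total).
#' @export
stage_venn <- function(calls_stage1, calls_stage2, universe) {
  s1 <- unique(calls_stage1)
  s2 <- unique(calls_stage2)
  total <- if (is.numeric(universe) && length(universe) == 1) universe
           else length(unique(universe))
  common <- intersect(s1, s2)
  list(
    stage1_only = setdiff(s1, s2),
    stage2_only = setdiff(s2, s1),
    common = common,
    n_stage1 = length(s1),
    n_stage2 = length(s2),
    n_common = length(common),
    n_union = length(union(s1, s2)),
    n_total = total,
    percent_common_of_all = 100 * length(common) / total
  )
}

#' Per-class divergent-metabolite counts per stage
#'
#' Contingency of metabolite class by evolutionary stage over the divergent
#' calls; classes with nonzero counts in exactly one stage are flagged
#' stage-specific. Metabolites without an annotation fall into
#' `"unclassified"`.
#'
#' @param calls named list of character vectors of divergent metabolite ids,
#'   one element per stage.
#' @param annotation data.frame with columns `metabolite` and `class`.
#' @return data.frame with `class`, one count column per stage, and
#'   `stage_specific` (the stage name, or `NA`).
#' @export
class_summary <- function(calls, annotation) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  if (all(lengths(calls) == 0)) {
    return(data.frame(class = character(), stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, lapply(names(calls), function(st) {
    ids <- calls[[st]]
    if (length(ids) == 0) return(NULL)
    cl <- annotation$class[match(ids, annotation$metabolite)]
    cl[is.na(cl)] <- "unclassified"
    data.frame(stage = st, class = cl, stringsAsFactors = FALSE)
  }))
  tab <- table(long$class, long$stage)
  # make sure all stages appear even if empty
  missing_stages <- setdiff(names(calls), colnames(tab))
  for (st in missing_stages) {
    tab <- cbind(tab, matrix(0L, nrow = nrow(tab), dimnames = list(NULL, st)))
  }
  tab <- tab[, names(calls), drop = FALSE]
  nz <- tab > 0
  spec <- apply(nz, 1, function(r) if (sum(r) == 1) names(calls)[which(r)] else NA_character_)
  out <- data.frame(class = rownames(tab), as.data.frame.matrix(tab),
                    stage_specific = spec, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[2:(1 + length(calls))] <- names(calls)
  out
}
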