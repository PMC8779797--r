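#' Build a group's gene pool (per-site consensus sequence)
#'
#' For each SNP site the pool takes the majority allele within the group:
#' minority variants are treated as errors rather than falling back to the
#' reference base. Exact frequency ties are broken by a seeded uniform choice
#' among the tied alleles, so pools are reproducible.
#'
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param group group label (non-empty; a single-accession group yields that
#'   accession's alleles verbatim).
#' @param seed seed for tie-breaking.
#' @return object of class `gene_pool`: list with `group`, `allele_idx`
#'   (1-based allele index per site), `alleles` (allele strings) and the
#'   site table.
#' @export
build_gene_pool <- function(geno, groups, group, seed = 1) {
  rows <- group_rows(geno, groups, group)
  counts <- site_allele_counts(geno, rows)
  idx <- withr::with_seed(as.integer(seed), {
    apply(counts, 2, function(c) {
      top <- which(c == max(c))
      if (length(top) == 1) top else top[sample.int(length(top), 1)]
    })
  })
  structure(
    list(group = group,
         allele_idx = as.integer(idx),
         alleles = mapply(function(a, i) a[[i]], geno$sites$alleles, idx),
         sites = geno$sites[, c("chrom", "pos")]),
    class = "gene_pool"
  )
}

#' @export
print.gene_pool <- function(x, ...) {
  cat("<gene_pool> group '", x$group, "', ", length(x$allele_idx),
      " sites\n", sep = "")
  invisible(x)
}

#' Sliding-window genomic similarity between two gene pools
#'
#' Windows are 0-based half-open spans of `window_bp` (default 150 kb)
#' stepped by `step_bp` (default 75 kb), anchored at position 0 of each
#' chromosome; the final partial window is kept if it passes the SNP-count
#' filter. Per window the similarity is the fraction of sites whose consensus
#' alleles agree between the two pools. Windows with `n_snps <=
#' min_snps_exclusive` are removed before thresholding; a window is retained
#' iff its similarity is at least `retain_threshold`.
#'
#' @param pool_a,pool_b gene pools over the same site list.
#' @param window_bp,step_bp window span and step in bp.
#' @param min_snps_exclusive windows with at most this many SNPs are removed
#'   (default 10, i.e. only windows with >= 11 SNPs are kept).
#' @param retain_threshold similarity retention threshold (default 0.95).
#' @param chrom_lengths optional named chromosome lengths; default last SNP
#'   position per chromosome.
#' @return data.frame of class `similarity_windows` with columns `chrom`,
#'   `start`, `end`, `n_snps`, `n_identical`, `similarity`, `retained`;
#'   attribute `comparison` labels the pair.
#' @export
window_similarity <- function(pool_a, pool_b, window_bp = 150000,
                              step_bp = 75000, min_snps_exclusive = 10,
                              retain_threshold = 0.95,
                              chrom_lengths = NULL) {
  if (!identical(pool_a$sites, pool_b$sites)) {
    stop("gene pools must share the same site list")
  }
  same <- pool_a$alleles == pool_b$alleles
  sites <- pool_a$sites
  out <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(ix) {
    ch <- sites$chrom[ix[1]]
    lim <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(sites$pos[ix])
    grid <- window_grid(lim, window_bp, step_bp)
    p0 <- sites$pos[ix] - 1
    res <- lapply(seq_len(nrow(grid)), function(i) {
      inw <- ix[p0 >= grid$start[i] & p0 < grid$end[i]]
      n <- length(inw)
      if (n == 0 || n <= min_snps_exclusive) return(NULL)
      nid <- sum(same[inw])
      data.frame(chrom = ch, start = grid$start[i], end = grid$end[i],
                 n_snps = n, n_identical = nid, similarity = nid / n,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$retained <- out$similarity >= retain_threshold
  class(out) <- c("similarity_windows", "data.frame")
  attr(out, "comparison") <- paste(pool_a$group, "vs", pool_b$group)
  out
}

window_key <- function(w) paste(w$chrom, w$start, w$end, sep = ":")

#' Venn partition of retained similarity windows across three comparisons
#'
#' Windows are identified by their comparison-independent grid coordinates
#' (`chrom:start:end`); all three comparisons must come from the same
#' windowing grid. Retained windows are partitioned into the 7 Venn cells,
#' and "unique" windows (retained in exactly one comparison) are also counted
#' per chromosome.
#'
#' @param comparisons named list of three `similarity_windows` data.frames
#'   (or data.frames with at least `chrom`, `start`, `end`, `retained`).
#' @return list with `cells` (named list of window keys for the 7 cells,
#'   names like `"A"`, `"A&B"`, `"A&B&C"` built from the comparison names),
#'   `counts` (named integer vector over cells), `unique_by_chrom`
#'   (data.frame comparison x chromosome counts of unique windows),
#'   `n_retained` (per-comparison totals), `total_pairs` (sum of
#'   per-comparison totals) and `total_merged` (count of distinct window
#'   coordinates retained in any comparison).
#' @export
venn_partition <- function(comparisons) {
  stopifnot(length(comparisons) == 3)
  nm <- names(comparisons) %||% paste0("cmp", 1:3)
  if (is.null(names(comparisons))) names(comparisons) <- nm
  keys <- lapply(comparisons, function(w) {
    w <- w[w$retained %||% rep(TRUE, nrow(w)), , drop = FALSE]
    window_key(w)
  })
  all_keys <- unique(unlist(keys))
  # windows with identical chrom+start must agree on end (same grid)
  allw <- do.call(rbind, lapply(comparisons, function(w)
    w[, c("chrom", "start", "end")]))
  cs <- paste(allw$chrom, allw$start)
  if (any(tapply(allw$end, cs, function(e) length(unique(e))) > 1)) {
    stop("comparisons come from different windowing grids")
  }
  inA <- all_keys %in% keys[[1]]
  inB <- all_keys %in% keys[[2]]
  inC <- all_keys %in% keys[[3]]
  cells <- list(
    all_keys[inA & !inB & !inC],
    all_keys[!inA & inB & !inC],
    all_keys[!inA & !inB & inC],
    all_keys[inA & inB & !inC],
    all_keys[inA & !inB & inC],
    all_keys[!inA & inB & inC],
    all_keys[inA & inB & inC]
  )
  names(cells) <- c(nm, paste(nm[1], nm[2], sep = "&"),
                    paste(nm[1], nm[3], sep = "&"),
                    paste(nm[2], nm[3], sep = "&"),
                    paste(nm, collapse = "&"))
  uniq_chrom <- do.call(rbind, lapply(1:3, function(k) {
    u <- cells[[k]]
    ch <- sub(":.*", "", u)
    if (length(u) == 0) return(NULL)
    data.frame(comparison = nm[k], chrom = ch, stringsAsFactors = FALSE)
  }))
  unique_by_chrom <- if (is.null(uniq_chrom)) {
    data.frame(comparison = character(), chrom = character(), n = integer())
  } else {
    agg <- stats::aggregate(list(n = uniq_chrom$comparison),
                            by = list(comparison = uniq_chrom$comparison,
                                      chrom = uniq_chrom$chrom), FUN = length)
    agg[order(agg$comparison, agg$chrom), ]
  }
  list(
    cells = cells,
    counts = vapply(cells, length, integer(1)),
    unique_by_chrom = unique_by_chrom,
    n_retained = vapply(keys, length, integer(1)),
    total_pairs = sum(vapply(keys, length, integer(1))),
    total_merged = length(all_keys)
  )
}

#' Write windows as a BED file
#'
#' 0-based half-open BED intervals with a score column (similarity or mean
#' Fst, whichever the window table carries).
#'
#' @param windows window data.frame with `chrom`, `start`, `end` and a score
#'   column.
#' @param path output path.
#' @param score name of the score column (default the first of `similarity`,
#'   `mean_fst` present).
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path,
                              score = intersect(c("similarity", "mean_fst"),
                                                names(windows))[1]) {
  if (nrow(windows) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = windows$chrom,
                    start = format(windows$start, scientific = FALSE, trim = TRUE),
                    end = format(windows$end, scientific = FALSE, trim = TRUE),
                    name = paste0("w", seq_len(nrow(windows))),
                    score = windows[[score]])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
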