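#' Classify accessions at the Btr1/Btr2 domestication loci
#'
#' An accession carries the loss-of-function `btr1` allele iff the diagnostic
#' 1-bp deletion (REF `GC` -> ALT `G`) is called at the Btr1 locus, and
#' `btr2` iff the 11-bp deletion is called at the Btr2 locus; otherwise the
#' wild (uppercase) allele. A locus with no covering record is `unknown`;
#' conflicting calls at one locus give `unknown` with a warning. The
#' classification is idempotent and independent of record order.
#'
#' @param variants long-format variant records: data.frame with columns
#'   `accession`, `chrom`, `pos`, `ref`, `alt`, `gt` (0 = reference,
#'   1 = deletion allele), e.g. from [simulate_btr_locus()] or
#'   [vcf_indel_records()].
#' @param loci diagnostic locus table (default [btr_loci()]).
#' @return data.frame of class `btr_genotypes`: `accession`, `btr1_allele`,
#'   `btr2_allele`, `genotype` (e.g. `"btr1Btr2"`), plus a `fingerprint`
#'   list-column of the accession's non-diagnostic records
#'   (`chrom:pos:allele`), usable for haplotype-novelty assessment.
#' @export
classify_btr <- function(variants, loci = btr_loci()) {
  need <- c("accession", "chrom", "pos", "ref", "alt", "gt")
  stopifnot(all(need %in% names(variants)))
  acc <- unique(variants$accession)
  diag_key <- paste(loci$chrom, loci$pos, loci$ref, loci$alt)
  var_key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  one <- function(a) {
    va <- variants[variants$accession == a, , drop = FALSE]
    ka <- var_key[variants$accession == a]
    alleles <- character(2)
    for (i in 1:2) {
      hit <- which(ka == diag_key[i])
      if (length(hit) == 0) {
        alleles[i] <- "unknown"
      } else {
        g <- unique(va$gt[hit])
        if (length(g) > 1) {
          warning("conflicting calls at the ", loci$locus[i], " locus for ",
                  a, "; set to unknown")
          alleles[i] <- "unknown"
        } else {
          alleles[i] <- if (g == 1) tolower(loci$locus[i]) else loci$locus[i]
        }
      }
    }
    fp <- paste0(va$chrom, ":", va$pos, ":",
                 ifelse(va$gt == 1, va$alt, va$ref))[!(ka %in% diag_key)]
    list(alleles = alleles, fingerprint = fp)
  }
  res <- lapply(acc, one)
  out <- data.frame(
    accession = acc,
    btr1_allele = vapply(res, function(r) r$alleles[1], character(1)),
    btr2_allele = vapply(res, function(r) r$alleles[2], character(1)),
    stringsAsFactors = FALSE
  )
  out$genotype <- ifelse(out$btr1_allele == "unknown" |
                           out$btr2_allele == "unknown", "unknown",
                         paste0(out$btr1_allele, out$btr2_allele))
  out$fingerprint <- lapply(res, `[[`, "fingerprint")
  class(out) <- c("btr_genotypes", "data.frame")
  out
}

#' Group accessions by missense-SNP haplotypes at a candidate gene
#'
#' Each accession's alleles at the given missense sites are concatenated into
#' a haplotype string. All possible haplotypes over the sites' allele sets
#' are enumerated (2^k for k biallelic sites); observed haplotypes are
#' labelled `hap1`, `hap2`, ... by descending accession count, ties broken
#' lexicographically, and unobserved ones continue the numbering in
#' lexicographic order so the labelling is always auditable.
#'
#' @param geno a [genotype_matrix()].
#' @param groups group assignment.
#' @param chrom chromosome of the gene.
#' @param missense_pos 1-based positions of the missense SNPs (must exist in
#'   the matrix).
#' @param gene_start,gene_end optional 0-based half-open gene interval; when
#'   given, all `missense_pos` must fall inside it.
#' @return list of class `haplotype_table` with `sites` (site table),
#'   `assignment` (accession, group, haplotype, label), `table` (haplotype,
#'   label, per-group counts, total, observed flag over all 2^k
#'   possibilities) and `n_possible`.
#' @export
haplotype_group <- function(geno, groups, chrom, missense_pos,
                            gene_start = NULL, gene_end = NULL) {
  idx <- match(paste(chrom, missense_pos),
               paste(geno$sites$chrom, geno$sites$pos))
  if (anyNA(idx)) {
    stop("missense position(s) absent from the matrix: ",
         paste(missense_pos[is.na(idx)], collapse = ", "))
  }
  if (!is.null(gene_start) && !is.null(gene_end)) {
    p0 <- missense_pos - 1
    if (any(p0 < gene_start | p0 >= gene_end)) {
      stop("missense positions must lie within the gene interval")
    }
  }
  allele_sets <- geno$sites$alleles[idx]
  hap_of <- function(row) {
    paste(mapply(function(a, j) a[[geno$calls[row, j]]], allele_sets, idx),
          collapse = "")
  }
  haps <- vapply(seq_along(geno$accession_ids), hap_of, character(1))
  possible <- do.call(expand.grid,
                      c(rev(allele_sets), stringsAsFactors = FALSE))
  possible <- apply(possible[, rev(seq_along(allele_sets)), drop = FALSE],
                    1, paste, collapse = "")
  possible <- sort(unique(possible))
  counts <- table(factor(haps, levels = possible))
  ord <- order(-as.integer(counts), names(counts))
  # order(ord) is the inverse permutation: rank of each haplotype
  labels <- stats::setNames(paste0("hap", order(ord)), possible)
  lab_of <- labels[haps]
  grp <- groups$group[match(geno$accession_ids, groups$accession)]
  gtab <- table(factor(haps, levels = possible), grp)
  tab <- data.frame(haplotype = possible,
                    label = labels[possible],
                    as.data.frame.matrix(gtab),
                    total = as.integer(counts),
                    observed = as.integer(counts) > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(as.integer(sub("hap", "", tab$label))), ]
  rownames(tab) <- NULL
  structure(list(
    sites = geno$sites[idx, c("chrom", "pos")],
    assignment = data.frame(accession = geno$accession_ids, group = grp,
                            haplotype = haps, label = unname(lab_of),
                            stringsAsFactors = FALSE),
    table = tab,
    n_possible = length(possible)
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", nrow(x$sites), " missense site(s), ",
      x$n_possible, " possible haplotypes, ",
      sum(x$table$observed), " observed\n", sep = "")
  print(x$table[x$table$observed, ], ...)
  invisible(x)
}

#' Compare metabolite content between two haplotype groups
#'
#' Welch two-sample t-test on accession-mean log2 contents of one metabolite
#' between two accession sets (e.g. the carriers of two haplotypes). If both
#' sides have zero variance: equal means give `t = 0, p = 1` by convention;
#' different means give a separation call (`p = 0`, infinite t).
#'
#' @param m a log2-transformed [metabolite_matrix()].
#' @param accessions_a,accessions_b accession id vectors (each >= 2).
#' @param metabolite metabolite id.
#' @return list with `t`, `p`, `mean_a`, `mean_b`, `direction` (`"A > B"`,
#'   `"B > A"` or `"equal"`).
#' @export
compare_haplotype_content <- function(m, accessions_a, accessions_b,
                                      metabolite) {
  if (length(accessions_a) < 2 || length(accessions_b) < 2) {
    stop("each haplotype group needs at least 2 accessions")
  }
  A <- accession_means(m)
  if (!metabolite %in% colnames(A)) stop("unknown metabolite: ", metabolite)
  miss <- setdiff(c(accessions_a, accessions_b), rownames(A))
  if (length(miss)) stop("unknown accession(s): ", paste(miss, collapse = ", "))
  xa <- A[accessions_a, metabolite]
  xb <- A[accessions_b, metabolite]
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    if (mean(xa) == mean(xb)) {
      res <- list(t = 0, p = 1)
    } else {
      res <- list(t = sign(mean(xa) - mean(xb)) * Inf, p = 0)
    }
  } else {
    tt <- stats::t.test(xa, xb, var.equal = FALSE)
    res <- list(t = unname(tt$statistic), p = tt$p.value)
  }
  dir <- if (mean(xa) > mean(xb)) "A > B" else
    if (mean(xa) < mean(xb)) "B > A" else "equal"
  c(res, list(mean_a = mean(xa), mean_b = mean(xb), direction = dir))
}

#' Count fingerprint sites separating an accession from two reference panels
#'
#' Generic haplotype-novelty assessment: over the given sites (default all),
#' count how many sites have the accession matching the consensus of panel B
#' but not panel A, and vice versa. An accession carrying the wild-type
#' genotype but matching the cultivated panel's flanking variants is a novel
#' (recombinant) haplotype rather than an ancestral one.
#'
#' @param geno a [genotype_matrix()].
#' @param accessions accessions to assess.
#' @param panel_a,panel_b accession id vectors defining the two reference
#'   panels (consensus = majority allele; sites where a panel is tied are
#'   skipped).
#' @param site_idx optional site indices to restrict to (e.g. a locus
#'   neighbourhood).
#' @return data.frame with `accession`, `n_match_a_not_b`, `n_match_b_not_a`,
#'   `n_informative`.
#' @export
haplotype_novelty <- function(geno, accessions, panel_a, panel_b,
                              site_idx = NULL) {
  cols <- site_idx %||% seq_len(nrow(geno$sites))
  cons <- function(panel) {
    rows <- accession_rows(geno, panel)
    counts <- site_allele_counts(geno, rows)[, cols, drop = FALSE]
    apply(counts, 2, function(c) {
      top <- which(c == max(c))
      if (length(top) == 1) top else NA_integer_
    })
  }
  ca <- cons(panel_a)
  cb <- cons(panel_b)
  informative <- !is.na(ca) & !is.na(cb) & ca != cb
  rows <- accession_rows(geno, accessions)
  out <- lapply(seq_along(rows), function(k) {
    g <- geno$calls[rows[k], cols]
    data.frame(accession = accessions[k],
               n_match_a_not_b = sum(informative & g == ca),
               n_match_b_not_a = sum(informative & g == cb),
               n_informative = sum(informative),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
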