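#' Construct a haploid genotype matrix
#'
#' The central genotype container: an accessions x sites matrix of allele
#' indices over a list of SNP sites. Genotypes are haploid (one allele per
#' accession per site), which matches selfing species where each accession is
#' treated as a single sequence; homozygous diploid calls collapse to the
#' same representation. Missing genotypes are not allowed.
#'
#' @param calls integer matrix, accessions x sites; entry `calls[i, j]` is the
#'   1-based index into `sites$alleles[[j]]` of the allele carried by
#'   accession `i` at site `j`.
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   position, VCF convention) and `alleles` (list column of character
#'   vectors; first element is the reference allele).
#' @param accession_ids character vector of accession labels, one per row of
#'   `calls`.
#' @return an object of class `geno_matrix`.
#' @export
genotype_matrix <- function(calls, sites, accession_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(
    is.data.frame(sites),
    all(c("chrom", "pos", "alleles") %in% names(sites)),
    nrow(calls) == length(accession_ids),
    ncol(calls) == nrow(sites)
  )
  if (anyNA(calls)) stop("missing genotypes are not supported")
  if (any(sites$pos < 1)) stop("positions must be >= 1 (1-based)")
  by_chrom <- split(sites$pos, sites$chrom)
  if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("positions must be strictly increasing within each chromosome")
  }
  n_alleles <- lengths(sites$alleles)
  if (any(calls < 1L) || any(calls > n_alleles[col(calls)])) {
    stop("allele index out of range for its site")
  }
  rownames(calls) <- accession_ids
  structure(
    list(accession_ids = as.character(accession_ids),
         sites = sites, calls = calls),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$accession_ids), " accessions x ",
      nrow(x$sites), " sites on ",
      length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by accessions and/or sites
#'
#' @param geno a [genotype_matrix()].
#' @param accessions accession ids or row indices to keep (default all).
#' @param site_idx site indices to keep (default all).
#' @return a `geno_matrix`.
#' @export
geno_subset <- function(geno, accessions = NULL, site_idx = NULL) {
  rows <- if (is.null(accessions)) seq_along(geno$accession_ids) else
    accession_rows(geno, accessions)
  cols <- site_idx %||% seq_len(nrow(geno$sites))
  genotype_matrix(geno$calls[rows, cols, drop = FALSE],
                  geno$sites[cols, , drop = FALSE],
                  geno$accession_ids[rows])
}

accession_rows <- function(geno, accessions) {
  if (is.numeric(accessions)) return(as.integer(accessions))
  idx <- match(accessions, geno$accession_ids)
  if (anyNA(idx)) {
    stop("unknown accession(s): ",
         paste(accessions[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Build a group assignment table
#'
#' @param accession character vector of accession ids.
#' @param group character vector of group labels (e.g. `"Wb-NE"`, `"Wb-T"`,
#'   `"Cb-C"`), parallel to `accession`.
#' @return data.frame with columns `accession` and `group`; every accession
#'   belongs to exactly one group.
#' @export
group_assignment <- function(accession, group) {
  stopifnot(length(accession) == length(group))
  if (anyDuplicated(accession)) stop("each accession must appear exactly once")
  data.frame(accession = as.character(accession), group = as.character(group),
             stringsAsFactors = FALSE)
}

#' Rows of a genotype matrix belonging to one group
#' @noRd
group_rows <- function(geno, groups, group) {
  acc <- groups$accession[groups$group == group]
  if (length(acc) == 0) stop("no accessions in group '", group, "'")
  accession_rows(geno, acc)
}

#' Per-site allele counts for a set of accessions
#'
#' @param geno a `geno_matrix`.
#' @param rows integer row indices (accessions) to count over.
#' @return integer matrix `max_alleles x n_sites`; entry `[a, j]` is the
#'   number of selected accessions carrying allele `a` at site `j`.
#' @noRd
site_allele_counts <- function(geno, rows) {
  calls <- geno$calls[rows, , drop = FALSE]
  amax <- max(lengths(geno$sites$alleles))
  out <- matrix(0L, nrow = amax, ncol = ncol(calls))
  for (a in seq_len(amax)) out[a, ] <- .colSums(calls == a, nrow(calls), ncol(calls))
  out
}

#' Read a group assignment table from TSV
#'
#' Expects a header with columns `accession` and `group`.
#'
#' @param path TSV file path.
#' @return data.frame as from [group_assignment()].
#' @export
read_group_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "group") %in% names(df))) {
    stop("group table must have columns 'accession' and 'group'")
  }
  group_assignment(df$accession, df$group)
}

#' Read haploid SNP genotypes from a VCF file
#'
#' Accepts haploid GT fields (`0`, `1`, ...) or homozygous diploid calls
#' (`0/0`, `1|1`, ...). Heterozygous calls are rejected by default because
#' the downstream statistics assume one sequence per accession; with
#' `het = "major"` they are instead set to the site's major allele (among
#' unambiguous calls) and a warning reports how many were converted.
#'
#' @param path VCF file (v4.x, plain text or gzip).
#' @param het `"error"` (default) or `"major"`.
#' @return a [genotype_matrix()]. Indel records (where any allele is longer
#'   than 1 bp) are kept; use [classify_btr()] on records extracted with
#'   [vcf_indel_records()] for deletion genotyping.
#' @export
read_vcf_genotypes <- function(path, het = c("error", "major")) {
  het <- match.arg(het)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  first <- substr(gt, 1, 1)
  second <- sub("^.[/|]", "", gt)
  diploid <- nchar(gt) > 1
  hetero <- diploid & first != second
  if (any(hetero)) {
    if (het == "error") {
      stop("heterozygous calls found (", sum(hetero),
           "); haploid/homozygous input required, or use het = \"major\"")
    }
  }
  idx <- suppressWarnings(as.integer(first)) + 1L
  if (anyNA(idx)) stop("missing or unparseable GT calls are not supported")
  calls <- t(matrix(idx, nrow = nrow(gt), ncol = ncol(gt),
                    dimnames = dimnames(gt)))
  if (any(hetero)) {
    # replace each het call by the site's major allele among unambiguous calls
    het_t <- t(hetero)
    n_conv <- 0L
    for (j in seq_len(ncol(calls))) {
      hj <- het_t[, j]
      if (!any(hj)) next
      tab <- tabulate(calls[!hj, j])
      major <- if (length(tab)) which.max(tab) else 1L
      calls[hj, j] <- major
      n_conv <- n_conv + sum(hj)
    }
    warning(n_conv, " heterozygous call(s) set to the site major allele")
  }
  alleles <- mapply(function(ref, alt) c(ref, strsplit(alt, ",")[[1]]),
                    fix[, "REF"], fix[, "ALT"], SIMPLIFY = FALSE,
                    USE.NAMES = FALSE)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      stringsAsFactors = FALSE)
  sites$alleles <- alleles
  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(calls[, ord, drop = FALSE], sites[ord, , drop = FALSE],
                  colnames(gt))
}

#' Write a haploid genotype matrix as VCF v4.2
#'
#' Emits one record per site with haploid GT fields, plus any extra
#' pre-formatted records (used to inject indel records at domestication loci).
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @param extra_records optional data.frame of additional variant records with
#'   columns `chrom`, `pos`, `ref`, `alt` and one column per accession of
#'   0/1 haploid calls (as produced by [simulate_btr_locus()] after
#'   reshaping); may be `NULL`.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(geno, path, extra_records = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=popmetab",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  chroms <- unique(geno$sites$chrom)
  writeLines(sprintf("##contig=<ID=%s>", chroms), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$accession_ids), collapse = "\t"),
             con)
  ref <- vapply(geno$sites$alleles, `[`, character(1), 1)
  alt <- vapply(geno$sites$alleles, function(a) {
    if (length(a) > 1) paste(a[-1], collapse = ",") else "."
  }, character(1))
  gt <- t(geno$calls) - 1L  # sites x accessions, 0-based
  body <- paste(geno$sites$chrom, geno$sites$pos, ".", ref, alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  if (!is.null(extra_records)) {
    acc_cols <- as.matrix(extra_records[, geno$accession_ids, drop = FALSE])
    extra <- paste(extra_records$chrom, extra_records$pos, ".",
                   extra_records$ref, extra_records$alt, ".", "PASS", ".",
                   "GT",
                   apply(acc_cols, 1, paste, collapse = "\t"),
                   sep = "\t")
    body <- c(body, extra)
  }
  writeLines(body, con)
  invisible(path)
}

#' Extract per-accession indel records from a VCF
#'
#' Returns the long-format variant records [classify_btr()] consumes: one row
#' per accession per indel site (any record whose REF or an ALT allele is
#' longer than 1 bp).
#'
#' @param path VCF file.
#' @return data.frame with columns `accession`, `chrom`, `pos`, `ref`, `alt`,
#'   `gt` (0 = reference allele, 1 = first alternate).
#' @export
vcf_indel_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  is_indel <- nchar(fix[, "REF"]) > 1 |
    vapply(strsplit(fix[, "ALT"], ","),
           function(a) any(nchar(a) > 1), logical(1))
  if (!any(is_indel)) {
    return(data.frame(accession = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gt = integer(), stringsAsFactors = FALSE))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[is_indel, , drop = FALSE]
  fix <- fix[is_indel, , drop = FALSE]
  n_site <- nrow(fix)
  n_acc <- ncol(gt)
  data.frame(
    accession = rep(colnames(gt), each = n_site),
    chrom = rep(fix[, "CHROM"], n_acc),
    pos = rep(as.integer(fix[, "POS"]), n_acc),
    ref = rep(fix[, "REF"], n_acc),
    alt = rep(fix[, "ALT"], n_acc),
    gt = as.integer(substr(as.vector(gt), 1, 1)),
    stringsAsFactors = FALSE
  )
}
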