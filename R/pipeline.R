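#' Build a pipeline configuration
#'
#' All numeric knobs default to the method's canonical constants: 150 kb
#' windows with a 75 kb step and the <=10-SNP removal rule with a 95%
#' similarity retention threshold for the genomic-similarity scan; 20,000
#' permutations at p < 0.01 for the Fst outlier test; 1000 bootstrap
#' resamples and a 99% CI for Qst; the top-5% quantile for sweep windows.
#' Any override is recorded in the run manifest.
#'
#' @param vcf,groups_tsv,metabolite_tsv,annotation_tsv,gff input paths;
#'   unset inputs disable the stages that need them unless `simulate = TRUE`.
#' @param simulate if `TRUE`, a synthetic cohort is generated (and written to
#'   the output directory) instead of reading `vcf`/`groups_tsv`/
#'   `metabolite_tsv`.
#' @param sim_config [simulation_config()] used when `simulate = TRUE`.
#' @param pairs list of group-label pairs to analyse; default consecutive
#'   pairs of the groups' order of appearance (the evolutionary stages).
#' @param window_bp,step_bp sliding-window span and step (bp).
#' @param min_snps windows with at most this many SNPs are removed in the
#'   similarity scan.
#' @param similarity_threshold retention threshold for similarity windows.
#' @param n_perm,alpha permutation count and outlier level for the Fst test.
#' @param n_boot,ci_level bootstrap resamples and CI level for Qst.
#' @param sweep_quantile quantile defining sweep windows.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, groups_tsv = NULL,
                            metabolite_tsv = NULL, annotation_tsv = NULL,
                            gff = NULL, simulate = is.null(vcf),
                            sim_config = simulation_config(seed = seed),
                            pairs = NULL,
                            window_bp = 150000, step_bp = 75000,
                            min_snps = 10, similarity_threshold = 0.95,
                            n_perm = 20000, alpha = 0.01,
                            n_boot = 1000, ci_level = 0.99,
                            sweep_quantile = 0.95, seed = 1) {
  cfg <- list(vcf = vcf, groups_tsv = groups_tsv,
              metabolite_tsv = metabolite_tsv,
              annotation_tsv = annotation_tsv, gff = gff,
              simulate = isTRUE(simulate), sim_config = sim_config,
              pairs = pairs,
              window_bp = window_bp, step_bp = step_bp, min_snps = min_snps,
              similarity_threshold = similarity_threshold,
              n_perm = n_perm, alpha = alpha, n_boot = n_boot,
              ci_level = ci_level, sweep_quantile = sweep_quantile,
              seed = as.integer(seed))
  stopifnot(cfg$window_bp > 0, cfg$step_bp > 0, cfg$min_snps >= 0,
            cfg$similarity_threshold > 0, cfg$similarity_threshold <= 1,
            cfg$n_perm >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_boot >= 2, cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$sweep_quantile > 0, cfg$sweep_quantile <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `sim_config:` are passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, y$sim_config %||% list())
  y$sim_config <- NULL
  if (!is.null(y$pairs)) y$pairs <- lapply(y$pairs, unlist)
  do.call(pipeline_config, c(y, list(sim_config = sim)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the divergence-analysis pipeline end to end
#'
#' Stages, in order: `simulate` (optional synthetic cohort), `diversity`
#' (per-group summaries), `fst` (per-SNP AMOVA Fst with the permutation
#' outlier test, per stage pair), `similarity` (gene pools and sliding-window
#' similarity for all three pairwise comparisons, with Venn partition),
#' `qstscan` (per-metabolite Qst and divergence calls against the neutral
#' Fst of each stage), `sweeps` (windowed Fst, top-quantile windows, gene
#' mapping if a GFF is configured) and `btr` (deletion-genotype
#' classification from indel records in the VCF). Each stage writes its
#' TSV/BED outputs into `out_dir`; a JSON manifest records package version,
#' seeds, thresholds and input checksums. A stage failure aborts with an
#' error naming the stage; outputs of earlier stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (default all applicable).
#' @return named list with the in-memory results of each executed stage,
#'   invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "diversity", "fst",
                                    "similarity", "qstscan", "sweeps",
                                    "btr")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  inputs <- character()

  if (config$simulate && "simulate" %in% stages) {
    stop_stage("simulate", {
      groups <- simulate_group_assignment(config$sim_config)
      geno <- simulate_genotypes(config$sim_config, groups)
      metab <- simulate_metabolites(config$sim_config, groups)
      # Btr plan mirroring the canonical group pattern: wild ancestral all
      # wild-type, intermediate mixed, cultivated carrying one deletion each
      n_g <- config$sim_config$accessions_per_group
      plan_geno <- unlist(lapply(seq_along(n_g), function(g) {
        if (g == 1) rep("Btr1Btr2", n_g[g]) else
          rep(c("btr1Btr2", "Btr1btr2", "Btr1Btr2"), length.out = n_g[g])
      }))
      plan <- data.frame(accession = groups$accession,
                         genotype = plan_geno, stringsAsFactors = FALSE)
      btr_records <- simulate_btr_locus(config$sim_config, plan)
      write_cohort(file.path(out_dir, "simulated"), geno, groups, metab,
                   btr_records = btr_records)
      res$geno <- geno; res$groups <- groups; res$metab <- metab
      res$btr_records <- btr_records
      res$btr_plan <- plan
    })
  } else {
    stop_stage("load", {
      if (is.null(config$vcf) || is.null(config$groups_tsv)) {
        stop("vcf and groups_tsv are required when simulate = FALSE")
      }
      for (p in c(config$vcf, config$groups_tsv)) {
        if (!file.exists(p)) stop("input file not found: ", p)
      }
      inputs <- c(config$vcf, config$groups_tsv)
      res$geno <- read_vcf_genotypes(config$vcf)
      res$groups <- read_group_table(config$groups_tsv)
      if (!is.null(config$metabolite_tsv)) {
        if (!file.exists(config$metabolite_tsv)) {
          stop("metabolite table not found: ", config$metabolite_tsv)
        }
        inputs <- c(inputs, config$metabolite_tsv)
        res$metab <- read_metabolite_table(config$metabolite_tsv)
      }
    })
  }
  glabs <- unique(res$groups$group)
  pairs <- config$pairs %||%
    lapply(seq_len(length(glabs) - 1), function(i) glabs[c(i, i + 1)])
  stage_name <- vapply(pairs, paste, character(1), collapse = "_vs_")
  seeds <- fan_seeds(config$seed, 3)

  if ("diversity" %in% stages) {
    stop_stage("diversity", {
      res$diversity <- diversity_summary(res$geno, res$groups)
      write_tsv(res$diversity, file.path(out_dir, "diversity.tsv"))
    })
  }

  if ("fst" %in% stages) {
    stop_stage("fst", {
      res$fst <- lapply(seq_along(pairs), function(k) {
        permutation_outlier_test(res$geno, res$groups, pairs[[k]],
                                 n_perm = config$n_perm,
                                 alpha = config$alpha, seed = seeds[1])
      })
      names(res$fst) <- stage_name
      for (k in seq_along(pairs)) {
        write_tsv(as.data.frame(res$fst[[k]]),
                  file.path(out_dir, paste0("fst_", stage_name[k], ".tsv")))
        write_tsv(as.data.frame(res$fst[[k]][res$fst[[k]]$neutral, ]),
                  file.path(out_dir, paste0("neutral_", stage_name[k], ".tsv")))
      }
    })
  }

  if ("similarity" %in% stages && length(glabs) >= 3) {
    stop_stage("similarity", {
      pools <- lapply(glabs[1:3], function(g)
        build_gene_pool(res$geno, res$groups, g, seed = seeds[2]))
      cmb <- utils::combn(3, 2)
      sims <- lapply(seq_len(ncol(cmb)), function(k) {
        window_similarity(pools[[cmb[1, k]]], pools[[cmb[2, k]]],
                          window_bp = config$window_bp,
                          step_bp = config$step_bp,
                          min_snps_exclusive = config$min_snps,
                          retain_threshold = config$similarity_threshold)
      })
      names(sims) <- vapply(seq_len(ncol(cmb)), function(k)
        paste(glabs[cmb[1, k]], glabs[cmb[2, k]], sep = "_vs_"), character(1))
      res$similarity <- sims
      res$venn <- venn_partition(sims)
      for (k in seq_along(sims)) {
        write_windows_bed(sims[[k]][sims[[k]]$retained, ],
                          file.path(out_dir, paste0("similarity_",
                                                    names(sims)[k], ".bed")))
      }
      venn_df <- data.frame(cell = names(res$venn$counts),
                            n = as.integer(res$venn$counts))
      write_tsv(venn_df, file.path(out_dir, "similarity_venn.tsv"))
      write_tsv(res$venn$unique_by_chrom,
                file.path(out_dir, "similarity_unique_by_chrom.tsv"))
    })
  }

  if ("qstscan" %in% stages) {
    stop_stage("qstscan", {
      if (is.null(res$metab)) stop("metabolite data required (configure metabolite_tsv or simulate)")
      if (is.null(res$fst)) stop("run the fst stage first (neutral reference)")
      metab <- if (res$metab$log2) res$metab else log2_transform(res$metab)
      res$qst <- lapply(seq_along(pairs), function(k) {
        ref <- neutral_fst_reference(res$fst[[k]])
        qst_scan(metab, res$groups, pairs[[k]], neutral_fst = ref,
                 n_boot = config$n_boot, level = config$ci_level,
                 seed = seeds[3], stage = stage_name[k])
      })
      names(res$qst) <- stage_name
      for (k in seq_along(res$qst)) {
        write_tsv(res$qst[[k]],
                  file.path(out_dir, paste0("qst_", stage_name[k], ".tsv")))
      }
      if (length(res$qst) >= 2) {
        calls <- lapply(res$qst[1:2], function(q)
          q$metabolite[which(q$divergent)])
        venn <- stage_venn(calls[[1]], calls[[2]],
                           unique(res$qst[[1]]$metabolite))
        write_tsv(data.frame(quantity = c("n_stage1", "n_stage2", "n_common",
                                          "n_union", "n_total",
                                          "percent_common_of_all"),
                             value = c(venn$n_stage1, venn$n_stage2,
                                       venn$n_common, venn$n_union,
                                       venn$n_total,
                                       venn$percent_common_of_all)),
                  file.path(out_dir, "divergent_venn.tsv"))
        res$metab_venn <- venn
        if (!is.null(config$annotation_tsv)) {
          ann <- utils::read.delim(config$annotation_tsv,
                                   stringsAsFactors = FALSE)
          inputs <- c(inputs, config$annotation_tsv)
          res$class_summary <- class_summary(
            stats::setNames(calls, stage_name[1:2]), ann)
          write_tsv(res$class_summary,
                    file.path(out_dir, "divergent_classes.tsv"))
        }
      }
    })
  }

  if ("sweeps" %in% stages) {
    stop_stage("sweeps", {
      if (is.null(res$fst)) stop("run the fst stage first")
      res$sweeps <- lapply(res$fst, function(f) {
        sweep_regions(windowed_fst(f, window_bp = config$window_bp,
                                   step_bp = config$step_bp),
                      quantile = config$sweep_quantile)
      })
      for (k in seq_along(res$sweeps)) {
        write_windows_bed(res$sweeps[[k]],
                          file.path(out_dir, paste0("fst_windows_",
                                                    stage_name[k], ".bed")))
      }
      if (!is.null(config$gff)) {
        ann <- read_gene_annotation(config$gff)
        inputs <- c(inputs, config$gff)
        res$sweep_genes <- lapply(res$sweeps, function(s)
          map_windows_to_genes(s[s$is_sweep, ], ann))
        for (k in seq_along(res$sweep_genes)) {
          write_tsv(res$sweep_genes[[k]],
                    file.path(out_dir, paste0("sweep_genes_",
                                              stage_name[k], ".tsv")))
        }
      }
    })
  }

  if ("btr" %in% stages && (!is.null(res$btr_records) || !is.null(config$vcf))) {
    stop_stage("btr", {
      recs <- res$btr_records %||% vcf_indel_records(config$vcf)
      if (nrow(recs) > 0) {
        res$btr <- classify_btr(recs)
        write_tsv(res$btr[, c("accession", "btr1_allele", "btr2_allele",
                              "genotype")],
                  file.path(out_dir, "btr_genotypes.tsv"))
      }
    })
  }

  manifest <- list(
    package = "popmetab",
    version = as.character(utils::packageVersion("popmetab")),
    seed = config$seed,
    stages = stages,
    thresholds = config[c("window_bp", "step_bp", "min_snps",
                          "similarity_threshold", "n_perm", "alpha",
                          "n_boot", "ci_level", "sweep_quantile")],
    inputs = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
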