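#' Simulate a complete synthetic study bundle
#'
#' One call producing everything the pipeline consumes, with known ground
#' truth: a multigenerational pedigree, its additive relationship matrix,
#' heritable latent expression traits, negative-binomial sequencing counts
#' with a two-batch instrument structure, pleiotropic liver/depression-style
#' phenotypes driven by designated causal genes, and a small seeded gene-set
#' annotation. Optionally writes the bundle as plain-text files.
#'
#' @param n_families,n_generations,mean_sibship pedigree shape (defaults:
#'   20 families, 3 generations, mean sibship 4.5 — roughly 30 members per
#'   family, n near 600).
#' @param n_genes number of expression traits (default 200).
#' @param h2 per-gene heritability (default 0.4, recycled).
#' @param pheno_h2 phenotype polygenic heritability (default 0.35).
#' @param causal_effect effect size of each causal gene (default 0.5).
#' @param batch_offsets named log-scale batch shifts (default
#'   `c(hiseq = 0, novaseq = 0.5)`).
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional directory to write the bundle to.
#' @return list with `pedigree`, `A`, `latent`, `counts`, `gene_lengths`,
#'   `batch`, `phenotypes`, `truth`, `gene_sets`, and (if written) `paths`.
#' @export
simulate_study <- function(n_families = 20, n_generations = 3,
                           mean_sibship = 4.5, n_genes = 200, h2 = 0.4,
                           pheno_h2 = 0.35, causal_effect = 0.5,
                           batch_offsets = c(hiseq = 0, novaseq = 0.5),
                           dispersion = 0.1, seed = 1, out_dir = NULL) {
  ped <- simulate_pedigree(n_families, n_generations, mean_sibship,
                           seed = seed)
  A <- kinship_from_pedigree(ped)
  sim <- simulate_expression(ped, A, n_genes = n_genes, h2 = h2,
                             seed = seed + 1000L)
  genes <- colnames(sim$expr)
  # two pleiotropic causal genes with opposite-signed effects on the
  # depression trait, echoing the liver-up / depression-down pattern
  causal <- tibble(
    gene = rep(genes[1:2], each = 6),
    phenotype = rep(c("AST", "ALT", "AST_ALT", "CAP", "FAST", "BDI_II"), 2),
    effect = c(rep(causal_effect, 5), -causal_effect,
               rep(-causal_effect, 5), causal_effect)
  )
  ph <- simulate_phenotypes(ped, A, sim$truth, causal_genes = causal,
                            pheno_h2 = pheno_h2, seed = seed + 2000L)
  withr_seed(seed + 3000L)
  n <- nrow(ped)
  gene_lengths <- setNames(round(runif(n_genes, 500, 5000)), genes)
  library_sizes <- exp(rnorm(n, log(40), 0.3))
  batch <- sample(names(batch_offsets), n, replace = TRUE)
  counts <- simulate_counts(sim$expr, gene_lengths, library_sizes, batch,
                            batch_offsets, dispersion = dispersion,
                            seed = seed + 4000L)
  ph$phenotypes$batch <- batch
  truth <- ph$truth
  truth$batch_offsets <- batch_offsets
  # seeded annotation terms over the simulated genes
  withr_seed(seed + 5000L)
  terms <- tibble(
    term_id = sprintf("T%03d", 1:10),
    term_name = sprintf("synthetic term %d", 1:10),
    members = lapply(1:10, function(i)
      sample(genes, sample(2:max(2, min(30, n_genes - 1)), 1)))
  )
  sets <- gene_set_collection(terms, universe = genes)
  out <- list(pedigree = ped, A = A, latent = sim$expr, counts = counts,
              gene_lengths = gene_lengths, batch = batch,
              phenotypes = ph$phenotypes, truth = truth, gene_sets = sets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      pedigree = file.path(out_dir, "pedigree.csv"),
      counts = file.path(out_dir, "counts.tsv"),
      phenotypes = file.path(out_dir, "phenotypes.tsv"),
      gene_sets = file.path(out_dir, "gene_sets.gmt"),
      truth_h2 = file.path(out_dir, "truth_h2.tsv")
    )
    write_pedigree(ped, paths$pedigree)
    write_counts(counts, gene_lengths, paths$counts)
    write_phenotypes(ph$phenotypes, paths$phenotypes)
    writeLines(vapply(seq_len(nrow(terms)), function(i)
      paste(c(terms$term_id[i], terms$term_name[i], terms$members[[i]]),
            collapse = "\t"), ""), paths$gene_sets)
    write_commented(data.frame(gene = genes, true_h2 = truth$true_h2),
                    paths$truth_h2)
    out$paths <- paths
  }
  out
}

#' Read a pipeline run configuration
#'
#' YAML with fields `inputs` (paths: `pedigree` or `grm`, `counts`,
#' `phenotypes`, optional `gene_sets`), `out_dir`, `seed`, and options
#' `batch_correction` (default TRUE), `method` (ML/REML), `int_offset`
#' (inverse-normal rank offset) and `trait_set` (traits for the combined
#' test).
#'
#' @param path YAML file path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Config file not found: %s", path),
          class = "famendo_validation_error")
  yaml::read_yaml(path)
}

validate_config <- function(config) {
  if (is.null(config$inputs))
    abort("Config needs an `inputs` block.", class = "famendo_validation_error")
  need <- c("counts", "phenotypes")
  for (f in need)
    if (is.null(config$inputs[[f]]))
      abort(sprintf("Config input `%s` is required.", f),
            class = "famendo_validation_error")
  if (is.null(config$inputs$pedigree) && is.null(config$inputs$grm))
    abort("Config needs either a `pedigree` or a `grm` input.",
          class = "famendo_validation_error")
  for (f in names(config$inputs)) {
    p <- config$inputs[[f]]
    if (!is.null(p) && !file.exists(p))
      abort(sprintf("Input path does not exist: %s (%s)", p, f),
            class = "famendo_validation_error")
  }
  if (is.null(config$out_dir))
    abort("Config needs `out_dir`.", class = "famendo_validation_error")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$batch_correction <-
    if (is.null(config$batch_correction)) TRUE else isTRUE(config$batch_correction)
  config$method <- if (is.null(config$method)) "ML" else config$method
  config$int_offset <- if (is.null(config$int_offset)) 3/8 else config$int_offset
  if (is.null(config$trait_set))
    config$trait_set <- c("AST", "ALT", "AST_ALT", "CAP", "FAST", "BDI_II")
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: normalize (geTMM, optional batch removal, PCA
#' diagnostics before/after), prep (covariate residualization +
#' inverse-normal + sex test), heritability (per-gene polygenic fits),
#' endophenotypes (BLUP genetic values), scan (kinship-aware association of
#' every endophenotype with every prepared phenotype), combine (Fisher joint
#' test over the configured trait set) and enrich (hypergeometric
#' over-representation of the significant genes, when annotations are
#' given). Every output file carries the tool version, config hash and seed
#' in its comment header; a manifest records each stage and its outputs.
#' Rerunning with an identical config reproduces identical files.
#'
#' @param config a config list (see [read_run_config()]) or YAML path.
#' @return the output directory, invisibly; `manifest.tsv` inside lists the
#'   stages.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  hdr <- c(sprintf("# config_hash=%s", chash),
           sprintf("# seed=%d", config$seed))
  manifest <- list()
  note <- function(stage, files, status = "ok") {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, status = status,
      outputs = paste(basename(files), collapse = ";"),
      params_hash = chash)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "famendo_stage_error", parent = e)
    })
  }

  # --- load inputs
  A <- if (!is.null(config$inputs$pedigree)) {
    kinship_from_pedigree(read_pedigree(config$inputs$pedigree))
  } else {
    read_grm(config$inputs$grm, format = config$grm_format %||% "square_tsv",
             id_file = config$inputs$grm_ids)
  }
  counts <- read_counts(config$inputs$counts)
  pheno <- read_phenotypes(config$inputs$phenotypes)

  # --- normalize
  expr_final <- NULL
  run_stage("normalize", {
    norm <- getmm_normalize(counts, log_offset = config$log_offset %||% 0.5)
    files <- file.path(out_dir, "expression_getmm.tsv")
    write_expression(norm, files, extra = hdr)
    if (!is.null(pheno$batch)) {
      batch <- pheno$batch[match(colnames(norm$values), pheno$id)]
      pca_before <- pca_scores(norm, k = 2, batch = batch)
      f2 <- file.path(out_dir, "pca_before.tsv")
      write_commented(as.data.frame(pca_before), f2, extra = hdr)
      files <- c(files, f2)
      if (config$batch_correction) {
        norm <- remove_batch(norm, batch)
        f3 <- file.path(out_dir, "expression_corrected.tsv")
        write_expression(norm, f3, extra = hdr)
        pca_after <- pca_scores(norm, k = 2, batch = batch)
        f4 <- file.path(out_dir, "pca_after.tsv")
        write_commented(as.data.frame(pca_after), f4, extra = hdr)
        files <- c(files, f3, f4)
      }
    }
    note("normalize", files)
    expr_final <- norm
  })

  # --- prep
  prepared <- NULL
  run_stage("prep", {
    prepared <- prepare_phenotypes(pheno, offset = config$int_offset)
    f1 <- file.path(out_dir, "phenotypes_prepared.tsv")
    write_phenotypes(prepared, f1, extra = hdr)
    f2 <- file.path(out_dir, "prep_report.tsv")
    write_commented(as.data.frame(attr(prepared, "report")), f2, extra = hdr)
    note("prep", c(f1, f2))
  })

  # --- heritability + endophenotypes (expression traits prepared the same
  # way as the clinical phenotypes: residualize on age/sex, inverse-normal)
  ids <- intersect(pheno$id, colnames(expr_final$values))
  expr_t <- t(expr_final$values[, ids, drop = FALSE])
  age <- pheno$age[match(ids, pheno$id)]
  sex <- pheno$sex[match(ids, pheno$id)]
  expr_prep <- apply(expr_t, 2, function(v)
    inverse_normal(residualize(v, age, sex), offset = config$int_offset))
  rownames(expr_prep) <- ids
  eres <- NULL
  run_stage("heritability", {
    eres <- endophenotypes(expr_prep, A, method = config$method)
    f <- file.path(out_dir, "heritability_fits.tsv")
    write_commented(as.data.frame(eres$fits), f, extra = hdr)
    note("heritability", f)
  })
  run_stage("endophenotypes", {
    f <- file.path(out_dir, "endophenotypes.tsv")
    write_commented(data.frame(id = rownames(eres$endo), eres$endo,
                               check.names = FALSE), f, extra = hdr)
    note("endophenotypes", f)
  })

  # --- scan
  scan <- NULL
  run_stage("scan", {
    scan <- assoc_scan(eres$endo, prepared[prepared$id %in% ids, ], A,
                        method = config$method)
    f <- file.path(out_dir, "scan.tsv")
    write_commented(as.data.frame(scan), f, extra = hdr)
    note("scan", f)
  })

  # --- combine
  combined <- NULL
  run_stage("combine", {
    traits <- intersect(config$trait_set, unique(scan$phenotype))
    combined <- combine_scan(scan, traits = traits)
    f <- file.path(out_dir, "combined_tests.tsv")
    write_commented(as.data.frame(combined), f, extra = hdr)
    note("combine", f)
  })

  # --- enrich
  run_stage("enrich", {
    if (is.null(config$inputs$gene_sets)) {
      note("enrich", character(), status = "skipped")
    } else {
      sets <- read_gmt(config$inputs$gene_sets)
      sig <- unique(scan$gene[!is.na(scan$q) & scan$q < 0.05])
      if (!length(sig))
        sig <- combined$gene[order(combined$p_combined)][1:min(10, nrow(combined))]
      enr <- hypergeom_enrich(intersect(sig, sets$universe), sets)
      f <- file.path(out_dir, "enrichment.tsv")
      write_commented(as.data.frame(enr), f, extra = hdr)
      note("enrich", f)
    }
  })

  mf <- dplyr::bind_rows(manifest)
  write_commented(as.data.frame(mf), file.path(out_dir, "manifest.tsv"),
                  extra = hdr)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
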