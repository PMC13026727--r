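#' Simulate multigenerational family pedigrees
#'
#' Generates disjoint extended-family pedigrees of the kind used in
#' family-based quantitative-trait studies. Each family starts from a founding
#' couple; every mating produces a Poisson-distributed number of offspring, and
#' each offspring that goes on to reproduce marries an unrelated immigrant
#' founder. This mating scheme avoids inbreeding loops, so closed-form kinship
#' values (parent-offspring 0.25, full sibs 0.25, etc.) hold exactly.
#'
#' @param n_families number of independent families (positive integer).
#' @param n_generations number of generations including the founders
#'   (positive integer; `1` means founders only).
#' @param mean_sibship mean number of offspring per mating (positive real;
#'   Poisson distributed, minimum 0).
#' @param seed integer seed; the same seed reproduces the pedigree exactly.
#' @return A tibble with columns `id`, `father`, `mother` (`NA` for founders),
#'   `sex` (`"male"`/`"female"`) and `generation` (0 = founding generation).
#' @examples
#' ped <- simulate_pedigree(n_families = 2, n_generations = 3,
#'                          mean_sibship = 2, seed = 1)
#' table(ped$generation)
#' @export
simulate_pedigree <- function(n_families, n_generations, mean_sibship, seed) {
  if (length(n_families) != 1 || !is.finite(n_families) || n_families < 1)
    abort("`n_families` must be a positive integer.", class = "famendo_argument_error")
  if (length(n_generations) != 1 || !is.finite(n_generations) || n_generations < 1)
    abort("`n_generations` must be a positive integer.", class = "famendo_argument_error")
  if (length(mean_sibship) != 1 || !is.finite(mean_sibship) || mean_sibship <= 0)
    abort("`mean_sibship` must be a positive real.", class = "famendo_argument_error")
  n_families <- as.integer(n_families)
  n_generations <- as.integer(n_generations)

  withr_seed(seed)
  fams <- lapply(seq_len(n_families), function(f) {
    prefix <- sprintf("F%03d", f)
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("%s_I%04d", prefix, counter)
    }
    rows <- list()
    add <- function(id, father, mother, sex, gen) {
      rows[[length(rows) + 1L]] <<- tibble(
        id = id, father = father, mother = mother, sex = sex, generation = gen
      )
    }
    dad0 <- new_id(); mom0 <- new_id()
    add(dad0, NA_character_, NA_character_, "male", 0L)
    add(mom0, NA_character_, NA_character_, "female", 0L)
    matings <- list(c(dad0, mom0))
    for (g in seq_len(n_generations - 1L)) {
      next_matings <- list()
      for (m in matings) {
        n_kids <- rpois(1L, mean_sibship)
        if (n_kids == 0L) next
        for (k in seq_len(n_kids)) {
          kid <- new_id()
          kid_sex <- if (runif(1) < 0.5) "male" else "female"
          add(kid, m[1], m[2], kid_sex, g)
          if (g < n_generations - 1L) {
            # marry in an unrelated immigrant founder of the opposite sex
            spouse <- new_id()
            spouse_sex <- if (kid_sex == "male") "female" else "male"
            add(spouse, NA_character_, NA_character_, spouse_sex, g)
            pair <- if (kid_sex == "male") c(kid, spouse) else c(spouse, kid)
            next_matings[[length(next_matings) + 1L]] <- pair
          }
        }
      }
      matings <- next_matings
    }
    dplyr::bind_rows(rows)
  })
  ped <- dplyr::bind_rows(fams)
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks id uniqueness, that every named parent exists, that fathers are male
#' and mothers female, and that parent links are acyclic (no individual is its
#' own ancestor), by explicit ancestor traversal.
#'
#' @param ped pedigree tibble as produced by [simulate_pedigree()].
#' @return `ped`, invisibly, if valid; otherwise an error of class
#'   `famendo_structure_error`.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "father", "mother", "sex")
  if (!all(req %in% names(ped)))
    abort("Pedigree must have columns id, father, mother, sex.",
          class = "famendo_structure_error")
  if (anyDuplicated(ped$id))
    abort("Pedigree ids are not unique.", class = "famendo_structure_error")
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (col in c("father", "mother")) {
    named <- ped[[col]][!is.na(ped[[col]])]
    missing_par <- setdiff(named, ped$id)
    if (length(missing_par))
      abort(sprintf("Unknown %s id(s): %s", col,
                    paste(head(missing_par, 5), collapse = ", ")),
            class = "famendo_structure_error")
  }
  bad_f <- ped$sex[idx[ped$father[!is.na(ped$father)]]] != "male"
  bad_m <- ped$sex[idx[ped$mother[!is.na(ped$mother)]]] != "female"
  if (any(bad_f) || any(bad_m))
    abort("Fathers must be male and mothers female.",
          class = "famendo_structure_error")
  # acyclicity by ancestor-set traversal from every individual
  for (i in seq_len(nrow(ped))) {
    seen <- character()
    frontier <- c(ped$father[i], ped$mother[i])
    frontier <- frontier[!is.na(frontier)]
    while (length(frontier)) {
      if (ped$id[i] %in% frontier)
        abort(sprintf("Cyclic pedigree: %s is its own ancestor.", ped$id[i]),
              class = "famendo_structure_error")
      seen <- union(seen, frontier)
      j <- idx[frontier]
      frontier <- c(ped$father[j], ped$mother[j])
      frontier <- setdiff(frontier[!is.na(frontier)], seen)
    }
  }
  invisible(ped)
}

#' Simulate heritable expression traits on a pedigree
#'
#' For each gene the latent trait is the sum of an additive genetic component,
#' drawn from a zero-mean multivariate normal with covariance
#' `h2[j] * total_var * A` (via the symmetric eigen-factorization of `A`), and
#' an independent environmental component with variance
#' `(1 - h2[j]) * total_var`. The simulated genetic values are stored as ground
#' truth for parameter-recovery tests.
#'
#' @param ped pedigree tibble.
#' @param A additive relationship matrix over the pedigree roster
#'   (see [kinship_from_pedigree()]).
#' @param n_genes number of genes to simulate.
#' @param h2 per-gene heritabilities in `[0, 1]`; recycled to length `n_genes`.
#' @param total_var total trait variance per gene (default 1).
#' @param seed integer seed.
#' @return A list with `expr` (individuals x genes latent matrix, dimnames set)
#'   and `truth`, a `sim_truth` list carrying `true_h2`, `true_genetic_values`,
#'   `causal_genes` (empty; filled by [simulate_phenotypes()]), `batch_offsets`
#'   and `seed`.
#' @export
simulate_expression <- function(ped, A, n_genes, h2, total_var = 1, seed = 1) {
  stopifnot(n_genes >= 1)
  h2 <- rep_len(h2, n_genes)
  if (any(h2 < 0 | h2 > 1))
    abort("All `h2` values must lie in [0, 1].", class = "famendo_argument_error")
  if (total_var <= 0)
    abort("`total_var` must be positive.", class = "famendo_argument_error")
  A <- align_matrix(A, ped$id)
  n <- nrow(A)
  eig <- relationship_eigen(A)
  fac <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)

  withr_seed(seed)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  g_mat <- matrix(0, n, n_genes, dimnames = list(ped$id, gene_ids))
  e_mat <- matrix(0, n, n_genes)
  for (j in seq_len(n_genes)) {
    if (h2[j] > 0)
      g_mat[, j] <- sqrt(h2[j] * total_var) * as.vector(fac %*% rnorm(n))
    e_mat[, j] <- rnorm(n, sd = sqrt((1 - h2[j]) * total_var))
  }
  expr <- g_mat + e_mat
  truth <- structure(list(
    true_h2 = setNames(h2, gene_ids),
    true_genetic_values = g_mat,
    causal_genes = tibble(gene = character(), phenotype = character(),
                          effect = numeric()),
    batch_offsets = numeric(),
    seed = seed
  ), class = "sim_truth")
  list(expr = expr, truth = truth)
}

#' Simulate sequencing-like counts from latent expression
#'
#' Expected count for gene j in sample i is proportional to
#' `exp(latent[i, j] + batch_offset[batch[i]]) * gene_length[j] * library_size[i]`;
#' counts are drawn negative-binomial with a single global dispersion,
#' emulating RNA-seq overdispersion and a two-instrument batch structure.
#'
#' @param latent individuals x genes latent matrix (log scale).
#' @param gene_lengths per-gene lengths in bp.
#' @param library_sizes per-sample library scale factors.
#' @param batch per-sample batch labels.
#' @param batch_offsets named per-batch additive log-scale shifts.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion * mu^2).
#' @param seed integer seed.
#' @return genes x samples integer count matrix with dimnames.
#' @export
simulate_counts <- function(latent, gene_lengths, library_sizes, batch,
                            batch_offsets, dispersion = 0.1, seed = 1) {
  n <- nrow(latent); G <- ncol(latent)
  if (length(gene_lengths) != G || any(gene_lengths <= 0))
    abort("`gene_lengths` must be positive, one per gene.",
          class = "famendo_argument_error")
  if (length(library_sizes) != n || any(library_sizes <= 0))
    abort("`library_sizes` must be positive, one per sample.",
          class = "famendo_argument_error")
  if (length(batch) != n)
    abort("`batch` must have one label per sample.", class = "famendo_argument_error")
  if (dispersion <= 0)
    abort("`dispersion` must be positive.", class = "famendo_argument_error")
  offs <- batch_offsets[as.character(batch)]
  if (any(is.na(offs)))
    abort("Every batch label needs an entry in `batch_offsets`.",
          class = "famendo_argument_error")
  withr_seed(seed)
  # mu[g, s]: genes x samples
  mu <- exp(t(latent) + rep(offs, each = G)) *
    (gene_lengths / 1000) * rep(library_sizes, each = G)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = G, ncol = n,
                   dimnames = list(colnames(latent), rownames(latent)))
  counts
}

#' Simulate pleiotropic phenotypes with known causal genes
#'
#' Builds clinical-style phenotypes (defaults mirror liver-injury and
#' depression measures: AST, ALT, AST/ALT, CAP, FAST, kPa, BDI-II analogues).
#' Each phenotype is the sum of designated causal-gene genetic values times
#' their effect sizes, its own polygenic component with heritability
#' `pheno_h2`, age/sex covariate terms (age, sex, age^2, sex x age,
#' sex x age^2) and independent noise. Ages are uniform on 18-80 and sex is
#' Bernoulli(0.5).
#'
#' @param ped pedigree tibble.
#' @param A additive relationship matrix over the roster.
#' @param truth `sim_truth` from [simulate_expression()].
#' @param causal_genes tibble with columns `gene`, `phenotype`, `effect`;
#'   every gene must exist in `truth`.
#' @param pheno_h2 heritability of each phenotype's own polygenic term.
#' @param covariate_effects named numeric vector with any of
#'   `age`, `sex`, `age2`, `sex_age`, `sex_age2` (unnamed terms are 0).
#' @param phenotypes character vector of phenotype names to generate.
#' @param missing_rate optional per-phenotype missingness (named, default none),
#'   emulating incomplete elastography data.
#' @param seed integer seed.
#' @return A list with `phenotypes` (tibble: id, age, sex, one column per
#'   phenotype) and the updated `truth` carrying `causal_genes`.
#' @export
simulate_phenotypes <- function(ped, A, truth,
                                causal_genes = NULL,
                                pheno_h2 = 0.35,
                                covariate_effects = c(age = 0.02, sex = 0.3),
                                phenotypes = c("AST", "ALT", "AST_ALT", "CAP",
                                               "FAST", "kPa", "BDI_II"),
                                missing_rate = NULL,
                                seed = 1) {
  if (pheno_h2 < 0 || pheno_h2 > 1)
    abort("`pheno_h2` must lie in [0, 1].", class = "famendo_argument_error")
  if (is.null(causal_genes))
    causal_genes <- tibble(gene = character(), phenotype = character(),
                           effect = numeric())
  unknown <- setdiff(causal_genes$gene, colnames(truth$true_genetic_values))
  if (length(unknown))
    abort(sprintf("Causal gene(s) not in simulated truth: %s",
                  paste(unknown, collapse = ", ")),
          class = "famendo_argument_error")
  A <- align_matrix(A, ped$id)
  n <- nrow(A)
  eig <- relationship_eigen(A)
  fac <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)

  withr_seed(seed)
  age <- runif(n, 18, 80)
  sex <- rbinom(n, 1, 0.5)  # 1 = male
  eff <- function(nm) if (nm %in% names(covariate_effects)) covariate_effects[[nm]] else 0
  cov_term <- eff("age") * age + eff("sex") * sex + eff("age2") * age^2 +
    eff("sex_age") * sex * age + eff("sex_age2") * sex * age^2

  out <- tibble(id = ped$id, age = age,
                sex = ifelse(sex == 1, "male", "female"))
  for (ph in phenotypes) {
    y <- cov_term
    cg <- causal_genes[causal_genes$phenotype == ph, , drop = FALSE]
    if (nrow(cg))
      for (k in seq_len(nrow(cg)))
        y <- y + cg$effect[k] * truth$true_genetic_values[, cg$gene[k]]
    if (pheno_h2 > 0)
      y <- y + sqrt(pheno_h2) * as.vector(fac %*% rnorm(n))
    y <- y + rnorm(n, sd = sqrt(1 - pheno_h2))
    if (!is.null(missing_rate) && ph %in% names(missing_rate)) {
      drop <- runif(n) < missing_rate[[ph]]
      y[drop] <- NA_real_
    }
    out[[ph]] <- as.vector(y)
  }
  truth$causal_genes <- causal_genes
  list(phenotypes = out, truth = truth)
}

# seed helper: validate and set the RNG for a reproducible draw
withr_seed <- function(seed) {
  if (length(seed) != 1 || !is.finite(seed))
    abort("`seed` must be a single integer.", class = "famendo_argument_error")
  set.seed(as.integer(seed))
  invisible(seed)
}
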