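#' Residualize a trait on age and sex polynomial terms
#'
#' Ordinary least squares of the trait on intercept, age, sex, age squared,
#' sex-by-age and sex-by-age-squared, with sex coded 0/1. Residuals are
#' returned aligned to the input; missing trait values propagate as `NA`.
#'
#' @param trait numeric trait values (may contain `NA`).
#' @param age ages in years.
#' @param sex sex labels (`"male"`/`"female"`, factor, or 0/1).
#' @return numeric residual vector, same length as `trait`.
#' @export
residualize <- function(trait, age, sex) {
  sx <- code_sex(sex)
  keep <- !is.na(trait) & !is.na(age) & !is.na(sx)
  if (sum(keep) < 10)
    abort("At least 10 non-missing observations are required.",
          class = "famendo_argument_error")
  if (length(unique(sx[keep])) < 2)
    abort("Both sexes must be present.", class = "famendo_argument_error")
  X <- cbind(1, age, sx, age^2, sx * age, sx * age^2)[keep, , drop = FALSE]
  if (qr(X)$rank < ncol(X))
    abort("Rank-deficient covariate design (constant age?).",
          class = "famendo_design_error")
  fit <- lm.fit(X, trait[keep])
  out <- rep(NA_real_, length(trait))
  out[keep] <- fit$residuals
  out
}

code_sex <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("male", "m", "1"), 1,
                ifelse(s %in% c("female", "f", "0"), 0, NA_real_))
  if (any(is.na(out) & !is.na(sex)))
    abort("Unrecognized sex labels.", class = "famendo_argument_error")
  out
}

#' Rank-based inverse-normal transformation
#'
#' Maps values to normal quantiles of their ranks:
#' `z_i = qnorm((r_i - offset) / (n - 2*offset + 1))`, with the Blom offset
#' 3/8 by default (so the denominator is `n + 1/4`). Ties receive average
#' ranks, making the transform deterministic; missing values propagate.
#'
#' @param values numeric vector.
#' @param offset rank offset; 3/8 (Blom) by default, configurable to other
#'   conventions (e.g. 0.5 for van der Waerden-style scores).
#' @return numeric z-score vector aligned to the input.
#' @export
inverse_normal <- function(values, offset = 3/8) {
  keep <- !is.na(values)
  n <- sum(keep)
  if (n < 3)
    abort("At least 3 non-missing values are required.",
          class = "famendo_argument_error")
  v <- values[keep]
  if (max(v) == min(v))
    abort("All values identical: inverse-normal transform is undefined.",
          class = "famendo_degenerate_error")
  r <- rank(v, ties.method = "average")
  z <- qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(values))
  out[keep] <- z
  out
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where a-group values exceed b-group values, ties counting
#' one half. Exact mode enumerates every assignment of the pooled values into
#' groups (feasible for pooled n up to 20 and required below 13); normal mode
#' uses the tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @param mode `"auto"` (exact when pooled n <= 12), `"exact"` or `"normal"`.
#' @return a tibble with `U`, `p`, `n_a`, `n_b`, `mode`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    abort("Both groups must be non-empty.", class = "famendo_argument_error")
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U <- u_stat(a, b)
  mu <- n_a * n_b / 2
  if (mode == "exact") {
    if (N > 20)
      abort("Exact enumeration is limited to pooled n <= 20; use mode = \"normal\".",
            class = "famendo_resource_error")
    pooled <- c(a, b)
    combos <- combn(N, n_a)
    us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
  }
  tibble(U = U, p = min(p, 1), n_a = n_a, n_b = n_b, mode = mode)
}

#' Prepare analysis-ready phenotypes
#'
#' For each trait column: residualize on the age/sex polynomial
#' ([residualize()]), then inverse-normal transform the residuals
#' ([inverse_normal()]). Missing values are dropped pairwise per trait. A
#' per-trait report records sample size and the Mann-Whitney sex-difference
#' test on the raw trait.
#'
#' @param pheno tibble with `id`, `age`, `sex` and trait columns.
#' @param traits character vector of trait column names (default: every
#'   column other than id/age/sex/batch).
#' @param offset inverse-normal rank offset (default Blom 3/8).
#' @return a tibble `id`, `age`, `sex` plus transformed traits, with a
#'   `report` attribute (tibble: trait, n, U, p_sex).
#' @export
prepare_phenotypes <- function(pheno, traits = NULL, offset = 3/8) {
  if (is.null(traits))
    traits <- setdiff(names(pheno), c("id", "age", "sex", "batch"))
  out <- pheno[c("id", "age", "sex")]
  rep_rows <- vector("list", length(traits))
  sx <- code_sex(pheno$sex)
  for (i in seq_along(traits)) {
    tr <- traits[i]
    res <- residualize(pheno[[tr]], pheno$age, pheno$sex)
    out[[tr]] <- inverse_normal(res, offset = offset)
    raw <- pheno[[tr]]
    mw <- mann_whitney(raw[sx == 1 & !is.na(raw)],
                       raw[sx == 0 & !is.na(raw)], mode = "normal")
    rep_rows[[i]] <- tibble(trait = tr, n = sum(!is.na(raw)),
                            U = mw$U, p_sex = mw$p)
  }
  attr(out, "report") <- dplyr::bind_rows(rep_rows)
  out
}
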