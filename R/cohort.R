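# Synthetic two-group biomarker cohort generator.
#
# Marginals: lognormal per group/variable, moment-matched in closed form to
# a target (mean, SD).  Reported "mean +/- x" cells are interpreted as mean
# +/- SEM by default, so SD = SEM * sqrt(n) (overridable).  Dependence:
# Gaussian copula calibrated to target Spearman rank correlations via
# rho_latent = 2 sin(pi * r_s / 6); rank correlations are preserved exactly
# by the monotone lognormal transforms, so recovery does not depend on how
# heavy the marginal tails are.

#' Cohort generator specification
#'
#' Defines a two-group (PDA / aPDA) cohort with a day-3 and day-5 serum
#' biomarker level and two echocardiographic indices (duct diameter, LA/AO
#' ratio) per subject.
#'
#' @param n_per_group named integer vector, e.g. `c(aPDA = 56, PDA = 13)`.
#' @param biomarker named list per group: each a list with `mean3`, `se3`,
#'   `mean5`, `se5` (pg/mL).
#' @param indices named list per group: each a list with `diam_mean`,
#'   `diam_sd` (mm), `laao_mean`, `laao_sd`.
#' @param rank_cor target Spearman correlations, named list with `d3_diam`,
#'   `d5_diam`, `d5_laao`, `d3_laao`, `d3_d5`, `diam_laao`.
#' @param se_is_sem if `TRUE` (default) `se3`/`se5` are standard errors of
#'   the mean and the marginal SD is `se * sqrt(n_ref)`; if `FALSE` they are
#'   SDs already.
#' @param n_ref named integer vector: the group sizes the reported SEMs
#'   refer to (the source study's group sizes), used for the SEM-to-SD
#'   conversion regardless of how many subjects are generated.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(aPDA = 56, PDA = 13),
                        biomarker = list(
                          aPDA = list(mean3 = 10068, se3 = 1361, mean5 = 3116, se5 = 665),
                          PDA  = list(mean3 = 48539, se3 = 8114, mean5 = 19713, se5 = 5730)),
                        indices = list(
                          aPDA = list(diam_mean = 1.8, diam_sd = 0.5,
                                      laao_mean = 1.2, laao_sd = 0.15),
                          PDA  = list(diam_mean = 2.5, diam_sd = 0.6,
                                      laao_mean = 1.5, laao_sd = 0.2)),
                        rank_cor = list(d3_diam = 0.856, d5_diam = 0.528,
                                        d5_laao = 0.721, d3_laao = 0.62,
                                        d3_d5 = 0.60, diam_laao = 0.68),
                        se_is_sem = TRUE, n_ref = c(aPDA = 56, PDA = 13),
                        seed = 1) {
  grps <- names(n_per_group)
  if (is.null(grps) || length(grps) < 1L) stop("`n_per_group` must be named", call. = FALSE)
  if (any(n_per_group < 1)) stop("group sizes must be >= 1", call. = FALSE)
  for (g in grps) {
    b <- biomarker[[g]]
    if (is.null(b) || any(unlist(b) <= 0)) {
      stop(sprintf("biomarker parameters for group '%s' must be positive", g), call. = FALSE)
    }
  }
  rc <- unlist(rank_cor)
  if (any(rc <= -1 | rc >= 1)) stop("rank correlations must lie in (-1, 1)", call. = FALSE)
  if (isTRUE(se_is_sem) && !all(grps %in% names(n_ref))) {
    stop("`n_ref` must name every group when `se_is_sem = TRUE`", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, biomarker = biomarker,
                 indices = indices, rank_cor = rank_cor,
                 se_is_sem = isTRUE(se_is_sem), n_ref = n_ref, seed = seed),
            class = "cohort_spec")
}

# lognormal parameters matching a target mean/SD
lognorm_params <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("moments must be positive", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# latent Gaussian correlation giving Spearman rho_s under a Gaussian copula
latent_from_spearman <- function(r_s) 2 * sin(pi * r_s / 6)

# latent 4x4 correlation matrix; variable order: d3, d5, diam, laao
latent_matrix <- function(rank_cor) {
  R <- diag(4)
  pairs <- list(c(1, 2, "d3_d5"), c(1, 3, "d3_diam"), c(1, 4, "d3_laao"),
                c(2, 3, "d5_diam"), c(2, 4, "d5_laao"), c(3, 4, "diam_laao"))
  for (p in pairs) {
    i <- as.integer(p[1]); j <- as.integer(p[2])
    R[i, j] <- R[j, i] <- latent_from_spearman(rank_cor[[p[3]]])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop("rank-correlation targets yield a non-positive-definite copula", call. = FALSE)
  }
  R
}

#' Generate a synthetic cohort
#'
#' Draws, per group, a latent multivariate normal (via the Cholesky factor
#' of the calibrated copula correlation), transforms each coordinate through
#' its moment-matched lognormal marginal, and assembles the per-subject
#' table.  Deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id`, `group`, `ntprobnp_d3`,
#'   `ntprobnp_d5`, `duct_diameter`, `la_ao_ratio`.
#' @export
#' @examples
#' head(generate_cohort(cohort_spec(seed = 42)))
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  R <- latent_matrix(spec$rank_cor)
  ch <- chol(R)
  out <- with_seed(spec$seed, {
    rows <- lapply(names(spec$n_per_group), function(g) {
      n <- spec$n_per_group[[g]]
      b <- spec$biomarker[[g]]; ix <- spec$indices[[g]]
      f <- if (spec$se_is_sem) sqrt(spec$n_ref[[g]]) else 1
      pars <- list(lognorm_params(b$mean3, b$se3 * f),
                   lognorm_params(b$mean5, b$se5 * f),
                   lognorm_params(ix$diam_mean, ix$diam_sd),
                   lognorm_params(ix$laao_mean, ix$laao_sd))
      Z <- matrix(rnorm(n * 4), n, 4) %*% ch
      X <- vapply(1:4, function(j) exp(pars[[j]]$mu + pars[[j]]$sigma * Z[, j]),
                  numeric(n))
      data.frame(group = g, ntprobnp_d3 = X[, 1], ntprobnp_d5 = X[, 2],
                 duct_diameter = X[, 3], la_ao_ratio = X[, 4],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- cbind(id = sprintf("S%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Read / write a cohort CSV
#'
#' Column layout: `id,group,ntprobnp_d3,ntprobnp_d5,duct_diameter,la_ao_ratio`.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns the data.frame; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "ntprobnp_d3", "ntprobnp_d5",
            "duct_diameter", "la_ao_ratio")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("cohort file lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  num <- need[-(1:2)]
  bad <- !vapply(x[num], function(v) all(is.finite(v) & v >= 0), TRUE)
  if (any(bad)) {
    stop(sprintf("non-finite or negative values in: %s",
                 paste(num[bad], collapse = ", ")), call. = FALSE)
  }
  x
}

#' @rdname read_cohort
#' @param cohort data.frame as returned by [generate_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
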