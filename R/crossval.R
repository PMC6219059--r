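#' Partition a phenotype table into partial and masked records
#'
#' `scheme = "random"` masks `floor(fraction * n)` records at random;
#' `scheme = "cutoff"` masks all records of generations `>= cutoff` (the
#' table needs a `generation` column). The validation set is defined as the
#' individuals with at least one masked record.
#'
#' @param phenotypes Record table (one row per record).
#' @param fraction Fraction of records to mask under the random scheme.
#' @param scheme `"random"` or `"cutoff"`.
#' @param cutoff First masked generation under the cutoff scheme.
#' @param id Name of the id column.
#' @return A list with `partial` (records kept), `masked` (records removed)
#'   and `validation_ids` (character).
#' @export
make_partition <- function(phenotypes, fraction = 0.5,
                           scheme = c("random", "cutoff"), cutoff = NULL,
                           id = "id") {
  scheme <- match.arg(scheme)
  n <- nrow(phenotypes)
  if (scheme == "random") {
    stopifnot(fraction >= 0, fraction < 1)
    n_mask <- floor(fraction * n)
    drop <- sort(sample.int(n, n_mask))
  } else {
    if (is.null(cutoff)) stop("cutoff scheme needs `cutoff`", call. = FALSE)
    if (!"generation" %in% names(phenotypes)) {
      stop("cutoff scheme needs a `generation` column", call. = FALSE)
    }
    drop <- which(phenotypes$generation >= cutoff)
  }
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) == 0) stop("partition removes every record", call. = FALSE)
  list(partial = phenotypes[keep, , drop = FALSE],
       masked = phenotypes[drop, , drop = FALSE],
       validation_ids = unique(as.character(phenotypes[[id]][drop])))
}

# canonical names of the replicate statistics table
lr_statistic_names <- c(
  "h2", "b_wp", "b_wp_r", "b_wp_v", "b_pw", "b_pw_r", "b_pw_v",
  "rho_wp", "rho_wp_r", "rho_wp_v", "r_yr_ur", "r_yv_uv",
  "d_wp_r", "d_wp_v", "vd_wp_r", "vd_wp_v")

#' One LR cross-validation replicate
#'
#' Solves the animal model on the whole and on one partial dataset and
#' returns the 16 comparison statistics (heritability; slopes, correlations
#' and EBV changes overall and within the reference / validation subsets;
#' predictivity of precorrected phenotypes in both subsets) plus the bias
#' statistics `mu_wp`, `mu_wp_r`, `mu_wp_v`.
#'
#' @param whole Whole record table.
#' @param partial Partial record table (a subset of `whole`'s rows).
#' @param validation_ids Individuals whose records were masked.
#' @param K Relationship matrix.
#' @param vc [variance_components()] used for both solves.
#' @param fixed Fixed-effect formula.
#' @param reml If `TRUE`, re-estimate `h2` on the partial data by
#'   [em_reml()].
#' @param use_reml_components If `TRUE` (and `reml`), the partial-data solve
#'   uses its own REML estimates, emulating an analysis pipeline that
#'   re-estimates components per dataset; by default the supplied `vc` is
#'   used for both solves, matching the derivation of the LR expectations
#'   under a single variance structure.
#' @param reml_tol,reml_max_iter Convergence controls forwarded to
#'   [em_reml()].
#' @param id,response Column names.
#' @return A one-row tibble.
#' @export
run_lr_replicate <- function(whole, partial, validation_ids, K, vc,
                             fixed = ~1, reml = FALSE,
                             use_reml_components = FALSE, id = "id",
                             response = "y", reml_tol = 1e-6,
                             reml_max_iter = 2000) {
  fit_w <- solve_mme(whole, K, vc, fixed = fixed, response = response,
                     id = id, pev = FALSE, data_tag = "whole")
  vc_p <- vc
  h2 <- vc$h2
  if (reml) {
    est <- em_reml(partial, K, start = vc, fixed = fixed,
                   response = response, id = id, tol = reml_tol,
                   max_iter = reml_max_iter)
    h2 <- est$h2
    if (use_reml_components) vc_p <- est
  }
  fit_p <- solve_mme(partial, K, vc_p, fixed = fixed, response = response,
                     id = id, pev = FALSE, data_tag = "partial")
  phen_ids <- unique(as.character(whole[[id]]))
  pair <- tibble::tibble(
    id = phen_ids,
    ebv_partial = unname(fit_p$u[phen_ids]),
    ebv_whole = unname(fit_w$u[phen_ids]),
    subset = ifelse(phen_ids %in% validation_ids, "validation", "reference"))
  ystar <- precorrect(whole, fit_w)
  ystar_by_id <- tapply(ystar$y_star, as.character(whole[[id]]), mean)
  pair$y_star <- unname(ystar_by_id[pair$id])
  lr_replicate_row(pair, h2)
}

lr_replicate_row <- function(pair, h2) {
  na_row <- list(mu = NA_real_, b_wp = NA_real_, b_pw = NA_real_,
                 rho = NA_real_, d = NA_real_, vd = NA_real_, r = NA_real_)
  st <- function(rows) {
    if (sum(rows) < 2) return(na_row)  # empty/degenerate subset
    up <- pair$ebv_partial[rows]; uw <- pair$ebv_whole[rows]
    ch <- ebv_change(up, uw)
    list(mu = mu_wp(up, uw), b_wp = slope_w_on_p(up, uw),
         b_pw = slope_p_on_w(up, uw), rho = rho_w_p(up, uw),
         d = ch$d_wp, vd = ch$vd_wp,
         r = predictivity(pair$y_star[rows], up))
  }
  a <- st(rep(TRUE, nrow(pair)))
  r <- st(pair$subset == "reference")
  v <- st(pair$subset == "validation")
  tibble::tibble(
    h2 = h2,
    b_wp = a$b_wp, b_wp_r = r$b_wp, b_wp_v = v$b_wp,
    b_pw = a$b_pw, b_pw_r = r$b_pw, b_pw_v = v$b_pw,
    rho_wp = a$rho, rho_wp_r = r$rho, rho_wp_v = v$rho,
    r_yr_ur = r$r, r_yv_uv = v$r,
    d_wp_r = r$d, d_wp_v = v$d, vd_wp_r = r$vd, vd_wp_v = v$vd,
    mu_wp = a$mu, mu_wp_r = r$mu, mu_wp_v = v$mu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicated LR cross-validation of one dataset
#'
#' Repeatedly masks records of a (real or simulated) whole dataset, runs the
#' paired partial/whole evaluations, and collects the per-replicate LR
#' statistics. Replicates whose partial design becomes rank deficient (a
#' masked-out fixed-effect level) are skipped and logged.
#'
#' @inheritParams run_lr_replicate
#' @param phenotypes Whole record table.
#' @param fraction Masking fraction per replicate.
#' @param n_rep Number of replicates.
#' @param seed Optional seed set before the replicate loop.
#' @return An object of class `"lr_crossval"`: list with `replicates`
#'   (tibble, one row per successful replicate), `failed` (indices of skipped
#'   replicates), and `settings`.
#' @export
lr_crossval <- function(phenotypes, K, vc, fixed = ~1, fraction = 0.5,
                        n_rep = 100, reml = FALSE,
                        use_reml_components = FALSE, seed = NULL, id = "id",
                        response = "y", reml_tol = 1e-6,
                        reml_max_iter = 2000) {
  stopifnot(n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_rep)
  failed <- integer(0)
  for (r in seq_len(n_rep)) {
    part <- make_partition(phenotypes, fraction = fraction, id = id)
    row <- tryCatch(
      run_lr_replicate(phenotypes, part$partial, part$validation_ids, K, vc,
                       fixed = fixed, reml = reml,
                       use_reml_components = use_reml_components, id = id,
                       response = response, reml_tol = reml_tol,
                       reml_max_iter = reml_max_iter),
      error = function(e) e)
    if (inherits(row, "error")) {
      failed <- c(failed, r)
      warning("replicate ", r, " skipped: ", conditionMessage(row),
              call. = FALSE)
    } else {
      reps[[r]] <- dplyr::bind_cols(tibble::tibble(replicate = r), row)
    }
  }
  structure(list(
    replicates = dplyr::bind_rows(reps), failed = failed,
    settings = list(fraction = fraction, n_rep = n_rep, reml = reml,
                    vc = vc, seed = seed)
  ), class = "lr_crossval")
}

#' @export
print.lr_crossval <- function(x, ...) {
  cat(sprintf("LR cross-validation: %d replicates (%d failed), masking fraction %.2f\n",
              x$settings$n_rep, length(x$failed), x$settings$fraction))
  print(summarize_replicates(x)$summary, n = 5)
  invisible(x)
}

#' Summarize replicate statistics
#'
#' Mean, SD, min and max of each statistic over replicates, plus the Pearson
#' correlation matrix among the statistics. Correlations with a constant
#' statistic are reported as `NA`.
#'
#' @param replicates An [lr_crossval()] / [lr_sim_experiment()] object or
#'   their `replicates` tibble.
#' @return List of class `"lr_cv_summary"` with `summary` (tibble:
#'   `statistic`, `mean`, `sd`, `min`, `max`) and `correlations` (matrix).
#' @export
summarize_replicates <- function(replicates) {
  if (inherits(replicates, c("lr_crossval", "lr_experiment"))) {
    replicates <- replicates$replicates
  }
  stopifnot(is.data.frame(replicates), nrow(replicates) >= 2)
  num <- replicates[setdiff(names(replicates)[vapply(replicates, is.numeric,
                                                     logical(1))],
                            "replicate")]
  summary <- purrr::map_dfr(names(num), function(s) {
    x <- num[[s]]
    tibble::tibble(statistic = s, mean = mean(x), sd = stats::sd(x),
                   min = min(x), max = max(x))
  })
  cors <- suppressWarnings(stats::cor(as.matrix(num)))
  cors[!is.finite(cors)] <- NA_real_
  diag(cors) <- 1
  structure(list(summary = summary, correlations = cors),
            class = "lr_cv_summary")
}

#' @export
print.lr_cv_summary <- function(x, ...) {
  print(x$summary, n = Inf)
  invisible(x)
}

#' Simulation experiment comparing LR statistics with their expectations
#'
#' Builds one fixed design — pedigree, contemporary-group assignment and
#' effects, masking pattern — from a [sim_config()], then replicates the
#' random draws of breeding values and residuals, solving the partial and
#' whole mixed models for every replicate (reusing the factorized
#' coefficient matrices when the mask is fixed). Because the true breeding
#' values are known, the replicate table carries both the LR statistics and
#' their direct oracles (empirical accuracies, the regression of TBV on
#' partial EBV). The theoretical expectations are computed once from the
#' exact PEV/PEC blocks of the two designs.
#'
#' @param config A [sim_config()].
#' @param n_rep Number of replicates.
#' @param fraction Masking fraction (floor rule, random records).
#' @param resample_mask If `TRUE`, draw a fresh random mask each replicate
#'   (the coefficient matrix is then refactorized per replicate and the
#'   reported expectations refer to the first mask).
#' @param seed Optional seed.
#' @param validation_ids Optional explicit validation set (ids); overrides
#'   the random mask and masks exactly those individuals' records.
#' @return Object of class `"lr_experiment"`: list with `replicates`
#'   (statistics on the validation set per replicate, plus oracle columns
#'   `acc_p_emp`, `acc_w_emp`, `b_true`), `expectations` (from
#'   [lr_expectations()]), `validation_ids`, `vc`, `config`, `seed`.
#' @export
lr_sim_experiment <- function(config, n_rep = 500, fraction = 0.5,
                              resample_mask = FALSE, seed = NULL,
                              validation_ids = NULL) {
  stopifnot(inherits(config, "sim_config"), n_rep >= 2)
  if (!is.null(seed)) set.seed(seed)
  vc <- variance_components(config$sigma2_u, config$sigma2_e)
  ped <- simulate_pedigree(config)
  K <- nrm(ped)
  F <- diag(K) - 1
  u0 <- simulate_tbv(ped, config$sigma2_u, F = F)
  phen0 <- simulate_phenotypes(ped, u0, config)
  beta <- stats::setNames(attr(phen0, "beta")$effect, attr(phen0, "beta")$cg)

  draw_mask <- function() {
    if (!is.null(validation_ids)) {
      which(phen0$id %in% validation_ids)
    } else {
      sort(sample.int(nrow(phen0), floor(fraction * nrow(phen0))))
    }
  }
  mask <- draw_mask()
  if (length(mask) == 0 || length(mask) == nrow(phen0)) {
    stop("mask must remove some but not all records", call. = FALSE)
  }
  val_ids <- unique(phen0$id[mask])

  fixed <- if (config$n_groups > 1) ~cg else ~1
  sys_w <- mme_build(phen0, K, vc, fixed = fixed)
  build_partial <- function(mask) {
    mme_build(droplevels_cg(phen0[-mask, , drop = FALSE]), K, vc,
              fixed = fixed)
  }
  sys_p <- build_partial(mask)

  expectations <- lr_expectations_from_systems(sys_p, sys_w, K, vc, val_ids)

  mu_cg <- beta[as.character(phen0$cg)]
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    if (resample_mask && r > 1) {
      mask <- draw_mask()
      val_ids <- unique(phen0$id[mask])
      sys_p <- build_partial(mask)
    }
    u <- simulate_tbv(ped, config$sigma2_u, F = F)
    y <- mu_cg + u[phen0$id] + stats::rnorm(nrow(phen0), 0,
                                            sqrt(config$sigma2_e))
    sol_w <- mme_solve_y(sys_w, y)
    sol_p <- mme_solve_y(sys_p, y[-mask])
    up <- sol_p$u[val_ids]
    uw <- sol_w$u[val_ids]
    uu <- u[val_ids]
    # whole-data precorrection of the masked (validation) records
    Xb_w <- fitted_fixed(sys_w, sol_w$beta)
    ystar <- y[mask] - Xb_w[mask]
    ystar_by_id <- tapply(ystar, phen0$id[mask], mean)[val_ids]
    ch <- ebv_change(up, uw)
    reps[[r]] <- tibble::tibble(
      replicate = r,
      mu_wp = mu_wp(up, uw),
      b_wp = slope_w_on_p(up, uw),
      b_pw = slope_p_on_w(up, uw),
      rho_wp = rho_w_p(up, uw),
      rho2_cov = as.numeric(rho2_cov(up, uw, K, focal = val_ids,
                                     sigma2_u_inf = vc$sigma2_u_inf)),
      d_wp = ch$d_wp, vd_wp = ch$vd_wp,
      predictivity = predictivity(as.numeric(ystar_by_id), up),
      acc_p_emp = stats::cor(uu, up),
      acc_w_emp = stats::cor(uu, uw),
      b_true = cov_n(up, uu) / cov_n(up))
  }
  structure(list(
    replicates = dplyr::bind_rows(reps),
    expectations = expectations,
    validation_ids = val_ids, vc = vc, config = config, seed = seed,
    resample_mask = resample_mask
  ), class = "lr_experiment")
}

droplevels_cg <- function(df) {
  df$cg <- droplevels(df$cg)
  df
}

fitted_fixed <- function(sys, beta) as.numeric(sys$X %*% beta)

# expectations straight from two factorized systems (avoids refitting)
lr_expectations_from_systems <- function(sys_p, sys_w, K, vc, focal) {
  fit_from <- function(sys, tag) {
    Cinv <- mme_inverse(sys)
    ui <- sys$p + seq_len(sys$q)
    C_uu <- vc$sigma2_e * Cinv[ui, ui]
    dimnames(C_uu) <- list(sys$ids, sys$ids)
    structure(list(C_uu = C_uu, vc = vc, data_tag = tag), class = "blup_fit")
  }
  lr_expectations(fit_from(sys_p, "partial"), fit_from(sys_w, "whole"),
                  K, vc, focal)
}

#' @export
print.lr_experiment <- function(x, ...) {
  cat(sprintf("LR simulation experiment: %d replicates, %d validation animals\n",
              nrow(x$replicates), length(x$validation_ids)))
  obs <- colMeans(x$replicates[c("mu_wp", "b_wp", "b_pw", "rho_wp",
                                 "rho2_cov")])
  exp <- unlist(x$expectations[c("expected_mu_wp", "expected_b_wp",
                                 "expected_b_pw", "expected_rho_wp",
                                 "expected_rho2_cov")])
  print(tibble::tibble(statistic = names(obs), observed_mean = unname(obs),
                       expected = unname(exp)))
  invisible(x)
}

#' Correlation between pedigree-based and genomic EBV
#'
#' The across-individual correlation of EBV from two models on the same data
#' (`rho_AG`), interpreted under the LR assumptions as the ratio of their
#' population accuracies `acc_A / acc_G`: the lower the correlation, the
#' larger the gain from the genomic model.
#'
#' @param ebv_a,ebv_g Named EBV vectors (e.g. `fit$u`) from the pedigree- and
#'   marker-based evaluations.
#' @param focal Ids over which to compute the correlation (default: common
#'   names).
#' @return One-row tibble with `n` and `rho_ag`.
#' @export
compare_models <- function(ebv_a, ebv_g, focal = NULL) {
  if (is.null(focal)) focal <- intersect(names(ebv_a), names(ebv_g))
  stopifnot(length(focal) >= 2)
  a <- ebv_a[focal]; g <- ebv_g[focal]
  if (anyNA(a) || anyNA(g)) stop("focal ids missing from an EBV vector",
                                 call. = FALSE)
  if (cov_n(a) <= 0 || cov_n(g) <= 0) stop("degenerate EBV variance",
                                           call. = FALSE)
  tibble::tibble(n = length(focal), rho_ag = stats::cor(a, g))
}

#' Compare PBLUP and GBLUP by the paired partial/whole protocol
#'
#' Runs the eight-step comparison: the whole and one partial dataset are
#' evaluated under both the pedigree NRM and the genomic GRM; the LR
#' statistics (bias, dispersion, accuracy ratio) are computed per model over
#' the validation set, together with the cross-model correlations
#' `rho(PBLUP_p, GBLUP_p)` and `rho(PBLUP_w, GBLUP_w)` that quantify the
#' inverse of the relative accuracy gain from markers.
#'
#' @param phenotypes Whole record table.
#' @param A Pedigree relationship matrix; `G` genomic relationship matrix.
#' @param vc [variance_components()] (used for both models).
#' @param validation_ids Individuals whose records are masked in the partial
#'   dataset.
#' @param fixed Fixed-effect formula.
#' @param id,response Column names.
#' @return List of class `"lr_model_comparison"`: `stats` (LR statistics per
#'   model, validation subset), `cross` (cross-model correlations), `fits`.
#' @export
pblup_vs_gblup <- function(phenotypes, A, G, vc, validation_ids, fixed = ~1,
                           id = "id", response = "y") {
  partial <- phenotypes[!as.character(phenotypes[[id]]) %in% validation_ids, ,
                        drop = FALSE]
  fits <- list(
    pblup_w = solve_mme(phenotypes, A, vc, fixed, response, id, pev = FALSE,
                        model = "pblup", data_tag = "whole"),
    pblup_p = solve_mme(partial, A, vc, fixed, response, id, pev = FALSE,
                        model = "pblup", data_tag = "partial"),
    gblup_w = solve_mme(phenotypes, G, vc, fixed, response, id, pev = FALSE,
                        model = "gblup", data_tag = "whole"),
    gblup_p = solve_mme(partial, G, vc, fixed, response, id, pev = FALSE,
                        model = "gblup", data_tag = "partial"))
  one <- function(model) {
    fp <- fits[[paste0(model, "_p")]]; fw <- fits[[paste0(model, "_w")]]
    up <- fp$u[validation_ids]; uw <- fw$u[validation_ids]
    tibble::tibble(model = model, n = length(validation_ids),
                   mu_wp = mu_wp(up, uw), b_wp = slope_w_on_p(up, uw),
                   rho_wp = rho_w_p(up, uw))
  }
  cross <- tibble::tibble(
    rho_pblup_gblup_partial =
      compare_models(fits$pblup_p$u, fits$gblup_p$u, validation_ids)$rho_ag,
    rho_pblup_gblup_whole =
      compare_models(fits$pblup_w$u, fits$gblup_w$u, validation_ids)$rho_ag)
  structure(list(stats = dplyr::bind_rows(one("pblup"), one("gblup")),
                 cross = cross, fits = fits),
            class = "lr_model_comparison")
}

#' @export
print.lr_model_comparison <- function(x, ...) {
  print(x$stats)
  print(x$cross)
  invisible(x)
}
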