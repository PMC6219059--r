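#' @keywords internal
#' Empirical (co)variance with 1/n normalization, the convention used by all
#' ratio statistics (the normalization cancels in slopes and correlations but
#' matters for the covariance-based accuracy).
cov_n <- function(x, y = x) mean((x - mean(x)) * (y - mean(y)))

check_pair <- function(u_p, u_w, min_n = 1) {
  stopifnot(is.numeric(u_p), is.numeric(u_w))
  if (length(u_p) != length(u_w)) {
    stop("partial and whole EBV vectors differ in length", call. = FALSE)
  }
  if (anyNA(u_p) || anyNA(u_w)) stop("missing EBV values", call. = FALSE)
  if (length(u_p) < min_n) {
    stop("need at least ", min_n, " individuals for this statistic",
         call. = FALSE)
  }
  invisible(length(u_p))
}

#' LR bias statistic: difference of EBV means
#'
#' `mu_wp = mean(u_hat_partial) - mean(u_hat_whole)` (sign convention:
#' partial minus whole), in trait EBV units. Expected value 0 for an unbiased
#' evaluation.
#'
#' @param u_p,u_w Numeric vectors of partial- and whole-data EBV for the same
#'   individuals.
#' @return A single number.
#' @export
mu_wp <- function(u_p, u_w) {
  check_pair(u_p, u_w, 1)
  mean(u_p) - mean(u_w)
}

#' LR dispersion statistic: regression of whole on partial EBV
#'
#' `b_wp = cov(u_hat_w, u_hat_p) / var(u_hat_p)`. Expectation 1 when there is
#' no over/under-dispersion; under uniform scaling of the two evaluations by
#' `theta_p`, `theta_w` it estimates `theta_w / theta_p` (< 1 indicates
#' overdispersion, i.e. inflation, of the partial EBV).
#'
#' @inheritParams mu_wp
#' @return A single number.
#' @export
slope_w_on_p <- function(u_p, u_w) {
  check_pair(u_p, u_w, 2)
  v <- cov_n(u_p)
  if (v <= 0) stop("zero variance of partial EBV", call. = FALSE)
  cov_n(u_p, u_w) / v
}

#' LR reverse regression: partial on whole EBV
#'
#' `b_pw = cov(u_hat_p, u_hat_w) / var(u_hat_w)`, with expectation
#' `acc_p^2 / acc_w^2`: the relative increase in reliability from partial to
#' whole data.
#'
#' @inheritParams mu_wp
#' @return A single number.
#' @export
slope_p_on_w <- function(u_p, u_w) {
  check_pair(u_p, u_w, 2)
  v <- cov_n(u_w)
  if (v <= 0) stop("zero variance of whole EBV", call. = FALSE)
  cov_n(u_p, u_w) / v
}

#' LR accuracy-ratio statistic: correlation of partial and whole EBV
#'
#' Pearson correlation of the two EBV vectors, with expectation
#' `acc_p / acc_w`. Invariant to uniform scaling of either vector.
#'
#' @inheritParams mu_wp
#' @return A single number in `[-1, 1]`.
#' @export
rho_w_p <- function(u_p, u_w) {
  check_pair(u_p, u_w, 2)
  vp <- cov_n(u_p); vw <- cov_n(u_w)
  if (vp <= 0 || vw <= 0) stop("zero EBV variance", call. = FALSE)
  cov_n(u_p, u_w) / sqrt(vp * vw)
}

#' LR covariance statistic: direct estimator of squared population accuracy
#'
#' `rho2_cov = cov(u_hat_p, u_hat_w) / (vf * sigma2_u_inf)` where
#' `vf = variance_factor(K, focal)` is the relationship-adjusted genetic
#' variance factor. Expectation `acc_p^2`. The value is returned as-is (it may
#' fall outside `[0, 1]` by sampling noise); attribute `"out_of_range"` flags
#' such cases.
#'
#' @inheritParams mu_wp
#' @param K Relationship matrix over (at least) the focal individuals.
#' @param focal Ids or index of the focal individuals within `K`; default all.
#' @param sigma2_u_inf Equilibrium additive genetic variance.
#' @return A single number.
#' @export
rho2_cov <- function(u_p, u_w, K, focal = NULL, sigma2_u_inf) {
  check_pair(u_p, u_w, 2)
  stopifnot(sigma2_u_inf > 0)
  vf <- variance_factor(K, focal)
  if (vf <= 0) stop("variance factor is not positive for this focal set",
                    call. = FALSE)
  val <- cov_n(u_p, u_w) / (vf * sigma2_u_inf)
  attr(val, "out_of_range") <- val < 0 || val > 1
  val
}

#' Change in EBV from partial to whole evaluation
#'
#' `d_wp = mean(|u_hat_w - u_hat_p|)` and `vd_wp`, the sample variance
#' (1/(n-1)) of the differences.
#'
#' @inheritParams mu_wp
#' @return A tibble with columns `d_wp` and `vd_wp`.
#' @export
ebv_change <- function(u_p, u_w) {
  check_pair(u_p, u_w, 2)
  d <- u_w - u_p
  tibble::tibble(d_wp = mean(abs(d)), vd_wp = stats::var(d))
}

#' Predictivity: correlation of EBV with precorrected phenotypes
#'
#' Pearson correlation of partial-data EBV and precorrected phenotypes
#' `y* = y - X beta_hat` of the same (validation) individuals.
#'
#' @param y_star Precorrected phenotypes (see [precorrect()]).
#' @param u_p Partial-data EBV for the same individuals.
#' @return A single number.
#' @export
predictivity <- function(y_star, u_p) {
  check_pair(y_star, u_p, 2)
  if (cov_n(y_star) <= 0 || cov_n(u_p) <= 0) {
    stop("zero variance", call. = FALSE)
  }
  stats::cor(y_star, u_p)
}

#' Population accuracy from predictivity
#'
#' `acc = r / h_inf`, the conversion of a cross-validation correlation with
#' precorrected phenotypes into a population accuracy, using the heritability
#' of the (possibly selection-reduced) equilibrium population. Using the base
#' `h` instead of `h_inf` under selection underestimates accuracy.
#'
#' @param r Observed correlation of precorrected phenotypes and EBV.
#' @param h_inf Square root of the equilibrium heritability, in `(0, 1]`.
#' @return Accuracy estimate; values above 1 are returned unaltered with
#'   attribute `"out_of_range" = TRUE`.
#' @export
acc_from_predictivity <- function(r, h_inf) {
  stopifnot(h_inf > 0)
  acc <- r / h_inf
  attr(acc, "out_of_range") <- abs(acc) > 1
  acc
}

#' Accuracy inflation caused by precorrection
#'
#' With `m` levels of a balanced fixed effect estimated from `n` records,
#' precorrected phenotypes lose between-group variance and the apparent
#' cross-validation accuracy is inflated by the proportional factor
#' `(m - 1) / (n - (m - 1))` (approximately `1/n_i` for `n_i = n/m` records
#' per group).
#'
#' @param n Number of records used to estimate the fixed effect.
#' @param m Number of fixed-effect levels (`m >= 1`).
#' @return The proportional inflation of apparent accuracy.
#' @export
precorrection_inflation <- function(n, m) {
  stopifnot(m >= 1, n > m - 1)
  (m - 1) / (n - (m - 1))
}

#' Convert a selected-population accuracy to an unselected-population scale
#'
#' Reverses the Bulmer reduction of genetic variance at equilibrium: with
#' reduction `k` (so `sigma2_u_inf = (1 - k) sigma2_u`), a population accuracy
#' `acc_sel` measured on the selected-variance scale corresponds to
#' `sqrt(k + (1 - k) * acc_sel^2)` on the unselected scale (the prediction
#' error variance is unchanged while the genetic variance is restored).
#'
#' @param acc_sel Accuracy in the selected population, in `[0, 1]`.
#' @param k Variance reduction due to selection, in `[0, 1)`.
#' @return Accuracy in the corresponding unselected population.
#' @export
selected_to_unselected_acc <- function(acc_sel, k) {
  stopifnot(acc_sel >= 0, acc_sel <= 1, k >= 0, k < 1)
  sqrt(k + (1 - k) * acc_sel^2)
}

#' Young-bull counterexample to the partial/whole covariance identity
#'
#' Closed-form covariance structure of two successive EBV of a young bull
#' when the information used is *dropped* rather than augmented: the partial
#' EBV uses one record of the dam, the whole EBV uses the mean of `n` progeny
#' records but not the dam's performance. Then `var(u_p) = h^4 / 4` and
#' `cov(u_p, u_w) = (1/8) h^4 * 2n / (n + lambda)` with the progeny-test
#' ratio `lambda = (4 - h^2) / h^2` (phenotypic variance 1). The covariance is
#' strictly smaller than `var(u_p)` for finite `n`, so the identity
#' `Cov(u_hat_w, u_hat_p) = Var(u_hat_p)` underlying the LR statistics fails
#' when data are discarded between evaluations.
#'
#' @param n Number of progeny records (vectorized, `n >= 0`).
#' @param h2 Heritability in `(0, 1)`.
#' @return A tibble with columns `n`, `cov_pw` and `var_p`.
#' @export
young_bull_counterexample <- function(n, h2) {
  stopifnot(all(n >= 0), h2 > 0, h2 < 1)
  lambda <- (4 - h2) / h2
  tibble::tibble(
    n = n,
    cov_pw = 0.125 * h2^2 * 2 * n / (n + lambda),
    var_p = h2^2 / 4
  )
}

#' All LR statistics for a partial/whole EBV pair
#'
#' Computes the LR comparison statistics over the full pair and, when a
#' `subset` column tags individuals as `"reference"` / `"validation"`, within
#' each subset (subset statistics use subset means).
#'
#' @param pair Data frame with columns `id`, `ebv_partial`, `ebv_whole` and
#'   optionally `subset` (values `"reference"`/`"validation"`) and `y_star`
#'   (precorrected phenotypes, enabling the predictivity column).
#' @param K Optional relationship matrix (enables `rho2_cov`).
#' @param sigma2_u_inf Equilibrium genetic variance, required with `K`.
#' @return A tibble with one row per subset (`"all"` first) and columns
#'   `subset`, `n`, `mu_wp`, `b_wp`, `b_pw`, `rho_wp`, `rho2_cov` (if `K`),
#'   `d_wp`, `vd_wp`, `predictivity` (if `y_star`).
#' @export
lr_stats <- function(pair, K = NULL, sigma2_u_inf = NULL) {
  stopifnot(is.data.frame(pair))
  need <- setdiff(c("id", "ebv_partial", "ebv_whole"), names(pair))
  if (length(need) > 0) {
    stop("pair is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(K) && is.null(sigma2_u_inf)) {
    stop("sigma2_u_inf is required when K is supplied", call. = FALSE)
  }
  groups <- list(all = rep(TRUE, nrow(pair)))
  if ("subset" %in% names(pair)) {
    for (s in c("reference", "validation")) {
      if (any(pair$subset == s)) groups[[s]] <- pair$subset == s
    }
  }
  purrr::map_dfr(names(groups), function(g) {
    rows <- groups[[g]]
    up <- pair$ebv_partial[rows]
    uw <- pair$ebv_whole[rows]
    out <- tibble::tibble(
      subset = g, n = sum(rows),
      mu_wp = mu_wp(up, uw),
      b_wp = slope_w_on_p(up, uw),
      b_pw = slope_p_on_w(up, uw),
      rho_wp = rho_w_p(up, uw)
    )
    if (!is.null(K)) {
      out$rho2_cov <- as.numeric(
        rho2_cov(up, uw, K, focal = pair$id[rows],
                 sigma2_u_inf = sigma2_u_inf))
    }
    out <- dplyr::bind_cols(out, ebv_change(up, uw))
    if ("y_star" %in% names(pair)) {
      out$predictivity <- predictivity(pair$y_star[rows], up)
    }
    out
  })
}

#' Theoretical expectations of the LR statistics
#'
#' Computes the mixed-model expectations of the LR statistics for a focal set
#' from the PEV/PEC blocks of the partial and whole fits:
#' `acc_p`, `acc_w` by the trace formulas, `E(b_wp) = 1`,
#' `E(rho_wp) = acc_p/acc_w`, `E(b_pw) = acc_p^2/acc_w^2`,
#' `E(rho2_cov) = acc_p^2`, and the expected predictivity `acc_p * h_inf`
#' (valid when fixed effects are estimated with high precision).
#'
#' @param fit_p,fit_w Partial- and whole-data [solve_mme()] fits with PEV.
#' @param K Relationship matrix used in the fits.
#' @param vc [variance_components()].
#' @param focal Ids of the focal individuals.
#' @return One-row tibble with columns `acc_p`, `acc_w`, `expected_mu_wp`,
#'   `expected_b_wp`, `expected_rho_wp`, `expected_b_pw`,
#'   `expected_rho2_cov`, `expected_predictivity`.
#' @export
lr_expectations <- function(fit_p, fit_w, K, vc, focal = NULL) {
  acc_p <- as.numeric(accuracy_from_pev(fit_p, K, vc, focal))
  acc_w <- as.numeric(accuracy_from_pev(fit_w, K, vc, focal))
  tibble::tibble(
    acc_p = acc_p, acc_w = acc_w,
    expected_mu_wp = 0,
    expected_b_wp = 1,
    expected_rho_wp = acc_p / acc_w,
    expected_b_pw = acc_p^2 / acc_w^2,
    expected_rho2_cov = acc_p^2,
    expected_predictivity = acc_p * sqrt(vc$h2_inf)
  )
}
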