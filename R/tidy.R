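#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a BLUP fit
#'
#' `effects = "random"` (default) returns one row per individual with EBV,
#' PEV and individual accuracy (when PEV was computed); `effects = "fixed"`
#' returns the BLUE fixed-effect estimates with standard errors from
#' `C_bb`.
#'
#' @param x A [solve_mme()] fit.
#' @param effects `"random"` or `"fixed"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.blup_fit <- function(x, effects = c("random", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    out <- tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
    if (!is.null(x$C_bb)) out$std.error <- sqrt(diag(x$C_bb))
    return(out)
  }
  out <- tibble::tibble(id = names(x$u), ebv = unname(x$u))
  if (!is.null(x$C_uu)) {
    out$pev <- diag(x$C_uu)
    out$accuracy <- sqrt(pmax(1 - out$pev / x$vc$sigma2_u_inf, 0))
  }
  out
}

#' One-row summary of a BLUP fit
#' @param x A [solve_mme()] fit.
#' @param ... Unused.
#' @return Tibble with model tags, sizes and variance components.
#' @export
glance.blup_fit <- function(x, ...) {
  tibble::tibble(model = x$model, data_tag = x$data_tag, n_records = x$n,
                 n_animals = length(x$u), n_fixed = x$p,
                 sigma2_u = x$vc$sigma2_u, sigma2_e = x$vc$sigma2_e,
                 h2 = x$vc$h2)
}

#' @export
tidy.variance_components <- function(x, ...) {
  tibble::tibble(component = c("sigma2_u", "sigma2_e", "sigma2_u_inf"),
                 estimate = c(x$sigma2_u, x$sigma2_e, x$sigma2_u_inf))
}

#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e,
                 sigma2_u_inf = x$sigma2_u_inf, k = x$k, lambda = x$lambda,
                 h2 = x$h2, h2_inf = x$h2_inf,
                 iterations = attr(x, "iterations") %||% NA_integer_,
                 converged = attr(x, "converged") %||% NA)
}

#' Tidy replicated LR results
#'
#' Returns the long replicate table: one row per replicate and statistic.
#'
#' @param x An [lr_crossval()] or [lr_sim_experiment()] object.
#' @param ... Unused.
#' @return Tibble with columns `replicate`, `statistic`, `value`.
#' @export
tidy.lr_crossval <- function(x, ...) {
  tidyr::pivot_longer(x$replicates, -"replicate", names_to = "statistic",
                      values_to = "value")
}

#' @rdname tidy.lr_crossval
#' @export
tidy.lr_experiment <- function(x, ...) {
  tidyr::pivot_longer(x$replicates, -"replicate", names_to = "statistic",
                      values_to = "value")
}

#' Replicate-mean summaries
#'
#' For a cross-validation, one row per statistic (mean, SD, min, max). For a
#' simulation experiment, the observed replicate means side by side with the
#' theoretical expectations and the Monte-Carlo standard error.
#'
#' @param x An [lr_crossval()] or [lr_sim_experiment()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.lr_crossval <- function(x, ...) {
  summarize_replicates(x)$summary
}

#' @rdname glance.lr_crossval
#' @export
glance.lr_experiment <- function(x, ...) {
  exp_map <- c(mu_wp = "expected_mu_wp", b_wp = "expected_b_wp",
               b_pw = "expected_b_pw", rho_wp = "expected_rho_wp",
               rho2_cov = "expected_rho2_cov",
               predictivity = "expected_predictivity",
               acc_p_emp = "acc_p", acc_w_emp = "acc_w")
  s <- summarize_replicates(x)$summary
  s$mc_se <- s$sd / sqrt(nrow(x$replicates))
  s$expected <- NA_real_
  hit <- s$statistic %in% names(exp_map)
  s$expected[hit] <- unlist(x$expectations[exp_map[s$statistic[hit]]])
  s
}
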