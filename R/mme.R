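#' Variance components of the animal model
#'
#' Holds the base additive variance, residual variance, and the equilibrium
#' additive variance under selection (the Bulmer-reduced variance
#' `sigma2_u_inf = (1 - k) * sigma2_u`). When no selection is modelled,
#' `sigma2_u_inf` equals `sigma2_u` (`k = 0`).
#'
#' @param sigma2_u Base additive genetic variance (> 0).
#' @param sigma2_e Residual variance (> 0).
#' @param sigma2_u_inf Equilibrium additive variance; defaults to `sigma2_u`.
#' @param k Alternatively, the proportional reduction due to selection in
#'   `[0, 1)`; overrides `sigma2_u_inf` when supplied.
#' @return An object of class `"variance_components"` with elements
#'   `sigma2_u`, `sigma2_e`, `sigma2_u_inf`, `k`, `lambda = sigma2_e/sigma2_u`,
#'   `h2` and `h2_inf` (heritability with the equilibrium variance).
#' @export
variance_components <- function(sigma2_u, sigma2_e, sigma2_u_inf = sigma2_u,
                                k = NULL) {
  if (!is.null(k)) {
    stopifnot(k >= 0, k < 1)
    sigma2_u_inf <- (1 - k) * sigma2_u
  }
  stopifnot(sigma2_u > 0, sigma2_e > 0, sigma2_u_inf > 0,
            sigma2_u_inf <= sigma2_u)
  structure(
    list(sigma2_u = sigma2_u, sigma2_e = sigma2_e,
         sigma2_u_inf = sigma2_u_inf,
         k = 1 - sigma2_u_inf / sigma2_u,
         lambda = sigma2_e / sigma2_u,
         h2 = sigma2_u / (sigma2_u + sigma2_e),
         h2_inf = sigma2_u_inf / (sigma2_u_inf + sigma2_e)),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components: sigma2_u = %.4g, sigma2_e = %.4g, h2 = %.3f",
    x$sigma2_u, x$sigma2_e, x$h2))
  if (x$k > 0) {
    cat(sprintf(" | sigma2_u_inf = %.4g (k = %.3f, h2_inf = %.3f)",
                x$sigma2_u_inf, x$k, x$h2_inf))
  }
  cat("\n")
  invisible(x)
}

# ---- internal MME machinery --------------------------------------------------
# Builds the Henderson coefficient matrix for one random genetic effect:
#   [X'X   X'Z ] [beta]   [X'y]
#   [Z'X  Z'Z + Kinv*lambda] [u  ] = [Z'y]
# The factorized system can be re-solved cheaply for many y vectors.

mme_build <- function(phenotypes, K, vc, fixed = ~1, id = "id",
                      lambda = vc$lambda) {
  stopifnot(is.data.frame(phenotypes), is.matrix(K))
  if (!id %in% names(phenotypes)) {
    stop("phenotype table has no id column '", id, "'", call. = FALSE)
  }
  ids <- rownames(K)
  if (is.null(ids)) stop("relationship matrix must have id dimnames",
                         call. = FALSE)
  rec_id <- as.character(phenotypes[[id]])
  missing_ids <- setdiff(rec_id, ids)
  if (length(missing_ids) > 0) {
    stop("phenotyped individual(s) absent from relationship matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }

  mf <- stats::model.frame(fixed, data = phenotypes, na.action = stats::na.fail)
  X <- stats::model.matrix(fixed, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; confounded columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  n_rec <- nrow(X)
  q <- length(ids)
  zi <- match(rec_id, ids)
  # Z'Z is diagonal counts; Z'X and Z'y are rowsum aggregations by animal.
  Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) {
    stop("relationship matrix is not positive definite; ",
         "consider a small diagonal ridge (see grm(ridge=))", call. = FALSE)
  })

  p <- ncol(X)
  bi <- seq_len(p)
  ui <- p + seq_len(q)
  LHS <- matrix(0, p + q, p + q)
  if (p > 0) {
    LHS[bi, bi] <- crossprod(X)
    ZtX <- rowsum_matrix(X, zi, q)
    LHS[ui, bi] <- ZtX
    LHS[bi, ui] <- t(ZtX)
  }
  nrec_by_animal <- tabulate(zi, q)
  LHS[ui, ui] <- Kinv * lambda
  diag(LHS)[ui] <- diag(LHS)[ui] + nrec_by_animal

  list(
    X = X, zi = zi, ids = ids, p = p, q = q, n = n_rec,
    Kinv = Kinv, lambda = lambda, LHS = LHS, chol = chol(LHS),
    terms = stats::terms(mf), xlevels = stats::.getXlevels(stats::terms(mf), mf)
  )
}

# t(Z) %*% X without forming Z
rowsum_matrix <- function(X, zi, q) {
  out <- matrix(0, q, ncol(X))
  agg <- rowsum(X, group = zi)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

mme_rhs <- function(sys, y) {
  Xty <- crossprod(sys$X, y)
  Zty <- numeric(sys$q)
  agg <- rowsum(y, group = sys$zi)
  Zty[as.integer(rownames(agg))] <- agg
  c(Xty, Zty)
}

# Fast repeat solves against the stored Cholesky factor.
mme_solve_y <- function(sys, y) {
  sol <- backsolve(sys$chol, forwardsolve(t(sys$chol), mme_rhs(sys, y)))
  list(beta = stats::setNames(sol[seq_len(sys$p)], colnames(sys$X)),
       u = stats::setNames(sol[sys$p + seq_len(sys$q)], sys$ids))
}

mme_inverse <- function(sys) chol2inv(sys$chol)

# ---- public solver -----------------------------------------------------------

#' Solve the animal-model mixed-model equations
#'
#' Fits the single-trait animal model `y = X beta + Z u + e` with
#' `Var(u) = K sigma2_u` and `Var(e) = I sigma2_e` by Henderson's mixed-model
#' equations, returning BLUE fixed effects, BLUP breeding values for every
#' individual in `K` (individuals without records are predicted through
#' relationships), and the exact prediction-error variance/covariance blocks
#' from the dense inverse of the coefficient matrix.
#'
#' @param phenotypes Data frame with one row per record: an id column plus the
#'   variables named in `fixed`. Repeated records per individual are allowed.
#' @param K Relationship matrix (pedigree NRM or genomic GRM) with id
#'   dimnames covering all phenotyped individuals.
#' @param vc A [variance_components()] object.
#' @param fixed One-sided formula for fixed effects (default `~ 1`). The
#'   response is always the `response` column.
#' @param response Name of the trait column (default `"y"`).
#' @param id Name of the id column (default `"id"`).
#' @param pev Logical: compute the PEV/PEC blocks `C_uu` and `C_bb`
#'   (default `TRUE`; skipping them makes repeated solves much faster).
#' @param model,data_tag Optional labels (`"pblup"`/`"gblup"`,
#'   `"partial"`/`"whole"`) stored on the fit.
#' @return An object of class `"blup_fit"`: a list with `beta`, `u` (named
#'   vector over all ids in `K`), `C_uu` (PEV on the diagonal, PEC off it, in
#'   variance units), `C_bb`, `vc`, `n`, `p`, and bookkeeping needed by
#'   [precorrect()]. Use [tidy()] / [glance()] to extract tibbles.
#' @export
solve_mme <- function(phenotypes, K, vc, fixed = ~1, response = "y",
                      id = "id", pev = TRUE, model = "pblup",
                      data_tag = "whole") {
  if (!response %in% names(phenotypes)) {
    stop("phenotype table has no response column '", response, "'",
         call. = FALSE)
  }
  y <- phenotypes[[response]]
  if (anyNA(y)) stop("missing trait values in included records", call. = FALSE)
  sys <- mme_build(phenotypes, K, vc, fixed = fixed, id = id)
  sol <- mme_solve_y(sys, y)
  fit <- list(beta = sol$beta, u = sol$u, vc = vc, n = sys$n, p = sys$p,
              ids = sys$ids, model = model, data_tag = data_tag,
              terms = sys$terms, xlevels = sys$xlevels,
              response = response, id = id)
  if (pev) {
    Cinv <- mme_inverse(sys)
    ui <- sys$p + seq_len(sys$q)
    fit$C_uu <- vc$sigma2_e * Cinv[ui, ui, drop = FALSE]
    dimnames(fit$C_uu) <- list(sys$ids, sys$ids)
    fit$C_bb <- vc$sigma2_e * Cinv[seq_len(sys$p), seq_len(sys$p), drop = FALSE]
    dimnames(fit$C_bb) <- list(colnames(sys$X), colnames(sys$X))
  }
  class(fit) <- "blup_fit"
  fit
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("animal-model BLUP fit (%s, %s data): %d records, %d animals, %d fixed-effect columns\n",
              x$model, x$data_tag, x$n, length(x$u), x$p))
  invisible(x)
}

#' Population accuracy from PEV/PEC
#'
#' The mixed-model (theoretical) population accuracy of a set of EBV:
#' `acc = sqrt((vf * s2 - (mean PEV - mean PEC)) / (vf * s2))` where
#' `vf = variance_factor(K, focal)`, `s2 = vc$sigma2_u_inf`, mean PEV is the
#' mean diagonal of the focal PEV block and mean PEC its grand mean
#' (the trace form `tr(S C)/n`). A negative numerator is clipped to zero and
#' flagged via attribute `"clipped"`.
#'
#' @param fit A [solve_mme()] fit computed with `pev = TRUE`.
#' @param K Relationship matrix used for the fit.
#' @param vc [variance_components()].
#' @param focal Ids of the focal individuals (default: all in `K`).
#' @return Population accuracy in `[0, 1]`.
#' @export
accuracy_from_pev <- function(fit, K, vc = fit$vc, focal = NULL) {
  if (is.null(fit$C_uu)) stop("fit has no PEV block; rerun with pev = TRUE",
                              call. = FALSE)
  if (!is.null(focal) && length(focal) == 1) {
    stop("population accuracy is undefined for a single individual ",
         "(variance factor is zero)", call. = FALSE)
  }
  vf <- variance_factor(K, focal)
  if (vf <= 0) stop("variance factor is not positive for this focal set",
                    call. = FALSE)
  Cf <- focal_block(fit$C_uu, focal)
  num <- vf * vc$sigma2_u_inf - (mean(diag(Cf)) - mean(Cf))
  clipped <- num < 0
  if (clipped) {
    warning("negative accuracy numerator clipped to zero")
    num <- 0
  }
  acc <- sqrt(num / (vf * vc$sigma2_u_inf))
  attr(acc, "clipped") <- clipped
  acc
}

#' Individual (classical) accuracies from PEV
#'
#' `acc_i = sqrt(1 - PEV_i / ((1 + F_i) * sigma2_u_inf))`, the per-animal
#' repeated-sampling correlation of TBV and EBV, as opposed to the population
#' accuracy of [accuracy_from_pev()].
#'
#' @inheritParams accuracy_from_pev
#' @return Tibble with columns `id`, `pev`, `accuracy`.
#' @export
individual_accuracy <- function(fit, K, vc = fit$vc, focal = NULL) {
  if (is.null(fit$C_uu)) stop("fit has no PEV block; rerun with pev = TRUE",
                              call. = FALSE)
  Cf <- focal_block(fit$C_uu, focal)
  Kf <- focal_block(K, focal)
  rel <- unname(1 - diag(Cf) / (diag(Kf) * vc$sigma2_u_inf))
  tibble::tibble(id = rownames(Cf), pev = unname(diag(Cf)),
                 accuracy = sqrt(pmax(rel, 0)))
}

#' Precorrect phenotypes for fixed effects
#'
#' `y* = y - X beta_hat`, where `beta_hat` is taken from a (typically
#' whole-data) fit and the design matrix is rebuilt for the supplied rows with
#' the fit's factor levels. Records with factor levels unseen by the fit give
#' an error.
#'
#' @param phenotypes Data frame of records to precorrect (any subset of the
#'   original rows, same columns).
#' @param fit A [solve_mme()] fit supplying `beta` and the fixed-effect
#'   design definition.
#' @return The input as a tibble with an extra column `y_star`.
#' @export
precorrect <- function(phenotypes, fit) {
  y <- phenotypes[[fit$response]]
  X <- tryCatch(
    stats::model.matrix(stats::delete.response(fit$terms),
                        stats::model.frame(stats::delete.response(fit$terms),
                                           data = phenotypes,
                                           xlev = fit$xlevels)),
    error = function(e) {
      stop("cannot rebuild fixed-effect design for precorrection: ",
           conditionMessage(e), call. = FALSE)
    })
  out <- tibble::as_tibble(phenotypes)
  out$y_star <- as.numeric(y - X %*% fit$beta[colnames(X)])
  out
}

#' EM-REML variance components for the animal model
#'
#' Expectation-maximisation REML for one genetic and one residual variance:
#' given current components, solve the MME, then update
#' `sigma2_u <- (u' Kinv u + sigma2_e * tr(Kinv C)) / q` and
#' `sigma2_e <- (y'y - beta'X'y - u'Z'y) / (n - p)`, iterating to a relative
#' change below `tol`. Robust but slow near the boundary; a collapse of
#' `sigma2_u` toward zero is flagged, not an error.
#'
#' @inheritParams solve_mme
#' @param start Starting [variance_components()].
#' @param max_iter,tol Iteration cap (default 500) and relative-change
#'   tolerance (default 1e-6).
#' @return A [variance_components()] object with attributes `iterations`,
#'   `converged` and `boundary`.
#' @export
em_reml <- function(phenotypes, K, start, fixed = ~1, response = "y",
                    id = "id", max_iter = 500, tol = 1e-6) {
  y <- phenotypes[[response]]
  s2u <- start$sigma2_u
  s2e <- start$sigma2_e
  sys0 <- mme_build(phenotypes, K, start, fixed = fixed, id = id)
  if (sys0$n <= sys0$p) stop("more fixed-effect parameters than records",
                             call. = FALSE)
  Kinv <- sys0$Kinv
  q <- sys0$q
  p <- sys0$p
  ui <- p + seq_len(q)
  yty <- sum(y^2)
  trajectory <- matrix(NA_real_, max_iter, 2,
                       dimnames = list(NULL, c("sigma2_u", "sigma2_e")))
  boundary <- FALSE
  converged <- FALSE
  LHS0 <- sys0$LHS  # data part, fixed across iterations
  LHS0[ui, ui] <- LHS0[ui, ui] - Kinv * sys0$lambda
  rhs <- mme_rhs(sys0, y)
  for (it in seq_len(max_iter)) {
    lambda <- s2e / s2u
    LHS <- LHS0
    LHS[ui, ui] <- LHS[ui, ui] + Kinv * lambda
    ch <- chol(LHS)
    Cinv <- chol2inv(ch)
    sol <- Cinv %*% rhs
    beta <- sol[seq_len(p)]
    u <- sol[ui]
    s2e_new <- (yty - sum(sol * rhs)) / (sys0$n - p)
    s2u_new <- (crossprod(u, Kinv %*% u) + s2e_new * sum(Kinv * Cinv[ui, ui])) / q
    s2u_new <- as.numeric(s2u_new)
    trajectory[it, ] <- c(s2u_new, s2e_new)
    total <- s2u_new + s2e_new
    if (s2u_new < 1e-6 * total) {
      boundary <- TRUE
      s2u <- max(s2u_new, 1e-10)
      s2e <- s2e_new
      break
    }
    # change relative to the total variance: near the boundary the genetic
    # component shrinks geometrically and a per-component criterion stalls
    delta <- max(abs(s2u_new - s2u), abs(s2e_new - s2e)) / total
    s2u <- s2u_new
    s2e <- s2e_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !boundary) {
    cond <- simpleError(sprintf(
      "EM-REML did not converge in %d iterations (last sigma2_u = %.4g)",
      max_iter, s2u))
    cond$trajectory <- trajectory[seq_len(max_iter), , drop = FALSE]
    stop(cond)
  }
  out <- variance_components(s2u, s2e)
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "boundary") <- boundary
  out
}
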