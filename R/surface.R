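## Quadratic response-surface model ----------------------------------------
##
## The model is y = b0 + sum_i b_i x_i + sum_i b_ii x_i^2 +
##              sum_{i<j} b_ij x_i x_j
## where x_i is the coded dose level of drug i (0 = vehicle, so the
## all-vehicle run sits at the coded origin and predicts b0 exactly).
## Interaction terms are stored in fixed lexicographic (i < j) order.

quad_term_names <- function(drugs) {
  n <- length(drugs)
  int <- character(0)
  if (n >= 2) {
    idx <- utils::combn(n, 2)
    int <- paste0("b:", drugs[idx[1, ]], ":", drugs[idx[2, ]])
  }
  c("b0", paste0("b:", drugs), paste0("b2:", drugs), int)
}

quad_model_matrix <- function(runs) {
  runs <- as.matrix(runs)
  n <- ncol(runs)
  drugs <- colnames(runs) %||% paste0("x", seq_len(n))
  X <- cbind(1, runs, runs^2)
  if (n >= 2) {
    idx <- utils::combn(n, 2)
    X <- cbind(X, runs[, idx[1, ], drop = FALSE] * runs[, idx[2, ], drop = FALSE])
  }
  colnames(X) <- quad_term_names(drugs)
  X
}

new_surface <- function(drugs, L, beta0, beta_lin, beta_quad, beta_int,
                        diagnostics = list()) {
  n <- length(drugs)
  names(beta_lin) <- drugs
  names(beta_quad) <- drugs
  if (n >= 2) {
    idx <- utils::combn(n, 2)
    names(beta_int) <- paste0(drugs[idx[1, ]], ":", drugs[idx[2, ]])
  }
  coefs <- c(beta0, beta_lin, beta_quad, beta_int)
  if (any(!is.finite(coefs))) abort_fit("surface coefficients are not all finite")
  structure(
    list(
      drugs = drugs, n = n, L = L,
      beta0 = beta0, beta_lin = beta_lin, beta_quad = beta_quad,
      beta_int = beta_int, diagnostics = diagnostics
    ),
    class = "qpop_surface"
  )
}

surface_coef_vector <- function(surface) {
  c(surface$beta0, surface$beta_lin, surface$beta_quad, surface$beta_int)
}

#' Fit the second-order polynomial viability surface
#'
#' Ordinary least squares fit of normalized viability on the coded dose
#' levels: intercept, linear, quadratic self terms and all pairwise
#' interactions (`1 + 2n + n(n-1)/2` coefficients). An optional ridge penalty
#' (excluding the intercept) is available as a guarded fallback for
#' rank-deficient or user-supplied designs; the default is exact OLS.
#'
#' @param design a `qpop_design` carrying viability readouts.
#' @param ridge nonnegative ridge penalty (default 0 = OLS).
#' @return a `qpop_surface` with coefficients and `diagnostics` (R-squared,
#'   residual SD, model-matrix condition number, leave-one-out RMSE, run and
#'   coefficient counts).
#' @examples
#' p <- example_panel()
#' tr <- surface_truth_planted(p)
#' d <- simulate_screen(tr, build_oacd(p), noise_sd = 0)
#' s <- fit_surface(d)
#' all.equal(s$beta0, tr$surface$beta0)
#' @export
fit_surface <- function(design, ridge = 0) {
  stopifnot(inherits(design, "qpop_design"))
  check_number(ridge, "ridge", lower = 0)
  y <- design$viability
  if (is.null(y)) abort_validation("design has no viability readouts to fit")
  if (any(!is.finite(y))) abort_validation("viability contains non-finite values")
  X <- quad_model_matrix(design$runs)
  p <- ncol(X)
  if (nrow(X) < p) {
    warning(sprintf("fewer runs (%d) than coefficients (%d); fit may be unstable",
                    nrow(X), p))
  }
  qrX <- qr(X)
  if (ridge == 0) {
    if (qrX$rank < p) {
      confounded <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
      abort_estimability(sprintf(
        "quadratic model not estimable from this design (rank %d < %d); confounded terms: %s. Use ridge > 0 or a richer design.",
        qrX$rank, p, paste(confounded, collapse = ", ")
      ))
    }
    beta <- qr.coef(qrX, y)
  } else {
    pen <- diag(p)
    pen[1, 1] <- 0 # never shrink the intercept
    beta <- drop(solve(crossprod(X) + ridge * pen, crossprod(X, y)))
  }
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  dfres <- max(nrow(X) - p, 1)
  tss <- sum((y - mean(y))^2)
  loocv <- NA_real_
  if (ridge == 0 && qrX$rank == p && nrow(X) > p) {
    h <- rowSums(qr.Q(qrX)[, seq_len(p), drop = FALSE]^2)
    ok <- h < 1 - 1e-10
    if (any(ok)) loocv <- sqrt(mean((resid[ok] / (1 - h[ok]))^2))
  }
  diag_list <- list(
    r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_,
    sigma = sqrt(sum(resid^2) / dfres),
    kappa = kappa(X, exact = FALSE),
    loocv_rmse = loocv,
    n_runs = nrow(X),
    n_coefficients = p,
    ridge = ridge
  )
  n <- design$panel$n
  new_surface(
    drugs = design$panel$drugs, L = design$panel$L,
    beta0 = unname(beta[1]),
    beta_lin = beta[1 + seq_len(n)],
    beta_quad = beta[1 + n + seq_len(n)],
    beta_int = if (n >= 2) beta[(2 * n + 2):p] else numeric(0),
    diagnostics = diag_list
  )
}

#' Predict viability from a fitted surface
#'
#' Evaluates the quadratic form at coded dose values. Values on the panel
#' grid are integers `0..L`; fractional values are allowed (used by response
#' surface maps) and values outside `[0, L]` are extrapolation.
#'
#' @param surface a `qpop_surface`.
#' @param dv numeric vector of coded dose values (length = panel size), or a
#'   matrix with one dose vector per row.
#' @return predicted viability, scalar or vector.
#' @export
predict_viability <- function(surface, dv) {
  stopifnot(inherits(surface, "qpop_surface"))
  x <- if (is.matrix(dv)) dv else matrix(dv, nrow = 1)
  if (ncol(x) != surface$n) {
    abort_validation(sprintf(
      "dose vector has %d entries but the surface covers %d drugs",
      ncol(x), surface$n
    ))
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), surface$drugs)) {
    abort_validation("dose vector drug names do not match the surface's panel")
  }
  pred <- surface$beta0 +
    drop(x %*% surface$beta_lin) +
    drop(x^2 %*% surface$beta_quad)
  if (surface$n >= 2) {
    idx <- utils::combn(surface$n, 2)
    cross <- x[, idx[1, ], drop = FALSE] * x[, idx[2, ], drop = FALSE]
    pred <- pred + drop(cross %*% surface$beta_int)
  }
  if (is.matrix(dv)) pred else unname(pred)
}

#' Surface coefficients as a tidy table
#'
#' @param object a `qpop_surface`.
#' @param ... unused.
#' @return data.frame with columns `term` (labels `b0`, `b:<drug>`,
#'   `b2:<drug>`, `b:<drugA>:<drugB>`) and `estimate`.
#' @export
coef.qpop_surface <- function(object, ...) {
  data.frame(
    term = quad_term_names(object$drugs),
    estimate = unname(surface_coef_vector(object)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.qpop_surface <- function(x, ...) {
  cat(sprintf("qpop_surface: %d drugs, %d coefficients\n",
              x$n, 1 + 2 * x$n + x$n * (x$n - 1) / 2))
  d <- x$diagnostics
  if (length(d)) {
    cat(sprintf("  R^2 = %.4f, residual SD = %.4g, kappa = %.3g, LOOCV RMSE = %.4g\n",
                d$r_squared %||% NA, d$sigma %||% NA, d$kappa %||% NA,
                d$loocv_rmse %||% NA))
  }
  invisible(x)
}
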