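## Dose-response pharmacodynamics ------------------------------------------
##
## Follow-up analysis of single agents and fixed-ratio combinations:
## four-parameter logistic (4PL) curves for IC50s, the median-effect model
## fa/fu = (D/Dm)^m, and the Chou-Talalay combination index
## CI(fa) = sum_i d_i / D_i(fa) (mutually exclusive / Loewe form; CI < 1
## synergy, = 1 additivity, > 1 antagonism).

pl4 <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`.
#' Initialization is deterministic multi-start (five starts built from data
#' quantiles: the half-range crossing dose and the dose geometric mean,
#' crossed with hill slopes 0.5/1/2/4), each refined by bounded
#' quasi-Newton minimization and polished with Gauss-Newton when it
#' converges. Data whose per-dose mean response range falls below
#' `noise_floor` are flagged as showing no dose effect and `ic50` is
#' reported as `NA`.
#'
#' @param doses positive dose vector (replicates allowed; at least 5
#'   distinct doses).
#' @param responses viability (or other response) vector, same length.
#' @param label curve label for reporting.
#' @param dose_unit unit string carried through to outputs.
#' @param noise_floor response range below which the data are declared flat
#'   (default 0.05 on normalized viability).
#' @return object of class `qpop_4pl` with `top`, `bottom`, `ic50`, `hill`,
#'   `sigma` (residual SD), `no_dose_effect`, `converged`, `label`,
#'   `dose_unit`.
#' @examples
#' d <- 10^seq(-3, 1, length.out = 8)
#' fit_4pl(d, 1 / (1 + d / 0.02))$ic50
#' @export
fit_4pl <- function(doses, responses, label = "curve", dose_unit = "uM",
                    noise_floor = 0.05) {
  if (length(doses) != length(responses)) {
    abort_validation("`doses` and `responses` must have equal length")
  }
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    abort_validation("doses must be positive and finite")
  }
  if (any(!is.finite(responses))) abort_validation("responses must be finite")
  ud <- sort(unique(doses))
  if (length(ud) < 5) abort_validation("need at least 5 distinct doses")

  mean_by_dose <- tapply(responses, doses, mean)
  rng <- diff(range(mean_by_dose))
  base <- list(label = label, dose_unit = dose_unit, n = length(doses))
  if (rng < noise_floor) {
    return(structure(c(base, list(
      top = max(responses), bottom = min(responses), ic50 = NA_real_,
      hill = NA_real_, sigma = NA_real_, no_dose_effect = TRUE,
      converged = FALSE
    )), class = "qpop_4pl"))
  }

  top0 <- max(mean_by_dose)
  bot0 <- min(mean_by_dose)
  mid <- (top0 + bot0) / 2
  # dose where the per-dose means cross the half range, by log interpolation
  mm <- mean_by_dose[as.character(ud)]
  cross <- ud[which.min(abs(mm - mid))]
  geo <- exp(mean(log(ud)))
  sgn <- if (suppressWarnings(stats::cor(log(doses), responses)) <= 0) 1 else -1
  starts <- list(
    c(top0, bot0, log(cross), sgn * 1),
    c(top0, bot0, log(cross), sgn * 0.5),
    c(top0, bot0, log(cross), sgn * 2),
    c(top0, bot0, log(cross), sgn * 4),
    c(top0, bot0, log(geo), sgn * 1)
  )
  sse <- function(p) {
    r <- responses - pl4(doses, p[1], p[2], exp(p[3]), p[4])
    sum(r * r)
  }
  lo <- c(-Inf, -Inf, log(min(ud)) - log(1e4), -20)
  hi <- c(Inf, Inf, log(max(ud)) + log(1e4), 20)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort_fit("4PL fit failed to converge from all starts")
  # Gauss-Newton polish from the best quasi-Newton solution
  p <- best$par
  # warnOnly + suppressWarnings: on noise-free data the gradient goes
  # singular at the exact optimum, which is success, not failure
  nl <- tryCatch(
    suppressWarnings(stats::nls(
      responses ~ pl4(doses, top, bottom, exp(lic50), hill),
      start = list(top = p[1], bottom = p[2], lic50 = p[3], hill = p[4]),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                                   minFactor = 1e-10)
    )),
    error = function(e) NULL
  )
  if (!is.null(nl)) {
    cf <- stats::coef(nl)
    if (sum(stats::resid(nl)^2) <= best$value + 1e-12) {
      p <- c(cf[["top"]], cf[["bottom"]], cf[["lic50"]], cf[["hill"]])
    }
  }
  # orient so top > bottom (the two parameterizations are equivalent under
  # top<->bottom with hill -> -hill)
  top <- p[1]; bottom <- p[2]; ic50 <- exp(p[3]); hill <- p[4]
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  resid <- responses - pl4(doses, top, bottom, ic50, hill)
  dfres <- max(length(doses) - 4, 1)
  structure(c(base, list(
    top = top, bottom = bottom, ic50 = ic50, hill = hill,
    sigma = sqrt(sum(resid^2) / dfres),
    no_dose_effect = FALSE, converged = TRUE
  )), class = "qpop_4pl")
}

#' @export
print.qpop_4pl <- function(x, ...) {
  if (x$no_dose_effect) {
    cat(sprintf("qpop_4pl '%s': no dose effect detected; IC50 not determined\n",
                x$label))
  } else {
    cat(sprintf(
      "qpop_4pl '%s': IC50 = %.4g %s, hill = %.3g, top = %.3g, bottom = %.3g, residual SD = %.3g\n",
      x$label, x$ic50, x$dose_unit, x$hill, x$top, x$bottom, x$sigma
    ))
  }
  invisible(x)
}

#' @export
predict.qpop_4pl <- function(object, doses, ...) {
  if (object$no_dose_effect) abort_validation("curve has no determined parameters")
  pl4(doses, object$top, object$bottom, object$ic50, object$hill)
}

#' Convert normalized viability to fraction affected
#'
#' `fa = 1 - viability`, clamped to `(eps, 1 - eps)` for numerical safety
#' ahead of the log transforms of the median-effect model.
#'
#' @param viability numeric vector.
#' @param eps clamp width (default 1e-6).
#' @return fraction affected in the open unit interval.
#' @export
fa_from_viability <- function(viability, eps = 1e-6) {
  pmin(pmax(1 - viability, eps), 1 - eps)
}

#' Fit the median-effect model
#'
#' Linear regression of `log(fa/(1-fa))` on `log(D)`:
#' slope is the median-effect slope `m`, and the median-effect dose is
#' `Dm = exp(-intercept/m)`. Points with `fa` outside the open interval
#' `(0, 1)` are excluded with a warning; at least 3 interior points are
#' required.
#'
#' @param doses positive dose vector.
#' @param fa fraction affected, strictly inside (0, 1) to be used.
#' @param label label for reporting.
#' @return object of class `qpop_me` with `Dm`, `m`, `r` (correlation of the
#'   linearized plot), `n_used`.
#' @export
fit_median_effect <- function(doses, fa, label = "curve") {
  if (length(doses) != length(fa)) {
    abort_validation("`doses` and `fa` must have equal length")
  }
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    abort_validation("doses must be positive and finite")
  }
  keep <- is.finite(fa) & fa > 0 & fa < 1
  if (any(!keep)) {
    warning(sprintf("excluding %d point(s) with fa outside (0, 1)", sum(!keep)))
  }
  if (sum(keep) < 3) {
    abort_validation("need at least 3 points with fa strictly inside (0, 1)")
  }
  x <- log(doses[keep])
  y <- log(fa[keep] / (1 - fa[keep]))
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- unname(fit$coefficients[2])
  if (!is.finite(m) || m == 0) abort_fit("degenerate median-effect slope")
  Dm <- exp(-unname(fit$coefficients[1]) / m)
  structure(
    list(Dm = Dm, m = m,
         r = suppressWarnings(stats::cor(x, y)),
         n_used = sum(keep), label = label),
    class = "qpop_me"
  )
}

#' @export
print.qpop_me <- function(x, ...) {
  cat(sprintf("qpop_me '%s': Dm = %.4g, m = %.3g, r = %.4f (n = %d)\n",
              x$label, x$Dm, x$m, x$r, x$n_used))
  invisible(x)
}

#' Iso-effective dose of a single agent at a given effect level
#'
#' Inverts the median-effect equation: `D(fa) = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a `qpop_me`.
#' @param fa effect level(s) strictly inside (0, 1).
#' @return dose vector.
#' @export
dose_at_fa <- function(fit, fa) {
  stopifnot(inherits(fit, "qpop_me"))
  if (any(fa <= 0 | fa >= 1)) abort_validation("fa must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index along a combination series
#'
#' For each combination point with fraction affected `fa` in (0, 1), computes
#' the iso-effective single-agent doses `D_i(fa)` from the median-effect fits
#' and the combination index `CI(fa) = sum_i d_i / D_i(fa)` (mutually
#' exclusive / Loewe form). With `exclusive = FALSE` the non-exclusive
#' cross-term `prod_i d_i / prod_i D_i` is added (two components only).
#' Points at fa = 0 or 1 are skipped with a warning.
#'
#' @param single_fits list of `qpop_me`, one per component.
#' @param combo_doses matrix (points x components) of component doses at each
#'   combination point.
#' @param combo_fa fraction affected at each combination point.
#' @param exclusive use the mutually exclusive form (default TRUE).
#' @param additive_band half-width of the CI band called "additive" in the
#'   verdict column (default 0.05).
#' @return data.frame of class `qpop_ci`: `fa`, `CI`, component doses
#'   (`d_<label>`), iso-effective doses (`D_<label>`) and a `verdict` column
#'   (synergy / additive / antagonism).
#' @export
combination_index <- function(single_fits, combo_doses, combo_fa,
                              exclusive = TRUE, additive_band = 0.05) {
  if (!is.list(single_fits) || !all(vapply(single_fits, inherits, TRUE, "qpop_me"))) {
    abort_validation("`single_fits` must be a list of median-effect fits")
  }
  combo_doses <- as.matrix(combo_doses)
  nc <- length(single_fits)
  if (ncol(combo_doses) != nc) {
    abort_validation("`combo_doses` needs one column per single-agent fit")
  }
  if (nrow(combo_doses) != length(combo_fa)) {
    abort_validation("`combo_fa` must align with the rows of `combo_doses`")
  }
  if (!exclusive && nc != 2) {
    abort_validation("the non-exclusive CI form is defined here for 2 components")
  }
  keep <- is.finite(combo_fa) & combo_fa > 0 & combo_fa < 1
  if (any(!keep)) {
    warning(sprintf("skipping %d point(s) with fa at 0 or 1 (CI undefined)",
                    sum(!keep)))
  }
  fa <- combo_fa[keep]
  d <- combo_doses[keep, , drop = FALSE]
  D <- vapply(single_fits, function(f) dose_at_fa(f, fa), numeric(length(fa)))
  D <- matrix(D, ncol = nc)
  ci <- rowSums(d / D)
  if (!exclusive) ci <- ci + apply(d, 1, prod) / apply(D, 1, prod)
  labels <- vapply(single_fits, function(f) f$label, character(1))
  out <- data.frame(fa = fa, CI = ci)
  for (i in seq_len(nc)) out[[paste0("d_", labels[i])]] <- d[, i]
  for (i in seq_len(nc)) out[[paste0("D_", labels[i])]] <- D[, i]
  out$verdict <- ifelse(ci < 1 - additive_band, "synergy",
                        ifelse(ci > 1 + additive_band, "antagonism", "additive"))
  class(out) <- c("qpop_ci", "data.frame")
  out
}

#' Two-drug response surface map
#'
#' Evaluates predicted viability over the coded dose rectangle of a drug
#' pair with all other drugs at vehicle (when given a fitted surface), or
#' bilinearly interpolates a measured two-drug grid.
#'
#' @param source a `qpop_surface`, or a data.frame with columns `dose_a`,
#'   `dose_b`, `response` forming a rectangular measured grid.
#' @param pair character vector of the two drug names (surface source) or
#'   labels (measured source).
#' @param resolution grid points per axis, at least 2 (`resolution = 2`
#'   evaluates exactly the four corners).
#' @return object of class `qpop_rsm`: list with `pair`, `x`, `y` (axis
#'   values), `viability` (matrix, rows = x) and `grid` (long data.frame).
#' @export
response_surface_map <- function(source, pair, resolution = 25) {
  check_number(resolution, "resolution", lower = 2, integral = TRUE)
  if (inherits(source, "qpop_surface")) {
    idx <- match(pair, source$drugs)
    if (anyNA(idx) || length(idx) != 2) {
      abort_validation(sprintf(
        "pair not on the panel: %s",
        paste(pair[is.na(idx)], collapse = ", ")
      ))
    }
    ax <- seq(0, source$L, length.out = resolution)
    g <- expand.grid(a = ax, b = ax)
    runs <- matrix(0, nrow(g), source$n)
    runs[, idx[1]] <- g$a
    runs[, idx[2]] <- g$b
    v <- predict_viability(source, runs)
  } else {
    df <- as.data.frame(source)
    need <- c("dose_a", "dose_b", "response")
    if (!all(need %in% names(df))) {
      abort_validation("measured source needs columns dose_a, dose_b, response")
    }
    xa <- sort(unique(df$dose_a))
    xb <- sort(unique(df$dose_b))
    mz <- matrix(NA_real_, length(xa), length(xb))
    mz[cbind(match(df$dose_a, xa), match(df$dose_b, xb))] <- df$response
    if (anyNA(mz)) abort_validation("measured grid is not rectangular/complete")
    ax_a <- seq(min(xa), max(xa), length.out = resolution)
    ax_b <- seq(min(xb), max(xb), length.out = resolution)
    g <- expand.grid(a = ax_a, b = ax_b)
    v <- bilinear_interp(xa, xb, mz, g$a, g$b)
    ax <- NULL
  }
  if (inherits(source, "qpop_surface")) {
    x <- ax; y <- ax
  } else {
    x <- ax_a; y <- ax_b
  }
  vm <- matrix(v, resolution, resolution) # rows follow x (a), cols y (b)
  grid <- data.frame(dose_a = g$a, dose_b = g$b, viability = v)
  if (any(!is.finite(v))) abort_fit("non-finite viability on the response grid")
  structure(
    list(pair = pair, x = x, y = y, viability = vm, grid = grid),
    class = "qpop_rsm"
  )
}

bilinear_interp <- function(xa, xb, z, qa, qb) {
  ia <- pmin(pmax(findInterval(qa, xa, all.inside = TRUE), 1), length(xa) - 1)
  ib <- pmin(pmax(findInterval(qb, xb, all.inside = TRUE), 1), length(xb) - 1)
  ta <- (qa - xa[ia]) / (xa[ia + 1] - xa[ia])
  tb <- (qb - xb[ib]) / (xb[ib + 1] - xb[ib])
  z[cbind(ia, ib)] * (1 - ta) * (1 - tb) +
    z[cbind(ia + 1, ib)] * ta * (1 - tb) +
    z[cbind(ia, ib + 1)] * (1 - ta) * tb +
    z[cbind(ia + 1, ib + 1)] * ta * tb
}

#' Render a response surface map to a file
#'
#' @param rsm a `qpop_rsm` from [response_surface_map()].
#' @param file output PNG path.
#' @param ... passed to [graphics::filled.contour()].
#' @return `file`, invisibly.
#' @export
plot_response_surface <- function(rsm, file, ...) {
  stopifnot(inherits(rsm, "qpop_rsm"))
  grDevices::png(file, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  graphics::filled.contour(
    rsm$x, rsm$y, rsm$viability,
    color.palette = function(n) grDevices::hcl.colors(n, "RdYlBu"),
    xlab = rsm$pair[1], ylab = rsm$pair[2],
    main = sprintf("Predicted viability: %s x %s", rsm$pair[1], rsm$pair[2]),
    ...
  )
  invisible(file)
}
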