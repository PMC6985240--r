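## Two-level array constructions -------------------------------------------
##
## Strength-2 arrays (main-effect screening): Sylvester Hadamard matrices for
## n <= 7 and the cyclic 12-run Plackett-Burman array for n <= 11.
## Strength-4 arrays (all two-factor interactions clear, i.e. resolution V
## regular fractions): full factorials for n <= 5 and fixed generator sets on
## 5-7 base factors for n = 6..11.  Every word of each generator subgroup has
## length >= 5 (checked in the test suite), which is what makes the full
## quadratic model estimable from the composite design.

MAX_OA_FACTORS <- 11L

sylvester_hadamard <- function(order) {
  h <- matrix(1, 1, 1)
  while (nrow(h) < order) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

pb12 <- function() {
  first <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)
  rows <- t(vapply(0:10, function(s) first[((seq_len(11) - 1 + s) %% 11) + 1],
                   numeric(11)))
  rbind(rows, rep(-1, 11))
}

## Regular resolution-V fraction generators: new factor = product of the base
## columns listed. Chosen so all defining words have length >= 5.
resv_generators <- list(
  `6`  = list(base = 5L, gens = list(c(1, 2, 3, 4, 5))),
  `7`  = list(base = 6L, gens = list(c(1, 2, 3, 4, 5, 6))),
  `8`  = list(base = 6L, gens = list(c(1, 2, 3, 4), c(1, 2, 5, 6))),
  `9`  = list(base = 7L, gens = list(c(1, 2, 3, 4), c(1, 2, 5, 6))),
  `10` = list(base = 7L, gens = list(c(1, 2, 3, 4), c(1, 2, 5, 6), c(1, 3, 5, 7))),
  `11` = list(base = 7L, gens = list(c(1, 2, 3, 4), c(1, 2, 5, 6),
                                     c(1, 3, 5, 7), c(2, 4, 6, 7)))
)

two_level_array <- function(n, strength) {
  if (n > MAX_OA_FACTORS) {
    abort_validation(sprintf(
      "panel size %d exceeds the largest available orthogonal array (%d factors)",
      n, MAX_OA_FACTORS
    ))
  }
  if (strength == 2) {
    if (n <= 3) {
      m <- sylvester_hadamard(4)[, -1, drop = FALSE]
    } else if (n <= 7) {
      m <- sylvester_hadamard(8)[, -1, drop = FALSE]
    } else {
      m <- pb12()
    }
    return(m[, seq_len(n), drop = FALSE])
  }
  if (strength == 4) {
    if (n <= 5) {
      return(as.matrix(expand.grid(rep(list(c(-1, 1)), n))))
    }
    spec <- resv_generators[[as.character(n)]]
    base <- as.matrix(expand.grid(rep(list(c(-1, 1)), spec$base)))
    extra <- vapply(
      spec$gens,
      function(g) apply(base[, g, drop = FALSE], 1, prod),
      numeric(nrow(base))
    )
    return(unname(cbind(base, extra)))
  }
  abort_validation("`oa_strength` must be 2 (screening) or 4 (interaction-clear)")
}

## Design container ---------------------------------------------------------

new_design <- function(panel, runs, viability = NULL, replicate = NULL,
                       portion = NULL) {
  runs <- as.matrix(runs)
  storage.mode(runs) <- "integer"
  colnames(runs) <- panel$drugs
  if (nrow(runs) == 0) abort_validation("design has no runs")
  if (any(runs < 0 | runs > panel$L)) {
    abort_validation(sprintf("coded levels must lie in {0..%d}", panel$L))
  }
  if (!is.null(viability)) {
    if (length(viability) != nrow(runs)) {
      abort_validation("`viability` length must equal the number of runs")
    }
    if (any(!is.finite(viability))) {
      abort_validation("viability contains non-finite values")
    }
  }
  structure(
    list(
      panel = panel,
      runs = runs,
      viability = viability,
      replicate = replicate %||% rep(1L, nrow(runs)),
      portion = portion %||% rep("user", nrow(runs))
    ),
    class = "qpop_design"
  )
}

#' @export
print.qpop_design <- function(x, ...) {
  cat(sprintf(
    "qpop_design: %d runs x %d drugs (%s)%s\n",
    nrow(x$runs), x$panel$n,
    paste(sprintf("%s=%d", names(table(x$portion)), table(x$portion)), collapse = ", "),
    if (is.null(x$viability)) ", no readout" else ", with viability"
  ))
  invisible(x)
}

#' @export
as.data.frame.qpop_design <- function(x, ...) {
  df <- data.frame(run_id = seq_len(nrow(x$runs)), x$runs, check.names = FALSE)
  if (!is.null(x$viability)) df$viability <- x$viability
  df$replicate <- x$replicate
  df$portion <- x$portion
  df
}

#' Build an orthogonal array composite design (OACD)
#'
#' Constructs a screening design for a quadratic viability surface as the
#' concatenation of three portions:
#' \describe{
#'   \item{oa}{a two-level orthogonal array over coded levels \{1, 2\}
#'     (internally \eqn{-1/+1}); with `oa_strength = 4` this is a regular
#'     resolution-V fraction (or full factorial for small panels) so that all
#'     pairwise interaction terms are estimable, with `oa_strength = 2` a
#'     Hadamard/Plackett-Burman screening array (main effects only).}
#'   \item{axial}{for each drug, one run at each non-zero level with all
#'     other drugs at vehicle; these separate the quadratic self terms from
#'     the linear terms.}
#'   \item{center}{`n_center` all-vehicle runs anchoring the intercept.}
#' }
#' The construction is deterministic; `seed` is accepted for interface
#' stability but no randomness is used.
#'
#' @param panel a [drug_panel()] with `L = 2` non-zero levels.
#' @param oa_strength 2 or 4 (default 4; required for full quadratic
#'   estimability at n > 5 — see [validate_design()]).
#' @param seed unused; kept for call-signature compatibility.
#' @param n_center number of vehicle-control center runs (default 3).
#' @return a `qpop_design` without viability.
#' @examples
#' d <- build_oacd(example_panel())
#' nrow(d$runs)  # far smaller than 3^11 = 177147
#' @export
build_oacd <- function(panel, oa_strength = 4, seed = 0, n_center = 3) {
  stopifnot(inherits(panel, "qpop_panel"))
  check_number(oa_strength, "oa_strength", integral = TRUE)
  check_number(n_center, "n_center", lower = 1, integral = TRUE)
  if (panel$n < 2) abort_validation("panel too small: need at least 2 drugs")
  if (panel$L != 2) {
    abort_validation(sprintf(
      "unsupported design: the composite construction requires L = 2 non-zero levels, got L = %d",
      panel$L
    ))
  }
  oa <- two_level_array(panel$n, oa_strength)
  oa_levels <- (oa + 3) / 2 # -1 -> level 1, +1 -> level 2
  axial <- matrix(0L, 2L * panel$n, panel$n)
  for (i in seq_len(panel$n)) {
    axial[2 * i - 1, i] <- 1L
    axial[2 * i, i] <- 2L
  }
  center <- matrix(0L, n_center, panel$n)
  runs <- rbind(oa_levels, axial, center)
  portion <- c(
    rep("oa", nrow(oa_levels)),
    rep("axial", nrow(axial)),
    rep("center", n_center)
  )
  new_design(panel, runs, portion = portion)
}

#' Diagnose a screening design
#'
#' Reports, per drug, how often each coded level occurs; for the orthogonal
#' array portion (if labeled), the exact pairwise column correlations; and
#' whether the full quadratic surface model is estimable from the design
#' (model matrix of [fit_surface()] has full column rank). Always returns a
#' report rather than erroring.
#'
#' @param design a `qpop_design`.
#' @return a list of class `qpop_design_report` with elements
#'   `level_counts` (drugs x levels matrix), `oa_max_abs_correlation`,
#'   `oa_correlations` (matrix or NULL if no OA portion), `estimable`
#'   (logical), `n_runs`, `n_coefficients`, `rank`, `deficient_terms`
#'   (character, empty when estimable) and `pass`.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "qpop_design"))
  panel <- design$panel
  lev <- vapply(
    0:panel$L,
    function(l) colSums(design$runs == l),
    numeric(panel$n)
  )
  lev <- matrix(lev, nrow = panel$n,
                dimnames = list(panel$drugs, paste0("level", 0:panel$L)))

  oa_cor <- NULL
  oa_max <- NA_real_
  oa_rows <- design$portion == "oa"
  if (any(oa_rows) && panel$n >= 2) {
    m <- design$runs[oa_rows, , drop = FALSE]
    keep <- apply(m, 2, function(x) stats::var(x) > 0)
    if (sum(keep) >= 2) {
      oa_cor <- suppressWarnings(stats::cor(m[, keep, drop = FALSE]))
      oa_max <- max(abs(oa_cor[upper.tri(oa_cor)]))
    }
  }

  X <- quad_model_matrix(design$runs)
  qrX <- qr(X)
  estimable <- qrX$rank == ncol(X)
  deficient <- character(0)
  if (!estimable) {
    deficient <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
  }
  structure(
    list(
      level_counts = lev,
      oa_correlations = oa_cor,
      oa_max_abs_correlation = oa_max,
      estimable = estimable,
      n_runs = nrow(design$runs),
      n_coefficients = ncol(X),
      rank = qrX$rank,
      deficient_terms = deficient,
      pass = estimable
    ),
    class = "qpop_design_report"
  )
}

#' @export
print.qpop_design_report <- function(x, ...) {
  cat(sprintf(
    "design report: %d runs, %d quadratic coefficients, rank %d -> %s\n",
    x$n_runs, x$n_coefficients, x$rank, if (x$pass) "PASS" else "FAIL"
  ))
  if (!is.na(x$oa_max_abs_correlation)) {
    cat(sprintf("OA portion max |pairwise correlation|: %g\n",
                x$oa_max_abs_correlation))
  }
  if (length(x$deficient_terms)) {
    cat("non-estimable terms:", paste(x$deficient_terms, collapse = ", "), "\n")
  }
  invisible(x)
}
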