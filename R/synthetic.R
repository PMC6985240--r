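## Synthetic data with known ground truth ----------------------------------
##
## Two generators make every stage of the workflow testable without any
## experimental data: (i) viability screens drawn from a known quadratic
## surface plus Gaussian readout noise, and (ii) two-drug fixed-ratio
## dose-response series built by Loewe inversion of known single-agent Hill
## curves with a tunable interaction parameter (the target combination
## index). All generators are pure functions of (truth, design, seed).

#' Define a ground-truth quadratic surface for simulation
#'
#' @param panel a [drug_panel()].
#' @param beta0 intercept (viability at all-vehicle; default 1).
#' @param beta_lin,beta_quad length-n coefficient vectors (default 0).
#' @param beta_int length-`C(n,2)` interaction vector in lexicographic
#'   `i < j` order (default 0).
#' @param noise_sd Gaussian readout noise SD on normalized viability.
#' @param seed integer seed making generation deterministic.
#' @return object of class `qpop_surface_truth` wrapping a `qpop_surface`.
#' @export
surface_truth <- function(panel, beta0 = 1, beta_lin = NULL, beta_quad = NULL,
                          beta_int = NULL, noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(panel, "qpop_panel"))
  check_number(noise_sd, "noise_sd", lower = 0)
  n <- panel$n
  surface <- new_surface(
    drugs = panel$drugs, L = panel$L,
    beta0 = beta0,
    beta_lin = beta_lin %||% rep(0, n),
    beta_quad = beta_quad %||% rep(0, n),
    beta_int = beta_int %||% rep(0, n * (n - 1) / 2),
    diagnostics = list(source = "truth")
  )
  structure(list(surface = surface, panel = panel, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "qpop_surface_truth")
}

#' Ground truth with a planted optimal combination
#'
#' Convenience truth whose global best k-drug combination is the given member
#' set at its highest levels, separated from the runner-up by a wide margin:
#' planted drugs get linear coefficient `lin_planted` and pairwise
#' interactions `int_planted` among themselves; all other drugs get a small
#' positive linear term. With the defaults on an `L = 2` panel the planted
#' triple at levels (2,2,2) scores about 0.46 below any other 3-drug
#' combination, well separated relative to screen noise of SD 0.05.
#'
#' @param panel a [drug_panel()].
#' @param members drug names to plant (default: the cisplatin + cytarabine +
#'   l-asparaginase triple of [example_panel()]).
#' @param lin_planted,int_planted,lin_other coefficient magnitudes.
#' @inheritParams surface_truth
#' @return a `qpop_surface_truth`.
#' @export
surface_truth_planted <- function(panel,
                                  members = c("cisplatin", "cytarabine",
                                              "l-asparaginase"),
                                  lin_planted = -0.2, int_planted = -0.05,
                                  lin_other = 0.02, noise_sd = 0.05, seed = 1) {
  idx <- match(members, panel$drugs)
  if (anyNA(idx)) {
    abort_validation(sprintf("planted drug(s) not on the panel: %s",
                             paste(members[is.na(idx)], collapse = ", ")))
  }
  n <- panel$n
  beta_lin <- rep(lin_other, n)
  beta_lin[idx] <- lin_planted
  beta_int <- rep(0, n * (n - 1) / 2)
  pairs <- utils::combn(n, 2)
  inside <- pairs[1, ] %in% idx & pairs[2, ] %in% idx
  beta_int[inside] <- int_planted
  surface_truth(panel, beta0 = 1, beta_lin = beta_lin,
                beta_int = beta_int, noise_sd = noise_sd, seed = seed)
}

#' Simulate a viability screen from a ground-truth surface
#'
#' `viability = predict_viability(truth, run) + N(0, noise_sd)`, with
#' independent noise per run/replicate. Deterministic given the seed; the
#' caller's RNG state is untouched.
#'
#' @param truth a [surface_truth()].
#' @param design a `qpop_design` on the same panel.
#' @param noise_sd override of the truth's noise SD (optional).
#' @param seed override of the truth's seed (optional).
#' @return the design with `viability` filled in.
#' @export
simulate_screen <- function(truth, design, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(truth, "qpop_surface_truth"), inherits(design, "qpop_design"))
  if (!identical(truth$panel$drugs, design$panel$drugs)) {
    abort_validation("truth panel does not match the design panel")
  }
  sd <- noise_sd %||% truth$noise_sd
  check_number(sd, "noise_sd", lower = 0)
  mu <- predict_viability(truth$surface, design$runs)
  y <- with_seed(seed %||% truth$seed, mu + stats::rnorm(length(mu), 0, sd))
  new_design(design$panel, design$runs, viability = y,
             replicate = design$replicate, portion = design$portion)
}

#' Define a two-drug Hill-curve truth with a Loewe interaction parameter
#'
#' Each component is a 4PL curve with `top = 1`, `bottom = 0` (so viability
#' maps directly to fraction affected and the single-agent median-effect
#' parameters are exactly `Dm = ic50`, `m = hill`). `loewe_alpha` is the
#' combination index the generated series embeds: at every combination point
#' the fraction affected solves `sum_i d_i / D_i(fa) = alpha`, so `alpha < 1`
#' is synergy (less drug needed), `alpha = 1` exact Loewe additivity and
#' `alpha > 1` antagonism.
#'
#' @param ic50s,hills numeric vectors (one entry per component).
#' @param labels component labels.
#' @param loewe_alpha interaction parameter, > 0.
#' @param noise_sd Gaussian noise SD on the simulated responses.
#' @param seed integer seed.
#' @return object of class `qpop_combo_truth`.
#' @export
hill_combo_truth <- function(ic50s, hills = rep(1, length(ic50s)),
                             labels = paste0("drug", seq_along(ic50s)),
                             loewe_alpha = 1, noise_sd = 0, seed = 1) {
  if (length(ic50s) < 2) abort_validation("need at least 2 components")
  if (any(ic50s <= 0) || any(!is.finite(ic50s))) {
    abort_validation("ic50s must be positive and finite")
  }
  if (any(hills <= 0)) abort_validation("hills must be positive")
  check_number(loewe_alpha, "loewe_alpha")
  if (loewe_alpha <= 0) abort_validation("`loewe_alpha` must be > 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(ic50s = ic50s, hills = hills, labels = labels,
         alpha = loewe_alpha, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "qpop_combo_truth"
  )
}

## fa of the combination at component doses d (vector), by Loewe inversion:
## solve sum_i d_i / (Dm_i (fa/(1-fa))^{1/m_i}) = alpha for fa.
loewe_fa <- function(truth, d, eps = 1e-9) {
  g <- function(fa) {
    D <- truth$ic50s * (fa / (1 - fa))^(1 / truth$hills)
    sum(d / D) - truth$alpha
  }
  if (g(eps) < 0) return(eps)       # doses too low for any effect at alpha
  if (g(1 - eps) > 0) return(1 - eps) # saturating effect
  stats::uniroot(g, c(eps, 1 - eps), tol = 1e-12)$root
}

#' Simulate a fixed-ratio combination dose-response series
#'
#' Builds a geometric dilution series of total dose split between the
#' components at a fixed ratio; combination responses come from Loewe
#' inversion of the single-agent curves at the truth's interaction parameter,
#' and matched single-agent series are generated from the component 4PL
#' curves at the same component doses. Gaussian noise (truth's `noise_sd`)
#' is added to all responses, seeded.
#'
#' @param truth a [hill_combo_truth()].
#' @param ratio positive vector of component dose fractions (normalized
#'   internally; default equal split).
#' @param n_points number of dilution points (>= 5).
#' @param dilution fold-change between consecutive totals (default 2).
#' @param seed optional seed override.
#' @return list with `combo` (data.frame: per-component doses `d_<label>`,
#'   `total`, `response`) and `singles` (named list of data.frames `dose`,
#'   `response`). Responses are viabilities (`1 - fa`) plus noise.
#' @export
simulate_combo_series <- function(truth, ratio = NULL, n_points = 8,
                                  dilution = 2, seed = NULL) {
  stopifnot(inherits(truth, "qpop_combo_truth"))
  check_number(n_points, "n_points", lower = 5, integral = TRUE)
  nc <- length(truth$ic50s)
  ratio <- ratio %||% rep(1, nc)
  if (length(ratio) != nc || any(ratio <= 0)) {
    abort_validation("`ratio` needs one positive entry per component")
  }
  r <- ratio / sum(ratio)
  # center the series on the total giving fa = 0.5 under the truth's alpha
  t50 <- truth$alpha / sum(r / truth$ic50s)
  expo <- seq_len(n_points) - (n_points + 1) / 2
  totals <- t50 * dilution^expo
  d <- outer(totals, r)
  colnames(d) <- truth$labels
  fa <- vapply(seq_len(n_points), function(i) loewe_fa(truth, d[i, ]), numeric(1))
  with_seed(seed %||% truth$seed, {
    combo <- data.frame(d, check.names = FALSE)
    names(combo) <- paste0("d_", truth$labels)
    combo$total <- totals
    combo$response <- 1 - fa + stats::rnorm(n_points, 0, truth$noise_sd)
    singles <- lapply(seq_len(nc), function(i) {
      v <- pl4(d[, i], 1, 0, truth$ic50s[i], truth$hills[i])
      data.frame(dose = d[, i],
                 response = v + stats::rnorm(n_points, 0, truth$noise_sd))
    })
    names(singles) <- truth$labels
    list(combo = combo, singles = singles)
  })
}
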