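#' Construct a drug panel
#'
#' A panel holds the drugs available to the screen together with their
#' discrete concentration grids. Each drug has `L + 1` concentrations: the
#' first is exactly 0 (vehicle) and the remaining `L` are strictly
#' increasing. Coded dose levels `0, 1, ..., L` index into this grid; level 0
#' is always vehicle. All drugs in a panel share the same number of levels so
#' that a single coded dose vector addresses the whole panel.
#'
#' @param drugs character vector of unique drug names.
#' @param concentrations numeric matrix with one row per drug and `L + 1`
#'   columns (first column all zero, rows strictly increasing), or a list of
#'   such numeric vectors, one per drug.
#' @param unit dose unit string, recycled across drugs (default `"uM"`).
#' @return an object of class `qpop_panel` with elements `drugs`, `unit`,
#'   `conc` (matrix, rownames = drugs), `n` (panel size) and `L` (number of
#'   non-zero levels).
#' @examples
#' p <- drug_panel(c("bortezomib", "panobinostat"),
#'                 rbind(c(0, 0.01, 0.1), c(0, 0.001, 0.01)))
#' p$L
#' @export
drug_panel <- function(drugs, concentrations, unit = "uM") {
  if (!is.character(drugs) || length(drugs) < 2) {
    abort_validation("a panel needs at least 2 drug names")
  }
  if (anyDuplicated(drugs)) {
    abort_validation(sprintf(
      "duplicate drug names: %s",
      paste(unique(drugs[duplicated(drugs)]), collapse = ", ")
    ))
  }
  if (is.list(concentrations)) {
    len <- lengths(concentrations)
    if (length(unique(len)) != 1) {
      abort_validation("all drugs must have the same number of concentration levels")
    }
    concentrations <- do.call(rbind, concentrations)
  }
  conc <- as.matrix(concentrations)
  if (nrow(conc) != length(drugs)) {
    abort_validation("`concentrations` must have one row per drug")
  }
  if (ncol(conc) < 2) {
    abort_validation("each drug needs at least one non-zero level (L >= 1)")
  }
  if (any(!is.finite(conc))) abort_validation("concentrations must all be finite")
  if (any(conc[, 1] != 0)) {
    abort_validation("the first concentration of every drug must be exactly 0 (vehicle)")
  }
  if (any(apply(conc, 1, function(r) any(diff(r) <= 0)))) {
    bad <- drugs[apply(conc, 1, function(r) any(diff(r) <= 0))]
    abort_validation(sprintf(
      "concentrations must be strictly increasing; offending drug(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  rownames(conc) <- drugs
  colnames(conc) <- paste0("c", seq_len(ncol(conc)) - 1)
  structure(
    list(
      drugs = drugs,
      unit = rep_len(as.character(unit), length(drugs)),
      conc = conc,
      n = length(drugs),
      L = ncol(conc) - 1L
    ),
    class = "qpop_panel"
  )
}

#' @export
print.qpop_panel <- function(x, ...) {
  cat(sprintf("qpop_panel: %d drugs, %d non-zero levels each\n", x$n, x$L))
  df <- data.frame(drug = x$drugs, unit = x$unit, x$conc, check.names = FALSE)
  rownames(df) <- NULL
  print(df, ...)
  invisible(x)
}

check_dose_vector <- function(panel, levels, allow_fractional = FALSE) {
  levels <- as.numeric(levels)
  if (length(levels) != panel$n) {
    abort_validation(sprintf(
      "dose vector length %d does not match panel size %d",
      length(levels), panel$n
    ))
  }
  if (any(!is.finite(levels))) abort_validation("dose levels must be finite")
  if (!allow_fractional && any(levels != round(levels))) {
    abort_validation("coded dose levels must be integers")
  }
  if (any(levels < 0 | levels > panel$L)) {
    abort_validation(sprintf("coded dose levels must lie in {0..%d}", panel$L))
  }
  levels
}

#' Map coded dose levels to concentrations
#'
#' Level 0 maps to 0 (vehicle); level `l` maps to the drug's `l`-th non-zero
#' concentration.
#'
#' @param panel a [drug_panel()].
#' @param levels integer vector of coded levels (length = panel size), or a
#'   matrix with one run per row.
#' @return numeric vector (or matrix) of concentrations, named by drug.
#' @export
coded_to_concentration <- function(panel, levels) {
  stopifnot(inherits(panel, "qpop_panel"))
  if (is.matrix(levels)) {
    out <- t(apply(levels, 1, function(r) coded_to_concentration(panel, r)))
    colnames(out) <- panel$drugs
    return(out)
  }
  lv <- check_dose_vector(panel, levels)
  out <- panel$conc[cbind(seq_len(panel$n), lv + 1)]
  names(out) <- panel$drugs
  out
}

#' Map concentrations back to coded dose levels
#'
#' Inverse of [coded_to_concentration()] on the panel grid; concentrations
#' not on the grid are an error.
#'
#' @inheritParams coded_to_concentration
#' @param conc numeric vector of concentrations, one per drug.
#' @return integer vector of coded levels.
#' @export
concentration_to_coded <- function(panel, conc) {
  stopifnot(inherits(panel, "qpop_panel"))
  if (length(conc) != panel$n) {
    abort_validation("`conc` must have one entry per drug")
  }
  out <- integer(panel$n)
  for (i in seq_len(panel$n)) {
    hit <- which(abs(panel$conc[i, ] - conc[i]) <= 1e-12 * max(1, abs(conc[i])))
    if (length(hit) != 1) {
      abort_validation(sprintf(
        "concentration %g for drug '%s' is not on its grid", conc[i], panel$drugs[i]
      ))
    }
    out[i] <- hit - 1L
  }
  names(out) <- panel$drugs
  out
}

#' Synthetic 11-drug example panel
#'
#' A fixture panel shaped like a T-cell lymphoma salvage screen: 11 drugs,
#' two non-zero concentration levels each. The drug names allow the named
#' regimens SMILE (dexamethasone, methotrexate, ifosfamide, l-asparaginase,
#' etoposide), GDP (gemcitabine, dexamethasone, cisplatin) and BP
#' (bortezomib, panobinostat) to be looked up in rankings. The concentration
#' values are synthetic placeholders on clinically plausible orders of
#' magnitude, not measured data.
#'
#' @return a `qpop_panel` with `n = 11`, `L = 2`.
#' @export
example_panel <- function() {
  drugs <- c(
    "bortezomib", "panobinostat", "pralatrexate", "cisplatin", "cytarabine",
    "l-asparaginase", "gemcitabine", "dexamethasone", "methotrexate",
    "etoposide", "ifosfamide"
  )
  conc <- rbind(
    c(0, 0.01, 0.1),    # bortezomib
    c(0, 0.001, 0.01),  # panobinostat
    c(0, 10, 100),      # pralatrexate
    c(0, 1, 10),        # cisplatin
    c(0, 0.5, 5),       # cytarabine
    c(0, 0.1, 1),       # l-asparaginase (IU/ml scale, coded alike)
    c(0, 0.05, 0.5),    # gemcitabine
    c(0, 0.1, 1),       # dexamethasone
    c(0, 0.05, 0.5),    # methotrexate
    c(0, 0.5, 5),       # etoposide
    c(0, 5, 50)         # ifosfamide
  )
  drug_panel(drugs, conc, unit = "uM")
}
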