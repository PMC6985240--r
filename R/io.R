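## File formats -------------------------------------------------------------
##
## All files are plain CSV (comma, UTF-8, "." decimal, mandatory header).
## Writers prepend a provenance comment line ("# qpopr <version> ...");
## readers skip comment lines. Schemas:
##   panel:         drug,unit,c0,c1,...           (c0 must be 0)
##   design:        run_id,<drug...>,viability,replicate  (viability optional)
##   dose_response: label,dose,response,replicate
##   combo:         label,dose_<A>,dose_<B>,response,replicate
##   regimen:       regimen,drug                  (long form)
##   surface:       term,estimate                 (+ JSON diagnostics sidecar)

provenance_header <- function(seed = NA, extra = "") {
  ver <- as.character(utils::packageVersion("qpopr"))
  sprintf("# qpopr %s | seed=%s | %s | hash=%s",
          ver, seed, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
          fnv1a_hash(paste(ver, seed, extra)))
}

write_csv_prov <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, paste(names(df), collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE),
    error = function(e) abort_schema(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e)))
  )
  df
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort_schema(sprintf("%s: missing required column(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
}

check_numeric_col <- function(df, col, path, offset = 1L) {
  x <- df[[col]]
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(x))
  if (length(bad)) {
    abort_schema(sprintf(
      "%s: non-numeric or non-finite value in column '%s' at data row %d",
      path, col, bad[1] + offset
    ))
  }
  x
}

#' Read a typed table from CSV
#'
#' Parses and validates one of the package's file schemas, reporting the
#' offending column/row on failure.
#'
#' @param path file path.
#' @param schema one of `"panel"`, `"design"`, `"dose_response"`, `"combo"`,
#'   `"regimen"`, `"surface"`.
#' @param panel a `qpop_panel`, required by the `design` and `surface`
#'   schemas.
#' @return a typed object: `qpop_panel`, `qpop_design`, data.frame
#'   (dose_response/combo), named list of character vectors (regimen), or
#'   `qpop_surface`.
#' @export
read_table <- function(path, schema, panel = NULL) {
  schema <- match.arg(schema,
                      c("panel", "design", "dose_response", "combo",
                        "regimen", "surface"))
  df <- read_csv_checked(path)
  switch(schema,
    panel = {
      require_cols(df, c("drug", "unit", "c0", "c1"), path)
      ccols <- grep("^c[0-9]+$", names(df), value = TRUE)
      ccols <- ccols[order(as.integer(sub("^c", "", ccols)))]
      conc <- sapply(ccols, function(cl) check_numeric_col(df, cl, path))
      drug_panel(df$drug, matrix(conc, nrow = nrow(df)), unit = df$unit)
    },
    design = {
      if (is.null(panel)) abort_validation("the design schema needs a `panel`")
      require_cols(df, c("run_id", panel$drugs), path)
      if (anyDuplicated(df$run_id)) {
        abort_schema(sprintf("%s: duplicate run_id '%s'",
                             path, df$run_id[duplicated(df$run_id)][1]))
      }
      runs <- sapply(panel$drugs, function(d) check_numeric_col(df, d, path))
      runs <- matrix(runs, nrow = nrow(df))
      for (j in seq_len(ncol(runs))) {
        bad <- which(runs[, j] != round(runs[, j]) | runs[, j] < 0 |
                       runs[, j] > panel$L)
        if (length(bad)) {
          abort_schema(sprintf(
            "%s: coded level %g out of range {0..%d} for drug '%s' at data row %d",
            path, runs[bad[1], j], panel$L, panel$drugs[j], bad[1] + 1L
          ))
        }
      }
      viab <- if ("viability" %in% names(df)) {
        check_numeric_col(df, "viability", path)
      }
      repl <- if ("replicate" %in% names(df)) df$replicate
      portion <- if ("portion" %in% names(df)) df$portion
      new_design(panel, runs, viability = viab, replicate = repl,
                 portion = portion)
    },
    dose_response = {
      require_cols(df, c("label", "dose", "response"), path)
      df$dose <- check_numeric_col(df, "dose", path)
      df$response <- check_numeric_col(df, "response", path)
      if (!"replicate" %in% names(df)) df$replicate <- 1L
      df
    },
    combo = {
      dcols <- grep("^dose_", names(df), value = TRUE)
      if (length(dcols) < 2 || !"response" %in% names(df)) {
        abort_schema(sprintf(
          "%s: combo schema needs >= 2 dose_<drug> columns and a response column",
          path
        ))
      }
      for (cl in c(dcols, "response")) df[[cl]] <- check_numeric_col(df, cl, path)
      df
    },
    regimen = {
      require_cols(df, c("regimen", "drug"), path)
      split(df$drug, df$regimen)
    },
    surface = {
      if (is.null(panel)) abort_validation("the surface schema needs a `panel`")
      require_cols(df, c("term", "estimate"), path)
      df$estimate <- check_numeric_col(df, "estimate", path)
      expected <- quad_term_names(panel$drugs)
      est <- df$estimate[match(expected, df$term)]
      if (anyNA(est)) {
        abort_schema(sprintf("%s: missing coefficient term(s): %s", path,
                             paste(utils::head(expected[is.na(est)], 5),
                                   collapse = ", ")))
      }
      n <- panel$n
      new_surface(panel$drugs, panel$L,
                  beta0 = est[1],
                  beta_lin = est[1 + seq_len(n)],
                  beta_quad = est[1 + n + seq_len(n)],
                  beta_int = est[-(seq_len(1 + 2 * n))],
                  diagnostics = read_surface_sidecar(path))
    }
  )
}

read_surface_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
}

#' Write a typed table to CSV
#'
#' Inverse of [read_table()]; every file starts with a provenance comment.
#'
#' @param x the object (`qpop_panel`, `qpop_design`, `qpop_surface`,
#'   `qpop_ranking`, or a plain data.frame).
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, seed = NA) {
  df <- if (inherits(x, "qpop_panel")) {
    data.frame(drug = x$drugs, unit = x$unit, x$conc, check.names = FALSE,
               row.names = NULL)
  } else if (inherits(x, "qpop_design")) {
    as.data.frame(x)
  } else if (inherits(x, "qpop_surface")) {
    side <- paste0(path, ".json")
    jsonlite::write_json(x$diagnostics, side, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    coef(x)
  } else if (inherits(x, "qpop_ranking")) {
    as.data.frame(x)
  } else {
    as.data.frame(x)
  }
  write_csv_prov(df, path, seed = seed)
}

## Configuration ------------------------------------------------------------

#' Read a flat key-value configuration file
#'
#' Lines of the form `key: value` (a YAML-compatible subset); `#` comments
#' and blank lines are ignored; comma-separated values become vectors;
#' numeric-looking values are coerced.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) abort_schema(sprintf("config: cannot parse line '%s'", ln))
    val <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Run the full screening-to-ranking pipeline
#'
#' Executes: read panel -> read (or build) the design with readouts ->
#' validate estimability -> fit the quadratic surface -> rank combinations
#' for each requested k -> look up named regimens -> optional response
#' surface map. All outputs plus a human-readable `summary.txt` go to
#' `out_dir`; every file carries a provenance header.
#'
#' @param config named list (or path to a [read_config()] file) with fields:
#'   `panel` (path, required), `readout` (path to a design CSV with a
#'   viability column, required), `out_dir` (required), `k` (vector of
#'   combination sizes, default 3), `ridge` (default 0), `top_m` (default
#'   10), `regimens` (path, optional), `map_pair` (two drug names, optional),
#'   `map_resolution` (default 25), `seed` (default 0).
#' @return invisibly, a list with the fitted surface, rankings, regimen
#'   lookups and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  for (f in c("panel", "readout", "out_dir")) {
    if (is.null(config[[f]])) abort_validation(sprintf("config is missing '%s'", f))
  }
  seed <- config$seed %||% 0
  ks <- as.integer(config$k %||% 3)
  ridge <- config$ridge %||% 0
  top_m <- config$top_m %||% 10

  panel <- read_table(config$panel, "panel")
  if (any(ks > panel$n)) {
    abort_validation(sprintf("requested k = %d exceeds panel size %d",
                             max(ks), panel$n))
  }
  design <- read_table(config$readout, "design", panel = panel)
  if (is.null(design$viability)) {
    abort_validation("readout file has no viability column")
  }

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    provenance_header(seed, "pipeline"),
    sprintf("panel: %s (%d drugs, L = %d)", config$panel, panel$n, panel$L),
    sprintf("readout: %s (%d runs)", config$readout, nrow(design$runs))
  )

  report <- validate_design(design)
  log_lines <- c(log_lines, sprintf(
    "design: rank %d / %d coefficients -> %s",
    report$rank, report$n_coefficients, if (report$pass) "estimable" else "DEFICIENT"
  ))
  if (!report$pass && ridge == 0) {
    abort_estimability(sprintf(
      "[validate-design] quadratic model not estimable; deficient terms: %s",
      paste(report$deficient_terms, collapse = ", ")
    ))
  }

  surface <- fit_surface(design, ridge = ridge)
  surface_path <- file.path(out_dir, "surface.csv")
  write_table(surface, surface_path, seed = seed)
  d <- surface$diagnostics
  log_lines <- c(log_lines, sprintf(
    "surface: R^2 = %.4f, residual SD = %.4g, LOOCV RMSE = %.4g",
    d$r_squared, d$sigma, d$loocv_rmse
  ))

  regimens <- if (!is.null(config$regimens)) {
    read_table(config$regimens, "regimen")
  }

  rankings <- list()
  lookups <- list()
  for (k in ks) {
    rk <- rank_combinations(surface, k)
    rk_path <- file.path(out_dir, sprintf("ranking_k%d.csv", k))
    write_table(rk, rk_path, seed = seed)
    rankings[[as.character(k)]] <- rk
    top <- top_combinations(rk, min(top_m, length(rk$score)))
    log_lines <- c(log_lines,
                   sprintf("-- top %d of %d possible %d-drug combinations --",
                           nrow(top), length(rk$score), k),
                   utils::capture.output(print(top, row.names = FALSE)))
    if (!is.null(regimens)) {
      for (nm in names(regimens)) {
        if (length(regimens[[nm]]) == k) {
          loc <- locate_regimen(rk, regimens[[nm]], name = nm)
          lookups[[nm]] <- loc
          log_lines <- c(log_lines, sprintf(
            "regimen %s: rank %d out of %d possible %d-drug combinations",
            nm, loc$rank, length(rk$score), k
          ))
        }
      }
    }
  }

  map_path <- NULL
  if (!is.null(config$map_pair)) {
    rsm <- response_surface_map(surface, as.character(config$map_pair),
                                resolution = config$map_resolution %||% 25)
    map_path <- file.path(out_dir, "response_surface.csv")
    write_table(rsm$grid, map_path, seed = seed)
    plot_response_surface(rsm, file.path(out_dir, "response_surface.png"))
    log_lines <- c(log_lines, sprintf("response surface map: %s x %s",
                                      rsm$pair[1], rsm$pair[2]))
  }

  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(log_lines, summary_path)
  invisible(list(
    panel = panel, design = design, report = report, surface = surface,
    rankings = rankings, regimen_lookups = lookups,
    paths = list(surface = surface_path, summary = summary_path, map = map_path,
                 rankings = file.path(out_dir, sprintf("ranking_k%d.csv", ks)))
  ))
}
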