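# Shared fixtures and independent oracles. Every oracle here is written from
# first principles (explicit loops / closed forms), deliberately avoiding the
# package's own model-matrix, enumeration and ranking code paths.

new_design_for_test <- function(panel, runs, ...) qpopr:::new_design(panel, runs, ...)

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("qpopr")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# evaluate a CLI call, swallowing its console output; returns the exit code
suppress_cli_output <- function(expr) {
  val <- NULL
  suppressMessages(utils::capture.output(val <- expr))
  val
}

tiny_panel <- function(n = 3, L = 2) {
  conc <- t(vapply(seq_len(n), function(i) c(0, i * 10^(seq_len(L) - 1)),
                   numeric(L + 1)))
  drug_panel(paste0("drug", letters[seq_len(n)]), conc)
}

# term-by-term quadratic evaluation, one scalar at a time
oracle_quad_eval <- function(beta0, beta_lin, beta_quad, beta_int, x) {
  n <- length(x)
  y <- beta0
  for (i in seq_len(n)) y <- y + beta_lin[i] * x[i] + beta_quad[i] * x[i]^2
  t <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      t <- t + 1
      y <- y + beta_int[t] * x[i] * x[j]
    }
  }
  unname(y)
}

# model matrix built by explicit per-row evaluation (independent of
# quad_model_matrix's vectorized construction)
oracle_model_matrix <- function(runs) {
  n <- ncol(runs)
  p <- 1 + 2 * n + n * (n - 1) / 2
  X <- matrix(NA_real_, nrow(runs), p)
  for (r in seq_len(nrow(runs))) {
    x <- runs[r, ]
    row <- c(1, x, x^2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) row <- c(row, x[i] * x[j])
    X[r, ] <- row
  }
  X
}

# closed-form normal-equations least squares
oracle_ols <- function(runs, y) {
  X <- oracle_model_matrix(runs)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# nested-loop enumeration counter (no combinatorics shortcuts)
oracle_count_assignments <- function(n, k, L) {
  count <- 0
  subsets <- utils::combn(n, k, simplify = FALSE)
  for (s in subsets) {
    lv <- rep(1, k)
    repeat {
      count <- count + 1
      pos <- k
      while (pos >= 1 && lv[pos] == L) {
        lv[pos] <- 1
        pos <- pos - 1
      }
      if (pos < 1) break
      lv[pos] <- lv[pos] + 1
    }
  }
  count
}

# independent score-then-stable-sort ranking oracle: enumerate by nested
# loops in lexicographic order, score each dose vector term-by-term, sort
oracle_ranking <- function(surface, k) {
  n <- surface$n
  L <- surface$L
  rows <- list()
  for (s in utils::combn(n, k, simplify = FALSE)) {
    lv <- rep(1, k)
    repeat {
      x <- rep(0, n)
      x[s] <- lv
      rows[[length(rows) + 1]] <- list(
        members = s, levels = lv,
        score = oracle_quad_eval(surface$beta0, surface$beta_lin,
                                 surface$beta_quad, surface$beta_int, x)
      )
      pos <- k
      while (pos >= 1 && lv[pos] == L) {
        lv[pos] <- 1
        pos <- pos - 1
      }
      if (pos < 1) break
      lv[pos] <- lv[pos] + 1
    }
  }
  scores <- vapply(rows, `[[`, numeric(1), "score")
  rows[order(scores, seq_along(scores))]
}

random_surface <- function(panel, seed) {
  set.seed(seed)
  n <- panel$n
  surface_truth(
    panel,
    beta0 = 1,
    beta_lin = rnorm(n, 0, 0.2),
    beta_quad = rnorm(n, 0, 0.05),
    beta_int = rnorm(n * (n - 1) / 2, 0, 0.05),
    noise_sd = 0
  )$surface
}
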