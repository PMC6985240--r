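test_that("enumeration counts match the nested-loop oracle", {
  cases <- expand.grid(n = 2:8, k = 1:4, L = 1:3)
  cases <- cases[cases$k <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; k <- cases$k[i]; L <- cases$L[i]
    asg <- enumerate_combinations(n, k, L)
    expect_equal(nrow(asg$members), oracle_count_assignments(n, k, L),
                 info = sprintf("n=%d k=%d L=%d", n, k, L))
  }
})

test_that("assignments are distinct and lexicographically ordered", {
  asg <- enumerate_combinations(5, 2, 3)
  keys <- apply(cbind(asg$members, asg$levels), 1, paste, collapse = "-")
  expect_false(anyDuplicated(keys) > 0)
  # lexicographic by member tuple then level tuple
  ord_key <- asg$members[, 1] * 1e6 + asg$members[, 2] * 1e4 +
    asg$levels[, 1] * 1e2 + asg$levels[, 2]
  expect_true(all(diff(ord_key) > 0))
  expect_error(enumerate_combinations(3, 4, 2), class = "qpop_validation_error")
  expect_equal(nrow(enumerate_combinations(2, 1, 1)$members), 2)
})

test_that("rank_combinations equals the independent score-then-sort oracle", {
  for (cfg in list(c(n = 4, k = 2, L = 2), c(n = 5, k = 3, L = 2),
                   c(n = 6, k = 3, L = 3))) {
    p <- tiny_panel(cfg["n"], cfg["L"])
    s <- random_surface(p, seed = 50 + cfg["n"])
    rk <- rank_combinations(s, cfg["k"])
    oracle <- oracle_ranking(s, cfg["k"])
    df <- as.data.frame(rk)
    expect_equal(nrow(df), length(oracle))
    for (r in seq_along(oracle)) {
      expect_equal(df$score[r], oracle[[r]]$score, tolerance = 1e-12)
      expect_equal(
        unlist(df[r, paste0("drug", seq_len(cfg["k"]))], use.names = FALSE),
        p$drugs[oracle[[r]]$members]
      )
      expect_equal(
        unlist(df[r, paste0("level", seq_len(cfg["k"]))], use.names = FALSE),
        oracle[[r]]$levels
      )
    }
  }
})

test_that("a dominant single drug owns the top of the ranking", {
  p <- tiny_panel(5)
  beta_lin <- rep(0, 5); beta_lin[2] <- -1 # drugb strongly cytotoxic
  s <- surface_truth(p, beta_lin = beta_lin, noise_sd = 0)$surface
  rk <- rank_combinations(s, 2)
  top <- top_combinations(rk, 4) # L^1 * (n-1) blocks; check first few
  expect_true(all(apply(top, 1, function(r) "drugb" %in% r[c("drug1", "drug2")])))
  expect_true(all(top[top$drug1 == "drugb", "level1"] == 2))
})

test_that("all-zero coefficients rank in enumeration order via the tie rule", {
  p <- tiny_panel(4)
  s <- surface_truth(p, beta0 = 0.7, noise_sd = 0)$surface
  rk <- rank_combinations(s, 2)
  expect_true(all(rk$score == 0.7))
  expect_equal(rk$perm, seq_along(rk$score))
})

test_that("ranks form a permutation with non-decreasing scores", {
  p <- tiny_panel(6)
  s <- random_surface(p, seed = 99)
  rk <- rank_combinations(s, 3)
  df <- as.data.frame(rk)
  expect_equal(sort(df$rank), seq_len(nrow(df)))
  expect_true(all(diff(df$score) >= -1e-14))
})

test_that("locate_regimen agrees with a brute-force minimum over levels", {
  p <- tiny_panel(6)
  s <- random_surface(p, seed = 123)
  rk <- rank_combinations(s, 3)
  members <- c("drugb", "drugd", "drugf")
  loc <- locate_regimen(rk, members, name = "test")
  # brute force: rank of every explicit level assignment
  best <- Inf
  for (l1 in 1:2) for (l2 in 1:2) for (l3 in 1:2) {
    r <- locate_regimen(rk, members, levels = c(l1, l2, l3))$rank
    best <- min(best, r)
  }
  expect_equal(loc$rank, best)
  expect_equal(nrow(loc$matches), 2^3)

  # the rank-1 assignment locates at rank 1
  top1 <- top_combinations(rk, 1)
  loc1 <- locate_regimen(rk, unlist(top1[paste0("drug", 1:3)]),
                         levels = unlist(top1[paste0("level", 1:3)]))
  expect_equal(loc1$rank, 1)

  expect_error(locate_regimen(rk, c("drugb", "drugd", "nosuchdrug")),
               regexp = "nosuchdrug", class = "qpop_validation_error")
  expect_error(locate_regimen(rk, c("drugb", "drugd")),
               class = "qpop_validation_error")
})

test_that("top_combinations bounds are enforced", {
  p <- tiny_panel(4)
  s <- random_surface(p, seed = 1)
  rk <- rank_combinations(s, 2)
  expect_equal(nrow(top_combinations(rk, length(rk$score))), length(rk$score))
  expect_error(top_combinations(rk, 0), class = "qpop_validation_error")
  expect_error(top_combinations(rk, length(rk$score) + 1),
               class = "qpop_validation_error")
})

test_that("ranking is invariant under drug relabeling", {
  p <- tiny_panel(5)
  s <- random_surface(p, seed = 8)
  rk <- as.data.frame(rank_combinations(s, 2))

  perm <- c(4, 2, 5, 1, 3)
  p2 <- drug_panel(p$drugs[perm], p$conc[perm, ])
  d <- build_oacd(p)
  y <- predict_viability(s, d$runs)
  s2 <- fit_surface(new_design_for_test(p2, d$runs[, perm], viability = y))
  rk2 <- as.data.frame(rank_combinations(s2, 2))
  # same multiset of (sorted member names, levels) at each score
  key <- function(df) {
    apply(df, 1, function(r) {
      m <- c(r[["drug1"]], r[["drug2"]])
      l <- c(r[["level1"]], r[["level2"]])
      o <- order(m)
      paste(c(m[o], l[o]), collapse = "|")
    })
  }
  expect_equal(sort(key(rk)), sort(key(rk2)))
  expect_equal(rk$score, rk2$score, tolerance = 1e-9)
})

test_that("more synergy never worsens the best rank of the affected pair", {
  p <- tiny_panel(5)
  base <- random_surface(p, seed = 77)
  pair_idx <- which(utils::combn(5, 2)[1, ] == 2 & utils::combn(5, 2)[2, ] == 4)
  prev_rank <- Inf
  for (delta in c(0, -0.1, -0.3, -0.6)) {
    s <- base
    s$beta_int[pair_idx] <- base$beta_int[pair_idx] + delta
    rk <- rank_combinations(s, 2)
    r <- locate_regimen(rk, c("drugb", "drugd"))$rank
    expect_lte(r, prev_rank)
    prev_rank <- r
  }
})
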