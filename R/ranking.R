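## Exhaustive combination enumeration and ranking --------------------------
##
## A "combination" is a size-k drug subset together with one non-zero coded
## level per member; an 11-drug panel with 2 non-zero levels therefore has
## C(11,5) * 2^5 = 14784 distinct 5-drug combinations and C(11,3) * 2^3 =
## 1320 3-drug combinations. Enumeration order is lexicographic by member
## index tuple, then by level tuple, and doubles as the deterministic
## tie-break for ranking.

#' Enumerate all k-drug combination assignments
#'
#' @param n panel size.
#' @param k combination size, `1 <= k <= n`.
#' @param L number of non-zero levels per drug.
#' @return list of class `qpop_assignments` with `members` (rows = ascending
#'   drug index tuples) and `levels` (rows = level tuples in `1..L`) matrices,
#'   one row per assignment, `C(n,k) * L^k` rows total, in lexicographic
#'   order.
#' @examples
#' nrow(enumerate_combinations(11, 5, 2)$members)  # 14784
#' @export
enumerate_combinations <- function(n, k, L) {
  check_number(n, "n", lower = 1, integral = TRUE)
  check_number(k, "k", lower = 1, integral = TRUE)
  check_number(L, "L", lower = 1, integral = TRUE)
  if (k > n) abort_validation(sprintf("k = %d exceeds panel size n = %d", k, n))
  subsets <- t(utils::combn(n, k)) # rows already in lexicographic order
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), k)))[, k:1, drop = FALSE]
  dimnames(grid) <- NULL
  n_sub <- nrow(subsets)
  n_lev <- nrow(grid)
  members <- subsets[rep(seq_len(n_sub), each = n_lev), , drop = FALSE]
  levels <- grid[rep(seq_len(n_lev), times = n_sub), , drop = FALSE]
  structure(
    list(members = members, levels = levels, n = as.integer(n),
         k = as.integer(k), L = as.integer(L)),
    class = "qpop_assignments"
  )
}

assignments_to_runs <- function(asg) {
  nr <- nrow(asg$members)
  runs <- matrix(0L, nr, asg$n)
  runs[cbind(rep(seq_len(nr), asg$k), as.vector(asg$members))] <-
    as.integer(as.vector(asg$levels))
  runs
}

#' Rank every k-drug combination by predicted viability
#'
#' Scores each assignment from [enumerate_combinations()] by evaluating the
#' fitted surface at its implied dose vector (members at their levels, all
#' other drugs at vehicle) and sorts ascending: rank 1 is the lowest
#' predicted viability, i.e. the most efficacious combination. Ties are
#' broken by enumeration order.
#'
#' @param surface a `qpop_surface`.
#' @param k combination size.
#' @return object of class `qpop_ranking`: list with `k`, `L`, `drugs`,
#'   `assignments` (enumeration order), `score` (enumeration order), and
#'   `perm` (the stable ordering permutation). Use [as.data.frame()] or
#'   [top_combinations()] for a readable table.
#' @export
rank_combinations <- function(surface, k) {
  stopifnot(inherits(surface, "qpop_surface"))
  asg <- enumerate_combinations(surface$n, k, surface$L)
  runs <- assignments_to_runs(asg)
  colnames(runs) <- surface$drugs
  score <- predict_viability(surface, runs)
  perm <- order(score, seq_along(score)) # stable: enumeration-order tie break
  structure(
    list(
      k = as.integer(k), L = surface$L, drugs = surface$drugs,
      assignments = asg, score = score, perm = perm,
      tie_rule_id = "enumeration-order"
    ),
    class = "qpop_ranking"
  )
}

#' @export
as.data.frame.qpop_ranking <- function(x, ...) {
  asg <- x$assignments
  m <- asg$members[x$perm, , drop = FALSE]
  l <- asg$levels[x$perm, , drop = FALSE]
  df <- data.frame(rank = seq_along(x$perm), score = x$score[x$perm])
  for (j in seq_len(x$k)) {
    df[[paste0("drug", j)]] <- x$drugs[m[, j]]
    df[[paste0("level", j)]] <- l[, j]
  }
  df
}

#' @export
print.qpop_ranking <- function(x, ...) {
  cat(sprintf("qpop_ranking: %d combinations of size k = %d (L = %d)\n",
              length(x$score), x$k, x$L))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' First m entries of a combination ranking
#'
#' @param ranking a `qpop_ranking`.
#' @param m number of entries, `1 <= m <=` total count.
#' @return data.frame of the top `m` rows (rank, score, members, levels).
#' @export
top_combinations <- function(ranking, m) {
  stopifnot(inherits(ranking, "qpop_ranking"))
  check_number(m, "m", lower = 1, upper = length(ranking$score), integral = TRUE)
  utils::head(as.data.frame(ranking), m)
}

#' Locate a named regimen within a ranking
#'
#' @param ranking a `qpop_ranking`.
#' @param members character vector of drug names (must all be on the panel,
#'   size = `ranking$k`).
#' @param levels optional integer vector of non-zero levels aligned with
#'   `members`; when absent the best (lowest) rank over all level assignments
#'   of the member set is returned.
#' @param name optional regimen label for reporting.
#' @return list with `name`, `rank` (best rank), and `matches` (data.frame of
#'   all matched entries with their ranks and levels).
#' @examples
#' # SMILE is steroid/dexamethasone + methotrexate + ifosfamide +
#' # l-asparaginase + etoposide on the example panel
#' @export
locate_regimen <- function(ranking, members, levels = NULL, name = NULL) {
  stopifnot(inherits(ranking, "qpop_ranking"))
  idx <- match(members, ranking$drugs)
  if (anyNA(idx)) {
    abort_validation(sprintf(
      "regimen drug(s) not on the panel: %s",
      paste(members[is.na(idx)], collapse = ", ")
    ))
  }
  if (anyDuplicated(idx)) abort_validation("regimen members must be unique")
  if (length(idx) != ranking$k) {
    abort_validation(sprintf(
      "regimen has %d members but the ranking is over %d-drug combinations",
      length(idx), ranking$k
    ))
  }
  target <- sort(idx)
  asg <- ranking$assignments
  hit <- which(rowSums(asg$members != matrix(target, nrow(asg$members),
                                             ranking$k, byrow = TRUE)) == 0)
  if (!is.null(levels)) {
    if (length(levels) != length(members) || any(levels < 1 | levels > ranking$L)) {
      abort_validation("`levels` must give one non-zero level per member")
    }
    lv <- levels[order(idx)]
    hit <- hit[rowSums(asg$levels[hit, , drop = FALSE] !=
                         matrix(lv, length(hit), ranking$k, byrow = TRUE)) == 0]
  }
  rank_of <- order(ranking$perm) # enumeration index -> rank
  ranks <- rank_of[hit]
  ord <- order(ranks)
  matches <- data.frame(rank = ranks[ord], score = ranking$score[hit][ord])
  for (j in seq_len(ranking$k)) {
    matches[[paste0("drug", j)]] <- ranking$drugs[asg$members[hit[ord], j]]
    matches[[paste0("level", j)]] <- asg$levels[hit[ord], j]
  }
  list(name = name %||% paste(members, collapse = "+"),
       rank = min(ranks), matches = matches)
}
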