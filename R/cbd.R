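# Core statistics for cyclic systems of dichotomous measurements:
# disturbance, context correlations, s_odd, the CbD criterion and Boole's
# condition of possible experience.

#' Disturbance of a 4-cycle system (probability scale)
#'
#' The disturbance statistic sums, over the four facets, the absolute
#' difference between a facet's marginal "judged fake" probability in the two
#' contexts that contain it:
#' \deqn{\Delta = |p_0-p_3| + |p_1-p_0| + |p_1-p_2| + |p_3-p_2|}
#' where \eqn{(p_0,p_1,p_2,p_3)} are the designated-outcome marginals of
#' contexts C0..C3 (see [designated_outcome()]).  A nondisturbing
#' (marginally selective) system has \eqn{\Delta = 0}; the maximum is 4.
#'
#' Note this is the probability-scale quantity; the expectation-scale
#' (\eqn{\pm 1}-coded) disturbance of the CbD literature is twice as large.
#'
#' @param p Numeric vector `c(p0, p1, p2, p3)` of marginal probabilities,
#'   or a matrix/data frame with four such columns (one row per coin).
#' @return Nonnegative disturbance value(s) in `[0, 4]`.
#' @examples
#' disturbance_delta(c(0.56, 0.46, 0.42, 0.46))  # 0.28
#' disturbance_delta(c(0.3, 0.3, 0.3, 0.3))      # 0
#' @seealso [cbd_statistic()], [s_odd()]
#' @export
disturbance_delta <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.matrix(p)) {
    if (ncol(p) != 4L) stop("marginal matrix must have 4 columns", call. = FALSE)
    return(apply(p, 1L, disturbance_delta))
  }
  if (length(p) != 4L) stop("need exactly 4 marginal probabilities", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("marginal probabilities must lie in [0, 1]", call. = FALSE)
  }
  unname(abs(p[1L] - p[4L]) + abs(p[2L] - p[1L]) +
           abs(p[2L] - p[3L]) + abs(p[4L] - p[3L]))
}

#' Product correlation of a measurement context
#'
#' Expectation of the product of the two outcomes of a context with "fake"
#' (top) coded +1 and "real" (bottom) coded -1:
#' `P(bb) + P(tt) - P(tb) - P(bt)`.  Forced-choice contexts, where the joint
#' outcomes (top,top) and (bottom,bottom) are impossible, always give -1.
#'
#' @param joint Numeric vector of the four joint-outcome probabilities in the
#'   order (bottom,bottom), (top,bottom), (bottom,top), (top,top); must sum
#'   to 1.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' context_correlation(c(0, 0.3, 0.7, 0))        # -1 (forced choice)
#' context_correlation(c(0.25, 0.25, 0.25, 0.25)) # 0
#' @export
context_correlation <- function(joint) {
  joint <- as.numeric(joint)
  if (length(joint) != 4L) stop("a context joint has 4 outcome probabilities",
                                call. = FALSE)
  if (anyNA(joint) || any(joint < 0)) {
    stop("joint probabilities must be nonnegative", call. = FALSE)
  }
  if (abs(sum(joint) - 1) > 1e-9) {
    stop("joint probabilities must sum to 1", call. = FALSE)
  }
  joint[1L] + joint[4L] - joint[2L] - joint[3L]
}

#' Maximal odd-sign correlation sum s_odd
#'
#' The contextuality "signal" of a cyclic system of `n` context correlations
#' `c_1..c_n`.  Two conventions are implemented:
#'
#' * `"canonical"` — the CbD-literature definition: the maximum of
#'   \eqn{\sum_i \lambda_i c_i} over all sign vectors
#'   \eqn{\lambda \in \{-1,+1\}^n} with an odd number of negative entries.
#'   Closed form: \eqn{\sum_i |c_i|} when the number of strictly negative
#'   correlations is odd (or any correlation is zero), otherwise
#'   \eqn{\sum_i |c_i| - 2\min_i |c_i|}.
#' * `"study"` — the convention used in the behavioural forced-choice
#'   analysis this package reproduces: the maximum over odd-cardinality
#'   subsets `S` of the absolute subset sum \eqn{|\sum_{i\in S} c_i|}.  For
#'   the four perfect anticorrelations of a forced-choice 4-cycle this
#'   equals 3 (the size-3 subsets), so the criterion of [cbd_statistic()]
#'   reduces to \eqn{1 - \Delta}.
#'
#' The two conventions disagree for perfectly anticorrelated systems: the
#' canonical value for `(-1,-1,-1,-1)` is 2, under which an ideal
#' forced-choice coin is *not* contextual (an alternating deterministic
#' assignment reproduces it).  The default is `"study"` so that published
#' forced-choice tables are reproduced; the canonical convention is provided
#' for reuse outside that setting.
#'
#' @param correlations Numeric vector of `n >= 3` context correlations in
#'   `[-1, 1]`.
#' @param convention `"study"` (default) or `"canonical"`.
#' @return The s_odd value.
#' @examples
#' s_odd(rep(-1, 4))                       # 3 (study convention)
#' s_odd(rep(-1, 4), "canonical")          # 2
#' s_odd(c(1, 1, 1, -1), "canonical")      # 4 (maximally contextual pattern)
#' @export
s_odd <- function(correlations, convention = c("study", "canonical")) {
  convention <- match.arg(convention)
  cc <- as.numeric(correlations)
  n <- length(cc)
  if (n < 3L) stop("s_odd needs at least 3 context correlations", call. = FALSE)
  if (anyNA(cc) || any(abs(cc) > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (convention == "canonical") {
    tot <- sum(abs(cc))
    n_neg <- sum(cc < 0)
    if (n_neg %% 2L == 1L || any(cc == 0)) tot else tot - 2 * min(abs(cc))
  } else {
    # max over odd-cardinality subsets S of |sum(cc[S])|; n stays small in
    # cyclic designs so direct subset enumeration is fine
    best <- -Inf
    for (size in seq(1L, n, by = 2L)) {
      sums <- utils::combn(cc, size, FUN = sum)
      best <- max(best, abs(sums))
    }
    best
  }
}

#' Cyclic-system contextuality statistic
#'
#' Left-hand side of the CbD criterion for a cyclic system of rank
#' `n_cycle` with disturbance allowed:
#' \deqn{s_{odd} - (n - 2) - \Delta}
#' A strictly positive value classifies the system as contextual.
#'
#' @param s_odd_value The s_odd statistic (see [s_odd()]).
#' @param n_cycle Rank of the cyclic system (number of contexts), `>= 3`.
#' @param delta Nonnegative disturbance (see [disturbance_delta()]).
#' @return The criterion value; positive means contextual by the point
#'   criterion.
#' @examples
#' cbd_statistic(3, 4, 0)     # 1: the ideal forced-choice coin is contextual
#' cbd_statistic(3, 4, 0.28)  # 0.72
#' @export
cbd_statistic <- function(s_odd_value, n_cycle, delta) {
  if (length(n_cycle) != 1L || n_cycle < 3L || n_cycle != as.integer(n_cycle)) {
    stop("n_cycle must be a single integer >= 3", call. = FALSE)
  }
  if (any(delta < 0)) stop("delta must be nonnegative", call. = FALSE)
  s_odd_value - (n_cycle - 2) - delta
}

#' Boole's condition of possible experience for four events
#'
#' For four events with single probabilities `p_i` and pairwise "both true"
#' probabilities `p_ij`, a joint probability distribution can exist only if
#' \deqn{\sum_i p_i - \sum_{i<j} p_{ij} \le 1.}
#' Violation (value > 1) shows that no joint distribution over the four
#' variables reproduces the observed frequencies.  In the cyclic
#' forced-choice design the non-adjacent pairs (0,2) and (1,3) are never
#' measured together; their `p_ij` must be supplied explicitly (the coin
#' analysis passes 0, the value forced on the adjacent pairs by the design).
#'
#' @param single_marginals Numeric vector of the four `P(top)` marginals.
#' @param pairwise_top Numeric vector of the six `P(top, top)` probabilities
#'   for the pairs (0,1), (0,2), (0,3), (1,2), (1,3), (2,3); may be named
#'   `p01, p02, p03, p12, p13, p23`.
#' @return A list with `value` (the left-hand side) and `satisfied`
#'   (`value <= 1`).
#' @examples
#' # ideal forced-choice coin: fair marginals, no (top,top) outcomes
#' boole_lhs(rep(0.5, 4), rep(0, 6))   # value 2, violated
#' # four independent fair coins
#' boole_lhs(rep(0.5, 4), rep(0.25, 6))  # value 0.5, satisfied
#' @export
boole_lhs <- function(single_marginals, pairwise_top) {
  p <- as.numeric(single_marginals)
  if (length(p) != 4L) stop("need 4 single marginals", call. = FALSE)
  pair_names <- c("p01", "p02", "p03", "p12", "p13", "p23")
  q <- pairwise_top
  if (!is.null(names(q)) && all(pair_names %in% names(q))) q <- q[pair_names]
  q <- as.numeric(q)
  if (length(q) != 6L || anyNA(q)) {
    stop("need all 6 pairwise P(top,top) values (pairs 01,02,03,12,13,23)",
         call. = FALSE)
  }
  if (any(p < 0) || any(p > 1) || any(q < 0) || any(q > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  value <- sum(p) - sum(q)
  list(value = value, satisfied = value <= 1)
}

#' Per-coin marginals from context tallies
#'
#' Converts designated-outcome counts `(k, n)` for the four contexts of each
#' coin into the marginal probabilities `p_i = k_i / n_i`, assigned in
#' context order (C0 -> p0, ..., C3 -> p3).
#'
#' @param counts Data frame with columns `coin_id`, `context` (`"C0"`..`"C3"`
#'   or 0--3), `n` and `k`, e.g. from [tally_judgments()].  All four contexts
#'   must be present for every coin, each with `n > 0`.
#' @return Data frame with columns `coin_id`, `p0`..`p3` (one row per coin),
#'   plus `gender_group` if present in `counts`.
#' @examples
#' counts <- data.frame(coin_id = 1, context = paste0("C", 0:3),
#'                      n = 50, k = c(28, 23, 21, 23))
#' marginals_from_counts(counts)  # p = (0.56, 0.46, 0.42, 0.46)
#' @export
marginals_from_counts <- function(counts) {
  required <- c("coin_id", "context", "n", "k")
  if (!all(required %in% names(counts))) {
    stop("counts must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$n <= 0)) stop("every context cell needs n > 0", call. = FALSE)
  if (any(counts$k < 0 | counts$k > counts$n)) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  counts$context <- as_context_index(counts$context)
  coins <- sort(unique(counts$coin_id))
  out <- lapply(coins, function(cid) {
    cell <- counts[counts$coin_id == cid, ]
    if (anyDuplicated(cell$context)) {
      stop("duplicate context cell for coin ", cid, call. = FALSE)
    }
    if (!setequal(cell$context, 0:3)) {
      stop("coin ", cid, " is missing context(s) ",
           paste0("C", setdiff(0:3, cell$context), collapse = ", "),
           call. = FALSE)
    }
    cell <- cell[order(cell$context), ]
    p <- cell$k / cell$n
    row <- data.frame(coin_id = cid, p0 = p[1L], p1 = p[2L], p2 = p[3L],
                      p3 = p[4L])
    if ("gender_group" %in% names(cell)) {
      row$gender_group <- as.character(cell$gender_group[1L])
    }
    row
  })
  do.call(rbind, out)
}
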