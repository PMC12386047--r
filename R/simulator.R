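# Simulator for the generalized n-cycle coin: every toss selects a context
# (an adjacent facet pair) and reveals exactly one "top" outcome, the two
# facets perfectly anticorrelating.

.JOINT_LEVELS <- c("bot.bot", "top.bot", "bot.top", "top.top")

#' Specify a generalized coin
#'
#' A generalized coin of cycle rank `n_cycle` is parameterized by one
#' probability per context: the probability that a toss in context `i`
#' yields the joint outcome (top, bottom), i.e. that the context's first
#' facet `A_i` shows top and its partner `A_{i+1}` shows bottom.  The ideal
#' coin has all probabilities 0.5; biased variants reproduce empirical
#' forced-choice behaviors with one sampling engine (see
#' [coin_spec_from_marginals()]).
#'
#' @param first_top_prob Numeric vector of per-context P(top, bottom)
#'   values; its length sets `n_cycle` (default: the ideal 4-cycle coin,
#'   `rep(0.5, 4)`).
#' @return Object of class `"coin_spec"`.
#' @examples
#' coin_spec()               # ideal coin
#' coin_spec(c(1, 1, 1, 1))  # deterministic: first facet always top
#' @export
coin_spec <- function(first_top_prob = rep(0.5, 4)) {
  q <- as.numeric(first_top_prob)
  if (length(q) < 3L) stop("a cyclic coin needs at least 3 contexts", call. = FALSE)
  if (anyNA(q) || any(q < 0) || any(q > 1)) {
    stop("context probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_cycle = length(q), first_top_prob = q), class = "coin_spec")
}

#' Coin specification matching observed forced-choice marginals
#'
#' Maps the four designated-outcome marginals `(p0, p1, p2, p3)` of the
#' 4-cycle face design onto a [coin_spec()].  The designated facet is the
#' *first* facet of the pair in contexts C0 and C2 but the *second* in C1
#' and C3 (see [designated_outcome()]), so the context P(top, bottom)
#' probabilities are `(p0, 1 - p1, p2, 1 - p3)`.
#'
#' @param p Numeric vector `c(p0, p1, p2, p3)`.
#' @return A `"coin_spec"` whose behavior has the given marginals.
#' @examples
#' coin_spec_from_marginals(c(0.56, 0.46, 0.42, 0.46))
#' @export
coin_spec_from_marginals <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 4L) stop("need 4 marginals", call. = FALSE)
  coin_spec(c(p[1L], 1 - p[2L], p[3L], 1 - p[4L]))
}

#' @export
print.coin_spec <- function(x, ...) {
  cat(sprintf("Generalized coin, %d-cycle; P(top,bottom) per context:\n",
              x$n_cycle))
  cat(" ", paste(sprintf("C%d=%.3g", seq_len(x$n_cycle) - 1L, x$first_top_prob),
                 collapse = "  "), "\n")
  invisible(x)
}

#' Toss a generalized coin in one context
#'
#' Draws `n` independent tosses in the given context.  Each toss yields
#' (top, bottom) with the context's probability and (bottom, top) otherwise;
#' the joint outcomes (top, top) and (bottom, bottom) never occur.
#'
#' @param spec A [coin_spec()].
#' @param context Context index `0..n_cycle-1` (or `"C0"`-style label for
#'   the 4-cycle).
#' @param n Number of tosses.
#' @return Factor of length `n` with levels
#'   `"bot.bot", "top.bot", "bot.top", "top.top"` giving the joint outcome
#'   (first facet, second facet) of each toss.
#' @examples
#' set.seed(1)
#' table(toss_coin(coin_spec(), 0, 1000))
#' @export
toss_coin <- function(spec, context, n = 1) {
  stopifnot(inherits(spec, "coin_spec"))
  i <- if (is.numeric(context) && spec$n_cycle != 4L) {
    i <- as.integer(context)
    if (length(i) != 1L || is.na(i) || i < 0L || i >= spec$n_cycle) {
      stop("context index out of range", call. = FALSE)
    }
    i
  } else {
    as_context_index(context)
  }
  if (length(i) != 1L) stop("context must be a single value", call. = FALSE)
  if (i >= spec$n_cycle) stop("context index out of range", call. = FALSE)
  first_top <- stats::runif(n) < spec$first_top_prob[i + 1L]
  factor(ifelse(first_top, "top.bot", "bot.top"), levels = .JOINT_LEVELS)
}

#' Estimate the empirical behavior of a generalized coin
#'
#' Tosses the coin `n_tosses` times in every context and assembles the
#' empirical behavior: per-context joint distributions, product
#' correlations, per-facet marginals and adjacent P(top, top) values.
#' Facet `A_i` is measured in context `i` (as first facet) and context
#' `i-1` (as second); `single_marginals` pools both estimates, while
#' `facet_marginals_by_context` keeps them separate for nondisturbance
#' checks.
#'
#' @param spec A [coin_spec()].
#' @param n_tosses Tosses per context.
#' @param seed Optional seed; the caller's random-number state is preserved.
#' @return Object of class `"coin_behavior"`: list with `n_cycle`, `joints`
#'   (list of named length-4 joint distributions, one per context),
#'   `context_correlations`, `single_marginals`,
#'   `facet_marginals_by_context` (matrix: rows = facets, columns =
#'   first/second context estimate), `pairwise_top_adjacent` and `n_tosses`.
#' @examples
#' est <- estimate_behavior(coin_spec(), n_tosses = 2000, seed = 1)
#' est$context_correlations   # all exactly -1 (forced choice)
#' @export
estimate_behavior <- function(spec, n_tosses, seed = NULL) {
  stopifnot(inherits(spec, "coin_spec"))
  if (n_tosses < 1) stop("n_tosses must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  n_cyc <- spec$n_cycle
  joints <- vector("list", n_cyc)
  for (i in seq_len(n_cyc) - 1L) {
    tosses <- if (n_cyc == 4L) toss_coin(spec, i, n_tosses) else {
      first_top <- stats::runif(n_tosses) < spec$first_top_prob[i + 1L]
      factor(ifelse(first_top, "top.bot", "bot.top"), levels = .JOINT_LEVELS)
    }
    joints[[i + 1L]] <- as.vector(table(tosses)) / n_tosses
    names(joints[[i + 1L]]) <- .JOINT_LEVELS
  }
  names(joints) <- paste0("C", seq_len(n_cyc) - 1L)
  correlations <- vapply(joints, context_correlation, numeric(1))
  # facet i: first-facet marginal in context i, second-facet in context i-1
  first_est <- vapply(joints, function(j) j["top.bot"] + j["top.top"], numeric(1))
  second_est <- vapply(joints, function(j) j["bot.top"] + j["top.top"], numeric(1))
  facet_mat <- cbind(first = unname(first_est),
                     second = unname(second_est[c(n_cyc, seq_len(n_cyc - 1L))]))
  rownames(facet_mat) <- paste0("A", seq_len(n_cyc) - 1L)
  out <- list(
    n_cycle = n_cyc, joints = joints, context_correlations = correlations,
    single_marginals = rowMeans(facet_mat),
    facet_marginals_by_context = facet_mat,
    pairwise_top_adjacent = vapply(joints, function(j) unname(j["top.top"]),
                                   numeric(1)),
    n_tosses = n_tosses
  )
  class(out) <- "coin_behavior"
  out
}

#' Boole condition of a 4-cycle behavior
#'
#' Evaluates [boole_lhs()] on an estimated behavior.  The cyclic design
#' never measures the non-adjacent pairs (0,2) and (1,3); their
#' P(top, top) must be assumed and defaults to 0, the value the design
#' forces on every adjacent pair.
#'
#' @param behavior A `"coin_behavior"` from [estimate_behavior()] with
#'   `n_cycle = 4`.
#' @param nonadjacent_top Assumed P(top, top) for the two unmeasured pairs
#'   (default 0).
#' @return As [boole_lhs()]: list with `value` and `satisfied`.
#' @examples
#' est <- estimate_behavior(coin_spec(), n_tosses = 5000, seed = 1)
#' boole_from_behavior(est)   # value near 2: condition violated
#' @export
boole_from_behavior <- function(behavior, nonadjacent_top = 0) {
  stopifnot(inherits(behavior, "coin_behavior"))
  if (behavior$n_cycle != 4L) {
    stop("Boole evaluation is implemented for the 4-cycle", call. = FALSE)
  }
  adj <- behavior$pairwise_top_adjacent
  boole_lhs(behavior$single_marginals,
            c(p01 = unname(adj[1L]), p02 = nonadjacent_top,
              p03 = unname(adj[4L]), p12 = unname(adj[2L]),
              p13 = nonadjacent_top, p23 = unname(adj[3L])))
}
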