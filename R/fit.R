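# Single-coin estimator: point statistics plus percentile-bootstrap interval.

#' Fit the contextuality statistic of one forced-choice coin
#'
#' Given the designated-outcome counts of a coin's four measurement contexts,
#' computes the marginals, the disturbance, the CbD statistic, a percentile
#' bootstrap confidence interval, and the contextual classification.
#'
#' Resampling is at the level of individual judgments within each
#' (coin, context) cell: each bootstrap replicate redraws
#' `k* ~ Binomial(n_i, k_i/n_i)` per context (equivalent to resampling the
#' `n_i` binary judgments with replacement), recomputes the marginals and the
#' statistic, and the interval is formed from empirical quantiles (linear
#' interpolation) of the replicates.  Forced choice makes every context
#' correlation exactly -1 in every replicate, so under the `"study"`
#' convention the statistic is `1 - delta` throughout.
#'
#' @param k Integer vector of designated-outcome counts for contexts C0..C3.
#' @param n Judgments per context; a single number or a vector of four.
#' @param coin_id Optional coin identifier carried into the result.
#' @param gender Optional group label (`"F"`/`"M"`) carried into the result.
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param ci_level Confidence level of the percentile interval (default 0.95).
#' @param convention s_odd convention, `"study"` (default) or `"canonical"`;
#'   see [s_odd()].
#' @param seed Optional integer seed; when supplied the fit is reproducible
#'   and the caller's random-number state is left untouched.
#' @param keep_replicates Keep the vector of bootstrap replicates in the
#'   returned object (default `TRUE`; set `FALSE` to save memory in large
#'   batch runs).
#' @return An object of class `"cbd_coin"`: a list with components
#'   `coin_id`, `gender`, `counts` (data frame), `marginals` (named numeric,
#'   `p0`..`p3`), `delta`, `s_odd`, `n_cycle`, `cbd`, `ci` (length-2 numeric),
#'   `ci_level`, `n_boot`, `seed`, `convention`, `contextual`, `boundary`
#'   (is an interval endpoint within 0.02 of zero?) and optionally
#'   `replicates`.
#' @examples
#' fit <- cbd_coin(k = c(28, 23, 21, 23), n = 50, coin_id = 1, seed = 1)
#' fit
#' coef(fit)     # the four marginals
#' confint(fit)  # percentile bootstrap interval
#' @seealso [cbd_analysis()] for fitting a whole study at once.
#' @export
cbd_coin <- function(k, n = 50, coin_id = NA_integer_, gender = NA_character_,
                     n_boot = 10000, ci_level = 0.95,
                     convention = c("study", "canonical"), seed = NULL,
                     keep_replicates = TRUE) {
  convention <- match.arg(convention)
  k <- as.numeric(k)
  if (length(k) != 4L) stop("k must give counts for the 4 contexts", call. = FALSE)
  if (length(n) == 1L) n <- rep(n, 4L)
  n <- as.numeric(n)
  if (length(n) != 4L || any(n <= 0)) {
    stop("n must be positive, one value per context", call. = FALSE)
  }
  if (anyNA(k) || any(k < 0) || any(k > n) || any(k != round(k))) {
    stop("counts must be integers with 0 <= k <= n", call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)", call. = FALSE)

  p <- k / n
  names(p) <- paste0("p", 0:3)
  delta <- disturbance_delta(p)
  # forced choice: both joint outcomes in every context anticorrelate exactly
  correlations <- rep(-1, 4L)
  s <- s_odd(correlations, convention)
  cbd <- cbd_statistic(s, 4L, delta)

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
  kstar <- vapply(1:4, function(j) stats::rbinom(n_boot, n[j], p[j]),
                  numeric(n_boot))
  if (n_boot == 1L) kstar <- matrix(kstar, nrow = 1L)
  if (length(unique(n)) == 1L) {
    # equal cell sizes: integer count differences with a single division keep
    # replicates exactly on the k/n grid, so the strict lower-endpoint rule
    # is not perturbed by ~1e-16 float noise at the zero atom
    dstar <- (abs(kstar[, 1L] - kstar[, 4L]) + abs(kstar[, 2L] - kstar[, 1L]) +
                abs(kstar[, 2L] - kstar[, 3L]) + abs(kstar[, 4L] - kstar[, 3L])) /
      n[1L]
  } else {
    pstar <- sweep(kstar, 2L, n, "/")
    dstar <- abs(pstar[, 1L] - pstar[, 4L]) + abs(pstar[, 2L] - pstar[, 1L]) +
      abs(pstar[, 2L] - pstar[, 3L]) + abs(pstar[, 4L] - pstar[, 3L])
  }
  cbdstar <- s - 2 - dstar
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(cbdstar, c(alpha, 1 - alpha), type = 7))

  out <- list(
    coin_id = coin_id, gender = gender,
    counts = data.frame(context = paste0("C", 0:3), n = n, k = k),
    marginals = p, delta = delta, s_odd = s, n_cycle = 4L, cbd = cbd,
    ci = ci, ci_level = ci_level, n_boot = as.integer(n_boot), seed = seed,
    convention = convention,
    contextual = classify_contextual(cbd, ci[1L], ci[2L]),
    boundary = any(abs(ci) < 0.02)
  )
  if (keep_replicates) out$replicates <- cbdstar
  class(out) <- "cbd_coin"
  out
}

#' Contextuality classification rule
#'
#' A coin is classified contextual when its point statistic lies inside the
#' bootstrap interval (inclusive) *and* the interval's lower endpoint is
#' strictly positive.  The strict inequality matters in practice: a coin
#' whose lower endpoint is exactly 0 is not contextual.
#'
#' @param cbd Point value of the contextuality statistic, or a `"cbd_coin"`
#'   object (in which case the other arguments are ignored).
#' @param ci_lower,ci_upper Interval endpoints.
#' @return Logical.
#' @examples
#' classify_contextual(0.72, 0.24, 0.88)   # TRUE
#' classify_contextual(0.40, 0.00, 0.62)   # FALSE: lower bound not > 0
#' @export
classify_contextual <- function(cbd, ci_lower = NULL, ci_upper = NULL) {
  if (inherits(cbd, "cbd_coin")) {
    ci_lower <- cbd$ci[1L]
    ci_upper <- cbd$ci[2L]
    cbd <- cbd$cbd
  }
  if (is.null(ci_lower) || is.null(ci_upper)) {
    stop("supply interval endpoints or a cbd_coin object", call. = FALSE)
  }
  if (ci_lower > ci_upper) stop("ci_lower must not exceed ci_upper", call. = FALSE)
  (ci_lower <= cbd) && (cbd <= ci_upper) && (ci_lower > 0)
}

#' @export
print.cbd_coin <- function(x, digits = 2, ...) {
  id <- if (is.na(x$coin_id)) "" else paste0(" ", x$coin_id)
  cat(sprintf("Forced-choice coin%s (%s convention)\n", id, x$convention))
  cat("  marginals: ",
      paste(sprintf("%s=%.*f", names(x$marginals), digits, x$marginals),
            collapse = "  "), "\n", sep = "")
  cat(sprintf("  disturbance  = %.*f\n", digits, x$delta))
  cat(sprintf("  CbD value    = %.*f   %d%% CI [%.*f, %.*f]  (%d resamples)\n",
              digits, x$cbd, round(100 * x$ci_level), digits, x$ci[1L],
              digits, x$ci[2L], x$n_boot))
  cat("  contextual   =", if (x$contextual) "yes" else "no",
      if (x$boundary) " (interval endpoint near 0)" else "", "\n")
  invisible(x)
}

#' @export
coef.cbd_coin <- function(object, ...) object$marginals

#' @export
confint.cbd_coin <- function(object, parm = "cbd", level = NULL, ...) {
  if (!is.null(level) && abs(level - object$ci_level) > 1e-12) {
    if (is.null(object$replicates)) {
      stop("replicates were not kept; refit with keep_replicates = TRUE ",
           "to extract a different level", call. = FALSE)
    }
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(object$replicates, c(alpha, 1 - alpha),
                                 type = 7))
  } else {
    level <- object$ci_level
    ci <- object$ci
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("cbd", sprintf("%g %%", 100 * c((1 - level) / 2,
                                                                1 - (1 - level) / 2))))
  out
}
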