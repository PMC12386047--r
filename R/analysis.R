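# Whole-study estimator: fits every coin, assembles the results table and
# the fake/real accuracy summary.

#' @keywords internal
coin_seed <- function(master_seed, coin_id) {
  # deterministic per-coin substream so any coin can be refit independently;
  # kept inside the 32-bit integer range
  as.integer((as.numeric(master_seed) * 1009 + as.numeric(coin_id) * 7919) %%
               2147483647)
}

#' @keywords internal
as_counts_input <- function(x, n_per_context, quiet = FALSE) {
  if (!is.data.frame(x)) stop("input must be a data frame (judgments, counts ",
                              "or marginals)", call. = FALSE)
  if (nrow(x) == 0L) stop("input is empty", call. = FALSE)
  if (all(c("coin_id", "context", "n", "k") %in% names(x))) return(x)
  if ("judged_fake_facet" %in% names(x)) return(tally_judgments(x))
  if (all(paste0("p", 0:3) %in% names(x))) {
    names(x)[tolower(names(x)) == "coin"] <- "coin_id"
    names(x)[tolower(names(x)) == "gender"] <- "gender_group"
    if (!"coin_id" %in% names(x)) x$coin_id <- seq_len(nrow(x))
    return(reconstruct_counts(x, n = n_per_context, quiet = quiet))
  }
  stop("cannot interpret input: expected judgment records, (coin_id, context, ",
       "n, k) counts, or a marginals table with p0..p3", call. = FALSE)
}

#' Contextuality analysis of a forced-choice study
#'
#' Fits the CbD contextuality statistic with a percentile-bootstrap interval
#' for every coin (image set) of a forced-choice study.  Accepts any of
#' three inputs and converts them internally:
#'
#' * raw judgment records (as read by [read_judgments()] or produced by
#'   [generate_judgments()]);
#' * a counts table with columns `coin_id`, `context`, `n`, `k`;
#' * a marginals table with columns `coin_id`, `p0`..`p3` (a published-style
#'   summary is a valid input; counts are reconstructed as
#'   `k = round(n * p)`, see [reconstruct_counts()]).
#'
#' Point statistics depend only on the counts; the bootstrap intervals are
#' seeded per coin from `seed` so the whole analysis is reproducible and any
#' coin can be recomputed on its own.
#'
#' @param x Input data frame (see above).
#' @param n_boot Bootstrap iterations per coin (default 10000).
#' @param ci_level Confidence level (default 0.95).
#' @param convention s_odd convention, `"study"` or `"canonical"` ([s_odd()]).
#' @param seed Master seed for the bootstrap (default 1).
#' @param n_per_context Judgments per context assumed when reconstructing
#'   counts from a marginals table (default 50).
#' @param quiet Suppress count-reconstruction messages.
#' @return Object of class `"cbd_analysis"`: list with `results` (one row
#'   per coin: `coin_id`, `p0`..`p3`, `gender_group`, `delta`, `s_odd`,
#'   `cbd`, `ci_lower`, `ci_upper`, `contextual`, `boundary`), `coins`
#'   (list of [cbd_coin()] fits), `accuracy` (see [summarize_accuracy()];
#'   `NULL` without gender labels) and `config`.
#' @examples
#' fit <- cbd_analysis(face_study_marginals(), n_boot = 500, seed = 42)
#' fit
#' coef(fit)[1:3, ]
#' @seealso [cbd_coin()], [summarize_accuracy()], [write_results()]
#' @export
cbd_analysis <- function(x, n_boot = 10000, ci_level = 0.95,
                         convention = c("study", "canonical"), seed = 1L,
                         n_per_context = 50, quiet = FALSE) {
  convention <- match.arg(convention)
  counts <- as_counts_input(x, n_per_context = n_per_context, quiet = quiet)
  marg <- marginals_from_counts(counts)
  counts$context <- context_label(counts$context)

  coins <- lapply(seq_len(nrow(marg)), function(i) {
    cid <- marg$coin_id[i]
    cell <- counts[counts$coin_id == cid, ]
    cell <- cell[order(as_context_index(cell$context)), ]
    cbd_coin(k = cell$k, n = cell$n, coin_id = cid,
             gender = if ("gender_group" %in% names(marg))
               marg$gender_group[i] else NA_character_,
             n_boot = n_boot, ci_level = ci_level, convention = convention,
             seed = coin_seed(seed, cid), keep_replicates = FALSE)
  })
  results <- do.call(rbind, lapply(coins, function(f) {
    data.frame(coin_id = f$coin_id, p0 = f$marginals[1L], p1 = f$marginals[2L],
               p2 = f$marginals[3L], p3 = f$marginals[4L],
               gender_group = f$gender, delta = f$delta, s_odd = f$s_odd,
               cbd = f$cbd, ci_lower = f$ci[1L], ci_upper = f$ci[2L],
               contextual = f$contextual, boundary = f$boundary,
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  accuracy <- if ("gender_group" %in% names(marg) &&
                  !anyNA(marg$gender_group)) {
    summarize_accuracy(marg)
  }
  out <- list(results = results, coins = coins, accuracy = accuracy,
              config = list(n_boot = as.integer(n_boot), ci_level = ci_level,
                            convention = convention, seed = seed,
                            n_per_context = n_per_context),
              call = match.call())
  class(out) <- "cbd_analysis"
  out
}

#' Fake/real accuracy summary
#'
#' Participant accuracy in the forced-choice task, split by face type: the
#' marginals `p0` and `p2` are probabilities of *correctly* judging a fake
#' face fake, while `p1` and `p3` are probabilities of *incorrectly* judging
#' a real face fake, whose mean is reported as the real-face column of the
#' published-style summary.  Means are taken within each gender group, over
#' all coins, and over all 4 marginals of every coin (grand mean).
#'
#' @param marginals Data frame with columns `p0`..`p3` and `gender_group`
#'   (one row per coin).
#' @return Object of class `"cbd_accuracy"`: list with `table` (rows per
#'   group plus `"Total"`; columns `group`, `fake`, `real`) and
#'   `grand_mean`.
#' @examples
#' summarize_accuracy(face_study_marginals())
#' @export
summarize_accuracy <- function(marginals) {
  needed <- c(paste0("p", 0:3), "gender_group")
  if (!all(needed %in% names(marginals))) {
    stop("marginals must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  fake_cols <- as.matrix(marginals[, c("p0", "p2")])
  real_cols <- as.matrix(marginals[, c("p1", "p3")])
  groups <- unique(as.character(marginals$gender_group))
  tab <- do.call(rbind, lapply(groups, function(g) {
    sel <- marginals$gender_group == g
    data.frame(group = g, fake = mean(fake_cols[sel, ]),
               real = mean(real_cols[sel, ]), stringsAsFactors = FALSE)
  }))
  tab <- rbind(tab, data.frame(group = "Total", fake = mean(fake_cols),
                               real = mean(real_cols)))
  out <- list(table = tab, grand_mean = mean(cbind(fake_cols, real_cols)))
  class(out) <- "cbd_accuracy"
  out
}

#' @export
print.cbd_accuracy <- function(x, digits = 2, ...) {
  cat("Forced-choice accuracy by face type\n")
  tab <- x$table
  tab$fake <- sprintf("%.*f", digits, tab$fake)
  tab$real <- sprintf("%.*f", digits, tab$real)
  print(tab, row.names = FALSE)
  cat(sprintf("Grand mean: %.*f\n", digits, x$grand_mean))
  invisible(x)
}

#' @export
print.cbd_analysis <- function(x, digits = 2, ...) {
  res <- x$results
  cat(sprintf(
    "Contextuality-by-Default analysis: %d coins, %d%% percentile bootstrap (%d iterations, %s convention)\n\n",
    nrow(res), round(100 * x$config$ci_level), x$config$n_boot,
    x$config$convention))
  fmt <- function(v) sprintf("%.*f", digits, v)
  disp <- data.frame(Coin = res$coin_id, p0 = fmt(res$p0), p1 = fmt(res$p1),
                     p2 = fmt(res$p2), p3 = fmt(res$p3),
                     Gender = res$gender_group, Delta = fmt(res$delta),
                     CbD = fmt(res$cbd),
                     Interval = format_interval(res$ci_lower, res$ci_upper,
                                                digits),
                     Contextual = ifelse(res$contextual, "yes", "no"),
                     stringsAsFactors = FALSE)
  print(disp, row.names = FALSE)
  cat(sprintf("\n%d of %d coins contextual (CbD inside interval and lower bound > 0)\n",
              sum(res$contextual), nrow(res)))
  invisible(x)
}

#' @export
summary.cbd_analysis <- function(object, digits = 2, ...) {
  print(object, digits = digits)
  res <- object$results
  if (any(res$boundary)) {
    cat("\nBoundary coins (interval endpoint within 0.02 of 0): ",
        paste(res$coin_id[res$boundary], collapse = ", "),
        "\n  their classification may be sensitive to the bootstrap seed.\n",
        sep = "")
  }
  if (!is.null(object$accuracy)) {
    cat("\n")
    print(object$accuracy, digits = digits)
  }
  invisible(object)
}

#' @export
coef.cbd_analysis <- function(object, ...) {
  m <- as.matrix(object$results[, paste0("p", 0:3)])
  rownames(m) <- object$results$coin_id
  m
}

#' @export
as.data.frame.cbd_analysis <- function(x, ...) x$results

#' Interval plot of a contextuality analysis
#'
#' Draws each coin's CbD point statistic with its bootstrap interval;
#' contextual coins (interval lower bound above the dashed zero line, point
#' inside the interval) are filled.
#'
#' @param x A [cbd_analysis()] object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cbd_analysis <- function(x, ...) {
  res <- x$results
  idx <- seq_len(nrow(res))
  graphics::plot(idx, res$cbd, ylim = range(res$ci_lower, res$ci_upper, 0),
                 pch = ifelse(res$contextual, 19, 1),
                 xlab = "Coin", ylab = "CbD statistic", xaxt = "n", ...)
  graphics::axis(1, at = idx, labels = res$coin_id)
  graphics::segments(idx, res$ci_lower, idx, res$ci_upper)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
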