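# Readers, writers and the tally layer for judgment records and result
# tables.  The judgment CSV schema is the package's canonical format:
# coin_id, gender_group, context, participant_id, position_swapped,
# judged_fake_facet.

.JUDGMENT_COLUMNS <- c("coin_id", "gender_group", "context", "participant_id",
                       "position_swapped", "judged_fake_facet")

#' @keywords internal
validate_judgments <- function(records, where = "judgment data") {
  missing_cols <- setdiff(.JUDGMENT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop(where, " is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$context <- context_label(records$context)  # validates labels too
  records$coin_id <- as.integer(records$coin_id)
  records$judged_fake_facet <- as.integer(records$judged_fake_facet)
  records$position_swapped <- as.logical(records$position_swapped)
  bad <- which(
    is.na(records$coin_id) | records$coin_id < 1L |
      is.na(records$judged_fake_facet) |
      is.na(records$position_swapped) |
      !(records$judged_fake_facet == as_context_index(records$context) |
          records$judged_fake_facet == (as_context_index(records$context) + 1L) %% 4L)
  )
  if (length(bad)) {
    show <- utils::head(bad, 5L)
    stop(where, ": ", length(bad), " invalid row(s); e.g. row",
         if (length(show) > 1L) "s", " ",
         paste(show, collapse = ", "),
         " (judged facet must belong to the context's pair; coin_id >= 1)",
         call. = FALSE)
  }
  records[, .JUDGMENT_COLUMNS]
}

#' Read forced-choice judgment records
#'
#' Reads a judgment CSV (UTF-8, header required) with columns `coin_id`,
#' `gender_group`, `context` (`"C0"`..`"C3"`), `participant_id`,
#' `position_swapped` (logical; `TRUE` when the real face was shown on the
#' right) and `judged_fake_facet` (facet index 0--3).  Every record is
#' validated: the judged facet must be one of the two facets measured in the
#' record's context.  Invalid rows abort with row-level diagnostics.
#'
#' `position_swapped` is carried through but ignored by all statistics (the
#' design counterbalances presentation order and then pools), so order-effect
#' checks remain possible downstream.
#'
#' @param file Path or connection of the CSV.
#' @return Validated data frame of judgment records.
#' @seealso [write_judgments()], [tally_judgments()], [generate_judgments()]
#' @export
read_judgments <- function(file) {
  records <- utils::read.csv(file, stringsAsFactors = FALSE,
                             colClasses = c(gender_group = "character",
                                            context = "character",
                                            participant_id = "character"))
  if (nrow(records) == 0L) {
    stop("judgment file ", if (is.character(file)) file else "", " is empty",
         call. = FALSE)
  }
  validate_judgments(records, where = if (is.character(file)) file else "judgment data")
}

#' Write forced-choice judgment records
#'
#' Writes judgment records in the package's canonical CSV schema; a
#' round-trip through [write_judgments()] and [read_judgments()] reproduces
#' the records exactly.
#'
#' @param records Data frame of judgment records (validated before writing).
#' @param file Path or connection to write to.
#' @return `records`, invisibly.
#' @export
write_judgments <- function(records, file) {
  records <- validate_judgments(records)
  utils::write.csv(records, file, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' Tally judgments into designated-outcome counts
#'
#' Collapses raw judgment records into one `(n, k)` cell per
#' (coin, context): `n` counts all judgments in the cell and `k` those whose
#' judged facet equals the context's designated outcome facet (see
#' [designated_outcome()]).  Cells with no records are simply absent;
#' downstream analysis reports them as errors.
#'
#' @param records Data frame of judgment records.
#' @return Data frame with columns `coin_id`, `context`, `n`, `k` (plus
#'   `gender_group` when present), ordered by coin and context.
#' @examples
#' design <- experiment_design(n_participants_per_context = 10, master_seed = 1)
#' head(tally_judgments(generate_judgments(design)))
#' @export
tally_judgments <- function(records) {
  records <- validate_judgments(records)
  hit <- records$judged_fake_facet == designated_outcome(records$context)
  key <- interaction(records$coin_id, records$context, drop = TRUE)
  n <- as.vector(rowsum(rep(1L, nrow(records)), key))
  k <- as.vector(rowsum(as.integer(hit), key))
  first <- !duplicated(key)
  out <- data.frame(coin_id = records$coin_id[first],
                    context = records$context[first])
  out <- out[order(match(key[first], levels(key))), , drop = FALSE]
  out$n <- n
  out$k <- k
  gender <- unique(records[, c("coin_id", "gender_group")])
  if (!anyDuplicated(gender$coin_id)) out <- merge(out, gender, by = "coin_id")
  out <- out[order(out$coin_id, out$context), ]
  rownames(out) <- NULL
  out
}

#' Read a marginals table
#'
#' Reads a TSV shaped like the study's published summary: columns `Coin` (or
#' `coin_id`), `p0`..`p3`, optionally `Gender` (or `gender_group`) and
#' optionally per-cell sample sizes `n0`..`n3` (or a single `n`).
#'
#' @param file Path or connection of the TSV.
#' @return Data frame with standardized columns `coin_id`, `p0`..`p3` and,
#'   when present, `gender_group` and `n0`..`n3`.
#' @seealso [reconstruct_counts()]
#' @export
read_marginals <- function(file) {
  # read everything as character first: a single-gender column ("F") would
  # otherwise be parsed as logical
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  names(tab)[tolower(names(tab)) == "coin"] <- "coin_id"
  names(tab)[tolower(names(tab)) == "gender"] <- "gender_group"
  for (col in intersect(c("coin_id", paste0("p", 0:3), "n", paste0("n", 0:3)),
                        names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  needed <- c("coin_id", paste0("p", 0:3))
  if (!all(needed %in% names(tab))) {
    stop("marginals table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if ("n" %in% names(tab) && !all(paste0("n", 0:3) %in% names(tab))) {
    for (j in 0:3) tab[[paste0("n", j)]] <- tab$n
  }
  p <- as.matrix(tab[, paste0("p", 0:3)])
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("marginal probabilities must lie in [0, 1]", call. = FALSE)
  }
  keep <- intersect(c("coin_id", "gender_group", paste0("p", 0:3), paste0("n", 0:3)),
                    names(tab))
  tab[, keep]
}

#' Reconstruct context counts from marginal probabilities
#'
#' Inverts a published-style marginals table into integer designated-outcome
#' counts via `k_i = round(n_i * p_i)`, so that a printed summary table is a
#' valid analysis input.  Cells where `n * p` is not an integer (e.g. a
#' marginal of 0.55 at `n = 50`) are reported with a message, since their
#' reconstructed frequency differs from the printed one.
#'
#' @param marginals Data frame with columns `coin_id`, `p0`..`p3`, optional
#'   `gender_group` and optional per-cell `n0`..`n3` overrides.
#' @param n Default judgments per context used where no per-cell override is
#'   given (default 50).
#' @param quiet Suppress the non-integer cell message.
#' @return Counts data frame (`coin_id`, `context`, `n`, `k`, and
#'   `gender_group` when available) suitable for [marginals_from_counts()]
#'   and [cbd_analysis()].
#' @examples
#' counts <- reconstruct_counts(face_study_marginals())
#' head(counts)
#' @export
reconstruct_counts <- function(marginals, n = 50, quiet = FALSE) {
  needed <- c("coin_id", paste0("p", 0:3))
  if (!all(needed %in% names(marginals))) {
    stop("marginals must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(marginals)), function(i) {
    m <- marginals[i, ]
    ncell <- vapply(0:3, function(j) {
      cn <- paste0("n", j)
      if (cn %in% names(m) && !is.na(m[[cn]])) as.numeric(m[[cn]]) else n
    }, numeric(1))
    p <- as.numeric(m[paste0("p", 0:3)])
    data.frame(coin_id = m$coin_id, context = paste0("C", 0:3),
               n = ncell, k = round(ncell * p), exact = ncell * p,
               gender_group = if ("gender_group" %in% names(m))
                 m$gender_group else NA_character_)
  })
  out <- do.call(rbind, rows)
  off_grid <- abs(out$exact - out$k) > 1e-8
  if (any(off_grid) && !quiet) {
    message("non-integer count(s) rounded: ",
            paste(sprintf("coin %s %s (n*p = %.2f -> k = %d)",
                          out$coin_id[off_grid], out$context[off_grid],
                          out$exact[off_grid], out$k[off_grid]),
                  collapse = "; "))
  }
  out$exact <- NULL
  if (all(is.na(out$gender_group))) out$gender_group <- NULL
  rownames(out) <- NULL
  out
}

#' @keywords internal
format_interval <- function(lower, upper, digits = 2) {
  sprintf("[%.*f,%.*f]", digits, lower, digits, upper)
}

#' Write the per-coin results table (and accuracy summary)
#'
#' Writes a TSV mirroring the study's published layout: columns `Coin`,
#' `p0`..`p3`, `Gender`, `Delta`, `CbD`, `Interval`, `Contextual`, with all
#' statistics displayed at 2 decimals (computation elsewhere keeps full
#' precision).  Optionally writes the fake/real accuracy summary as a second
#' TSV.
#'
#' @param x A [cbd_analysis()] object, or a results data frame with columns
#'   `coin_id`, `p0`..`p3`, `delta`, `cbd`, `ci_lower`, `ci_upper`,
#'   `contextual` (a zero-row frame yields a header-only file).
#' @param file Path of the results TSV.
#' @param summary_file Optional path of the accuracy-summary TSV (requires
#'   `x` to be a `cbd_analysis` with gender labels).
#' @param digits Display digits (default 2).
#' @return Invisibly, the displayed results data frame.
#' @export
write_results <- function(x, file, summary_file = NULL, digits = 2) {
  res <- if (inherits(x, "cbd_analysis")) x$results else x
  fmt <- function(v) sprintf("%.*f", digits, v)
  if (nrow(res)) {
    disp <- data.frame(
      Coin = res$coin_id,
      p0 = fmt(res$p0), p1 = fmt(res$p1), p2 = fmt(res$p2), p3 = fmt(res$p3),
      Gender = if ("gender_group" %in% names(res)) res$gender_group else NA,
      Delta = fmt(res$delta), CbD = fmt(res$cbd),
      Interval = format_interval(res$ci_lower, res$ci_upper, digits),
      Contextual = ifelse(res$contextual, "yes", "no"),
      stringsAsFactors = FALSE)
  } else {
    disp <- data.frame(Coin = integer(), p0 = character(), p1 = character(),
                       p2 = character(), p3 = character(), Gender = character(),
                       Delta = character(), CbD = character(),
                       Interval = character(), Contextual = character(),
                       stringsAsFactors = FALSE)
  }
  utils::write.table(disp, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_file)) {
    if (!inherits(x, "cbd_analysis") || is.null(x$accuracy)) {
      stop("accuracy summary requires a cbd_analysis with gender labels",
           call. = FALSE)
    }
    acc <- x$accuracy
    stab <- data.frame(Group = c(paste("Mean", acc$table$group), "Grand Mean"),
                       Fake = c(fmt(acc$table$fake), fmt(acc$grand_mean)),
                       Real = c(fmt(acc$table$real), ""),
                       stringsAsFactors = FALSE)
    utils::write.table(stab, summary_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(disp)
}
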