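# Synthetic judgment-data generator emulating the crowdsourced study design:
# between-subjects contexts, one forced-choice judgment per participant per
# coin, left/right counterbalancing within every (coin, context) cell.

#' Describe a synthetic forced-choice experiment
#'
#' Captures the study design the generator emulates: `n_coins` image sets
#' (by default 20: 10 female then 10 male), four between-subjects
#' measurement contexts with `n_participants_per_context` participants each,
#' one judgment per participant per coin, and per-coin true marginals
#' (defaulting to the reference study's values, so the default design
#' regenerates a study-like dataset with no external data).
#'
#' @param n_participants_per_context Participants recruited into each of the
#'   four contexts (default 50).
#' @param true_marginals Data frame with columns `coin_id`, `p0`..`p3` and
#'   optionally `gender_group` (default [face_study_marginals()]).
#' @param master_seed Integer seed making generation fully reproducible
#'   (default 1).
#' @return Object of class `"experiment_design"`.
#' @examples
#' design <- experiment_design(n_participants_per_context = 10, master_seed = 7)
#' design
#' @seealso [generate_judgments()], [recover_marginals()]
#' @export
experiment_design <- function(n_participants_per_context = 50,
                              true_marginals = face_study_marginals(),
                              master_seed = 1L) {
  n_pp <- as.integer(n_participants_per_context)
  if (is.na(n_pp) || n_pp < 1L) {
    stop("n_participants_per_context must be a positive integer", call. = FALSE)
  }
  needed <- c("coin_id", paste0("p", 0:3))
  if (!all(needed %in% names(true_marginals))) {
    stop("true_marginals must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  p <- as.matrix(true_marginals[, paste0("p", 0:3)])
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("true marginals must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(true_marginals$coin_id)) {
    stop("duplicate coin_id in true_marginals", call. = FALSE)
  }
  if (!"gender_group" %in% names(true_marginals)) {
    true_marginals$gender_group <- NA_character_
  }
  structure(list(n_coins = nrow(true_marginals),
                 n_participants_per_context = n_pp,
                 true_marginals = true_marginals,
                 master_seed = as.integer(master_seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0("Forced-choice experiment design: %d coins, 4 ",
                     "between-subjects contexts x %d participants ",
                     "(seed %d)\n"),
              x$n_coins, x$n_participants_per_context, x$master_seed))
  invisible(x)
}

#' Generate synthetic judgment records
#'
#' Simulates the full study: every participant belongs to exactly one
#' context (between subjects) and judges every coin once, in coin order.
#' For each judgment the context's designated facet is chosen as "fake" with
#' the coin's true marginal for that context, otherwise the other facet of
#' the pair is chosen — judgments are conditionally independent Bernoulli
#' draws given the marginals, the minimal model consistent with a
#' cell-frequency analysis.  Presentation side alternates across
#' participants within every (coin, context) cell, so the swapped/unswapped
#' split is exact for even cell sizes and differs by one for odd sizes.
#'
#' @param design An [experiment_design()].
#' @return Data frame of judgment records in the canonical schema
#'   (`coin_id`, `gender_group`, `context`, `participant_id`,
#'   `position_swapped`, `judged_fake_facet`), reproducible from
#'   `design$master_seed`.
#' @examples
#' design <- experiment_design(n_participants_per_context = 4, master_seed = 1)
#' head(generate_judgments(design))
#' @export
generate_judgments <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(design$master_seed)

  tm <- design$true_marginals
  n_pp <- design$n_participants_per_context
  n_coins <- design$n_coins
  if (n_pp %% 2L == 1L) {
    message("odd participant count per context (", n_pp,
            "): counterbalancing split is floor/ceil")
  }

  # one block per context; within a block participants judge coins in order
  blocks <- lapply(0:3, function(ctx) {
    participant <- rep(seq_len(n_pp), each = n_coins)
    coin_row <- rep(seq_len(n_coins), times = n_pp)
    p_true <- tm[[paste0("p", ctx)]][coin_row]
    hit <- stats::rbinom(n_pp * n_coins, 1L, p_true) == 1L
    data.frame(
      coin_id = tm$coin_id[coin_row],
      gender_group = tm$gender_group[coin_row],
      context = paste0("C", ctx),
      participant_id = sprintf("C%d_P%03d", ctx, participant),
      # alternate sides across participants, offset by coin so no
      # participant always sees the real face on the same side
      position_swapped = (participant + coin_row) %% 2L == 0L,
      judged_fake_facet = ifelse(hit, designated_outcome(ctx), other_facet(ctx)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Recover per-coin marginals from judgment records
#'
#' Convenience composition of [tally_judgments()] and
#' [marginals_from_counts()], used for parameter-recovery checks: the
#' returned `p_i` are the empirical designated-outcome frequencies `k/n`.
#'
#' @param records Data frame of judgment records.
#' @return Data frame with `coin_id`, `p0`..`p3` (and `gender_group` when
#'   available).
#' @examples
#' design <- experiment_design(n_participants_per_context = 200, master_seed = 2)
#' recover_marginals(generate_judgments(design))[1:3, ]
#' @export
recover_marginals <- function(records) {
  marginals_from_counts(tally_judgments(records))
}
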