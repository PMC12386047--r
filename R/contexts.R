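# Fixed geometry of the 4-cycle face-judgment design: four facets
# {F0, R1, F2, R3} (fake faces at even indices, real faces at odd indices)
# and four measurement contexts C0..C3, context i pairing facets
# (i, (i+1) mod 4).

.FACET_LABELS <- c("F0", "R1", "F2", "R3")
.FACET_ROLES  <- c("fake", "real", "fake", "real")
.CONTEXT_LABELS <- paste0("C", 0:3)

# facet whose "judged fake" (top) probability defines the marginal p_i of
# context i: C0 -> F0, C1 -> F2, C2 -> F2, C3 -> F0
.DESIGNATED_FACET <- c(0L, 2L, 2L, 0L)

#' Facet roles of the 4-cycle face design
#'
#' The four facets of the face-judgment "generalized coin": two AI-generated
#' (fake) faces at indices 0 and 2 and two real faces at indices 1 and 3.
#'
#' @return A data frame with columns `index` (0--3), `role`
#'   (`"fake"`/`"real"`) and `label` (`"F0"`, `"R1"`, `"F2"`, `"R3"`).
#' @examples
#' facet_roles()
#' @export
facet_roles <- function() {
  data.frame(index = 0:3, role = .FACET_ROLES, label = .FACET_LABELS,
             stringsAsFactors = FALSE)
}

#' @keywords internal
as_context_index <- function(context) {
  if (is.character(context) || is.factor(context)) {
    context <- as.character(context)
    idx <- match(toupper(context), .CONTEXT_LABELS) - 1L
    if (anyNA(idx)) {
      stop("invalid context label(s): ",
           paste(unique(context[is.na(idx)]), collapse = ", "),
           " (expected C0..C3)", call. = FALSE)
    }
    return(idx)
  }
  if (is.numeric(context)) {
    idx <- as.integer(context)
    if (any(is.na(idx)) || any(idx != context) || any(idx < 0L) || any(idx > 3L)) {
      stop("context index must be an integer in 0..3", call. = FALSE)
    }
    return(idx)
  }
  stop("context must be an integer 0..3 or a label C0..C3", call. = FALSE)
}

#' @keywords internal
context_label <- function(context) .CONTEXT_LABELS[as_context_index(context) + 1L]

#' Facet pair measured in a context
#'
#' Context `i` of the 4-cycle jointly measures facets `i` and `(i+1) mod 4`,
#' giving the pairs \{F0,R1\}, \{R1,F2\}, \{F2,R3\}, \{R3,F0\}.
#'
#' @param context Context given as an integer 0--3 or a label `"C0"`..`"C3"`.
#' @return Integer vector of the two facet indices measured together.
#' @examples
#' context_facets("C3")   # facets 3 and 0
#' @export
context_facets <- function(context) {
  i <- as_context_index(context)
  if (length(i) != 1L) stop("context must be a single value", call. = FALSE)
  c(i, (i + 1L) %% 4L)
}

#' Designated outcome facet of a context
#'
#' Each context's marginal probability `p_i` is the probability that one
#' specific facet of its pair is judged fake (measured "top"):
#' `p0 = P(F0 fake | C0)`, `p1 = P(F2 fake | C1)`, `p2 = P(F2 fake | C2)`,
#' `p3 = P(F0 fake | C3)`.  This function returns that facet's index.
#'
#' @param context Context (vector allowed), integer 0--3 or label `"C0"`..`"C3"`.
#' @return Integer facet index (0 or 2), vectorised over `context`.
#' @examples
#' designated_outcome("C0")      # 0 (F0)
#' designated_outcome(c(1, 2))   # 2 2 (F2 in both C1 and C2)
#' @export
designated_outcome <- function(context) {
  .DESIGNATED_FACET[as_context_index(context) + 1L]
}

#' @keywords internal
other_facet <- function(context) {
  i <- as_context_index(context)
  pair_sum <- i + ((i + 1L) %% 4L)
  pair_sum - .DESIGNATED_FACET[i + 1L]
}
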