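# Independent oracles used across the suite.

# s_odd by exhaustive enumeration over all sign vectors with an odd number
# of -1 entries (canonical definition), feasible for n <= 8
s_odd_enumerate <- function(cc) {
  n <- length(cc)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  odd <- rowSums(signs == -1) %% 2 == 1
  max(as.vector(signs[odd, , drop = FALSE] %*% cc))
}

# study-convention s_odd by direct subset enumeration (independent of the
# combn-based implementation path)
s_odd_subsets <- function(cc) {
  n <- length(cc)
  best <- -Inf
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(members) %% 2 == 1) best <- max(best, abs(sum(cc[members])))
  }
  best
}

# a random explicit joint distribution over 4 binary variables, returned as
# the 16 cell probabilities with their variable assignments
random_joint4 <- function() {
  cells <- as.matrix(expand.grid(a0 = 0:1, a1 = 0:1, a2 = 0:1, a3 = 0:1))
  w <- stats::rexp(16)
  list(assign = cells, prob = w / sum(w))
}

# marginal p_i and pairwise p_ij implied by an explicit joint distribution
joint4_boole_inputs <- function(joint) {
  cells <- joint$assign
  p <- vapply(1:4, function(i) sum(joint$prob[cells[, i] == 1]), numeric(1))
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  q <- vapply(pairs, function(ij) {
    sum(joint$prob[cells[, ij[1]] == 1 & cells[, ij[2]] == 1])
  }, numeric(1))
  list(single = p, pairwise = q)
}

# reference study table kept handy for tests
ref_tab <- cbdcoin::face_study_reference()
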