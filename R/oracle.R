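# Brute-force CTMC oracle for small lattices.
#
# Enumerates every legal ribosome configuration (positions p1 < ... < pk with
# gaps >= s), builds the generator from the same event rules as the
# event-driven simulator, solves for the stationary distribution and returns
# the stationary termination flux. Independent of the simulation kernel:
# used to verify it, never to replace it.

# number of legal configurations (gap >= s), without enumerating them:
# N(k) = N(k-1) + N(k-s), N(k <= 0) = 1 (the empty lattice)
count_states <- function(n, s) {
  N <- numeric(n + 1)
  for (k in 0:n) {
    N[k + 1] <- if (k == 0) 1
                else N[k] + (if (k - s >= 0) N[k - s + 1] else 1)
  }
  N[n + 1]
}

enumerate_states <- function(n, s) {
  states <- list(integer(0))
  grow <- function(prefix, min_pos) {
    for (p in seq(min_pos, n)) {
      st <- c(prefix, p)
      states[[length(states) + 1L]] <<- st
      if (p + s <= n) grow(st, p + s)
    }
  }
  grow(integer(0), 1L)
  states
}

#' Exact steady-state translation rate on a small lattice
#'
#' Solves the continuous-time Markov chain of the TASEP translation model
#' exactly: all legal ribosome configurations are enumerated, the generator
#' matrix is assembled from the same initiation/elongation/termination rules
#' as [simulate_tasep()], and the stationary distribution is obtained by a
#' sparse linear solve. Returns the stationary termination flux
#' \eqn{\lambda_n \cdot P(\text{codon } n \text{ occupied by a decoding
#' ribosome})}, the exact translation rate.
#'
#' Intended as a verification oracle: the state space grows exponentially,
#' so the gene must be small (the default cap refuses above 20000 states).
#'
#' @param gene A [gene_model()]; keep \eqn{n \le 14} with \eqn{s \le 3}.
#' @param max_states Refuse to build chains larger than this.
#' @param details If `TRUE`, also return the stationary distribution and the
#'   exact expected number of bound ribosomes.
#' @return Numeric scalar (the exact translation rate), or a list when
#'   `details = TRUE`.
#' @examples
#' g <- gene_model("tiny", rates = c(1, 1), init_rate = 1, footprint = 1)
#' exact_small_lattice_rate(g) # 0.4 by hand-solved 4-state chain
#' @export
exact_small_lattice_rate <- function(gene, max_states = 20000L,
                                     details = FALSE) {
  stopifnot(inherits(gene, "gene_model"))
  n <- length(gene$rates)
  s <- gene$footprint
  n_states <- count_states(n, s)
  if (n_states > max_states) {
    stop(sprintf("state space too large (%.0f states > cap %d)",
                 n_states, max_states))
  }
  states <- enumerate_states(n, s)
  N <- length(states)
  key <- vapply(states, function(st) paste(c("s", st), collapse = ","), "")
  idx <- setNames(seq_len(N), key)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    ii <<- c(ii, from); jj <<- c(jj, to); xx <<- c(xx, rate)
  }
  for (a in seq_len(N)) {
    st <- states[[a]]
    k <- length(st)
    # initiation
    if (k == 0L || st[1] > s) {
      to <- idx[[paste(c("s", 1L, st), collapse = ",")]]
      add(a, to, gene$init_rate)
    }
    for (j in seq_len(k)) {
      i <- st[j]
      if (i == n) { # termination
        to <- idx[[paste(c("s", st[-j]), collapse = ",")]]
        add(a, to, gene$rates[n])
      } else {
        free <- (j == k) || (st[j + 1] - i > s)
        if (free) {
          st2 <- st; st2[j] <- i + 1L
          add(a, idx[[paste(c("s", st2), collapse = ",")]], gene$rates[i])
        }
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  A <- Matrix::t(Q)
  A[N, ] <- 1
  pi_vec <- as.numeric(Matrix::solve(A, c(rep(0, N - 1), 1)))

  has_term <- vapply(states, function(st) length(st) > 0 && st[length(st)] == n,
                     TRUE)
  flux <- sum(pi_vec[has_term]) * gene$rates[n]
  if (!details) return(flux)
  list(rate = flux, stationary = pi_vec, states = states,
       mean_ribosomes = sum(pi_vec * vapply(states, length, 0L)))
}
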