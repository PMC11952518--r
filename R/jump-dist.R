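#' Distribution of dimensionless conductance jumps
#'
#' The jump distribution is the sole carrier of input synchrony in the
#' shot-noise description: a synaptic event arrives as a Poisson process
#' with rate `rate_hz`, and at each event the neurons in the set receive a
#' jump vector `(W_e,a, W_i,a)` drawn independently from this law.  The
#' finite support is stored atom-by-atom: row `j` of `w_e`/`w_i` holds the
#' per-neuron excitatory/inhibitory jump of atom `j`, with probability
#' `prob[j]`.
#'
#' Every atom must carry a positive total jump summed over the neuron set
#' (events during which no neuron receives input are not events of the set).
#'
#' @param prob Atom probabilities; normalized to sum to one.
#' @param w_e,w_i Numeric matrices (atoms x neurons) of nonnegative
#'   dimensionless jumps; vectors are treated as single-neuron columns.
#' @param rate_hz Poisson rate of synaptic events for the neuron set, Hz.
#' @return An object of class `jump_dist`.
#' @seealso [jump_distribution()] to build the law implied by a synchrony
#'   model, [jd_marginal()] for subsampling to a neuron subset.
#' @export
jump_dist <- function(prob, w_e, w_i, rate_hz) {
  if (is.vector(w_e)) w_e <- matrix(w_e, ncol = 1L)
  if (is.vector(w_i)) w_i <- matrix(w_i, ncol = 1L)
  stopifnot(is.matrix(w_e), is.matrix(w_i),
            all(dim(w_e) == dim(w_i)),
            length(prob) == nrow(w_e))
  if (any(!is.finite(w_e)) || any(!is.finite(w_i)) ||
      any(w_e < 0) || any(w_i < 0))
    stop("jumps must be finite and nonnegative")
  if (any(prob < 0)) stop("probabilities must be nonnegative")
  tot <- rowSums(w_e) + rowSums(w_i)
  if (any(tot <= 0))
    stop("every support atom must have positive total jump over the neuron set")
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz >= 0)
  s <- sum(prob)
  if (abs(s - 1) > 1e-8 && s > 0) prob <- prob / s
  structure(list(prob = prob, w_e = w_e, w_i = w_i, rate_hz = rate_hz),
            class = "jump_dist")
}

#' @export
print.jump_dist <- function(x, ...) {
  cat(sprintf("Jump distribution: %d atoms over %d neuron(s), event rate %.4g Hz\n",
              length(x$prob), ncol(x$w_e), x$rate_hz))
  ew <- sum(x$prob * (rowSums(x$w_e) + rowSums(x$w_i)))
  cat(sprintf("  mean total jump per event: %.4g\n", ew))
  invisible(x)
}

#' @rdname jump_dist
#' @param x Object to test.
#' @export
is_jump_dist <- function(x) inherits(x, "jump_dist")

n_neurons <- function(jd) ncol(jd$w_e)

#' Expectation of a jump functional
#'
#' Computes `E[f(W_e, W_i)]` over the atoms of a finite-support jump law.
#'
#' @param jd A [jump_dist()].
#' @param f Function of two matrices (atoms x neurons) returning a per-atom
#'   numeric vector.
#' @return The expectation, a scalar.
#' @export
jd_expect <- function(jd, f) {
  v <- f(jd$w_e, jd$w_i)
  sum(jd$prob * v)
}

#' Marginal jump law of a neuron subset
#'
#' Subsampling consistency: for a subset `A` of the modeled neuron set `B`,
#' the events seen by `A` are the events of `B` during which some neuron of
#' `A` receives a positive jump, so `b_A = b_B * P(sum_A W_a > 0)` and the
#' jump law is the conditional law of the restricted jumps.
#'
#' @param jd A [jump_dist()].
#' @param neurons Integer indices of the neurons to keep.
#' @return A [jump_dist()] over the subset.
#' @export
jd_marginal <- function(jd, neurons) {
  w_e <- jd$w_e[, neurons, drop = FALSE]
  w_i <- jd$w_i[, neurons, drop = FALSE]
  tot <- rowSums(w_e) + rowSums(w_i)
  keep <- tot > 0
  p_pos <- sum(jd$prob[keep])
  if (p_pos <= 0) stop("subset receives no input under this law")
  jump_dist(jd$prob[keep] / p_pos,
            w_e[keep, , drop = FALSE], w_i[keep, , drop = FALSE],
            rate_hz = jd$rate_hz * p_pos)
}

## internal: merge duplicate atoms (exact matches) to keep supports small
jd_compress <- function(jd) {
  key <- do.call(paste, c(as.data.frame(jd$w_e), as.data.frame(jd$w_i),
                          list(sep = "\r")))
  if (!anyDuplicated(key)) return(jd)
  idx <- match(key, unique(key))
  prob <- as.vector(rowsum(jd$prob, idx))
  first <- !duplicated(key)
  jump_dist(prob, jd$w_e[first, , drop = FALSE],
            jd$w_i[first, , drop = FALSE], jd$rate_hz)
}

#' Empirical jump law from a sampler
#'
#' Monte-Carlo fallback for synchrony models without a tractable finite
#' support: draws `n` jump vectors and returns the empirical law (equal
#' atom weights), which can then be fed to any exact-summation routine.
#'
#' @param sampler Function `(n)` returning `list(w_e =, w_i =)` matrices.
#' @param n Number of draws.
#' @param rate_hz Event rate of the sampled process, Hz.
#' @param seed Optional integer seed.
#' @return A [jump_dist()] with `n` equally weighted atoms (duplicates merged).
#' @export
jd_empirical <- function(sampler, n, rate_hz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sampler(n)
  jd_compress(jump_dist(rep(1 / n, n), s$w_e, s$w_i, rate_hz))
}

## internal: per-atom auxiliary functionals of the Marcus rule for neuron a:
##   Y_a = exp(-(W_e+W_i)),  (1-Y_a),  and R_a (jump target, only where W>0).
## Atoms with zero jump for neuron a contribute Y_a = 1 so that all
## (1-Y_a)-weighted expectations are formed without ever dividing by zero.
jd_aux <- function(jd, a, params) {
  we <- jd$w_e[, a]; wi <- jd$w_i[, a]
  w <- we + wi
  y <- exp(-w)
  r <- numeric(length(w))
  pos <- w > 0
  r[pos] <- (we[pos] * params$v_exc + wi[pos] * params$v_inh) / w[pos]
  list(y = y, one_m_y = 1 - y, r = r, pos = pos)
}
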