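#' Generic stationary moment solver (PASTA fixed point)
#'
#' Solves the triangular linear system obeyed by the shifted stationary
#' moments `mu_B = E[ prod_{a in B} (V_a - I_a/G_a) ]` of a feedforward
#' AONCB population, for every multiset `B` of neuron indices up to
#' `max_order`.  The system follows from stationarity under the Palm (PASTA)
#' identity: just before an event, per neuron,
#' `V' - I/G = (Y (V - I/G) + D) * exp(-S/tau)` with
#' `Y = exp(-(W_e+W_i))`, `D = (1-Y)(R - I/G)` (zero-jump atoms contribute
#' `Y = 1`, `D = 0`), `S` the exponential inter-event interval (so
#' `E[exp(-c S)] = b/(b + c)`), and the pre-event state independent of the
#' incoming jump.  Expanding the product multinomially couples each order-n
#' moment only to lower orders, with own-coefficient
#' `1 - (b/(b + sum 1/tau_a)) E[prod Y_a^{n_a}] < 1`, so the system is
#' solved exactly, lowest order first, with no iteration.
#'
#' Heterogeneous time constants are supported: the decay factor of a
#' multiset `B` is `b / (b + sum_{a in B} 1/tau_a)` with indices counted
#' with multiplicity.
#'
#' @param jd A [jump_dist()] over the neuron set.
#' @param params [neuron_params()] per neuron (recycled).
#' @param max_order Highest moment order (default 3, capped at 4 by cost).
#' @return A named numeric vector of shifted moments; names are
#'   comma-separated sorted multisets of neuron indices (e.g. `"1,1,2"`),
#'   with attributes `n_neurons` and `mu1` (first-order moments).
#' @seealso [centered_from_shifted()] to convert to centered moments.
#' @export
solve_shifted_moments <- function(jd, params, max_order = 3L) {
  stopifnot(max_order >= 1L)
  if (max_order > 4L) stop("order cap is 4 (multiset lattice cost)")
  nn <- n_neurons(jd)
  params <- as_params_list(params, nn)
  tau <- vapply(params, `[[`, numeric(1), "tau")
  b <- hz_to_per_ms(jd$rate_hz)
  ## per-atom auxiliaries
  Y <- matrix(0, length(jd$prob), nn)
  D <- matrix(0, length(jd$prob), nn)
  for (a in seq_len(nn)) {
    aux <- jd_aux(jd, a, params[[a]])
    Y[, a] <- aux$y
    D[, a] <- aux$one_m_y * (aux$r - params[[a]]$i_ext_over_g)
  }
  Ejd <- function(jpow, dpow) {   # E[prod_a Y_a^j_a D_a^d_a]
    v <- jd$prob
    for (a in seq_len(nn)) {
      if (jpow[a] > 0) v <- v * Y[, a]^jpow[a]
      if (dpow[a] > 0) v <- v * D[, a]^dpow[a]
    }
    sum(v)
  }
  ## enumerate multisets as count vectors, by total order
  counts <- as.matrix(expand.grid(lapply(seq_len(nn), function(a) 0:max_order)))
  counts <- counts[rowSums(counts) >= 1 & rowSums(counts) <= max_order, ,
                   drop = FALSE]
  counts <- counts[order(rowSums(counts)), , drop = FALSE]
  key_of <- function(cnt) paste(rep(seq_len(nn), cnt), collapse = ",")
  mu <- numeric(nrow(counts))
  names(mu) <- apply(counts, 1L, key_of)
  for (r in seq_len(nrow(counts))) {
    cnt <- counts[r, ]
    g <- b / (b + sum(cnt / tau))
    ## all splits j <= cnt of the multinomial expansion
    grid <- as.matrix(expand.grid(lapply(cnt, function(x) 0:x)))
    rhs <- 0
    for (s in seq_len(nrow(grid))) {
      j <- grid[s, ]
      if (all(j == cnt)) next          # own term, moved to the left side
      coef <- prod(choose(cnt, j)) * Ejd(j, cnt - j)
      mu_low <- if (sum(j) == 0L) 1 else mu[[key_of(j)]]
      rhs <- rhs + coef * mu_low
    }
    own <- g * Ejd(cnt, integer(nn))
    mu[r] <- g * rhs / (1 - own)
  }
  attr(mu, "n_neurons") <- nn
  attr(mu, "mu1") <- mu[apply(diag(nn)[, seq_len(nn), drop = FALSE], 2L,
                              key_of)]
  mu
}

#' Centered moments from shifted moments
#'
#' Binomial re-expansion of shifted moments (about the resting offsets
#' I/G) into centered moments about the stationary means
#' `m_a = mu_a + I_a/G_a`:
#' `M_B = E[ prod (V_a - m_a) ] = sum_j prod C(n_a, j_a) (-mu1_a)^(n_a-j_a)
#'  mu_{B_j}`.
#'
#' @param shifted Output of [solve_shifted_moments()].
#' @param mu1 First-order shifted moments (taken from `shifted` if omitted).
#' @return Named numeric vector of centered moments over the same multisets
#'   (first-order entries are 0 by construction).
#' @export
centered_from_shifted <- function(shifted, mu1 = NULL) {
  nn <- attr(shifted, "n_neurons")
  if (is.null(mu1)) mu1 <- attr(shifted, "mu1")
  key_of <- function(cnt) paste(rep(seq_len(nn), cnt), collapse = ",")
  cnt_of <- function(key) {
    idx <- as.integer(strsplit(key, ",")[[1]])
    tabulate(idx, nbins = nn)
  }
  out <- shifted
  for (r in seq_along(shifted)) {
    cnt <- cnt_of(names(shifted)[r])
    grid <- as.matrix(expand.grid(lapply(cnt, function(x) 0:x)))
    val <- 0
    for (s in seq_len(nrow(grid))) {
      j <- grid[s, ]
      mu_j <- if (sum(j) == 0L) 1 else shifted[[key_of(j)]]
      val <- val + prod(choose(cnt, j)) * prod((-mu1)^(cnt - j)) * mu_j
    }
    out[r] <- val
  }
  out
}

#' Moment of a specific neuron multiset
#'
#' Convenience accessor: centered stationary moment
#' `E[prod_{a in B}(V_a - m_a)]` for a multiset of neuron indices.
#'
#' @param jd A [jump_dist()].
#' @param params [neuron_params()] per neuron.
#' @param neurons Integer multiset, e.g. `c(1, 1)` for the variance of
#'   neuron 1 or `c(1, 2)` for the pair covariance.
#' @return The centered moment.
#' @export
pasta_moment <- function(jd, params, neurons) {
  ord <- length(neurons)
  sh <- solve_shifted_moments(jd, params, max_order = ord)
  ce <- centered_from_shifted(sh)
  key <- paste(sort(neurons), collapse = ",")
  unname(ce[[key]])
}
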