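#' Jump sampler of a synchrony model
#'
#' Returns a function drawing i.i.d. per-event jump vectors from the model's
#' law, used by [sample_event_train()] and as the Monte-Carlo fallback when
#' exact support enumeration is impractical (see [jd_empirical()]).
#'
#' @param model A `synchrony_model`.
#' @return A function `(n)` returning `list(w_e =, w_i =)` matrices
#'   (`n` x neurons).
#' @export
model_sampler <- function(model) {
  comps <- model$components
  rates <- vapply(comps, `[[`, numeric(1), "rate_hz")
  nn <- model$n_neurons
  function(n) {
    w_e <- matrix(0, n, nn); w_i <- matrix(0, n, nn)
    ci <- sample.int(length(comps), n, replace = TRUE, prob = rates)
    for (k in seq_along(comps)) {
      idx <- which(ci == k)
      if (!length(idx)) next
      comp <- comps[[k]]
      if (comp$flavor == "atoms") {
        ai <- sample.int(length(comp$prob), length(idx), replace = TRUE,
                         prob = comp$prob)
        w_e[idx, ] <- comp$w_e[ai, , drop = FALSE]
        w_i[idx, ] <- comp$w_i[ai, , drop = FALSE]
      } else {
        g <- comp$groups
        cnt <- sample.int(length(comp$pmf), length(idx), replace = TRUE,
                          prob = comp$pmf)
        ## sequential hypergeometric split of the active count across groups
        remainK <- rev(cumsum(rev(g$K)))
        left <- cnt
        for (j in seq_len(nrow(g))) {
          take <- if (j == nrow(g)) left else
            stats::rhyper(length(idx), g$K[j], remainK[j] - g$K[j], left)
          if (g$type[j] == "e")
            w_e[idx, g$neuron[j]] <- w_e[idx, g$neuron[j]] + take * g$w[j]
          else
            w_i[idx, g$neuron[j]] <- w_i[idx, g$neuron[j]] + take * g$w[j]
          left <- left - take
        }
      }
    }
    list(w_e = w_e, w_i = w_i)
  }
}

#' Sample a synaptic event train from a synchrony model
#'
#' Event times follow a Poisson process with the model's collective rate
#' `b_A`; jump vectors are drawn i.i.d. from the model's jump law.
#'
#' @param model A `synchrony_model`.
#' @param horizon_ms Simulation horizon (events on `[0, horizon_ms]`).
#' @param seed Optional integer seed; identical (model, horizon, seed)
#'   reproduce the train exactly.
#' @return An [event_train()].
#' @export
sample_event_train <- function(model, horizon_ms, seed = NULL) {
  stopifnot(horizon_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  b <- model_event_rate(model)
  n <- stats::rpois(1L, hz_to_per_ms(b) * horizon_ms)
  if (n == 0L)
    return(event_train(numeric(0), matrix(0, 0, model$n_neurons),
                       matrix(0, 0, model$n_neurons),
                       horizon = c(0, horizon_ms), rate_hz = b))
  times <- sort(stats::runif(n, 0, horizon_ms))
  jumps <- model_sampler(model)(n)
  if (anyDuplicated(times)) {   # merge exact ties into one event
    idx <- match(times, unique(times))
    jumps$w_e <- rowsum(jumps$w_e, idx)
    jumps$w_i <- rowsum(jumps$w_i, idx)
    times <- unique(times)
  }
  event_train(times, jumps$w_e, jumps$w_i, horizon = c(0, horizon_ms),
              rate_hz = b)
}

#' Sample per-input spike trains from a synchrony model
#'
#' Draws the synaptic events of the model and records which of the tracked
#' inputs activate at each event, yielding individual spike trains.  For
#' exchangeable (beta-binomial) components the tracked activations follow
#' the exact hypergeometric marginal of the full pool, so a small subset of
#' a large pool can be tracked without simulating every input.
#'
#' @param model A `synchrony_model`.
#' @param horizon_ms Horizon, ms.
#' @param inputs Data frame `(neuron, type, index)` of inputs to track, or
#'   `NULL` for all inputs (only allowed for total pool sizes <= 200).
#' @param seed Optional integer seed.
#' @return A [spike_list()].
#' @export
sample_spike_list <- function(model, horizon_ms, inputs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- model$pool
  if (is.null(inputs)) {
    tot <- model$n_neurons * (pool$n_exc + pool$n_inh)
    if (tot > 200L)
      stop("tracking all inputs of a large pool; pass an explicit `inputs` subset")
    inputs <- do.call(rbind, lapply(seq_len(model$n_neurons), function(a)
      rbind(if (pool$n_exc) data.frame(neuron = a, type = "e", index = seq_len(pool$n_exc)),
            if (pool$n_inh) data.frame(neuron = a, type = "i", index = seq_len(pool$n_inh)))))
  }
  id_of <- function(nrn, type, index) sprintf("n%d:%s%d", nrn, type, index)
  out_t <- list(); out_id <- list(); out_pool <- list(); out_nrn <- list()
  push <- function(t, id, pl, nrn) {
    k <- length(out_t) + 1L
    out_t[[k]] <<- t; out_id[[k]] <<- id
    out_pool[[k]] <<- pl; out_nrn[[k]] <<- nrn
  }

  if (model$kind %in% c("asynchronous", "shared_inputs")) {
    share <- function(type) {
      if (model$kind != "shared_inputs") return(0L)
      if (type == "e") model$n_shared_e else model$n_shared_i
    }
    for (r in seq_len(nrow(inputs))) {
      a <- inputs$neuron[r]; type <- inputs$type[r]; k <- inputs$index[r]
      rate <- if (type == "e") pool$rate_exc[k] else pool$rate_inh[k]
      if (rate <= 0) next
      shared_k <- k <= share(type)
      if (shared_k && a == 2L) next  # shared train emitted once, tagged "1,2"
      n <- stats::rpois(1L, hz_to_per_ms(rate) * horizon_ms)
      if (n == 0L) next
      push(stats::runif(n, 0, horizon_ms),
           rep(id_of(if (shared_k) 0L else a, type, k), n),
           rep(type, n),
           rep(if (shared_k) "1,2" else as.character(a), n))
    }
  } else {
    for (comp in model$components) {
      if (comp$flavor != "bb") next
      g <- comp$groups
      ## tracked inputs belonging to this component's union
      tr <- inputs[mapply(function(a, ty) any(g$neuron == a & g$type == ty),
                          inputs$neuron, inputs$type), , drop = FALSE]
      j <- nrow(tr)
      if (j == 0L) next
      N <- sum(g$K)
      n_ev <- stats::rpois(1L, hz_to_per_ms(comp$rate_hz) * horizon_ms)
      if (n_ev == 0L) next
      cnt <- sample.int(length(comp$pmf), n_ev, replace = TRUE, prob = comp$pmf)
      hits <- stats::rhyper(n_ev, j, N - j, cnt)
      ev <- which(hits > 0L)
      if (!length(ev)) next
      t_ev <- stats::runif(length(ev), 0, horizon_ms)
      for (q in seq_along(ev)) {
        who <- sample.int(j, hits[ev[q]])
        push(rep(t_ev[q], length(who)),
             id_of(tr$neuron[who], tr$type[who], tr$index[who]),
             tr$type[who], as.character(tr$neuron[who]))
      }
    }
  }
  w_of <- function(type, index)
    if (type == "e") pool$w_exc[index] else pool$w_inh[index]
  r_of <- function(type, index)
    if (type == "e") pool$rate_exc[index] else pool$rate_inh[index]
  cat_neuron <- inputs$neuron
  cat_set <- as.character(inputs$neuron)
  if (model$kind == "shared_inputs") {
    n_sh <- ifelse(inputs$type == "e", model$n_shared_e, model$n_shared_i)
    shared <- inputs$index <= n_sh
    cat_neuron[shared] <- 0L
    cat_set[shared] <- "1,2"
  }
  catalog <- data.frame(
    input_id = id_of(cat_neuron, inputs$type, inputs$index),
    pool = inputs$type,
    neurons = cat_set,
    w = mapply(w_of, inputs$type, inputs$index),
    rate_hz = mapply(r_of, inputs$type, inputs$index),
    stringsAsFactors = FALSE)
  catalog <- catalog[!duplicated(catalog$input_id), ]
  spike_list(unlist(out_t), unlist(out_id), unlist(out_pool), unlist(out_nrn),
             horizon = c(0, horizon_ms), catalog = catalog)
}

#' Shared-input spike trains for a neuron pair
#'
#' Two neurons receive asynchronous Poisson inputs, sharing a fraction
#' `f_e` of excitatory and `f_i` of inhibitory inputs (counts rounded half
#' up); shared inputs deliver identical trains to both neurons, private
#' inputs are independent.
#'
#' @inheritParams sample_spike_list
#' @param pool [input_pool()] per neuron.
#' @param f_e,f_i Shared fractions in \[0, 1\].
#' @return A [spike_list()] whose shared spikes carry neuron set `"1,2"`.
#' @export
shared_input_trains <- function(pool, f_e, f_i = f_e, horizon_ms, seed = NULL) {
  model <- sync_shared_inputs(pool, f_e, f_i)
  sample_spike_list(model, horizon_ms, inputs = NULL, seed = seed)
}

#' Jitter spike times
#'
#' Shifts every spike independently by a centered Gaussian with standard
#' deviation `sigma_j` (ms), the standard surrogate for temporally
#' broadened synchrony: instantaneous coincidences are erased below the
#' jitter timescale while per-input rates are preserved in expectation.
#' Jittered spikes should be delivered to the simulator as singleton events
#' (no re-merging).
#'
#' @param spikes A [spike_list()].
#' @param sigma_j Jitter standard deviation, ms (`0` is the identity).
#' @param seed Optional integer seed.
#' @return The jittered, re-sorted [spike_list()].
#' @export
jitter_spikes <- function(spikes, sigma_j, seed = NULL) {
  stopifnot(sigma_j >= 0)
  if (sigma_j == 0 || nrow(spikes) == 0L) return(spikes)
  if (!is.null(seed)) set.seed(seed)
  t2 <- spikes$time_ms + stats::rnorm(nrow(spikes), 0, sigma_j)
  h <- attr(spikes, "horizon")
  spike_list(t2, spikes$input_id, spikes$pool, spikes$neurons,
             horizon = c(min(h[1], min(t2)), max(h[2], max(t2))),
             catalog = attr(spikes, "catalog"))
}

#' Fold spike trains into synaptic events
#'
#' Spikes closer than `coincidence_tol` (chained) merge into a single
#' synaptic event whose per-neuron jumps sum the weights of the coactive
#' inputs; with the default `coincidence_tol = 0` only exactly tied spike
#' times merge.  Applying the fold twice with the same tolerance is the
#' identity on the first output.
#'
#' @param spikes A [spike_list()] with a weight catalog (or pass `weights`).
#' @param n_neurons Number of neurons addressed by the train.
#' @param coincidence_tol Merge tolerance, ms.
#' @param weights Optional data frame `(input_id, w)` overriding the catalog.
#' @return An [event_train()].
#' @export
spikes_to_events <- function(spikes, n_neurons = NULL, coincidence_tol = 0,
                             weights = NULL) {
  stopifnot(coincidence_tol >= 0)
  cat_df <- attr(spikes, "catalog")
  if (!is.null(weights)) {
    cat_df$w <- weights$w[match(cat_df$input_id, weights$input_id)]
  }
  if (is.null(cat_df)) stop("spike list carries no weight catalog")
  if (is.null(n_neurons))
    n_neurons <- max(as.integer(unlist(strsplit(spikes$neurons, ","))), 1L)
  h <- attr(spikes, "horizon")
  if (nrow(spikes) == 0L)
    return(event_train(numeric(0), matrix(0, 0, n_neurons),
                       matrix(0, 0, n_neurons), horizon = h))
  o <- order(spikes$time_ms)
  t <- spikes$time_ms[o]
  grp <- cumsum(c(1L, as.integer(diff(t) > coincidence_tol)))
  ev_t <- t[!duplicated(grp)]
  w <- cat_df$w[match(spikes$input_id[o], cat_df$input_id)]
  if (anyNA(w)) stop("catalog is missing weights for some inputs")
  pool <- spikes$pool[o]
  nrns <- strsplit(spikes$neurons[o], ",")
  n_ev <- max(grp)
  w_e <- matrix(0, n_ev, n_neurons)
  w_i <- matrix(0, n_ev, n_neurons)
  for (s in seq_along(t)) {
    for (a in as.integer(nrns[[s]])) {
      if (pool[s] == "e") w_e[grp[s], a] <- w_e[grp[s], a] + w[s]
      else                w_i[grp[s], a] <- w_i[grp[s], a] + w[s]
    }
  }
  keep <- rowSums(w_e) + rowSums(w_i) > 0
  event_train(ev_t[keep], w_e[keep, , drop = FALSE], w_i[keep, , drop = FALSE],
              horizon = c(min(h[1], ev_t[1]), max(h[2], ev_t[length(ev_t)])))
}
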