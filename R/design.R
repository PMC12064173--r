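#' Structure design loss
#'
#' Negative log of the probability-like score of folding into the target:
#' `-log(target_structure_probability(psi, target, model))`. Zero iff the
#' score is 1; always nonnegative.
#'
#' @inheritParams target_structure_probability
#' @param target an [rna_structure()].
#' @return scalar loss.
#' @export
structure_design_loss <- function(psi, target, model, scale = 1,
                                  validate = TRUE) {
  if (validate) validate_psi(psi)
  num <- expected_structure_weight(psi, target, model, validate = FALSE)
  if (num <= 0) return(Inf)
  lz <- expected_partition(psi, model, scale = scale, validate = FALSE)$log_z
  lz - log(num)
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# chain rule through row-wise softmax: g_psi -> g_logits
softmax_backprop <- function(psi, g_psi) {
  psi * (g_psi - rowSums(psi * g_psi))
}

adam_init <- function(dim) list(m = array(0, dim), v = array(0, dim), t = 0)

adam_step <- function(state, par, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, par = par - lr * mhat / (sqrt(vhat) + eps))
}

new_design_result <- function(method, trace, psi, target, model, steps,
                              learning_rate, seed, param_count) {
  sequence <- decode_psi(psi)
  structure(list(
    method = method,
    trace = trace,
    psi = psi,
    sequence = sequence,
    target = target,
    probability = discrete_target_probability(sequence, target, model),
    best_loss = min(trace$loss),
    steps = steps,
    learning_rate = learning_rate,
    seed = seed,
    param_count = param_count
  ), class = "design_result")
}

# Boltzmann probability of the target structure for a decoded discrete
# sequence (evaluation honesty: reported probabilities are recomputed from
# the discrete sequence, never from Psi).
discrete_target_probability <- function(seq, target, model) {
  codes <- seq_to_codes(seq)
  ok <- apply(target$pairs, 1, function(ij)
    is_allowed_pair(pair_string(codes[ij[1]], codes[ij[2]])))
  if (nrow(target$pairs) > 0 && !all(ok)) return(0)
  e <- structure_energy(seq, target, model)
  if (!is.finite(e)) return(0)
  lz <- partition_discrete(seq, model)$log_z
  exp(-e / model$kT - lz)
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result>", x$method, " n =", x$target$n, "\n")
  cat("  target   ", format_dotbracket(x$target), "\n")
  cat("  sequence ", x$sequence, "\n")
  cat("  P(target | decoded sequence) =", format(x$probability, digits = 10),
      "\n")
  cat("  best loss", format(x$best_loss, digits = 10), "after", x$steps,
      "steps\n")
  invisible(x)
}

run_adam_design <- function(par0, forward, backward, target, model, steps,
                            learning_rate, scale) {
  # forward(par) -> psi; backward(par, g_psi) -> gradient w.r.t. par
  state <- adam_init(dim_of(par0))
  par <- par0
  best <- list(loss = Inf, psi = NULL)
  trace <- vector("list", steps + 1)
  for (t in 0:steps) {
    psi <- forward(par)
    num <- expected_structure_weight(psi, target, model, validate = FALSE)
    fr <- expected_partition(psi, model, scale = scale, grad = TRUE,
                             validate = FALSE)
    loss <- fr$log_z - log(num)
    if (is.nan(loss))
      abort("objective became NaN during optimization",
            class = "psifold_numerical_error",
            trace_data = dplyr::bind_rows(trace[seq_len(t)]))
    g_psi <- fr$grad_psi - structure_weight_log_gradient(psi, target, model)
    g_par <- backward(par, g_psi)
    gnorm <- sqrt(sum(unlist(g_par)^2))
    trace[[t + 1]] <- tibble(step = t, loss = loss, grad_norm = gnorm)
    if (loss < best$loss) best <- list(loss = loss, psi = psi)
    if (t < steps) {
      upd <- adam_step(state, par, g_par, learning_rate)
      state <- upd$state
      par <- upd$par
    }
  }
  list(trace = dplyr::bind_rows(trace), psi = best$psi)
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Design a sequence for a target structure by direct optimization
#'
#' First-order (Adam) minimization of [structure_design_loss()] over an
#' unconstrained logits matrix mapped to Psi by row-wise softmax. The
#' returned Psi is the best iterate (lowest loss seen), not the last; the
#' reported probability is recomputed from the decoded discrete sequence.
#'
#' @param target an [rna_structure()].
#' @param model an [energy_model()].
#' @param psi0 optional warm-start distribution; default starts at the
#'   uniform Psi.
#' @param steps number of gradient steps (>= 1).
#' @param learning_rate Adam step size.
#' @param seed integer seed; controls the small logits jitter that breaks
#'   the symmetry of the uniform start.
#' @param jitter_sd standard deviation of the initial logits jitter.
#' @param scale scaling constant for the partition evaluations.
#' @return a `design_result`: best-iterate `psi`, decoded `sequence`, the
#'   target probability of the decoded sequence, and a trace tibble with
#'   `step`, `loss`, `grad_norm` (length `steps + 1`).
#' @export
#' @examples
#' \donttest{
#' res <- optimize_direct(hairpin_target(11), energy_model(), steps = 50)
#' res$sequence
#' }
optimize_direct <- function(target, model, psi0 = NULL, steps = 500,
                            learning_rate = 0.05, seed = 0, jitter_sd = 0.01,
                            scale = 1) {
  if (steps < 1) abort("steps must be >= 1", class = "psifold_input_error")
  n <- target$n
  logits0 <- if (is.null(psi0)) matrix(0, n, 4) else log(pmax(psi0, 1e-12))
  logits0 <- logits0 + with_local_seed(seed, matrix(rnorm(n * 4, sd = jitter_sd), n, 4))
  out <- run_adam_design(
    par0 = logits0,
    forward = softmax_rows,
    backward = function(par, g_psi) softmax_backprop(softmax_rows(par), g_psi),
    target = target, model = model, steps = steps,
    learning_rate = learning_rate, scale = scale
  )
  new_design_result("direct", out$trace, out$psi, target, model, steps,
                    learning_rate, seed, param_count = n * 4L)
}

# ---------------------------------------------------------------------------
# Generator network: a fully connected net with a fixed random input vector
# ("seed vector") whose output, reshaped to n x 4 logits and passed through
# row-wise softmax, is the sequence distribution. Overparameterizing the
# search this way helps escape poor local optima of the non-convex design
# landscape.
# ---------------------------------------------------------------------------

#' Construct a generator network
#'
#' Fully connected network `input_dim -> hidden ... -> 4 n` with tanh hidden
#' activations and a linear output layer. The input is a fixed vector drawn
#' once from `seed`; optimization trains the weights, so the network is a
#' deterministic function thereafter.
#'
#' @param n target sequence length (output is reshaped to `n x 4` logits).
#' @param input_dim dimension of the fixed input vector.
#' @param hidden integer vector of hidden-layer widths (may be empty for a
#'   single linear layer).
#' @param seed integer seed for the input vector and weight initialization
#'   (Glorot normal).
#' @return object of class `generator_network`.
#' @export
generator_network <- function(n, input_dim = 16, hidden = c(64, 64),
                              seed = 0) {
  sizes <- c(input_dim, hidden, 4L * n)
  with_local_seed(seed, {
    z <- rnorm(input_dim)
    layers <- lapply(seq_len(length(sizes) - 1), function(k) {
      sd <- sqrt(2 / (sizes[k] + sizes[k + 1]))
      list(W = matrix(rnorm(sizes[k + 1] * sizes[k], sd = sd),
                      sizes[k + 1], sizes[k]),
           b = numeric(sizes[k + 1]))
    })
    structure(list(n = as.integer(n), input = z, layers = layers,
                   sizes = sizes),
              class = "generator_network")
  })
}

#' Number of trainable parameters of a generator network
#' @param net a [generator_network()].
#' @return integer count.
#' @export
generator_param_count <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Evaluate a generator network into a sequence distribution
#'
#' Forward pass: tanh hidden layers, linear output, reshape to `n x 4`
#' (position-major) and row-wise softmax. Deterministic for fixed weights
#' and input.
#'
#' @param net a [generator_network()].
#' @return an `n x 4` sequence distribution.
#' @export
generator_forward <- function(net) {
  softmax_rows(generator_logits(net)$logits)
}

generator_logits <- function(net) {
  h <- net$input
  acts <- list(h)
  nl <- length(net$layers)
  for (k in seq_len(nl)) {
    a <- as.vector(net$layers[[k]]$W %*% h + net$layers[[k]]$b)
    h <- if (k < nl) tanh(a) else a
    acts[[k + 1]] <- h
  }
  logits <- matrix(h, nrow = net$n, ncol = 4, byrow = TRUE)
  list(logits = logits, acts = acts)
}

# backprop d loss / d weights given d loss / d logits (n x 4)
generator_backprop <- function(net, acts, g_logits) {
  nl <- length(net$layers)
  delta <- as.vector(t(g_logits)) # position-major vec matches forward reshape
  grads <- vector("list", nl)
  for (k in rev(seq_len(nl))) {
    hin <- acts[[k]]
    grads[[k]] <- list(W = delta %o% hin, b = delta)
    if (k > 1) {
      back <- as.vector(crossprod(net$layers[[k]]$W, delta))
      delta <- back * (1 - acts[[k]]^2) # tanh'
    }
  }
  grads
}

# flat-vector views used by Adam over heterogeneous parameter lists
flatten_net <- function(layers) unlist(lapply(layers, function(l) c(l$W, l$b)))
unflatten_net <- function(flat, template) {
  pos <- 0
  lapply(template, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(flat[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- as.vector(flat[pos + nw + seq_len(nb)])
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
}

#' Design a sequence for a target structure through a generator network
#'
#' Same loss as [optimize_direct()], but the optimization variables are the
#' weights of a [generator_network()] whose output is Psi; gradients flow
#' end-to-end through the folding dynamic program and the network.
#'
#' @inheritParams optimize_direct
#' @param net0 optional pre-built [generator_network()]; default builds one
#'   from `seed` with `hidden` widths.
#' @param input_dim,hidden architecture of the default network.
#' @return a `design_result` (with `param_count` of the network).
#' @export
optimize_generator <- function(target, model, net0 = NULL, steps = 500,
                               learning_rate = 0.05, seed = 0,
                               input_dim = 16, hidden = c(64, 64),
                               scale = 1) {
  if (steps < 1) abort("steps must be >= 1", class = "psifold_input_error")
  n <- target$n
  net <- net0 %||% generator_network(n, input_dim = input_dim,
                                     hidden = hidden, seed = seed)
  template <- net$layers
  cache <- new.env(parent = emptyenv())
  forward <- function(flat) {
    net$layers <- unflatten_net(flat, template)
    fl <- generator_logits(net)
    cache$acts <- fl$acts
    cache$logits <- fl$logits
    softmax_rows(fl$logits)
  }
  backward <- function(flat, g_psi) {
    net$layers <- unflatten_net(flat, template)
    g_logits <- softmax_backprop(softmax_rows(cache$logits), g_psi)
    flatten_net(generator_backprop(net, cache$acts, g_logits))
  }
  out <- run_adam_design(
    par0 = flatten_net(template),
    forward = forward, backward = backward,
    target = target, model = model, steps = steps,
    learning_rate = learning_rate, scale = scale
  )
  res <- new_design_result("generator", out$trace, out$psi, target, model,
                           steps, learning_rate, seed,
                           param_count = generator_param_count(net))
  res
}

#' Design a sequence for a target secondary structure
#'
#' High-level front end dispatching to [optimize_direct()] or
#' [optimize_generator()].
#'
#' @inheritParams optimize_direct
#' @param method `"direct"` or `"generator"`.
#' @param ... passed through to the chosen optimizer.
#' @return a `design_result`.
#' @export
#' @examples
#' \donttest{
#' design_structure(hairpin_target(11), energy_model(), steps = 100)
#' }
design_structure <- function(target, model, method = c("direct", "generator"),
                             steps = 500, learning_rate = 0.05, seed = 0,
                             ...) {
  method <- match.arg(method)
  if (method == "direct")
    optimize_direct(target, model, steps = steps,
                    learning_rate = learning_rate, seed = seed, ...)
  else
    optimize_generator(target, model, steps = steps,
                       learning_rate = learning_rate, seed = seed, ...)
}
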