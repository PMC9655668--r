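# Builder for the instruction tape the C++ engine executes. A "net" is a
# flat list of instructions over value ids plus parameter / state metadata
# (name, shape, initializer, component group). Weights are materialized
# separately by init_weights() so parameter audits never touch memory beyond
# the shape lists.

new_net <- function() {
  nb <- new.env(parent = emptyenv())
  nb$instrs <- list()
  nb$nval <- 1L            # value 1 is the network input
  nb$params <- list()      # list(name, shape, init, group)
  nb$states <- list()      # list(name, len, init)
  nb$taps <- list()
  nb
}

nb_newval <- function(nb) {
  nb$nval <- nb$nval + 1L
  nb$nval
}

nb_param <- function(nb, name, shape, init, group) {
  nb$params[[length(nb$params) + 1L]] <-
    list(name = name, shape = as.integer(shape), init = init, group = group)
  length(nb$params)
}

nb_state <- function(nb, name, len, init) {
  nb$states[[length(nb$states) + 1L]] <- list(name = name, len = as.integer(len),
                                              init = init)
  length(nb$states)
}

nb_instr <- function(nb, op, ins, p = NULL, s = NULL, k = NULL) {
  out <- nb_newval(nb)
  nb$instrs[[length(nb$instrs) + 1L]] <-
    list(op = op, `in` = as.integer(ins), out = out,
         p = if (is.null(p)) NULL else as.integer(p),
         s = if (is.null(s)) NULL else as.integer(s),
         k = if (is.null(k)) NULL else as.numeric(k))
  out
}

# standard conv; weight (Co, Ci, KH, KW); kaiming fan-out init
nb_conv <- function(nb, x, cin, cout, kernel, stride = 1, pad = 0,
                    dilation = 1, bias = FALSE, name, group,
                    init = NULL, bias_init = 0) {
  if (is.null(init))
    init <- list(kind = "kaiming", fan = cout * kernel * kernel)
  pw <- nb_param(nb, paste0(name, ".w"), c(cout, cin, kernel, kernel), init, group)
  p <- pw
  if (bias) {
    pb <- nb_param(nb, paste0(name, ".b"), cout,
                   list(kind = "const", val = bias_init), group)
    p <- c(pw, pb)
  }
  nb_instr(nb, "conv", x, p = p, k = c(stride, pad, dilation, as.integer(bias)))
}

# conv reusing existing parameter ids (shared-MLP branches)
nb_conv_shared <- function(nb, x, pids, stride = 1, pad = 0, dilation = 1) {
  nb_instr(nb, "conv", x, p = pids,
           k = c(stride, pad, dilation, as.integer(length(pids) > 1)))
}

nb_dwconv <- function(nb, x, channels, kernel, stride = 1, pad = 0, name, group) {
  pw <- nb_param(nb, paste0(name, ".w"), c(channels, kernel, kernel),
                 list(kind = "kaiming", fan = kernel * kernel), group)
  nb_instr(nb, "dwconv", x, p = pw, k = c(stride, pad))
}

nb_bn <- function(nb, x, channels, name, group, eps = 1e-3, momentum = 0.1) {
  pg <- nb_param(nb, paste0(name, ".gamma"), channels,
                 list(kind = "const", val = 1), group)
  pb <- nb_param(nb, paste0(name, ".beta"), channels,
                 list(kind = "const", val = 0), group)
  sm <- nb_state(nb, paste0(name, ".rmean"), channels, 0)
  sv <- nb_state(nb, paste0(name, ".rvar"), channels, 1)
  nb_instr(nb, "bn", x, p = c(pg, pb), s = c(sm, sv), k = c(eps, momentum))
}

nb_act <- function(nb, x, type) nb_instr(nb, type, x)
nb_gap <- function(nb, x) nb_instr(nb, "gap", x)
nb_gmp <- function(nb, x) nb_instr(nb, "gmp", x)
nb_mul <- function(nb, a, b) nb_instr(nb, "mul", c(a, b))
nb_add <- function(nb, a, b) nb_instr(nb, "add", c(a, b))
nb_chstat <- function(nb, x) nb_instr(nb, "chstat", x)

nb_conv1dch <- function(nb, x, kernel, name, group) {
  pw <- nb_param(nb, paste0(name, ".w"), kernel,
                 list(kind = "normal", sd = 0.1), group)
  nb_instr(nb, "conv1dch", x, p = pw)
}

nb_tap <- function(nb, name, id) nb$taps[[name]] <- id

# finished net description (plain list; safe to store in a model object)
nb_finish <- function(nb, outputs) {
  list(instrs = nb$instrs, params = nb$params, states = nb$states,
       outputs = outputs, taps = nb$taps, n_values = nb$nval)
}

#' Initialize network weights
#'
#' Materializes the parameter arrays of a built network: Kaiming (fan-out)
#' normal for convolutions, unit gamma / zero beta for batch norm, declared
#' constants for biases (classification priors included).
#'
#' @param net net description from the architecture builders.
#' @param seed integer RNG seed.
#' @return named list of numeric arrays.
#' @keywords internal
init_net_params <- function(net, seed = 1L) {
  rs <- rng_scope(seed)
  on.exit(rs(), add = TRUE)
  out <- vector("list", length(net$params))
  names(out) <- vapply(net$params, `[[`, "", "name")
  for (i in seq_along(net$params)) {
    pm <- net$params[[i]]
    n <- prod(pm$shape)
    v <- switch(pm$init$kind,
                kaiming = rnorm(n, sd = sqrt(2 / pm$init$fan)),
                normal  = rnorm(n, sd = pm$init$sd),
                const   = rep(pm$init$val, n),
                stop("unknown init"))
    if (length(pm$shape) > 1L) dim(v) <- pm$shape
    out[[i]] <- v
  }
  out
}

init_net_state <- function(net) {
  st <- lapply(net$states, function(s) rep(as.numeric(s$init), s$len))
  names(st) <- vapply(net$states, `[[`, "", "name")
  st
}

# deterministic local RNG: returns a restore function
rng_scope <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# run a built net through the engine
net_forward <- function(net, params, state, x, training = FALSE,
                        outputs = NULL, keep_cache = FALSE,
                        precision = c("float", "double")) {
  precision <- match.arg(precision)
  if (is.null(outputs)) outputs <- net$outputs
  res <- eng_forward(net$instrs, unname(params), unname(state), x,
                     training, as.integer(unlist(outputs)), keep_cache,
                     precision == "double")
  names(res$values) <- names(outputs)
  names(res$state) <- names(state)
  res
}

net_backward <- function(cache, grads, gout_ids) {
  eng_backward(cache, grads, as.integer(gout_ids))
}
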