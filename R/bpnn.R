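#' Network hyperparameter configuration
#'
#' Defaults are the operating point used for the binary amyloid-PET
#' experiments: a 400-45-2 topology, logistic-sigmoid activations, bias
#' weights, learning rate 0.00079, momentum 0.90 and an RMS-error stopping
#' threshold of 0.003. `max_epochs` is a safety valve against settings that
#' converge late or never.
#'
#' @param n_input number of input neurons (default 400 = APPN features of a
#'   200x200 image with 10-pixel segments).
#' @param n_hidden hidden neurons (default 45).
#' @param n_output output neurons (default 2, one per class).
#' @param learning_rate gradient step scale, > 0.
#' @param momentum fraction of the previous weight update re-applied,
#'   in `[0, 1)`.
#' @param min_rms RMS-error convergence threshold, > 0.
#' @param activation hidden-layer activation: `"logistic_sigmoid"` or
#'   `"relu"`. The output layer is always logistic sigmoid (ReLU is unbounded
#'   above and cannot emit the (0,1) targets).
#' @param use_bias train bias weights (`TRUE`) or freeze them at zero.
#' @param max_epochs epoch cap for non-converging runs.
#' @param seed integer governing weight initialization and epoch shuffling.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_input = 400L, n_hidden = 45L, n_output = 2L,
                           learning_rate = 0.00079, momentum = 0.90,
                           min_rms = 0.003,
                           activation = c("logistic_sigmoid", "relu"),
                           use_bias = TRUE, max_epochs = 50000L, seed = 1L) {
  activation <- match.arg(activation)
  n_input <- as.integer(n_input); n_hidden <- as.integer(n_hidden)
  n_output <- as.integer(n_output); max_epochs <- as.integer(max_epochs)
  if (any(c(n_input, n_hidden, n_output, max_epochs) < 1L))
    stop_amypet("neuron counts and max_epochs must be >= 1",
                class = "amypet_validation_error")
  if (learning_rate <= 0) stop_amypet("learning_rate must be > 0",
                                      class = "amypet_validation_error")
  if (momentum < 0 || momentum >= 1)
    stop_amypet("momentum must be in [0, 1)", class = "amypet_validation_error")
  if (min_rms <= 0) stop_amypet("min_rms must be > 0",
                                class = "amypet_validation_error")
  structure(list(n_input = n_input, n_hidden = n_hidden, n_output = n_output,
                 learning_rate = learning_rate, momentum = momentum,
                 min_rms = min_rms, activation = activation,
                 use_bias = use_bias, max_epochs = max_epochs,
                 seed = as.integer(seed)),
            class = "network_config")
}

act_code <- function(cfg) if (cfg$activation == "relu") 1L else 0L

new_state <- function(W_ih, W_ho, prev_delta_ih = NULL, prev_delta_ho = NULL) {
  structure(list(
    W_ih = W_ih, W_ho = W_ho,
    prev_delta_ih = prev_delta_ih %||% array(0, dim(W_ih)),
    prev_delta_ho = prev_delta_ho %||% array(0, dim(W_ho))
  ), class = "network_state")
}

#' Initialize network weights
#'
#' Weights (including the bias row appended to each matrix) are drawn
#' uniformly from `[-0.5, 0.5]` using `cfg$seed`; momentum buffers start at
#' zero. `W_ih` is `(n_input+1) x n_hidden` and `W_ho` is
#' `(n_hidden+1) x n_output`, the final row of each holding the biases.
#' With `use_bias = FALSE` the bias rows are zero and stay zero.
#'
#' @param cfg a [network_config()].
#' @return A list of class `network_state` with weight matrices and momentum
#'   buffers.
#' @export
init_state <- function(cfg) {
  with_seed(cfg$seed, init_weights(cfg))
}

# draws from the current RNG stream; callers are responsible for seeding
init_weights <- function(cfg) {
  W_ih <- matrix(runif((cfg$n_input + 1L) * cfg$n_hidden, -0.5, 0.5),
                 cfg$n_input + 1L, cfg$n_hidden)
  W_ho <- matrix(runif((cfg$n_hidden + 1L) * cfg$n_output, -0.5, 0.5),
                 cfg$n_hidden + 1L, cfg$n_output)
  if (!isTRUE(cfg$use_bias)) {
    W_ih[nrow(W_ih), ] <- 0
    W_ho[nrow(W_ho), ] <- 0
  }
  new_state(W_ih, W_ho)
}

as_input <- function(x) {
  if (inherits(x, "feature_vector")) x$values else as.numeric(x)
}

#' Forward pass
#'
#' Computes `hidden_j = act(sum_i w_ij x_i + b_j)` and
#' `out_k = sigma(sum_j v_jk hidden_j + c_k)` with
#' `sigma(z) = 1/(1 + exp(-z))`.
#'
#' @param state a `network_state`.
#' @param x input pattern (`feature_vector` or numeric vector) of length
#'   `n_input`.
#' @param activation hidden activation name (default logistic sigmoid).
#' @return List with `hidden` and `output` activation vectors; sigmoid
#'   outputs are strictly inside (0, 1).
#' @export
nn_forward <- function(state, x, activation = "logistic_sigmoid") {
  x <- as_input(x)
  if (length(x) != nrow(state$W_ih) - 1L)
    stop_amypet("input length %d does not match n_input %d",
                length(x), nrow(state$W_ih) - 1L, class = "amypet_shape_error")
  out <- .cpp_forward(state$W_ih, state$W_ho, x,
                      if (identical(activation, "relu")) 1L else 0L)
  list(hidden = as.numeric(out$hidden), output = as.numeric(out$output))
}

#' One online back-propagation update
#'
#' Standard delta rule with momentum: output deltas
#' `delta_k = (t_k - o_k) sigma'(z_k)`, hidden deltas by the back-propagated
#' weighted sum, and `dW(t) = eta * delta * activation + alpha * dW(t-1)`.
#' The returned state carries the updated weights and the momentum buffers
#' holding `dW(t)`.
#'
#' @param state a `network_state`.
#' @param x input pattern of length `n_input`.
#' @param target numeric target vector of length `n_output` (one-hot for
#'   classification).
#' @param cfg a [network_config()] supplying `learning_rate`, `momentum`,
#'   `activation` and `use_bias`.
#' @return The updated `network_state`.
#' @export
backprop_step <- function(state, x, target, cfg) {
  x <- as_input(x)
  if (length(x) != nrow(state$W_ih) - 1L ||
      length(target) != ncol(state$W_ho))
    stop_amypet("pattern/target shape does not match the network",
                class = "amypet_shape_error")
  res <- .cpp_backprop_step(state$W_ih, state$W_ho, state$prev_delta_ih,
                            state$prev_delta_ho, x, as.numeric(target),
                            cfg$learning_rate, cfg$momentum, act_code(cfg),
                            isTRUE(cfg$use_bias))
  new_state(res$W_ih, res$W_ho, res$prev_delta_ih, res$prev_delta_ho)
}

one_hot_targets <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx))
    stop_amypet("label not in classes: %s",
                paste(unique(labels[is.na(idx)]), collapse = ", "),
                class = "amypet_validation_error")
  T <- matrix(0, length(labels), length(classes))
  T[cbind(seq_along(labels), idx)] <- 1
  T
}

#' Train the network by online back-propagation
#'
#' Each epoch visits every pattern once in a freshly shuffled order (seeded,
#' reproducible) and applies a per-pattern weight update. After each epoch
#' the RMS error `sqrt(sum_p sum_k (t_pk - o_pk)^2 / (P K))` is computed with
#' the weights frozen; training stops when it reaches `cfg$min_rms`
#' (converged) or after `cfg$max_epochs` epochs.
#'
#' @param x numeric matrix of input patterns, one row per pattern, or a
#'   feature `data.frame` from [prepare_manifest()].
#' @param labels class label per pattern (character or factor); exactly the
#'   classes in `classes` must appear, each at least once.
#' @param cfg a [network_config()]; `cfg$seed` drives both weight
#'   initialization and epoch shuffling.
#' @param classes class-to-output-neuron order; defaults to the sorted unique
#'   labels. Output neuron `k` is trained toward 1 for class `classes[k]`.
#' @return A list of class `train_result`: `state`, `epochs_run`,
#'   `final_rms`, `converged`, `rms_history`, `classes`.
#' @export
nn_train <- function(x, labels, cfg = network_config(), classes = NULL) {
  if (is.data.frame(x)) {
    if (missing(labels) || is.null(labels)) labels <- x$label
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    stop_amypet("empty training set", class = "amypet_validation_error")
  labels <- as.character(labels)
  classes <- classes %||% sort(unique(labels))
  if (length(classes) != cfg$n_output)
    stop_amypet("%d classes but n_output = %d", length(classes), cfg$n_output,
                class = "amypet_validation_error")
  if (!all(classes %in% labels))
    stop_amypet("every class needs at least one training pattern",
                class = "amypet_validation_error")
  if (ncol(x) != cfg$n_input)
    stop_amypet("feature length %d does not match n_input %d", ncol(x),
                cfg$n_input, class = "amypet_shape_error")
  T <- one_hot_targets(labels, classes)
  # one seeded stream: initialization draws first, epoch shuffles follow
  res <- with_seed(cfg$seed, {
    st <- init_weights(cfg)
    .cpp_train(st$W_ih, st$W_ho, st$prev_delta_ih, st$prev_delta_ho,
               x, T, cfg$learning_rate, cfg$momentum, cfg$min_rms,
               cfg$max_epochs, act_code(cfg), isTRUE(cfg$use_bias), TRUE)
  })
  structure(list(
    state = new_state(res$W_ih, res$W_ho, res$prev_delta_ih,
                      res$prev_delta_ho),
    epochs_run = res$epochs_run,
    final_rms = res$rms_history[length(res$rms_history)],
    converged = res$converged,
    rms_history = res$rms_history,
    classes = classes,
    config = cfg
  ), class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %s after %d epochs, final RMS %.6f\n",
              if (x$converged) "converged" else "stopped", x$epochs_run,
              x$final_rms))
  invisible(x)
}

#' Predict class indices
#'
#' Argmax over the output activations, ties broken toward the lower index.
#' Indices are 0-based (output neuron `k` corresponds to index `k`), matching
#' the order of `classes` passed to [nn_train()].
#'
#' @param state a `network_state` (or a `train_result`, whose state is used).
#' @param x one pattern (vector / `feature_vector`) or a matrix of patterns,
#'   one per row.
#' @param activation hidden activation name.
#' @return Integer vector of 0-based class indices.
#' @export
nn_predict <- function(state, x, activation = "logistic_sigmoid") {
  if (inherits(state, "train_result")) {
    activation <- state$config$activation
    state <- state$state
  }
  if (inherits(x, "feature_vector") || is.null(dim(x)))
    x <- matrix(as_input(x), nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != nrow(state$W_ih) - 1L)
    stop_amypet("input length %d does not match n_input %d", ncol(x),
                nrow(state$W_ih) - 1L, class = "amypet_shape_error")
  .cpp_predict(state$W_ih, state$W_ho, x,
               if (identical(activation, "relu")) 1L else 0L)
}

#' RMS output error of a network on a pattern set
#' @inheritParams nn_predict
#' @param targets matrix of targets, one row per pattern.
#' @return The scalar RMS error.
#' @export
nn_rms <- function(state, x, targets, activation = "logistic_sigmoid") {
  if (inherits(state, "train_result")) {
    activation <- state$config$activation
    state <- state$state
  }
  .cpp_rms(state$W_ih, state$W_ho, as.matrix(x), as.matrix(targets),
           if (identical(activation, "relu")) 1L else 0L)
}

#' Save a trained model as JSON
#'
#' Serializes weights, momentum buffers, configuration, class order, and
#' training metadata to a single JSON file from which [load_model()] restores
#' the model (weights are written at full decimal precision; reload agrees to
#' within a couple of ULPs per weight).
#'
#' @param result a `train_result` from [nn_train()].
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(result, path) {
  stopifnot(inherits(result, "train_result"))
  obj <- list(
    format = "amypet-bpnn-1",
    config = unclass(result$config),
    classes = result$classes,
    epochs_run = result$epochs_run,
    final_rms = result$final_rms,
    converged = result$converged,
    W_ih = result$state$W_ih,
    W_ho = result$state$W_ho,
    prev_delta_ih = result$state$prev_delta_ih,
    prev_delta_ho = result$state$prev_delta_ho
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path `.json` file.
#' @return A `train_result`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "amypet-bpnn-1"))
    stop_amypet("not an amypet model file: %s", path,
                class = "amypet_format_error")
  cfg <- do.call(network_config, obj$config[names(formals(network_config))[
    names(formals(network_config)) %in% names(obj$config)]])
  structure(list(
    state = new_state(obj$W_ih, obj$W_ho, obj$prev_delta_ih,
                      obj$prev_delta_ho),
    epochs_run = obj$epochs_run,
    final_rms = obj$final_rms,
    converged = obj$converged,
    rms_history = NULL,
    classes = obj$classes,
    config = cfg
  ), class = "train_result")
}
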