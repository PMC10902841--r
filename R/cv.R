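# Uniform evaluator interface: every biasing routine consumes an object
# that maps a configuration to CV value(s) plus the gradient with respect
# to every coordinate. Evaluators exist for the analytical CVs, trained
# graph models (with isolated-particle gradient masking), and bare
# coordinates (used by the closed-form double-well diagnostics).

#' Construct a CV evaluator
#'
#' @param fun function(configuration, gradient, graph) returning a list
#'   with `values` (numeric vector of length `dim`) and `gradients` (list
#'   of N x 3 matrices, one per component); `graph` may be NULL, in which
#'   case the evaluator builds its own at `cutoff`.
#' @param dim number of CV components.
#' @param name label used in logs and output headers.
#' @param cutoff neighbor-graph cutoff the evaluator needs (0 if none);
#'   lets simulation loops share one neighbor search per step.
#' @return object of class `cv_evaluator`; call it via [eval_cv()].
#' @export
cv_evaluator <- function(fun, dim = 1L, name = "cv", cutoff = 0) {
  structure(list(fun = fun, dim = as.integer(dim), name = name,
                 cutoff = cutoff),
            class = "cv_evaluator")
}

#' Evaluate a CV evaluator on a configuration
#' @param cv a [cv_evaluator()].
#' @param config a [configuration()].
#' @param gradient whether gradients are needed.
#' @param graph optional prebuilt graph at a cutoff >= `cv$cutoff` (it is
#'   restricted via [subgraph()] as needed).
#' @return list with `values` and (if requested) `gradients`.
#' @export
eval_cv <- function(cv, config, gradient = TRUE, graph = NULL) {
  if (!is.null(graph) && cv$cutoff > 0 && graph$cutoff < cv$cutoff)
    graph <- NULL
  cv$fun(config, gradient, graph)
}

#' Analytical CV evaluator
#'
#' @param which "nQ6" (crystalline-particle count) or "n" (droplet size).
#' @param p a [switch_params()].
#' @param t a [threshold_params()].
#' @param cutoff neighbor-graph cutoff for the CV.
#' @return a [cv_evaluator()] of dimension 1.
#' @export
make_analytical_cv <- function(which = c("nQ6", "n"), p, t, cutoff) {
  which <- match.arg(which)
  f <- if (which == "nQ6") cv_nQ6 else cv_n
  cv_evaluator(function(config, gradient = TRUE, graph = NULL) {
    g <- if (is.null(graph)) build_graph(config, cutoff)
         else subgraph(graph, cutoff)
    r <- f(config, g, p, t, gradient = gradient)
    list(values = r$value,
         gradients = if (gradient) list(r$gradient) else NULL)
  }, dim = 1L, name = paste0("analytical_", which), cutoff = cutoff)
}

#' Trained-model CV evaluator
#'
#' Wraps a `gnn_model`; gradients are masked so isolated particles feel no
#' bias force.
#'
#' @param model a `gnn_model`.
#' @return a [cv_evaluator()] of dimension `out_dim`.
#' @export
make_model_cv <- function(model) {
  cv_evaluator(function(config, gradient = TRUE, graph = NULL) {
    if (!is.null(graph)) graph <- subgraph(graph, model$config$cutoff)
    if (gradient) {
      pr <- gnn_gradient(model, config, graph)
      list(values = pr$values, gradients = pr$gradients)
    } else {
      list(values = gnn_forward(model, config, graph), gradients = NULL)
    }
  }, dim = model$config$out_dim, name = "model_cv",
  cutoff = model$config$cutoff)
}

#' Bare-coordinate CV evaluator
#'
#' The (wrapped) coordinate of one particle along one axis, minus an
#' offset. Used with external closed-form potentials for integrator and
#' free-energy diagnostics.
#'
#' @param particle particle index.
#' @param axis 1, 2 or 3.
#' @param offset value subtracted from the coordinate (e.g. box center).
#' @return a [cv_evaluator()] of dimension 1.
#' @export
make_coordinate_cv <- function(particle = 1L, axis = 1L, offset = 0) {
  cv_evaluator(function(config, gradient = TRUE, graph = NULL) {
    v <- config$positions[particle, axis] - offset
    g <- NULL
    if (gradient) {
      G <- matrix(0, nrow(config$positions), 3)
      G[particle, axis] <- 1
      g <- list(G)
    }
    list(values = v, gradients = g)
  }, dim = 1L, name = sprintf("x[%d,%d]", particle, axis))
}
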