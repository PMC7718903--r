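## Glowworm swarm optimization engine.
##
## The standard formulation: each agent carries a luciferin level updated as
##   l' = (1 - rho) * l + gamma * score(x)
## (clamped at zero), probabilistically moves a fixed step toward a brighter
## neighbour within its adaptive vision range (probability proportional to
## the luciferin excess), and adapts its vision range toward holding
## `max_neighbors` neighbours. Agents with no brighter neighbour in range do
## not move. The engine is generic over the search space: positions are rows
## of a numeric matrix and the distance and move rules are pluggable, which
## is how the same machinery optimizes 2-D test functions and rigid-body
## ligand poses (translation moved linearly, rotation by quaternion slerp).

#' GSO engine parameters
#'
#' @param rho luciferin decay in (0,1); default 0.4.
#' @param gamma luciferin gain; default 0.6.
#' @param beta vision-range adaptation rate; default 0.08.
#' @param max_neighbors target neighbour count for the vision update;
#'   default 5.
#' @param step_size move distance per iteration (units of the search space);
#'   default 0.1.
#' @param initial_luciferin starting luciferin; default 5.
#' @param initial_vision starting vision range; default 3.
#' @param max_vision upper bound on the vision range; default
#'   \code{initial_vision}.
#' @param dist_fn function(positions) returning the full pairwise distance
#'   matrix; default Euclidean.
#' @param move_fn function(xi, xj, f) moving \code{xi} a fraction \code{f} of
#'   the way to \code{xj}; default linear interpolation. \code{f} is
#'   \code{min(1, step_size / distance)} so a move never overshoots.
#' @return list of engine parameters.
#' @export
gso_params <- function(rho = 0.4, gamma = 0.6, beta = 0.08,
                       max_neighbors = 5, step_size = 0.1,
                       initial_luciferin = 5, initial_vision = 3,
                       max_vision = initial_vision,
                       dist_fn = NULL, move_fn = NULL) {
  stopifnot(rho > 0, rho < 1, gamma > 0, beta > 0, step_size > 0,
            max_neighbors >= 1)
  list(rho = rho, gamma = gamma, beta = beta,
       max_neighbors = max_neighbors, step_size = step_size,
       initial_luciferin = initial_luciferin,
       initial_vision = initial_vision, max_vision = max_vision,
       dist_fn = dist_fn, move_fn = move_fn)
}

gso_init_state <- function(positions, score_fn, params) {
  n <- nrow(positions)
  scores <- score_fn(positions)
  list(positions = positions,
       luciferin = rep(params$initial_luciferin, n),
       vision = rep(params$initial_vision, n),
       scores = scores,
       best_positions = positions,
       best_scores = scores)
}

# One synchronous GSO iteration. Uses the current RNG stream for the
# probabilistic neighbour choice.
gso_iterate <- function(state, score_fn, params) {
  n <- nrow(state$positions)
  ## 1. luciferin update from current scores
  l <- pmax(0, (1 - params$rho) * state$luciferin +
              params$gamma * state$scores)
  ## 2. probabilistic movement toward a brighter neighbour
  D <- if (is.null(params$dist_fn)) {
    cross_dist(state$positions, state$positions)
  } else {
    params$dist_fn(state$positions)
  }
  newpos <- state$positions
  moved <- logical(n)
  n_neighbors <- integer(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < state$vision[i] & l > l[i])
    n_neighbors[i] <- length(nb)
    if (length(nb) == 0) next
    p <- l[nb] - l[i]
    j <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1, prob = p)]
    f <- min(1, params$step_size / D[i, j])
    newpos[i, ] <- if (is.null(params$move_fn)) {
      state$positions[i, ] + f * (state$positions[j, ] - state$positions[i, ])
    } else {
      params$move_fn(state$positions[i, ], state$positions[j, ], f)
    }
    moved[i] <- TRUE
  }
  ## 3. vision-range adaptation toward max_neighbors
  vision <- pmin(params$max_vision,
                 pmax(0, state$vision +
                        params$beta * (params$max_neighbors - n_neighbors)))
  ## 4. re-score moved agents only
  scores <- state$scores
  if (any(moved))
    scores[moved] <- score_fn(newpos[moved, , drop = FALSE])
  better <- scores > state$best_scores
  state$best_positions[better, ] <- newpos[better, , drop = FALSE]
  state$best_scores[better] <- scores[better]
  state$positions <- newpos
  state$luciferin <- l
  state$vision <- vision
  state$scores <- scores
  state
}

#' Run glowworm swarm optimization
#'
#' Generic driver used both for analytic test functions and (through custom
#' distance/move rules) for rigid-body pose optimization.
#'
#' @param positions numeric matrix, one agent per row.
#' @param score_fn function(matrix of positions) returning a numeric score
#'   per row; higher is better.
#' @param steps number of iterations.
#' @param params engine parameters from \code{\link{gso_params}}.
#' @param seed optional integer seed for the probabilistic neighbour choice.
#' @return list with final \code{positions}, \code{scores},
#'   \code{luciferin}, \code{vision}, and the best-ever
#'   \code{best_positions}/\code{best_scores} per agent.
#' @export
gso_run <- function(positions, score_fn, steps, params = gso_params(),
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- gso_init_state(positions, score_fn, params)
  for (s in seq_len(steps)) state <- gso_iterate(state, score_fn, params)
  state
}
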