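# Quantum-inspired fruit fly optimizer (QFOA) and the classic FOA baseline.
#
# QFOA encodes each candidate solution as a pair of phase-angle vectors
# (X_axis, Y_axis). Dimension j carries two angles (theta_x_j, theta_y_j)
# whose cosine/sine amplitudes decode to two complementary solutions in
# [0, 1]^n, so a swarm of M flies effectively searches a doubled space.
# Search proceeds by uniform perturbation of the angles around the swarm
# axes, quantum NOT-gate mutation (theta -> pi/2 - theta, which swaps the
# cosine and sine amplitudes), Boltzmann acceptance of worsening mutations,
# and greedy relocation of the axes to the best fly.

#' Optimizer configuration
#'
#' @param population_size number of fruit flies M per iteration.
#' @param max_iterations iteration budget after initialization; 0 means the
#'   result is the best member of the initial population only.
#' @param mutation_prob probability `P_m` that a fly undergoes a NOT-gate
#'   mutation in a given iteration.
#' @param perturb_range half-width of the uniform angle perturbation `V`,
#'   in radians; draws are from `[-perturb_range, perturb_range]`.
#' @param seed integer seed driving every stochastic operation of a run.
#' @param dimension number of optimized dimensions n (2 for SVM tuning:
#'   one for C, one for gamma).
#' @return An object of class `"optimizer_config"`.
#' @export
optimizer_config <- function(population_size = 20L, max_iterations = 100L,
                             mutation_prob = 0.2, perturb_range = 1,
                             seed = 1L, dimension = 2L) {
  if (!is.numeric(perturb_range) || length(perturb_range) != 1L ||
      is.na(perturb_range) || perturb_range < 0) {
    stopf("`perturb_range` must be a single non-negative number")
  }
  structure(
    list(
      population_size = check_count(population_size, "population_size"),
      max_iterations = check_count(max_iterations, "max_iterations", min = 0L),
      mutation_prob = check_prob(mutation_prob, "mutation_prob"),
      perturb_range = as.numeric(perturb_range),
      seed = check_count(seed, "seed", min = -.Machine$integer.max),
      dimension = check_count(dimension, "dimension")
    ),
    class = "optimizer_config"
  )
}

#' Construct a phase position
#'
#' @param x_angles,y_angles numeric vectors of equal length n with phase
#'   angles in radians; angles are wrapped into `[-pi, pi]`.
#' @return An object of class `"phase_position"`.
#' @export
phase_position <- function(x_angles, y_angles) {
  if (length(x_angles) != length(y_angles) || length(x_angles) < 1L) {
    stopf("`x_angles` and `y_angles` must be non-empty vectors of equal length")
  }
  structure(
    list(x_angles = wrap_angle(as.numeric(x_angles)),
         y_angles = wrap_angle(as.numeric(y_angles))),
    class = "phase_position"
  )
}

#' Wrap angles into \[-pi, pi\]
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles shifted by multiples of 2*pi into `[-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # keep +pi representable: x %% 2pi maps pi to -pi; restore exact +pi inputs
  out[theta == pi] <- pi
  out
}

#' Initialize a population of phase positions
#'
#' Each angle is drawn as `pi * (2 * u - 1)` with `u ~ Uniform(0, 1)`,
#' i.e. uniformly on `[-pi, pi]`. Consumes the current RNG stream; seeded
#' entry points such as [qfoa_optimize()] set the seed beforehand.
#'
#' @param config an [optimizer_config()].
#' @return A list of `population_size` [phase_position()] objects.
#' @export
init_phase_population <- function(config) {
  stopifnot(inherits(config, "optimizer_config"))
  lapply(seq_len(config$population_size), function(i) {
    phase_position(
      x_angles = pi * (2 * stats::runif(config$dimension) - 1),
      y_angles = pi * (2 * stats::runif(config$dimension) - 1)
    )
  })
}

#' Decode a phase position into its cosine and sine solutions
#'
#' For dimension j the squared amplitude distance
#' `cos^2(theta_x_j) + cos^2(theta_y_j)` lies in `[0, 2]`; dividing by its
#' maximum 2 normalizes the smell-concentration determination value into
#' `[0, 1]` and makes the two solutions exactly complementary,
#' `s_cos + s_sin = 1`, mirroring the quantum amplitude identity
#' `cos^2 + sin^2 = 1`.
#'
#' @param pos a [phase_position()].
#' @return A list with `s_cos` and `s_sin`, vectors in `[0, 1]^n` summing
#'   to 1 elementwise.
#' @examples
#' decode_solutions(phase_position(pi / 4, pi / 4))
#' @export
decode_solutions <- function(pos) {
  stopifnot(inherits(pos, "phase_position"))
  s_cos <- (cos(pos$x_angles)^2 + cos(pos$y_angles)^2) / 2
  list(s_cos = s_cos, s_sin = 1 - s_cos)
}

#' Perturb a phase position around the swarm axes
#'
#' Adds an independent Uniform(`-perturb_range`, `perturb_range`) draw to
#' every angle (one draw per dimension per axis), then wraps back into
#' `[-pi, pi]`. Consumes the current RNG stream.
#'
#' @param base a [phase_position()] (the swarm axes).
#' @param config an [optimizer_config()] supplying `perturb_range`.
#' @return A new [phase_position()].
#' @export
perturb_position <- function(base, config) {
  stopifnot(inherits(base, "phase_position"), inherits(config, "optimizer_config"))
  n <- length(base$x_angles)
  r <- config$perturb_range
  phase_position(
    x_angles = base$x_angles + stats::runif(n, -r, r),
    y_angles = base$y_angles + stats::runif(n, -r, r)
  )
}

#' Quantum NOT-gate mutation
#'
#' With probability `mutation_prob`, one coordinate chosen uniformly among
#' the 2n angles is replaced by `pi/2 - theta`, which exchanges the cosine
#' and sine amplitudes of that coordinate (`cos(pi/2 - theta) = sin(theta)`).
#' The gate is an involution: applied twice it restores the angle. Consumes
#' the current RNG stream: one uniform mutation coin, then (only if the coin
#' fires) one uniform coordinate draw.
#'
#' @param pos a [phase_position()].
#' @param mutation_prob probability of mutating, in `[0, 1]`.
#' @return A list with `position` (the possibly-mutated [phase_position()])
#'   and `mutated` (logical flag).
#' @export
mutate_not_gate <- function(pos, mutation_prob) {
  stopifnot(inherits(pos, "phase_position"))
  mutation_prob <- check_prob(mutation_prob, "mutation_prob")
  if (stats::runif(1) >= mutation_prob) {
    return(list(position = pos, mutated = FALSE))
  }
  n <- length(pos$x_angles)
  idx <- sample.int(2L * n, 1L)
  x <- pos$x_angles
  y <- pos$y_angles
  if (idx <= n) x[idx] <- pi / 2 - x[idx] else y[idx - n] <- pi / 2 - y[idx - n]
  list(position = phase_position(x, y), mutated = TRUE)
}

#' Boltzmann acceptance probability for a mutated position
#'
#' A strict improvement (`f_new < f_old`) is accepted with probability 1.
#' A worsening is accepted with the annealed logistic probability
#' `1 / (1 + exp(iteration * (f_new - f_old)))`, which is at most 1/2 and
#' decays both in the size of the worsening and in the iteration count, so
#' exploration is damped as the search matures.
#'
#' @param f_new fitness of the mutated position.
#' @param f_old fitness of the original position.
#' @param iteration current iteration number `l >= 1`.
#' @return A probability in `(0, 1]`.
#' @export
acceptance_probability <- function(f_new, f_old, iteration) {
  iteration <- check_count(iteration, "iteration")
  if (!is.finite(f_new) || !is.finite(f_old)) {
    stopf("fitness values must be finite")
  }
  if (f_new < f_old) return(1)
  1 / (1 + exp(iteration * (f_new - f_old)))
}

# Evaluate one fly: decode both solutions, score each, keep the better
# (smaller) smell. Errors if the objective returns a non-finite value.
eval_fly <- function(objective, pos) {
  sp <- decode_solutions(pos)
  f_cos <- objective(sp$s_cos)
  f_sin <- objective(sp$s_sin)
  for (v in list(list(f_cos, sp$s_cos), list(f_sin, sp$s_sin))) {
    if (!is.numeric(v[[1]]) || length(v[[1]]) != 1L || !is.finite(v[[1]])) {
      stop(structure(
        class = c("qfoa_objective_error", "error", "condition"),
        list(message = sprintf(
          "objective returned a non-finite value at solution (%s)",
          paste(signif(v[[2]], 6), collapse = ", ")
        ), call = NULL, solution = v[[2]])
      ))
    }
  }
  if (f_cos <= f_sin) list(fitness = f_cos, solution = sp$s_cos)
  else list(fitness = f_sin, solution = sp$s_sin)
}

# One mutation/acceptance pass over the population. RNG order per fly:
# mutation coin, coordinate draw (if mutated), acceptance draw (if mutated).
mutation_pass <- function(objective, flies, fits, sols, config, iteration) {
  for (i in seq_along(flies)) {
    mut <- mutate_not_gate(flies[[i]], config$mutation_prob)
    if (!mut$mutated) next
    cand <- eval_fly(objective, mut$position)
    p <- acceptance_probability(cand$fitness, fits[[i]], iteration)
    if (stats::runif(1) < p) {
      flies[[i]] <- mut$position
      fits[[i]] <- cand$fitness
      sols[[i]] <- cand$solution
    }
  }
  list(flies = flies, fits = fits, sols = sols)
}

#' Minimize an objective on \[0, 1\]^n with the quantum fruit fly optimizer
#'
#' Runs the full loop: a random initial population is evaluated (both the
#' cosine and sine solutions of every fly are scored and the better smell
#' kept), mutated with the NOT gate under Boltzmann acceptance, and the
#' swarm axes move to the best fly. Each subsequent iteration perturbs all
#' flies around the axes, repeats decoding/evaluation/mutation, and
#' relocates the axes whenever the population minimum improves on the
#' incumbent. The returned best-so-far trajectory has one entry for the
#' initial population plus one per iteration and is non-increasing.
#'
#' @param objective function mapping a vector in `[0, 1]^n` to a finite
#'   scalar; smaller is better.
#' @param config an [optimizer_config()]; `config$seed` makes the run
#'   fully reproducible.
#' @return An object of class `"optimization_result"`: list with
#'   `best_fitness`, `best_solution`, `best_position`,
#'   `best_fitness_per_iteration`, `evaluations`, `seed`, `method`.
#' @examples
#' res <- qfoa_optimize(
#'   function(s) (s[1] - 0.4)^2 + (s[2] - 0.6)^2,
#'   optimizer_config(population_size = 10, max_iterations = 30, seed = 7)
#' )
#' res$best_fitness
#' @export
qfoa_optimize <- function(objective, config) {
  stopifnot(is.function(objective), inherits(config, "optimizer_config"))
  with_seed(config$seed, {
    n_eval <- 0L
    counted <- function(s) {
      n_eval <<- n_eval + 1L
      objective(s)
    }
    flies <- init_phase_population(config)
    scored <- lapply(flies, function(p) eval_fly(counted, p))
    fits <- vapply(scored, `[[`, numeric(1), "fitness")
    sols <- lapply(scored, `[[`, "solution")
    mp <- mutation_pass(counted, flies, fits, sols, config, iteration = 1L)
    flies <- mp$flies; fits <- unlist(mp$fits); sols <- mp$sols
    best_i <- which.min(fits)
    best_fit <- fits[[best_i]]
    best_sol <- sols[[best_i]]
    best_pos <- flies[[best_i]]
    axes <- best_pos
    traj <- numeric(config$max_iterations + 1L)
    traj[1L] <- best_fit
    l <- 1L
    while (l <= config$max_iterations) {
      flies <- lapply(seq_len(config$population_size),
                      function(i) perturb_position(axes, config))
      scored <- lapply(flies, function(p) eval_fly(counted, p))
      fits <- vapply(scored, `[[`, numeric(1), "fitness")
      sols <- lapply(scored, `[[`, "solution")
      mp <- mutation_pass(counted, flies, fits, sols, config, iteration = l)
      flies <- mp$flies; fits <- unlist(mp$fits); sols <- mp$sols
      cand_i <- which.min(fits)
      if (fits[[cand_i]] < best_fit) {
        best_fit <- fits[[cand_i]]
        best_sol <- sols[[cand_i]]
        best_pos <- flies[[cand_i]]
        axes <- best_pos
      }
      traj[l + 1L] <- best_fit
      l <- l + 1L
    }
    structure(
      list(
        best_fitness = best_fit,
        best_solution = best_sol,
        best_position = best_pos,
        best_fitness_per_iteration = traj,
        evaluations = n_eval,
        seed = config$seed,
        method = "qfoa"
      ),
      class = "optimization_result"
    )
  })
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<%s optimization: best fitness %.6g after %d evaluations, seed %d>\n",
    x$method, x$best_fitness, x$evaluations, x$seed
  ))
  cat("best solution:", paste(signif(x$best_solution, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Decode classic-FOA coordinates into smell-concentration values
#'
#' Per dimension, `dist = sqrt(x^2 + y^2)` and `s = 1 / dist`.
#'
#' @param x,y numeric vectors of fly coordinates.
#' @return A list with `dist` and `s`.
#' @examples
#' foa_decode(3, 4)  # dist 5, s 0.2
#' @export
foa_decode <- function(x, y) {
  dist <- sqrt(x^2 + y^2)
  list(dist = dist, s = 1 / dist)
}

#' Optimize an objective with the classic fruit fly algorithm
#'
#' The baseline swarm: real-valued axes `(X_axis, Y_axis)` per dimension,
#' each fly perturbed by Uniform(`-perturb_range`, `perturb_range`) draws,
#' decoded through `S = 1 / sqrt(X^2 + Y^2)`, and scored by the objective.
#' The axes move to the best fly whenever it improves on the incumbent.
#' A fly landing exactly on the origin (undefined `1/dist`) is re-sampled.
#'
#' @param objective function of the decoded `S` vector returning a finite
#'   scalar.
#' @param config an [optimizer_config()].
#' @param sense `"min"` (default; smaller smell is better) or `"max"`
#'   (the classic formulation's `max Smell`).
#' @param init_lower,init_upper bounds of the uniform axis initialization;
#'   the defaults place `S = 1/dist` in (0, 1).
#' @return An `"optimization_result"` (see [qfoa_optimize()]); for
#'   `sense = "min"` the trajectory is non-increasing, for `"max"`
#'   non-decreasing. `best_position` is a list with `x` and `y` axes.
#' @export
foa_optimize <- function(objective, config, sense = c("min", "max"),
                         init_lower = 1, init_upper = 10) {
  stopifnot(is.function(objective), inherits(config, "optimizer_config"))
  sense <- match.arg(sense)
  better <- if (sense == "min") `<` else `>`
  with_seed(config$seed, {
    n <- config$dimension
    r <- config$perturb_range
    n_eval <- 0L
    score <- function(s) {
      n_eval <<- n_eval + 1L
      val <- objective(s)
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
        stop(structure(
          class = c("qfoa_objective_error", "error", "condition"),
          list(message = sprintf(
            "objective returned a non-finite value at solution (%s)",
            paste(signif(s, 6), collapse = ", ")
          ), call = NULL, solution = s)
        ))
      }
      val
    }
    draw_fly <- function(ax, ay) {
      repeat {
        x <- ax + stats::runif(n, -r, r)
        y <- ay + stats::runif(n, -r, r)
        d <- foa_decode(x, y)
        if (all(d$dist > 0)) return(list(x = x, y = y, s = d$s))
      }
    }
    ax <- stats::runif(n, init_lower, init_upper)
    ay <- stats::runif(n, init_lower, init_upper)
    best_fit <- NULL
    best_sol <- NULL
    best_pos <- NULL
    traj <- numeric(config$max_iterations + 1L)
    for (l in seq_len(config$max_iterations + 1L)) {
      flies <- lapply(seq_len(config$population_size),
                      function(i) draw_fly(ax, ay))
      fits <- vapply(flies, function(f) score(f$s), numeric(1))
      i <- if (sense == "min") which.min(fits) else which.max(fits)
      if (is.null(best_fit) || better(fits[[i]], best_fit)) {
        best_fit <- fits[[i]]
        best_sol <- flies[[i]]$s
        best_pos <- list(x = flies[[i]]$x, y = flies[[i]]$y)
        ax <- flies[[i]]$x
        ay <- flies[[i]]$y
      }
      traj[l] <- best_fit
    }
    structure(
      list(
        best_fitness = best_fit,
        best_solution = best_sol,
        best_position = best_pos,
        best_fitness_per_iteration = traj,
        evaluations = n_eval,
        seed = config$seed,
        method = "foa"
      ),
      class = "optimization_result"
    )
  })
}
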