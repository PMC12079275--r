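#' Gray-Scott model parameters
#'
#' Two-species reaction-diffusion kinetics
#' \deqn{\partial A/\partial t = D_A \nabla^2 A - A B^2 + F (1 - A)}
#' \deqn{\partial B/\partial t = D_B \nabla^2 B + A B^2 - (k + F) B}
#' with feed rate \eqn{F} and kill rate \eqn{k}. `gs_params()` with a
#' preparation name returns the published parameter sets inferred from
#' capacitance measurements of actin, proteinoid and their mixture (all share
#' kill rate k = 0.0600).
#'
#' @param d_a,d_b Diffusion coefficients (grid units; must be below 0.25 for
#'   stability of the explicit scheme at dt = 1).
#' @param feed Feed rate F.
#' @param kill Kill rate k.
#' @param compound Instead of explicit values, one of `"actin"`,
#'   `"proteinoid"`, `"mixture"`.
#' @return A `gs_params` list.
#' @examples
#' gs_params(compound = "actin")
#' @export
gs_params <- function(d_a = 0.1592, d_b = 0.0604, feed = 0.0202, kill = 0.0600,
                      compound = NULL) {
  if (!is.null(compound)) {
    compound <- match.arg(compound, c("actin", "proteinoid", "mixture"))
    vals <- switch(compound,
      actin      = list(d_a = 0.1592, d_b = 0.0604, feed = 0.0202, kill = 0.0600),
      proteinoid = list(d_a = 0.1548, d_b = 0.0618, feed = 0.0209, kill = 0.0600),
      mixture    = list(d_a = 0.1582, d_b = 0.0606, feed = 0.0203, kill = 0.0600)
    )
    d_a <- vals$d_a; d_b <- vals$d_b; feed <- vals$feed; kill <- vals$kill
  }
  for (v in list(d_a = d_a, d_b = d_b, feed = feed, kill = kill)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort("Gray-Scott parameters must be non-negative finite numbers.",
            class = "protoelec_invalid_spec")
    }
  }
  if (d_a > 0.25 || d_b > 0.25) {
    abort("diffusion coefficients above 0.25 are unstable at dt = 1.",
          class = "protoelec_invalid_spec")
  }
  structure(list(d_a = d_a, d_b = d_b, feed = feed, kill = kill),
            class = "gs_params")
}

#' Initialise a Gray-Scott state
#'
#' The activator field A is set to 1 everywhere; the substrate B is 1 inside
#' a small central square (side `2 * seed_region_half_width + 1`) and 0
#' elsewhere. Optional uniform noise of amplitude `noise_amp` is added to
#' both fields to break symmetry.
#'
#' @param grid_size Side of the square grid (default 100).
#' @param seed_region_half_width Half-width of the central seeded square.
#' @param noise_amp Uniform noise amplitude (0 = deterministic).
#' @param seed RNG seed for the noise.
#' @return A `gs_state`: list with matrices `a`, `b` and `step_count`.
#' @export
gs_init <- function(grid_size = 100, seed_region_half_width = 5,
                    noise_amp = 0, seed = 1L) {
  if (grid_size < 3) {
    abort("grid_size must be at least 3.", class = "protoelec_invalid_spec")
  }
  if (2 * seed_region_half_width + 1 > grid_size) {
    abort("seed region does not fit inside the grid.",
          class = "protoelec_invalid_spec")
  }
  a <- matrix(1, grid_size, grid_size)
  b <- matrix(0, grid_size, grid_size)
  c0 <- ceiling(grid_size / 2)
  idx <- (c0 - seed_region_half_width):(c0 + seed_region_half_width)
  b[idx, idx] <- 1
  if (noise_amp > 0) {
    with_seed(seed, {
      a <- a + noise_amp * matrix(runif(grid_size^2), grid_size)
      b <- b + noise_amp * matrix(runif(grid_size^2), grid_size)
    })
  }
  structure(list(a = a, b = b, step_count = 0L), class = "gs_state")
}

# 5-point Laplacian with periodic (torus) boundaries.
laplacian_periodic <- function(m) {
  n <- nrow(m)
  up <- m[c(2:n, 1), , drop = FALSE]
  down <- m[c(n, 1:(n - 1)), , drop = FALSE]
  left <- m[, c(2:ncol(m), 1), drop = FALSE]
  right <- m[, c(ncol(m), 1:(ncol(m) - 1)), drop = FALSE]
  up + down + left + right - 4 * m
}

#' Advance a Gray-Scott state by one explicit Euler step
#'
#' @param state A `gs_state` from [gs_init()].
#' @param params A [gs_params()].
#' @param dt Time step (default 1 grid-time unit).
#' @return The updated `gs_state`.
#' @export
gs_step <- function(state, params, dt = 1.0) {
  a <- state$a
  b <- state$b
  rxn <- a * b^2
  a2 <- a + dt * (params$d_a * laplacian_periodic(a) - rxn + params$feed * (1 - a))
  b2 <- b + dt * (params$d_b * laplacian_periodic(b) + rxn - (params$kill + params$feed) * b)
  if (any(!is.finite(a2)) || any(!is.finite(b2))) {
    abort(sprintf(
      "Gray-Scott step diverged (d_a=%.4g, d_b=%.4g, F=%.4g, k=%.4g, dt=%.3g).",
      params$d_a, params$d_b, params$feed, params$kill, dt),
      class = "protoelec_instability")
  }
  state$a <- a2
  state$b <- b2
  state$step_count <- state$step_count + 1L
  state
}

#' Run a Gray-Scott simulation
#'
#' Repeated application of [gs_step()], optionally with a per-step parameter
#' schedule (see [modulate_params()]) and optional intermediate snapshots.
#'
#' @param params A [gs_params()] or a parameter schedule tibble from
#'   [modulate_params()] (one row per step).
#' @param n_steps Number of steps (default 5000).
#' @param dt Time step.
#' @param init A `gs_state`, or NULL to call [gs_init()] with `...`.
#' @param snapshot_every If positive, keep a copy of the state every that
#'   many steps (returned as the `snapshots` attribute).
#' @param ... Passed to [gs_init()] when `init` is NULL.
#' @return Final `gs_state`.
#' @examples
#' st <- gs_simulate(gs_params(compound = "actin"), n_steps = 200,
#'                   grid_size = 50)
#' pattern_metrics(st)
#' @export
gs_simulate <- function(params, n_steps = 5000, dt = 1.0, init = NULL,
                        snapshot_every = 0, ...) {
  if (n_steps < 1) {
    abort("n_steps must be at least 1.", class = "protoelec_invalid_spec")
  }
  state <- init %||% gs_init(...)
  schedule <- NULL
  if (is.data.frame(params)) {
    schedule <- params
    if (nrow(schedule) != n_steps) {
      # resample the schedule to the requested number of steps
      idx <- round(seq(1, nrow(schedule), length.out = n_steps))
      schedule <- schedule[idx, , drop = FALSE]
    }
  }
  snaps <- list()
  for (i in seq_len(n_steps)) {
    p <- if (is.null(schedule)) params else
      gs_params(schedule$d_a[i], schedule$d_b[i], schedule$feed[i], schedule$kill[i])
    state <- gs_step(state, p, dt = dt)
    if (snapshot_every > 0 && i %% snapshot_every == 0) {
      snaps[[length(snaps) + 1]] <- state
    }
  }
  if (snapshot_every > 0) attr(state, "snapshots") <- snaps
  state
}

#' Capacitance-driven Gray-Scott parameter schedule
#'
#' Maps a measured (or synthetic) capacitance series onto a per-step
#' parameter schedule: diffusion coefficients and the feed rate are scaled by
#' the relative capacitance fluctuation,
#' \deqn{p_t = p_{base} \left(1 + \beta \frac{C_t - \bar C}{\bar C}\right)}
#' for \eqn{p \in \{D_A, D_B, F\}}, while the kill rate is held fixed
#' (consistent kill rate across all conditions). The schedule is resampled to
#' `n_steps` by nearest-index interpolation.
#'
#' @param base A [gs_params()].
#' @param capacitance Positive numeric series (any units; only relative
#'   fluctuations matter), or a tibble with a capacitance column (last
#'   column used).
#' @param beta Coupling gain (default 0.5).
#' @param n_steps Length of the schedule.
#' @return Tibble with columns `step`, `d_a`, `d_b`, `feed`, `kill`.
#' @export
modulate_params <- function(base, capacitance, beta = 0.5, n_steps = 5000) {
  if (is.data.frame(capacitance)) {
    capacitance <- capacitance[[ncol(capacitance)]]
  }
  if (any(!is.finite(capacitance)) || any(capacitance <= 0)) {
    abort("capacitance must be positive and finite.",
          class = "protoelec_domain_error")
  }
  rel <- (capacitance - mean(capacitance)) / mean(capacitance)
  idx <- round(seq(1, length(rel), length.out = n_steps))
  scale <- 1 + beta * rel[idx]
  sched <- tibble(
    step = seq_len(n_steps),
    d_a = base$d_a * scale,
    d_b = base$d_b * scale,
    feed = base$feed * scale,
    kill = base$kill
  )
  if (any(sched$d_a < 0) || any(sched$d_b < 0) || any(sched$feed < 0) ||
      any(sched$d_a > 0.25) || any(sched$d_b > 0.25)) {
    abort("beta drives a parameter negative or past the stability bound.",
          class = "protoelec_invalid_spec")
  }
  sched
}

#' Summary metrics of a Gray-Scott pattern
#'
#' @param state A `gs_state`.
#' @return One-row tibble with `spatial_sd_b` (sd of B over cells),
#'   `spot_count` (connected components, 4-connectivity, of cells with
#'   B above mean(B) + sd(B)), and `mean_b`.
#' @export
pattern_metrics <- function(state) {
  b <- state$b
  if (any(!is.finite(b))) {
    abort("state contains non-finite values.", class = "protoelec_instability")
  }
  s <- sd(as.vector(b))
  thr <- mean(b) + s
  mask <- b > thr
  tibble(spatial_sd_b = s,
         spot_count = count_components(mask),
         mean_b = mean(b))
}

# Connected components of a logical matrix under 4-connectivity (non-periodic
# for counting purposes), via iterative flood fill with an explicit stack.
count_components <- function(mask) {
  if (!any(mask)) return(0L)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- comp
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          k <- (nb[2] - 1L) * nr + nb[1]
          if (mask[k] && lab[k] == 0L) stack <- c(stack, k)
        }
      }
    }
  }
  comp
}

#' @export
print.gs_state <- function(x, ...) {
  cat(sprintf("<gs_state: %dx%d grid, %d steps, mean B = %.4f>\n",
              nrow(x$b), ncol(x$b), x$step_count, mean(x$b)))
  invisible(x)
}

#' Plot the substrate field of a Gray-Scott state
#'
#' @param object A `gs_state`.
#' @param field `"b"` (default) or `"a"`.
#' @param ... Unused.
#' @return A ggplot raster of the chosen concentration field.
#' @method autoplot gs_state
#' @export
autoplot.gs_state <- function(object, field = c("b", "a"), ...) {
  field <- match.arg(field)
  m <- object[[field]]
  df <- tibble(x = rep(seq_len(nrow(m)), times = ncol(m)),
               y = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = toupper(field)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
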