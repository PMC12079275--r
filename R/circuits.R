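#' Impedance circuit elements
#'
#' Constructors for the passive elements used in equivalent-circuit models of
#' electrochemical impedance spectra: resistor, capacitor, inductor,
#' constant-phase element (CPE), semi-infinite Warburg element, and the
#' finite-length ("O") diffusion element.
#'
#' Element impedances at angular frequency \eqn{\omega} (rad/s):
#' \describe{
#'   \item{resistor}{\eqn{Z = R}}
#'   \item{capacitor}{\eqn{Z = 1/(j\omega C)}}
#'   \item{inductor}{\eqn{Z = j\omega L}}
#'   \item{cpe}{\eqn{Z = 1/(Q (j\omega)^n)}, \eqn{n \in [0,1]}; a pure
#'     resistor of value \eqn{1/Q} at \eqn{n = 0} and a pure capacitor
#'     \eqn{C = Q} at \eqn{n = 1}}
#'   \item{warburg}{semi-infinite diffusion,
#'     \eqn{Z = W (1 - j)/\sqrt{2\omega} \equiv W/\sqrt{j\omega}}, with the
#'     coefficient \eqn{W} in \eqn{\Omega\,s^{-1/2}}}
#'   \item{o_element}{finite-length open diffusion,
#'     \eqn{Z = \coth(B\sqrt{j\omega}) / (Y_0 \sqrt{j\omega})} with admittance
#'     coefficient \eqn{Y_0} (\eqn{S\,s^{1/2}}) and characteristic diffusion
#'     parameter \eqn{B} (\eqn{s^{1/2}}); set `form = "tanh"` for the
#'     short-circuit (bounded) variant}
#' }
#'
#' @param r,c,l,q,n,w,y0,b Element parameter values (SI units: ohm, farad,
#'   henry; `q` in S s^n; `w` in ohm s^-1/2; `y0` in S s^1/2; `b` in s^1/2).
#' @param form For `elem_o()`, `"coth"` (open boundary, default) or `"tanh"`.
#' @return A `circuit_element` object.
#' @examples
#' elem_cpe(q = 1.13e-4, n = 0.489)
#' element_impedance(elem_capacitor(1), omega = 1) # 0 - 1i
#' @name circuit_elements
NULL

new_element <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "circuit_element")
}

#' @rdname circuit_elements
#' @export
elem_resistor <- function(r) {
  check_positive(r, "r")
  new_element("resistor", list(r = r))
}

#' @rdname circuit_elements
#' @export
elem_capacitor <- function(c) {
  check_positive(c, "c")
  new_element("capacitor", list(c = c))
}

#' @rdname circuit_elements
#' @export
elem_inductor <- function(l) {
  check_positive(l, "l")
  new_element("inductor", list(l = l))
}

#' @rdname circuit_elements
#' @export
elem_cpe <- function(q, n) {
  check_positive(q, "q")
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n > 1) {
    abort("CPE exponent `n` must lie in [0, 1].",
          class = "protoelec_invalid_spec")
  }
  new_element("cpe", list(q = q, n = n))
}

#' @rdname circuit_elements
#' @export
elem_warburg <- function(w) {
  check_positive(w, "w")
  new_element("warburg", list(w = w))
}

#' @rdname circuit_elements
#' @export
elem_o <- function(y0, b, form = c("coth", "tanh")) {
  check_positive(y0, "y0")
  check_positive(b, "b")
  form <- match.arg(form)
  new_element("o_element", list(y0 = y0, b = b, form = form))
}

#' @export
print.circuit_element <- function(x, ...) {
  p <- paste(sprintf("%s = %.6g", names(x$params)[!vapply(x$params, is.character, TRUE)],
                     unlist(x$params[!vapply(x$params, is.character, TRUE)])),
             collapse = ", ")
  cat(sprintf("<%s: %s>\n", x$kind, p))
  invisible(x)
}

#' Impedance of a single circuit element
#'
#' @param element A [circuit_element][circuit_elements].
#' @param omega Angular frequencies in rad/s, all positive.
#' @return Complex impedance in ohm, one value per `omega`.
#' @export
element_impedance <- function(element, omega) {
  if (!inherits(element, "circuit_element")) {
    abort("`element` must be a circuit_element.", class = "protoelec_invalid_spec")
  }
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    abort("`omega` must be positive and finite.", class = "protoelec_domain_error")
  }
  p <- element$params
  jw <- complex(real = 0, imaginary = omega)
  switch(element$kind,
    resistor  = rep(complex(real = p$r), length(omega)),
    capacitor = 1 / (jw * p$c),
    inductor  = jw * p$l,
    cpe       = 1 / (p$q * jw^p$n),
    warburg   = p$w / sqrt(jw),
    o_element = {
      s <- sqrt(jw)
      ratio <- if (p$form == "coth") 1 / tanh(p$b * s) else tanh(p$b * s)
      ratio / (p$y0 * s)
    },
    abort(sprintf("unknown element kind '%s'", element$kind),
          class = "protoelec_invalid_spec")
  )
}

#' Equivalent-circuit models
#'
#' A circuit model is a series chain of nodes; each node is either a single
#' element or a parallel group of two or more nodes. `circuit_model()` builds
#' one from nodes, `parallel()` groups nodes in parallel.
#'
#' @param ... Nodes: `circuit_element`s or `parallel()` groups.
#' @param name Optional model name.
#' @return A `circuit_model` (for `circuit_model()`) or a parallel group node.
#' @examples
#' m <- circuit_model(
#'   parallel(elem_resistor(74.79), elem_capacitor(6.983e-5)),
#'   parallel(elem_resistor(835.1), elem_cpe(1.13e-4, 0.489)),
#'   elem_resistor(143.3),
#'   name = "actin"
#' )
#' circuit_impedance(m, frequencies = c(0.01, 1, 100))
#' @export
circuit_model <- function(..., name = "") {
  nodes <- list(...)
  if (length(nodes) == 0) {
    abort("a circuit model needs at least one node.",
          class = "protoelec_invalid_model")
  }
  ok <- vapply(nodes, function(n) inherits(n, c("circuit_element", "circuit_parallel")),
               logical(1))
  if (!all(ok)) {
    abort("circuit nodes must be elements or parallel() groups.",
          class = "protoelec_invalid_model")
  }
  structure(list(nodes = nodes, name = name), class = "circuit_model")
}

#' @rdname circuit_model
#' @export
parallel <- function(...) {
  children <- list(...)
  if (length(children) < 2) {
    abort("parallel() needs at least two children.",
          class = "protoelec_invalid_model")
  }
  structure(list(children = children), class = "circuit_parallel")
}

node_impedance <- function(node, omega) {
  if (inherits(node, "circuit_element")) {
    element_impedance(node, omega)
  } else if (inherits(node, "circuit_parallel")) {
    y <- Reduce(`+`, lapply(node$children, function(ch) 1 / node_impedance(ch, omega)))
    1 / y
  } else {
    abort("invalid circuit node.", class = "protoelec_invalid_model")
  }
}

#' @export
print.circuit_model <- function(x, ...) {
  lab <- function(node) {
    if (inherits(node, "circuit_element")) node$kind
    else paste0("(", paste(vapply(node$children, lab, ""), collapse = " || "), ")")
  }
  cat(sprintf("<circuit_model%s: %s>\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              paste(vapply(x$nodes, lab, ""), collapse = " - ")))
  invisible(x)
}

#' Impedance spectrum of a circuit model
#'
#' Series nodes add impedances; parallel groups combine by reciprocal sum of
#' admittances. Frequencies are interpreted in Hz (\eqn{\omega = 2\pi f}).
#'
#' @param model A [circuit_model()].
#' @param frequencies Frequencies in Hz, all positive.
#' @return A tibble with columns `freq_hz`, `z_real_ohm`, `z_imag_ohm`,
#'   aligned row-for-row with `frequencies`.
#' @export
circuit_impedance <- function(model, frequencies) {
  if (!inherits(model, "circuit_model") || length(model$nodes) == 0) {
    abort("`model` must be a non-empty circuit_model.",
          class = "protoelec_invalid_model")
  }
  if (length(frequencies) == 0 || any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    abort("`frequencies` must be positive and finite.",
          class = "protoelec_domain_error")
  }
  omega <- 2 * pi * frequencies
  z <- Reduce(`+`, lapply(model$nodes, node_impedance, omega = omega))
  tibble(freq_hz = frequencies, z_real_ohm = Re(z), z_imag_ohm = Im(z))
}

#' Reference equivalent circuits for the three preparations
#'
#' Builds one of the three published equivalent-circuit topologies:
#' \describe{
#'   \item{actin}{(R1 || C1) - (R2 || Q1) - R3: two relaxation arcs plus a
#'     series resistance. Parameters: `r1`, `c1`, `r2`, `q1`, `n1`, `r3`.}
#'   \item{proteinoid}{R1 - W1 - O1 - (R2 || C1): series resistance,
#'     semi-infinite Warburg, finite-length diffusion element, and a parallel
#'     RC. Parameters: `r1`, `w1`, `o1`, `b`, `r2`, `c1`. The O element is
#'     parameterised by its magnitude `o1` (ohm s^-1/2, so Y0 = 1/o1) and
#'     characteristic parameter `b` (s^1/2).}
#'   \item{mixture}{(R1 || C1) - W1 - (R2 || Q1): interfacial RC, Warburg
#'     diffusion, and a low-frequency RQ arc. Parameters: `r1`, `c1`, `w1`,
#'     `r2`, `q1`, `n1`.}
#' }
#'
#' @param name One of `"actin"`, `"proteinoid"`, `"mixture"`.
#' @param params Named list/vector of parameter values; defaults to the
#'   published fits, see [circuit_params()].
#' @param o_form Diffusion-element branch for the proteinoid circuit.
#' @return A [circuit_model()].
#' @examples
#' build_named_circuit("actin")
#' @export
build_named_circuit <- function(name = c("actin", "proteinoid", "mixture"),
                                params = circuit_params(name),
                                o_form = c("coth", "tanh")) {
  name <- match.arg(name)
  o_form <- match.arg(o_form)
  params <- as.list(params)
  required <- switch(name,
    actin      = c("r1", "c1", "r2", "q1", "n1", "r3"),
    proteinoid = c("r1", "w1", "o1", "b", "r2", "c1"),
    mixture    = c("r1", "c1", "w1", "r2", "q1", "n1")
  )
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    abort(sprintf("missing circuit parameter(s) for '%s': %s",
                  name, paste(missing, collapse = ", ")),
          class = "protoelec_invalid_spec")
  }
  p <- params
  switch(name,
    actin = circuit_model(
      parallel(elem_resistor(p$r1), elem_capacitor(p$c1)),
      parallel(elem_resistor(p$r2), elem_cpe(p$q1, p$n1)),
      elem_resistor(p$r3),
      name = "actin"
    ),
    proteinoid = circuit_model(
      elem_resistor(p$r1),
      elem_warburg(p$w1),
      elem_o(y0 = 1 / p$o1, b = p$b, form = o_form),
      parallel(elem_resistor(p$r2), elem_capacitor(p$c1)),
      name = "proteinoid"
    ),
    mixture = circuit_model(
      parallel(elem_resistor(p$r1), elem_capacitor(p$c1)),
      elem_warburg(p$w1),
      parallel(elem_resistor(p$r2), elem_cpe(p$q1, p$n1)),
      name = "mixture"
    )
  )
}

#' Published equivalent-circuit parameter sets
#'
#' Fitted parameter values reported for actin, Glu:Phe proteinoid, and their
#' mixture. Units: resistances in ohm, capacitances in farad, CPE `q1` in
#' S s^n, Warburg `w1` and O-element magnitude `o1` in ohm s^-1/2, `b` in
#' s^1/2.
#'
#' @param name One of `"actin"`, `"proteinoid"`, `"mixture"`.
#' @return Named list of parameter values.
#' @export
circuit_params <- function(name = c("actin", "proteinoid", "mixture")) {
  name <- match.arg(name)
  switch(name,
    actin = list(r1 = 74.79, c1 = 6.983e-5, r2 = 835.1,
                 q1 = 1.130e-4, n1 = 0.489, r3 = 143.3),
    proteinoid = list(r1 = 4334, w1 = 8224, o1 = 9741, b = 0.329,
                      r2 = 1068, c1 = 1.000e-12),
    mixture = list(r1 = 3694, c1 = 1e-12, w1 = 308,
                   r2 = 1.0e4, q1 = 25.97e-6, n1 = 0.632)
  )
}

# Flatten a model's free parameters to a named numeric vector and rebuild the
# model from such a vector; used by the fitter. The O-element `form` and the
# topology itself are fixed.
circuit_free_params <- function(model) {
  out <- numeric(0)
  walk <- function(node, prefix) {
    if (inherits(node, "circuit_element")) {
      p <- node$params[!vapply(node$params, is.character, logical(1))]
      nm <- paste0(prefix, node$kind, ".", names(p))
      out[nm] <<- unlist(p)
    } else {
      for (i in seq_along(node$children)) {
        walk(node$children[[i]], paste0(prefix, "p", i, "."))
      }
    }
  }
  for (i in seq_along(model$nodes)) walk(model$nodes[[i]], paste0("n", i, "."))
  out
}

circuit_set_params <- function(model, values) {
  idx <- 0
  walk <- function(node) {
    if (inherits(node, "circuit_element")) {
      free <- !vapply(node$params, is.character, logical(1))
      k <- sum(free)
      node$params[free] <- as.list(unname(values[idx + seq_len(k)]))
      idx <<- idx + k
      node
    } else {
      node$children <- lapply(node$children, walk)
      node
    }
  }
  model$nodes <- lapply(model$nodes, walk)
  stopifnot(idx == length(values))
  model
}
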