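# Independent brute-force oracles used across test files. These deliberately
# re-derive quantities with naive loops / direct formulas, independent of the
# package's implementation paths.

# Walk a circuit model tree recursively, evaluating one frequency at a time
# with scalar complex arithmetic.
oracle_circuit_z <- function(model, f_hz) {
  omega <- 2 * pi * f_hz
  eval_node <- function(node) {
    if (inherits(node, "circuit_element")) {
      p <- node$params
      switch(node$kind,
        resistor  = p$r + 0i,
        capacitor = 1 / (1i * omega * p$c),
        inductor  = 1i * omega * p$l,
        cpe       = 1 / (p$q * (1i * omega)^p$n),
        warburg   = p$w * (1 - 1i) / sqrt(2 * omega),
        o_element = {
          s <- sqrt(1i * omega)
          rat <- if (p$form == "coth") cosh(p$b * s) / sinh(p$b * s)
                 else sinh(p$b * s) / cosh(p$b * s)
          rat / (p$y0 * s)
        }
      )
    } else {
      inv <- 0 + 0i
      for (ch in node$children) inv <- inv + 1 / eval_node(ch)
      1 / inv
    }
  }
  tot <- 0 + 0i
  for (nd in model$nodes) tot <- tot + eval_node(nd)
  tot
}

# Elementwise-loop chi-squared with modulus weighting (no dof scaling).
oracle_chi_squared_raw <- function(spectrum, model) {
  s <- 0
  for (i in seq_len(nrow(spectrum))) {
    z <- oracle_circuit_z(model, spectrum$freq_hz[i])
    m2 <- spectrum$z_real_ohm[i]^2 + spectrum$z_imag_ohm[i]^2
    s <- s + ((spectrum$z_real_ohm[i] - Re(z))^2 +
              (spectrum$z_imag_ohm[i] - Im(z))^2) / m2
  }
  s
}

# All-maxima-then-filter spike detector mirroring the documented definition
# with explicit loops.
oracle_detect_count <- function(v, dt, prominence, refractory,
                                pre_n = 10, gap = 2) {
  n <- length(v)
  cand <- c()
  for (i in 2:(n - 1)) {
    j1 <- max(1, i - gap - pre_n + 1)
    j2 <- max(1, i - gap)
    if (v[i] > v[i - 1] && v[i] >= v[i + 1] &&
        (v[i] - median(v[j1:j2])) >= prominence) {
      cand <- c(cand, i)
    }
  }
  kept <- c()
  last <- -Inf
  for (i in cand) {
    if (i - last >= refractory / dt) {
      kept <- c(kept, i)
      last <- i
    }
  }
  length(kept)
}

# Textbook summation form of the Pearson correlation.
oracle_pearson <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx <- dx + (x[i] - xb)^2
    dy <- dy + (y[i] - yb)^2
  }
  num / sqrt(dx * dy)
}

# Double-loop Gray-Scott step with explicit periodic index wrapping.
oracle_gs_step <- function(a, b, p, dt = 1) {
  n <- nrow(a)
  wrap <- function(i) ((i - 1) %% n) + 1
  a2 <- a; b2 <- b
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      la <- a[wrap(i - 1), j] + a[wrap(i + 1), j] +
            a[i, wrap(j - 1)] + a[i, wrap(j + 1)] - 4 * a[i, j]
      lb <- b[wrap(i - 1), j] + b[wrap(i + 1), j] +
            b[i, wrap(j - 1)] + b[i, wrap(j + 1)] - 4 * b[i, j]
      r <- a[i, j] * b[i, j]^2
      a2[i, j] <- a[i, j] + dt * (p$d_a * la - r + p$feed * (1 - a[i, j]))
      b2[i, j] <- b[i, j] + dt * (p$d_b * lb + r - (p$kill + p$feed) * b[i, j])
    }
  }
  list(a = a2, b = b2)
}

# Recursive flood-fill component count (4-connectivity).
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  fill <- function(i, j) {
    stack <- list(c(i, j))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cur[1]; cj <- cur[2]
      if (ci < 1 || ci > nr || cj < 1 || cj > nc) next
      if (seen[ci, cj] || !mask[ci, cj]) next
      seen[ci, cj] <<- TRUE
      stack <- c(stack, list(c(ci - 1, cj), c(ci + 1, cj),
                             c(ci, cj - 1), c(ci, cj + 1)))
    }
  }
  count <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && !seen[i, j]) {
        count <- count + 1
        fill(i, j)
      }
    }
  }
  count
}

# Published parameter truth as named flat vectors matching fit_circuit terms.
true_params_flat <- function(name) {
  protoelec:::circuit_free_params(build_named_circuit(name))
}
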