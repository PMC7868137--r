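# Shared fixtures and independent oracles, all built in code.

# small deterministic raw slice with values in [0, 4096]
tiny_slice <- function(n = 8, seed = 1) {
  with_seed_local(seed, matrix(round(runif(n * n, 200, 1800)), n, n))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# square mask block helper
block_mask <- function(n, r, c, h = 2, w = 2) {
  m <- matrix(0, n, n)
  m[r:(r + h - 1), c:(c + w - 1)] <- 1
  m
}

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b)
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))

# --- independent receptive-field probe ---------------------------------------
# Forward a linear chain of all-ones kernels with the candidate geometry and,
# for every output unit, count how many whole-row (and whole-column) input
# perturbations change it. The maximum over units (those with fields fully
# interior to the input) is the receptive-field side. Independent of the
# analytic recursion.
probe_receptive_field <- function(block_specs, input_size) {
  cos_ <- function(n, k, s, p, d) (n + 2 * p - ((k - 1) * d + 1)) %/% s + 1
  fwd <- function(x, n) {
    m <- matrix(x, n * n, 1)
    h <- w <- n
    for (b in block_specs) {
      m <- ctinpaint:::im2col_cpp(m, h, w, b$kernel, b$stride, b$pad,
                                  b$dilation) %*%
        matrix(1, b$kernel^2, 1)
      h <- cos_(h, b$kernel, b$stride, b$pad, b$dilation)
      w <- cos_(w, b$kernel, b$stride, b$pad, b$dilation)
    }
    m
  }
  n <- input_size
  x0 <- matrix(0, n, n)
  f0 <- fwd(x0, n)
  # hits[u, r]: does perturbing input row r change output unit u? The field
  # side is the extent (span) of affecting rows — dilation leaves holes, so
  # extent, not count, is the measure. Units whose fields are clipped at the
  # border span less; the maximum over units is the true side.
  span <- function(hits) {
    max(apply(hits, 1, function(h) {
      w <- which(h)
      if (length(w) == 0) 0L else max(w) - min(w) + 1L
    }))
  }
  row_hits <- t(vapply(seq_len(n), function(r) {
    x <- x0; x[r, ] <- 1
    as.vector(fwd(x, n) != f0)
  }, logical(length(f0))))
  col_hits <- t(vapply(seq_len(n), function(cc) {
    x <- x0; x[, cc] <- 1
    as.vector(fwd(x, n) != f0)
  }, logical(length(f0))))
  c(rows = span(t(row_hits)), cols = span(t(col_hits)))
}

# random six-block geometry plus an input size large enough that some output
# unit's field is fully interior
random_disc_specs <- function() {
  repeat {
    specs <- lapply(1:6, function(i) list(
      kernel = sample(1:5, 1), stride = sample(1:2, 1),
      pad = sample(0:2, 1), channels = 2L,
      activation = if (i < 6) "relu" else "sigmoid",
      batchnorm = FALSE, dilation = sample(1:2, 1)))
    rf <- 1; jump <- 1
    for (b in specs) {
      rf <- rf + ((b$kernel - 1) * b$dilation) * jump
      jump <- jump * b$stride
    }
    if (rf > 100) next
    n <- 2 * rf + 65
    ok <- TRUE
    s <- n
    for (b in specs) {
      s <- (s + 2 * b$pad - ((b$kernel - 1) * b$dilation + 1)) %/% b$stride + 1
      if (s < 1) { ok <- FALSE; break }
    }
    if (ok) return(list(specs = specs, probe_size = n))
  }
}

# --- independent dihedral-group enumeration ----------------------------------
# All 8 orientations of a matrix, generated by transpose and column reversal
# (a different primitive pair than the implementation uses).
dihedral_orbit <- function(m) {
  out <- list()
  x <- m
  for (i in 1:4) {
    out <- c(out, list(x), list(x[, rev(seq_len(ncol(x))), drop = FALSE]))
    x <- t(x)[, rev(seq_len(nrow(x))), drop = FALSE]  # not used as the impl path
  }
  unique(out)
}
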