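# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_validation <- function(msg, field = NULL) {
  cls <- c("glioseg_validation_error", "glioseg_error")
  cond <- structure(
    class = c(cls, "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  )
  stop(cond)
}

check_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_validation(sprintf("'%s' must be a finite number in [%s, %s]",
                            name, format(min), format(max)), field = name)
  }
  invisible(as.numeric(x))
}

softplus <- function(x) {
  # log(1 + exp(x)) computed stably for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

inv_softplus <- function(y) {
  # inverse of softplus for y > 0
  y + log(-expm1(-y))
}

# Channel-wise softmax of a (C, X, Y, Z) logit array; returns same shape.
channel_softmax <- function(z) {
  d <- dim(z)
  m <- matrix(z, nrow = d[1L])
  mx <- do.call(pmax, lapply(seq_len(d[1L]), function(i) m[i, ]))
  e <- exp(sweep(m, 2L, mx, "-"))
  p <- sweep(e, 2L, colSums(e), "/")
  array(p, dim = d)
}

# Argmax over the channel dimension; ties broken by lowest class index.
# Returns a 3D integer array of 0-based class ids.
channel_argmax <- function(p) {
  d <- dim(p)
  m <- matrix(p, nrow = d[1L])
  idx <- max.col(t(m), ties.method = "first") - 1L
  array(as.integer(idx), dim = d[-1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
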