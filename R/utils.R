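# Internal helpers shared across modules.

# Classed conditions so callers can distinguish format/data/config failures.
hr_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "hr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

hr_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) hr_error(class, msg, ...)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centred moving average with edge replication; window forced odd so the
# smoother is symmetric (no time bias at phase boundaries).
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window == 1L || n < 2L) return(as.numeric(x))
  half <- window %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  sm <- stats::filter(xp, rep(1 / window, window), sides = 2)
  as.numeric(sm)[(half + 1L):(half + n)]
}

# Central-difference gradient, one-sided at the ends.
central_gradient <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1L] <- (x[2L] - x[1L]) / dt
  g[n] <- (x[n] - x[n - 1L]) / dt
  if (n > 2L) g[2L:(n - 1L)] <- (x[3L:n] - x[1L:(n - 2L)]) / (2 * dt)
  g
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Index of the sample nearest to time t (nearest-sample boundary mapping).
nearest_index <- function(time, t) {
  vapply(t, function(ti) which.min(abs(time - ti)), integer(1))
}

is_strictly_increasing <- function(x) all(diff(x) > 0)

# Run set.seed() without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
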