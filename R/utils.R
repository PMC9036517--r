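# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derived per-replica / per-frame seed streams: fixed offsets from a master
# seed, kept inside 32-bit integer range.
derive_seed <- function(master, stream, index) {
  offsets <- c(frame = 104729L, replica = 7919L, misc = 15485863L)
  as.integer((as.numeric(master) + offsets[[stream]] * index) %% 2147483647)
}

# Periodic wrap of coordinates into [0, L).
wrap_pbc <- function(x, L) {
  x - L * floor(x / L)
}

# Minimum-image separation along one axis.
min_image <- function(dx, L) {
  dx - L * round(dx / L)
}

# Trapezoidal integral.
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
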