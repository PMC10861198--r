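# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed, kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 2654435761) %% 2147483647
}

assert_scalar_num <- function(x, name, min = -Inf, max = Inf,
                              strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < min || (strict_min && x <= min) || x > max)
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}

# Min-max scale a vector to [0, 1]; constant input maps to 0.
minmax01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[2] <= r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

msg <- function(...) message("[tissuemorph] ", sprintf(...))

# Pixel-centre coordinates in micrometres (origin lower-left, y up).
px_to_um_x <- function(col, pixel_size) (col - 0.5) * pixel_size
px_to_um_y <- function(row, nrow_img, pixel_size) {
  (nrow_img - row + 0.5) * pixel_size
}
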