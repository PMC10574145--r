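# Internal helpers.

# Set the RNG seed locally, returning the previous .Random.seed (or NULL)
# so callers can restore it and leave the global RNG stream untouched.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Euclidean norm of a 3-vector / rows of a matrix.
vec_norm <- function(v) sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))

unit_vec <- function(v) v / vec_norm(v)

# A uniformly random unit 3-vector.
random_unit_vec <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vec_norm(v)
    if (n > 1e-12) return(v / n)
  }
}
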