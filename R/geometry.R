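# Small 3D geometry helpers used by the builder and analysis code.

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

# Apply a 3x3 rotation to an n x 3 coordinate matrix.
rot_apply <- function(R, xyz) t(R %*% t(xyz))

vec_norm <- function(v) sqrt(sum(v^2))

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
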