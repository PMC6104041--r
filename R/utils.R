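# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do not
#' disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647L)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angular difference into (-180, 180] degrees.
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Rotate 2-column coordinates counterclockwise by `angle` degrees.
rotate_xy <- function(xy, angle) {
  a <- deg2rad(angle)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  xy <- as.matrix(xy)
  out <- xy %*% t(R)
  colnames(out) <- c("x", "y")
  out
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
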