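# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards. Every stochastic step in the package goes
# through this, so identical seeds give identical results regardless of what
# the surrounding session has done with the RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    },
    add = TRUE
  )
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a cell table / data frame / matrix to an n x 2 coordinate matrix (um).
as_xy <- function(x) {
  if (inherits(x, "cell_table") || is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x))) {
      stop("expected columns `x` and `y`", call. = FALSE)
    }
    return(cbind(x = as.numeric(x$x), y = as.numeric(x$y)))
  }
  m <- as.matrix(x)
  if (ncol(m) != 2L) stop("expected a two-column coordinate matrix", call. = FALSE)
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

# Squared Euclidean distances between the rows of `a` (n x 2) and `b` (m x 2).
pairwise_sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
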