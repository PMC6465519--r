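#' @importFrom stats rnorm runif qnorm pnorm median sd rnbinom rpois rlnorm
#'   lm lm.fit coef pf pt pchisq AIC cooks.distance chisq.test t.test cor
#'   model.matrix terms as.formula complete.cases setNames
NULL

# Deterministic 32-bit seed derived from a base seed and arbitrary tokens
# (subject ids, stage names).  Kept below 2^31 - 1.
deriveSeed <- function(seed, ...) {
  tokens <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(tokens)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Truncated-normal sampler by inverse-CDF; vectorised.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

# Lognormal parameters matched to a target arithmetic mean and SD.
lognormalMoments <- function(m, s) {
  stopifnot(m > 0, s >= 0)
  if (s == 0) return(c(meanlog = log(m), sdlog = 0))
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Median over a logical mask; errors on empty selection.
maskedMedian <- function(values, mask) {
  v <- values[mask]
  if (length(v) == 0L) stop("empty region: no voxels under mask")
  median(v)
}

.gridCache <- new.env(parent = emptyenv())

gridCoords <- function(dim) {
  # normalised voxel-centre coordinates in [-1, 1] per axis, full grid;
  # memoised per grid shape (pure function of dim)
  key <- paste0("co", paste(dim, collapse = "x"))
  if (!is.null(.gridCache[[key]])) return(.gridCache[[key]])
  ax <- lapply(dim, function(d) {
    if (d == 1L) 0 else seq(-1, 1, length.out = d)
  })
  out <- list(
    x = array(rep(ax[[1]], times = dim[2] * dim[3]), dim = dim),
    y = array(rep(rep(ax[[2]], each = dim[1]), times = dim[3]), dim = dim),
    z = array(rep(ax[[3]], each = dim[1] * dim[2]), dim = dim)
  )
  .gridCache[[key]] <- out
  out
}

fullGridBasis <- function(dim, degree) {
  key <- paste0("pb", paste(dim, collapse = "x"), "d", degree)
  if (!is.null(.gridCache[[key]])) return(.gridCache[[key]])
  co <- gridCoords(dim)
  out <- polyBasis3D(as.vector(co$x), as.vector(co$y), as.vector(co$z), degree)
  .gridCache[[key]] <- out
  out
}

# 3D polynomial basis of given total degree evaluated at coordinate vectors.
polyBasis3D <- function(x, y, z, degree) {
  stopifnot(degree %in% 1:3)
  cols <- list(rep(1, length(x)))
  nm <- "1"
  for (d in 1:degree) {
    for (i in 0:d) for (j in 0:(d - i)) {
      k <- d - i - j
      cols[[length(cols) + 1L]] <- x^i * y^j * z^k
      nm <- c(nm, paste0("x", i, "y", j, "z", k))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}
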