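# Internal helpers: typed error conditions, geometry utilities, RNG scoping.

.stopCond <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fqError")))
}

.stopValidation <- function(msg) .stopCond("fqValidationError", msg)
.stopFormat     <- function(msg) .stopCond("fqFormatError", msg)
.stopIO         <- function(msg) .stopCond("fqIOError", msg)
.stopEmptySection <- function(msg) .stopCond("fqEmptySectionError", msg)
.stopEmptyMap     <- function(msg) .stopCond("fqEmptyMapError", msg)

.assertScalarNum <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopValidation(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    .stopValidation(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Disc mask painting: returns matrix index (i, j) pairs of disc pixels
# clipped to an H x W canvas.
.discIndices <- function(ci, cj, r, H, W) {
  i0 <- max(1L, floor(ci - r)); i1 <- min(H, ceiling(ci + r))
  j0 <- max(1L, floor(cj - r)); j1 <- min(W, ceiling(cj + r))
  if (i0 > i1 || j0 > j1) return(cbind(integer(0), integer(0)))
  ii <- i0:i1; jj <- j0:j1
  di <- (ii - ci)^2
  dj <- (jj - cj)^2
  keep <- outer(di, dj, "+") <= r^2
  cbind(rep(ii, times = length(jj))[keep],
        rep(jj, each = length(ii))[keep])
}

# Rotated-ellipse mask (collagen bundles): semi-axes a >= b, angle theta.
.ellipseIndices <- function(ci, cj, a, b, theta, H, W) {
  r <- max(a, b)
  i0 <- max(1L, floor(ci - r)); i1 <- min(H, ceiling(ci + r))
  j0 <- max(1L, floor(cj - r)); j1 <- min(W, ceiling(cj + r))
  if (i0 > i1 || j0 > j1) return(cbind(integer(0), integer(0)))
  ii <- i0:i1; jj <- j0:j1
  x <- outer(ii - ci, rep(1, length(jj)))
  y <- outer(rep(1, length(ii)), jj - cj)
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(rep(ii, times = length(jj))[keep],
        rep(jj, each = length(ii))[keep])
}

# EBImage binary-morphology wrappers on logical matrices.
.binClose <- function(m, radius) {
  if (radius <= 0) return(m)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  as.matrix(EBImage::closing(m * 1, k)) > 0.5
}

.binDilate <- function(m, radius) {
  if (radius <= 0) return(m)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  as.matrix(EBImage::dilate(m * 1, k)) > 0.5
}

.fillHoles <- function(m) {
  as.matrix(EBImage::fillHull(m * 1)) > 0.5
}

# Connected components (8-connectivity) of a logical matrix.
.labelComponents <- function(m) {
  lab <- as.matrix(EBImage::bwlabel(m * 1))
  storage.mode(lab) <- "integer"
  lab
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    blk <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}
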