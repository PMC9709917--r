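# HEALPix nested pixelization of the sphere.
#
# Implemented from the canonical HEALPix algorithms (Gorski et al. scheme):
# the sphere is partitioned into 12 base rhombi, each subdivided into
# n_side^2 equal-area pixels; nested ordering interleaves the in-face (x, y)
# bits so that the four children of pixel p at resolution n_side are pixels
# 4p..4p+3 at resolution 2*n_side.

JRLL <- c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L)
JPLL <- c(1L, 3L, 5L, 7L, 0L, 2L, 4L, 6L, 1L, 3L, 5L, 7L)

is_power_of_two <- function(n) {
  n >= 1 && abs(log2(n) - round(log2(n))) < 1e-12
}

# de-interleave even/odd bits of x (vectorized); returns list(ix, iy)
deinterleave_bits <- function(x, nbits) {
  ix <- numeric(length(x))
  iy <- numeric(length(x))
  for (b in seq_len(nbits) - 1L) {
    ix <- ix + (x %/% 4^b %% 2) * 2^b
    iy <- iy + (x %/% (2 * 4^b) %% 2) * 2^b
  }
  list(ix = ix, iy = iy)
}

interleave_bits <- function(ix, iy, nbits) {
  p <- numeric(length(ix))
  for (b in seq_len(nbits) - 1L) {
    p <- p + (ix %/% 2^b %% 2) * 4^b + (iy %/% 2^b %% 2) * (2 * 4^b)
  }
  p
}

# nested pixel index -> (z, phi), vectorized over pix (0-based indices)
healpix_pix2ang <- function(n_side, pix) {
  face <- pix %/% (n_side^2)
  within <- pix %% (n_side^2)
  nbits <- max(1L, as.integer(round(log2(n_side))))
  xy <- deinterleave_bits(within, nbits)
  ix <- xy$ix
  iy <- xy$iy

  jr <- JRLL[face + 1L] * n_side - ix - iy - 1

  nr <- numeric(length(pix))
  z <- numeric(length(pix))
  kshift <- numeric(length(pix))

  north <- jr < n_side
  eq <- jr >= n_side & jr <= 3 * n_side
  south <- jr > 3 * n_side

  nr[north] <- jr[north]
  z[north] <- 1 - nr[north]^2 / (3 * n_side^2)
  kshift[north] <- 0

  nr[eq] <- n_side
  z[eq] <- (2 * n_side - jr[eq]) * 2 / (3 * n_side)
  kshift[eq] <- (jr[eq] - n_side) %% 2

  nr[south] <- 4 * n_side - jr[south]
  z[south] <- -1 + nr[south]^2 / (3 * n_side^2)
  kshift[south] <- 0

  jp <- (JPLL[face + 1L] * nr + ix - iy + 1 + kshift) %/% 2
  jp <- ifelse(jp > 4 * nr, jp - 4 * nr, jp)
  jp <- ifelse(jp < 1, jp + 4 * nr, jp)

  phi <- (jp - (kshift + 1) * 0.5) * (pi / (2 * nr))
  list(z = z, phi = phi)
}

# unit vectors (z, phi) -> nested pixel index (0-based), vectorized
healpix_ang2pix <- function(n_side, z, phi) {
  phi <- phi %% (2 * pi)
  za <- abs(z)
  tt <- (phi / (pi / 2)) %% 4
  n <- length(z)
  face <- integer(n)
  ix <- numeric(n)
  iy <- numeric(n)

  eq <- za <= 2 / 3
  if (any(eq)) {
    temp1 <- n_side * (0.5 + tt[eq])
    temp2 <- n_side * (z[eq] * 0.75)
    jp <- floor(temp1 - temp2)
    jm <- floor(temp1 + temp2)
    ifp <- jp %/% n_side
    ifm <- jm %/% n_side
    f <- ifelse(ifp == ifm, ifp %% 4 + 4,
      ifelse(ifp < ifm, ifp %% 4, ifm %% 4 + 8))
    face[eq] <- f
    ix[eq] <- jm %% n_side
    iy[eq] <- n_side - jp %% n_side - 1
  }
  pol <- !eq
  if (any(pol)) {
    ntt <- pmin(floor(tt[pol]), 3)
    tp <- tt[pol] - ntt
    tmp <- n_side * sqrt(3 * (1 - za[pol]))
    jp <- pmin(floor(tp * tmp), n_side - 1)
    jm <- pmin(floor((1 - tp) * tmp), n_side - 1)
    zs <- z[pol] >= 0
    face[pol] <- ifelse(zs, ntt, ntt + 8)
    ix[pol] <- ifelse(zs, n_side - jm - 1, jp)
    iy[pol] <- ifelse(zs, n_side - jp - 1, jm)
  }
  nbits <- max(1L, as.integer(round(log2(n_side))))
  face * n_side^2 + interleave_bits(ix, iy, nbits)
}

#' HEALPix pixel grid
#'
#' Builds the nested-ordered HEALPix sampling of the unit sphere at
#' resolution `n_side`. The grid has `12 * n_side^2` equal-area pixels;
#' nested ordering places the four children of pixel `p` at resolution
#' `n_side` at indices `4p..4p+3` at resolution `2 * n_side`, which is what
#' makes 4:1 hierarchical pooling a contiguous-block operation.
#'
#' @param n_side Resolution parameter; must be a power of two.
#' @return An object of class `pixel_grid`: a list with `n_side`, `n_pix`,
#'   `vec` (an `n_pix x 3` matrix of pixel-center unit vectors) and
#'   `ordering = "nested"`.
#' @examples
#' g <- healpix_grid(4)
#' g$n_pix  # 192
#' @export
healpix_grid <- function(n_side) {
  if (length(n_side) != 1 || !is.finite(n_side) || !is_power_of_two(n_side)) {
    stop("n_side must be a power of two")
  }
  n_side <- as.integer(n_side)
  n_pix <- 12L * n_side^2
  ang <- healpix_pix2ang(n_side, seq_len(n_pix) - 1)
  st <- sqrt(pmax(0, 1 - ang$z^2))
  vec <- cbind(st * cos(ang$phi), st * sin(ang$phi), ang$z)
  structure(
    list(n_side = n_side, n_pix = n_pix, vec = vec, ordering = "nested"),
    class = "pixel_grid"
  )
}

#' Nearest HEALPix pixel for unit vectors
#'
#' Maps direction vectors to the nested pixel index containing them.
#'
#' @param grid A `pixel_grid`.
#' @param vec An `n x 3` matrix of direction vectors (need not be unit).
#' @return Integer vector of 1-based pixel indices.
#' @export
healpix_lookup <- function(grid, vec) {
  stopifnot(inherits(grid, "pixel_grid"))
  vec <- rbind(vec)
  nrm <- sqrt(rowSums(vec^2))
  z <- vec[, 3] / nrm
  phi <- atan2(vec[, 2], vec[, 1])
  as.integer(healpix_ang2pix(grid$n_side, z, phi)) + 1L
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("HEALPix grid: n_side=%d, n_pix=%d, %s ordering\n",
    x$n_side, x$n_pix, x$ordering))
  invisible(x)
}
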