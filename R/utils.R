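# Internal array helpers shared across modules.

#' @useDynLib prmstrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate an expression with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# voxel index (1-based triple matrix) -> physical mm (0-based convention:
# position = (index - 1) * spacing)
vox_to_mm <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, `*`)
}

mm_to_vox <- function(mm, spacing) {
  sweep(mm, 2, spacing, `/`) + 1
}

# linear indices of TRUE voxels as an n x 3 index matrix
mask_which <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# shift a 3D array by integer voxels, padding with `fill`
shift_array <- function(a, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    b <- by[k]
    if (abs(b) >= d[k]) return(out)
    if (b >= 0) {
      src[[k]] <- seq_len(d[k] - b)
      dst[[k]] <- seq_len(d[k] - b) + b
    } else {
      src[[k]] <- seq_len(d[k] + b) - b
      dst[[k]] <- seq_len(d[k] + b)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighbourhood binary dilation / erosion (face-connected structuring element)
dilate6 <- function(mask) {
  m <- mask
  for (k in 1:3) for (s in c(-1L, 1L)) {
    by <- integer(3); by[k] <- s
    m <- m | shift_array(mask, by, FALSE)
  }
  m
}

erode6 <- function(mask) {
  m <- mask
  for (k in 1:3) for (s in c(-1L, 1L)) {
    by <- integer(3); by[k] <- s
    m <- m & shift_array(mask, by, TRUE)
  }
  # treat the volume border as background so erosion shrinks border voxels
  d <- dim(mask)
  m[c(1, d[1]), , ] <- FALSE
  m[, c(1, d[2]), ] <- FALSE
  m[, , c(1, d[3])] <- FALSE
  m
}

dilate_n <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate6(mask)
  mask
}

# one-voxel morphological closing (dilate then erode, 6-connectivity),
# without the border clearing used by erode6 (closing must not eat borders)
close1 <- function(mask) {
  d <- dilate6(mask)
  m <- d
  for (k in 1:3) for (s in c(-1L, 1L)) {
    by <- integer(3); by[k] <- s
    m <- m & shift_array(d, by, TRUE)
  }
  m | mask
}

# connected components (6-connectivity) by flood fill; returns integer labels
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  cur <- 0L
  nxy <- d[1] * d[2]
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      x <- (v - 1L) %% d[1] + 1L
      y <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      z <- (v - 1L) %/% nxy + 1L
      for (off in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                       c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
        xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
        ok <- xx >= 1L & xx <= d[1] & yy >= 1L & yy <= d[2] & zz >= 1L & zz <= d[3]
        if (!any(ok)) next
        nb <- (zz[ok] - 1L) * nxy + (yy[ok] - 1L) * d[1] + xx[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# Gaussian blur via FFT (circular boundary), sigma in voxels per axis
gauss_blur_fft <- function(a, sigma_vox) {
  d <- dim(a)
  kern <- lapply(1:3, function(k) {
    n <- d[k]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-0.5 * (x / max(sigma_vox[k], 1e-9))^2)
    g / sum(g)
  })
  K <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  dim(K) <- d
  Re(fft(fft(a) * fft(K), inverse = TRUE)) / prod(d)
}
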