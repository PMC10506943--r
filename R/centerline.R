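# Centerline extraction: the muscle mask is reduced to an ordered medial
# voxel path (erosion-depth weighted geodesic), smoothed by a per-coordinate
# polynomial fit, and densely resampled with analytic tangents. The tangent
# field is the proxy for the local muscle-fiber direction.

# erosion depth: number of successive 6-connectivity erosions a voxel survives
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  m <- mask
  i <- 0L
  while (any(m)) {
    i <- i + 1L
    depth[m] <- i
    m <- erode6(m)
  }
  depth
}

# weighted 26-neighbourhood graph over mask voxels; weights penalize
# distance from the erosion-depth ridge so shortest paths hug the middle
mask_graph <- function(mask, spacing, depth) {
  d <- dim(mask)
  node <- array(0L, d)
  lin <- which(mask)
  node[lin] <- seq_along(lin)
  dmax <- max(depth[lin])
  pen <- array(Inf, d)
  pen[lin] <- (1 + dmax - depth[lin])^3
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- apply(offs, 1, function(o) {
    w <- which(o != 0)[1]
    o[w] > 0  # half the offsets: each undirected edge once
  })
  offs <- offs[keep, , drop = FALSE]
  from <- to <- integer(0)
  wts <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- shift_array(node, -o, 0L)      # node id of voxel at idx + o
    pb <- shift_array(pen, -o, Inf)
    sel <- lin[node[lin] > 0 & nb[lin] > 0]
    if (!length(sel)) next
    step <- sqrt(sum((o * spacing)^2))
    from <- c(from, node[sel])
    to <- c(to, nb[sel])
    wts <- c(wts, step * (pen[sel] + pb[sel]) / 2)
  }
  list(graph = igraph::make_graph(rbind(from, to), n = length(lin),
                                  directed = FALSE),
       weights = wts, lin = lin)
}

#' Extract the muscle centerline from a binary mask
#'
#' Step 1 reduces the mask to a medial voxel curve: an erosion-depth
#' transform (iterative morphological erosion over the entire mask) scores
#' how interior each voxel is, and the geodesic path between the two
#' mutually farthest deep voxels — with step costs that penalize leaving the
#' erosion ridge — traces the middle of the band end to end. Step 2 fits
#' each coordinate of the ordered path, parameterized by normalized
#' cumulative chord length, with a least-squares polynomial; path voxels
#' farther than two voxels from the fit are dropped as outliers and the fit
#' repeated once. The curve is resampled densely (about 0.4 voxel spacing)
#' with unit tangents from the analytic polynomial derivative.
#'
#' @param mask logical 3D array, non-empty, single connected component.
#' @param spacing mm triple.
#' @param degree polynomial degree per coordinate (default 5).
#' @param flip if `TRUE`, reverse the default orientation (default puts
#'   `s = 0` at the end with the smaller x-coordinate, labelled "right").
#' @param largest_component if `TRUE`, a disconnected mask is reduced to
#'   its largest connected component instead of raising an error (used for
#'   automatically propagated masks, which can shed small fragments).
#' @return Object of class `prm_centerline`: `points` (n x 3 mm),
#'   `tangents` (unit n x 3), `arc_length` (mm, from 0), `poly_degree`.
#' @export
extract_centerline <- function(mask, spacing, degree = 5L, flip = FALSE,
                               largest_component = FALSE) {
  if (!any(mask)) stop("input error: empty mask")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    if (!largest_component)
      stop("disconnected mask: ", ncomp, " components (expected 1)")
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    mask <- lab == which.max(sizes)
  }
  depth <- erosion_depth(mask)
  g <- mask_graph(mask, spacing, depth)
  lin <- g$lin
  dvals <- depth[lin]
  cand <- which(dvals >= max(dvals) - 1L)  # near-ridge voxels only
  # double-sweep: farthest candidate from the deepest voxel, then farthest
  # candidate from that end; the weighted metric keeps both near the ridge
  v0 <- cand[which.max(dvals[cand])]
  d1 <- igraph::distances(g$graph, v = v0, weights = g$weights)[1, ]
  e1 <- cand[which.max(d1[cand])]
  d2 <- igraph::distances(g$graph, v = e1, weights = g$weights)[1, ]
  e2 <- cand[which.max(d2[cand])]
  path <- igraph::shortest_paths(g$graph, from = e1, to = e2,
                                 weights = g$weights)$vpath[[1]]
  pv <- as.integer(path)
  if (length(pv) < degree + 2)
    stop("skeleton path too short (", length(pv),
         " points) for polynomial degree ", degree)
  pts <- vox_to_mm(arrayInd(lin[pv], dim(mask)), spacing)
  # recenter each path point on the centroid of the surrounding mask voxels
  # (two mean-shift passes): damps the voxel zigzag of the discrete path
  # and pulls it onto the band axis before the polynomial fit
  r <- max(dvals) * mean(spacing)
  mpts <- vox_to_mm(arrayInd(lin, dim(mask)), spacing)
  for (pass in 1:2) {
    for (i in seq_len(nrow(pts))) {
      d2 <- (mpts[, 1] - pts[i, 1])^2 + (mpts[, 2] - pts[i, 2])^2 +
            (mpts[, 3] - pts[i, 3])^2
      sel <- d2 <= r^2
      if (sum(sel) >= 3) pts[i, ] <- colMeans(mpts[sel, , drop = FALSE])
    }
  }
  # the erosion-depth ridge degenerates to a cone near the band end caps,
  # so the outermost path points are unreliable: trim about one tube
  # radius from each end (the fitted curve is re-extended to the cap by
  # fit_polyline) while keeping enough points for the fit
  trim <- max(dvals)
  while (nrow(pts) - 2 * trim < max(degree + 2, 6) && trim > 0)
    trim <- trim - 1L
  if (trim > 0) pts <- pts[(trim + 1):(nrow(pts) - trim), , drop = FALSE]
  fit_polyline(pts, degree, spacing, flip, mask = mask)
}

# fit x(t), y(t), z(t) polynomials with one outlier-rejection pass, then
# resample densely with analytic tangents. When a mask is supplied the
# curve is extrapolated past both path ends until it leaves the mask: the
# medial path stops about one tube radius short of the band ends (erosion
# eats the end caps), and voxels beyond a truncated centerline would all
# clamp onto its last sample, corrupting arc coordinates there.
fit_polyline <- function(pts, degree, spacing, flip = FALSE,
                         outlier_mm = 2 * mean(spacing), mask = NULL) {
  chord <- function(p) {
    dl <- sqrt(rowSums(diff(p)^2))
    c(0, cumsum(dl))
  }
  fit_once <- function(p) {
    tt <- chord(p)
    tt <- tt / max(tt)
    deg <- min(degree, nrow(p) - 2)
    X <- outer(tt, 0:deg, `^`)
    coef <- qr.solve(X, p)
    list(coef = coef, t = tt, fitted = X %*% coef)
  }
  f <- fit_once(pts)
  resid <- sqrt(rowSums((pts - f$fitted)^2))
  keep <- resid <= outlier_mm
  if (any(!keep) && sum(keep) > degree + 1)
    f <- fit_once(pts[keep, , drop = FALSE])
  coef <- f$coef
  deg <- nrow(coef) - 1
  len_est <- sum(sqrt(rowSums(diff(f$fitted)^2)))
  # dense resample at <= ~0.4 voxel spacing along the curve
  ns <- max(64L, ceiling(len_est / (0.4 * min(spacing))))
  tg <- seq(0, 1, length.out = ns)
  X <- outer(tg, 0:deg, `^`)
  P <- X %*% coef
  Dc <- coef[-1, , drop = FALSE] * (1:deg)
  XD <- outer(tg, 0:(deg - 1), `^`)
  Tn <- XD %*% Dc
  nrm <- sqrt(rowSums(Tn^2))
  Tn <- Tn / nrm
  if (xor(P[1, 1] > P[ns, 1], flip)) {  # orient: s = 0 at smaller x unless flipped
    P <- P[ns:1, , drop = FALSE]
    Tn <- -Tn[ns:1, , drop = FALSE]
  }
  if (!is.null(mask)) {
    # extend straight along the end tangents until the curve leaves the
    # mask (capped at a quarter of the curve length per end); polynomial
    # extrapolation would be the less stable choice here
    d <- dim(mask)
    inside <- function(p) {
      v <- round(p / spacing) + 1
      all(v >= 1) && all(v <= d) && mask[v[1], v[2], v[3]]
    }
    step <- 0.25 * min(spacing)
    kmax <- ceiling(0.25 * len_est / step)
    extend <- function(p0, dir) {
      out <- NULL
      for (k in seq_len(kmax)) {
        q <- p0 + k * step * dir
        if (!inside(q)) break
        out <- rbind(out, q)
      }
      out
    }
    head_ext <- extend(P[1, ], -Tn[1, ])
    tail_ext <- extend(P[nrow(P), ], Tn[nrow(P), ])
    if (!is.null(head_ext)) {
      P <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], P)
      Tn <- rbind(matrix(Tn[1, ], nrow(head_ext), 3, byrow = TRUE), Tn)
    }
    if (!is.null(tail_ext)) {
      n0 <- nrow(Tn)
      P <- rbind(P, tail_ext)
      Tn <- rbind(Tn, matrix(Tn[n0, ], nrow(tail_ext), 3, byrow = TRUE))
    }
  }
  al <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  structure(list(points = P, tangents = Tn, arc_length = al,
                 poly_degree = as.integer(deg)),
            class = "prm_centerline")
}

#' @export
print.prm_centerline <- function(x, ...) {
  cat(sprintf("prm_centerline: %d samples, length %.1f mm, degree %d\n",
              nrow(x$points), max(x$arc_length), x$poly_degree))
  invisible(x)
}

#' Map mask voxels to arc-length coordinates on the centerline
#'
#' Each mask voxel is assigned the nearest centerline sample (Euclidean
#' distance in mm; ties resolved toward the smaller arc coordinate) and
#' inherits that sample's arc coordinate `s` and unit tangent.
#'
#' @param mask logical 3D array.
#' @param cl a [extract_centerline()] result.
#' @param spacing mm triple.
#' @return Object of class `arc_coordinate_map`: voxel indices `idx`
#'   (n x 3, 1-based), linear indices `lin`, `s` (mm), `tangent` (n x 3),
#'   `distance` (mm), `dims`, `total_length`.
#' @export
build_arc_map <- function(mask, cl, spacing) {
  stopifnot(inherits(cl, "prm_centerline"))
  idx <- mask_which(mask)
  if (!nrow(idx)) stop("input error: empty mask")
  pts <- vox_to_mm(idx, spacing)
  cp <- cl$points
  nearest <- integer(nrow(pts))
  dist <- numeric(nrow(pts))
  chunk <- 2000L
  for (st in seq(1L, nrow(pts), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(pts))
    block <- pts[st:en, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(cp))) +
          outer(rep(1, nrow(block)), rowSums(cp^2)) -
          2 * block %*% t(cp)
    nearest[st:en] <- max.col(-d2, ties.method = "first")
    dist[st:en] <- sqrt(pmax(d2[cbind(seq_len(nrow(block)),
                                      nearest[st:en])], 0))
  }
  d <- dim(mask)
  lin <- (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
  structure(list(idx = idx, lin = lin, s = cl$arc_length[nearest],
                 tangent = cl$tangents[nearest, , drop = FALSE],
                 distance = dist, dims = d,
                 total_length = max(cl$arc_length)),
            class = "arc_coordinate_map")
}

#' Project displacement vectors onto the fiber direction
#'
#' Scalar tangential displacement per mask voxel: the dot product of the
#' voxel's 3-vector with the unit tangent of its nearest centerline point.
#' Positive along increasing arc coordinate.
#'
#' @param vectors either a full-grid `[nx, ny, nz, 3]` array (mm) or an
#'   n x 3 matrix aligned with `map$idx`.
#' @param map an [build_arc_map()] result.
#' @return numeric vector of tangential displacements (mm), `NA` where the
#'   source vector is undefined.
#' @export
project_displacements <- function(vectors, map) {
  stopifnot(inherits(map, "arc_coordinate_map"))
  if (is.array(vectors) && length(dim(vectors)) == 4) {
    npl <- prod(map$dims)
    v <- cbind(vectors[map$lin], vectors[map$lin + npl],
               vectors[map$lin + 2 * npl])
  } else {
    v <- as.matrix(vectors)
    if (nrow(v) != nrow(map$idx)) stop("input error: vector/map size mismatch")
  }
  rowSums(v * map$tangent)
}
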