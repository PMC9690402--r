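# Low-level spatial helpers shared by the analyzers. All physical
# quantities go through the voxel spacing; nothing assumes isotropy.

# Shift a logical 3-D array by integer voxel offset d = c(dx, dy, dz),
# filling exposed planes with FALSE (outside the grid is background).
.shiftArray <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
    }
    if (!length(src[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Integer voxel offsets whose centers lie within a physical ball of
# radius `radius` mm, excluding the origin.
.ballOffsets <- function(radius, spacing) {
  r <- pmax(0L, floor(radius / spacing))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  g <- g[d2 <= radius^2 & d2 > 0, , drop = FALSE]
  as.matrix(g)
}

# Morphological erosion of a logical mask by a physical ball (mm).
# A voxel survives iff every ball neighbour (clipped at the grid edge,
# where outside counts as background) is foreground.
.erodeBall <- function(mask, radius, spacing) {
  if (radius <= 0) return(mask)
  off <- .ballOffsets(radius, spacing)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (!any(out)) break
    out <- out & .shiftArray(mask, off[i, ])
  }
  out
}

# Bounding box of a logical array as index ranges, grown by `pad` voxels.
.bbox <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  dm <- dim(mask)
  lapply(seq_along(dm), function(ax)
    max(1L, min(w[, ax]) - pad):min(dm[ax], max(w[, ax]) + pad))
}

# Physical distance from each foreground voxel center to the nearest
# background voxel center (brute force over the boundary shell; intended
# for compact regions such as a liver mask).
.interiorDistance <- function(mask, spacing) {
  dm <- dim(mask)
  shell <- array(FALSE, dm)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    d <- c(0L, 0L, 0L); d[ax] <- s
    shell <- shell | (!.shiftArray(mask, d) & mask)
  }
  # shell: foreground voxels touching background (incl. the grid edge).
  fg <- which(mask, arr.ind = TRUE)
  bd <- which(shell, arr.ind = TRUE)
  dist <- rep(Inf, nrow(fg))
  if (!nrow(bd)) return(list(idx = fg, dist = dist))
  fgp <- sweep(fg, 2L, spacing, `*`)
  bdp <- sweep(bd, 2L, spacing, `*`)
  chunk <- max(1L, floor(5e6 / nrow(bdp)))
  for (start in seq(1L, nrow(fgp), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(fgp))
    d2 <- outer(fgp[rows, 1], bdp[, 1], `-`)^2 +
          outer(fgp[rows, 2], bdp[, 2], `-`)^2 +
          outer(fgp[rows, 3], bdp[, 3], `-`)^2
    dist[rows] <- sqrt(apply(d2, 1L, min))
  }
  list(idx = fg, dist = dist)
}

# Two-pass union-find labeling of connected components in a logical
# matrix with 8-connectivity. Returns an integer matrix of component ids
# (0 = background).
.labelComponents2D <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  nlab <- 0L
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(bw, arr.ind = TRUE)
  if (!nrow(idx)) return(lab)
  ord <- order(idx[, 2], idx[, 1])  # column-major scan
  for (p in ord) {
    i <- idx[p, 1]; j <- idx[p, 2]
    neigh <- integer(0)
    if (i > 1L && lab[i - 1L, j] > 0L) neigh <- c(neigh, lab[i - 1L, j])
    if (j > 1L) {
      if (lab[i, j - 1L] > 0L) neigh <- c(neigh, lab[i, j - 1L])
      if (i > 1L && lab[i - 1L, j - 1L] > 0L)
        neigh <- c(neigh, lab[i - 1L, j - 1L])
      if (i < nr && lab[i + 1L, j - 1L] > 0L)
        neigh <- c(neigh, lab[i + 1L, j - 1L])
    }
    if (!length(neigh)) {
      nlab <- nlab + 1L
      parent[nlab] <- nlab
      lab[i, j] <- nlab
    } else {
      roots <- vapply(unique(neigh), find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (o in roots) parent[o] <- r
    }
  }
  # resolve and renumber compactly
  if (nlab) {
    rootmap <- vapply(seq_len(nlab), find, integer(1))
    compact <- match(rootmap, sort(unique(rootmap)))
    lab[lab > 0L] <- compact[lab[lab > 0L]]
  }
  lab
}

# Breadth-first 3-D connected components (26-connectivity) of a logical
# array. Returns integer array of component ids (0 = background).
.labelComponents3D <- function(bw) {
  dm <- dim(bw)
  lab <- array(0L, dm)
  w <- which(bw)
  if (!length(w)) return(lab)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  coord <- arrayInd(w, dm)
  inmask <- array(FALSE, dm); inmask[w] <- TRUE
  nextid <- 0L
  for (s in seq_along(w)) {
    if (lab[w[s]] > 0L) next
    nextid <- nextid + 1L
    queue <- matrix(coord[s, ], ncol = 3L)
    lab[w[s]] <- nextid
    while (nrow(queue)) {
      frontier <- NULL
      for (r in seq_len(nrow(off))) {
        cand <- sweep(queue, 2L, off[r, ], `+`)
        ok <- cand[, 1] >= 1L & cand[, 1] <= dm[1] &
              cand[, 2] >= 1L & cand[, 2] <= dm[2] &
              cand[, 3] >= 1L & cand[, 3] <= dm[3]
        if (!any(ok)) next
        cand <- cand[ok, , drop = FALSE]
        lin <- cand[, 1] + (cand[, 2] - 1L) * dm[1] +
               (cand[, 3] - 1L) * dm[1] * dm[2]
        take <- inmask[lin] & lab[lin] == 0L
        if (!any(take)) next
        lin <- unique(lin[take])
        lab[lin] <- nextid
        frontier <- rbind(frontier, arrayInd(lin, dm))
      }
      queue <- if (is.null(frontier)) matrix(numeric(0), ncol = 3L)
               else unique(frontier)
    }
  }
  lab
}
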