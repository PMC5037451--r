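# Binary skeletonization and skeleton-graph analysis used by neurite tracing.
# Sequential Golay-mask thinning, vectorized over the whole image per pass.

# EBImage Image -> plain 2D matrix (as.matrix() would drop dims)
ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  m
}

# clamp to [0, 1] preserving dims (pmin/pmax with a scalar first arg drop them)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

shift_mat <- function(m, dx, dy) {
  # shift so that result[x, y] = m[x + dx, y + dy]; zero-padded
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0L, nx, ny)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  out[xs - dx, ys - dy] <- m[xs, ys]
  out
}

neighbor_stack <- function(m) {
  # clockwise neighbors P2..P9 starting north (y - 1)
  list(p2 = shift_mat(m, 0, -1), p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 1, 0),  p5 = shift_mat(m, 1, 1),
       p6 = shift_mat(m, 0, 1),  p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, -1, 0), p9 = shift_mat(m, -1, -1))
}

# crossing number: 0->1 transitions around the 8-neighborhood; 1 for an
# endpoint, 2 along a curve, >= 3 at a junction
crossing_number <- function(m) {
  nb <- neighbor_stack(m)
  seqv <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) a <- a + (seqv[[i]] == 0L & seqv[[i + 1]] == 1L)
  a
}

# the two Golay "L" thinning masks and their 90-degree rotations
# (1 = foreground required, 0 = background required, 2 = don't care);
# mask[i, j] corresponds to offset (dx = j - 2, dy = i - 2)
golay_l_masks <- function() {
  l1 <- matrix(c(0, 0, 0,
                 2, 1, 2,
                 1, 1, 1), 3, 3, byrow = TRUE)
  l2 <- matrix(c(2, 0, 0,
                 1, 1, 0,
                 2, 1, 2), 3, 3, byrow = TRUE)
  rot <- function(m) t(m)[, 3:1]  # 90-degree rotation
  out <- list(l1, l2)
  for (k in 1:3) {
    l1 <- rot(l1); l2 <- rot(l2)
    out <- c(out, list(l1, l2))
  }
  out
}

#' Skeletonize a binary mask by sequential morphological thinning
#'
#' Repeatedly thins the mask with the eight rotated Golay "L" structuring
#' elements (hit-or-miss thinning) until stable, leaving a one-pixel-wide,
#' 8-connected skeleton. Connectivity and holes are preserved; unlike the
#' parallel two-subiteration scheme, sequential application of the eight
#' masks does not annihilate thin diagonal limbs.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer 0/1 matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  masks <- golay_l_masks()
  repeat {
    changed <- FALSE
    for (se in masks) {
      hit <- matrix(TRUE, nrow(m), ncol(m))
      for (i in 1:3) for (j in 1:3) {
        v <- se[i, j]
        if (v == 2) next
        nbv <- if (i == 2 && j == 2) m else shift_mat(m, j - 2L, i - 2L)
        hit <- hit & (nbv == v)
      }
      if (any(hit)) { m[hit] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Adjacency (8-connectivity) bookkeeping for a skeleton image: pixel
# coordinates, per-pixel degree and crossing number, adjacency list (pixel
# ids), and whether each neighbor step is diagonal.
skeleton_graph <- function(skel) {
  idx <- which(skel == 1L)
  empty <- list(idx = integer(0), x = integer(0), y = integer(0),
                degree = integer(0), cn = integer(0), adj = list(),
                diag = list())
  if (!length(idx)) return(empty)
  nx <- nrow(skel)
  x <- ((idx - 1L) %% nx) + 1L
  y <- ((idx - 1L) %/% nx) + 1L
  pos <- match(seq_len(nx * ncol(skel)), idx)  # image index -> pixel id
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  adj <- vector("list", length(idx))
  dia <- vector("list", length(idx))
  deg <- integer(length(idx))
  ny <- ncol(skel)
  for (k in seq_len(nrow(offs))) {
    isdiag <- offs$dx[k] != 0 & offs$dy[k] != 0
    xn <- x + offs$dx[k]; yn <- y + offs$dy[k]
    ok <- xn >= 1 & xn <= nx & yn >= 1 & yn <= ny
    nb_img <- (yn - 1L) * nx + xn
    nb_id <- rep(NA_integer_, length(idx))
    nb_id[ok] <- pos[nb_img[ok]]
    hit <- which(!is.na(nb_id))
    deg[hit] <- deg[hit] + 1L
    for (i in hit) {
      adj[[i]] <- c(adj[[i]], nb_id[i])
      dia[[i]] <- c(dia[[i]], isdiag)
    }
  }
  cnm <- crossing_number(matrix(as.integer(skel), nx, ny))
  list(idx = idx, x = x, y = y, degree = deg, cn = cnm[idx],
       adj = adj, diag = dia)
}

# Remove short terminal spurs (endpoint-to-junction paths of length <= max_len
# pixels). Junctions are identified by crossing number >= 3.
prune_spurs <- function(skel, max_len = 3L) {
  g <- skeleton_graph(skel)
  if (!length(g$idx)) return(skel)
  keep <- rep(TRUE, length(g$idx))
  endpoints <- which(g$cn == 1L)
  for (e in endpoints) {
    path <- e; cur <- e; prev <- 0L
    repeat {
      nxt <- setdiff(g$adj[[cur]], c(prev, path))
      if (!length(nxt)) { path <- NULL; break }          # isolated arc
      if (any(g$cn[nxt] >= 3L)) break                    # reached a junction
      if (length(path) >= max_len) { path <- NULL; break }
      prev <- cur; cur <- nxt[1]; path <- c(path, cur)
    }
    if (!is.null(path) && length(path) <= max_len) keep[path] <- FALSE
  }
  out <- skel
  out[g$idx[!keep]] <- 0L
  out
}

# Arc length (px) of a skeleton component as a minimum spanning tree over
# 8-adjacency, orthogonal steps (weight 1) preferred over diagonal (sqrt 2).
# The tree removes the redundant triangle adjacencies a thinned staircase
# carries, which a naive pairwise count would double-book.
component_length_px <- function(g, members) {
  k <- length(members)
  if (k <= 1) return(0)
  id_of <- integer(max(members)); id_of[members] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edges_o <- list(); edges_d <- list()
  for (i in members) {
    nb <- g$adj[[i]]; dd <- g$diag[[i]]
    sel <- nb > i
    if (any(sel)) {
      eo <- nb[sel & !dd]; ed <- nb[sel & dd]
      if (length(eo)) edges_o[[length(edges_o) + 1]] <- cbind(i, eo)
      if (length(ed)) edges_d[[length(edges_d) + 1]] <- cbind(i, ed)
    }
  }
  len <- 0
  for (phase in 1:2) {
    ee <- if (phase == 1) edges_o else edges_d
    if (!length(ee)) next
    ee <- do.call(rbind, ee)
    w <- if (phase == 1) 1 else sqrt(2)
    for (r in seq_len(nrow(ee))) {
      a <- find(id_of[ee[r, 1]]); b <- find(id_of[ee[r, 2]])
      if (a != b) { parent[a] <- b; len <- len + w }
    }
  }
  len
}
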