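## Independent oracles, deliberately implemented without the package's own
## image primitives: erosion by shifted logical ANDs, connected components by
## graph traversal (igraph), and a direct quadrant-resolved arctangent.

## 3x3 box erosion: a pixel survives iff its full 8-neighbourhood (and
## itself) is foreground; borders treated as background
oracleErode <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    out <- out & pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  }
  out
}

## 8-connected component sizes via igraph
oracleComponents <- function(m) {
  idx <- which(m)
  if (!length(idx)) return(integer(0))
  h <- nrow(m)
  ids <- seq_along(idx)
  lookup <- integer(length(m))
  lookup[idx] <- ids
  rc <- arr.ind <- arrayInd(idx, dim(m))
  edges <- NULL
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nr <- rc[, 1] + dy; nc <- rc[, 2] + dx
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= ncol(m)
    nidx <- (nc - 1) * h + nr
    ok[ok] <- m[nidx[ok]]
    if (any(ok))
      edges <- rbind(edges, cbind(ids[ok], lookup[nidx[ok]]))
  }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sort(as.integer(comp$csize), decreasing = TRUE)
}

## erosion iteration at which the mask first has >= 2 components of at least
## minArea pixels; NA if never within maxIters
oracleSplitIteration <- function(m, maxIters = 10, minArea = 5) {
  cur <- m
  for (it in 0:maxIters) {
    if (it > 0) cur <- oracleErode(cur)
    sizes <- oracleComponents(cur)
    if (sum(sizes >= minArea) >= 2) return(it)
  }
  NA_integer_
}

## quadrant-resolved arctangent from first principles (no atan2)
oracleAngle <- function(dy, dx) {
  if (dx > 0) return(atan(dy / dx))
  if (dx < 0 && dy >= 0) return(atan(dy / dx) + pi)
  if (dx < 0) return(atan(dy / dx) - pi)
  if (dy > 0) return(pi / 2)
  if (dy < 0) return(-pi / 2)
  0
}

## Holm step-down adjustment written directly from the definition
oracleHolm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}
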