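#' @importFrom stats sd rnorm runif quantile optimize uniroot setNames predict var coef residuals
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed (kept within 32-bit integer range).
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

stopifnot_binary <- function(x, name = deparse(substitute(x))) {
  if (!all(x %in% c(0L, 1L, FALSE, TRUE)))
    stop(sprintf("'%s' must be a binary array", name), call. = FALSE)
}

# The 26 unit offsets of the 3-D Moore neighbourhood.
neighbour_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(abs(off)) > 0, , drop = FALSE]
}

# The 6 face-adjacent unit offsets.
neighbour_offsets_6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

#' Label 6-connected components of a binary 3-D mask
#'
#' Connected components are computed under the face (6-)neighbourhood, the
#' adjacency used when cleaning up voxel-wise segmentations.
#'
#' @param mask logical or 0/1 numeric 3-D array.
#' @return Integer array of the same shape: 0 outside the mask, components
#'   labelled 1..k in decreasing order of size (ties by first voxel index).
#' @export
label_components_6 <- function(mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array", call. = FALSE)
  stopifnot_binary(mask, "mask")
  dims <- dim(mask)
  lab <- array(0L, dims)
  idx <- which(mask > 0)
  if (length(idx) == 0L) return(lab)
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  coord <- arrayInd(idx, dims)
  edges <- vector("list", 3L)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (ax in 1:3) {
    ok <- coord[, ax] < dims[ax]
    nb <- idx[ok] + strides[ax]
    keep <- pos[nb] > 0L
    edges[[ax]] <- cbind(pos[idx[ok]][keep], pos[nb][keep])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(em) > 0L) g <- igraph::add_edges(g, t(em))
  memb <- igraph::components(g)$membership
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes)); relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  lab[idx] <- relabel[memb]
  lab
}

# Drop dimnames-free slice of a 4-D array at frame i as a 3-D array.
frame_of <- function(arr4, i) {
  d <- dim(arr4)
  array(arr4[, , , i], d[1:3])
}
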