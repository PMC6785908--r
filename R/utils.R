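# internal helpers

# run code with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_point_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  stopifnot(length(x) == 3)
  matrix(as.numeric(x), nrow = 1)
}

# world coordinates of all voxel centres of a grid, as an N x 3 matrix in
# column-major voxel order (matching array storage)
grid_centers <- function(dim, origin, voxel) {
  xs <- origin[1] + (seq_len(dim[1]) - 1) * voxel
  ys <- origin[2] + (seq_len(dim[2]) - 1) * voxel
  zs <- origin[3] + (seq_len(dim[3]) - 1) * voxel
  cbind(
    rep(xs, times = dim[2] * dim[3]),
    rep(rep(ys, each = dim[1]), times = dim[3]),
    rep(zs, each = dim[1] * dim[2])
  )
}

# block-mean downsampling of a 3D array by an integer factor
block_mean <- function(arr, f) {
  if (f == 1) return(arr)
  d <- dim(arr)
  nd <- d %/% f
  arr <- arr[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  dim(arr) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(arr, c(2, 4, 6), mean)
  dim(out) <- nd
  out
}
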