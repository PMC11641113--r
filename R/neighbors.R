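# Grid cell-list neighbour search. Points are binned into cubic voxels of
# edge r; candidate pairs come from the same voxel and the 13 forward
# voxel offsets, so each unordered pair is produced once. Scales linearly
# in the number of points for lattice-like densities.

#' @import data.table
NULL

.datatable.aware <- TRUE

# All unordered point pairs at distance <= r. Returns a data.table with
# columns i, j (row indices, i < j) and d (distance).
pairs_within <- function(pos, r) {
  stopifnot(is.matrix(pos), ncol(pos) == 3, r > 0)
  n <- nrow(pos)
  i <- kx <- ky <- kz <- NULL # data.table NSE
  if (n < 2)
    return(data.table::data.table(i = integer(), j = integer(), d = numeric()))
  dt <- data.table::data.table(
    i = seq_len(n),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    kx = as.integer(floor(pos[, 1] / r)),
    ky = as.integer(floor(pos[, 2] / r)),
    kz = as.integer(floor(pos[, 3] / r))
  )
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 |
               (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  res <- vector("list", nrow(offs) + 1L)
  same <- merge(dt, dt, by = c("kx", "ky", "kz"),
                suffixes = c("", ".j"), allow.cartesian = TRUE)
  res[[1L]] <- same[same$i < same$i.j]
  for (k in seq_len(nrow(offs))) {
    shifted <- data.table::copy(dt)
    shifted[, `:=`(kx = kx - offs[k, 1], ky = ky - offs[k, 2],
                   kz = kz - offs[k, 3])]
    res[[k + 1L]] <- merge(dt, shifted, by = c("kx", "ky", "kz"),
                           suffixes = c("", ".j"), allow.cartesian = TRUE)
  }
  all <- data.table::rbindlist(res)
  if (!nrow(all))
    return(data.table::data.table(i = integer(), j = integer(), d = numeric()))
  d2 <- (all$x - all$x.j)^2 + (all$y - all$y.j)^2 + (all$z - all$z.j)^2
  keep <- d2 <= r * r
  out <- data.table::data.table(
    i = pmin(all$i[keep], all$i.j[keep]),
    j = pmax(all$i[keep], all$i.j[keep]),
    d = sqrt(d2[keep]))
  data.table::setorder(out, i, j)
  out
}

# Nearest-neighbour distance for each point; widens the search radius
# until every point has a neighbour.
nn_distances <- function(pos, r0) {
  n <- nrow(pos)
  nnd <- rep(Inf, n)
  r <- r0
  repeat {
    pr <- pairs_within(pos, r)
    if (nrow(pr)) {
      dt <- data.table::rbindlist(list(
        data.table::data.table(id = pr$i, d = pr$d),
        data.table::data.table(id = pr$j, d = pr$d)))
      agg <- dt[, list(d = min(d)), by = "id"]
      nnd[agg$id] <- agg$d
    }
    if (all(is.finite(nnd)) || r > 1e3 * r0) break
    r <- r * 2
  }
  nnd
}

# Adjacency list (integer row indices) from a pair table.
pairs_to_adjacency <- function(pairs, n) {
  adj <- vector("list", n)
  if (!nrow(pairs)) return(lapply(adj, function(x) integer()))
  both <- data.table::data.table(
    a = c(pairs$i, pairs$j), b = c(pairs$j, pairs$i))
  data.table::setorder(both, a, b)
  split_idx <- split(both$b, both$a)
  for (nm in names(split_idx)) adj[[as.integer(nm)]] <- split_idx[[nm]]
  for (k in seq_len(n)) if (is.null(adj[[k]])) adj[[k]] <- integer()
  adj
}
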