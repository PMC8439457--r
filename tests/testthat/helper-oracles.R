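# Independent oracles used across test files.  These deliberately avoid the
# package's own implementations: accumulation by per-cell path tracing,
# watershed membership by path tracing, truncated-Poisson moments by brute
# force summation.

d8_offsets <- list(dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
                   dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
                   code = as.integer(2^(0:7)))

# follow the D8 path from (r, c); returns matrix of visited cells
trace_path <- function(dirmat, r, c, max_steps = 1e4) {
  path <- matrix(NA_integer_, 0, 2)
  for (i in seq_len(max_steps)) {
    path <- rbind(path, c(r, c))
    code <- dirmat[r, c]
    if (is.na(code) || code == 0L) return(path)
    k <- match(code, d8_offsets$code)
    r <- r + d8_offsets$dr[k]; c <- c + d8_offsets$dc[k]
  }
  stop("path did not terminate")
}

# brute-force flow accumulation: count paths passing through each cell
accumulation_oracle <- function(dirmat) {
  nr <- nrow(dirmat); nc <- ncol(dirmat)
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(dirmat[r, c])) next
    p <- trace_path(dirmat, r, c)
    for (i in seq_len(nrow(p))) acc[p[i, 1], p[i, 2]] <- acc[p[i, 1], p[i, 2]] + 1
  }
  acc[is.na(dirmat)] <- NA
  acc
}

# brute-force watershed: cells whose path passes through the pour cell
watershed_oracle <- function(dirmat, pour) {
  nr <- nrow(dirmat); nc <- ncol(dirmat)
  m <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(dirmat[r, c])) next
    p <- trace_path(dirmat, r, c)
    if (any(p[, 1] == pour[1] & p[, 2] == pour[2])) m[r, c] <- 1
  }
  m
}

# random rough DEM used for property tests
random_dem <- function(n, seed) {
  set.seed(seed)
  mp_raster(matrix(runif(n * n, 0, 10), n, n), cell_size_m = 25)
}

# brute-force zero-truncated Poisson pmf via renormalised Poisson
ztp_pmf_oracle <- function(k, lambda) {
  dpois(k, lambda) / (1 - dpois(0, lambda))
}

expect_monotone_path_to_edge <- function(dem) {
  dir <- d8_flow_direction(fill_depressions(dem))
  filled <- fill_depressions(dem)$values
  nr <- nrow(filled); nc <- ncol(filled)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    p <- trace_path(dir$values, r, c)
    els <- filled[p]
    expect_true(all(diff(els) <= 1e-12),
                label = sprintf("non-ascending path from (%d,%d)", r, c))
  }
}
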