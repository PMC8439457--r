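# D8 neighbour ordering is fixed package-wide: E, SE, S, SW, W, NW, N, NE.
# Direction codes are the matching powers of two; 0 marks an outlet cell.
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_CODE <- as.integer(2^(0:7))
D8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

#' Fill depressions in a DEM (priority-flood)
#'
#' Raises every interior depression exactly to its spill elevation so that
#' each cell has a non-ascending path to the grid edge.  Flat areas created
#' by filling are left flat; [d8_flow_direction()] resolves them by
#' distance-to-drainage ordering.
#'
#' @param dem an [mp_raster] of elevations.
#' @return an [mp_raster] with `values >= dem$values` everywhere.
#' @export
fill_depressions <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (all(is.na(z))) stop("DEM is entirely nodata")
  filled <- matrix(NA_real_, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  visited[is.na(z)] <- TRUE

  # binary heap over cell ids keyed by filled elevation
  cap <- nr * nc
  hk <- numeric(cap); hv <- integer(cap); hn <- 0L
  push <- function(key, id) {
    hn <<- hn + 1L; i <- hn; hk[i] <<- key; hv[i] <<- id
    while (i > 1L) {
      p <- i %/% 2L
      if (hk[p] <= hk[i]) break
      tmpk <- hk[p]; hk[p] <<- hk[i]; hk[i] <<- tmpk
      tmpv <- hv[p]; hv[p] <<- hv[i]; hv[i] <<- tmpv
      i <- p
    }
  }
  pop <- function() {
    k <- hk[1L]; v <- hv[1L]
    hk[1L] <<- hk[hn]; hv[1L] <<- hv[hn]; hn <<- hn - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; s <- i
      if (l <= hn && hk[l] < hk[s]) s <- l
      if (r <= hn && hk[r] < hk[s]) s <- r
      if (s == i) break
      tmpk <- hk[s]; hk[s] <<- hk[i]; hk[i] <<- tmpk
      tmpv <- hv[s]; hv[s] <<- hv[i]; hv[i] <<- tmpv
      i <- s
    }
    c(k, v)
  }

  # seed with all non-nodata edge cells at their own elevation
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if ((r == 1L || r == nr || c == 1L || c == nc) && !is.na(z[r, c])) {
      id <- (c - 1L) * nr + r
      filled[r, c] <- z[r, c]
      visited[r, c] <- TRUE
      push(z[r, c], id)
    }
  }
  if (hn == 0L) stop("DEM has no usable edge cell")

  while (hn > 0L) {
    kv <- pop()
    id <- as.integer(kv[2])
    r <- ((id - 1L) %% nr) + 1L
    c <- ((id - 1L) %/% nr) + 1L
    for (k in 1:8) {
      rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (visited[rr, cc]) next
      visited[rr, cc] <- TRUE
      filled[rr, cc] <- max(z[rr, cc], filled[r, c])
      push(filled[rr, cc], (cc - 1L) * nr + rr)
    }
  }
  out <- dem
  out$values <- filled
  out
}

#' D8 flow directions
#'
#' Each cell drains to the steepest-descent neighbour among its eight
#' neighbours (drop divided by centre distance; diagonals are sqrt(2) cells
#' away).  Ties are broken by the fixed neighbour ordering E, SE, S, SW, W,
#' NW, N, NE.  Edge cells with no lower neighbour are outlets (code 0).
#' Interior flats (expected only after [fill_depressions()]) are resolved by
#' a breadth-first sweep from already-draining cells of equal elevation, so
#' flat cells drain along shortest paths towards lower ground.
#'
#' @param dem a depression-filled [mp_raster].
#' @return an [mp_raster] of direction codes (powers of two; 0 = outlet;
#'   `NA` = nodata).
#' @export
d8_flow_direction <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  dir <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c])) next
    best_k <- 0L; best_slope <- 0
    for (k in 1:8) {
      rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc || is.na(z[rr, cc])) next
      slope <- (z[r, c] - z[rr, cc]) / D8_DIST[k]
      if (slope > best_slope) { best_slope <- slope; best_k <- k }
    }
    if (best_k > 0L) {
      dir[r, c] <- D8_CODE[best_k]
    } else {
      on_edge <- r == 1L || r == nr || c == 1L || c == nc
      if (!on_edge) {
        for (k in 1:8) {
          if (is.na(z[r + D8_DR[k], c + D8_DC[k]])) { on_edge <- TRUE; break }
        }
      }
      if (on_edge) dir[r, c] <- 0L  # outlet: nothing lower at the grid margin
      # else left NA for the flat-resolution sweep
    }
  }

  # resolve flats: BFS from resolved cells across equal-elevation neighbours
  pending <- which(is.na(dir) & !is.na(z))
  if (length(pending)) {
    queue <- integer(0)
    resolved <- !is.na(dir)
    # seeds: flat cells with a resolved neighbour at <= elevation
    for (id in pending) {
      r <- ((id - 1L) %% nr) + 1L; c <- ((id - 1L) %/% nr) + 1L
      for (k in 1:8) {
        rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (resolved[rr, cc] && !is.na(z[rr, cc]) && z[rr, cc] <= z[r, c]) {
          dir[r, c] <- D8_CODE[k]
          queue <- c(queue, id)
          break
        }
      }
    }
    resolved <- !is.na(dir)
    head <- 1L
    while (head <= length(queue)) {
      id <- queue[head]; head <- head + 1L
      r <- ((id - 1L) %% nr) + 1L; c <- ((id - 1L) %/% nr) + 1L
      for (k in 1:8) {
        rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (is.na(z[rr, cc]) || resolved[rr, cc]) next
        if (z[rr, cc] == z[r, c]) {
          # point the unresolved flat neighbour back towards this cell
          dir[rr, cc] <- D8_CODE[((k + 3L) %% 8L) + 1L]
          resolved[rr, cc] <- TRUE
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
    if (any(is.na(dir) & !is.na(z)))
      stop("flat interior region with no outlet; run fill_depressions() first")
  }
  out <- dem
  out$values <- dir
  out
}

d8_target <- function(dir_code, r, c) {
  k <- match(dir_code, D8_CODE)
  c(r + D8_DR[k], c + D8_DC[k])
}

#' Flow accumulation
#'
#' Number of cells (including itself) draining through each cell, computed by
#' topological (Kahn) traversal of the D8 direction grid.
#'
#' @param direction direction raster from [d8_flow_direction()].
#' @return an [mp_raster] of cell counts (`>= 1` on all non-nodata cells).
#' @export
flow_accumulation <- function(direction) {
  d <- direction$values
  nr <- nrow(d); nc <- ncol(d)
  acc <- matrix(NA_real_, nr, nc)
  acc[!is.na(d)] <- 1
  indeg <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dc <- d[r, c]
    if (is.na(dc) || dc == 0L) next
    t <- d8_target(dc, r, c)
    if (t[1] < 1L || t[1] > nr || t[2] < 1L || t[2] > nc || is.na(d[t[1], t[2]]))
      stop(sprintf("cell (%d, %d) drains outside the grid or into nodata", r, c))
    indeg[t[1], t[2]] <- indeg[t[1], t[2]] + 1L
  }
  queue <- which(indeg == 0L & !is.na(d))
  head <- 1L; n_done <- 0L
  while (head <= length(queue)) {
    id <- queue[head]; head <- head + 1L; n_done <- n_done + 1L
    r <- ((id - 1L) %% nr) + 1L; c <- ((id - 1L) %/% nr) + 1L
    dc <- d[r, c]
    if (dc != 0L) {
      t <- d8_target(dc, r, c)
      acc[t[1], t[2]] <- acc[t[1], t[2]] + acc[r, c]
      indeg[t[1], t[2]] <- indeg[t[1], t[2]] - 1L
      if (indeg[t[1], t[2]] == 0L)
        queue <- c(queue, (t[2] - 1L) * nr + t[1])
    }
  }
  if (n_done < sum(!is.na(d))) {
    bad <- which(indeg > 0L & !is.na(d))[1]
    stop(sprintf("flow-direction cycle detected at cell (%d, %d)",
                 ((bad - 1L) %% nr) + 1L, ((bad - 1L) %/% nr) + 1L))
  }
  out <- direction
  out$values <- acc
  out
}

#' Pour point of a lake
#'
#' The cell of highest flow accumulation within the lake mask (optionally
#' dilated by `buffer_px` rings of 8-neighbours, mirroring the one-pixel
#' buffer used when the land around an outflow is flat).  Ties are broken by
#' row-major order.
#'
#' @param accumulation accumulation raster from [flow_accumulation()].
#' @param lake_mask raster with nonzero values marking lake cells.
#' @param buffer_px number of dilation rings (default 0).
#' @return integer `c(row, col)` of the pour cell.
#' @export
find_pour_point <- function(accumulation, lake_mask, buffer_px = 0L) {
  raster_check_aligned(accumulation, lake_mask)
  m <- !is.na(lake_mask$values) & lake_mask$values != 0
  if (!any(m)) stop("lake mask is empty")
  if (buffer_px > 0L) for (i in seq_len(buffer_px)) m <- dilate8(m)
  a <- accumulation$values
  a[!m | is.na(a)] <- -Inf
  nr <- nrow(a)
  # row-major tie-break: scan rows first
  best <- c(NA_integer_, NA_integer_); best_a <- -Inf
  for (r in seq_len(nr)) for (c in seq_len(ncol(a))) {
    if (a[r, c] > best_a) { best_a <- a[r, c]; best <- c(r, c) }
  }
  if (!is.finite(best_a)) stop("no accumulation values inside the lake mask")
  best
}

dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (k in 1:8) {
    sr <- pmin(pmax(seq_len(nr) + D8_DR[k], 1L), nr)
    sc <- pmin(pmax(seq_len(nc) + D8_DC[k], 1L), nc)
    out <- out | m[sr, sc, drop = FALSE]
  }
  out
}

#' Delineate the watershed of a pour cell
#'
#' All cells whose D8 path reaches the pour cell, plus the pour cell itself.
#'
#' @param direction direction raster from [d8_flow_direction()].
#' @param pour_cell integer `c(row, col)`.
#' @return an [mp_raster] mask (1 inside the watershed, 0 outside).
#' @export
delineate_watershed <- function(direction, pour_cell) {
  d <- direction$values
  nr <- nrow(d); nc <- ncol(d)
  stopifnot(length(pour_cell) == 2, pour_cell[1] >= 1, pour_cell[1] <= nr,
            pour_cell[2] >= 1, pour_cell[2] <= nc)
  inws <- matrix(FALSE, nr, nc)
  inws[pour_cell[1], pour_cell[2]] <- TRUE
  queue <- (pour_cell[2] - 1L) * nr + pour_cell[1]
  head <- 1L
  while (head <= length(queue)) {
    id <- queue[head]; head <- head + 1L
    r <- ((id - 1L) %% nr) + 1L; c <- ((id - 1L) %/% nr) + 1L
    for (k in 1:8) {
      rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      dc <- d[rr, cc]
      if (is.na(dc) || dc == 0L || inws[rr, cc]) next
      # neighbour drains into (r, c) iff its code is the opposite direction
      if (dc == D8_CODE[((k + 3L) %% 8L) + 1L]) {
        inws[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1L) * nr + rr)
      }
    }
  }
  out <- direction
  out$values <- inws + 0
  out
}

#' Summarise land cover within a catchment
#'
#' @param landcover coded land-cover raster.
#' @param mask watershed mask raster (nonzero = inside).
#' @param class_map named character vector mapping raster codes (as names) to
#'   `"forest"`, `"urban"` or `"other"`.
#' @return list with `forest_prop`, `urban_prop`, `n_cells`, `area_km2`.
#'   Nodata land-cover cells inside the mask are excluded from the
#'   denominator.
#' @export
summarize_landcover <- function(landcover, mask, class_map) {
  raster_check_aligned(landcover, mask)
  inmask <- !is.na(mask$values) & mask$values != 0
  if (!any(inmask)) stop("catchment mask is empty")
  codes <- landcover$values[inmask]
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("no land-cover data inside the catchment mask")
  cls <- unname(class_map[as.character(codes)])
  cls[is.na(cls)] <- "other"
  n <- length(cls)
  list(forest_prop = sum(cls == "forest") / n,
       urban_prop = sum(cls == "urban") / n,
       n_cells = n,
       area_km2 = sum(inmask) * (mask$cell_size_m / 1000)^2)
}

#' Total wastewater treatment load within a catchment
#'
#' Sums plant loads (population equivalents) whose coordinates fall in cells
#' of the mask; a plant on a cell boundary belongs to the cell containing it
#' under the half-open `[x, x + cellsize)` rule.
#'
#' @param wwtw_points data frame with columns `x`, `y`, `load_pe`.
#' @param mask watershed mask raster.
#' @return total load in population equivalents.
#' @export
sum_wwtw_load <- function(wwtw_points, mask) {
  if (is.null(wwtw_points) || nrow(wwtw_points) == 0) return(0)
  stopifnot(all(c("x", "y", "load_pe") %in% names(wwtw_points)),
            all(wwtw_points$load_pe >= 0))
  total <- 0
  for (i in seq_len(nrow(wwtw_points))) {
    rc <- raster_cell_at(mask, wwtw_points$x[i], wwtw_points$y[i])
    if (!is.na(rc[1]) && !is.na(mask$values[rc[1], rc[2]]) &&
        mask$values[rc[1], rc[2]] != 0)
      total <- total + wwtw_points$load_pe[i]
  }
  total
}

#' Full catchment summary for a lake
#'
#' Convenience wrapper: fill the DEM, route flow, find the lake pour point,
#' delineate its watershed and summarise land cover and wastewater load.
#'
#' @param dem,lake_mask,landcover aligned [mp_raster]s.
#' @param wwtw_points data frame with `x`, `y`, `load_pe` (or `NULL`).
#' @param class_map as in [summarize_landcover()].
#' @param buffer_px pour-point search buffer (set 1 when the outflow area is
#'   flat; the criterion is left to the user).
#' @return list with the watershed mask and the summary fields `area_km2`,
#'   `forest_prop`, `urban_prop`, `wwtw_load_pe`.
#' @export
catchment_summary <- function(dem, lake_mask, landcover, wwtw_points = NULL,
                              class_map = c(`1` = "forest", `2` = "urban"),
                              buffer_px = 0L) {
  filled <- fill_depressions(dem)
  dir <- d8_flow_direction(filled)
  acc <- flow_accumulation(dir)
  pour <- find_pour_point(acc, lake_mask, buffer_px = buffer_px)
  ws <- delineate_watershed(dir, pour)
  lc <- summarize_landcover(landcover, ws, class_map)
  list(watershed = ws, pour_cell = pour,
       area_km2 = lc$area_km2,
       forest_prop = lc$forest_prop, urban_prop = lc$urban_prop,
       wwtw_load_pe = sum_wwtw_load(wwtw_points, ws))
}
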