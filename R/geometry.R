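# Brain domains: synthetic generator, labeled-grid reader, tumour seeding.

#' Construct a brain geometry object
#'
#' @param mask Logical matrix; `TRUE` marks brain tissue, `FALSE` marks
#'   skull/skin/background, which are impermeable to tumour cells.
#' @param B0 Initial brain-cell density per voxel (1 inside the mask,
#'   0 outside).  Defaults to `1 * mask`.
#' @param D Dimensionless diffusion-enhancement field (1 inside the mask by
#'   default; elevated values emulate white-matter tracks).
#' @param spacing Voxel edge length in mm.  The default 1.5 mm gives the
#'   2.25 mm2 voxel area of the reference 112 x 83 mesh.
#' @return An object of class `brain_geometry` with fields `mask`, `B0`,
#'   `D`, `spacing`, `shape`.
#' @export
brain_geometry <- function(mask, B0 = NULL, D = NULL, spacing = 1.5) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask: no brain voxels", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (is.null(B0)) B0 <- 1 * mask
  if (is.null(D)) D <- 1 * mask
  if (!same_shape(mask, B0) || !same_shape(mask, D))
    stop("mask, B0 and D must share one shape", call. = FALSE)
  if (any(B0[!mask] != 0) || any(D[!mask] != 0))
    stop("B0 and D must be 0 outside the mask", call. = FALSE)
  if (any(B0[mask] <= 0)) stop("B0 must be > 0 inside the mask", call. = FALSE)
  if (any(D < 0)) stop("D must be >= 0", call. = FALSE)
  structure(list(mask = mask, B0 = B0, D = D, spacing = spacing, shape = dim(mask)),
            class = "brain_geometry")
}

#' @export
print.brain_geometry <- function(x, ...) {
  cat(sprintf("brain_geometry: %d x %d grid, %d brain voxels (%.1f%%), spacing %.3g mm\n",
              x$shape[1], x$shape[2], sum(x$mask),
              100 * mean(x$mask), x$spacing))
  invisible(x)
}

# keep only the largest 4-connected component of a logical mask
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      r <- (v - 1L) %% nr + 1L; c <- (v - 1L) %/% nr + 1L
      for (nb in c(if (r > 1L) v - 1L, if (r < nr) v + 1L,
                   if (c > 1L) v - nr, if (c < ncol(mask)) v + nr)) {
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- cur; queue <- c(queue, nb) }
      }
    }
  }
  if (cur == 0L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Generate a synthetic 2-D brain domain
#'
#' Produces a roughly elliptical brain mask with an irregular (seed-dependent)
#' boundary occupying 40-75% of the grid, a one-voxel impermeable margin at
#' the grid border, `B0 = 1` and `D = 1` inside the mask.  This is a stand-in
#' for a segmented axial MRI slice; optional smooth "white-matter" ridges of
#' elevated `D` can be requested.
#'
#' @param rows,cols Grid dimensions (both >= 16).
#' @param seed Integer seed; fixed seed gives a bitwise-identical geometry.
#' @param spacing Voxel edge length in mm (default 1.5, i.e. 2.25 mm2 voxels).
#' @param white_matter_ridges If `TRUE`, add two smooth bands of elevated `D`
#'   emulating preferential migration along white-matter tracks (off by
#'   default: the reference parameterisation uses `D = 1`).
#' @return A [brain_geometry()].
#' @export
generate_synthetic_brain <- function(rows, cols, seed = 1L, spacing = 1.5,
                                     white_matter_ridges = FALSE) {
  if (rows < 16 || cols < 16)
    stop("grid too small to contain a brain mask (need rows, cols >= 16)", call. = FALSE)
  with_seed(seed, {
    r0 <- (rows + 1) / 2; c0 <- (cols + 1) / 2
    a <- 0.42 * rows; b <- 0.44 * cols
    # irregular boundary: low-order angular harmonics of the radius
    k <- 2:5
    amp <- runif(length(k), -1, 1) * 0.08 / (k - 1)
    phs <- runif(length(k), 0, 2 * pi)
    rr <- matrix((seq_len(rows) - r0) / a, rows, cols)
    cc <- matrix((seq_len(cols) - c0) / b, rows, cols, byrow = TRUE)
    theta <- atan2(cc, rr)
    rho <- sqrt(rr^2 + cc^2)
    bound <- 1 + Reduce(`+`, lapply(seq_along(k), function(i) amp[i] * cos(k[i] * theta + phs[i])))
    mask <- rho <= bound
    mask[c(1, rows), ] <- FALSE
    mask[, c(1, cols)] <- FALSE
    mask <- largest_component(mask)
    occ <- mean(mask)
    if (occ < 0.40 || occ > 0.75)
      stop(sprintf("synthetic mask occupies %.0f%% of the grid (outside 40-75%%)", 100 * occ),
           call. = FALSE)
    D <- 1 * mask
    if (white_matter_ridges) {
      # two smooth sinusoidal bands of doubled diffusion support
      for (i in 1:2) {
        off <- runif(1, -0.15, 0.15) * rows
        ampl <- runif(1, 0.05, 0.15) * rows
        ctr <- r0 + off + ampl * sin(2 * pi * (seq_len(cols) - c0) / cols + runif(1, 0, 2 * pi))
        dist2 <- (matrix(seq_len(rows), rows, cols) -
                    matrix(ctr, rows, cols, byrow = TRUE))^2
        D <- D + 1.0 * exp(-dist2 / (2 * (0.04 * rows)^2)) * mask
      }
    }
    brain_geometry(mask = mask, B0 = 1 * mask, D = D, spacing = spacing)
  })
}

#' Load a labeled tissue grid as a brain geometry
#'
#' Reads a 2-D labeled grid (PGM gray levels or CSV labels, in the style of a
#' discrete tissue phantom) and marks voxels whose label belongs to
#' `brain_labels` as brain tissue (`mask = TRUE`, `B0 = 1`, `D = 1`); all
#' other voxels are impermeable.
#'
#' @param path Path to a `.pgm` (P2/P5) or CSV file.
#' @param brain_labels Vector of labels (numbers or strings) counting as brain.
#' @param spacing Voxel edge length in mm.
#' @return A [brain_geometry()].
#' @export
load_labeled_grid <- function(path, brain_labels, spacing = 1.5) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    grid <- read_pgm(path)
  } else {
    rows <- strsplit(trimws(readLines(path, warn = FALSE)), ",")
    rows <- rows[lengths(rows) > 0]
    if (!length(rows)) stop("empty grid file", call. = FALSE)
    if (length(unique(lengths(rows))) != 1L)
      stop(sprintf("non-rectangular grid in '%s'", path), call. = FALSE)
    grid <- matrix(trimws(unlist(rows)), nrow = length(rows), byrow = TRUE)
  }
  mask <- matrix(as.character(grid) %in% as.character(brain_labels), nrow(grid), ncol(grid))
  if (!any(mask)) stop("empty mask: no voxel carries a brain label", call. = FALSE)
  brain_geometry(mask = mask, spacing = spacing)
}

#' Write a geometry's tissue labels to PGM or CSV
#'
#' Brain voxels are written as label 1, non-brain as 0, so that
#' `load_labeled_grid(path, brain_labels = 1)` round-trips the mask.
#'
#' @param geom A [brain_geometry()].
#' @param path Output path; format chosen by extension (`.pgm` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  labels <- 1L * geom$mask
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    write_pgm(labels, path, maxval = 1)
  } else {
    write.table(labels, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Seed a tumour into a brain geometry
#'
#' Inserts a small concentration of proliferative cells (order 1e-1) and
#' invasive cells (order 1e-2) into a single voxel; brain cells start at
#' `B0` and necrosis at zero.
#'
#' @param geom A [brain_geometry()].
#' @param voxel `c(row, col)` of the seeded voxel; defaults to the mask voxel
#'   nearest the mask centroid.
#' @param p0,i0 Seeded proliferative / invasive concentrations
#'   (defaults 0.1 and 0.01).
#' @return A `tumor_state`: matrices `P`, `I`, `B`, `N` plus time `t = 0`.
#' @export
seed_tumor <- function(geom, voxel = NULL, p0 = 0.1, i0 = 0.01) {
  if (p0 < 0 || i0 < 0) stop("p0 and i0 must be >= 0", call. = FALSE)
  if (is.null(voxel)) {
    idx <- which(geom$mask, arr.ind = TRUE)
    ctr <- colMeans(idx)
    voxel <- idx[which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2), ]
  }
  voxel <- as.integer(voxel)
  if (length(voxel) != 2L || any(voxel < 1L) || voxel[1] > geom$shape[1] || voxel[2] > geom$shape[2])
    stop("voxel index out of range", call. = FALSE)
  if (!geom$mask[voxel[1], voxel[2]])
    stop("seed voxel lies outside the brain mask (skull/background)", call. = FALSE)
  zero <- matrix(0, geom$shape[1], geom$shape[2])
  P <- zero; P[voxel[1], voxel[2]] <- p0
  I <- zero; I[voxel[1], voxel[2]] <- i0
  structure(list(P = P, I = I, B = geom$B0, N = zero, t = 0),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("tumor_state at t = %.1f hr: sum P = %.4g, I = %.4g, B = %.4g, N = %.4g\n",
              x$t, sum(x$P), sum(x$I), sum(x$B), sum(x$N)))
  invisible(x)
}
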