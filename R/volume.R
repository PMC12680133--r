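# Deskew, registration and fusion of sheared dual-view oblique stacks.
#
# Lab-frame convention: z is the distance from the coverslip, the sheet is
# scanned along y, x is the camera column direction. The camera row
# direction of a view is tilted by the OPM angle; the two views tilt
# symmetrically (+theta for view 1, -theta for view 2) about the scan axis.
# A raw voxel (i, r, c) (scan frame, camera row, camera column; zero-based)
# sits at lab position
#   x = c * pixel_col
#   y = scan_origin + i * scan_step + s * r * pixel_row * cos(theta)
#   z = r * pixel_row * sin(theta)
# with s = +1 for view 1 and s = -1 for view 2. scan_origin (default 0)
# records where the sheet scan started, so that a positively sheared view
# can cover lab positions ahead of the first frame.

#' Lab-frame volume
#'
#' A 3D intensity array on an axis-aligned grid with voxel sizes and origin
#' in micrometres. Array dimensions are ordered (x, y, z).
#'
#' @param voxels 3D numeric array, intensities `>= 0`.
#' @param voxel_size_um Voxel size, length 1 (isotropic) or 3 (x, y, z).
#' @param origin_um Lab position of the center of voxel `[1, 1, 1]`.
#' @return Object of class `lab_volume`.
#' @export
lab_volume <- function(voxels, voxel_size_um, origin_um = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            all(is.finite(voxels)))
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3)
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0),
            length(origin_um) == 3)
  if (min(voxels) < 0) stop("intensities must be >= 0")
  structure(
    list(voxels = voxels, voxel_size_um = as.numeric(voxel_size_um),
         origin_um = as.numeric(origin_um)),
    class = "lab_volume")
}

#' @export
print.lab_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<lab_volume> %d x %d x %d voxels, voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
    x$voxel_size_um[3]))
  invisible(x)
}

#' Raw oblique image stack of one view
#'
#' Per-view sheared acquisition: one camera frame per sheet scan position,
#' ordered (scan frame, camera row, camera column).
#'
#' @param voxels 3D numeric array `(n_scan, n_row, n_col)`, finite,
#'   `>= 0`.
#' @param scan_step_um Sheet translation per frame, micrometres.
#' @param pixel_row_um,pixel_col_um Camera sampling mapped to sample space,
#'   micrometres.
#' @param opm_angle_deg OPM angle of the acquisition, degrees, in
#'   `(0, 90]`.
#' @param view_id 1 or 2.
#' @param scan_origin_um Lab y position of the first scan frame (default
#'   0).
#' @return Object of class `raw_oblique_stack`.
#' @export
raw_oblique_stack <- function(voxels, scan_step_um, pixel_row_um,
                              pixel_col_um, opm_angle_deg, view_id,
                              scan_origin_um = 0) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            all(is.finite(voxels)), min(voxels) >= 0,
            scan_step_um > 0, pixel_row_um > 0, pixel_col_um > 0,
            view_id %in% c(1L, 2L), is.numeric(scan_origin_um))
  if (opm_angle_deg <= 0 || opm_angle_deg > 90)
    stop("`opm_angle_deg` must lie in (0, 90]")
  structure(
    list(voxels = voxels, scan_step_um = scan_step_um,
         pixel_row_um = pixel_row_um, pixel_col_um = pixel_col_um,
         opm_angle_deg = opm_angle_deg, view_id = as.integer(view_id),
         scan_origin_um = scan_origin_um),
    class = "raw_oblique_stack")
}

# trilinear sampling of a 3D array at fractional zero-based coordinates;
# points outside the array sample zero
trilinear_sample <- function(arr, f1, f2, f3) {
  d <- dim(arr)
  i0 <- floor(f1); j0 <- floor(f2); k0 <- floor(f3)
  t1 <- f1 - i0; t2 <- f2 - j0; t3 <- f3 - k0
  out <- numeric(length(f1))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    w <- (if (di) t1 else 1 - t1) * (if (dj) t2 else 1 - t2) *
      (if (dk) t3 else 1 - t3)
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] &
      w > 0
    if (any(ok)) {
      idx <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- out[ok] + w[ok] * arr[idx]
    }
  }
  out
}

view_sign <- function(view_id) if (view_id == 1L) 1 else -1

# lab-frame bounding box of a raw stack (voxel centers)
stack_lab_extent <- function(raw) {
  d <- dim(raw$voxels)
  th <- raw$opm_angle_deg * pi / 180
  s <- view_sign(raw$view_id)
  i <- c(0, d[1] - 1); r <- c(0, d[2] - 1); cc <- c(0, d[3] - 1)
  x <- range(cc * raw$pixel_col_um)
  yc <- raw$scan_origin_um +
    outer(i * raw$scan_step_um, s * r * raw$pixel_row_um * cos(th), "+")
  y <- range(yc)
  z <- range(r * raw$pixel_row_um * sin(th))
  list(x = x, y = y, z = z)
}

#' Default lab-frame output grid for a raw stack
#'
#' Bounding axis-aligned grid of the swept region with isotropic voxels at
#' `min(pixel_row * sin(theta), pixel_col)` micrometres (configurable).
#'
#' @param raw A [raw_oblique_stack()].
#' @param voxel_size_um Optional voxel size override (length 1 or 3).
#' @return A list with `origin_um`, `dim`, `voxel_size_um`, usable as the
#'   `grid` argument of [deskew()].
#' @export
deskew_grid <- function(raw, voxel_size_um = NULL) {
  stopifnot(inherits(raw, "raw_oblique_stack"))
  th <- raw$opm_angle_deg * pi / 180
  if (is.null(voxel_size_um))
    voxel_size_um <- min(raw$pixel_row_um * sin(th), raw$pixel_col_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3)
  ext <- stack_lab_extent(raw)
  origin <- c(ext$x[1], ext$y[1], ext$z[1])
  dims <- pmax(1L, as.integer(ceiling(
    c(diff(ext$x), diff(ext$y), diff(ext$z)) / voxel_size_um)) + 1L)
  list(origin_um = origin, dim = dims, voxel_size_um = voxel_size_um)
}

#' Deskew a raw oblique stack into the lab frame
#'
#' Resample the sheared per-view acquisition onto an axis-aligned lab-frame
#' grid by inverting the acquisition geometry (see the coordinate
#' convention in the package documentation) and sampling the raw stack with
#' trilinear interpolation. Voxels outside the swept region are
#' zero-filled.
#'
#' @param raw A [raw_oblique_stack()].
#' @param grid Output grid as returned by [deskew_grid()] (the default), or
#'   any list with `origin_um`, `dim` and `voxel_size_um` — pass the same
#'   grid for both views to deskew them onto a common frame.
#' @return A [lab_volume()].
#' @export
deskew <- function(raw, grid = deskew_grid(raw)) {
  stopifnot(inherits(raw, "raw_oblique_stack"))
  th <- raw$opm_angle_deg * pi / 180
  s <- view_sign(raw$view_id)
  dims <- grid$dim
  vs <- grid$voxel_size_um
  if (length(vs) == 1L) vs <- rep(vs, 3)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  x <- grid$origin_um[1] + (idx[, 1] - 1) * vs[1]
  y <- grid$origin_um[2] + (idx[, 2] - 1) * vs[2]
  z <- grid$origin_um[3] + (idx[, 3] - 1) * vs[3]
  r <- z / (raw$pixel_row_um * sin(th))
  cc <- x / raw$pixel_col_um
  i <- (y - raw$scan_origin_um - s * r * raw$pixel_row_um * cos(th)) /
    raw$scan_step_um
  vals <- trilinear_sample(raw$voxels, i, r, cc)
  lab_volume(array(vals, dims), vs, grid$origin_um)
}

#' Forward acquisition model: skew a lab volume into a raw oblique stack
#'
#' Exact adjoint-style counterpart of [deskew()]: sample the lab-frame
#' volume along the tilted camera planes at successive sheet scan
#' positions. `deskew(forward_skew(v))` reproduces `v` on the interior up
#' to interpolation error; this is the forward model used by the synthetic
#' data generators.
#'
#' @param lab A [lab_volume()].
#' @param scan_step_um,pixel_row_um,pixel_col_um Acquisition sampling,
#'   micrometres.
#' @param opm_angle_deg OPM angle, degrees, in `(0, 90]`.
#' @param view_id 1 or 2.
#' @param n_scan,n_row,n_col Output stack dimensions; defaults cover the
#'   lab volume extent.
#' @return A [raw_oblique_stack()].
#' @export
forward_skew <- function(lab, scan_step_um, pixel_row_um, pixel_col_um,
                         opm_angle_deg, view_id,
                         n_scan = NULL, n_row = NULL, n_col = NULL) {
  stopifnot(inherits(lab, "lab_volume"))
  if (opm_angle_deg <= 0 || opm_angle_deg > 90)
    stop("`opm_angle_deg` must lie in (0, 90]")
  th <- opm_angle_deg * pi / 180
  s <- view_sign(view_id)
  d <- dim(lab$voxels)
  ext_x <- lab$origin_um[1] + (d[1] - 1) * lab$voxel_size_um[1]
  ext_y <- lab$origin_um[2] + (d[2] - 1) * lab$voxel_size_um[2]
  ext_z <- lab$origin_um[3] + (d[3] - 1) * lab$voxel_size_um[3]
  if (is.null(n_row)) n_row <- ceiling(ext_z / (pixel_row_um * sin(th))) + 1
  if (is.null(n_col)) n_col <- ceiling(ext_x / pixel_col_um) + 1
  # start the scan early enough that the sheared frames cover the whole
  # volume, whichever the shear sign
  off <- range(s * (c(0, n_row - 1)) * pixel_row_um * cos(th))
  scan_origin <- lab$origin_um[2] - off[2]
  if (is.null(n_scan))
    n_scan <- ceiling((ext_y - off[1] - scan_origin) / scan_step_um) + 1
  dims <- as.integer(c(n_scan, n_row, n_col))
  idx <- arrayInd(seq_len(prod(dims)), dims)
  i <- idx[, 1] - 1; r <- idx[, 2] - 1; cc <- idx[, 3] - 1
  x <- cc * pixel_col_um
  y <- scan_origin + i * scan_step_um + s * r * pixel_row_um * cos(th)
  z <- r * pixel_row_um * sin(th)
  f1 <- (x - lab$origin_um[1]) / lab$voxel_size_um[1]
  f2 <- (y - lab$origin_um[2]) / lab$voxel_size_um[2]
  f3 <- (z - lab$origin_um[3]) / lab$voxel_size_um[3]
  vals <- trilinear_sample(lab$voxels, f1, f2, f3)
  raw_oblique_stack(array(vals, dims), scan_step_um, pixel_row_um,
                    pixel_col_um, opm_angle_deg, view_id,
                    scan_origin_um = scan_origin)
}

# circularly shift-aware conversion of an FFT peak index to a signed shift
fft_shift_index <- function(peak_idx, n) {
  s <- peak_idx - 1
  ifelse(s > n / 2, s - n, s)
}

#' Register two deskewed views by phase correlation
#'
#' Estimate the residual translation between two views deskewed onto the
#' same grid (the rotation between views is fixed by the known acquisition
#' geometry). Uses 3D phase correlation with sub-voxel refinement by the
#' local intensity centroid of the correlation peak.
#'
#' @param v1,v2 [lab_volume()] objects on identical grids.
#' @param peak_threshold Minimum normalized correlation-peak height below
#'   which the result is flagged low-confidence (default 0.03).
#' @return Object of class `rigid_transform`: `rotation` (identity),
#'   `translation_vox` (the shift such that `v2` is `v1` translated by it),
#'   `translation_um`, `peak` and `low_confidence`.
#' @export
register_views <- function(v1, v2, peak_threshold = 0.03) {
  stopifnot(inherits(v1, "lab_volume"), inherits(v2, "lab_volume"))
  if (!identical(dim(v1$voxels), dim(v2$voxels)))
    stop("views must share the same grid")
  a <- v1$voxels; b <- v2$voxels
  Fa <- fft(a); Fb <- fft(b)
  xps <- Fa * Conj(Fb)
  mag <- Mod(xps)
  mag[mag < .Machine$double.eps] <- 1
  corr <- Re(fft(xps / mag, inverse = TRUE)) / length(a)
  pk <- which.max(corr)
  d <- dim(a)
  pkidx <- arrayInd(pk, d)
  peak_val <- corr[pk]
  # v2[x] = v1[x - s] puts the correlation peak at index -s (mod N)
  raw_shift <- -fft_shift_index(as.numeric(pkidx), d)
  # sub-voxel refinement: centroid over the 3x3x3 neighborhood (circular)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- sweep(nb, 2, as.numeric(pkidx), "+")
  for (ax in 1:3) ii[, ax] <- ((ii[, ax] - 1) %% d[ax]) + 1
  vals <- corr[cbind(ii[, 1], ii[, 2], ii[, 3])]
  vals <- pmax(0, vals)
  frac <- if (sum(vals) > 0) colSums(nb * vals) / sum(vals) else c(0, 0, 0)
  shift <- unname(raw_shift - frac)
  structure(
    list(rotation = diag(3), translation_vox = shift,
         translation_um = shift * v1$voxel_size_um,
         peak = peak_val, low_confidence = peak_val < peak_threshold),
    class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> shift (%.2f, %.2f, %.2f) vox%s\n",
              x$translation_vox[1], x$translation_vox[2],
              x$translation_vox[3],
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

# translate a 3D array by a (possibly fractional) voxel shift, zero-filling
shift_volume <- function(arr, shift_vox) {
  d <- dim(arr)
  idx <- arrayInd(seq_len(prod(d)), d)
  f1 <- idx[, 1] - 1 - shift_vox[1]
  f2 <- idx[, 2] - 1 - shift_vox[2]
  f3 <- idx[, 3] - 1 - shift_vox[3]
  array(trilinear_sample(arr, f1, f2, f3), d)
}

#' Fuse two registered views
#'
#' Weighted mean of the two aligned views. If a transform from
#' [register_views()] is supplied, view 2 is translated back onto view 1
#' before averaging.
#'
#' @param v1,v2 [lab_volume()] objects on identical grids.
#' @param transform Optional [register_views()] result.
#' @param weights Length-2 non-negative weights (default equal).
#' @return A [lab_volume()].
#' @export
fuse <- function(v1, v2, transform = NULL, weights = c(0.5, 0.5)) {
  stopifnot(inherits(v1, "lab_volume"), inherits(v2, "lab_volume"),
            length(weights) == 2, all(weights >= 0), sum(weights) > 0)
  if (!identical(dim(v1$voxels), dim(v2$voxels)))
    stop("views must share the same grid")
  b <- v2$voxels
  if (!is.null(transform)) {
    stopifnot(inherits(transform, "rigid_transform"))
    if (any(abs(transform$translation_vox) > 1e-9))
      b <- shift_volume(b, -transform$translation_vox)
  }
  w <- weights / sum(weights)
  lab_volume(w[1] * v1$voxels + w[2] * b, v1$voxel_size_um, v1$origin_um)
}
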