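#' Virtual scene camera specification
#'
#' A level pinhole camera mounted at driver eye height above the ground
#' plane, aligned with the vehicle heading. The vertical field of view
#' follows from the horizontal one and the pixel aspect (square pixels).
#'
#' @param eye_height Camera height above the ground, metres.
#' @param hfov Horizontal field of view, degrees.
#' @param width,height Image resolution in pixels.
#' @param fps Frame rate, Hz (carried for bookkeeping).
#' @param roll Optional camera roll angle in radians (vehicle roll), default 0.
#' @param near Near-plane clipping distance, metres.
#' @return A `gw_camera` list with precomputed focal length in pixels.
#' @export
camera_spec <- function(eye_height = 1.5, hfov = 70, width = 1920,
                        height = 1080, fps = 60, roll = 0, near = 0.1) {
  if (hfov <= 0 || hfov >= 180) abort("`hfov` must be in (0, 180).")
  stopifnot_scalar_pos(width, "width"); stopifnot_scalar_pos(height, "height")
  f <- (width / 2) / tan(deg2rad(hfov) / 2)
  structure(
    list(eye_height = eye_height, hfov = hfov, width = width, height = height,
         fps = fps, roll = roll, near = near, f = f,
         cx = width / 2, cy = height / 2,
         vfov = 2 * rad2deg(atan((height / 2) / f))),
    class = "gw_camera"
  )
}

#' Physical viewing geometry of the display
#'
#' The screen subtends the camera's horizontal field of view at the viewing
#' distance, so on-screen pixel offsets map to the same visual angles as in
#' the rendered scene.
#'
#' @param distance Eye-to-screen distance, metres.
#' @param hfov Horizontal field of view subtended by the screen, degrees.
#' @param width_px,height_px Screen resolution in pixels.
#' @return A `gw_viewing` list (`screen_width_m`, `m_per_px`, centre pixel).
#' @export
viewing_geometry <- function(distance = 0.85, hfov = 70, width_px = 1920,
                             height_px = 1080) {
  screen_width_m <- 2 * distance * tan(deg2rad(hfov) / 2)
  structure(
    list(distance = distance, hfov = hfov, width_px = width_px,
         height_px = height_px, screen_width_m = screen_width_m,
         m_per_px = screen_width_m / width_px,
         cx = width_px / 2, cy = height_px / 2),
    class = "gw_viewing"
  )
}

# camera basis at a pose: forward/right/up in world coords (z up).
# screen y grows downward (image convention).
camera_axes <- function(heading, roll = 0) {
  fwd <- c(cos(heading), sin(heading), 0)
  right <- c(sin(heading), -cos(heading), 0)
  up <- c(0, 0, 1)
  if (roll != 0) {
    cr <- cos(roll); sr <- sin(roll)
    right2 <- cr * right + sr * up
    up2 <- -sr * right + cr * up
    right <- right2; up <- up2
  }
  list(fwd = fwd, right = right, up = up)
}

#' Project ground points to screen pixels
#'
#' @param pose A one-row data frame (or list) with `x`, `y`, `heading`
#'   giving the vehicle pose; the camera sits `eye_height` above it.
#' @param points Data frame with ground coordinates `x`, `y` (metres);
#'   an optional `z` column gives height above ground (default 0).
#' @param camera A [camera_spec()].
#' @return A tibble with `px`, `py`, `depth` (forward distance, m),
#'   `on_screen`, and `edge` (`"behind"`, `"left"`, `"right"`, `"top"`,
#'   `"bottom"` or `NA` when on screen).
#' @export
project_ground_to_screen <- function(pose, points, camera = camera_spec()) {
  ax <- camera_axes(pose$heading[1], camera$roll)
  eye <- c(pose$x[1], pose$y[1], camera$eye_height)
  z <- if ("z" %in% names(points)) points$z else 0
  vx <- points$x - eye[1]; vy <- points$y - eye[2]; vz <- z - eye[3]
  f_comp <- vx * ax$fwd[1] + vy * ax$fwd[2] + vz * ax$fwd[3]
  r_comp <- vx * ax$right[1] + vy * ax$right[2] + vz * ax$right[3]
  u_comp <- vx * ax$up[1] + vy * ax$up[2] + vz * ax$up[3]
  px <- camera$cx + camera$f * r_comp / f_comp
  py <- camera$cy - camera$f * u_comp / f_comp
  behind <- f_comp <= camera$near
  edge <- rep(NA_character_, length(px))
  edge[py > camera$height] <- "bottom"
  edge[py < 0] <- "top"
  edge[px > camera$width] <- "right"
  edge[px < 0] <- "left"
  edge[behind] <- "behind"
  px[behind] <- NA_real_; py[behind] <- NA_real_
  on_screen <- !behind & is.na(edge)
  tibble::tibble(px = px, py = py, depth = f_comp,
                 on_screen = on_screen, edge = edge)
}

#' Unit world direction of a screen pixel
#'
#' Inverse of the pinhole projection, up to scale: the world-space viewing
#' direction from the eye through a given pixel.
#'
#' @inheritParams project_ground_to_screen
#' @param px,py Pixel coordinates.
#' @return An `n x 3` matrix of unit direction vectors.
#' @export
screen_direction <- function(pose, px, py, camera = camera_spec()) {
  ax <- camera_axes(pose$heading[1], camera$roll)
  r <- (px - camera$cx) / camera$f
  u <- (camera$cy - py) / camera$f
  d <- cbind(
    ax$fwd[1] + r * ax$right[1] + u * ax$up[1],
    ax$fwd[2] + r * ax$right[2] + u * ax$up[2],
    ax$fwd[3] + r * ax$right[3] + u * ax$up[3]
  )
  d / sqrt(rowSums(d^2))
}

#' Intersect a gaze pixel's viewing ray with the ground plane
#'
#' @inheritParams screen_direction
#' @return Tibble with ground `x`, `y` (NA when the ray does not hit the
#'   ground ahead of the camera).
#' @export
screen_to_ground <- function(pose, px, py, camera = camera_spec()) {
  d <- screen_direction(pose, px, py, camera)
  eye <- c(pose$x[1], pose$y[1], camera$eye_height)
  tt <- -eye[3] / d[, 3]
  bad <- !is.finite(tt) | tt <= 0
  x <- eye[1] + tt * d[, 1]; y <- eye[2] + tt * d[, 2]
  x[bad] <- NA_real_; y[bad] <- NA_real_
  tibble::tibble(x = x, y = y)
}

#' Convert screen pixel offsets to visual angles
#'
#' Angles are measured from the screen centre per axis:
#' `atan((p - centre) * m_per_px / distance)`.
#'
#' @param px,py Pixel coordinates (either may be omitted).
#' @param viewing A [viewing_geometry()].
#' @return Tibble with `deg_x`, `deg_y` (degrees; `deg_y` positive below
#'   centre, following the image convention).
#' @export
pixels_to_degrees <- function(px, py = NULL, viewing = viewing_geometry()) {
  dx <- rad2deg(atan((px - viewing$cx) * viewing$m_per_px / viewing$distance))
  if (is.null(py)) return(tibble::tibble(deg_x = dx))
  dy <- rad2deg(atan((py - viewing$cy) * viewing$m_per_px / viewing$distance))
  tibble::tibble(deg_x = dx, deg_y = dy)
}

#' Angular distance between screen points
#'
#' The angle between the two eye-to-pixel direction vectors implied by the
#' viewing geometry (not the Euclidean norm of the per-axis angles).
#'
#' @param px1,py1,px2,py2 Pixel coordinates (vectorized).
#' @param viewing A [viewing_geometry()].
#' @return Angular distances in degrees.
#' @export
screen_angular_distance <- function(px1, py1, px2, py2,
                                    viewing = viewing_geometry()) {
  mpp <- viewing$m_per_px; d <- viewing$distance
  v1 <- cbind((px1 - viewing$cx) * mpp, (py1 - viewing$cy) * mpp, d)
  v2 <- cbind((px2 - viewing$cx) * mpp, (py2 - viewing$cy) * mpp, d)
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  rad2deg(acos(pmin(1, pmax(-1, num / den))))
}

#' Forward distance at which a ground point leaves the bottom of the frame
#'
#' For a level camera the bottom frustum edge meets the ground at
#' `eye_height / tan(vfov / 2)` ahead of the camera; waypoints are removed
#' from view around this distance (about 3.8 m with the default geometry,
#' i.e. roughly 3 m in front of the driver).
#'
#' @param camera A [camera_spec()].
#' @return Distance in metres.
#' @export
frustum_ground_cutoff <- function(camera = camera_spec()) {
  camera$eye_height / tan(deg2rad(camera$vfov) / 2)
}
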