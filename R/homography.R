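#' Estimate a projective transform from point correspondences
#'
#' Direct linear transform (DLT) estimate of the 3x3 homography mapping the
#' eye tracker's forward-camera image to monitor coordinates, from the known
#' screen positions of optical markers. Coordinates are Hartley-normalized
#' before the SVD solve for numerical stability.
#'
#' @param src Data frame with columns `x`, `y`: points in the source
#'   (camera) frame. At least 4, not all collinear.
#' @param dst Data frame with columns `x`, `y`: corresponding screen points.
#' @return A `gw_homography` object: the 3x3 matrix (normalized so
#'   `H[3,3] = 1`) with per-point residuals (px) attached.
#' @export
estimate_homography <- function(src, dst) {
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n) {
    abort("need >= 4 point correspondences of equal length")
  }
  norm_pts <- function(p) {
    ctr <- c(mean(p$x), mean(p$y))
    d <- sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2)
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3,
                byrow = TRUE)
    list(T = T, x = s * (p$x - ctr[1]), y = s * (p$y - ctr[2]))
  }
  a <- norm_pts(src); b <- norm_pts(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(a$x[i], a$y[i], 1)
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, b$x[i] * X)
    A[2 * i, ] <- c(0, 0, 0, -X, b$y[i] * X)
  }
  sv <- svd(A)
  if (sv$d[8] < 1e-10 * sv$d[1]) {
    abort("degenerate correspondence configuration (collinear points?)")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(b$T) %*% Hn %*% a$T
  H <- H / H[3, 3]
  mapped <- apply_homography(structure(list(H = H), class = "gw_homography"),
                             src)
  res <- sqrt((mapped$x - dst$x)^2 + (mapped$y - dst$y)^2)
  structure(list(H = H, residuals = res), class = "gw_homography")
}

#' Apply a homography to points
#'
#' Projective application with homogeneous normalization. Points mapped to
#' infinity (|w| ~ 0) come back as `NA` and are flagged.
#'
#' @param h A `gw_homography` or plain 3x3 matrix.
#' @param points Data frame with columns `x`, `y`.
#' @return Tibble with mapped `x`, `y` and logical `at_infinity`.
#' @export
apply_homography <- function(h, points) {
  H <- if (inherits(h, "gw_homography")) h$H else h
  P <- rbind(points$x, points$y, 1)
  Q <- H %*% P
  w <- Q[3, ]
  bad <- abs(w) < 1e-12
  x <- Q[1, ] / w; y <- Q[2, ] / w
  x[bad] <- NA_real_; y[bad] <- NA_real_
  tibble::tibble(x = x, y = y, at_infinity = bad)
}

#' Invert a homography
#' @param h A `gw_homography` or 3x3 matrix.
#' @return A `gw_homography` with the inverse transform.
#' @export
invert_homography <- function(h) {
  H <- if (inherits(h, "gw_homography")) h$H else h
  Hi <- solve(H); Hi <- Hi / Hi[3, 3]
  structure(list(H = Hi, residuals = NULL), class = "gw_homography")
}

#' Serialize / read a homography as a row-major 9-value JSON array
#' @param h A `gw_homography`.
#' @param path File path.
#' @return `read_homography()` returns a `gw_homography`.
#' @export
write_homography <- function(h, path) {
  H <- if (inherits(h, "gw_homography")) h$H else h
  jsonlite::write_json(as.vector(t(H)), path, digits = NA)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(v) != 9) abort("homography file must hold 9 values")
  structure(list(H = matrix(v, 3, 3, byrow = TRUE), residuals = NULL),
            class = "gw_homography")
}
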