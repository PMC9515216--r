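# Image-grid geometry primitives. The whole package uses 0-based
# (row, column) pixel indexing with half-open crop intervals at its
# interfaces; matrices themselves are ordinary 1-based R matrices with
# rows = image rows (y, downward) and columns = image columns (x,
# rightward).

#' Bilinear resize of a 2D map
#'
#' Samples the source at target pixel centers using the half-pixel
#' convention: target pixel `t` (0-based) maps to source coordinate
#' `(t + 0.5) * S/T - 0.5`, clamped to the source border. This is the
#' convention used throughout for salience upsampling and preprocessing.
#'
#' @param x numeric matrix.
#' @param target integer `(H, W)` output size.
#' @return numeric `target[1] x target[2]` matrix.
#' @export
resizeBilinear <- function(x, target) {
  stopIfNot2d(x)
  H <- nrow(x); W <- ncol(x)
  Ho <- as.integer(target[1]); Wo <- as.integer(target[2])
  if (Ho < 1L || Wo < 1L) stop("target size must be positive")
  sr <- pmin(pmax((seq_len(Ho) - 0.5) * H / Ho - 0.5, 0), H - 1)
  sc <- pmin(pmax((seq_len(Wo) - 0.5) * W / Wo - 0.5, 0), W - 1)
  r0 <- pmin(floor(sr), H - 1); r1 <- pmin(r0 + 1, H - 1)
  c0 <- pmin(floor(sc), W - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- sr - r0; fc <- sc - c0
  # outer-product blend of the four neighbor grids
  a <- x[r0 + 1, c0 + 1, drop = FALSE]; b <- x[r0 + 1, c1 + 1, drop = FALSE]
  d <- x[r1 + 1, c0 + 1, drop = FALSE]; e <- x[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, Ho, Wo); wc <- matrix(fc, Ho, Wo, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}

#' Nearest-neighbor resize (for integer label maps)
#'
#' Same half-pixel center mapping as [resizeBilinear()], rounding to the
#' nearest source pixel, so label identities survive without blending.
#'
#' @inheritParams resizeBilinear
#' @return matrix of the same storage mode as `x`.
#' @export
resizeNearest <- function(x, target) {
  stopIfNot2d(x, "label map")
  H <- nrow(x); W <- ncol(x)
  Ho <- as.integer(target[1]); Wo <- as.integer(target[2])
  sr <- pmin(pmax(round((seq_len(Ho) - 0.5) * H / Ho - 0.5), 0), H - 1)
  sc <- pmin(pmax(round((seq_len(Wo) - 0.5) * W / Wo - 0.5), 0), W - 1)
  x[sr + 1, sc + 1, drop = FALSE]
}

#' Zero-pad a map to a square frame
#'
#' Pads the shorter dimension symmetrically (extra pixel trailing when
#' odd) with a constant fill, the "shape fixing" step before resizing.
#'
#' @param x numeric matrix.
#' @param fill pad value (0 for images and label maps).
#' @return square matrix of side `max(dim(x))`.
#' @export
padSquare <- function(x, fill = 0) {
  stopIfNot2d(x)
  H <- nrow(x); W <- ncol(x)
  S <- max(H, W)
  out <- matrix(fill, S, S)
  r0 <- (S - H) %/% 2L; c0 <- (S - W) %/% 2L
  out[r0 + seq_len(H), c0 + seq_len(W)] <- x
  out
}

# Inverse-mapped affine sampler shared by augmentation. Rotation is
# about the image center, in degrees, counterclockwise in (x right,
# y down) coordinates; translation in fractions of the image size;
# isotropic scale. Out-of-frame samples fill with 0.
affineSample <- function(x, rotation = 0, translate = c(0, 0), scale = 1,
                         interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(x); W <- ncol(x)
  th <- rotation * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  g <- expand.grid(r = seq_len(H) - 1, c = seq_len(W) - 1)
  yo <- g$r - cy - translate[1] * H
  xo <- g$c - cx - translate[2] * W
  # inverse rotation then inverse scale
  xs <- ( cos(th) * xo + sin(th) * yo) / scale + cx
  ys <- (-sin(th) * xo + cos(th) * yo) / scale + cy
  if (interp == "nearest") {
    ri <- round(ys); ci <- round(xs)
    ok <- ri >= 0 & ri <= H - 1 & ci >= 0 & ci <= W - 1
    v <- numeric(length(ri))
    v[ok] <- x[cbind(ri[ok] + 1, ci[ok] + 1)]
    return(matrix(v, H, W))
  }
  r0 <- floor(ys); c0 <- floor(xs)
  fr <- ys - r0; fc <- xs - c0
  v <- numeric(length(ys))
  for (dr in 0:1) for (dc in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc
    wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- rr >= 0 & rr <= H - 1 & cc >= 0 & cc <= W - 1 & wgt > 0
    if (any(ok)) v[ok] <- v[ok] + wgt[ok] * x[cbind(rr[ok] + 1, cc[ok] + 1)]
  }
  matrix(v, H, W)
}
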