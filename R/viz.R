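# Attention topography and scalp-map rendering.

#' Electrode x band attention topography
#'
#' Averages the per-plane attention weights (produced by the CFA block on
#' probe stacks) over folds and probes, reshapes the 177 planes into a
#' 59 x 3 electrode-by-band matrix using the stacking convention
#' `plane = electrode_index * 3 + band_index`, and min-max normalises the
#' whole matrix to [0, 1] (an all-equal matrix maps to 0).
#'
#' @param attention folds x 177 matrix of mean attention weights (the
#'   `attention` element of [trainSubject()]), or the [trainSubject()]
#'   result itself.
#' @param montage an [EEGMontage-class].
#' @return An [AttentionTopography-class].
#' @export
attentionTopography <- function(attention, montage = standardMontage()) {
  if (is.list(attention) && !is.null(attention$attention))
    attention <- attention$attention
  if (is.null(attention)) stop("no attention weights (CFA disabled?)")
  att <- colMeans(rbind(attention))
  if (length(att) != 3L * length(montage@labels))
    stop("convention error: expected ", 3L * length(montage@labels),
         " planes, got ", length(att))
  w <- matrix(att, ncol = 3L, byrow = TRUE,
              dimnames = list(montage@labels, BAND_NAMES))
  rng <- range(w)
  w <- if (rng[2] - rng[1] < 1e-12) w * 0 else (w - rng[1]) / (rng[2] - rng[1])
  new("AttentionTopography", weights = w, montage = montage,
      bands = c("0-15 Hz", "15-30 Hz", "30-45 Hz"))
}

setMethod("show", "AttentionTopography", function(object) {
  top <- apply(object@weights, 2, function(v)
    rownames(object@weights)[which.max(v)])
  cat("AttentionTopography (59 electrodes x 3 bands), strongest per band:",
      paste(sprintf("%s:%s", colnames(object@weights), top), collapse = " "),
      "\n")
})

# Inverse-distance-weighted interpolation of electrode values on a grid
# masked to the unit disc.
.scalpGrid <- function(pos, vals, n = 80L, power = 2) {
  gx <- seq(-1, 1, length.out = n)
  gy <- seq(-1, 1, length.out = n)
  z <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (gx[i]^2 + gy[j]^2 > 1) next
      d2 <- (pos[, 1] - gx[i])^2 + (pos[, 2] - gy[j])^2
      if (any(d2 < 1e-12)) z[i, j] <- vals[which.min(d2)]
      else {
        w <- 1 / d2^(power / 2)
        z[i, j] <- sum(w * vals) / sum(w)
      }
    }
  }
  list(x = gx, y = gy, z = z)
}

#' Render one band of an attention topography as a scalp map
#'
#' Inverse-distance interpolation of the 59 electrode weights over the
#' unit-disc scalp projection, written as a PNG (blue = low weight,
#' red = high weight). Deterministic given its inputs.
#'
#' @param topo an [AttentionTopography-class].
#' @param band "low", "mid" or "high".
#' @param file output PNG path.
#' @param width,height image size in pixels.
#' @return `file`, invisibly.
#' @export
renderTopomap <- function(topo, band = c("low", "mid", "high"), file,
                          width = 480, height = 480) {
  stopifnot(is(topo, "AttentionTopography"))
  band <- match.arg(band)
  b <- match(band, BAND_NAMES)
  vals <- topo@weights[, b]
  pos <- topo@montage@positions
  g <- .scalpGrid(pos, vals)
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B"))(64)
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::image(g$x, g$y, g$z, col = pal, zlim = c(0, 1), axes = FALSE,
                  asp = 1, xlab = "", ylab = "",
                  main = paste("Attention,", topo@bands[b]))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::points(pos[, 1], pos[, 2], pch = 20, cex = 0.5)
  invisible(file)
}
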