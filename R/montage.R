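#' The 59-electrode 10-20 montage used by the decoding pipeline
#'
#' Returns the fixed 59-electrode arrangement (international 10-20/10-10
#' positions from Fpz through O2) with planar coordinates obtained by an
#' azimuthal projection of the scalp onto the unit disc (head rim at radius
#' 0.8, vertex Cz at the origin, nose towards positive y). The label order is
#' the acquisition order assumed by every other function in the package.
#'
#' @return An [EEGMontage-class] with 59 electrodes.
#' @examples
#' m <- standardMontage()
#' length(channelNames(m))  # 59
#' @export
standardMontage <- function() {
  labels <- c(
    "Fpz", "Fp1", "Fp2", "AF3", "AF4", "AF7", "AF8",
    "Fz", "F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8",
    "FCz", "FC1", "FC2", "FC3", "FC4", "FC5", "FC6", "FT7", "FT8",
    "Cz", "C1", "C2", "C3", "C4", "C5", "C6", "T7", "T8",
    "CP1", "CP2", "CP3", "CP4", "CP5", "CP6", "TP7", "TP8",
    "Pz", "P3", "P4", "P5", "P6", "P7", "P8",
    "POz", "PO3", "PO4", "PO5", "PO6", "PO7", "PO8",
    "Oz", "O1", "O2")

  # Row angle: polar angle (degrees) of the row's rim crossing, measured
  # from the nose (+y). Side fraction: 0 on the midline, 1 on the rim.
  rowAngle <- c(Fp = 18, AF = 36, F = 54, FC = 72, C = 90,
                CP = 108, P = 126, PO = 144, O = 162)
  rim <- 0.8

  pos <- matrix(0, length(labels), 2,
                dimnames = list(labels, c("x", "y")))
  for (lab in labels) {
    row <- sub("[z0-9]+$", "", lab)
    row <- switch(row, Fp = "Fp", AF = "AF", FT = "FC", TP = "CP",
                  T = "C", row)
    th <- rowAngle[[row]] * pi / 180
    if (grepl("z$", lab)) {
      t <- 0; s <- 0
    } else {
      n <- as.integer(sub("^[A-Za-z]+", "", lab))
      s <- if (n %% 2 == 1) -1 else 1
      # Fp1/2 and O1/2 sit on the rim; T7/8, FT7/8, TP7/8 are the 7/8
      # electrodes of the C, FC and CP rows.
      t <- if (row %in% c("Fp", "O")) 1 else c(0.25, 0.5, 0.75, 1)[ceiling(n / 2)]
      if (grepl("^(T|FT|TP)[78]$", lab)) t <- 1
    }
    pos[lab, ] <- c(s * t * rim * sin(th), rim * cos(th))
  }
  new("EEGMontage", labels = labels, positions = pos)
}

#' @describeIn standardMontage Electrode labels of a montage (or of any
#'   object carrying one).
#' @param x an object with a montage.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname standardMontage
#' @export
setMethod("channelNames", "EEGMontage", function(x) x@labels)

#' @rdname standardMontage
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@montage@labels)

#' Electrode positions
#' @param x an [EEGMontage-class].
#' @return n x 2 matrix of planar coordinates.
#' @export
electrodePositions <- function(x) {
  stopifnot(is(x, "EEGMontage"))
  x@positions
}

setMethod("show", "EEGMontage", function(object) {
  cat("EEGMontage with", length(object@labels), "electrodes:",
      paste(head(object@labels, 4), collapse = ", "), "...",
      tail(object@labels, 1), "\n")
})

# Indices of the k nearest montage neighbours of an electrode (excluding it).
.nearestNeighbours <- function(montage, label, k = 2L) {
  p <- montage@positions
  i <- match(label, montage@labels)
  if (is.na(i)) stop("unknown electrode label: ", label)
  d <- sqrt(colSums((t(p) - p[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(k)]
}
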