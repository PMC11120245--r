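# Architecture description, initialisation and forward evaluation of the
# attention CNN. The numerical engine lives in src/cnn.cpp.

#' Architecture description of the attention CNN
#'
#' Returns the fixed layer table of the classifier: four convolutions with a
#' channel-and-frequency attention (CFA) block after the first, three max
#' pools, dropout before the last pool, and a 960 -> 4 linear readout.
#' Paddings (1 for the 3x3 convolution, 2 for the 5x5 ones) are forced by
#' the requirement that convolutions preserve the spatial size.
#'
#' @param cfaEnabled include the CFA block.
#' @param dropout dropout probability applied after conv4.
#' @return list with elements `layers` (data.frame), `dropout`,
#'   `cfaEnabled`, `nClasses`.
#' @export
networkSpec <- function(cfaEnabled = TRUE, dropout = 0.5) {
  layers <- data.frame(
    name   = c("conv1", "cfa_fc1", "cfa_fc2", "pool1", "conv2", "pool2",
               "conv3", "conv4", "dropout", "pool3", "flatten", "fc"),
    type   = c("conv", "linear", "linear", "maxpool", "conv", "maxpool",
               "conv", "conv", "dropout", "maxpool", "flatten", "linear"),
    kernel = c(3, NA, NA, 5, 5, 2, 5, 5, NA, 2, NA, NA),
    stride = c(1, NA, NA, 5, 1, 2, 1, 1, NA, 2, NA, NA),
    pad    = c(1, NA, NA, 0, 2, 0, 2, 2, NA, 0, NA, NA),
    nIn    = c(177, 177, 59, 177, 177, 128, 128, 128, 64, 64, 64, 960),
    nOut   = c(177, 59, 177, 177, 128, 128, 128, 64, 64, 64, 960, 4),
    stringsAsFactors = FALSE)
  if (!cfaEnabled)
    layers <- layers[!grepl("^cfa_", layers$name), , drop = FALSE]
  list(layers = layers, dropout = dropout, cfaEnabled = cfaEnabled,
       nClasses = 4L)
}

#' Trainable parameter counts
#'
#' Counts weights and biases per layer from the architecture table
#' (convolutions: nIn x k^2 x nOut + nOut; linear layers: nIn x nOut +
#' nOut; pooling/dropout/flatten contribute none).
#'
#' @param spec a [networkSpec()] (or a spec with an edited layer table).
#' @return data.frame of per-layer counts with a `total` attribute.
#' @export
countParameters <- function(spec = networkSpec()) {
  ly <- spec$layers
  cnt <- mapply(function(type, k, nIn, nOut) {
    switch(type,
      conv   = nIn * k^2 * nOut + nOut,
      linear = nIn * nOut + nOut,
      0)
  }, ly$type, ly$kernel, ly$nIn, ly$nOut)
  out <- data.frame(layer = ly$name, parameters = as.numeric(cnt))
  attr(out, "total") <- sum(cnt)
  out
}

#' Rectified linear activation
#'
#' `max(x, 0)` elementwise: passes positive inputs unchanged and maps
#' non-positive inputs to zero.
#'
#' @param x numeric vector/matrix/array.
#' @export
relu <- function(x) {
  stopifnot(all(is.finite(x)))
  pmax(x, 0)
}

#' Initialise network weights
#'
#' Uniform fan-in initialisation, `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` per
#' layer, fully determined by `seed`.
#'
#' @param spec a [networkSpec()].
#' @param seed integer seed.
#' @return A [CNNModel-class].
#' @export
initNetwork <- function(spec = networkSpec(), seed = 1L) {
  w <- cpp_init_weights(as.integer(seed), spec$cfaEnabled)
  new("CNNModel", weights = w, spec = spec)
}

setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel: attention CNN (CFA %s), %s trainable parameters\n",
              if (object@spec$cfaEnabled) "enabled" else "disabled",
              format(attr(countParameters(object@spec), "total"),
                     big.mark = ",")))
})

# Coerce stacks input (TFStackSet or 60x100x177xn array) to the engine array.
.stackArray <- function(stacks) {
  if (is(stacks, "TFStackSet")) return(stacks@stacks)
  d <- dim(stacks)
  if (length(d) == 3L) { dim(stacks) <- c(d, 1L); d <- dim(stacks) }
  if (length(d) != 4L || !all(d[1:3] == c(60L, 100L, 177L)))
    stop("shape error: expected stacks of 60 x 100 x 177 (x n)")
  stacks
}

#' Evaluation-mode forward pass
#'
#' Runs the network on a batch of stacks without dropout (deterministic)
#' and returns class probabilities; optionally also the intermediate
#' feature-map shapes actually produced layer by layer.
#'
#' @param model a [CNNModel-class].
#' @param stacks a [TFStackSet-class] or 60 x 100 x 177 x n array.
#' @param returnShapes also return the per-layer (batch, channels, height,
#'   width) shapes.
#' @return matrix n x 4 of class probabilities; with `returnShapes`, a list
#'   with `probs` and `shapes`.
#' @export
forwardNetwork <- function(model, stacks, returnShapes = FALSE) {
  x <- .stackArray(stacks)
  res <- cpp_forward_shapes(x, model@weights, model@spec$cfaEnabled)
  colnames(res$probs) <- COG_STATES
  if (returnShapes) list(probs = res$probs, shapes = res$shapes)
  else res$probs
}

#' Channel-and-frequency attention block, standalone
#'
#' Squeeze-and-excitation-style gating over the 177 scalogram planes:
#' global max pooling and global average pooling are summed into a
#' per-plane statistic, passed through a 177 -> 59 -> 177 perceptron with
#' ReLU after each layer, and squashed with a sigmoid into per-plane
#' weights that rescale the input. Because the sigmoid is applied to a
#' ReLU output (non-negative), all weights lie in [0.5, 1).
#'
#' @param x numeric array h x w x 177 x n (any spatial size; pooling is
#'   global).
#' @param model a [CNNModel-class] whose spec has the CFA block enabled.
#' @return list with `output` (same shape as `x`) and `weights` (n x 177).
#' @export
cfaForward <- function(x, model) {
  if (!model@spec$cfaEnabled) stop("model has no CFA block")
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  w <- model@weights
  cpp_cfa_forward(x, w$cfa_fc1_W, as.numeric(w$cfa_fc1_b),
                  w$cfa_fc2_W, as.numeric(w$cfa_fc2_b))
}
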