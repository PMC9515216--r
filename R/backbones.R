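# Backbone registry. The trainable desk-scale regressor is tiny-cnn;
# the EfficientNet-B0 stage plan and a ResNet-50 ledger are kept as
# faithful architecture descriptions with exact trainable-parameter
# arithmetic (batch-norm scale/shift counted as trainable).

#' The tiny-cnn backbone specification
#'
#' Three same-padded 3x3 convolutions with ReLU, 2x2 max pooling after
#' the first two stages, global average pooling and a linear
#' single-output head. The final convolutional map has resolution
#' `inputSize / 4` and `channels[3]` maps -- the Grad-CAM target layer.
#'
#' @param inputSize `(H, W)`, both divisible by 4.
#' @param channels three stage widths.
#' @param inputChannels 1 for plain images, 2 with a salience channel.
#' @return backbone spec list with a `stagePlan` data.frame.
#' @export
tinyCnnBackbone <- function(inputSize = c(64L, 64L), channels = c(8L, 16L, 16L),
                            inputChannels = 1L) {
  inputSize <- as.integer(inputSize)
  if (any(inputSize %% 4L != 0L)) stop("inputSize must be divisible by 4")
  if (any(inputSize %/% 4L < 4L))
    stop("final feature map must be at least 4x4")
  res <- function(d) sprintf("%dx%d", inputSize[1] %/% d, inputSize[2] %/% d)
  plan <- data.frame(
    operator = c("Conv3x3+ReLU", "MaxPool2", "Conv3x3+ReLU", "MaxPool2",
                 "Conv3x3+ReLU", "GAP+FC"),
    resolution = c(res(1), res(2), res(2), res(4), res(4), "1x1"),
    channels = c(channels[1], channels[1], channels[2], channels[2],
                 channels[3], 1L),
    layers = 1L, stringsAsFactors = FALSE)
  list(name = "tiny-cnn", inputSize = inputSize,
       channels = as.integer(channels),
       inputChannels = as.integer(inputChannels), kernel = 3L,
       stagePlan = plan)
}

#' The EfficientNet-B0 stage plan
#'
#' The nine-stage plan: a 3x3 stem, seven MBConv stages (mobile inverted
#' bottlenecks with squeeze-and-excitation) and the 1x1 conv + pooling +
#' fully connected head, with input resolution 224x224, final feature
#' width 1280 and final feature resolution 7x7.
#'
#' @return backbone spec list with a `stagePlan` data.frame (stage,
#'   operator, resolution, channels, layers).
#' @export
effnetB0Plan <- function() {
  plan <- data.frame(
    stage = 1:9,
    operator = c("Conv3x3", "MBConv1,k3x3", "MBConv6,k3x3", "MBConv6,k5x5",
                 "MBConv6,k3x3", "MBConv6,k5x5", "MBConv6,k5x5",
                 "MBConv6,k3x3", "Conv1x1&Pooling&FC"),
    resolution = c("224x224", "112x112", "112x112", "56x56", "28x28",
                   "14x14", "14x14", "7x7", "7x7"),
    channels = c(32L, 16L, 24L, 24L, 80L, 112L, 192L, 320L, 1280L),
    layers = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 1L, 1L),
    stringsAsFactors = FALSE)
  list(name = "effnet-b0-plan", inputSize = c(224L, 224L),
       inputChannels = 3L, stagePlan = plan)
}

# Trainable parameters of one MBConv block (expansion e, kernel k,
# squeeze-and-excitation reduction 1/4 of the block input width, batch
# norm after every conv, biases only in the SE convs).
mbconvParams <- function(cin, cout, e, k) {
  cm <- cin * e
  n <- 0
  if (e != 1) n <- n + cin * cm + 2 * cm          # expand 1x1 + BN
  n <- n + k * k * cm + 2 * cm                    # depthwise + BN
  cs <- max(1L, cin %/% 4L)                       # SE squeeze width
  n <- n + (cm * cs + cs) + (cs * cm + cm)        # SE reduce/expand, biased
  n + cm * cout + 2 * cout                        # project 1x1 + BN
}

effnetB0Params <- function(numClasses = 1000L) {
  stages <- list(  # (expansion, kernel, cout, layers)
    c(1, 3, 16, 1), c(6, 3, 24, 2), c(6, 5, 40, 2), c(6, 3, 80, 3),
    c(6, 5, 112, 3), c(6, 5, 192, 4), c(6, 3, 320, 1))
  n <- 3 * 3 * 3 * 32 + 2 * 32                    # stem conv + BN
  cin <- 32
  for (s in stages) {
    e <- s[1]; k <- s[2]; cout <- s[3]; L <- s[4]
    for (l in seq_len(L)) {
      n <- n + mbconvParams(cin, cout, e, k)
      cin <- cout
    }
  }
  n <- n + 320 * 1280 + 2 * 1280                  # head 1x1 conv + BN
  n + 1280 * numClasses + numClasses              # FC
}

# ResNet-50 bottleneck ledger (1000-way head): 7x7 stem, four stages of
# [3, 4, 6, 3] bottlenecks, 1x1 downsample projections, BN everywhere,
# biased FC.
resnet50Params <- function(numClasses = 1000L) {
  bott <- function(cin, p) {
    n <- cin * p + 2 * p +                        # 1x1 reduce + BN
      9 * p * p + 2 * p +                         # 3x3 + BN
      p * 4 * p + 8 * p                           # 1x1 expand + BN
    n
  }
  n <- 7 * 7 * 3 * 64 + 2 * 64                    # stem + BN
  cin <- 64
  for (st in list(c(64, 3), c(128, 4), c(256, 6), c(512, 3))) {
    p <- st[1]; blocks <- st[2]
    for (b in seq_len(blocks)) {
      n <- n + bott(cin, p)
      if (b == 1) n <- n + cin * 4 * p + 8 * p    # downsample proj + BN
      cin <- 4 * p
    }
  }
  n + 2048 * numClasses + numClasses
}

#' Count trainable parameters
#'
#' For a trained [AgeModel-class] the count sums the actual weight
#' arrays; for a backbone spec or registry name it is computed from the
#' architecture ledger. Registry names: `"tiny-cnn"`, `"effnet-b0"`,
#' `"resnet50"`.
#'
#' @param x an [AgeModel-class], a backbone spec list, or a registry
#'   name.
#' @param ... for registry names, passed on (e.g. `numClasses`).
#' @return integer parameter count.
#' @export
setGeneric("countParameters", function(x, ...)
  standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "AgeModel", function(x, ...)
  sum(vapply(x@weights, length, integer(1))))

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(x, ...) {
  if (identical(x$name, "tiny-cnn")) return(tinyCnnParams(x))
  if (identical(x$name, "effnet-b0-plan")) return(effnetB0Params(...))
  stop("cannot count parameters for backbone: ", x$name)
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "character", function(x, ...) {
  switch(x,
    "resnet50" = resnet50Params(...),
    "effnet-b0" = effnetB0Params(...),
    "tiny-cnn" = tinyCnnParams(tinyCnnBackbone()),
    stop("unknown backbone name: ", x))
})

tinyCnnParams <- function(backbone) {
  ch <- c(backbone$inputChannels, backbone$channels)
  n <- 0L
  for (i in 1:3) n <- n + 9L * ch[i] * ch[i + 1] + ch[i + 1]
  n + ch[4] + 1L                                  # FC weight + bias
}
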