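#' @include AllClasses.R nn.R map-indices.R
NULL

#' Configuration of the compact convolutional-transformer map encoder
#'
#' A deliberately small CNN-to-transformer architecture sized for CPU
#' training on a few hundred 64x64 maps in minutes: a two-layer strided
#' convolutional stem (3x3, stride 2), 4x4 patch tokenization with a
#' learned positional embedding, transformer blocks (pre-layer-norm
#' multi-head self-attention plus an MLP), mean pooling and a projection to
#' a unit-norm embedding. Training aligns map embeddings with two jointly
#' learned diagnosis-node embeddings via a symmetric InfoNCE loss, using
#' SGD with momentum, plateau-based learning-rate decay and early stopping
#' on validation loss. All sizes, the contrastive temperature and the
#' schedule are configuration.
#'
#' @param gridSize input grid edge length (pixels).
#' @param convChannels integer(2): channels of the two conv layers.
#' @param patch patch edge length for tokenization.
#' @param blocks,heads,dim transformer depth, attention heads, embedding dim.
#' @param mlpDim hidden width of the per-block MLP.
#' @param temperature contrastive softmax temperature.
#' @param lr,momentum,lrDecay,lrPatience SGD learning rate, momentum, the
#'   factor applied when validation loss plateaus and the plateau length.
#' @param patience early-stopping patience (epochs without val improvement).
#' @param maxEpochs,batchSize,valFraction training-loop sizes.
#' @param seed mandatory integer seed (initialization, split, shuffling).
#' @return a validated configuration list.
#' @export
encoderConfig <- function(gridSize = 64, convChannels = c(8, 16), patch = 4,
                          blocks = 2, heads = 4, dim = 64, mlpDim = 128,
                          temperature = 0.1, lr = 0.05, momentum = 0.9,
                          lrDecay = 0.5, lrPatience = 3, patience = 5,
                          maxEpochs = 40, batchSize = 32, valFraction = 0.2,
                          seed) {
  if (missing(seed) || !num1(seed)) stop("a scalar integer seed is mandatory")
  vals <- c(gridSize, convChannels, patch, blocks, heads, dim, mlpDim,
            temperature, lr, lrDecay, lrPatience, patience, maxEpochs,
            batchSize, valFraction)
  if (any(vals <= 0)) stop("all encoder configuration sizes must be positive")
  if (dim %% heads != 0) stop("dim must be divisible by heads")
  stemOut <- gridSize / 4            # two stride-2 convs
  if (stemOut %% patch != 0)
    stop("gridSize/4 must be divisible by the patch size")
  cfg <- list(gridSize = as.integer(gridSize),
              convChannels = as.integer(convChannels),
              patch = as.integer(patch), blocks = as.integer(blocks),
              heads = as.integer(heads), dim = as.integer(dim),
              mlpDim = as.integer(mlpDim), temperature = temperature,
              lr = lr, momentum = momentum, lrDecay = lrDecay,
              lrPatience = as.integer(lrPatience),
              patience = as.integer(patience),
              maxEpochs = as.integer(maxEpochs),
              batchSize = as.integer(batchSize), valFraction = valFraction,
              seed = as.integer(seed))
  cfg$nTokens <- as.integer((stemOut / patch)^2)
  cfg$patchDim <- as.integer(patch^2 * convChannels[2])
  cfg
}

ENCODER_CLASSES <- c("normal_cornea", "early_keratoconus")

# fixed input normalization on the clinical color scale midpoint
normalizeMapInput <- function(values) (values - 45) / 7

mapToInput <- function(m, cfg, resample = TRUE) {
  v <- if (is(m, "CurvatureMap")) {
    if (nrow(m@values) != cfg$gridSize) {
      if (!resample)
        stop("map grid ", nrow(m@values), " does not match encoder grid ",
             cfg$gridSize, " and resampling is disabled")
      m <- resampleMap(m, cfg$gridSize)
    }
    m@values
  } else as.matrix(m)
  if (nrow(v) != cfg$gridSize)
    stop("map grid does not match the configured encoder grid size")
  normalizeMapInput(v)
}

labelToClassIndex <- function(labels) {
  lab <- as.character(labels)
  lab[lab == "normal"] <- "normal_cornea"
  lab[lab == "early_kc"] <- "early_keratoconus"
  idx <- match(lab, ENCODER_CLASSES)
  if (anyNA(idx))
    stop("labels must be normal/early_kc (or the diagnosis node ids)")
  idx
}

#' Train the map encoder with contrastive feature-to-knowledge alignment
#'
#' Trains the compact CNN-transformer encoder of [encoderConfig()] so that
#' curvature-map embeddings align with the embeddings of their labeled
#' diagnosis node (normal cornea vs early keratoconus), which are learned
#' jointly, under a symmetric InfoNCE objective. The labeled data are split
#' into training and validation folds (stratified, seeded); validation
#' labels are only ever read through the early-stopping loss. Training is
#' single-threaded and fully seeded, hence reproducible bit-for-bit.
#'
#' @param maps list of [CurvatureMap-class] (or numeric grids).
#' @param labels class labels parallel to \code{maps} ("normal" /
#'   "early_kc"); both classes must be present.
#' @param g a [KnowledgeGraph-class] carrying the two diagnosis nodes.
#' @param cfg an [encoderConfig()].
#' @return a [TrainedEncoder-class] (parameters at the best validation
#'   loss, training history, config snapshot).
#' @export
trainEncoder <- function(maps, labels, g = buildDefaultGraph(), cfg) {
  y <- labelToClassIndex(labels)
  if (length(unique(y)) < 2)
    stop("training requires both diagnosis classes to be present")
  if (!all(ENCODER_CLASSES %in% graphNodes(g)$node_id))
    stop("graph lacks the diagnosis nodes the encoder aligns to")
  plans <- encoderPlans(cfg)
  X <- lapply(maps, mapToInput, cfg = cfg)
  n <- length(X)
  withSeed(cfg$seed, {
    # stratified validation split
    val <- unlist(lapply(split(seq_len(n), y), function(ix) {
      nv <- max(1L, round(length(ix) * cfg$valFraction))
      sample(ix, nv)
    }), use.names = FALSE)
    tr <- setdiff(seq_len(n), val)
    if (!length(tr)) stop("no training samples left after validation split")
    p <- initEncoderParams(cfg)
    vel <- zeroLike(p)
    lr <- cfg$lr
    best <- list(loss = Inf, params = p)
    bad <- 0L; sinceDecay <- 0L
    hist <- list()
    valLoss <- function(p) {
      Z <- t(vapply(val, function(i) encForward(X[[i]], p, cfg, plans)$z,
                    numeric(cfg$dim)))
      infoNCE(Z, p$node_E, y[val], cfg$temperature)$loss
    }
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample(tr)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
      epLoss <- 0
      for (b in batches) {
        fw <- lapply(b, function(i) encForward(X[[i]], p, cfg, plans))
        Z <- t(vapply(fw, `[[`, numeric(cfg$dim), "z"))
        nce <- infoNCE(Z, p$node_E, y[b], cfg$temperature)
        if (!is.finite(nce$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (lr = ", lr, "); try a smaller learning rate")
        epLoss <- epLoss + nce$loss * length(b)
        grads <- zeroLike(p)
        for (j in seq_along(b))
          grads <- encBackward(nce$dZ[j, ], p, cfg, plans, fw[[j]]$cache, grads)
        grads$node_E <- grads$node_E + nce$dE
        for (nm in names(p)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] - lr * grads[[nm]]
          p[[nm]] <- p[[nm]] + vel[[nm]]
        }
      }
      vl <- valLoss(p)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = epLoss / length(tr),
                                  val_loss = vl, lr = lr)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = p)
        bad <- 0L; sinceDecay <- 0L
      } else {
        bad <- bad + 1L; sinceDecay <- sinceDecay + 1L
        if (sinceDecay >= cfg$lrPatience) {
          lr <- lr * cfg$lrDecay
          sinceDecay <- 0L
        }
        if (bad >= cfg$patience) break
      }
    }
    new("TrainedEncoder", params = best$params, config = cfg,
        history = do.call(rbind, hist), classes = ENCODER_CLASSES)
  })
}

#' Embed a curvature map
#'
#' Deterministic forward pass through a trained encoder, returning the
#' unit-norm embedding vector. Maps whose grid differs from the configured
#' input size are bilinearly resampled unless \code{resample = FALSE}.
#'
#' @param m a [CurvatureMap-class].
#' @param enc a [TrainedEncoder-class].
#' @param resample allow automatic grid resampling.
#' @return numeric embedding of length \code{config dim}, unit norm.
#' @export
encodeMap <- function(m, enc, resample = TRUE) {
  stopifnot(is(enc, "TrainedEncoder"))
  x <- mapToInput(m, enc@config, resample = resample)
  encForward(x, enc@params, enc@config, encoderPlans(enc@config))$z
}

#' Neural keratoconus score of a curvature map
#'
#' Softmax over the cosine similarities between the map embedding and the
#' two learned diagnosis-node embeddings (at the configured contrastive
#' temperature); returns the early-keratoconus component, a probability-like
#' score in (0, 1) that complements to 1 with the normal-cornea component.
#'
#' @inheritParams encodeMap
#' @return scalar score in (0, 1).
#' @export
neuralScore <- function(m, enc, resample = TRUE) {
  z <- encodeMap(m, enc, resample = resample)
  E <- enc@params$node_E
  if (is.null(E) || nrow(E) != 2) stop("encoder is missing node embeddings")
  Nn <- E / sqrt(rowSums(E^2))
  s <- as.numeric(Nn %*% z) / enc@config$temperature
  e <- exp(s - max(s))
  (e / sum(e))[match("early_keratoconus", enc@classes)]
}
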