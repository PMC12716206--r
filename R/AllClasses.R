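# Central S4 classes. Height maps and masks are small wrappers around plain
# matrices so that validity (finiteness, normalization state, binarity) is
# checked once at construction and every downstream operation can rely on it.

#' HeightMap: a single-channel SICM topography image
#'
#' A rectangular grid of heights with the slow-scan (Y) axis along rows --
#' row 1 is the first scanned line -- and the fast (X) axis along columns.
#' Heights are either in raw physical units (micrometres by convention) or
#' min-max normalized to \code{[0, 1]}; the normalization records the original
#' (min, max) so it can be inverted exactly.
#'
#' @slot values numeric matrix of heights.
#' @slot pixelSize physical length per pixel in micrometres (\code{NA} if
#'   unknown); metadata only, never used by the models.
#' @slot normState \code{"raw"} or \code{"unit_normalized"}.
#' @slot normParams numeric length-2 \code{(min, max)} recorded at
#'   normalization; \code{NA} while raw.
#'
#' @seealso [HeightMap()], [normalizeMap()], [readHeightMap()]
#' @export
setClass("HeightMap",
  slots = c(values = "matrix", pixelSize = "numeric",
            normState = "character", normParams = "numeric"))

setValidity("HeightMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("values must be non-empty")
  if (anyNA(v) || any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)
    return(sprintf("non-finite heights at [%d, %d]%s",
                   bad[1L, 1L], bad[1L, 2L],
                   if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L) else ""))
  }
  if (!object@normState %in% c("raw", "unit_normalized"))
    return("normState must be 'raw' or 'unit_normalized'")
  if (length(object@normParams) != 2L) return("normParams must have length 2")
  if (object@normState == "unit_normalized") {
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
      return("unit_normalized heights must lie in [0, 1]")
    if (anyNA(object@normParams)) return("normParams required once normalized")
  }
  TRUE
})

#' Construct a HeightMap
#'
#' @param values numeric matrix (rows = slow-scan lines, top line first).
#' @param pixelSize physical pixel size in micrometres, or \code{NA}.
#' @param normState \code{"raw"} (default) or \code{"unit_normalized"}.
#' @param normParams length-2 numeric \code{(min, max)}; required when
#'   \code{normState = "unit_normalized"}.
#' @return a \linkS4class{HeightMap}.
#' @examples
#' h <- HeightMap(matrix(runif(16), 4))
#' dim(h)
#' @export
HeightMap <- function(values, pixelSize = NA_real_, normState = "raw",
                      normParams = c(NA_real_, NA_real_)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  methods::new("HeightMap", values = values, pixelSize = as.numeric(pixelSize),
               normState = normState, normParams = as.numeric(normParams))
}

#' LineMask: the per-line scan/skip plan
#'
#' A boolean keep vector over slow-axis lines: \code{TRUE} lines are scanned,
#' \code{FALSE} lines are skipped. Masks generated for acquisition always keep
#' the first and last lines (anchoring interpolation and the inpainting
#' boundary) and skip exactly \code{round(p * m)} lines (round half up).
#' Masks extracted from scar detection use \code{pattern = "scar"} and are
#' exempt from those two rules.
#'
#' @slot keep logical vector, one element per scan line.
#' @slot fraction the masked (skipped) fraction p requested or observed.
#' @slot pattern provenance: one of \code{"random"}, \code{"random_limited"},
#'   \code{"fixed_distance"}, \code{"geometric"}, \code{"block"},
#'   \code{"scar"}, \code{"manual"}.
#' @slot maxConsecutive limit on consecutive skipped lines
#'   (\code{Inf} = unlimited).
#' @slot seed RNG seed used for random patterns (\code{NA} otherwise).
#' @export
setClass("LineMask",
  slots = c(keep = "logical", fraction = "numeric", pattern = "character",
            maxConsecutive = "numeric", seed = "numeric"))

.acqPatterns <- c("random", "random_limited", "fixed_distance", "geometric", "block")

setValidity("LineMask", function(object) {
  k <- object@keep
  if (length(k) < 1L || anyNA(k)) return("keep must be NA-free and non-empty")
  if (object@pattern %in% .acqPatterns) {
    if (!k[1L] || !k[length(k)])
      return("first and last lines must be scanned")
    expected <- roundHalfUp(object@fraction * length(k))
    if (sum(!k) != expected)
      return(sprintf("mask skips %d lines but round(p*m) = %d", sum(!k), expected))
    if (is.finite(object@maxConsecutive)) {
      runs <- rle(k)
      if (any(runs$lengths[!runs$values] > object@maxConsecutive))
        return("a skipped run exceeds maxConsecutive")
    }
  }
  TRUE
})

#' MaskRaster: the 2D binary expansion of a line mask
#'
#' @slot values numeric 0/1 matrix; 1 = scanned/valid, 0 = skipped.
#' @export
setClass("MaskRaster", slots = c(values = "matrix"))

setValidity("MaskRaster", function(object) {
  v <- object@values
  if (!all(v %in% c(0, 1))) return("mask raster must be strictly binary")
  TRUE
})

#' @rdname MaskRaster-class
#' @param values numeric or logical matrix of 0/1.
#' @return a \linkS4class{MaskRaster}.
#' @export
MaskRaster <- function(values) {
  v <- as.matrix(values) * 1
  methods::new("MaskRaster", values = v)
}

#' ScanSignal: the modified slow-axis (Y) waveform
#'
#' Sampled piecewise-linear waveform of slow-axis position against time.
#' During each scanned line the position ramps toward the next scanned line;
#' across a run of k skipped lines the ramp advances k + 1 lines within one
#' line period (a steeper slope rather than a step, avoiding piezo creep).
#'
#' @slot time sample times in seconds.
#' @slot position slow-axis position in line units (non-decreasing).
#' @slot linePeriod seconds per scanned line.
#' @slot totalTime linePeriod x number of scanned lines.
#' @slot rampPolicy currently \code{"ramped"}.
#' @export
setClass("ScanSignal",
  slots = c(time = "numeric", position = "numeric", linePeriod = "numeric",
            totalTime = "numeric", rampPolicy = "character"))

setValidity("ScanSignal", function(object) {
  if (is.unsorted(object@position)) return("position must be non-decreasing")
  if (is.unsorted(object@time, strictly = TRUE)) return("time must be increasing")
  if (object@linePeriod <= 0) return("linePeriod must be positive")
  TRUE
})

#' SceneParams: parameters of the synthetic SICM topography generator
#'
#' Defaults emulate adherent cells imaged by hopping-mode SICM: a gently
#' tilted substrate, 1--3 smooth cell-body elevations of a few micrometres,
#' thin curvilinear processes (neurite/filopodium-like ridges) of tens to
#' hundreds of nanometres, band-limited membrane texture, a per-line offset
#' noise (SICM acquires line by line) and per-pixel sensor noise.
#'
#' @slot imageSize integer (rows, cols).
#' @slot nCellBodies number of cell-body bumps.
#' @slot bodyHeightRange micrometres, sampled uniformly per body.
#' @slot bodyRadiusRange pixels, sampled uniformly per body.
#' @slot nRidges number of curvilinear processes.
#' @slot ridgeHeightRange micrometres.
#' @slot ridgeWidthRange pixels (Gaussian cross-section sigma).
#' @slot backgroundTilt maximum substrate slope in micrometres per pixel.
#' @slot textureAmplitude micrometres (sd of the band-limited texture).
#' @slot lineNoiseSd micrometres, per-row offset noise sd.
#' @slot pixelNoiseSd micrometres, per-pixel noise sd.
#' @slot seed RNG seed.
#' @export
setClass("SceneParams",
  slots = c(imageSize = "integer", nCellBodies = "integer",
            bodyHeightRange = "numeric", bodyRadiusRange = "numeric",
            nRidges = "integer", ridgeHeightRange = "numeric",
            ridgeWidthRange = "numeric", backgroundTilt = "numeric",
            textureAmplitude = "numeric", lineNoiseSd = "numeric",
            pixelNoiseSd = "numeric", seed = "numeric"))

setValidity("SceneParams", function(object) {
  if (any(object@imageSize < 16L)) return("imageSize must be >= 16 in each dimension")
  rng <- c(object@bodyHeightRange, object@bodyRadiusRange,
           object@ridgeHeightRange, object@ridgeWidthRange,
           object@backgroundTilt, object@textureAmplitude,
           object@lineNoiseSd, object@pixelNoiseSd)
  if (any(rng < 0)) return("all amplitude/size parameters must be non-negative")
  if (object@nCellBodies < 0L || object@nRidges < 0L)
    return("feature counts must be non-negative")
  TRUE
})

#' ScarSpec: where and how scan-line artifacts are planted
#'
#' @slot nScars number of scar events.
#' @slot scarRows explicit 1-based row indices (empty = sample at random);
#'   explicit rows are displaced individually (width 1).
#' @slot scarWidthRange consecutive rows per randomly placed scar event
#'   (feedback overshoot typically affects several lines). Default 1--3.
#' @slot scarLengthRange scar length in pixels; \code{c(NA, NA)} = full row.
#' @slot scarOffsetRange micrometres; magnitude of the displacement, sign
#'   chosen at random per event.
#' @slot seed RNG seed.
#' @export
setClass("ScarSpec",
  slots = c(nScars = "integer", scarRows = "numeric",
            scarWidthRange = "numeric", scarLengthRange = "numeric",
            scarOffsetRange = "numeric", seed = "numeric"))

#' ModelConfig: architecture description of the encoder-decoder
#'
#' @slot arch \code{"cnn"} (masked image only; mask internally all-valid) or
#'   \code{"partial_cnn"} (image + mask inputs, partial convolutions with
#'   dynamically updated mask).
#' @slot filters encoder filter ladder (mirrored in the decoder); the default
#'   full-scale ladder is 64..512 over four stages.
#' @slot dropout dropout rate applied at the bottleneck (default 0.20).
#' @slot kernel integer (kh, kw) convolution kernel size; the default 5 x 3
#'   gives extra slow-axis (vertical) context, matching the row geometry of
#'   line masks.
#' @slot inputSize integer (rows, cols); must be divisible by
#'   2^length(filters).
#' @export
setClass("ModelConfig",
  slots = c(arch = "character", filters = "integer", dropout = "numeric",
            kernel = "integer", inputSize = "integer"))

setValidity("ModelConfig", function(object) {
  if (!object@arch %in% c("cnn", "partial_cnn"))
    return("arch must be 'cnn' or 'partial_cnn'")
  f <- object@filters
  if (length(f) < 1L || any(diff(f) < 0L))
    return("filter ladder must be non-decreasing")
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  k <- object@kernel
  if (length(k) != 2L || any(k < 1L) || any(k %% 2L == 0L))
    return("kernel must be a pair of odd positive sizes")
  d <- 2L^length(f)
  if (any(object@inputSize %% d != 0L))
    return(sprintf("inputSize must be divisible by 2^depth = %d", d))
  TRUE
})

#' LossConfig: combined structural + pixel loss
#'
#' The training objective is
#' \code{alpha * (1 - meanSSIM(y_true, y_pred)) + (1 - alpha) * MSE(y_true, y_pred)}.
#'
#' @slot alpha mixing weight of the structural term (default 0.96).
#' @slot ssimWindow odd uniform-window size for SSIM (default 7).
#' @export
setClass("LossConfig", slots = c(alpha = "numeric", ssimWindow = "integer"))

setValidity("LossConfig", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
  if (object@ssimWindow < 3L || object@ssimWindow %% 2L == 0L)
    return("ssimWindow must be odd and >= 3")
  TRUE
})

#' TrainConfig: optimization and data-split settings
#'
#' @slot batchSize minibatch size (default 16).
#' @slot learningRate Adam step size (default 0.0005).
#' @slot folds number of cross-validation folds over the non-test images
#'   (default 3; 1 = single train/validation split).
#' @slot valFraction validation fraction when folds = 1 (default 0.2).
#' @slot maxEpochs epoch budget.
#' @slot patience early-stopping patience on validation loss.
#' @slot pRange masked-fraction range for training masks (default 0.30-0.35).
#' @slot lrDecay multiplicative learning-rate factor applied when the
#'   validation loss has not improved for half the patience (1 = constant).
#' @slot emaDecay per-step decay of the Polyak (exponential moving) average
#'   of the weights; the averaged weights are validated and returned
#'   (0 = off).
#' @slot warmupEpochs linear learning-rate warmup over the first epochs.
#' @slot clipNorm global gradient-norm clip (Inf = off).
#' @slot cropCols train on random vertical strips of this many columns
#'   instead of full frames (NA = full frames); strips keep every scan line,
#'   so line-mask geometry is unchanged.
#' @slot seed RNG seed.
#' @export
setClass("TrainConfig",
  slots = c(batchSize = "integer", learningRate = "numeric", folds = "integer",
            valFraction = "numeric", maxEpochs = "integer", patience = "integer",
            pRange = "numeric", lrDecay = "numeric", emaDecay = "numeric",
            cropCols = "numeric", warmupEpochs = "integer", clipNorm = "numeric",
            seed = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@folds < 1L) return("folds must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (length(object@pRange) != 2L || any(object@pRange < 0) ||
      any(object@pRange >= 1) || diff(object@pRange) < 0)
    return("pRange must be an increasing pair in [0, 1)")
  TRUE
})

#' InpaintingModel: a (possibly trained) encoder-decoder
#'
#' @slot config the \linkS4class{ModelConfig}.
#' @slot weights list of parameter arrays (opaque; use [trainModel()] /
#'   [reconstruct()]).
#' @slot history per-epoch training/validation losses per fold.
#' @slot trained logical.
#' @export
setClass("InpaintingModel",
  slots = c(config = "ModelConfig", weights = "list", history = "data.frame",
            trained = "logical"))

#' MetricsReport: the evaluation panel for original/reconstruction pairs
#'
#' @slot metrics one row per pair with columns \code{mse}, \code{psnr},
#'   \code{ssim}, \code{pearson}, \code{edge_density_orig},
#'   \code{edge_density_recon}, \code{freq_ratio}.
#' @slot n number of pairs aggregated.
#' @export
setClass("MetricsReport", slots = c(metrics = "data.frame", n = "integer"))

#' SweepResult: reconstruction quality across masking fractions
#'
#' @slot table data.frame with columns \code{fraction}, \code{metric},
#'   \code{mean}, \code{sd}, \code{n}.
#' @slot replicates replicate masks per fraction.
#' @export
setClass("SweepResult", slots = c(table = "data.frame", replicates = "integer"))

#' BreakpointFit: continuous 3-segment piecewise-linear fit
#'
#' @slot breakpoints the two interior break abscissae, ascending (primary,
#'   secondary).
#' @slot slopes per-segment slopes (length 3).
#' @slot intercepts per-segment intercepts (length 3).
#' @slot residual residual sum of squares of the fit.
#' @slot r2 coefficient of determination.
#' @slot identifiable FALSE when the data are (near) collinear and the break
#'   locations are not determined.
#' @slot x,y the fitted data.
#' @export
setClass("BreakpointFit",
  slots = c(breakpoints = "numeric", slopes = "numeric", intercepts = "numeric",
            residual = "numeric", r2 = "numeric", identifiable = "logical",
            x = "numeric", y = "numeric"))

setValidity("BreakpointFit", function(object) {
  b <- object@breakpoints
  if (length(b) != 2L || b[1L] >= b[2L]) return("breakpoints must be ascending pair")
  TRUE
})
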