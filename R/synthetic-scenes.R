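# Synthetic SICM-like cell topography. The generator composes, in raw
# micrometre units: a tilted substrate plane, smooth Gaussian cell-body
# elevations, curvilinear ridge-like processes (smoothed random walks,
# emulating neurites/filopodia), band-limited membrane texture, a per-row
# offset noise (SICM acquires line by line, so each scan line carries its own
# small height offset) and per-pixel sensor noise.

#' Construct scene parameters
#'
#' Defaults describe a 256 x 256 frame of adherent cells: 1-3 cell bodies of
#' 1-5 um height and 20-60 px radius, 2-5 processes of 0.05-0.3 um height,
#' 20 nm per-line offset noise and 5 nm pixel noise. For smaller frames pass
#' a proportionally smaller \code{bodyRadiusRange}.
#'
#' @param imageSize integer (rows, cols), each >= 16.
#' @param nCellBodies number of cell bodies (sampled positions/sizes).
#' @param bodyHeightRange,bodyRadiusRange uniform sampling ranges (um, px).
#' @param nRidges number of ridge-like processes.
#' @param ridgeHeightRange,ridgeWidthRange uniform sampling ranges (um, px).
#' @param backgroundTilt maximum substrate slope (um per px).
#' @param textureAmplitude sd of band-limited surface texture (um).
#' @param lineNoiseSd per-row offset noise sd (um).
#' @param pixelNoiseSd per-pixel noise sd (um).
#' @param seed RNG seed.
#' @return a \linkS4class{SceneParams}.
#' @export
sceneParams <- function(imageSize = c(256L, 256L), nCellBodies = 3L,
                        bodyHeightRange = c(1, 5), bodyRadiusRange = c(20, 60),
                        nRidges = 4L, ridgeHeightRange = c(0.05, 0.3),
                        ridgeWidthRange = c(2, 5), backgroundTilt = 0.002,
                        textureAmplitude = 0.03, lineNoiseSd = 0.02,
                        pixelNoiseSd = 0.005, seed = 1L) {
  methods::new("SceneParams", imageSize = as.integer(imageSize),
               nCellBodies = as.integer(nCellBodies),
               bodyHeightRange = as.numeric(bodyHeightRange),
               bodyRadiusRange = as.numeric(bodyRadiusRange),
               nRidges = as.integer(nRidges),
               ridgeHeightRange = as.numeric(ridgeHeightRange),
               ridgeWidthRange = as.numeric(ridgeWidthRange),
               backgroundTilt = as.numeric(backgroundTilt),
               textureAmplitude = as.numeric(textureAmplitude),
               lineNoiseSd = as.numeric(lineNoiseSd),
               pixelNoiseSd = as.numeric(pixelNoiseSd),
               seed = as.numeric(seed))
}

#' Construct a scar specification
#'
#' @param nScars number of scar events to plant.
#' @param scarRows explicit 1-based rows (default: sampled interior events);
#'   explicit rows are displaced individually (width 1).
#' @param scarWidthRange consecutive rows per random event (default 1--3,
#'   emulating multi-line feedback overshoot).
#' @param scarLengthRange scar segment length in pixels, or \code{c(NA, NA)}
#'   for full-row scars (the default).
#' @param scarOffsetRange magnitude range of the height displacement (um);
#'   the sign of each event is random and its rows share the offset up to
#'   20 % per-row jitter.
#' @param seed RNG seed.
#' @return a \linkS4class{ScarSpec}.
#' @export
scarSpec <- function(nScars = 3L, scarRows = numeric(0L),
                     scarWidthRange = c(1, 3),
                     scarLengthRange = c(NA_real_, NA_real_),
                     scarOffsetRange = c(0.3, 1), seed = 1L) {
  methods::new("ScarSpec", nScars = as.integer(nScars),
               scarRows = as.numeric(scarRows),
               scarWidthRange = as.numeric(scarWidthRange),
               scarLengthRange = as.numeric(scarLengthRange),
               scarOffsetRange = as.numeric(scarOffsetRange),
               seed = as.numeric(seed))
}

.runif1 <- function(range) if (range[1L] == range[2L]) range[1L] else stats::runif(1L, range[1L], range[2L])

#' Generate one synthetic SICM topography scene
#'
#' Deterministic for a fixed seed. Heights are raw micrometres; normalize
#' with [normalizeMap()] before feeding models.
#'
#' @param p a \linkS4class{SceneParams}.
#' @return a raw \linkS4class{HeightMap}.
#' @examples
#' h <- generateScene(sceneParams(imageSize = c(64, 64), seed = 7))
#' @export
generateScene <- function(p) {
  stopifnot(methods::is(p, "SceneParams"))
  m <- p@imageSize[1L]
  n <- p@imageSize[2L]
  withSeed(p@seed, {
    v <- matrix(0, m, n)
    # substrate tilt in a random direction
    if (p@backgroundTilt > 0) {
      theta <- stats::runif(1L, 0, 2 * pi)
      slope <- stats::runif(1L, 0, p@backgroundTilt)
      ri <- matrix(seq_len(m), m, n)
      ci <- matrix(seq_len(n), m, n, byrow = TRUE)
      v <- v + slope * (cos(theta) * ri + sin(theta) * ci)
    }
    # cell bodies: smooth Gaussian bumps
    if (p@nCellBodies > 0L) {
      for (b in seq_len(p@nCellBodies)) {
        amp <- .runif1(p@bodyHeightRange)
        rad <- .runif1(p@bodyRadiusRange)
        cy <- stats::runif(1L, 0.2 * m, 0.8 * m)
        cx <- stats::runif(1L, 0.2 * n, 0.8 * n)
        if (amp > 0 && rad > 0) {
          sig <- rad / 2
          dy2 <- (seq_len(m) - cy)^2
          dx2 <- (seq_len(n) - cx)^2
          v <- v + amp * exp(-outer(dy2, dx2, "+") / (2 * sig^2))
        }
      }
    }
    # ridge-like processes: smoothed random-walk paths rasterized then blurred
    if (p@nRidges > 0L) {
      for (r in seq_len(p@nRidges)) {
        amp <- .runif1(p@ridgeHeightRange)
        wid <- .runif1(p@ridgeWidthRange)
        len <- round(stats::runif(1L, 0.3, 0.8) * min(m, n) * 2)  # path samples
        y <- stats::runif(1L, 1, m)
        x <- stats::runif(1L, 1, n)
        ang <- stats::runif(1L, 0, 2 * pi)
        turn <- stats::rnorm(len, 0, 0.08)
        canvas <- matrix(0, m, n)
        for (s in seq_len(len)) {
          ang <- ang + turn[s]
          y <- y + 0.5 * sin(ang)
          x <- x + 0.5 * cos(ang)
          iy <- round(y)
          ix <- round(x)
          if (iy < 1 || iy > m || ix < 1 || ix > n) break
          canvas[iy, ix] <- 1
        }
        if (amp > 0 && wid > 0 && any(canvas > 0)) {
          ridge <- gaussBlur(canvas, wid / 2)
          v <- v + amp * ridge / max(ridge)
        }
      }
    }
    # band-limited membrane texture (correlation length ~2 px)
    if (p@textureAmplitude > 0) {
      tex <- gaussBlur(matrix(stats::rnorm(m * n), m, n), 2)
      v <- v + p@textureAmplitude * tex / stats::sd(tex)
    }
    # per-line offsets then pixel noise
    if (p@lineNoiseSd > 0) v <- v + stats::rnorm(m, 0, p@lineNoiseSd)
    if (p@pixelNoiseSd > 0) v <- v + matrix(stats::rnorm(m * n, 0, p@pixelNoiseSd), m, n)
    HeightMap(v)
  })
}

#' Plant scan-line artifacts (scars) into a height map
#'
#' Selected rows (or row segments) are displaced by a sampled offset,
#' emulating pipette overshoot from feedback delays. Pixels outside the scars
#' are bit-identical to the input. The returned mask is the exact ground
#' truth: keep = 0 exactly on the scarred rows.
#'
#' @param h a \linkS4class{HeightMap} (raw or normalized; offsets are applied
#'   in the map's current units).
#' @param s a \linkS4class{ScarSpec}.
#' @return list with elements \code{scarred} (\linkS4class{HeightMap}) and
#'   \code{mask} (\linkS4class{LineMask}, pattern \code{"scar"}).
#' @export
addScars <- function(h, s) {
  stopifnot(methods::is(h, "HeightMap"), methods::is(s, "ScarSpec"))
  v <- h@values
  m <- nrow(v)
  n <- ncol(v)
  if (length(s@scarRows) && (any(s@scarRows < 1) || any(s@scarRows > m)))
    psStop("ps_parameter_error", "scar row out of range")
  keep <- rep(TRUE, m)
  if (s@nScars > 0L) {
    v <- withSeed(s@seed, {
      # each event is a run of consecutive displaced rows sharing one offset
      events <- if (length(s@scarRows)) {
        lapply(as.integer(s@scarRows), function(r) r)
      } else {
        widths <- if (s@scarWidthRange[1L] == s@scarWidthRange[2L])
          rep(as.integer(s@scarWidthRange[1L]), s@nScars)
        else sample(as.integer(s@scarWidthRange[1L]):as.integer(s@scarWidthRange[2L]),
                    s@nScars, replace = TRUE)
        starts <- sample(2:(m - 1L - max(widths)), min(s@nScars, m - 2L))
        Map(function(st, w) st:(st + w - 1L), starts, widths[seq_along(starts)])
      }
      for (rows_i in events) {
        off <- .runif1(s@scarOffsetRange) * sample(c(-1, 1), 1L)
        if (off == 0) off <- s@scarOffsetRange[2L]  # guarantee a displacement
        jitter <- stats::runif(length(rows_i), 0.8, 1.2)
        if (anyNA(s@scarLengthRange)) {
          cols <- seq_len(n)
        } else {
          len <- min(n, max(1L, round(.runif1(s@scarLengthRange))))
          start <- sample(seq_len(n - len + 1L), 1L)
          cols <- start:(start + len - 1L)
        }
        for (j in seq_along(rows_i)) {
          v[rows_i[j], cols] <- v[rows_i[j], cols] + off * jitter[j]
        }
        keep[rows_i] <- FALSE
      }
      v
    })
  }
  scarred <- HeightMap(v, pixelSize = h@pixelSize, normState = h@normState,
                       normParams = h@normParams)
  list(scarred = scarred,
       mask = .newLineMask(keep, mean(!keep), "scar", seed = s@seed))
}

#' Generate a reproducible dataset of synthetic scenes
#'
#' Scene k is drawn with the counter-based sub-seed
#' \code{subSeed(seed, k) = (seed + k * 100003) mod 2147483587}, so datasets
#' are extensible and scene k never depends on n.
#'
#' @param n number of scenes (>= 1).
#' @param p a \linkS4class{SceneParams} template (its own seed is ignored).
#' @param seed dataset seed.
#' @return list of raw \linkS4class{HeightMap}s, length n.
#' @export
generateDataset <- function(n, p, seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n) - 1L, function(k) {
    pk <- p
    pk@seed <- as.numeric(subSeed(seed, k))
    generateScene(pk)
  })
}
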