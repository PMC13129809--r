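#' @include AllClasses.R utils.R
NULL

#' Virtual Landscape Visualization scalar field
#'
#' Interpolates per-node scalar values (a feature's 0-1 normalized
#' response per category) over the atlas embedding: at every grid
#' point p the field is the softmax-weighted average of node values,
#' with weights exp(-d_i/tau) / sum_j exp(-d_j/tau) on the Euclidean
#' distances d_i to the node coordinates. As tau shrinks the field
#' approaches the nearest-node (Voronoi) value map. Histogram
#' normalization rank-transforms the field to uniform [0, 1] (average
#' ranks for ties) to increase visibility of compressed ranges.
#'
#' @param g an \linkS4class{AtlasGraph}.
#' @param nodeValues named numeric vector over the graph's categories,
#'   expected min-max normalized to [0, 1].
#' @param grid integer(2) output (H, W), default c(128, 128).
#' @param temperature softmax temperature tau in embedding-coordinate
#'   units; default 0.05 times the embedding bounding-box diagonal.
#' @param normalization "linear" (convex combination of node values)
#'   or "histogram".
#' @param margin fractional margin added around the node bounding box.
#' @return list: \code{field} (H x W matrix), \code{extent}
#'   (xmin, xmax, ymin, ymax), \code{temperature},
#'   \code{normalization}, \code{nodeValues}.
#' @export
renderVLV <- function(g, nodeValues, grid = c(128L, 128L),
                      temperature = NULL,
                      normalization = c("linear", "histogram"),
                      margin = 0.05) {
  stopifnot(is(g, "AtlasGraph"))
  normalization <- match.arg(normalization)
  nodes <- g@nodes
  if (!nrow(nodes)) stop("graph has no nodes")
  v <- nodeValues[nodes$category]
  if (anyNA(v) || any(!is.finite(v)))
    stop("nodeValues must cover every graph category with finite values")
  dx <- diff(range(nodes$x)); dy <- diff(range(nodes$y))
  diag_ <- sqrt(dx^2 + dy^2)
  if (is.null(temperature)) temperature <- 0.05 * max(diag_, 1e-12)
  if (temperature <= 0) stop("temperature must be positive")
  H <- grid[1]; W <- grid[2]
  xs <- seq(min(nodes$x) - margin * max(dx, 1e-9),
            max(nodes$x) + margin * max(dx, 1e-9), length.out = W)
  ys <- seq(min(nodes$y) - margin * max(dy, 1e-9),
            max(nodes$y) + margin * max(dy, 1e-9), length.out = H)
  px <- rep(xs, each = H); py <- rep(ys, times = W)
  # distances: grid points x nodes
  D <- sqrt(outer(px, nodes$x, "-")^2 + outer(py, nodes$y, "-")^2)
  L <- -D / temperature
  Wgt <- exp(L - apply(L, 1L, max))
  Wgt <- Wgt / rowSums(Wgt)
  field <- matrix(as.numeric(Wgt %*% v), H, W)
  if (normalization == "histogram") {
    field[] <- (rank(field, ties.method = "average") - 0.5) / length(field)
  }
  list(field = field,
       extent = c(xmin = xs[1], xmax = xs[W], ymin = ys[1], ymax = ys[H]),
       temperature = temperature, normalization = normalization,
       nodeValues = stats::setNames(as.numeric(v), nodes$category))
}

.VPS_WHITE <- c(255, 255, 255)
.VPS_BROWN <- c(139, 69, 19)

#' Virtual Pathology Stain rendering
#'
#' Maps a nonnegative feature-intensity image to the white-to-brown
#' scale of a DAB immunostain: intensities are 0-1 normalized by the
#' image maximum and each pixel is linearly interpolated channel-wise
#' between white (255, 255, 255) and dark brown (139, 69, 19). The log
#' mode applies x <- log(1 + logGain*x) / log(1 + logGain) first,
#' enhancing high-intensity structure.
#'
#' @param intensityImage nonnegative H x W matrix.
#' @param mode "linear" or "log".
#' @param logGain gain of the log mode (default 99).
#' @return H x W x 3 integer array of RGB bytes (0-255) with
#'   attributes \code{mode} and \code{sourceMax}.
#' @export
renderVPS <- function(intensityImage, mode = c("linear", "log"),
                      logGain = 99) {
  mode <- match.arg(mode)
  if (any(intensityImage < 0)) stop("intensity image must be nonnegative")
  mx <- max(intensityImage)
  if (mx == 0) {
    warning("all-zero intensity image: stain is uniformly white")
    x <- intensityImage
  } else x <- intensityImage / mx
  if (mode == "log") x <- log1p(logGain * x) / log1p(logGain)
  rgb <- array(0L, c(dim(intensityImage), 3L))
  for (ch in 1:3)
    rgb[, , ch] <- as.integer(round((1 - x) * .VPS_WHITE[ch] +
                                    x * .VPS_BROWN[ch]))
  attr(rgb, "mode") <- mode
  attr(rgb, "sourceMax") <- mx
  rgb
}

#' Gross-region RGB composite
#'
#' Sums each gross region's associated feature images into one color
#' channel after removing features shared with any other channel's set
#' (set difference), then 0-1 normalizes each channel independently.
#'
#' @param cube a \linkS4class{BinnedCube}.
#' @param grossSets named list: gross region -> m/z vector of
#'   associated features.
#' @param channels named character vector gross -> "R"/"G"/"B"
#'   covering three distinct channels.
#' @return H x W x 3 numeric array in [0, 1]; the de-shared per-channel
#'   m/z sets are attached as attribute \code{"channelSets"}.
#' @export
regionRGBComposite <- function(cube, grossSets, channels) {
  stopifnot(is(cube, "BinnedCube"))
  if (length(channels) != 3L || anyDuplicated(channels) ||
      !all(channels %in% c("R", "G", "B")))
    stop("channels must map three gross regions to distinct R, G, B")
  gl <- names(channels)
  if (!all(gl %in% names(grossSets)))
    stop("missing association sets for: ",
         paste(setdiff(gl, names(grossSets)), collapse = ", "))
  dims <- imageDims(cube)
  out <- array(0, c(dims, 3L))
  chIdx <- c(R = 1L, G = 2L, B = 3L)
  used <- list()
  for (g in gl) {
    others <- unique(unlist(grossSets[setdiff(gl, g)]))
    own <- setdiff(grossSets[[g]], others)
    used[[g]] <- own
    if (!length(own)) {
      warning("gross region '", g, "' has no exclusive features; empty channel")
      next
    }
    img <- Reduce(`+`, lapply(own, function(mz) cubeImage(cube, mz)))
    if (max(img) > 0) img <- img / max(img)
    out[, , chIdx[[channels[[g]]]]] <- img
  }
  attr(out, "channelSets") <- used
  out
}

#' Write an RGB array or scalar field as PNG with a JSON sidecar
#'
#' @param img H x W x 3 byte array (stain/composite scale 0-255 or
#'   0-1) or an H x W scalar field in [0, 1].
#' @param path output PNG path.
#' @param sidecar optional list written to \code{paste0(path,
#'   ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeRenderPNG <- function(img, path, sidecar = NULL) {
  arr <- img
  if (length(dim(arr)) == 3L && max(arr) > 1) arr <- arr / 255
  png::writePNG(arr, path)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
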