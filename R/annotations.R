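#' @include AllClasses.R utils.R
NULL

#' Default gross-region prefix table
#'
#' Maps leading label tokens to gross anatomical regions: cortex (CTX),
#' cerebral nuclei (CNU), brainstem (BST), white matter (WM), choroid
#' plexus (PLX), plaque pathology (PLQ) and background (BG).
#'
#' @return named character vector, prefix -> gross region.
#' @export
defaultGrossPrefixes <- function() {
  p <- c("CTX", "CNU", "BST", "WM", "PLX", "PLQ", "BG")
  stats::setNames(p, p)
}

#' Parse a region label into (gross, category, subannotation)
#'
#' Labels carry the gross region as their leading prefix (for example
#' \code{"CTXL6"} is isocortex layer 6, gross region CTX). Trailing
#' \code{"sub<k>"} tokens mark subannotations of a parent category:
#' \code{"SNR sub2"} parses to category \code{"SNR"} with
#' subannotation 2.
#'
#' @param label nonempty label string.
#' @param prefixes named prefix table (default
#'   \code{\link{defaultGrossPrefixes}}); matched longest-first against
#'   the start of the label.
#' @return list with \code{gross}, \code{category} and \code{sub}
#'   (integer or NA).
#' @export
parseCategory <- function(label, prefixes = defaultGrossPrefixes()) {
  if (!is.character(label) || !nzchar(trimws(label)))
    stop("label must be a nonempty string")
  label <- trimws(label)
  sub <- NA_integer_
  m <- regmatches(label, regexec("^(.*?)[ _]?sub([0-9]+)$", label))[[1]]
  category <- label
  if (length(m) == 3L) {
    category <- trimws(m[2])
    sub <- as.integer(m[3])
  }
  ord <- order(nchar(prefixes), decreasing = TRUE)
  hit <- NA_character_
  for (p in names(prefixes)[ord]) {
    if (startsWith(category, p)) { hit <- prefixes[[p]]; break }
  }
  if (is.na(hit))
    stop(sprintf("label '%s' matches no known gross-region prefix (known: %s)",
                 label, paste(names(prefixes), collapse = ", ")))
  # normalize the category to drop a separator between prefix and detail
  category <- gsub("[ ]+", " ", category)
  list(gross = unname(hit), category = category, sub = sub)
}

#' Construct an AnnotationSet from polygons
#'
#' @param polygons list of lists with \code{vertices} (matrix with
#'   columns x, y) and \code{label}.
#' @param prefixes gross-region prefix table for
#'   \code{\link{parseCategory}}.
#' @return an \linkS4class{AnnotationSet}.
#' @export
AnnotationSet <- function(polygons, prefixes = defaultGrossPrefixes()) {
  polygons <- lapply(polygons, function(p) {
    list(vertices = matrix(as.numeric(p$vertices), ncol = 2L,
                           dimnames = list(NULL, c("x", "y"))),
         label = as.character(p$label))
  })
  labs <- unique(vapply(polygons, `[[`, "", "label"))
  cm <- do.call(rbind, lapply(labs, function(l) {
    pc <- parseCategory(l, prefixes)
    data.frame(label = l, gross = pc$gross, category = pc$category,
               sub = pc$sub, stringsAsFactors = FALSE)
  }))
  if (is.null(cm))
    cm <- data.frame(label = character(), gross = character(),
                     category = character(), sub = integer())
  new("AnnotationSet", polygons = polygons, categoryMap = cm)
}

#' Load polygon annotations from a VGG Image Annotator JSON export
#'
#' Reads polygon regions and their label attribute from a VIA project
#' or region export. Non-polygon shapes are skipped with a warning; a
#' polygon region without a label attribute is an error naming the
#' region. VIA x/y image coordinates map to column/row.
#'
#' @param path path to the VIA JSON file.
#' @param labelAttribute name of the region attribute holding the
#'   label (default "label"; falls back to the first attribute).
#' @param prefixes gross-region prefix table.
#' @return an \linkS4class{AnnotationSet}.
#' @export
loadViaPolygons <- function(path, labelAttribute = "label",
                            prefixes = defaultGrossPrefixes()) {
  j <- jsonlite::read_json(path)
  # VIA project exports nest files under _via_img_metadata; plain region
  # exports are keyed by filename directly
  meta <- if (!is.null(j[["_via_img_metadata"]])) j[["_via_img_metadata"]] else j
  polys <- list()
  for (fname in names(meta)) {
    regions <- meta[[fname]]$regions
    if (is.null(regions)) next
    for (ri in seq_along(regions)) {
      r <- regions[[ri]]
      shape <- r$shape_attributes
      if (is.null(shape$name) || !identical(shape$name, "polygon")) {
        warning(sprintf("skipping non-polygon region %d of '%s'", ri, fname))
        next
      }
      att <- r$region_attributes
      lab <- att[[labelAttribute]]
      if (is.null(lab) && length(att)) lab <- att[[1]]
      if (is.null(lab) || !nzchar(lab))
        stop(sprintf("region %d of '%s' has no label attribute", ri, fname))
      v <- cbind(x = unlist(shape$all_points_x),
                 y = unlist(shape$all_points_y))
      if (nrow(v) < 3L)
        stop(sprintf("region %d of '%s' (label '%s') has fewer than 3 vertices",
                     ri, fname, lab))
      polys[[length(polys) + 1L]] <- list(vertices = v, label = lab)
    }
  }
  AnnotationSet(polys, prefixes)
}

# Even-odd point-in-polygon for many points at once; points exactly on
# an edge count as inside.
pointsInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: point within the segment's bounding box and collinear
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg <- abs(cross) < 1e-9 &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    onEdge <- onEdge | seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Rasterize polygon annotations to a per-pixel label mask
#'
#' A pixel takes the label of the last-listed polygon containing its
#' center (even-odd rule; centers on a polygon edge count as inside).
#' Pixels covered by no polygon are background. Multiple polygons with
#' the same category merge at the mask level. Pixel centers are at
#' integer coordinates: column index c has x = c, row index r has
#' y = r (0-based).
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param shape integer(2), (height, width) of the target image.
#' @return a \linkS4class{LabelMask}.
#' @export
rasterizeAnnotations <- function(ann, shape) {
  stopifnot(is(ann, "AnnotationSet"), length(shape) == 2L)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  cm <- ann@categoryMap
  cats <- unique(cm$category[cm$category != "BG"])
  idxTab <- data.frame(
    index = seq_len(length(cats) + 1L) - 1L,
    category = c("BG", cats),
    gross = c("BG", cm$gross[match(cats, cm$category)]),
    stringsAsFactors = FALSE)
  labels <- matrix(0L, H, W)
  px <- rep(seq_len(W) - 1L, each = H)   # x = col
  py <- rep(seq_len(H) - 1L, times = W)  # y = row
  for (p in ann@polygons) {
    v <- p$vertices
    area <- abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                    c(v[-1, 1], v[1, 1]) * v[, 2])) / 2
    if (area == 0) {
      warning(sprintf("skipping zero-area polygon labeled '%s'", p$label))
      next
    }
    if (any(v[, 1] < 0 | v[, 1] > W - 1 | v[, 2] < 0 | v[, 2] > H - 1))
      warning(sprintf("polygon '%s' extends beyond the image and is clipped",
                      p$label))
    cat <- cm$category[match(p$label, cm$label)]
    idx <- idxTab$index[match(cat, idxTab$category)]
    inside <- pointsInPolygon(px, py, v[, 1], v[, 2])
    labels[cbind(py[inside] + 1L, px[inside] + 1L)] <- idx
  }
  new("LabelMask", labels = labels, indexTable = idxTab,
      backgroundIndex = 0L)
}

#' Write / read a label mask as paletted PNG plus JSON index table
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path output PNG path; the index table goes to
#'   \code{paste0(path, ".json")}.
#' @return \code{path} (write) or a \linkS4class{LabelMask} (read).
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  maxIdx <- max(mask@indexTable$index)
  img <- mask@labels / max(maxIdx, 1L)
  png::writePNG(img, path)
  jsonlite::write_json(
    list(indexTable = mask@indexTable,
         backgroundIndex = mask@backgroundIndex, maxIndex = maxIdx),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- matrix(as.integer(round(img * max(side$maxIndex, 1L))),
                   nrow(img), ncol(img))
  new("LabelMask", labels = labels,
      indexTable = as.data.frame(side$indexTable),
      backgroundIndex = as.integer(side$backgroundIndex))
}
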