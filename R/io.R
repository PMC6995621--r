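# Greyscale image I/O. PNG and TIFF are read natively; JPEG when the jpeg
# package is installed. Colour images are converted to luminance.

#' Read and write greyscale images
#'
#' \code{readGreyImage} reads PNG/TIFF/JPEG into a numeric matrix in
#' [0, 1] (rows x cols); colour channels are combined with the Rec. 601
#' luminance weights. \code{writeGreyImage} writes a matrix as 8-bit
#' greyscale PNG.
#'
#' @param path image file path; format chosen by extension.
#' @param image numeric matrix with values in [0, 1].
#' @return \code{readGreyImage} returns the image matrix;
#'   \code{writeGreyImage} returns \code{path} invisibly.
#' @name imageIO
NULL

#' @rdname imageIO
#' @export
readGreyImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  clamp01(img)
}

#' @rdname imageIO
#' @export
writeGreyImage <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(clamp01(image), path)
  invisible(path)
}

# --- scene spec / ground truth JSON (documented schema) ---------------------

#' Serialize scene specs and ground truth as JSON
#'
#' The scene-spec schema mirrors the [SceneSpec-class] slots (snake_case
#' keys, fish as an array of row objects). Ground-truth masks are stored as
#' column-major run-length encodings so the JSON stays compact while the
#' decoded masks are exact.
#'
#' @param spec a [SceneSpec-class].
#' @param truth a [GroundTruth-class].
#' @param path JSON file path.
#' @return readers return the decoded object; writers return \code{path}
#'   invisibly.
#' @name sceneIO
NULL

#' @rdname sceneIO
#' @export
writeSceneSpec <- function(spec, path) {
  stopifnot(is(spec, "SceneSpec"))
  doc <- list(format = "soleVision-scene-spec", version = 1L,
              image_shape_px = spec@imageShape,
              background_intensity = spec@backgroundIntensity,
              background_noise_sd = spec@backgroundNoiseSd,
              scale_true = spec@scaleTrue,
              reference_diameter_cm = spec@referenceDiameterCm,
              reference_center_px = spec@referenceCenter,
              reference_intensity = spec@referenceIntensity,
              fish = spec@fish, allow_overlap = spec@allowOverlap,
              seed = spec@seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname sceneIO
#' @export
readSceneSpec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "soleVision-scene-spec"))
    stop("not a scene-spec file", call. = FALSE)
  fish <- if (length(doc$fish)) as.data.frame(doc$fish) else emptyFishTable()
  SceneSpec(imageShape = as.integer(doc$image_shape_px), fish = fish,
            scaleTrue = doc$scale_true,
            referenceCenter = as.numeric(doc$reference_center_px),
            referenceDiameterCm = doc$reference_diameter_cm,
            referenceIntensity = doc$reference_intensity,
            backgroundIntensity = doc$background_intensity,
            backgroundNoiseSd = doc$background_noise_sd,
            allowOverlap = isTRUE(doc$allow_overlap),
            seed = as.integer(doc$seed))
}

# Column-major run-length encoding of a logical matrix.
rleEncodeMask <- function(mask) {
  r <- rle(as.logical(mask))
  list(dim = dim(mask), values = as.integer(r$values), lengths = r$lengths)
}

rleDecodeMask <- function(enc) {
  v <- inverse.rle(structure(list(values = as.logical(enc$values),
                                  lengths = as.integer(enc$lengths)),
                             class = "rle"))
  matrix(v, enc$dim[1], enc$dim[2])
}

#' @rdname sceneIO
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  objs <- lapply(truth@objects, function(o)
    list(class = o$class, bbox = o$bbox, length_cm = o$length_cm,
         width_cm = o$width_cm,
         weight_g = if (is.na(o$weight_g)) NULL else o$weight_g,
         mask_rle = rleEncodeMask(o$mask)))
  doc <- list(format = "soleVision-ground-truth", version = 1L,
              scale_true = truth@scaleTrue, objects = objs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname sceneIO
#' @export
readGroundTruth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "soleVision-ground-truth"))
    stop("not a ground-truth file", call. = FALSE)
  objs <- lapply(doc$objects, function(o)
    list(class = o$class, bbox = as.integer(unlist(o$bbox)),
         length_cm = o$length_cm, width_cm = o$width_cm,
         weight_g = if (is.null(o$weight_g)) NA_real_
                    else as.numeric(o$weight_g),
         mask = rleDecodeMask(list(dim = unlist(o$mask_rle$dim),
                                   values = unlist(o$mask_rle$values),
                                   lengths = unlist(o$mask_rle$lengths)))))
  new("GroundTruth", objects = objs, scaleTrue = doc$scale_true)
}
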