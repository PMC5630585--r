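## image I/O: PNG / TIFF / single-frame DICOM in, PNG masks and contour CSV out

#' Read a grayscale image file
#'
#' Loads an 8- or 16-bit grayscale image from PNG, TIFF or single-frame
#' uncompressed DICOM.  Color input is converted to gray by the Rec. 601
#' luminance (0.299 R + 0.587 G + 0.114 B, rounded).  For DICOM, the
#' \code{PixelSpacing} attribute is used when present (anisotropic spacing is
#' averaged with a warning); PNG/TIFF default to 1 mm/px unless overridden.
#'
#' @param path path to a .png, .tif(f) or .dcm file (format is detected from
#'   the file content, not the extension)
#' @param spacingOverride optional spacing in mm/px that takes precedence
#'   over any file metadata
#' @return an \linkS4class{UltrasoundImage}
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(7 / 255, 16, 16), f)
#' img <- readUltrasound(f)
#' range(pixelMatrix(img))
#' @export
readUltrasound <- function(path, spacingOverride = NULL) {
    if (!file.exists(path)) stop("cannot read image: file not found: ", path)
    magic <- readBin(path, "raw", n = 132L)
    if (length(magic) >= 8L &&
        identical(magic[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                       0x0d, 0x0a, 0x1a, 0x0a)))) {
        out <- .readPNGGray(path)
    } else if (length(magic) >= 2L &&
               (identical(magic[1:2], charToRaw("II")) ||
                identical(magic[1:2], charToRaw("MM")))) {
        out <- .readTIFFGray(path)
    } else if (length(magic) >= 132L &&
               identical(magic[129:132], charToRaw("DICM"))) {
        out <- .readDICOMGray(path)
    } else {
        stop("unreadable file (not PNG, TIFF or DICOM): ", path)
    }
    spacing <- if (!is.null(spacingOverride)) {
        stopifnot(is.numeric(spacingOverride), spacingOverride > 0)
        spacingOverride
    } else out$spacing
    ultrasoundImage(out$pixels, spacing = spacing, maxGray = out$maxGray,
                    sourceId = basename(path))
}

## collapse an [h, w, channels] array in [0, 1] to an integer gray matrix
.toGray <- function(arr, maxGray) {
    if (length(dim(arr)) == 3L) {
        nc <- dim(arr)[3]
        arr <- if (nc >= 3L) {
            0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
        } else arr[, , 1]
    }
    out <- round(arr * maxGray)
    attributes(out) <- list(dim = dim(out))   # drop reader metadata
    out
}

.readPNGGray <- function(path) {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    maxGray <- 2^bits - 1
    list(pixels = .toGray(arr, maxGray), spacing = 1, maxGray = maxGray)
}

.readTIFFGray <- function(path) {
    arr <- tiff::readTIFF(path, info = TRUE)
    if (is.list(arr)) stop("multi-frame TIFF is not supported: ", path)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    maxGray <- 2^max(bits) - 1
    list(pixels = .toGray(arr, maxGray), spacing = 1, maxGray = maxGray)
}

## ---------------------------------------------------------------------------
## Minimal DICOM reader: uncompressed little-endian (explicit or implicit
## VR), single frame, grayscale.  Only the tags the package needs are kept.
## ---------------------------------------------------------------------------

.dicomUint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

.readDICOMGray <- function(path) {
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 140L || !identical(raw[129:132], charToRaw("DICM")))
        stop("not a DICOM part-10 file: ", path)
    pos <- 133L                       # first byte after the 'DICM' magic
    n <- length(raw)
    longVR <- c("OB", "OW", "OF", "SQ", "UT", "UN")
    tags <- list()
    explicitMain <- TRUE              # decided by the transfer syntax
    transferSyntax <- "1.2.840.10008.1.2.1"
    repeat {
        if (pos + 7L > n) break
        group <- .dicomUint(raw[pos:(pos + 1L)])
        elem  <- .dicomUint(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
        explicit <- if (group == 0x0002) TRUE else explicitMain
        if (explicit) {
            vr <- rawToChar(raw[pos:(pos + 1L)])
            if (vr %in% longVR) {
                len <- .dicomUint(raw[(pos + 4L):(pos + 7L)])
                pos <- pos + 8L
            } else {
                len <- .dicomUint(raw[(pos + 2L):(pos + 3L)])
                pos <- pos + 4L
            }
        } else {
            vr <- ""
            len <- .dicomUint(raw[pos:(pos + 3L)])
            pos <- pos + 4L
        }
        if (len == 0xFFFFFFFF)
            stop("undefined-length (encapsulated/compressed) DICOM is not supported: ",
                 path)
        key <- sprintf("%04x,%04x", group, elem)
        if (key == "0002,0010")
            transferSyntax <- sub("\\s+$", "",
                                  rawToChar(raw[pos:(pos + len - 1L)]))
        if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103",
                       "0028,0008", "0028,0030", "0028,0004", "7fe0,0010"))
            tags[[key]] <- raw[pos:(pos + len - 1L)]
        pos <- pos + len
        if (key == "7fe0,0010") break
        ## after the meta group, switch VR mode per the transfer syntax
        if (group == 0x0002 && pos <= n - 1L &&
            .dicomUint(raw[pos:(pos + 1L)]) != 0x0002) {
            if (transferSyntax == "1.2.840.10008.1.2") {
                explicitMain <- FALSE
            } else if (transferSyntax == "1.2.840.10008.1.2.1") {
                explicitMain <- TRUE
            } else {
                stop("unsupported DICOM transfer syntax (compressed?): ",
                     transferSyntax)
            }
        }
    }
    str <- function(key) if (is.null(tags[[key]])) NULL else
        sub("\\s+$", "", rawToChar(tags[[key]]))
    u16 <- function(key) .dicomUint(tags[[key]])
    nframes <- str("0028,0008")
    if (!is.null(nframes) && as.integer(nframes) > 1L)
        stop("multi-frame DICOM is not supported")
    if (is.null(tags[["7fe0,0010"]]))
        stop("DICOM file has no PixelData: ", path)
    rows <- u16("0028,0010"); cols <- u16("0028,0011")
    bits <- if (!is.null(tags[["0028,0100"]])) u16("0028,0100") else 8L
    if (!bits %in% c(8L, 16L))
        stop("only 8- and 16-bit DICOM pixel data are supported")
    px <- tags[["7fe0,0010"]]
    if (length(px) < rows * cols * bits / 8L)
        stop("truncated DICOM pixel data")
    vals <- if (bits == 8L) {
        as.integer(px[seq_len(rows * cols)])
    } else {
        i <- seq_len(rows * cols)
        as.integer(px[2L * i - 1L]) + 256L * as.integer(px[2L * i])
    }
    pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
    spacing <- 1
    sp <- str("0028,0030")
    if (!is.null(sp)) {
        parts <- as.numeric(strsplit(sp, "\\\\")[[1]])
        if (length(parts) == 2L && abs(parts[1] - parts[2]) > 1e-9) {
            warning("anisotropic DICOM PixelSpacing (", sp,
                    "): using the mean")
            spacing <- mean(parts)
        } else spacing <- parts[1]
    }
    list(pixels = pixels, spacing = spacing, maxGray = 2^bits - 1)
}

## ---------------------------------------------------------------------------
## Writers
## ---------------------------------------------------------------------------

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) pixels are written as 255, background as 0, so that
#' \code{readUltrasound} followed by thresholding at 128 recovers the mask
#' exactly.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @param path output PNG path
#' @return invisibly, the path
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "BinaryMask"))
    ok <- tryCatch(png::writePNG(mask@pixels, path), error = function(e)
        stop("cannot write mask PNG to ", path, ": ", conditionMessage(e)))
    invisible(path)
}

#' Write a segmentation contour as CSV
#'
#' Writes the closed contour polygon of a segmentation with columns
#' \code{ray_index} (0-based), \code{x}, \code{y} (pixels).
#'
#' @param result a \linkS4class{SegmentationResult}
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeContour <- function(result, path) {
    stopifnot(is(result, "SegmentationResult"))
    ctr <- result@contour
    utils::write.csv(data.frame(ray_index = seq_len(nrow(ctr)) - 1L,
                                x = ctr[, 1], y = ctr[, 2]),
                     path, row.names = FALSE)
    invisible(path)
}

#' Write a segmentation result record as JSON
#'
#' Serializes seed, helper seeds, graph parameters, min-cut flow value and
#' the diameters in millimeters to a JSON file.
#'
#' @param result a \linkS4class{SegmentationResult}
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeResultJSON <- function(result, path) {
    stopifnot(is(result, "SegmentationResult"))
    p <- result@params
    rec <- list(
        seed = result@seed,
        helpers = result@helpers,
        params = list(nRays = p@nRays, nNodes = p@nNodes,
                      maxRadius = p@maxRadius, deltaR = p@deltaR,
                      avgWindow = p@avgWindow),
        flow = result@cut@flowValue,
        cut_index = result@cut@cutIndex,
        diameter_a_mm = result@diameters@a,
        diameter_b_mm = result@diameters@b,
        area_px = sum(result@mask@pixels),
        source_id = result@image@sourceId)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
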