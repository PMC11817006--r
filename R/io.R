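# Readers and writers.
#
# Frame stacks travel as multi-page uncompressed 8-bit grayscale TIFF
# (a minimal baseline codec implemented here, since no TIFF package is
# available in the deployment image) or as directories of numbered
# PNGs.  MP4/AVI input would need an external codec that the runtime
# does not ship, so those paths fail with a clear message rather than
# silently degrading.  Tabular and model artifacts are plain CSV/JSON;
# pipeline configuration is YAML.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

#' Write a frame sequence as multi-page TIFF
#'
#' Baseline TIFF: little-endian, one uncompressed full-height strip of
#' 8-bit grayscale per page.  Lossless and bit-exact on round trip.
#'
#' @param seq a [frame_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(seq, path) {
  stopifnot(inherits(seq, "frame_seq"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(seq$frames); h <- d[1]; w <- d[2]; n <- d[3]
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  writeBin(charToRaw("II"), con); u16(42L)
  # layout per page: pixel data, then its IFD
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_off <- integer(n); ifd_off <- integer(n)
  off <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- off
    ifd_off[i] <- off + h * w
    off <- off + h * w + ifd_size
  }
  u32(ifd_off[1])
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  for (i in seq_len(n)) {
    writeBin(as.raw(t(seq$frames[, , i])), con)   # rows, top to bottom
    u16(n_entries)
    entry(256L, 3L, 1L, w); entry(257L, 3L, 1L, h)
    entry(258L, 3L, 1L, 8L); entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L); entry(278L, 3L, 1L, h)
    entry(279L, 4L, 1L, h * w)
    u32(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF as a frame sequence
#'
#' Accepts baseline uncompressed TIFF (both byte orders, 8-bit,
#' grayscale or RGB pages; RGB is converted by luma weighting
#' 0.299 R + 0.587 G + 0.114 B).  Compressed or exotic layouts error.
#'
#' @param path TIFF file.
#' @param fps frame rate to attach (TIFF carries none).
#' @return A [frame_sequence()].
#' @export
read_tiff_stack <- function(path, fps) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stopf("'%s' is not a TIFF (truncated)", path)
  order <- rawToChar(raw[1:2])
  if (!order %in% c("II", "MM")) stopf("'%s' is not a TIFF", path)
  endian <- if (order == "II") "little" else "big"
  rd <- function(at, size, n = 1)
    readBin(raw[(at + 1):(at + size * n)], "integer", n = n, size = size,
            signed = size >= 4, endian = endian)   # 4-byte: R has no u32
  if (rd(2, 2) != 42L) stopf("'%s' has no TIFF magic", path)
  ifd <- rd(4, 4)
  frames <- list()
  while (ifd != 0L) {
    n_ent <- rd(ifd, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- rd(base, 2); type <- rd(base + 2, 2); cnt <- rd(base + 4, 4)
      val <- if (type == 3L && cnt == 1L) rd(base + 8, 2)
             else rd(base + 8, 4)
      if (cnt > 1L) {     # value field is an offset to the array
        sz <- if (type == 3L) 2L else 4L
        if (cnt * sz > 4L) val <- rd(val, sz, cnt)
        else val <- rd(base + 8, sz, cnt)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stopf("TIFF page lacks dimensions")
    if (g(259, 1L)[1] != 1L)
      stopf("'%s' uses TIFF compression %d; only uncompressed baseline TIFF is supported",
            path, g(259))
    bits <- g(258, 8L)
    if (any(bits != 8L)) stopf("only 8-bit TIFF is supported")
    spp <- g(277, 1L)
    offs <- g(273); cnts <- g(279, h * w * spp)
    buf <- raw[unlist(mapply(function(o, c) (o + 1):(o + c), offs, cnts,
                             SIMPLIFY = FALSE))]
    px <- as.integer(buf)
    if (spp == 1L) {
      fr <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    } else if (spp == 3L) {
      a <- array(px, c(3, w, h))
      fr <- t(0.299 * a[1, , ] + 0.587 * a[2, , ] + 0.114 * a[3, , ])
      fr <- round(fr)
    } else stopf("unsupported samples per pixel: %d", spp)
    pm <- g(262, 1L)
    if (pm == 0L) fr <- 255L - fr     # WhiteIsZero
    frames[[length(frames) + 1]] <- fr
    ifd <- rd(ifd + 2 + n_ent * 12, 4)
  }
  if (!length(frames)) stopf("'%s' contains no frames", path)
  frame_sequence(array(unlist(frames), c(dim(frames[[1]]),
                                         length(frames))), fps)
}

#' Write frames as a directory of numbered PNGs
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_png_frames <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_seq"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_frames(seq)))
    png::writePNG(seq$frames[, , i] / 255,
                  file.path(dir, sprintf("frame_%05d.png", i - 1)))
  invisible(dir)
}

#' Read a grayscale video
#'
#' Dispatches on the input: `.tif`/`.tiff` files go through
#' [read_tiff_stack()]; a directory is read as numbered PNG frames
#' (sorted by name; RGB converted by luma weighting).  `.mp4`/`.avi`
#' are recognized but unsupported in this build (no video codec is
#' available offline) and raise a descriptive error.
#'
#' @param path video file or frame directory.
#' @param fps frame rate; required (neither supported container
#'   carries a trustworthy rate).
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, fps) {
  if (missing(fps) || is.null(fps))
    stopf("fps must be supplied for '%s' (no container metadata available)",
          path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stopf("'%s' contains no .png frames", path)
    frames <- lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 3)
        a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
      round(a * 255)
    })
    return(frame_sequence(array(unlist(frames),
                                c(dim(frames[[1]]), length(frames))), fps))
  }
  if (!file.exists(path)) stopf("video '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff_stack(path, fps))
  if (ext %in% c("mp4", "avi"))
    stopf("'%s': MP4/AVI decoding is not available in this build; convert to multi-page TIFF or a PNG frame directory first",
          path)
  stopf("unrecognized video format '%s' (supported: .tif/.tiff, PNG directory)",
        ext)
}

#' Write a breath trace (CSV + JSON summary)
#'
#' The CSV holds the per-frame record (`frame`, `time_s`, `phase`,
#' `plume_count`); the JSON sidecar (same path with `.json`) holds the
#' start indices, fps and window so the trace round-trips losslessly.
#'
#' @param trace a `breath_trace`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "breath_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(expiration_start_idx = attr(trace, "expiration_start_idx"),
               inspiration_start_idx = attr(trace, "inspiration_start_idx"),
               fps = attr(trace, "fps"), window = attr(trace, "window"))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                    ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a breath trace written by [write_trace()]
#' @param path CSV path (JSON sidecar expected alongside).
#' @return A `breath_trace`.
#' @export
read_trace <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mp <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(mp)) stopf("trace summary '%s' missing", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  structure(df, class = c("breath_trace", "data.frame"),
            expiration_start_idx = as.integer(meta$expiration_start_idx),
            inspiration_start_idx = as.integer(meta$inspiration_start_idx),
            fps = meta$fps, window = meta$window)
}

#' Write ground truth as JSON
#' @param truth a `ground_truth` from [render_thermal_video()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a per-subject feature table
#' @param table data.frame with columns `subject_id`, `trv`, `ade_s`,
#'   `adi_s`, `trr` and optionally `label`.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trv", "ade_s", "adi_s", "trr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("feature table '%s' lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  df
}

#' Write / read a fitted score model as JSON
#' @param model a `score_model`.
#' @param path JSON path.
#' @return `path` (write) or the `score_model` (read).  The search log
#'   is not serialized.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  keep <- c("mu", "sigma", "weights", "threshold", "feature_subset",
            "sd_type", "youden", "below_criterion", "rng_seed",
            "criteria")
  out <- model[intersect(keep, names(model))]
  for (f in c("mu", "sigma", "weights"))
    out[[f]] <- as.list(out[[f]])     # keep names through JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$mu <- unlist(m$mu); m$sigma <- unlist(m$sigma)
  m$weights <- unlist(m$weights)
  structure(m, class = "score_model")
}
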