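# On-disk formats.  Image stacks travel as uncompressed little-endian
# multi-page TIFF (grayscale float32 for intensities, uint8 for mask
# codes; one page per frame and channel, frame-major) written and parsed
# here directly — the environment ships no R TIFF bindings, and the subset
# below (baseline TIFF, single or multiple strips, no compression) is
# self-contained and round-trips exactly.  Tables are CSV with a header
# row, records JSON-lines, models a binary blob with a JSON sidecar.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                            endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                            endian = "little")

tiff_entry <- function(tag, type, count, value) {
  v <- if (type == 3L) c(u16(value), u16(0L)) else u32(value)
  c(u16(tag), u16(type), u32(count), v)
}

#' Write a multi-page TIFF
#'
#' @param pages list of H x W numeric matrices (pages may differ in size),
#'   or a single matrix.
#' @param path output file.
#' @param mode `"float32"` for intensities or `"uint8"` for small integer
#'   codes.
#' @param description optional ASCII string stored in the first page's
#'   ImageDescription tag (used for JSON metadata).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, mode = c("float32", "uint8"),
                       description = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(pages)) pages <- list(pages)
  n <- length(pages)
  if (!n) stop("invalid-input: no pages")
  bps <- if (mode == "float32") 32L else 8L
  fmt <- if (mode == "float32") 3L else 1L
  sizes <- vapply(pages, function(m) nrow(m) * ncol(m) * (bps / 8L),
                  numeric(1))
  cur <- 8
  strip_off <- numeric(n)
  for (i in seq_len(n)) { strip_off[i] <- cur; cur <- cur + sizes[i] }
  desc_raw <- NULL; desc_off <- 0
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
    desc_off <- cur
    cur <- cur + length(desc_raw)
  }
  nent <- rep(10L, n)
  if (!is.null(description)) nent[1L] <- 11L
  ifd_size <- 2 + nent * 12 + 4
  ifd_off <- cur + c(0, cumsum(ifd_size))[seq_len(n)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42L), u32(ifd_off[1L])), con)
  for (i in seq_len(n)) {
    v <- as.numeric(t(pages[[i]]))       # scanline (row-major) order
    if (mode == "float32")
      writeBin(v, con, size = 4L, endian = "little")
    else
      writeBin(as.raw(as.integer(v)), con)
  }
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (i in seq_len(n)) {
    H <- nrow(pages[[i]]); W <- ncol(pages[[i]])
    entries <- list(
      tiff_entry(256L, 3L, 1L, W),             # ImageWidth
      tiff_entry(257L, 3L, 1L, H),             # ImageLength
      tiff_entry(258L, 3L, 1L, bps),           # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),            # Compression: none
      tiff_entry(262L, 3L, 1L, 1L))            # Photometric: BlackIsZero
    if (i == 1L && !is.null(description))
      entries <- c(entries,
                   list(tiff_entry(270L, 2L, length(desc_raw), desc_off)))
    entries <- c(entries, list(
      tiff_entry(273L, 4L, 1L, strip_off[i]),  # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),            # SamplesPerPixel
      tiff_entry(278L, 3L, 1L, H),             # RowsPerStrip
      tiff_entry(279L, 4L, 1L, sizes[i]),      # StripByteCounts
      tiff_entry(339L, 3L, 1L, fmt)))          # SampleFormat
    nxt <- if (i < n) ifd_off[i + 1L] else 0L
    # entries are already in ascending tag order as required
    writeBin(c(u16(length(entries)), do.call(c, entries), u32(nxt)), con)
  }
  invisible(path)
}

rd_u16 <- function(raw, off, n = 1L)
  readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
          endian = "little", signed = FALSE)
rd_u32 <- function(raw, off, n = 1L)
  readBin(raw[(off + 1L):(off + 4L * n)], "integer", n = n, size = 4L,
          endian = "little")

#' Read a multi-page TIFF written by [write_tiff()]
#'
#' Parses uncompressed little-endian baseline TIFF (grayscale, one sample
#' per pixel, float32 or uint8/16).
#'
#' @param path file path.
#' @return list with `pages` (list of H x W matrices) and `description`
#'   (string or `NULL`).
#' @export
read_tiff <- function(path) {
  rw <- readBin(path, "raw", file.size(path))
  if (rawToChar(rw[1:2]) != "II" || rd_u16(rw, 2L) != 42L)
    stop("invalid-input: not a little-endian TIFF")
  off <- rd_u32(rw, 4L)
  pages <- list()
  description <- NULL
  while (off != 0L) {
    nent <- rd_u16(rw, off)
    tags <- list()
    for (k in seq_len(nent)) {
      e <- off + 2L + (k - 1L) * 12L
      tag <- rd_u16(rw, e)
      type <- rd_u16(rw, e + 2L)
      count <- rd_u32(rw, e + 4L)
      val <- if (type == 3L && count == 1L) rd_u16(rw, e + 8L)
             else rd_u32(rw, e + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val)
    }
    gt <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    W <- gt(256L); H <- gt(257L)
    bps <- gt(258L, 8L); comp <- gt(259L, 1L); fmt <- gt(339L, 1L)
    if (comp != 1L) stop("invalid-input: compressed TIFF not supported")
    # strip offsets/counts may be inline (count 1) or stored at an offset
    so_t <- tags[["273"]]; sc_t <- tags[["279"]]
    strips <- if (so_t$count == 1L) so_t$value
              else rd_u32(rw, so_t$value, so_t$count)
    counts <- if (sc_t$count == 1L) sc_t$value
              else rd_u32(rw, sc_t$value, sc_t$count)
    vals <- unlist(lapply(seq_along(strips), function(s) {
      bytes <- rw[(strips[s] + 1L):(strips[s] + counts[s])]
      if (fmt == 3L && bps == 32L)
        readBin(bytes, "numeric", n = counts[s] / 4L, size = 4L,
                endian = "little")
      else if (bps == 8L)
        as.numeric(readBin(bytes, "integer", n = counts[s], size = 1L,
                           signed = FALSE))
      else if (bps == 16L)
        as.numeric(readBin(bytes, "integer", n = counts[s] / 2L, size = 2L,
                           endian = "little", signed = FALSE))
      else stop("invalid-input: unsupported sample layout")
    }))
    pages[[length(pages) + 1L]] <- matrix(vals, H, W, byrow = TRUE)
    dt <- tags[["270"]]
    if (!is.null(dt) && is.null(description)) {
      dr <- rw[(dt$value + 1L):(dt$value + dt$count)]
      description <- rawToChar(dr[dr != as.raw(0L)])
    }
    off <- rd_u32(rw, off + 2L + nent * 12L)
  }
  list(pages = pages, description = description)
}

#' Write a trap movie as a multi-page TIFF
#'
#' Pages are frame-major, channel-minor; movie metadata (dimensions,
#' channel names, frame interval, ROI id) travels in the ImageDescription
#' tag as JSON so [movie_read_tiff()] reconstructs the object exactly.
#'
#' @param movie a [trap_movie()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
movie_write_tiff <- function(movie, path) {
  d <- dim(movie$frames)
  pages <- vector("list", d[1] * d[4])
  k <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[4])) {
    k <- k + 1L
    pages[[k]] <- matrix(movie$frames[t, , , ch], d[2], d[3])
  }
  meta <- jsonlite::toJSON(list(
    T = d[1], H = d[2], W = d[3], C = d[4],
    channel_names = movie$channel_names,
    frame_interval_min = movie$frame_interval_min,
    roi_id = movie$roi_id, origin = movie$origin), auto_unbox = TRUE)
  write_tiff(pages, path, mode = "float32", description = as.character(meta))
}

#' Read a trap movie written by [movie_write_tiff()]
#'
#' @param path file path.
#' @return a [trap_movie()].
#' @export
movie_read_tiff <- function(path) {
  tf <- read_tiff(path)
  meta <- jsonlite::fromJSON(tf$description)
  fr <- array(0, dim = c(meta$T, meta$H, meta$W, meta$C))
  k <- 0L
  for (t in seq_len(meta$T)) for (ch in seq_len(meta$C)) {
    k <- k + 1L
    fr[t, , , ch] <- tf$pages[[k]]
  }
  trap_movie(fr, meta$frame_interval_min, meta$channel_names, meta$roi_id,
             meta$origin)
}

#' Write per-frame masks as a uint8 multi-page TIFF
#'
#' @param masks list of [segmentation_mask()]s (or integer matrices).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
masks_write_tiff <- function(masks, path) {
  pages <- lapply(masks, function(m)
    if (inherits(m, "segmentation_mask")) m$class_map else as.matrix(m))
  cs <- if (inherits(masks[[1L]], "segmentation_mask"))
    masks[[1L]]$class_set else NULL
  meta <- jsonlite::toJSON(list(kind = "masks", class_set = cs),
                           auto_unbox = TRUE)
  write_tiff(pages, path, mode = "uint8", description = as.character(meta))
}

#' Read masks written by [masks_write_tiff()]
#' @param path file path.
#' @return list of [segmentation_mask()]s.
#' @export
masks_read_tiff <- function(path) {
  tf <- read_tiff(path)
  cs <- jsonlite::fromJSON(tf$description)$class_set
  if (is.null(cs)) cs <- c("background", "mother", "other")
  lapply(tf$pages, function(p) segmentation_mask(p, class_set = cs))
}

## ---- records and groundtruth -------------------------------------------

record_to_list <- function(r) {
  list(roi_id = r$roi_id, budding_frames = I(r$budding_frames),
       cycle_durations_min = I(r$cycle_durations_min),
       death_frame = if (is.na(r$death_frame)) NULL else r$death_frame,
       end_reason = r$end_reason, censored = r$censored,
       excluded = r$excluded, rls = r$rls,
       frame_interval_min = r$frame_interval_min)
}

#' Write lifespan records as JSON lines
#'
#' @param records list of [lifespan_record()]s.
#' @param path output file (one JSON object per line).
#' @return `path`, invisibly.
#' @export
records_write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                  null = "null")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read lifespan records from JSON lines
#' @param path file path.
#' @return list of [lifespan_record()]s.
#' @export
records_read_jsonl <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    lifespan_record(x$roi_id, x$budding_frames,
                    death_frame = x$death_frame %||% NA_integer_,
                    end_reason = x$end_reason,
                    frame_interval_min = x$frame_interval_min)
  })
}

#' Write lifespan records as CSV (one row per record)
#'
#' `budding_frames` is a `|`-delimited list in a single column.
#'
#' @param records list of [lifespan_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
records_write_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(roi_id = r$roi_id,
               rls = r$rls,
               end_reason = r$end_reason,
               censored = r$censored,
               excluded = r$excluded,
               death_frame = r$death_frame,
               frame_interval_min = r$frame_interval_min,
               budding_frames = paste(r$budding_frames, collapse = "|"))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cell history's groundtruth as JSON
#' @param history a `cell_history`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
history_write_json <- function(history, path) {
  jsonlite::write_json(list(
    budding_frames = history$budding_frames,
    sep_frame = if (is.na(history$sep_frame)) NULL else history$sep_frame,
    sep_generation = if (is.na(history$sep_generation)) NULL
                     else history$sep_generation,
    death_frame = if (is.na(history$death_frame)) NULL
                  else history$death_frame,
    end_reason = history$end_reason,
    rls = history$rls,
    frame_interval_min = history$frame_interval_min,
    labels = history$per_frame_labels,
    sep_state = history$per_frame_sep
  ), path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

## ---- models -------------------------------------------------------------

#' Save a fitted model (binary blob + JSON sidecar)
#'
#' @param model a `frame_cnn`, `seq_lstm`, `sep_lstm` or `seg_model`.
#' @param path basename; writes `<path>.bin` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, paste0(path, ".bin"))
  side <- list(class = class(model)[1L],
               classes = model$classes %||% model$class_set,
               config = model$config %||%
                 list(hidden = model$hidden, epochs = model$epochs,
                      lr = model$lr, seed = model$seed),
               package_version = as.character(utils::packageVersion("traplife")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path basename used at save time.
#' @return the model object.
#' @export
load_model <- function(path) readRDS(paste0(path, ".bin"))
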