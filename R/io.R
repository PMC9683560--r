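# Image, mask, manifest and grade-table I/O.
#
# Native image format is PNM (PGM P2/P5 grayscale, PPM P3/P6 colour,
# 8- or 16-bit): the only image container with a plain-text dialect, which
# keeps every fixture in this package human-readable.  PNG is supported
# when the optional png package is installed.  Masks use 0/255 PGM on
# disk and 0/1 integer matrices in memory.
#
# In-memory conventions: images are [H, W, 3] double arrays scaled to
# [0, 1], row-major top-left origin; masks are [H, W] integer 0/1
# matrices; grades are integers 0..4 (normal .. proliferative DR).

pnm_read_tokens <- function(bytes, n_tokens) {
  tokens <- character(0)
  i <- 1L
  nb <- length(bytes)
  while (length(tokens) < n_tokens && i <= nb) {
    ch <- bytes[i]
    if (ch == charToRaw("#")) {
      while (i <= nb && !bytes[i] %in% charToRaw("\n")) i <- i + 1L
    } else if (rawToChar(ch) %in% c(" ", "\t", "\n", "\r")) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= nb && !rawToChar(bytes[j]) %in%
               c(" ", "\t", "\n", "\r", "#")) j <- j + 1L
      tokens <- c(tokens, rawToChar(bytes[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(tokens) < n_tokens) stop("truncated PNM header")
  list(tokens = tokens, pos = i)
}

#' Read a PNM (PPM/PGM) image
#'
#' @param path File in P2/P3 (ASCII) or P5/P6 (binary) format, 8- or
#'   16-bit.
#' @return List with `data` (integer array `[H, W, C]`, C = 1 or 3) and
#'   `maxval`.
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  hd <- pnm_read_tokens(bytes, 4L)
  magic <- hd$tokens[1]
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("not a supported PNM file (", magic, "): ", path)
  }
  w <- as.integer(hd$tokens[2])
  h <- as.integer(hd$tokens[3])
  maxval <- as.integer(hd$tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1 || h < 1 ||
      maxval < 1 || maxval > 65535) {
    stop("invalid PNM header in ", path)
  }
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.numeric(w) * h * nch
  if (magic %in% c("P2", "P3")) {
    txt <- rawToChar(bytes[hd$pos:length(bytes)])
    v <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(v) < n || anyNA(v)) stop("truncated or corrupt PNM data: ", path)
    v <- v[seq_len(n)]
  } else {
    # binary payload starts right after the single whitespace ending maxval
    payload <- bytes[(hd$pos + 1L):length(bytes)]
    if (maxval > 255) {
      if (length(payload) < 2 * n) stop("truncated PNM data: ", path)
      hi <- as.integer(payload[seq(1L, 2L * n, 2L)])
      lo <- as.integer(payload[seq(2L, 2L * n, 2L)])
      v <- hi * 256L + lo
    } else {
      if (length(payload) < n) stop("truncated PNM data: ", path)
      v <- as.integer(payload[seq_len(n)])
    }
  }
  data <- aperm(array(v, c(nch, w, h)), c(3L, 2L, 1L))
  list(data = data, maxval = maxval)
}

#' Write a PNM (PPM/PGM) image
#'
#' @param img `[H, W]` or `[H, W, C]` array of values in `[0, 1]` (C = 1
#'   or 3).
#' @param path Output path.
#' @param maxval Maximum sample value (255 or 65535).
#' @param ascii Write the plain-text dialect (P2/P3); default TRUE so that
#'   generated fixtures stay text.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, maxval = 255L, ascii = TRUE) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  nch <- dim(img)[3]
  stopifnot(nch %in% c(1L, 3L), maxval %in% c(255L, 65535L))
  v <- as.integer(round(pmin(pmax(img, 0), 1) * maxval))
  dim(v) <- dim(img)
  flat <- as.integer(aperm(v, c(3L, 2L, 1L)))
  magic <- if (nch == 3L) (if (ascii) "P3" else "P6") else
    (if (ascii) "P2" else "P5")
  header <- sprintf("%s\n%d %d\n%d\n", magic, dim(img)[2], dim(img)[1],
                    maxval)
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeLines(vapply(split(flat, ceiling(seq_along(flat) / 12)),
                      paste, character(1), collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    if (maxval > 255L) {
      writeBin(as.raw(rbind(flat %/% 256L, flat %% 256L)), con)
    } else {
      writeBin(as.raw(flat), con)
    }
  }
  invisible(path)
}

image_ext <- function(path) tolower(tools::file_ext(path))

#' Load an RGB image scaled to the unit interval
#'
#' PNM natively; PNG via the optional png package.  Grayscale sources are
#' promoted to three identical channels; 16-bit sources are rescaled by
#' their maxval.
#'
#' @param path Image file.
#' @return `[H, W, 3]` double array in `[0, 1]`.
#' @export
load_image <- function(path) {
  ext <- image_ext(path)
  if (ext %in% c("ppm", "pgm", "pnm")) {
    r <- read_pnm(path)
    img <- r$data / r$maxval
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the png package: ", path)
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (dim(img)[3] == 1L) {
    img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  }
  img
}

#' Load a binary vessel mask
#'
#' Pixels brighter than half the sample range map to 1 (the `> 127` rule
#' for 8-bit masks), the rest to 0.  A colour source must have three equal
#' channels.
#'
#' @param path Mask file (PGM/PPM or PNG).
#' @return `[H, W]` integer 0/1 matrix.
#' @export
load_mask <- function(path) {
  ext <- image_ext(path)
  if (ext %in% c("ppm", "pgm", "pnm")) {
    r <- read_pnm(path)
    data <- r$data
    cutoff <- r$maxval / 2
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the png package: ", path)
    }
    data <- png::readPNG(path) * 255
    if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
    if (dim(data)[3] == 4L) data <- data[, , 1:3, drop = FALSE]
    cutoff <- 127.5
  } else {
    stop("unsupported mask format '", ext, "': ", path)
  }
  if (dim(data)[3] == 3L) {
    if (!(all(data[, , 1] == data[, , 2]) &&
            all(data[, , 1] == data[, , 3]))) {
      stop("multi-channel mask with unequal channels: ", path)
    }
  }
  m <- (data[, , 1] > cutoff) * 1L
  dim(m) <- dim(data)[1:2]
  if (all(m == 0L)) warning("mask is all background: ", path)
  m
}

#' Write a binary mask as 0/255 PGM
#'
#' @param mask `[H, W]` 0/1 matrix.
#' @param path Output path.
#' @param ascii Plain-text P2 dialect (default TRUE).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, ascii = TRUE) {
  assert_binary_mask(mask)
  write_pnm(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
            ascii = ascii)
}

#' Resize an image/mask pair to the model grid
#'
#' The image is resampled bilinearly; the mask with nearest-neighbour so
#' it stays strictly binary.
#'
#' @param image `[H, W, 3]` array.
#' @param mask `[H, W]` 0/1 matrix, or NULL.
#' @param size Target side length, divisible by 16 (the networks'
#'   downsampling factor); 256 and 512 are the standard working sizes.
#' @return List `image`, `mask` at `size` x `size`.
#' @export
resize_pair <- function(image, mask = NULL, size = 512L) {
  if (size %% 16L != 0L) stop("size must be divisible by 16, got ", size)
  d <- dim(image)
  x <- image
  dim(x) <- c(d[1], d[2], d[3], 1L)
  img2 <- op_bilinear_resize_forward(x, size, size)$out
  dim(img2) <- c(size, size, d[3])
  m2 <- NULL
  if (!is.null(mask)) {
    m2 <- mask[nearest_index(nrow(mask), size),
               nearest_index(ncol(mask), size)]
    storage.mode(m2) <- "integer"
  }
  list(image = img2, mask = m2)
}

# ---- manifests -----------------------------------------------------------

MANIFEST_COLS <- c("id", "image", "mask", "grade", "split")

#' Construct a dataset manifest
#'
#' One row per record: `id`, `image` path, optional `mask` path, optional
#' integer `grade` 0..4, and a `split` tag (`train`/`test`/`""`).  Every
#' record must carry a mask or a grade (jointly labelled records may have
#' both).
#'
#' @param df data.frame with at least `id` and `image` columns.
#' @param source Free-text provenance note kept as an attribute.
#' @return A validated `ret_manifest` data.frame.
#' @export
as_manifest <- function(df, source = "unspecified") {
  for (col in MANIFEST_COLS) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "grade") NA_integer_ else NA_character_
    }
  }
  df <- df[MANIFEST_COLS]
  df$grade <- suppressWarnings(as.integer(df$grade))
  has_mask <- !is.na(df$mask) & nzchar(df$mask)
  has_grade <- !is.na(df$grade)
  if (any(!has_mask & !has_grade)) {
    stop("manifest rows without mask or grade: ",
         paste(which(!has_mask & !has_grade), collapse = ", "))
  }
  if (any(has_grade)) check_grades(df$grade[has_grade])
  if (anyDuplicated(df$id)) stop("duplicate manifest ids")
  attr(df, "source") <- source
  class(df) <- c("ret_manifest", "data.frame")
  df
}

#' Read / write a manifest (CSV or JSON, by extension)
#'
#' @param manifest A `ret_manifest`.
#' @param path `.csv` or `.json` file.
#' @return `read_manifest()` returns the `ret_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  if (image_ext(path) == "json") {
    jsonlite::write_json(df, path, auto_unbox = FALSE, na = "null",
                         pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- if (image_ext(path) == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = "")
  }
  as_manifest(df, source = basename(path))
}

#' Deterministically split a manifest into train/test
#'
#' The train size is `floor(n * train_fraction)` — at 3662 records and the
#' standard 4:1 ratio this yields the 2929/733 split.  The shuffle is
#' driven entirely by `seed`.
#'
#' @param manifest A `ret_manifest`.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return The manifest with `split` filled with `"train"`/`"test"`.
#' @export
split_manifest <- function(manifest, train_fraction = 0.8, seed = 0L) {
  n <- nrow(manifest)
  if (n == 0L) stop("cannot split an empty manifest")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(n * train_fraction)
  manifest$split <- "test"
  manifest$split[idx[seq_len(n_train)]] <- "train"
  manifest
}

#' Load a grade table (APTOS-style CSV)
#'
#' Accepts columns `id_code`/`diagnosis` (the APTOS dialect) or
#' `id`/`grade`.  Grades outside 0..4 and duplicate ids are rejected with
#' the offending row number.
#'
#' @param path CSV file.
#' @return Named integer vector: id -> grade.
#' @export
load_grade_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  id_col <- intersect(c("id_code", "id"), names(df))[1]
  gr_col <- intersect(c("diagnosis", "grade"), names(df))[1]
  if (is.na(id_col) || is.na(gr_col)) {
    stop("grade table needs id_code/diagnosis (or id/grade) columns: ",
         path)
  }
  ids <- as.character(df[[id_col]])
  grades <- df[[gr_col]]
  bad <- which(!is.finite(grades) | grades != as.integer(grades) |
                 grades < 0 | grades > 4)
  if (length(bad)) {
    stop("grade out of range 0..4 at row ", bad[1], " of ", path)
  }
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop("duplicate image id '", ids[dup[1]], "' at row ", dup[1], " of ",
         path)
  }
  stats::setNames(as.integer(grades), ids)
}

#' Load the images (and masks/grades) referenced by a manifest
#'
#' @param manifest A `ret_manifest`.
#' @param split Optional split tag filter (`"train"`/`"test"`).
#' @param size Optional working size passed to [resize_pair()].
#' @param base_dir Directory that relative paths are resolved against.
#' @return A `ret_dataset`: list of `images`, `masks`, `grades`, `ids`.
#' @export
load_dataset <- function(manifest, split = NULL, size = NULL,
                         base_dir = ".") {
  df <- as.data.frame(manifest)
  if (!is.null(split)) df <- df[df$split == split, , drop = FALSE]
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base_dir, p))
  }
  images <- list(); masks <- list()
  for (i in seq_len(nrow(df))) {
    img <- load_image(resolve(df$image[i]))
    msk <- if (!is.na(df$mask[i]) && nzchar(df$mask[i])) {
      load_mask(resolve(df$mask[i]))
    }
    if (!is.null(size)) {
      rp <- resize_pair(img, msk, size)
      img <- rp$image
      msk <- rp$mask
    }
    images[[i]] <- img
    masks[[i]] <- msk
  }
  ret_dataset(images = images,
              masks = if (all(vapply(masks, is.null, logical(1)))) NULL
                      else masks,
              grades = if (all(is.na(df$grade))) NULL else df$grade,
              ids = df$id)
}

#' In-memory dataset container
#'
#' @param images List of `[H, W, 3]` arrays.
#' @param masks Optional list of `[H, W]` 0/1 matrices.
#' @param grades Optional integer vector of grades 0..4.
#' @param ids Optional record ids.
#' @return A `ret_dataset` list.
#' @export
ret_dataset <- function(images, masks = NULL, grades = NULL, ids = NULL) {
  n <- length(images)
  stopifnot(n > 0)
  if (!is.null(masks)) stopifnot(length(masks) == n)
  if (!is.null(grades)) {
    stopifnot(length(grades) == n)
    check_grades(grades[!is.na(grades)])
  }
  structure(list(images = images, masks = masks, grades = grades,
                 ids = if (is.null(ids)) as.character(seq_len(n)) else ids),
            class = "ret_dataset")
}

#' @export
length.ret_dataset <- function(x) length(x$images)
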