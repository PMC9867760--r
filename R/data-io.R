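# Dataset manifests, image/mask loading and the two split protocols.
#
# A manifest is a data.frame with columns image, mask, source, split; on
# disk it is a plain CSV with that header. Images are PNG or TIFF (JPEG
# decoding is not available in this R stack and raises an explicit error);
# masks are single-channel PNGs binarized at 127/255.

#' Create a dataset manifest
#'
#' @param image,mask character vectors of file paths
#' @param source dataset name per record
#' @param split split tag per record ("train", "valid" or "test")
#' @return a `data.frame` with columns image, mask, source, split
#' @export
new_manifest <- function(image, mask, source = "unknown", split = "train") {
  data.frame(image = as.character(image), mask = as.character(mask),
             source = rep_len(as.character(source), length(image)),
             split = rep_len(as.character(split), length(image)),
             stringsAsFactors = FALSE)
}

#' Read a manifest CSV (columns image, mask, source, split)
#' @param path CSV path
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "mask", "source", "split")
  if (!all(need %in% names(df)))
    stop(sprintf("manifest '%s' must have columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  df[need]
}

#' Write a manifest CSV
#' @param manifest data.frame from [new_manifest()]
#' @param path output path
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Read an image file into an (h, w, c) array in [0, 1].
#' @keywords internal
read_image_array <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = stop(sprintf("JPEG decoding is not available; convert '%s' to PNG or TIFF", path),
                        call. = FALSE),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path), call. = FALSE))
  if (is.null(dim(img)) || length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  img
}

#' Load one image/mask pair, resized and normalized
#'
#' The image is bilinearly resized to `size` x `size`, scaled to \[0, 1\]
#' and normalized with mean 0.5 and standard deviation 0.5, giving the
#' \[-1, 1\] range the network trains on. The mask is nearest-neighbour
#' resized and binarized at 127/255.
#'
#' @param rec one manifest record (a list or single-row data.frame with
#'   `image` and `mask` paths)
#' @param size target side length
#' @return list with `image` (1, 3, size, size) and `mask` (1, 1, size,
#'   size, values 0/1)
#' @export
load_sample <- function(rec, size) {
  img <- read_image_array(rec$image[[1L]])
  msk <- read_image_array(rec$mask[[1L]])
  if (!all(dim(img)[1:2] == dim(msk)[1:2]))
    stop(sprintf("size mismatch between image (%s) and mask (%s)",
                 paste(dim(img)[1:2], collapse = "x"), paste(dim(msk)[1:2], collapse = "x")),
         call. = FALSE)
  ch <- dim(img)[3L]
  rgb <- if (ch >= 3L) img[, , 1:3, drop = FALSE] else img[, , c(1L, 1L, 1L), drop = FALSE]
  x <- aperm(rgb, c(3L, 1L, 2L))           # (3, h, w)
  dim(x) <- c(1L, dim(x))
  x <- ft_resize(x, size, size)
  x <- (pmin(pmax(x, 0), 1) - 0.5) / 0.5
  m <- msk[, , 1L]
  dim(m) <- c(1L, 1L, dim(m))
  m <- ft_resize_nearest(m, size, size)
  mb <- array(0, dim(m)); mb[m > 127 / 255] <- 1
  list(image = x, mask = mb)
}

#' Load a whole manifest into batched arrays
#'
#' @param manifest data.frame manifest
#' @param size target side length
#' @return list with `x` (n, 3, size, size), `y` (n, 1, size, size),
#'   `source`, `split`
#' @export
load_dataset <- function(manifest, size) {
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest", call. = FALSE)
  x <- array(0, c(n, 3L, size, size))
  y <- array(0, c(n, 1L, size, size))
  for (i in seq_len(n)) {
    s <- load_sample(manifest[i, ], size)
    x[i, , , ] <- s$image
    y[i, , , ] <- s$mask
  }
  list(x = x, y = y, source = manifest$source, split = manifest$split)
}

# --- Split protocols --------------------------------------------------------

#' Standard two-dataset split protocol
#'
#' Per source dataset, 10\% of the records (rounded up) are held out as the
#' test set; the remainder form the training pool. A validation set of 10\%
#' of the combined pool is then subsampled from it, leaving the rest tagged
#' "train". The combined training pool (train + valid) is what the protocol
#' counts as training data: 1000 + 612 records yield a pool of 1450
#' (900 + 550). All shuffling is seeded.
#'
#' @param kvasir,clinicdb manifests (data.frames) of the two sources
#' @param seed RNG seed for the shuffles
#' @param test_frac,valid_frac held-out fractions (0.10 each)
#' @return list with `manifest` (split tags assigned; a partition into
#'   train/valid/test), `n_train_pool` (train + valid count) and `counts`
#' @export
split_standard <- function(kvasir, clinicdb, seed = 1L,
                           test_frac = 0.1, valid_frac = 0.1) {
  if (nrow(kvasir) == 0L || nrow(clinicdb) == 0L)
    stop("empty manifest", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pool <- list(); test <- list()
  for (m in list(kvasir, clinicdb)) {
    idx <- sample.int(nrow(m))
    n_test <- ceiling(test_frac * nrow(m))
    test[[length(test) + 1L]] <- m[idx[seq_len(n_test)], ]
    pool[[length(pool) + 1L]] <- m[idx[-seq_len(n_test)], ]
  }
  test <- do.call(rbind, test)
  pool <- do.call(rbind, pool)
  pool <- pool[sample.int(nrow(pool)), ]
  n_valid <- ceiling(valid_frac * nrow(pool))
  pool$split <- c(rep("valid", n_valid), rep("train", nrow(pool) - n_valid))
  test$split <- "test"
  manifest <- rbind(pool, test)
  rownames(manifest) <- NULL
  list(manifest = manifest,
       n_train_pool = nrow(pool),
       counts = c(train = sum(manifest$split == "train"),
                  valid = sum(manifest$split == "valid"),
                  test = sum(manifest$split == "test")),
       protocol = "standard", seed = seed)
}

#' Merged five-dataset split protocol
#'
#' All manifests are pooled and shuffled; fixed-size test and validation
#' sets are drawn (224 records each for the five public polyp datasets,
#' whose pool totals 2248) and the remainder is tagged "train".
#'
#' @param manifests list of manifests (data.frames)
#' @param seed RNG seed
#' @param n_test,n_valid held-out set sizes
#' @return list as in [split_standard()]
#' @export
split_merged <- function(manifests, seed = 1L, n_test = 224L, n_valid = 224L) {
  pool <- do.call(rbind, manifests)
  if (nrow(pool) < n_test + n_valid)
    stop(sprintf("pool of %d records is smaller than test + valid = %d",
                 nrow(pool), n_test + n_valid), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pool <- pool[sample.int(nrow(pool)), ]
  pool$split <- c(rep("test", n_test), rep("valid", n_valid),
                  rep("train", nrow(pool) - n_test - n_valid))
  rownames(pool) <- NULL
  list(manifest = pool,
       n_train_pool = sum(pool$split != "test"),
       counts = c(train = sum(pool$split == "train"),
                  valid = n_valid, test = n_test),
       protocol = "merged", seed = seed)
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
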