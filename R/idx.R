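#' Read IDX-format image and label files
#'
#' The IDX container is the standard distribution format for handwritten
#' digit corpora: a big-endian header with a magic number (2051 for
#' 3-dimensional image files, 2049 for 1-dimensional label files) and
#' dimension sizes, followed by unsigned bytes. Gzip-compressed files are
#' accepted transparently. This reader is optional plumbing for running
#' the two-layer experiment on real digit data; nothing else in the
#' package depends on it.
#'
#' @param path Path to an IDX file (optionally gzipped).
#' @return `read_idx_images()`: a numeric matrix `n x (rows*cols)` with
#'   pixel values scaled to `[0, 1]` (rows of the matrix are flattened
#'   images). `read_idx_labels()`: an integer vector of length `n`.
#' @export
read_idx_images <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 2051) {
    stop(sprintf("not an IDX image file (magic %d, expected 2051)", magic),
         call. = FALSE)
  }
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; px <- dims[2] * dims[3]
  raw <- readBin(con, "integer", n * px, size = 1, signed = FALSE)
  if (length(raw) != n * px) stop("truncated IDX image file", call. = FALSE)
  matrix(raw, n, px, byrow = TRUE) / 255
}

#' @rdname read_idx_images
#' @export
read_idx_labels <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 2049) {
    stop(sprintf("not an IDX label file (magic %d, expected 2049)", magic),
         call. = FALSE)
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  raw <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(raw) != n) stop("truncated IDX label file", call. = FALSE)
  as.integer(raw)
}

#' Build a rated dataset from IDX digit files
#'
#' Wraps [read_idx_images()]/[read_idx_labels()] into the same
#' `rated_dataset` container as [generate_synthetic_images()], deriving
#' the two binary label tracks from the digit labels: track A is digit
#' parity (odd = 1), track B is digit magnitude (five or greater = 1).
#' Latent margins are unavailable for real data, so `margins` is `NULL`.
#'
#' @param image_path,label_path IDX files for one split.
#' @param train_frac Fraction assigned to the training split.
#' @return A `rated_dataset` (unrated; pass to [train_teacher()]).
#' @export
idx_dataset <- function(image_path, label_path, train_frac = 5 / 6) {
  X <- read_idx_images(image_path)
  digits <- read_idx_labels(label_path)
  stopifnot(nrow(X) == length(digits))
  labels <- cbind(A = as.integer(digits %% 2 == 1),
                  B = as.integer(digits >= 5))
  n <- nrow(X)
  n_train <- round(train_frac * n)
  idx <- sample.int(n)
  structure(list(stimuli = X, labels = labels, margins = NULL,
                 train = sort(idx[seq_len(n_train)]),
                 test = sort(idx[-seq_len(n_train)]),
                 difficulty = NULL, teacher = NULL, task = NULL),
            class = "rated_dataset")
}
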