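#' Construct a video sequence
#'
#' The package's basic data object: an ordered stack of grayscale frames
#' with a class label and a subject identifier. Intensities live in
#' [0, 1] with foreground (silhouette) = 1 and background = 0.
#'
#' @param frames numeric array (rows, cols, T) with values in [0, 1].
#' @param label class label, an integer >= 1.
#' @param subject subject identifier (string).
#' @param tag provenance tag: one of `"real"`, `"synthetic"`,
#'   `"occluded"`, `"concatenated"`.
#' @param first_label,second_label for concatenated sequences, the labels
#'   of the two constituent actions.
#' @return an `mstnn_video`.
#' @export
video_sequence <- function(frames, label, subject, tag = "real",
                           first_label = NULL, second_label = NULL) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] >= 1L)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 1)
    stop("frame intensities must lie in [0, 1]; got range [",
         signif(rng[1], 3), ", ", signif(rng[2], 3), "]")
  structure(list(frames = frames, label = as.integer(label),
                 subject = as.character(subject), tag = tag,
                 first_label = first_label, second_label = second_label),
            class = "mstnn_video")
}

#' @export
print.mstnn_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("mstnn video: %d frames of %dx%d, label %d, subject '%s' (%s)\n",
              d[3], d[1], d[2], x$label, x$subject, x$tag))
  invisible(x)
}

#' Read a frame-directory sequence
#'
#' Reads a directory of lexically ordered PNG or PGM frames into an
#' `mstnn_video`. PNG frames are read through the png package (color
#' images are averaged to grayscale); 8-bit values are scaled so that 255
#' maps to intensity 1. PGM (P2 ASCII and P5 binary) frames are parsed
#' directly.
#'
#' @param path directory containing the frames.
#' @param label,subject metadata for the sequence (usually from a
#'   manifest; see [read_manifest()]).
#' @param tag provenance tag.
#' @return an `mstnn_video`.
#' @export
read_sequence <- function(path, label, subject, tag = "real") {
  files <- sort(list.files(path, pattern = "\\.(png|pgm)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/PGM frames found in ", path)
  frames <- lapply(files, read_frame)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame dimensions in ", path)
  arr <- array(unlist(frames), c(dims[1, 1], dims[2, 1], length(frames)))
  video_sequence(arr, label, subject, tag)
}

read_frame <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    img <- png::readPNG(file)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    return(img)
  }
  read_pgm(file)
}

# minimal PGM reader (P2 ascii / P5 binary), intensities scaled to [0, 1]
read_pgm <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header in ", file)
      if (grepl("[ \t\r\n]", ch)) next
      if (ch == "#") { repeat { ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break }; next }
      word <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[ \t\r\n#]", ch)) break
        word <- paste0(word, ch)
      }
      return(word)
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop(file, " is not a PGM (P2/P5) file")
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  npix <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", npix))
  } else {
    scan(con, what = integer(), n = npix, quiet = TRUE)
  }
  # PGM is row-major (pixels left-to-right, top-to-bottom)
  t(matrix(vals, nrow = w, ncol = h)) / mx
}

#' Read a dataset manifest
#'
#' A manifest is a CSV/TSV file with columns `sequence_path`, `label`,
#' `subject` (and optionally `tag`); each row points at one frame
#' directory relative to the manifest's location.
#'
#' @param manifest path to the manifest file.
#' @return list of `mstnn_video` objects.
#' @export
read_manifest <- function(manifest) {
  sep <- if (grepl("\\.tsv$", manifest, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(manifest, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sequence_path", "label", "subject")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  root <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    read_sequence(file.path(root, tab$sequence_path[i]), tab$label[i],
                  tab$subject[i], tag = tab$tag[i] %||% "real")
  })
}

#' Write a sequence as a frame directory
#'
#' Inverse of [read_sequence()]: writes one PNG (or ASCII PGM) file per
#' frame, zero-padded so lexical order equals temporal order.
#'
#' @param seq an `mstnn_video`.
#' @param path output directory (created if needed).
#' @param format `"png"` or `"pgm"`.
#' @export
write_sequence <- function(seq, path, format = c("png", "pgm")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  T_ <- dim(seq$frames)[3L]
  for (t in seq_len(T_)) {
    f <- file.path(path, sprintf("frame_%04d.%s", t, format))
    if (format == "png") {
      png::writePNG(seq$frames[, , t], f)
    } else {
      m <- round(seq$frames[, , t] * 255)
      lines <- apply(m, 1L, paste, collapse = " ")
      writeLines(c("P2", paste(ncol(m), nrow(m)), "255", lines), f)
    }
  }
  invisible(path)
}

#' Resize frames to the network input size
#'
#' Bilinearly resizes every frame (via `EBImage::resize`) to the target
#' dimensions and clips intensities back into [0, 1].
#'
#' @param seq an `mstnn_video`.
#' @param target_rows,target_cols target frame size (default 48 x 54).
#' @return the resized `mstnn_video`.
#' @export
normalize_frames <- function(seq, target_rows = 48L, target_cols = 54L) {
  stopifnot(target_rows >= 2, target_cols >= 2)
  d <- dim(seq$frames)
  stopifnot(d[1] >= 2, d[2] >= 2)
  out <- array(0, c(target_rows, target_cols, d[3]))
  for (t in seq_len(d[3])) {
    r <- EBImage::resize(seq$frames[, , t], w = target_rows, h = target_cols)
    out[, , t] <- pmin(pmax(as.numeric(r), 0), 1)
  }
  seq$frames <- out
  seq
}

#' Append black frames (the delay-response window)
#'
#' Appends `d` all-zero frames to the end of the sequence. These frames
#' carry no input; they are the steps on which the classifier output is
#' supervised during training and voted over at recognition time.
#'
#' @param seq an `mstnn_video`.
#' @param d number of black frames, >= 1.
#' @return the extended `mstnn_video` (T grows by d).
#' @export
append_black_frames <- function(seq, d = 15L) {
  if (d < 1) stop("the delay-response window requires d >= 1 black frames")
  dm <- dim(seq$frames)
  seq$frames <- array(c(seq$frames, numeric(dm[1] * dm[2] * d)),
                      c(dm[1], dm[2], dm[3] + d))
  seq
}

#' Moving-stripe occlusion specification
#'
#' Vertical black bars of width `bar_width` separated by `gap` visible
#' columns, moving `speed` pixels per frame from right to left (the
#' pattern has period `bar_width + gap` and wraps modularly). At the first
#' frame a bar sits flush with the right image edge, shifted by `phase`
#' additional pixels.
#'
#' @param bar_width bar width in pixels (0 disables occlusion).
#' @param gap visible gap between bars in pixels (default 5).
#' @param speed bar speed in pixels per frame (default 2).
#' @param phase initial phase offset in pixels.
#' @return an `occlusion_spec`.
#' @export
occlusion_spec <- function(bar_width, gap = 5L, speed = 2L, phase = 0L) {
  stopifnot(bar_width >= 0, gap >= 1, speed >= 0, phase >= 0)
  structure(list(bar_width = as.integer(bar_width), gap = as.integer(gap),
                 speed = as.integer(speed), phase = as.integer(phase)),
            class = "occlusion_spec")
}

#' Occlude a sequence with moving vertical stripes
#'
#' Sets the columns covered by the bars to intensity 0 in every frame.
#' Already-black frames are unchanged in effect. The occlusion is
#' deterministic: applying the same spec twice gives the same result.
#'
#' @param seq an `mstnn_video`.
#' @param occ an [occlusion_spec()], or a bare bar width.
#' @return the occluded `mstnn_video` (tag becomes `"occluded"` when the
#'   bar width is positive).
#' @export
apply_occlusion <- function(seq, occ) {
  if (is.numeric(occ)) occ <- occlusion_spec(occ)
  if (occ$bar_width == 0L) return(seq)
  d <- dim(seq$frames)
  period <- occ$bar_width + occ$gap
  cols0 <- seq_len(d[2]) - 1L # 0-based column index from the left
  for (t in seq_len(d[3])) {
    # bars shift toward lower column indices (right to left) each frame
    offset <- (t - 1L) * occ$speed + occ$phase
    masked <- ((d[2] - 1L - cols0 - offset) %% period) < occ$bar_width
    seq$frames[, masked, t] <- 0
  }
  seq$tag <- "occluded"
  seq
}

# internal: the stripe mask of one frame (TRUE = blacked out)
occlusion_mask <- function(ncols, t, occ) {
  period <- occ$bar_width + occ$gap
  cols0 <- seq_len(ncols) - 1L
  ((ncols - 1L - cols0 - (t - 1L) * occ$speed - occ$phase) %% period) <
    occ$bar_width
}

#' Concatenate two actions into a composite sequence
#'
#' Builds a contextual-recognition sequence: the first
#' `frames_per_action` frames of `seq_a`, then the first
#' `frames_per_action` frames of `seq_b`, then `d` black frames
#' (42 + 42 + 15 = 99 frames with the defaults). Both sources must come
#' from the same subject. The composite label is the ordered-pair index
#' `(first - 1) * n_actions + second`, so with 3 base actions there are
#' 9 categories and (A,B) differs from (B,A).
#'
#' @param seq_a,seq_b source `mstnn_video`s of the same subject and size.
#' @param frames_per_action frames taken from each source (default 42).
#' @param d appended black frames (default 15).
#' @param n_actions number of base action classes (default 3).
#' @return the concatenated `mstnn_video` with `first_label` and
#'   `second_label` recorded.
#' @export
concatenate_actions <- function(seq_a, seq_b, frames_per_action = 42L,
                                d = 15L, n_actions = 3L) {
  if (!identical(seq_a$subject, seq_b$subject))
    stop("cannot concatenate actions from subjects '", seq_a$subject,
         "' and '", seq_b$subject, "'")
  da <- dim(seq_a$frames); db <- dim(seq_b$frames)
  if (!identical(da[1:2], db[1:2])) stop("frame dimensions differ")
  if (da[3] < frames_per_action || db[3] < frames_per_action)
    stop("source sequences must have at least ", frames_per_action, " frames")
  frames <- array(c(seq_a$frames[, , seq_len(frames_per_action)],
                    seq_b$frames[, , seq_len(frames_per_action)],
                    numeric(da[1] * da[2] * d)),
                  c(da[1], da[2], 2L * frames_per_action + d))
  label <- (seq_a$label - 1L) * n_actions + seq_b$label
  video_sequence(frames, label, seq_a$subject, tag = "concatenated",
                 first_label = seq_a$label, second_label = seq_b$label)
}

#' Leave-one-subject-out folds
#'
#' One fold per distinct subject: the fold's test set is that subject's
#' sequences and its training set is everyone else's, so train and test
#' subjects never overlap and the test sets partition the dataset.
#'
#' @param dataset list of `mstnn_video`.
#' @return list of folds, each a list with `subject`, `train` and `test`
#'   index vectors into `dataset`.
#' @export
loso_splits <- function(dataset) {
  subjects <- vapply(dataset, function(s) s$subject, character(1))
  uniq <- sort(unique(subjects))
  if (length(uniq) < 2L)
    stop("leave-one-subject-out needs at least 2 distinct subjects")
  lapply(uniq, function(s)
    list(subject = s, train = which(subjects != s), test = which(subjects == s)))
}
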