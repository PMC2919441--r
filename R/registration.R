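#' Per-image rigid shift specification
#'
#' Integer-pixel translations correcting motion misregistration before
#' fitting. Sign convention: positive `dx` moves an image right (towards
#' higher columns), positive `dy` moves it down (towards higher rows).
#' Sub-pixel shifts, rotation and non-rigid warping are out of scope.
#'
#' @param image_index 1-based indices into the stack, unique.
#' @param dx,dy integer displacements in pixels.
#' @return an object of class `shift_spec` (a data frame).
#' @export
shift_spec <- function(image_index = integer(0), dx = integer(0),
                       dy = integer(0)) {
  stopifnot(length(image_index) == length(dx),
            length(image_index) == length(dy))
  if (anyDuplicated(image_index)) {
    stop("duplicate image index in shift specification", call. = FALSE)
  }
  if (any(image_index < 1) || any(image_index != round(image_index)) ||
      any(dx != round(dx)) || any(dy != round(dy))) {
    stop("image indices must be positive integers and shifts whole pixels",
         call. = FALSE)
  }
  structure(data.frame(image_index = as.integer(image_index),
                       dx = as.integer(dx), dy = as.integer(dy)),
            class = c("shift_spec", "data.frame"))
}

translate_matrix <- function(m, dx, dy, fill = 0) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  if (any(ok_r) && any(ok_c)) {
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  }
  out
}

#' Apply rigid shifts to a source image set
#'
#' Translates each listed image by its `(dx, dy)`; vacated border pixels are
#' set to `fill` (default 0, which keeps them below any sensible noise gate
#' so they self-exclude from fitting). Unlisted images and all timing
#' metadata are untouched.
#'
#' @param stack a [source_image_set()].
#' @param spec a [shift_spec()].
#' @param fill intensity for vacated pixels.
#' @return the shifted [source_image_set()].
#' @export
apply_shifts <- function(stack, spec, fill = 0) {
  if (nrow(spec) == 0) return(stack)
  n <- length(stack$images)
  if (any(spec$image_index > n)) {
    stop("shift specification refers to image index beyond the stack",
         call. = FALSE)
  }
  d <- dim(stack$images[[1]])
  if (any(abs(spec$dx) >= d[2]) || any(abs(spec$dy) >= d[1])) {
    stop("shift larger than the image", call. = FALSE)
  }
  for (i in seq_len(nrow(spec))) {
    k <- spec$image_index[i]
    stack$images[[k]] <- translate_matrix(stack$images[[k]],
                                          spec$dx[i], spec$dy[i], fill)
  }
  stack
}

#' Read / write a shift file
#'
#' Plain-text format, one image per line: `index dx dy`, `#` comments and
#' blank lines ignored. Round trips exactly.
#'
#' @param path file path.
#' @return [read_shift_file()] returns a [shift_spec()].
#' @export
read_shift_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) return(shift_spec())
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 3 |
                 vapply(parts, function(p)
                   anyNA(suppressWarnings(as.integer(p))), logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed shift file line %d: '%s'",
                 keep[bad[1]], lines[keep[bad[1]]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(parts, as.integer))
  if (anyDuplicated(m[, 1])) {
    dup <- m[duplicated(m[, 1]), 1][1]
    stop(sprintf("duplicate image index %d in shift file", dup), call. = FALSE)
  }
  shift_spec(m[, 1], m[, 2], m[, 3])
}

#' @rdname read_shift_file
#' @param spec a [shift_spec()].
#' @export
write_shift_file <- function(spec, path) {
  writeLines(c("# image_index dx dy",
               sprintf("%d %d %d", spec$image_index, spec$dx, spec$dy)),
             path)
  invisible(path)
}

#' Render shifted source images for visual registration checks
#'
#' Writes one PNG per image with the shifts applied and a checkerboard grid
#' overlay, a static aid for judging alignment across the stack.
#'
#' @param stack a [source_image_set()].
#' @param spec a [shift_spec()].
#' @param out_dir output directory.
#' @param grid_size checker cell size in pixels.
#' @return paths of the written files, invisibly.
#' @export
register_preview <- function(stack, spec, out_dir, grid_size = 16) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  shifted <- apply_shifts(stack, spec)
  d <- dim(shifted$images[[1]])
  checker <- (outer(seq_len(d[1]) %/% grid_size,
                    seq_len(d[2]) %/% grid_size, "+") %% 2) * 0.15
  hi <- max(1, max(unlist(shifted$images)))
  paths <- character(length(shifted$images))
  for (i in seq_along(shifted$images)) {
    img <- pmin(shifted$images[[i]] / hi + checker, 1)
    paths[i] <- file.path(out_dir, sprintf("image_%02d.png", i))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
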