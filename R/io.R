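# Stack I/O: multi-page TIFF via the 'tiff' package (suggested).

#' Write / read an image stack as multi-page TIFF
#'
#' Thin wrappers around \pkg{tiff} for persisting rendered stacks; frame
#' times are not stored in the file and can be re-attached from the
#' matching drydown series.
#'
#' @param stack 3-d array `[row, col, frame]` with values in `[0, 1]`.
#' @param path File path.
#' @return `read_stack_tiff()` returns a 3-d array; `write_stack_tiff()`
#'   the path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O", call. = FALSE)
  frames <- tiff::readTIFF(path, all = TRUE)
  out <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) out[, , f] <- frames[[f]]
  class(out) <- "ovt_stack"
  out
}
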