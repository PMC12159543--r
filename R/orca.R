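# Object-of-interest Recursive Centering Algorithm (ORCA): re-extract a tile
# with shifted boundaries until the detected vessel sits at the tile center.

#' Centering target of a binary detection mask
#'
#' The default target is the centroid of the largest 8-connected vessel
#' component, which resolves multi-vessel tiles deterministically;
#' `mode = "union"` returns the centroid of all vessel pixels (useful for
#' clusters that should be centered as a group).
#'
#' @param mask binary matrix (non-zero = vessel).
#' @param mode `"largest"` or `"union"`.
#' @return numeric `(row, col)` centroid (0-based), or `NULL` when the mask
#'   is empty.
#' @export
target_point <- function(mask, mode = c("largest", "union")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mask))
  if (!any(mask != 0)) return(NULL)
  if (mode == "largest") {
    lab <- label_components(mask, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    idx <- which(lab == which.max(sizes), arr.ind = TRUE) - 1
  } else {
    idx <- which(mask != 0, arr.ind = TRUE) - 1
  }
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

clamp_origin <- function(origin, src_dim, tile_size) {
  pmin(pmax(round(origin), 0), src_dim - tile_size)
}

extract_tile <- function(source, origin, tile_size) {
  source[(origin[1] + 1):(origin[1] + tile_size),
         (origin[2] + 1):(origin[2] + tile_size), drop = FALSE]
}

#' Recursively center a tile onto the detected vessel
#'
#' Starting from `seed_origin`, each iteration extracts the current tile from
#' the source image, runs the segmenter, binarizes the output, finds the
#' centering target, and re-extracts the tile at the origin that puts the
#' target at the tile center (clamped to the source bounds, never padded).
#' Iteration stops when the Euclidean shift of the origin falls below
#' `shift_threshold` (converged), when no vessel is detected (empty
#' detection), or at `max_iter`.
#'
#' @param source numeric matrix, the image to extract tiles from.
#' @param seed_origin `(row, col)` 0-based top-left corner of the first tile.
#' @param segmenter function tile -> [probability_map()]; defaults to
#'   [reference_vessel_segmenter()].
#' @param tile_size tile edge length in pixels.
#' @param shift_threshold convergence threshold on the origin shift (px).
#' @param max_iter iteration cap.
#' @param target_mode passed to [target_point()].
#' @param binarize_threshold passed to [binarize()].
#' @return list with `tile` (the final tile) and `trace`, a
#'   `centering_trace` object: `origins` (matrix of 0-based origins, one row
#'   per visited origin), `shifts` (length `nrow(origins) - 1`), `converged`,
#'   `iterations`, `reason`, and `final_target` (absolute source coordinates
#'   of the last detected target, or `NULL`).
#' @export
orca_center <- function(source, seed_origin, segmenter = reference_vessel_segmenter,
                        tile_size = 512, shift_threshold = 8, max_iter = 10,
                        target_mode = c("largest", "union"),
                        binarize_threshold = 0.5) {
  target_mode <- match.arg(target_mode)
  stopifnot(is.matrix(source), length(seed_origin) == 2,
            shift_threshold > 0, max_iter >= 1)
  src_dim <- dim(source)
  if (any(src_dim < tile_size)) stop("source too small", call. = FALSE)
  origin <- clamp_origin(as.numeric(seed_origin), src_dim, tile_size)
  origins <- matrix(origin, 1, 2, dimnames = list(NULL, c("row", "col")))
  shifts <- numeric(0)
  converged <- FALSE
  reason <- "max_iter"
  final_target <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    tile <- extract_tile(source, origin, tile_size)
    mask <- binarize(segmenter(tile), threshold = binarize_threshold)
    tgt <- target_point(mask, mode = target_mode)
    if (is.null(tgt)) { reason <- "empty detection"; break }
    abs_tgt <- origin + tgt
    final_target <- unname(abs_tgt)
    new_origin <- clamp_origin(abs_tgt - tile_size / 2, src_dim, tile_size)
    shift <- sqrt(sum((new_origin - origin)^2))
    origins <- rbind(origins, new_origin)
    shifts <- c(shifts, shift)
    origin <- new_origin
    if (shift < shift_threshold) { converged <- TRUE; reason <- "converged"; break }
  }
  trace <- structure(list(origins = origins, shifts = shifts,
                          converged = converged, iterations = iter,
                          reason = reason, final_target = final_target,
                          tile_size = tile_size,
                          shift_threshold = shift_threshold),
                     class = "centering_trace")
  list(tile = extract_tile(source, origin, tile_size), trace = trace)
}

#' @export
print.centering_trace <- function(x, ...) {
  cat(sprintf("<centering_trace> %d iteration(s), %s (%s)\n", x$iterations,
              if (x$converged) "converged" else "not converged", x$reason))
  if (length(x$shifts))
    cat("  shifts (px):", paste(sprintf("%.1f", x$shifts), collapse = ", "), "\n")
  cat(sprintf("  final origin: (%d, %d)\n",
              x$origins[nrow(x$origins), 1], x$origins[nrow(x$origins), 2]))
  invisible(x)
}
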