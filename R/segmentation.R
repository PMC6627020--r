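#' Load a time-lapse TIFF stack
#'
#' Reads a multi-page TIFF (8/16-bit or float, single- or multi-channel)
#' into a `frame_stack`: an ordered list of 2-D intensity matrices plus the
#' spatial and temporal calibration. The image convention is matrix row =
#' y (downward), column = x (rightward), pixel centres at integer
#' coordinates starting at 1.
#'
#' @param path path to a multi-page TIFF file.
#' @param channel 1-based channel index for multi-channel pages.
#' @param pixel_size_um microns per pixel (> 0).
#' @param frame_interval_min minutes per frame (> 0).
#' @return A `frame_stack`: list with `frames` (list of matrices),
#'   `pixel_size_um`, `frame_interval_min`.
#' @export
load_stack <- function(path, channel = 1L, pixel_size_um = 1,
                       frame_interval_min = 1) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) {
      if (channel > dim(pg)[3]) {
        stop("channel ", channel, " missing: page has ", dim(pg)[3],
             " channel(s)")
      }
      pg <- pg[, , channel]
    } else if (channel != 1L) {
      stop("channel ", channel, " missing: single-channel stack")
    }
    pg
  })
  frame_stack(frames, pixel_size_um, frame_interval_min)
}

#' Construct a frame stack from in-memory images
#'
#' @param frames list of numeric matrices, identical dimensions.
#' @inheritParams load_stack
#' @return A `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size_um = 1, frame_interval_min = 1) {
  stopifnot(length(frames) >= 1L, pixel_size_um > 0, frame_interval_min > 0)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("non-uniform frame sizes in stack")
  }
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "frame_stack")
}

# merge 4-connected labels that touch diagonally, yielding 8-connectivity
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) <= 1L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  # tiny union-find over label ids
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment one frame into a nuclear mask
#'
#' Thresholds a fluorescence frame (automatic Otsu threshold, recomputed
#' per frame, or a fixed value), optionally fills holes, removes objects
#' below `min_area`, and labels the remaining objects with 8-connectivity.
#'
#' @param frame 2-D numeric matrix.
#' @param method `"otsu"` or a single numeric threshold (pixels strictly
#'   above the threshold are foreground).
#' @param min_area minimum object area in px^2; smaller components are
#'   dropped (default 200).
#' @param fill_holes fill interior holes of each object (default `TRUE`).
#' @param smooth_sigma Gaussian pre-smoothing s.d. in px applied before
#'   thresholding (default 0 = none). Recommended 1-2 for noisy movies: a
#'   nucleus occupying a small fraction of a wide field gives Otsu an
#'   extremely unbalanced histogram, and without smoothing the threshold
#'   can split the background mode instead of separating the nucleus.
#' @param frame_index frame number recorded in the result.
#' @return A `mask_frame`: list with `mask` (logical matrix), `labels`
#'   (integer matrix, 0 = background), `n_objects`, `threshold`,
#'   `frame_index`, and `empty` (flag: no object survived).
#' @export
segment_frame <- function(frame, method = "otsu", min_area = 200,
                          fill_holes = TRUE, smooth_sigma = 0,
                          frame_index = 1L) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  if (smooth_sigma > 0) frame <- EBImage::gblur(frame, sigma = smooth_sigma)
  rng <- range(frame)
  if (identical(method, "otsu")) {
    if (rng[1] == rng[2]) {
      thr <- rng[2]  # constant frame: nothing above threshold
    } else {
      norm <- (frame - rng[1]) / (rng[2] - rng[1])
      thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256L)
      thr <- rng[1] + thr * (rng[2] - rng[1])
    }
  } else if (is.numeric(method) && length(method) == 1L) {
    thr <- method
  } else {
    stop("method must be \"otsu\" or a single numeric threshold")
  }
  mask <- frame > thr
  storage.mode(mask) <- "integer"
  if (fill_holes && any(mask > 0)) {
    mask <- EBImage::fillHull(mask)
  }
  lab <- if (any(mask > 0)) merge_diagonal_labels(EBImage::bwlabel(mask))
         else mask
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0] <- match(lab[lab > 0], keep)
  }
  structure(list(mask = lab > 0, labels = lab,
                 n_objects = max(lab), threshold = thr,
                 frame_index = frame_index, empty = max(lab) == 0L),
            class = "mask_frame")
}

# area centroid (x = col, y = row) of labelled object `id`
label_centroid <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

#' Trace the outline of a single mask object
#'
#' Extracts a sub-pixel closed outline by marching squares at the 0.5
#' iso-level of the binary object (the contour passes through pixel-edge
#' midpoints), then applies a light circular moving-average smoothing of
#' the vertices so that perimeters of rasterised smooth shapes converge to
#' their continuum values instead of being inflated by staircase steps.
#'
#' @param mask_object logical/0-1 matrix containing exactly one connected
#'   component.
#' @param smooth_window odd vertex-smoothing window (1 = no smoothing;
#'   default 5).
#' @return A simple polygon `list(x, y)` in pixel coordinates (x = column,
#'   y = row).
#' @export
extract_outline <- function(mask_object, smooth_window = 5L) {
  m <- mask_object
  storage.mode(m) <- "integer"
  lab <- merge_diagonal_labels(EBImage::bwlabel(m))
  if (max(lab) == 0L) stop("empty mask: no object to outline")
  if (max(lab) > 1L) stop("multi-component input: expected a single object")
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  # contourLines wants z[i, j] at (x[i], y[j]); transpose so x = column
  cl <- grDevices::contourLines(x = 0:(nc + 1L), y = 0:(nr + 1L),
                                z = t(pad), levels = 0.5)
  if (length(cl) == 0L) stop("no contour found")
  areas <- vapply(cl, function(cc) poly_area(list(x = cc$x, y = cc$y)),
                  numeric(1))
  cc <- cl[[which.max(areas)]]
  p <- list(x = cc$x, y = cc$y)
  # contourLines duplicates the closing vertex on closed contours
  n <- length(p$x)
  if (n > 1 && p$x[1] == p$x[n] && p$y[1] == p$y[n]) {
    p$x <- p$x[-n]; p$y <- p$y[-n]
  }
  if (length(p$x) < 4L || poly_area(p) < 2) {
    stop("degenerate outline: object too small to trace")
  }
  smooth_polygon(p, smooth_window)
}

# circular moving average of polygon vertices
smooth_polygon <- function(p, window = 5L) {
  window <- as.integer(window)
  n <- length(p$x)
  if (window <= 1L || n <= window) return(p)
  half <- window %/% 2L
  idx <- outer(seq_len(n), -half:half, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  list(x = rowMeans(matrix(p$x[idx], n)), y = rowMeans(matrix(p$y[idx], n)))
}

#' Track a single nucleus across mask frames
#'
#' Selects one object per frame (the largest, or the one nearest the
#' previous centroid), bridges losses of up to `max_gap` consecutive empty
#' frames by linear centroid interpolation (flagged, with the last real
#' outline carried along at the interpolated position), and splits the
#' sequence at longer gaps, keeping the longest segment.
#'
#' @param masks list of `mask_frame` objects in temporal order.
#' @param policy `"largest"` or `"nearest_centroid"`.
#' @param seed_centroid `c(x, y)` in px, required starting point for
#'   `"nearest_centroid"` when the first frame has several objects.
#' @param max_gap maximum number of consecutive objectless frames to
#'   interpolate over (default 2).
#' @param pixel_size_um,frame_interval_min calibration used for centroid
#'   (um) and time (min) columns.
#' @param smooth_window passed to [extract_outline()].
#' @return A `shape_sequence`: list with `outlines` (px polygons), `masks`,
#'   `centroids_px` (n x 2), `centroids_um`, `times_min`, `frames`,
#'   `gap_interpolated` (logical), plus the calibration.
#' @export
track_single_nucleus <- function(masks, policy = c("largest", "nearest_centroid"),
                                 seed_centroid = NULL, max_gap = 2L,
                                 pixel_size_um = 1, frame_interval_min = 1,
                                 smooth_window = 5L) {
  policy <- match.arg(policy)
  if (!any(!vapply(masks, `[[`, logical(1), "empty"))) {
    stop("no non-empty mask frame to track")
  }
  n <- length(masks)
  picked <- vector("list", n)   # list(label_id, centroid) or NULL
  prev <- seed_centroid
  if (policy == "nearest_centroid" && is.null(prev)) {
    first <- masks[[which(!vapply(masks, `[[`, logical(1), "empty"))[1]]]
    if (first$n_objects > 1L) {
      stop("nearest_centroid policy needs seed_centroid when the first ",
           "frame holds several objects")
    }
  }
  for (i in seq_len(n)) {
    mf <- masks[[i]]
    if (mf$empty) next
    cents <- t(vapply(seq_len(mf$n_objects), function(id)
      label_centroid(mf$labels, id), numeric(2)))
    id <- if (policy == "largest" || is.null(prev)) {
      which.max(tabulate(mf$labels[mf$labels > 0], nbins = mf$n_objects))
    } else {
      which.min((cents[, 1] - prev[1])^2 + (cents[, 2] - prev[2])^2)
    }
    picked[[i]] <- list(id = id, centroid = cents[id, ])
    prev <- cents[id, ]
  }
  present <- !vapply(picked, is.null, logical(1))
  # segments separated by runs of > max_gap missing frames
  runs <- rle(present)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg_id <- integer(n); cur <- 1L
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k] && runs$lengths[k] > max_gap) cur <- cur + 1L
    seg_id[starts[k]:ends[k]] <- cur
  }
  counts <- tapply(present, seg_id, sum)
  best_seg <- as.integer(names(counts)[which.max(counts)])
  idx <- which(seg_id == best_seg)
  idx <- idx[cumsum(present[idx]) > 0]            # trim leading gap frames
  idx <- idx[rev(cumsum(rev(present[idx]))) > 0]  # trim trailing gap frames
  cents <- matrix(NA_real_, length(idx), 2)
  outlines <- vector("list", length(idx))
  msk <- vector("list", length(idx))
  gap <- !present[idx]
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (present[i]) {
      mf <- masks[[i]]
      obj <- mf$labels == picked[[i]]$id
      storage.mode(obj) <- "integer"
      cents[j, ] <- picked[[i]]$centroid
      outlines[[j]] <- extract_outline(obj, smooth_window)
      msk[[j]] <- obj
    }
  }
  # linear interpolation across flagged gap frames
  if (any(gap)) {
    cents[, 1] <- stats::approx(idx[!gap], cents[!gap, 1], xout = idx)$y
    cents[, 2] <- stats::approx(idx[!gap], cents[!gap, 2], xout = idx)$y
    for (j in which(gap)) {
      jprev <- max(which(!gap & seq_along(gap) < j))
      src <- outlines[[jprev]]
      shift <- cents[j, ] - cents[jprev, ]
      outlines[[j]] <- poly_translate(src, shift[1], shift[2])
      msk[[j]] <- msk[[jprev]]
    }
  }
  structure(list(
    outlines = outlines, masks = msk,
    centroids_px = cents,
    centroids_um = cents * pixel_size_um,
    times_min = (idx - 1L) * frame_interval_min,
    frames = idx,
    gap_interpolated = gap,
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min
  ), class = "shape_sequence")
}

#' Segment a whole stack and track the nucleus
#'
#' Convenience wrapper: [segment_frame()] on every frame, then
#' [track_single_nucleus()].
#'
#' @param stack a `frame_stack`.
#' @inheritParams segment_frame
#' @inheritParams track_single_nucleus
#' @return A `shape_sequence`.
#' @export
segment_stack <- function(stack, method = "otsu", min_area = 200,
                          fill_holes = TRUE, smooth_sigma = 0,
                          policy = "largest", seed_centroid = NULL,
                          max_gap = 2L, smooth_window = 5L) {
  masks <- lapply(seq_along(stack$frames), function(i) {
    segment_frame(stack$frames[[i]], method = method, min_area = min_area,
                  fill_holes = fill_holes, smooth_sigma = smooth_sigma,
                  frame_index = i)
  })
  track_single_nucleus(masks, policy = policy, seed_centroid = seed_centroid,
                       max_gap = max_gap,
                       pixel_size_um = stack$pixel_size_um,
                       frame_interval_min = stack$frame_interval_min,
                       smooth_window = smooth_window)
}

#' Write per-frame outlines to CSV
#'
#' Long format: frame, vertex_index, x_px, y_px.
#'
#' @param sequence a `shape_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_outlines <- function(sequence, path) {
  tabs <- lapply(seq_along(sequence$outlines), function(i) {
    p <- sequence$outlines[[i]]
    data.frame(frame = sequence$frames[i], vertex_index = seq_along(p$x),
               x_px = p$x, y_px = p$y)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Write a binary mask stack as multi-page TIFF
#'
#' @param sequence a `shape_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(sequence, path) {
  imgs <- lapply(sequence$masks, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(imgs, path)
  invisible(path)
}
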