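#' Probe geometry: optode layouts and channel enumeration
#'
#' A `probe_layout` holds optode positions on a planar head patch (mm, z = 0
#' at the scalp surface, origin at the layout centroid) together with the
#' enumerated source-detector channels grouped into distance classes.
#'
#' Two layouts are provided: a traditional sparse grid with 30 mm channel
#' spacing modeled after a 3 x 11 alternating source/detector arrangement,
#' and a high-density (HD) hexagonal layout whose nearest-neighbour channel
#' lengths are 8 mm (short separation), 19 mm, and 33 mm.
#'
#' @name probe
NULL

#' @keywords internal
new_optode <- function(id, role, x, y, z = 0) {
  stopifnot(role %in% c("source", "detector"))
  list(id = as.integer(id), role = role, pos = c(x, y, z))
}

distance_class_label <- function(center) {
  switch(as.character(center),
    "8"  = "SS8",
    "19" = "NN19",
    "30" = "NN30",
    "33" = "NN33",
    paste0("NN", center)
  )
}

#' Enumerate source-detector channels by distance bins
#'
#' Forms every source-detector pair whose Euclidean separation falls inside
#' one of the supplied distance bins. Ordering is deterministic: ascending
#' source id, then detector id.
#'
#' @param layout a `probe_layout` (only its `optodes` table is used), or a
#'   list with an `optodes` data frame.
#' @param bins a list of `c(center, tol)` pairs in mm; a pair is kept when
#'   `|separation - center| <= tol` for some bin.
#' @return a data frame with columns `source_id`, `detector_id`,
#'   `separation`, `distance_class`, `is_short`.
#' @export
enumerate_channels <- function(layout, bins) {
  if (length(bins) == 0) stop("no distance bins")
  opt <- layout$optodes
  src <- opt[opt$role == "source", , drop = FALSE]
  det <- opt[opt$role == "detector", , drop = FALSE]
  stopifnot(nrow(src) >= 1, nrow(det) >= 1)
  dx <- outer(src$x, det$x, "-")
  dy <- outer(src$y, det$y, "-")
  dz <- outer(src$z, det$z, "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  out <- NULL
  hit <- matrix(NA_real_, nrow(src), nrow(det))
  for (b in bins) {
    sel <- abs(dist - b[1]) <= b[2]
    hit[sel] <- b[1]
  }
  idx <- which(!is.na(hit), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(source_id = integer(), detector_id = integer(),
                      separation = numeric(), distance_class = character(),
                      is_short = logical()))
  }
  out <- data.frame(
    source_id = src$id[idx[, 1]],
    detector_id = det$id[idx[, 2]],
    separation = dist[idx],
    distance_class = vapply(hit[idx], distance_class_label, character(1)),
    is_short = hit[idx] == 8
  )
  out <- out[order(out$source_id, out$detector_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
make_layout <- function(name, optodes, bins, wavelengths = c(760, 850)) {
  # re-center so the origin sits at the optode centroid
  optodes$x <- optodes$x - mean(range(optodes$x))
  optodes$y <- optodes$y - mean(range(optodes$y))
  stopifnot(!anyDuplicated(optodes$id[optodes$role == "source"]),
            !anyDuplicated(optodes$id[optodes$role == "detector"]))
  layout <- list(name = name, optodes = optodes, wavelengths = wavelengths,
                 bins = bins)
  layout$channels <- enumerate_channels(layout, bins)
  class(layout) <- "probe_layout"
  layout
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout '%s'> %d sources, %d detectors, %d channels\n",
              x$name, sum(x$optodes$role == "source"),
              sum(x$optodes$role == "detector"), nrow(x$channels)))
  print(table(x$channels$distance_class))
  invisible(x)
}

# Attach one short-separation detector 8 mm from each designated source,
# offset outward (perpendicular to the rows, away from the array interior)
# so that the new detector falls inside no other layout distance bin.
attach_short_detectors <- function(optodes, ss_source_ids, next_det_id) {
  yc <- mean(range(optodes$y))
  add <- NULL
  for (sid in ss_source_ids) {
    s <- optodes[optodes$role == "source" & optodes$id == sid, ]
    dir <- if (s$y >= yc) 1 else -1
    add <- rbind(add, data.frame(id = next_det_id, role = "detector",
                                 x = s$x, y = s$y + dir * 8, z = 0,
                                 stringsAsFactors = FALSE))
    next_det_id <- next_det_id + 1L
  }
  rbind(optodes, add)
}

#' Build the sparse grid layout
#'
#' A 3-row by 11-column alternating source/detector grid at 30 mm pitch
#' (corners are sources), giving 17 sources and 16 detectors and 52 channels
#' at exactly 30 mm. Eight additional short-separation detectors are placed
#' 8 mm from the eight sources nearest the vertical midline in the top and
#' bottom rows, adding 8 channels at 8 mm (60 channels in total).
#'
#' @return a `probe_layout` named `"sparse"`.
#' @export
build_sparse_layout <- function() {
  pitch <- 30
  rows <- 0:2
  cols <- 0:10
  grid <- expand.grid(i = rows, j = cols)
  grid <- grid[order(grid$i, grid$j), ]
  role <- ifelse((grid$i + grid$j) %% 2 == 0, "source", "detector")
  optodes <- data.frame(
    id = NA_integer_, role = role,
    x = grid$j * pitch, y = grid$i * pitch, z = 0,
    stringsAsFactors = FALSE
  )
  optodes$id[optodes$role == "source"] <- seq_len(sum(role == "source"))
  optodes$id[optodes$role == "detector"] <- seq_len(sum(role == "detector"))

  # short-separation carriers: 4 sources nearest the midline in each of the
  # top and bottom rows (columns 2,4,6,8 at x = 60,120,180,240)
  ss_src <- optodes[optodes$role == "source" &
                      optodes$y %in% c(0, 60) &
                      optodes$x %in% c(60, 120, 180, 240), "id"]
  optodes <- attach_short_detectors(optodes, sort(ss_src),
                                    next_det_id = sum(role == "detector") + 1L)
  make_layout("sparse", optodes, bins = list(c(8, 2), c(30, 2)))
}

#' Build the high-density hexagonal layout
#'
#' All optodes sit on a five-row triangular lattice with 19 mm pitch, so
#' that lattice nearest neighbours are 19 mm apart and second lattice
#' neighbours are 19*sqrt(3) = 32.9 mm, i.e. the 33 mm distance class.
#' Rows 0, 2 and 4 carry 17 nodes, rows 1 and 3 carry 16 (83 optodes).
#' Sources occupy even columns of the outer rows (excluding the center
#' column) and odd columns plus the center column of the middle row: exactly
#' 25 sources and 58 detectors, mirror-symmetric about the midline. Eight
#' short-separation detectors at 8 mm are attached to the eight sources
#' nearest the midline. The field of view matches the sparse layout's
#' bounding box within 10%.
#'
#' @return a `probe_layout` named `"hd"`.
#' @export
build_hd_layout <- function() {
  pitch <- 19
  rowh <- pitch * sqrt(3) / 2
  nodes <- NULL
  for (j in 0:4) {
    xs <- if (j %% 2 == 0) pitch * (0:16) else pitch / 2 + pitch * (0:15)
    nodes <- rbind(nodes, data.frame(x = xs, y = rowh * j, row = j))
  }
  col <- round((nodes$x - ifelse(nodes$row %% 2 == 0, 0, pitch / 2)) / pitch)
  is_src <- ifelse(nodes$row %in% c(0, 4),
                   col %% 2 == 0 & col != 8,
                   ifelse(nodes$row == 2, col %% 2 == 1 | col == 8, FALSE))
  optodes <- data.frame(
    id = NA_integer_,
    role = ifelse(is_src, "source", "detector"),
    x = nodes$x, y = nodes$y, z = 0,
    stringsAsFactors = FALSE
  )
  optodes <- optodes[order(optodes$y, optodes$x), ]
  optodes$id[optodes$role == "source"] <- seq_len(sum(is_src))
  optodes$id[optodes$role == "detector"] <- seq_len(sum(!is_src))

  # short-separation carriers: the four sources nearest the midline in each
  # of the top and bottom rows (columns 4, 6, 10, 12); detectors offset
  # outward so no foreign source falls in a distance bin
  src <- optodes[optodes$role == "source", ]
  ss_src <- src$id[src$y %in% c(0, 4 * rowh) &
                     round(src$x / pitch) %in% c(4, 6, 10, 12)]
  optodes <- attach_short_detectors(optodes, sort(ss_src),
                                    next_det_id = sum(!is_src) + 1L)
  make_layout("hd", optodes, bins = list(c(8, 2), c(19, 2), c(33, 2)))
}

#' Optode positions for a set of channels
#'
#' @param layout a `probe_layout`.
#' @return a list with matrices `src` and `det` (one row per channel, mm)
#'   and `mid`, the channel midpoints projected on the scalp plane.
#' @export
channel_positions <- function(layout) {
  opt <- layout$optodes
  ch <- layout$channels
  src <- opt[opt$role == "source", ]
  det <- opt[opt$role == "detector", ]
  sp <- as.matrix(src[match(ch$source_id, src$id), c("x", "y", "z")])
  dp <- as.matrix(det[match(ch$detector_id, det$id), c("x", "y", "z")])
  rownames(sp) <- rownames(dp) <- NULL
  list(src = sp, det = dp, mid = (sp + dp) / 2)
}

#' Serialize a probe layout to JSON
#'
#' Writes name, optodes (id, role, x, y, z) and channels
#' (src, det, class) to a JSON file; `read_probe_json` restores it.
#'
#' @param layout a `probe_layout`.
#' @param path output file path.
#' @export
write_probe_json <- function(layout, path) {
  obj <- list(
    name = layout$name,
    wavelengths = layout$wavelengths,
    bins = lapply(layout$bins, function(b) list(center = b[1], tol = b[2])),
    optodes = layout$optodes[, c("id", "role", "x", "y", "z")],
    channels = data.frame(src = layout$channels$source_id,
                          det = layout$channels$detector_id,
                          class = layout$channels$distance_class)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probe_json
#' @export
read_probe_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bins <- lapply(seq_len(nrow(obj$bins)), function(i)
    c(obj$bins$center[i], obj$bins$tol[i]))
  layout <- list(name = obj$name, optodes = as.data.frame(obj$optodes),
                 wavelengths = obj$wavelengths, bins = bins)
  layout$channels <- enumerate_channels(layout, bins)
  class(layout) <- "probe_layout"
  layout
}
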