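ROI_LABELS <- c("tumor_mask", "capsule", "exclusion")

# Signed shoelace area; vertices is an n x 2 matrix of (x, y).
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- nrow(vertices)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Simplicity check: no non-adjacent pair of edges crosses or touches.
# Vectorized over the second edge so that a few-hundred-vertex outline stays
# cheap. Adjacent edges share a vertex by construction and are skipped.
polygon_is_simple <- function(vertices) {
  n <- nrow(vertices)
  nxt <- c(2:n, 1)
  x1 <- vertices[, 1]; y1 <- vertices[, 2]
  x2 <- x1[nxt]; y2 <- y1[nxt]
  cross2 <- function(ox, oy, ax, ay, px, py) (ax - ox) * (py - oy) - (ay - oy) * (px - ox)
  on_bbox <- function(ax, ay, bx, by, px, py)
    pmin(ax, bx) <= px & px <= pmax(ax, bx) & pmin(ay, by) <= py & py <= pmax(ay, by)
  for (i in seq_len(n - 1)) {
    js <- seq.int(i + 2, length.out = max(0, n - i - 1))
    if (i == 1) js <- js[js != n]  # edge n shares vertex 1 with edge 1
    if (!length(js)) next
    d1 <- cross2(x1[js], y1[js], x2[js], y2[js], x1[i], y1[i])
    d2 <- cross2(x1[js], y1[js], x2[js], y2[js], x2[i], y2[i])
    d3 <- cross2(x1[i], y1[i], x2[i], y2[i], x1[js], y1[js])
    d4 <- cross2(x1[i], y1[i], x2[i], y2[i], x2[js], y2[js])
    proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
              ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
    touch <- (d1 == 0 & on_bbox(x1[js], y1[js], x2[js], y2[js], x1[i], y1[i])) |
             (d2 == 0 & on_bbox(x1[js], y1[js], x2[js], y2[js], x2[i], y2[i])) |
             (d3 == 0 & on_bbox(x1[i], y1[i], x2[i], y2[i], x1[js], y1[js])) |
             (d4 == 0 & on_bbox(x1[i], y1[i], x2[i], y2[i], x2[js], y2[js]))
    if (any(proper | touch)) return(FALSE)
  }
  TRUE
}

#' Construct a region-of-interest polygon
#'
#' A simple (non-self-intersecting) closed polygon in 0-based pixel
#' coordinates, (x, y) ordered, labeling a tumor outline, a capsule region,
#' or an exclusion zone.
#'
#' @param vertices n x 2 numeric matrix (or list of pairs) of (x, y) vertex
#'   coordinates, at least 3 vertices, implicitly closed
#' @param label one of `"tumor_mask"`, `"capsule"`, `"exclusion"`
#' @param source_id free-text provenance
#' @return a `RegionOfInterest`
#' @export
region_of_interest <- function(vertices, label = "tumor_mask", source_id = "") {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stopf("vertices must be (x, y) pairs")
  if (nrow(vertices) < 3) stopf("polygon needs >= 3 vertices, got %d", nrow(vertices))
  if (!label %in% ROI_LABELS)
    stopf("label must be one of %s", paste(ROI_LABELS, collapse = ", "))
  if (anyDuplicated(vertices)) stopf("polygon has duplicated vertices")
  if (!polygon_is_simple(vertices)) stopf("polygon is self-intersecting")
  a <- polygon_area(vertices)
  if (a <= 0) stopf("polygon area must be > 0 (got %g)", a)
  structure(list(vertices = unname(vertices), label = label,
                 source_id = as.character(source_id)),
            class = "RegionOfInterest")
}

#' @export
print.RegionOfInterest <- function(x, ...) {
  cat(sprintf("RegionOfInterest '%s': %d vertices, area %.6g px^2 (source '%s')\n",
              x$label, nrow(x$vertices), polygon_area(x$vertices), x$source_id))
  invisible(x)
}

#' Read a region of interest from its JSON interchange file
#'
#' Schema: `{"label": str, "vertices": [[x, y], ...], "source_id": str}`,
#' coordinates 0-based pixels. The polygon is validated (simple, >= 3
#' vertices, positive area).
#'
#' @param path JSON file path
#' @return a `RegionOfInterest`
#' @export
read_roi <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$vertices)) stopf("ROI file '%s' has no vertices field", path)
  region_of_interest(doc$vertices, label = doc$label %||% "tumor_mask",
                     source_id = doc$source_id %||% path)
}

#' Write a region of interest as JSON
#' @param roi a `RegionOfInterest`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "RegionOfInterest"))
  jsonlite::write_json(list(label = roi$label,
                            vertices = unname(roi$vertices),
                            source_id = roi$source_id),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rasterize a polygon: logical (y, x) matrix, TRUE where the pixel center
# (0-based integer coordinates) lies inside the polygon. Scanline fill with
# the same even-odd, strict "center left of crossing" convention as
# cpp_points_in_polygon, so the two agree except on measure-zero ties.
rasterize_polygon <- function(vertices, ny, nx) {
  n <- nrow(vertices)
  nxt <- c(2:n, 1)
  vx1 <- vertices[, 1]; vy1 <- vertices[, 2]
  vx2 <- vx1[nxt]; vy2 <- vy1[nxt]
  m <- matrix(FALSE, ny, nx)
  for (yi in 0:(ny - 1)) {
    hit <- (vy1 > yi) != (vy2 > yi)
    if (!any(hit)) next
    xc <- sort(vx1[hit] + (yi - vy1[hit]) * (vx2[hit] - vx1[hit]) / (vy2[hit] - vy1[hit]))
    for (k in seq(1, length(xc) - 1, by = 2)) {
      lo <- max(0, ceiling(xc[k]))
      hi <- min(nx - 1, ceiling(xc[k + 1]) - 1)
      if (lo <= hi) m[yi + 1, (lo:hi) + 1] <- TRUE
    }
  }
  m
}

# Exact Euclidean distance from points (px, py) to the polygon boundary
# (minimum over edges of the point-to-segment distance). Vectorized over
# points; loops over edges.
points_to_polygon_boundary <- function(px, py, vertices) {
  n <- nrow(vertices)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    a <- vertices[i, ]; b <- vertices[i %% n + 1, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    if (len2 == 0) {
      d2 <- (px - a[1])^2 + (py - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
      d2 <- (px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Read a sample table
#'
#' CSV with header `sample_id,group_label,image_path,roi_path`. Sample ids
#' must be unique, group labels non-empty, and (by default) every referenced
#' path must exist.
#'
#' @param path CSV path
#' @param check_paths verify that referenced files exist (default TRUE)
#' @return data.frame with the four columns
#' @export
read_sample_table <- function(path, check_paths = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group_label", "image_path", "roi_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample table missing column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(df)) stopf("sample table is empty")
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id in sample table: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!nzchar(df$group_label))) stopf("empty group_label in sample table")
  if (check_paths) {
    base <- dirname(path)
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    df$image_path <- resolve(df$image_path)
    df$roi_path <- resolve(df$roi_path)
    for (col in c("image_path", "roi_path")) {
      bad <- !file.exists(df[[col]])
      if (any(bad)) stopf("%s not readable for sample(s): %s", col,
                          paste(df$sample_id[bad], collapse = ", "))
    }
  }
  df[need]
}
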