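#' The eight land-cover classes
#'
#' Classes of the 0.6 m classified land-cover raster.
#'
#' @return Character vector of the eight class labels.
#' @export
land_classes <- function() {
  c("TreeCanopy", "GrassShrub", "BareEarth", "Water",
    "Building", "Road", "OtherPaved", "Agriculture")
}

# Classes retained for energy-budget weighting: Grass/Shrub and Agriculture
# are merged; Water and Building are excluded (buildings are not part of the
# pedestrian energy-budget calculation).
interest_classes <- function() {
  c("TreeCanopy", "GrassShrubAgri", "BareEarth", "Road", "OtherPaved")
}

#' Tract land-cover composition
#'
#' Per-tract pixel counts by land class, with the pixel size and the
#' polygon area of the tract boundary for the area-consistency check.
#'
#' @param tract_id Tract identifier.
#' @param pixel_counts Named integer vector over [land_classes()].
#' @param pixel_edge_m Pixel edge length, m.
#' @param polygon_area_ha Tract polygon area, ha (optional, `NA` to skip the
#'   consistency check).
#' @return A list of class `tract_composition` with `areas_ha` filled in.
#' @export
tract_composition <- function(tract_id, pixel_counts, pixel_edge_m = 0.6,
                              polygon_area_ha = NA_real_) {
  cls <- land_classes()
  counts <- setNames(rep(0, length(cls)), cls)
  if (!all(names(pixel_counts) %in% cls))
    stop("unknown land class in pixel_counts: ",
         paste(setdiff(names(pixel_counts), cls), collapse = ", "))
  counts[names(pixel_counts)] <- pixel_counts
  if (any(counts < 0)) stop("pixel counts must be >= 0")
  structure(list(tract_id = tract_id,
                 pixel_counts = counts,
                 pixel_edge_m = pixel_edge_m,
                 areas_ha = counts_to_areas(counts, pixel_edge_m),
                 polygon_area_ha = polygon_area_ha),
            class = "tract_composition")
}

#' Convert pixel counts to areas in hectares
#'
#' @param counts Named vector of per-class pixel counts.
#' @param pixel_edge_m Pixel edge length, m (positive).
#' @return Per-class areas, ha.
#' @export
counts_to_areas <- function(counts, pixel_edge_m = 0.6) {
  if (pixel_edge_m <= 0) stop("pixel_edge_m must be > 0")
  if (any(counts < 0)) stop("pixel counts must be >= 0")
  counts * pixel_edge_m^2 / 1e4
}

#' Area-consistency check of the extraction
#'
#' Relative discrepancy between the summed per-class areas and the tract
#' polygon area, as a percentage of the polygon area. Small values confirm
#' that whole-pixel assignment to tracts loses or gains little area.
#'
#' @param comp A [tract_composition()].
#' @return Absolute discrepancy, percent of tract area.
#' @export
area_consistency_check <- function(comp) {
  if (is.na(comp$polygon_area_ha) || comp$polygon_area_ha <= 0)
    stop("polygon_area_ha must be a positive number")
  abs(sum(comp$areas_ha) - comp$polygon_area_ha) / comp$polygon_area_ha * 100
}

#' Proportions of the land classes of interest
#'
#' Merges Grass/Shrub with Agriculture, drops Water and Building, and
#' renormalises the remaining proportions (Tree Canopy, Grass/Shrub +
#' Agriculture, Bare Earth, Road, Other Paved) to sum to one.
#'
#' @param comp A [tract_composition()] or a named count/area vector over
#'   [land_classes()].
#' @return Named proportions over [interest_classes()], summing to 1.
#' @export
proportions_of_interest <- function(comp) {
  counts <- if (inherits(comp, "tract_composition")) comp$pixel_counts else {
    full <- setNames(rep(0, 8), land_classes())
    full[names(comp)] <- comp
    full
  }
  merged <- c(TreeCanopy = unname(counts["TreeCanopy"]),
              GrassShrubAgri = unname(counts["GrassShrub"] +
                                        counts["Agriculture"]),
              BareEarth = unname(counts["BareEarth"]),
              Road = unname(counts["Road"]),
              OtherPaved = unname(counts["OtherPaved"]))
  tot <- sum(merged)
  if (tot <= 0) stop("no pixels in any included land class")
  merged / tot
}

#' Count pixels of a greyscale plan image by land class
#'
#' Master-plan images render each land class of interest as one unique grey
#' level; counting pixels per level recovers the class composition.
#'
#' @param image Integer matrix of grey levels.
#' @param legend Named integer vector mapping class name -> grey level.
#' @param strict If `TRUE` (default), any grey level absent from the legend
#'   is an error; otherwise unknown levels are tallied under an
#'   `"unknown"` attribute.
#' @return Named per-class pixel counts (attribute `unknown` carries counts
#'   of unmapped grey levels when `strict = FALSE`).
#' @export
classify_grey_plan <- function(image, legend, strict = TRUE) {
  if (anyDuplicated(legend))
    stop("legend grey levels must be unique per class")
  vals <- as.vector(image)
  known <- vals %in% legend
  if (!all(known)) {
    bad <- sort(unique(vals[!known]))
    if (strict)
      stop("grey level(s) not in legend: ", paste(bad, collapse = ", "))
  }
  counts <- vapply(legend, function(g) sum(vals == g), numeric(1))
  names(counts) <- names(legend)
  if (!all(known)) {
    unk <- table(vals[!known])
    attr(counts, "unknown") <- setNames(as.numeric(unk), names(unk))
  }
  counts
}

#' Render a plan image from per-class pixel counts
#'
#' Inverse of [classify_grey_plan()]: builds a grey-level matrix whose
#' per-class pixel counts exactly equal `counts` (padding, if any, uses the
#' first legend level and is added to its count on read-back only if
#' requested; by default dimensions are chosen to fit exactly).
#'
#' @param counts Named per-class pixel counts.
#' @param legend Named grey-level legend covering `names(counts)`.
#' @param shuffle Randomly permute pixels (purely cosmetic; counts are
#'   unchanged).
#' @return Integer matrix of grey levels.
#' @export
render_grey_plan <- function(counts, legend, shuffle = FALSE) {
  if (!all(names(counts) %in% names(legend)))
    stop("legend must cover every class in counts")
  px <- rep(unname(legend[names(counts)]), times = counts)
  if (shuffle) px <- sample(px)
  n <- length(px)
  ncol <- max(1L, floor(sqrt(n)))
  while (n %% ncol != 0) ncol <- ncol - 1L
  matrix(px, ncol = ncol)
}

#' Read tract polygons from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of (planar, metre-coordinate)
#' polygons and computes each tract's area by the shoelace formula. Only
#' simple exterior rings are supported, which is sufficient for the
#' synthetic tract layouts used here.
#'
#' @param path GeoJSON file path.
#' @param id_property Feature property holding the tract id.
#' @return `data.frame` with `tract_id` and `polygon_area_ha`.
#' @export
read_tract_polygons <- function(path, id_property = "tract_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    n <- nrow(xy)
    area <- abs(sum(xy[, 1] * xy[c(2:n, 1), 2] -
                      xy[c(2:n, 1), 1] * xy[, 2])) / 2
    data.frame(tract_id = as.character(f$properties[[id_property]]),
               polygon_area_ha = area / 1e4, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
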