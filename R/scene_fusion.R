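#' Multi-source overlay scene
#'
#' Orders the three monitoring products over the lake twin in the canonical
#' back-to-top stacking: in-situ stations at the back, satellite extent in the
#' middle, video coverage on top, so no source occludes another in a renderer.
#' The order is canonical regardless of how arguments are supplied; missing
#' roles are allowed and recorded. At most one layer per role per timestamp.
#'
#' @param in_situ,satellite,video layer payloads: either
#'   `list(payload =, timestamp =)`, a bare object carrying `$timestamp`
#'   (e.g. a `hab_mask`), or a list of several such layers. `NULL` skips the
#'   role.
#' @param twin optional `twin_lake` the scene is draped on.
#' @return an object of class `overlay_stack` with `layers` (ordered list of
#'   role/payload/timestamp) and `missing` (roles not supplied).
#' @export
assemble_overlay <- function(in_situ = NULL, satellite = NULL, video = NULL,
                             twin = NULL) {
  roles <- list(in_situ = in_situ, satellite = satellite, video = video)
  if (all(vapply(roles, is.null, TRUE)))
    stop("all layers absent: supply at least one of in_situ, satellite, video")
  layers <- list()
  for (role in names(roles)) {            # canonical back-to-top order
    raw <- roles[[role]]
    if (is.null(raw)) next
    entries <- if (is.list(raw) && is.null(names(raw)) && !is.data.frame(raw))
      raw else list(raw)
    stamps <- character(0)
    for (e in entries) {
      ts <- if (is.list(e) && !is.null(e$timestamp)) e$timestamp
            else attr(e, "timestamp")
      if (is.null(ts)) stop(sprintf("layer for role '%s' carries no timestamp", role))
      ts <- as_utc(ts)
      payload <- if (is.list(e) && !is.null(e$payload)) e$payload else e
      key <- format(ts, "%Y-%m-%dT%H:%M:%SZ")
      if (key %in% stamps)
        stop(sprintf("two '%s' layers share timestamp %s", role, key))
      stamps <- c(stamps, key)
      layers[[length(layers) + 1L]] <-
        list(role = role, payload = payload, timestamp = ts)
    }
  }
  structure(
    list(layers = layers,
         missing = names(roles)[vapply(roles, is.null, TRUE)],
         twin = twin),
    class = "overlay_stack")
}

#' @export
print.overlay_stack <- function(x, ...) {
  cat(sprintf("<overlay_stack> %d layer(s), back to top:\n", length(x$layers)))
  for (l in x$layers)
    cat(sprintf("  %-10s %s (%s)\n", l$role,
                format(l$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
                class(l$payload)[1]))
  if (length(x$missing)) cat("  missing roles:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

overlay_role <- function(stack, role) {
  hit <- Filter(function(l) l$role == role, stack$layers)
  if (!length(hit)) NULL else hit[[length(hit)]]$payload
}

#' Situation summary across sources
#'
#' Aggregates the fused scene into the figures an operator needs: whole-lake
#' HAB area from the satellite mask, max and mean nearshore coverage ratio
#' from the video product, latest station values from the in-situ records, and
#' a per-cell risk flag for subsurface accumulation: a cell is flagged when
#' surface bloom coverage is *low* yet chlorophyll-a somewhere in the water
#' column below exceeds a threshold, the situation where a bloom can surface
#' with little warning.
#'
#' @param stack an [assemble_overlay()] result.
#' @param field3d optional `field_3d` of Chl-a used for the risk rule.
#' @param risk_chl_threshold Chl-a level (field units, e.g. ug/L) above which
#'   a subsurface cell is risky. Default `Inf` disables flags.
#' @param surface_low_threshold surface coverage below this counts as "no
#'   bloom at the surface" (default 0.05).
#' @return an object of class `situation_summary`.
#' @export
summarize_situation <- function(stack, field3d = NULL,
                                risk_chl_threshold = Inf,
                                surface_low_threshold = 0.05) {
  stopifnot(inherits(stack, "overlay_stack"), length(stack$layers) > 0)
  sat <- overlay_role(stack, "satellite")
  vid <- overlay_role(stack, "video")
  ins <- overlay_role(stack, "in_situ")

  area_km2 <- if (inherits(sat, "hab_mask")) sat$area_km2 else NA_real_

  cov_max <- cov_mean <- NA_real_
  if (!is.null(vid)) {
    vals <- if (inherits(vid, "field_2d")) vid$values[is.finite(vid$values)]
            else if (is.data.frame(vid) && "ratio" %in% names(vid)) vid$ratio
            else numeric(0)
    if (length(vals)) { cov_max <- max(vals); cov_mean <- mean(vals) }
  }

  stations <- NULL
  if (is.data.frame(ins) && all(c("station_id", "parameter", "value") %in% names(ins))) {
    stations <- do.call(rbind, lapply(
      split(ins, list(ins$station_id, ins$parameter), drop = TRUE),
      function(r) r[order(r$timestamp), ][nrow(r), ]))
    rownames(stations) <- NULL
  }

  flags <- NULL; n_flagged <- 0L
  if (!is.null(field3d) && is.finite(risk_chl_threshold)) {
    sub_max <- apply(field3d$values, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    surf <- matrix(0, nrow(sub_max), ncol(sub_max))
    if (inherits(sat, "hab_mask") && identical(dim(sat$mask), dim(sub_max)))
      surf <- sat$mask * 1
    if (inherits(vid, "field_2d") && identical(dim(vid$values), dim(sub_max))) {
      w <- is.finite(vid$values)
      surf[w] <- pmax(surf[w], vid$values[w])
    }
    flags <- !is.na(sub_max) & surf < surface_low_threshold &
      sub_max > risk_chl_threshold
    n_flagged <- sum(flags)
  }

  ts <- do.call(c, lapply(stack$layers, `[[`, "timestamp"))
  structure(
    list(timestamp = max(ts), hab_area_km2 = area_km2,
         coverage_max = cov_max, coverage_mean = cov_mean,
         stations = stations, risk_flags = flags, n_flagged = n_flagged,
         risk_chl_threshold = risk_chl_threshold,
         surface_low_threshold = surface_low_threshold,
         missing = stack$missing),
    class = "situation_summary")
}

#' @export
print.situation_summary <- function(x, ...) {
  cat(sprintf("<situation_summary> %s\n", format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ")))
  cat(sprintf("  whole-lake HAB area: %s km^2\n",
              if (is.na(x$hab_area_km2)) "n/a" else sprintf("%.4f", x$hab_area_km2)))
  cat(sprintf("  nearshore coverage: max %s, mean %s\n",
              if (is.na(x$coverage_max)) "n/a" else sprintf("%.3f", x$coverage_max),
              if (is.na(x$coverage_mean)) "n/a" else sprintf("%.3f", x$coverage_mean)))
  if (!is.null(x$stations))
    cat(sprintf("  stations: %d latest parameter readings\n", nrow(x$stations)))
  cat(sprintf("  subsurface risk cells: %d\n", x$n_flagged))
  if (length(x$missing)) cat("  missing layers:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Write a situation summary as JSON
#' @param summary a `situation_summary`.
#' @param path output path.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "situation_summary"))
  out <- list(
    timestamp = format(summary$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
    hab_area_km2 = summary$hab_area_km2,
    coverage_max = summary$coverage_max,
    coverage_mean = summary$coverage_mean,
    n_risk_cells = summary$n_flagged,
    risk_chl_threshold = summary$risk_chl_threshold,
    surface_low_threshold = summary$surface_low_threshold,
    missing_layers = summary$missing,
    stations = summary$stations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
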