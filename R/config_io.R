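# Scene-configuration files: plain key = value text describing one simulated
# scene (layout, motion condition, speed, seed, flow variations), so that a
# flow field can be regenerated exactly from a small sidecar file.

#' Read or write a scene configuration file
#'
#' The format is one `key = value` pair per line; `#` starts a comment.
#' Recognized keys: `radius`, `eccentricity`, `direction`, `lambda`, `H`,
#' `seed`, `noise_sigma`, `hemifield`, `heading_x`, `heading_y`. Missing
#' numeric keys default to an object-free scene with a random heading.
#'
#' @param config named list of scene settings.
#' @param path file path.
#' @return `read_scene_config` returns a named list; `write_scene_config`
#'   returns `path` invisibly.
#' @export
write_scene_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, format(config[[k]], digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  out <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v) && p[2] != "NA") p[2] else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Build a scene from a configuration list
#'
#' @param config a list as returned by [read_scene_config()].
#' @return list with the [build_scene()] result (`scene`) and the flow
#'   field after the configured variations (`flow`).
#' @export
scene_from_config <- function(config) {
  g <- function(k, default = NULL) if (!is.null(config[[k]])) config[[k]] else default
  layout <- NULL
  if (!is.null(config$radius))
    layout <- list(radius = g("radius"), eccentricity = g("eccentricity", 0),
                   direction = g("direction", 0))
  heading <- if (!is.null(config$heading_x)) c(g("heading_x"), g("heading_y", 0))
  scene <- build_scene(layout, lambda = g("lambda", 0), H = g("H", 0),
                       heading = heading, seed = g("seed"))
  flow <- scene$combined
  hemi <- g("hemifield", "none")
  if (!identical(hemi, "none") && !is.null(layout))
    flow <- remove_hemifield(flow, hemi, layout$direction)
  sigma <- g("noise_sigma", 0)
  if (sigma > 0) flow <- apply_directional_noise(flow, sigma, seed = g("seed"))
  list(scene = scene, flow = flow)
}
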