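# Readers/writers: track files, setup configs, run tables, SVG rendering.

#' Read a track file
#'
#' Parses the package's plain-text track dialect:
#' ```
#' # any comment
#' interval_min: 20
#' pixel_scale: 0.767        # optional, pixels per um
#' cell 1 origin=start destiny=split
#' 0 12.5 30.1
#' 1 14.0 29.0
#' cell 2 ...
#' ```
#' Per-cell blocks list `frame x y` rows; frames must be strictly
#' increasing. When a pixel scale is present, coordinates are divided by it
#' to obtain um. Malformed rows are rejected with their line number.
#'
#' @param path file path.
#' @return a [track_set()].
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_raw <- lines
  strip <- sub("#.*$", "", lines)
  strip <- trimws(strip)
  interval <- NA_real_; scale <- NA_real_
  cells <- list(); origin <- c(); destiny <- c()
  cur <- NULL; cur_rows <- list()
  flush_cell <- function() {
    if (is.null(cur)) return()
    if (!length(cur_rows))
      stop("cell ", cur, " has no coordinate rows")
    m <- do.call(rbind, cur_rows)
    if (any(diff(m[, 1]) <= 0))
      stop("non-monotone frame numbers for cell ", cur)
    cells[[as.character(cur)]] <<- m
  }
  for (ln in seq_along(strip)) {
    s <- strip[ln]
    if (s == "") next
    if (grepl("^interval_min:", s)) {
      interval <- as.numeric(sub("^interval_min:", "", s))
      next
    }
    if (grepl("^pixel_scale:", s)) {
      scale <- as.numeric(sub("^pixel_scale:", "", s))
      next
    }
    if (grepl("^cell\\s", s)) {
      flush_cell()
      toks <- strsplit(s, "\\s+")[[1]]
      if (length(toks) < 2) stop("line ", ln, ": malformed cell header")
      cur <- toks[2]; cur_rows <- list()
      ori <- sub("^origin=", "", grep("^origin=", toks, value = TRUE))
      des <- sub("^destiny=", "", grep("^destiny=", toks, value = TRUE))
      if (length(ori)) {
        if (!ori %in% ORIGIN_LABELS)
          stop("line ", ln, ": unknown origin '", ori, "'")
        origin <- c(origin, stats::setNames(ori, cur))
      }
      if (length(des)) {
        if (!des %in% DESTINY_LABELS)
          stop("line ", ln, ": unknown destiny '", des, "'")
        destiny <- c(destiny, stats::setNames(des, cur))
      }
      next
    }
    toks <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
    if (length(toks) != 3 || anyNA(toks))
      stop("line ", ln, ": malformed row '", lines_raw[ln], "'")
    if (is.null(cur)) stop("line ", ln, ": coordinates before cell header")
    cur_rows[[length(cur_rows) + 1L]] <- toks
  }
  flush_cell()
  if (!length(cells)) stop("no tracks found in ", path)
  if (is.na(interval) || interval <= 0)
    stop("missing or invalid interval_min header")
  conv <- if (!is.na(scale)) 1 / scale else 1
  frames <- do.call(rbind, lapply(names(cells), function(cid) {
    m <- cells[[cid]]
    data.frame(cell = cid, time = m[, 1] * interval,
               x = m[, 2] * conv, y = m[, 3] * conv)
  }))
  track_set(frames, interval,
            origin = if (length(origin)) origin else NULL,
            destiny = if (length(destiny)) destiny else NULL)
}

#' Write a track file
#'
#' Deterministic serialisation of a [track_set()] in the dialect read by
#' [read_tracks()]: sorted cell ids, fixed 4-decimal precision, coordinates
#' in um (no pixel scale header is emitted).
#'
#' @param tracks a [track_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  f <- tracks$frames
  ids <- sort(unique(as.character(f$cell)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("interval_min: %g", tracks$interval), con)
  for (cid in ids) {
    sub <- f[as.character(f$cell) == cid, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    hdr <- paste0("cell ", cid)
    ori <- tracks$origin[[cid]]
    des <- tracks$destiny[[cid]]
    if (!is.null(ori) && !is.na(ori)) hdr <- paste0(hdr, " origin=", ori)
    if (!is.null(des) && !is.na(des)) hdr <- paste0(hdr, " destiny=", des)
    writeLines(hdr, con)
    writeLines(sprintf("%g %.4f %.4f", round(sub$time / tracks$interval),
                       sub$x, sub$y), con)
  }
  invisible(path)
}

# ---- setup configs ----------------------------------------------------------

#' Validate (and normalise) a setup config
#'
#' Accepts a config list or a path to a JSON/YAML file. The schema:
#' ```
#' plate:      width, height, serum_type, serum_level, molecules,
#'             constraints, fields (uniform: name, value, cell_size,
#'             half_life, degradable, bias_gain)
#' cell_type:  a packaged name ("nih3t3_like", "vero_e6_like") or a full
#'             parameter list understood by cell_type_params()
#' seeding:    list of {count | positions, init}
#' events:     list of {time, kind, <payload fields>}
#' run:        duration_min, interval_min, seed, record_frames
#' ```
#' Unknown event kinds, out-of-range times and invalid parameters are
#' rejected with an informative message; validated configs carry the
#' resolved `cell_params` object.
#'
#' @param config list or file path.
#' @return the normalised config (class `culture_config`).
#' @export
validate_config <- function(config) {
  if (inherits(config, "culture_config")) return(config)
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  for (req in c("plate", "seeding", "run"))
    if (is.null(config[[req]])) stop("config misses section '", req, "'")
  pl <- config$plate
  if (is.null(pl$width) || is.null(pl$height) || pl$width <= 0 ||
      pl$height <= 0) stop("plate width/height must be positive")
  if (is.null(pl$serum_level)) config$plate$serum_level <- 10
  if (is.null(pl$serum_type)) config$plate$serum_type <- "FBS"
  run <- config$run
  if (is.null(run$duration_min) || run$duration_min <= 0)
    stop("run$duration_min must be positive")
  if (is.null(run$interval_min)) config$run$interval_min <- 20
  if (config$run$interval_min <= 0) stop("run$interval_min must be positive")
  ct <- config$cell_type
  if (is.null(ct)) ct <- "nih3t3_like"
  config$cell_params <- if (is.character(ct)) cell_type_library(ct)
    else if (inherits(ct, "cell_type_params")) ct
    else do.call(cell_type_params, ct)
  for (i in seq_along(config$seeding)) {
    s <- config$seeding[[i]]
    if (is.null(s$count) && is.null(s$positions))
      stop("seeding entry ", i, " needs `count` or `positions`")
    if (!is.null(s$init) && !s$init %in% c("staggered", "fresh"))
      stop("seeding init must be 'staggered' or 'fresh'")
    if (!is.null(s$positions))
      config$seeding[[i]]$positions <- as.data.frame(s$positions)
  }
  evs <- config$events
  config$events <- lapply(seq_along(evs), function(i) {
    e <- evs[[i]]
    if (inherits(e, "event_spec")) return(e)
    if (is.null(e$time) || is.null(e$kind))
      stop("event ", i, " needs `time` and `kind`")
    if (!e$kind %in% EVENT_KINDS)
      stop("event ", i, ": unknown kind '", e$kind, "'")
    if (e$time < 0 || e$time > run$duration_min)
      stop("event ", i, ": time outside the run duration")
    do.call(event_spec,
            c(list(time = e$time, kind = e$kind),
              e[setdiff(names(e), c("time", "kind"))]))
  })
  class(config) <- c("culture_config", "list")
  config
}

#' Read a setup config file
#'
#' @param path JSON (or YAML, by extension) setup file.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
}

#' Write a setup config as JSON
#'
#' @param config config list (unclassed before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config$cell_params <- NULL
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# Build the plate object described by a validated config.
build_plate <- function(config) {
  pl <- config$plate
  plate <- new_plate(pl$width, pl$height, serum_type = pl$serum_type,
                     serum_level = pl$serum_level,
                     molecules = if (is.null(pl$molecules)) list()
                                 else as.list(pl$molecules))
  for (cns in pl$constraints) plate$constraints[[cns$id]] <- cns
  for (f in pl$fields) {
    plate$fields[[f$name]] <- uniform_field(
      pl$width, pl$height, f$value,
      cell_size = if (is.null(f$cell_size)) 10 else f$cell_size,
      half_life = if (is.null(f$half_life)) Inf else f$half_life,
      degradable_by_cells = isTRUE(f$degradable),
      bias_gain = if (is.null(f$bias_gain)) 1 else f$bias_gain,
      name = f$name)
  }
  plate
}

# ---- rendering --------------------------------------------------------------

#' Render a plate as a symbolic SVG image
#'
#' Each live cell is drawn as an ellipse whose area matches its projected
#' surface, elongated along its previous displacement when polarised.
#' Grey-level styling mimics phase contrast: fully spread cells have dim
#' thin borders; de-spread (mitotic/apoptotic) cells get thicker, brighter
#' borders.
#'
#' @param plate plate state.
#' @param path output `.svg` path (optional; the SVG text is returned).
#' @return the SVG document as a character string, invisibly if written.
#' @export
render_frame <- function(plate, path = NULL) {
  pop <- plate$cells
  live <- which(pop$phase != "DEAD")
  hdr <- sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" ',
    'viewBox="0 0 %.1f %.1f">'), round(plate$width), round(plate$height),
    plate$width, plate$height)
  bg <- sprintf('<rect width="%.1f" height="%.1f" fill="#b8b8b8"/>',
                plate$width, plate$height)
  body <- character(0)
  if (length(live)) {
    r0 <- sqrt(pop$surface[live] / pi)
    pm <- sqrt(pop$pdx[live]^2 + pop$pdy[live]^2)
    polar <- pm > r0 * 0.2
    elong <- ifelse(polar, 1.3, 1)
    ang <- ifelse(polar, atan2(pop$pdy[live], pop$pdx[live]), 0) * 180 / pi
    despread <- pop$attach[live] == "DESPREADING" |
      pop$phase[live] %in% c("M", "APO")
    stroke <- ifelse(despread, "#f2f2f2", "#6b6b6b")
    sw <- ifelse(despread, 2.5, 0.8)
    fill <- ifelse(pop$phase[live] == "APO", "#9a9a9a", "#d4d4d4")
    body <- sprintf(paste0(
      '<ellipse cx="%.1f" cy="%.1f" rx="%.1f" ry="%.1f" ',
      'transform="rotate(%.1f %.1f %.1f)" fill="%s" stroke="%s" ',
      'stroke-width="%.1f" class="cell phase-%s attach-%s"/>'),
      pop$x[live], plate$height - pop$y[live], r0 * elong, r0 / elong,
      -ang, pop$x[live], plate$height - pop$y[live], fill, stroke, sw,
      pop$phase[live], pop$attach[live])
  }
  svg <- paste(c(hdr, bg, body, "</svg>"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}

#' Export a run's tables
#'
#' Writes `history.csv`, `paths.csv`, `frames.csv` (when recorded), a
#' `setup.json` echo and optionally the frames as a track file.
#'
#' @param run a `culture_run`.
#' @param dir output directory (created if needed).
#' @param tracks also write `tracks.txt` via [write_tracks()].
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir, tracks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(run$paths, file.path(dir, "paths.csv"),
                   row.names = FALSE)
  if (!is.null(run$frames))
    utils::write.csv(run$frames, file.path(dir, "frames.csv"),
                     row.names = FALSE)
  write_config(run$setup, file.path(dir, "setup.json"))
  if (tracks) write_tracks(as_tracks(run), file.path(dir, "tracks.txt"))
  invisible(dir)
}
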