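#' Write / read tracking records
#'
#' Serializes tracking records in any of four formats sharing one flat
#' schema: per frame, then per mouse \code{m} (0-based suffix):
#' \code{body_x_m, body_y_m, orient_m, lx_m, ly_m, lt_m, rx_m, ry_m, rt_m}.
#' CSV is comma-separated, TXT tab-separated; XML and HTML carry the same
#' fields as elements / a table. Coordinates are written with two decimal
#' places; lost paws have empty coordinate fields and a 0 tracked flag, so
#' losses survive the round trip and no row is ever dropped.
#'
#' @param records Tibble from [track_video()] (long, one row per frame per
#'   mouse).
#' @param path Output file; the format defaults to the file extension
#'   (\code{.csv}, \code{.txt}, \code{.xml}, \code{.html}).
#' @param format Explicit format overriding the extension.
#' @return \code{write_records}: \code{path} invisibly;
#'   \code{read_records}: the records tibble (coordinates at the written
#'   precision).
#' @export
write_records <- function(records, path,
                          format = c("auto", "csv", "txt", "xml", "html")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (!format %in% c("csv", "txt", "xml", "html")) {
    stop("config error: unsupported output format '", format,
         "' (use csv, txt, xml or html)", call. = FALSE)
  }
  wide <- .records_to_wide(records)
  switch(format,
    csv = utils::write.table(wide, path, sep = ",", row.names = FALSE,
                             quote = FALSE, na = ""),
    txt = utils::write.table(wide, path, sep = "\t", row.names = FALSE,
                             quote = FALSE, na = ""),
    xml = .write_records_xml(wide, path),
    html = .write_records_html(wide, path)
  )
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, format = c("auto", "csv", "txt", "xml", "html")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  wide <- switch(format,
    csv = utils::read.table(path, sep = ",", header = TRUE, na.strings = ""),
    txt = utils::read.table(path, sep = "\t", header = TRUE, na.strings = ""),
    xml = .read_records_markup(xml2::read_xml(path)),
    html = .read_records_markup(xml2::read_html(path)),
    stop("config error: unsupported input format '", format, "'",
         call. = FALSE)
  )
  .records_from_wide(wide)
}

.rec_cols <- c("body_x", "body_y", "orient", "lx", "ly", "lt", "rx", "ry", "rt")

.records_to_wide <- function(records) {
  mice <- if (nrow(records) > 0) sort(unique(records$mouse)) else 0L
  frames <- sort(unique(records$frame))
  out <- data.frame(frame = frames)
  fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
  for (m in mice) {
    r <- records[records$mouse == m, ][match(frames, records$frame[records$mouse == m]), ]
    blk <- data.frame(
      fmt2(r$body_x), fmt2(r$body_y), fmt2(r$orientation),
      fmt2(r$left_x), fmt2(r$left_y), as.integer(r$left_tracked),
      fmt2(r$right_x), fmt2(r$right_y), as.integer(r$right_tracked)
    )
    names(blk) <- paste0(.rec_cols, "_", m)
    out <- cbind(out, blk)
  }
  out
}

.records_from_wide <- function(wide) {
  if (nrow(wide) == 0) {
    return(tibble::tibble(
      frame = integer(), mouse = integer(),
      body_x = numeric(), body_y = numeric(), orientation = numeric(),
      left_x = numeric(), left_y = numeric(), left_tracked = logical(),
      right_x = numeric(), right_y = numeric(), right_tracked = logical()
    ))
  }
  suffixes <- sort(unique(as.integer(sub(
    "^lt_", "", grep("^lt_", names(wide), value = TRUE)))))
  num <- function(x) suppressWarnings(as.numeric(x))
  blocks <- lapply(suffixes, function(m) {
    g <- function(p) wide[[paste0(p, "_", m)]]
    tibble::tibble(
      frame = as.integer(wide$frame), mouse = as.integer(m),
      body_x = num(g("body_x")), body_y = num(g("body_y")),
      orientation = num(g("orient")),
      left_x = num(g("lx")), left_y = num(g("ly")),
      left_tracked = as.integer(g("lt")) == 1L,
      right_x = num(g("rx")), right_y = num(g("ry")),
      right_tracked = as.integer(g("rt")) == 1L
    )
  })
  dplyr::arrange(dplyr::bind_rows(blocks), .data$frame, .data$mouse)
}

.write_records_xml <- function(wide, path) {
  doc <- xml2::xml_new_root("records")
  for (i in seq_len(nrow(wide))) {
    rec <- xml2::xml_add_child(doc, "record")
    for (cn in names(wide)) {
      v <- wide[i, cn]
      xml2::xml_add_child(rec, cn, if (is.na(v)) "" else as.character(v))
    }
  }
  xml2::write_xml(doc, path)
}

.write_records_html <- function(wide, path) {
  doc <- xml2::xml_new_root("html")
  body <- xml2::xml_add_child(doc, "body")
  tab <- xml2::xml_add_child(body, "table")
  hdr <- xml2::xml_add_child(tab, "tr")
  for (cn in names(wide)) xml2::xml_add_child(hdr, "th", cn)
  for (i in seq_len(nrow(wide))) {
    tr <- xml2::xml_add_child(tab, "tr")
    for (cn in names(wide)) {
      v <- wide[i, cn]
      xml2::xml_add_child(tr, "td", if (is.na(v)) "" else as.character(v))
    }
  }
  xml2::write_html(doc, path)
}

.read_records_markup <- function(doc) {
  recs <- xml2::xml_find_all(doc, "//record")
  if (length(recs) == 0 &&
      length(xml2::xml_find_all(doc, "//records")) > 0) {
    return(data.frame(frame = integer(0)))
  }
  if (length(recs) > 0) {
    rows <- lapply(recs, function(r) {
      kids <- xml2::xml_children(r)
      vals <- xml2::xml_text(kids)
      vals[vals == ""] <- NA_character_
      stats::setNames(as.list(vals), xml2::xml_name(kids))
    })
  } else {
    trs <- xml2::xml_find_all(doc, "//table/tr")
    if (length(trs) == 0) stop("no records found in markup", call. = FALSE)
    header <- xml2::xml_text(xml2::xml_find_all(trs[[1]], "th"))
    rows <- lapply(trs[-1], function(tr) {
      vals <- xml2::xml_text(xml2::xml_find_all(tr, "td"))
      vals[vals == ""] <- NA_character_
      stats::setNames(as.list(vals), header)
    })
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df$frame <- as.integer(df$frame)
  df
}
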