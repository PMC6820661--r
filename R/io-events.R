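# Event-table I/O.
#
# The canonical on-disk form is CSV with a '#'-prefixed metadata header block
# ("#key: value" lines) followed by one header row of channel names. A minimal
# FCS 3.1 adapter (HEADER + TEXT segment + little-endian float32 DATA) is
# provided for interoperability with cytometry software; CSV is what the test
# fixtures use.

#' Write an event table
#'
#' @param table An `event_table`.
#' @param path Output file path.
#' @param format `"csv"` (metadata header block + channel header row) or
#'   `"fcs"` (FCS 3.1, list-mode float32).
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "event_table"))
  if (format == "csv") write_events_csv(table, path) else write_events_fcs(table, path)
  invisible(path)
}

#' Read an event table
#'
#' @param path File path.
#' @param format `"csv"` or `"fcs"`; inferred from the file extension by
#'   default.
#' @return An `event_table`.
#' @export
read_events <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  format <- match.arg(format, c("csv", "fcs"))
  if (format == "csv") read_events_csv(path) else read_events_fcs(path)
}

meta_to_lines <- function(meta) {
  keep <- !vapply(meta, is.null, logical(1))
  vapply(names(meta)[keep], function(k) {
    sprintf("#%s: %s", k, as.character(meta[[k]]))
  }, character(1))
}

write_events_csv <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_to_lines(event_meta(table)), con)
  utils::write.table(as.data.frame(table), con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}

read_events_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  body_start <- match(FALSE, is_meta)
  if (is.na(body_start) || body_start == length(lines) + 1L) {
    abort(sprintf("Parse error in '%s': no channel header row found.", path),
          class = "flowabc_parse_error")
  }
  meta_lines <- lines[seq_len(body_start - 1L)]
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) {
      meta[[m[2]]] <- utils::type.convert(m[3], as.is = TRUE)
    }
  }

  header <- strsplit(lines[body_start], ",", fixed = TRUE)[[1]]
  body <- lines[-seq_len(body_start)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    abort(sprintf(
      "Parse error in '%s': row %d has %d field(s), expected %d (file truncated?).",
      path, bad, nf[bad], length(header)),
      class = "flowabc_parse_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    abort(sprintf("Parse error in '%s': non-numeric channel value.", path),
          class = "flowabc_parse_error")
  }
  channels <- as_tibble(as.data.frame(matrix(vals, ncol = length(header),
                                             byrow = TRUE,
                                             dimnames = list(NULL, header))))
  if (is.null(meta$marker) || identical(meta$marker, "NA")) meta$marker <- NA_character_
  new_event_table(channels, meta = meta)
}

# ---- FCS 3.1 adapter --------------------------------------------------------

fcs_pad <- function(x, width = 8) formatC(x, width = width, flag = " ")

write_events_fcs <- function(table, path) {
  channels <- as.data.frame(table)
  n_par <- ncol(channels)
  n_tot <- nrow(channels)
  meta <- event_meta(table)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$NEXTDATA" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw[paste0("$P", i, "N")] <- names(channels)[i]
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "E")] <- "0,0"
    kw[paste0("$P", i, "R")] <- format(ceiling(max(channels[[i]], 1)),
                                       scientific = FALSE)
  }
  for (k in names(meta)) {
    if (!is.null(meta[[k]])) kw[paste0("FABC_", toupper(k))] <- as.character(meta[[k]])
  }

  build_text <- function(bd, ed) {
    kw2 <- kw
    kw2["$BEGINDATA"] <- sprintf("%010d", bd)
    kw2["$ENDDATA"] <- sprintf("%010d", ed)
    paste0("/", paste0(names(kw2), "/", unname(kw2), "/", collapse = ""))
  }
  # TEXT length is invariant because the offsets are zero-padded to 10 digits
  text_len <- nchar(build_text(0, 0), type = "bytes")
  text_start <- 58L                      # 10-byte version id + 6 x 8-byte offsets
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  text <- build_text(data_start, data_end)

  header <- paste0("FCS3.1    ",
                   fcs_pad(text_start), fcs_pad(text_end),
                   fcs_pad(data_start), fcs_pad(data_end),
                   fcs_pad(0), fcs_pad(0))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # list mode: events are stored row-major (all parameters of event 1, then 2, ...)
  writeBin(as.vector(t(as.matrix(channels))), con, size = 4, endian = "little")
}

read_events_fcs <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58) {
    abort(sprintf("Parse error in '%s': not an FCS file (too short).", path),
          class = "flowabc_parse_error")
  }
  con <- file(path, open = "rb")
  on.exit(close(con))
  version <- readChar(con, 10)
  if (!startsWith(version, "FCS3")) {
    abort(sprintf("Parse error in '%s': unsupported FCS version '%s'.",
                  path, trimws(version)), class = "flowabc_parse_error")
  }
  offs <- as.integer(trimws(vapply(1:6, function(i) readChar(con, 8), "")))
  text_start <- offs[1]; text_end <- offs[2]

  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)], parts[seq(1, length(parts), 2)])

  need <- c("$PAR", "$TOT", "$DATATYPE", "$BEGINDATA", "$ENDDATA")
  missing_kw <- setdiff(need, names(kw))
  if (length(missing_kw)) {
    abort(sprintf("Parse error in '%s': missing keyword(s) %s.",
                  path, paste(missing_kw, collapse = ", ")),
          class = "flowabc_parse_error")
  }
  if (kw[["$DATATYPE"]] != "F") {
    abort(sprintf("Parse error in '%s': only $DATATYPE F is supported.", path),
          class = "flowabc_parse_error")
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  data_start <- as.integer(kw[["$BEGINDATA"]])

  seek(con, data_start)
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4, endian = "little")
  if (length(vals) < n_par * n_tot) {
    abort(sprintf("Parse error in '%s': DATA segment truncated (%d of %d values).",
                  path, length(vals), n_par * n_tot),
          class = "flowabc_parse_error")
  }
  ch_names <- vapply(seq_len(n_par), function(i) kw[[paste0("$P", i, "N")]], "")
  channels <- as_tibble(as.data.frame(matrix(vals, ncol = n_par, byrow = TRUE,
                                             dimnames = list(NULL, ch_names))))

  meta_keys <- grep("^FABC_", names(kw), value = TRUE)
  meta <- lapply(kw[meta_keys], function(v) utils::type.convert(v, as.is = TRUE))
  names(meta) <- tolower(sub("^FABC_", "", meta_keys))
  if (is.null(meta$marker) || identical(meta$marker, "NA")) meta$marker <- NA_character_
  new_event_table(channels, meta = meta)
}

# ---- lot sheet and ground-truth persistence --------------------------------

#' Read or write a bead lot sheet
#'
#' The lot sheet is a two-column tab-delimited file (`pe_per_bead`,
#' `proportion`), as transcribed from a quantitation-kit insert.
#'
#' @param lot A [bead_lot].
#' @param path File path.
#' @return `read_lot_sheet()` returns a [bead_lot]; `write_lot_sheet()`
#'   returns `path` invisibly.
#' @export
write_lot_sheet <- function(lot, path) {
  stopifnot(inherits(lot, "bead_lot"))
  readr::write_tsv(tibble(pe_per_bead = lot$pe_per_bead,
                          proportion = lot$proportions), path)
  invisible(path)
}

#' @rdname write_lot_sheet
#' @export
read_lot_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("pe_per_bead", "proportion") %in% names(df))) {
    abort(sprintf("Parse error in '%s': expected columns pe_per_bead, proportion.",
                  path), class = "flowabc_parse_error")
  }
  bead_lot(df$pe_per_bead, df$proportion)
}

#' Persist or restore a ground-truth design
#'
#' Writes the design as delimited matrices (`abc_true.tsv`,
#' `frac_pos_true.tsv`) plus a JSON manifest of the per-subset and per-marker
#' vectors and block assignments.
#'
#' @param gt An `abc_ground_truth`.
#' @param dir Directory (created if needed).
#' @return `read_ground_truth()` returns the restored `abc_ground_truth`;
#'   `write_ground_truth()` returns `dir` invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "abc_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, f) {
    utils::write.table(m, file.path(dir, f), sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  write_mat(gt$abc_true, "abc_true.tsv")
  write_mat(gt$frac_pos_true, "frac_pos_true.tsv")
  manifest <- list(
    autofluor_abc = as.list(gt$autofluor_abc),
    conj_factor_true = as.list(gt$conj_factor_true),
    subset_mix = as.list(gt$subset_mix),
    marker_block = as.list(gt$marker_block),
    subset_block = as.list(gt$subset_block),
    lineage = as.list(gt$lineage),
    seed = gt$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  read_mat <- function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE))
  }
  manifest <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  unlist_named <- function(x) unlist(x)
  structure(
    list(
      abc_true = read_mat("abc_true.tsv"),
      frac_pos_true = read_mat("frac_pos_true.tsv"),
      autofluor_abc = unlist_named(manifest$autofluor_abc),
      conj_factor_true = unlist_named(manifest$conj_factor_true),
      subset_mix = unlist_named(manifest$subset_mix),
      marker_block = unlist_named(manifest$marker_block),
      subset_block = unlist_named(manifest$subset_block),
      lineage = unlist_named(manifest$lineage),
      seed = manifest$seed
    ),
    class = "abc_ground_truth"
  )
}
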