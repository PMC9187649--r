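#' Read a monitoring measurement file
#'
#' Measurement files are long-format CSVs with one row per sample x
#' pesticide quantification. Samples in which nothing was detected appear
#' once with an empty `pesticide` cell, so the full sample denominator is
#' recoverable from the same file. Required columns: `sample_id`,
#' `commodity`, `group`, `pesticide`, `concentration`; optional `lod` and
#' `loq` (mg/kg, default 0 when absent).
#'
#' @param path Path to the CSV file (UTF-8, header row; `#` lines are
#'   comments).
#' @param schema Optional named character vector remapping column names,
#'   e.g. `c(sample_id = "id", concentration = "conc_mgkg")`: names are the
#'   standard fields, values the file's column names.
#' @return A list with two data frames: `samples` (`sample_id`, `commodity`,
#'   `group`; one row per sample) and `measurements` (`sample_id`,
#'   `pesticide`, `concentration`, `lod`, `loq`; one row per residue
#'   quantification).
#' @seealso [write_measurements()] for the inverse operation.
#' @export
read_measurements <- function(path, schema = NULL) {
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  cols <- c(sample_id = "sample_id", commodity = "commodity",
            group = "group", pesticide = "pesticide",
            concentration = "concentration", lod = "lod", loq = "loq")
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(cols))
    if (length(bad) > 0)
      stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    cols[names(schema)] <- schema
  }
  required <- cols[c("sample_id", "commodity", "group", "pesticide",
                     "concentration")]
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("measurement file lacks required column(s): ",
         paste(missing, collapse = ", "))

  d <- data.frame(
    sample_id = trimws(raw[[cols["sample_id"]]]),
    commodity = trimws(raw[[cols["commodity"]]]),
    group = trimws(raw[[cols["group"]]]),
    pesticide = trimws(raw[[cols["pesticide"]]]),
    concentration = raw[[cols["concentration"]]],
    lod = if (cols["lod"] %in% names(raw)) raw[[cols["lod"]]] else "0",
    loq = if (cols["loq"] %in% names(raw)) raw[[cols["loq"]]] else "0",
    stringsAsFactors = FALSE
  )
  if (any(d$sample_id == "")) stop("empty sample_id in measurement file")
  if (any(d$commodity == "")) stop("empty commodity in measurement file")
  if (!all(d$group %in% c("vegetable", "fruit")))
    stop("group must be 'vegetable' or 'fruit'")

  is_residue <- !is.na(d$pesticide) & d$pesticide != ""
  num <- function(x, what, rows) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric %s in row %d", what, rows[bad[1]]))
    v
  }
  rows <- seq_len(nrow(d))
  d$concentration <- num(d$concentration, "concentration", rows)
  d$lod <- num(d$lod, "lod", rows)
  d$loq <- num(d$loq, "loq", rows)
  d$lod[is.na(d$lod)] <- 0
  d$loq[is.na(d$loq)] <- 0

  neg <- which(is_residue & (is.na(d$concentration) | d$concentration < 0))
  if (length(neg) > 0)
    stop(sprintf("invalid (missing or negative) concentration in row %d",
                 neg[1]))
  if (any(d$lod < 0) || any(d$loq < 0)) stop("lod/loq must be >= 0")
  if (any(is_residue & d$loq < d$lod))
    stop("loq must be >= lod for every measurement")

  key <- paste(d$sample_id[is_residue], d$pesticide[is_residue], sep = "\r")
  if (anyDuplicated(key) > 0)
    stop("duplicated (sample_id, pesticide) measurement row(s): ",
         paste(unique(sub("\r", " / ", key[duplicated(key)])), collapse = "; "))

  samples <- unique(d[, c("sample_id", "commodity", "group")])
  if (anyDuplicated(samples$sample_id) > 0)
    stop("sample_id appears with conflicting commodity/group: ",
         paste(samples$sample_id[duplicated(samples$sample_id)],
               collapse = ", "))
  rownames(samples) <- NULL

  measurements <- d[is_residue,
                    c("sample_id", "pesticide", "concentration", "lod", "loq")]
  rownames(measurements) <- NULL
  list(samples = samples, measurements = measurements)
}

#' Write a monitoring dataset back to the long measurement format
#'
#' @param samples,measurements Data frames as returned by
#'   [read_measurements()] or [build_survey_fixture()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(samples, measurements, path) {
  m <- merge(measurements, samples, by = "sample_id", all.x = TRUE)
  clean <- samples[!(samples$sample_id %in% measurements$sample_id), ]
  if (nrow(clean) > 0) {
    clean$pesticide <- ""
    clean$concentration <- NA_real_
    clean$lod <- NA_real_
    clean$loq <- NA_real_
  }
  cols <- c("sample_id", "commodity", "group", "pesticide",
            "concentration", "lod", "loq")
  out <- rbind(m[, cols], clean[, cols][seq_len(nrow(clean)), , drop = FALSE])
  out <- out[order(out$sample_id, out$pesticide), ]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read MRL, toxicological-reference and consumption tables
#'
#' `read_mrl_table()` expects columns `pesticide`, `commodity`, `mrl`
#' (mg/kg > 0) and optionally `source`. `read_tox_table()` expects
#' `pesticide`, `adi` (mg/kg bw/day > 0) and `arfd` (mg/kg bw); an absent
#' acute reference dose is written as an empty cell or a dash and is kept
#' as `NA`, never coerced to zero. `read_consumption_table()` expects
#' `commodity` and `daily_intake` (kg/person/day >= 0); commodities beyond
#' those in a given survey are allowed and simply unused.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the validated columns.
#' @export
read_mrl_table <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pesticide", "commodity", "mrl")
  if (!all(need %in% names(d)))
    stop("MRL table lacks required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (nrow(d) == 0)
    return(data.frame(pesticide = character(), commodity = character(),
                      mrl = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  d$mrl <- as.numeric(d$mrl)
  if (any(is.na(d$mrl) | d$mrl <= 0)) stop("mrl must be > 0")
  if (is.null(d$source)) d$source <- "registered"
  d[, c("pesticide", "commodity", "mrl", "source")]
}

#' @rdname read_mrl_table
#' @export
read_tox_table <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                colClasses = "character")
  need <- c("pesticide", "adi")
  if (!all(need %in% names(d)))
    stop("tox table lacks required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  absent <- function(x) is.na(x) | trimws(x) %in% c("", "-", "–", "—")
  adi <- as.numeric(d$adi)
  if (any(is.na(adi) | adi <= 0))
    stop("adi must be a number > 0 for every pesticide (row ",
         which(is.na(adi) | adi <= 0)[1], ")")
  arfd_raw <- if (is.null(d$arfd)) rep("", nrow(d)) else d$arfd
  arfd <- ifelse(absent(arfd_raw), NA, suppressWarnings(as.numeric(arfd_raw)))
  if (any(!absent(arfd_raw) & (is.na(arfd) | arfd <= 0)))
    stop("arfd must be > 0 when present")
  data.frame(pesticide = trimws(d$pesticide), adi = adi, arfd = arfd,
             stringsAsFactors = FALSE)
}

#' @rdname read_mrl_table
#' @export
read_consumption_table <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("commodity", "daily_intake")
  if (!all(need %in% names(d)))
    stop("consumption table lacks required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$daily_intake <- as.numeric(d$daily_intake)
  if (any(is.na(d$daily_intake) | d$daily_intake < 0))
    stop("daily_intake must be >= 0")
  d[, c("commodity", "daily_intake")]
}

#' @rdname read_mrl_table
#' @param mrl_path,tox_path,consumption_path Paths to the three reference
#'   CSVs.
#' @return For `read_reference_tables()`, a list with elements `mrl`, `tox`
#'   and `consumption`.
#' @export
read_reference_tables <- function(mrl_path, tox_path, consumption_path) {
  list(mrl = read_mrl_table(mrl_path),
       tox = read_tox_table(tox_path),
       consumption = read_consumption_table(consumption_path))
}

#' Write a summary table as CSV or a markdown pipe table
#'
#' CSV output round-trips: reading the file back reproduces the values
#' exactly at the stated decimals.
#'
#' @param rows A data frame of homogeneous summary rows (an occurrence,
#'   incidence, validation or exposure table).
#' @param path Output path.
#' @param format `"csv"` or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) stop("rows must be a data frame")
  rows <- as.data.frame(rows)
  if (format == "csv") {
    write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    cells <- vapply(rows, function(col) {
      out <- as.character(col)
      out[is.na(out)] <- ""
      out
    }, character(nrow(rows)))
    cells <- matrix(cells, nrow = nrow(rows))
    lines <- c(
      paste0("| ", paste(names(rows), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(rows)), collapse = "|"), "|"),
      apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
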