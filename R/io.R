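# Readers/writers for the tabular formats used throughout the package:
# degree-minute coordinates, site physicochemistry tables, OTU count
# tables and the genus -> guild reference.

# Variable sets are table-specific and fixed: soil tables carry TS but no
# ORP; water tables carry ORP but no TS.
.soil_vars <- c("pH", "TN", "NH4", "NO3", "TP", "PO4", "OM", "DOC",
                "TS", "SO4", "Fe2", "Fe3", "TFe", "TMn")
.water_vars <- c("pH", "TN", "NH4", "NO3", "TP", "PO4", "OM", "DOC",
                 "SO4", "Fe2", "Fe3", "TFe", "TMn", "ORP")

.soil_units <- c(pH = "unitless", TN = "g/kg", NH4 = "mg/kg", NO3 = "mg/kg",
                 TP = "g/kg", PO4 = "mg/kg", OM = "%", DOC = "g/kg",
                 TS = "g/kg", SO4 = "mg/kg", Fe2 = "g/kg", Fe3 = "g/kg",
                 TFe = "g/kg", TMn = "mg/kg")
.water_units <- c(pH = "unitless", TN = "mg/L", NH4 = "mg/L", NO3 = "mg/L",
                  TP = "mg/L", PO4 = "mg/L", OM = "mg/L", DOC = "mg/L",
                  SO4 = "mg/L", Fe2 = "mg/L", Fe3 = "mg/L", TFe = "mg/L",
                  TMn = "1e-3 mg/kg", ORP = "mV")

.regions <- c("SJ", "CB", "LK", "GK")
.peat_types <- c("fen", "fen_bog_complex", "bog")

#' Parse a degree-minute coordinate
#'
#' Converts coordinate strings of the form `"47°46′N"` (degrees,
#' arc-minutes, hemisphere) to signed decimal degrees: degrees + minutes/60,
#' positive for N/E and negative for S/W. Coordinates are carried at
#' arc-minute precision only; there is no seconds term.
#'
#' @param text character vector of coordinate tokens.
#' @return numeric vector of decimal degrees.
#' @seealso [format_dms()] for the inverse.
#' @examples
#' parse_dms("47°46′N")
#' @export
parse_dms <- function(text) {
  stopifnot(is.character(text))
  pat <- "^\\s*([0-9]+)°\\s*([0-9]+(?:\\.[0-9]+)?)′\\s*([NSEW])\\s*$"
  m <- regmatches(text, regexec(pat, text))
  vapply(seq_along(text), function(i) {
    g <- m[[i]]
    if (length(g) != 4L)
      stop("malformed degree-minute coordinate: '", text[i], "'")
    deg <- as.numeric(g[2L])
    mins <- as.numeric(g[3L])
    if (mins >= 60)
      stop("minutes out of range [0, 60) in coordinate token '", text[i], "'")
    sgn <- if (g[4L] %in% c("S", "W")) -1 else 1
    sgn * (deg + mins / 60)
  }, numeric(1))
}

#' Format decimal degrees as a degree-minute coordinate
#'
#' Inverse of [parse_dms()]: rounds to the nearest arc-minute, so
#' `format_dms(parse_dms(x), axis)` reproduces `x` for any minute-precision
#' coordinate.
#'
#' @param value numeric vector, decimal degrees (signed).
#' @param axis `"lat"` (N/S) or `"lon"` (E/W).
#' @return character vector like `"47°46′N"`.
#' @export
format_dms <- function(value, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(value))
  hemi <- if (axis == "lat") c("N", "S") else c("E", "W")
  vapply(value, function(v) {
    h <- if (v < 0) hemi[2L] else hemi[1L]
    total_min <- round(abs(v) * 60)
    deg <- total_min %/% 60
    mins <- total_min %% 60
    sprintf("%d°%02d′%s", deg, mins, h)
  }, character(1))
}

#' Parse a "lat, lon" coordinate pair
#'
#' @param text character vector like `"47°46′N, 132°54′E"`.
#' @return data.frame with columns `latitude`, `longitude` (decimal degrees).
#' @export
parse_coordinates <- function(text) {
  parts <- strsplit(text, ",")
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("expected 'lat, lon' coordinate pair, got: '", text[bad][1L], "'")
  lat <- parse_dms(trimws(vapply(parts, `[`, "", 1L)))
  lon <- parse_dms(trimws(vapply(parts, `[`, "", 2L)))
  data.frame(latitude = lat, longitude = lon)
}

.fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "feassembly")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

#' Load a site physicochemistry table
#'
#' Reads one of the packaged peatland site tables (`"table1_soil"`, 15 soil
#' sites; `"table2_water"`, 18 water sites) or a user TSV with the same
#' header layout: `site_id`, `coordinates` (degree-minute pair), `region`,
#' `peatland_type`, then the medium-specific physicochemical variables.
#' Soil tables carry TS but no ORP; water tables carry ORP but no TS.
#'
#' @param source `"table1_soil"`, `"table2_water"`, or a path to a TSV file.
#' @return data.frame of class `env_table` with parsed `latitude` and
#'   `longitude` columns, and attributes `medium` and `units`.
#' @export
load_env_table <- function(source) {
  path <- switch(source,
    table1_soil = .fixture_path("table1_soil.tsv"),
    table2_water = .fixture_path("table2_water.tsv"),
    source)
  if (!file.exists(path)) stop("env table not found: ", source)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                          colClasses = "character", fileEncoding = "UTF-8")
  meta_cols <- c("site_id", "coordinates", "region", "peatland_type")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing))
    stop("env table is missing column(s): ", paste(missing, collapse = ", "))
  vars <- setdiff(names(df), meta_cols)
  medium <- if (setequal(vars, .soil_vars)) "soil"
            else if (setequal(vars, .water_vars)) "water"
            else stop("env table header matches neither the soil nor the ",
                      "water variable set; unexpected variables: ",
                      paste(setdiff(vars, union(.soil_vars, .water_vars)),
                            collapse = ", "))
  vars <- if (medium == "soil") .soil_vars else .water_vars
  if (anyDuplicated(df$site_id))
    stop("duplicated site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  for (v in vars) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(x) & !is.na(df[[v]]))
    if (length(bad))
      stop("non-numeric cell in column '", v, "', row ", bad[1L],
           " (site ", df$site_id[bad[1L]], "): '", df[[v]][bad[1L]], "'")
    df[[v]] <- x
  }
  coords <- parse_coordinates(df$coordinates)
  df$latitude <- coords$latitude
  df$longitude <- coords$longitude
  if (any(df$pH <= 0 | df$pH >= 14, na.rm = TRUE))
    stop("pH outside (0, 14)")
  conc <- setdiff(vars, c("pH", "ORP"))
  if (any(as.matrix(df[conc]) < 0, na.rm = TRUE))
    stop("negative concentration value")
  bad_region <- !is.na(df$region) & !(df$region %in% .regions)
  if (any(bad_region))
    stop("unknown region: ", df$region[bad_region][1L])
  bad_type <- !is.na(df$peatland_type) & !(df$peatland_type %in% .peat_types)
  if (any(bad_type))
    stop("unknown peatland_type: ", df$peatland_type[bad_type][1L])
  df <- df[c(meta_cols, "latitude", "longitude", vars)]
  attr(df, "medium") <- medium
  attr(df, "units") <- if (medium == "soil") .soil_units else .water_units
  class(df) <- c("env_table", "data.frame")
  df
}

#' Re-serialize an environmental table
#'
#' Writes the table back to TSV in the packaged column layout, preserving
#' the degree-minute coordinate strings verbatim, so a packaged fixture
#' round-trips bit-exactly.
#'
#' @param table an `env_table` from [load_env_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(table, path) {
  stopifnot(inherits(table, "env_table"))
  out <- table[setdiff(names(table), c("latitude", "longitude"))]
  for (v in names(out))
    if (is.numeric(out[[v]])) out[[v]] <- sprintf("%.2f", out[[v]])
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistic of one environmental variable
#'
#' Statistics are taken over site records (one value per site, as tabulated;
#' replicate plot measurements are averaged upstream of these tables).
#'
#' @param table an `env_table`.
#' @param variable variable name, e.g. `"pH"`.
#' @param stat one of `"min"`, `"max"`, `"mean"`, `"range"` (max - min).
#' @return a single numeric value.
#' @examples
#' summarize_env(load_env_table("table1_soil"), "pH", "min")
#' @export
summarize_env <- function(table, variable, stat = c("min", "max", "mean", "range")) {
  stat <- match.arg(stat)
  vars <- setdiff(names(table),
                  c("site_id", "coordinates", "region", "peatland_type",
                    "latitude", "longitude"))
  if (!variable %in% vars)
    stop("unknown variable '", variable, "'; available: ",
         paste(vars, collapse = ", "))
  x <- table[[variable]]
  switch(stat,
         min = min(x, na.rm = TRUE),
         max = max(x, na.rm = TRUE),
         mean = mean(x, na.rm = TRUE),
         range = diff(range(x, na.rm = TRUE)))
}

.validate_counts <- function(counts) {
  if (is.null(dim(counts)) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop("no samples: OTU table must have at least one sample and one OTU")
  if (anyNA(counts)) stop("OTU table contains missing counts")
  if (any(counts < 0)) stop("OTU table contains negative counts")
  if (any(counts != round(counts))) stop("OTU table contains fractional counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table must carry sample and OTU identifiers")
  if (anyDuplicated(rownames(counts))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated OTU ids")
  invisible(counts)
}

#' Read / write an OTU count table
#'
#' TSV with sample ids in the first column and OTU ids as the header by
#' default; a `# orientation: otus_x_samples` comment line on top marks the
#' transposed layout. Counts must be non-negative integers. Writing then
#' reading reproduces the counts exactly.
#'
#' @param path TSV file path.
#' @return integer matrix, samples in rows, OTUs in columns.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("OTU table not found: ", path)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  orientation <- if (grepl("^#\\s*orientation:\\s*otus_x_samples", first))
    "otus_x_samples" else "samples_x_otus"
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          fileEncoding = "UTF-8")
  if (nrow(df) < 1L || ncol(df) < 2L) stop("no samples: empty OTU table")
  counts <- as.matrix(df[-1L])
  if (!is.numeric(counts)) stop("non-numeric counts in OTU table")
  rownames(counts) <- as.character(df[[1L]])
  if (orientation == "otus_x_samples") counts <- t(counts)
  storage.mode(counts) <- "integer"
  .validate_counts(counts)
  counts
}

#' @param table integer matrix, samples in rows.
#' @param orientation `"samples_x_otus"` (default) or `"otus_x_samples"`.
#' @rdname read_otu_table
#' @export
write_otu_table <- function(table, path, orientation = c("samples_x_otus", "otus_x_samples")) {
  orientation <- match.arg(orientation)
  .validate_counts(table)
  m <- if (orientation == "otus_x_samples") t(table) else table
  id_col <- if (orientation == "otus_x_samples") "otu_id" else "sample_id"
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# orientation: ", orientation), con)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a genus -> guild reference
#'
#' The default reference ships with the package: a flat, user-extensible
#' list of genera with documented Fe(II)-oxidizing (FeOB) or
#' Fe(III)-reducing (FeRB) metabolism. A user file is a two-column TSV
#' (`genus`, `guild` in {FeOB, FeRB}); with `extend_default = TRUE` it is
#' merged with the packaged list, and a genus mapped to conflicting guilds
#' is an error (a genus belongs to exactly one guild).
#'
#' @param path optional TSV path; `NULL` for the packaged default.
#' @param extend_default merge a user file with the packaged default.
#' @return named character vector mapping genus to `"FeOB"`/`"FeRB"`.
#' @export
load_guild_reference <- function(path = NULL, extend_default = FALSE) {
  read_one <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, fileEncoding = "UTF-8")
    if (!all(c("genus", "guild") %in% names(df)))
      stop("guild reference needs columns 'genus' and 'guild': ", p)
    bad <- !(df$guild %in% c("FeOB", "FeRB"))
    if (any(bad))
      stop("unknown guild label '", df$guild[bad][1L], "' for genus ",
           df$genus[bad][1L])
    stats::setNames(as.character(df$guild), as.character(df$genus))
  }
  ref <- read_one(.fixture_path("guild_default.tsv"))
  if (!is.null(path)) {
    user <- read_one(path)
    ref <- if (extend_default) c(ref, user) else user
  }
  dup <- unique(names(ref)[duplicated(names(ref))])
  for (g in dup) {
    if (length(unique(ref[names(ref) == g])) > 1L)
      stop("conflicting guild assignment for genus ", g)
  }
  ref[!duplicated(names(ref))]
}
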