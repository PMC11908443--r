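#' Read a tree inventory table
#'
#' Reads a CSV of inventoried stems (one row per tree) into a tidy tibble.
#' Column names in the file are mapped onto the package's canonical names via
#' `dialect`, so files from different inventory protocols can be loaded without
#' editing them. The decimal separator is configurable because South American
#' inventory exports commonly use a comma; with `decimal_mark = ","` the file
#' is read as semicolon-delimited (the usual pairing), and quoted
#' comma-decimal fields in comma-delimited files are handled either way.
#'
#' Rows whose DBH is missing, non-numeric, non-positive, or outside the
#' physically plausible range (0, 500) cm are rejected; the number of rejected
#' rows is reported via a message and stored in the `"rejected"` attribute of
#' the result. Heights outside (0, 120) m are set to `NA` (height is optional:
#' diameter-only biomass equations do not need it). When the file has no genus
#' column, genus is derived from the first token of the scientific name.
#'
#' @param path Path to a CSV file.
#' @param dialect Named list mapping canonical fields (`plot_id`, `tag`,
#'   `family`, `genus`, `species`, `dbh`, `height`, `forest_type`) to the
#'   column names used in the file. Fields absent from the file may be omitted
#'   (only `dbh` is mandatory).
#' @param decimal_mark Decimal separator used in the file, `"."` or `","`.
#'
#' @return A tibble with columns `plot_id`, `tag`, `family`, `genus`,
#'   `species`, `dbh` (cm), `height` (m), `forest_type` and, when present in
#'   the file, `wood_density` (g cm^-3) and `expansion_factor`.
#' @seealso [write_inventory()], [assign_wood_density()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "plot_id,tree_tag,species,dbh_cm,height_m,forest_type",
#'   "P1,1,Mora paraensis,12.5,14.2,varzea",
#'   "P1,2,Carapa guianensis,33.1,22.0,varzea"
#' ), path)
#' read_inventory(path)
read_inventory <- function(path,
                           dialect = inventory_dialect(),
                           decimal_mark = ".") {
  if (!file.exists(path)) {
    abort(sprintf("Inventory file not found: '%s'.", path))
  }
  reader <- if (identical(decimal_mark, ",")) readr::read_csv2 else readr::read_csv
  raw <- reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = decimal_mark),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) {
    abort(sprintf("Inventory file '%s' contains no data rows.", path))
  }
  dialect <- utils::modifyList(inventory_dialect(), as.list(dialect))
  if (!dialect$dbh %in% names(raw)) {
    abort(sprintf("Required DBH column `%s` is missing from '%s'.",
                  dialect$dbh, path))
  }

  pick <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA_character_
  }
  parse_num <- function(x) {
    readr::parse_double(x, locale = readr::locale(decimal_mark = decimal_mark),
                        na = c("", "NA"))
  }

  species <- trimws(pick("species"))
  genus <- trimws(pick("genus"))
  if (all(is.na(genus))) {
    genus <- vapply(strsplit(species, "\\s+"), function(x) x[1] %||% NA_character_,
                    character(1))
  }

  out <- tibble(
    plot_id = as.character(pick("plot_id")),
    tag = as.character(pick("tag")),
    family = trimws(pick("family")),
    genus = genus,
    species = species,
    dbh = suppressWarnings(parse_num(pick("dbh"))),
    height = suppressWarnings(parse_num(pick("height"))),
    forest_type = normalize_forest_type(pick("forest_type"))
  )
  if (!is.null(dialect$wood_density) && dialect$wood_density %in% names(raw)) {
    out$wood_density <- suppressWarnings(parse_num(raw[[dialect$wood_density]]))
  }
  if ("expansion_factor" %in% names(raw)) {
    out$expansion_factor <- suppressWarnings(parse_num(raw[["expansion_factor"]]))
  }

  bad_dbh <- is.na(out$dbh) | out$dbh <= 0 | out$dbh >= 500
  if (any(bad_dbh)) {
    inform(sprintf("Rejected %d row%s with missing or out-of-range DBH.",
                   sum(bad_dbh), if (sum(bad_dbh) > 1) "s" else ""))
    out <- out[!bad_dbh, ]
  }
  bad_h <- !is.na(out$height) & (out$height <= 0 | out$height >= 120)
  if (any(bad_h)) {
    inform(sprintf("Set %d out-of-range height%s to NA.",
                   sum(bad_h), if (sum(bad_h) > 1) "s" else ""))
    out$height[bad_h] <- NA_real_
  }
  attr(out, "rejected") <- sum(bad_dbh)
  attr(out, "provenance") <- path
  out
}

#' Default inventory column dialect
#'
#' @return Named list of canonical field -> CSV column name.
#' @export
inventory_dialect <- function() {
  list(
    plot_id = "plot_id", tag = "tree_tag", family = "family",
    genus = "genus", species = "species", dbh = "dbh_cm",
    height = "height_m", forest_type = "forest_type",
    wood_density = "wood_density_g_cm3"
  )
}

normalize_forest_type <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[grepl("^(terra|tf)", x)] <- "terra_firme"
  x[grepl("^v[aá]rzea|^vz", x)] <- "varzea"
  x[!x %in% c("terra_firme", "varzea")] <- NA_character_
  x
}

#' Write a tree inventory table
#'
#' Inverse of [read_inventory()]: the written file, read back with the default
#' dialect, reproduces the records exactly.
#'
#' @param data Inventory tibble as returned by [read_inventory()] or
#'   [generate_stand()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(data, path) {
  check_columns(data, c("plot_id", "tag", "species", "dbh"), "write_inventory")
  d <- inventory_dialect()
  out <- tibble(
    plot_id = data$plot_id, tree_tag = data$tag,
    family = data$family %||% NA_character_,
    genus = data$genus %||% NA_character_,
    species = data$species,
    dbh_cm = data$dbh, height_m = data$height %||% NA_real_,
    forest_type = data$forest_type %||% NA_character_
  )
  names(out) <- c(d$plot_id, d$tag, d$family, d$genus, d$species, d$dbh,
                  d$height, d$forest_type)
  if ("wood_density" %in% names(data)) out[[d$wood_density]] <- data$wood_density
  if ("expansion_factor" %in% names(data)) out$expansion_factor <- data$expansion_factor
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# Wood density ----------------------------------------------------------------

#' Read a wood-density lookup table
#'
#' Reads a CSV with `family`, `genus`, `species` (binomial) and wood density
#' (g cm^-3) columns, as distributed by the global wood density database.
#' Multiple entries for one binomial are averaged; genus- and family-level
#' means are precomputed so [assign_wood_density()] can fall back along the
#' taxonomic hierarchy.
#'
#' @param path CSV path.
#' @param dialect Named list mapping `family`, `genus`, `species`,
#'   `wood_density` to the file's column names.
#' @return A `wood_density_table` object: a list of `species`, `genus` and
#'   `family` tibbles of mean densities.
#' @export
read_wood_density <- function(path, dialect = list(
                                family = "family", genus = "genus",
                                species = "binomial",
                                wood_density = "wood_density_g_cm3")) {
  if (!file.exists(path)) {
    abort(sprintf("Wood-density file not found: '%s'.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  need <- unlist(dialect[c("family", "genus", "species", "wood_density")])
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Wood-density file is missing column%s %s.",
                  if (length(missing) > 1) "s" else "",
                  paste0("`", missing, "`", collapse = ", ")))
  }
  rho <- suppressWarnings(as.numeric(raw[[dialect$wood_density]]))
  bad <- which(is.na(rho) & !(raw[[dialect$wood_density]] %in% c("", "NA", NA)))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric wood density at row %d of '%s'.", bad[1], path))
  }
  df <- tibble(
    family = raw[[dialect$family]], genus = raw[[dialect$genus]],
    species = raw[[dialect$species]], wood_density = rho
  )
  wood_density_table(df)
}

#' Build a wood-density table from a data frame
#'
#' @param df Data frame with `family`, `genus`, `species`, `wood_density`
#'   columns (density in g cm^-3, one row per source record).
#' @return A `wood_density_table` with species, genus and family mean
#'   densities, keys whitespace-trimmed and case-folded.
#' @export
wood_density_table <- function(df) {
  check_columns(df, c("family", "genus", "species", "wood_density"),
                "wood_density_table")
  df <- dplyr::filter(df, !is.na(.data$wood_density))
  if (any(df$wood_density <= 0.05 | df$wood_density >= 1.5)) {
    abort("Wood densities must lie in (0.05, 1.5) g cm^-3.")
  }
  norm <- function(x) tolower(trimws(as.character(x)))
  df <- dplyr::mutate(df,
    family = norm(.data$family), genus = norm(.data$genus),
    species = norm(.data$species)
  )
  structure(list(
    species = dplyr::summarise(dplyr::group_by(df, .data$species),
                               wood_density = mean(.data$wood_density), .groups = "drop"),
    genus = dplyr::summarise(dplyr::group_by(df, .data$genus),
                             wood_density = mean(.data$wood_density), .groups = "drop"),
    family = dplyr::summarise(dplyr::group_by(df, .data$family),
                              wood_density = mean(.data$wood_density), .groups = "drop")
  ), class = "wood_density_table")
}

#' @export
print.wood_density_table <- function(x, ...) {
  cat(sprintf("<wood_density_table> %d species, %d genera, %d families\n",
              nrow(x$species), nrow(x$genus), nrow(x$family)))
  invisible(x)
}

#' Assign wood density to every tree by taxonomic fallback
#'
#' Resolves a density (g cm^-3) for each tree using, in order: the species
#' mean, the genus mean, the family mean, and finally the arithmetic mean of
#' the already-resolved trees in the same plot (for unidentified stems). The
#' plot-mean fallback is computed after all taxonomic matches. Trees that
#' arrive with a density already set are never overwritten (level `"preset"`),
#' which makes the operation idempotent.
#'
#' @param data Inventory tibble (see [read_inventory()]).
#' @param wd A `wood_density_table`.
#' @return `data` with columns `wood_density` and `wd_level` (one of
#'   `"preset"`, `"species"`, `"genus"`, `"family"`, `"plot"`) filled. The
#'   per-level assignment counts are attached as attribute
#'   `"wd_assignment"` and available via [wd_assignment_report()].
#' @export
assign_wood_density <- function(data, wd) {
  if (!inherits(wd, "wood_density_table")) {
    abort("`wd` must be a `wood_density_table` (see `read_wood_density()`).")
  }
  check_columns(data, c("plot_id", "family", "genus", "species"),
                "assign_wood_density")
  norm <- function(x) tolower(trimws(as.character(x)))
  n <- nrow(data)
  rho <- if ("wood_density" %in% names(data)) data$wood_density else rep(NA_real_, n)
  level <- if ("wd_level" %in% names(data)) data$wd_level else rep(NA_character_, n)
  level[!is.na(rho) & is.na(level)] <- "preset"

  lookup <- function(tbl, key) tbl$wood_density[match(key, tbl[[1]])]
  sp <- lookup(wd$species, norm(data$species))
  ge <- lookup(wd$genus, norm(data$genus))
  fa <- lookup(wd$family, norm(data$family))

  take <- is.na(rho) & !is.na(sp)
  rho[take] <- sp[take]; level[take] <- "species"
  take <- is.na(rho) & !is.na(ge)
  rho[take] <- ge[take]; level[take] <- "genus"
  take <- is.na(rho) & !is.na(fa)
  rho[take] <- fa[take]; level[take] <- "family"

  # plot-mean fallback, after every taxonomic match
  unresolved <- is.na(rho)
  if (any(unresolved)) {
    plot_means <- tapply(rho[!unresolved], data$plot_id[!unresolved], mean)
    pm <- plot_means[as.character(data$plot_id[unresolved])]
    if (any(is.na(pm))) {
      bad <- unique(data$plot_id[unresolved][is.na(pm)])
      abort(sprintf(
        "Plot%s %s ha%s no taxonomically resolved trees; no basis for a plot-mean density.",
        if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "),
        if (length(bad) > 1) "ve" else "s"))
    }
    rho[unresolved] <- as.numeric(pm)
    level[unresolved] <- "plot"
  }

  data$wood_density <- rho
  data$wd_level <- level
  attr(data, "wd_assignment") <- table(factor(
    level, levels = c("preset", "species", "genus", "family", "plot")))
  data
}

#' Summarise how wood densities were assigned
#'
#' @param data Result of [assign_wood_density()].
#' @return Tibble with `level` and `n` columns; `n` sums to `nrow(data)`.
#' @export
wd_assignment_report <- function(data) {
  if (!"wd_level" %in% names(data)) {
    abort("`data` has no `wd_level` column; run `assign_wood_density()` first.")
  }
  counts <- table(factor(data$wd_level,
                         levels = c("preset", "species", "genus", "family", "plot")))
  tibble(level = names(counts), n = as.integer(counts))
}
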