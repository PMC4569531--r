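#' tallstand: baseline analysis of permanent tall eucalypt forest plots
#'
#' Stem-census data model, community importance values, allometric
#' aboveground-carbon accounting, stand-structure summaries, hemispherical
#' canopy-cover estimation, carbon-climate model selection, and a synthetic
#' census generator for a network of 1-ha permanent forest plots.
#'
#' @keywords internal
"_PACKAGE"

# Column dictionaries for the three census CSVs. Names are the mandatory
# headers; values are the storage type each column is coerced to.
.stem_columns <- c(
  stem_tag = "character", plot_id = "character", species = "character",
  dbh_cm = "numeric", pom_m = "numeric", x_m = "numeric", y_m = "numeric",
  canopy_position = "character", growth_stage = "character",
  stem_form = "character", alive = "logical", mortality_code = "character",
  height_m = "numeric", buttressed = "logical"
)

.plot_columns <- c(
  plot_id = "character", region = "character", area_ha = "numeric",
  mat_c = "numeric", map_mm = "numeric", pan_evap_mm = "numeric",
  elevation_m = "numeric", establishment_year = "integer",
  census_date = "character", agc_excluded = "logical"
)

.species_columns <- c(
  species = "character", guild = "character", is_eucalypt = "logical"
)

.canopy_positions <- c("suppressed", "dominant", "co-dominant", "emergent", "none")
.growth_stages <- c("regrowth", "regenerating", "mature", "senescent", "none")
.guilds <- c("Euc", "Scl", "RF")

#' Assemble a forest census object
#'
#' Bundles the three census tables — stems, plots and the species-guild
#' lookup — into a single `forest_census` object. Structural requirements
#' (mandatory columns, column types, a default point of measurement of
#' 1.3 m) are enforced here; content rules derived from the field protocol
#' (minimum DBH, coordinate bounds, referential integrity, mortality
#' coding) are checked by [validate_census()], which reports violations as
#' data rather than raising errors.
#'
#' @param stems data frame of stem records, one row per tagged stem; see
#'   [read_census()] for the column dictionary.
#' @param plots data frame of plot metadata, one row per plot.
#' @param species data frame of the species-guild lookup with columns
#'   `species`, `guild` (one of `"Euc"`, `"Scl"`, `"RF"`) and
#'   `is_eucalypt`.
#' @return An object of class `forest_census`: a list with components
#'   `stems`, `plots` and `species`.
#' @seealso [read_census()], [write_census()], [validate_census()]
#' @export
#' @examples
#' cen <- census(
#'   stems = data.frame(
#'     stem_tag = "T001", plot_id = "P1", species = "Eucalyptus regnans",
#'     dbh_cm = 65, pom_m = 1.3, x_m = 10, y_m = 20,
#'     canopy_position = "dominant", growth_stage = "mature", stem_form = "",
#'     alive = TRUE, mortality_code = NA, height_m = 55, buttressed = FALSE
#'   ),
#'   plots = data.frame(
#'     plot_id = "P1", region = "VIC", area_ha = 1, mat_c = 11.1,
#'     map_mm = 1624, pan_evap_mm = 1100, elevation_m = 600,
#'     establishment_year = 1939L, census_date = "2014-03-01",
#'     agc_excluded = FALSE
#'   ),
#'   species = data.frame(
#'     species = "Eucalyptus regnans", guild = "Euc", is_eucalypt = TRUE
#'   )
#' )
#' cen
census <- function(stems, plots, species) {
  stems <- .check_table(stems, .stem_columns, "stems")
  plots <- .check_table(plots, .plot_columns, "plots")
  species <- .check_table(species, .species_columns, "species")
  # protocol default: diameter measured at 1.3 m unless recorded otherwise
  stems$pom_m[is.na(stems$pom_m)] <- 1.3
  stems$buttressed[is.na(stems$buttressed)] <- FALSE
  structure(list(stems = stems, plots = plots, species = species),
            class = "forest_census")
}

.check_table <- function(df, spec, what) {
  if (!is.data.frame(df)) {
    stop(sprintf("'%s' must be a data frame", what), call. = FALSE)
  }
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df[names(spec)], stringsAsFactors = FALSE)
  for (col in names(spec)) {
    df[[col]] <- switch(spec[[col]],
      character = as.character(df[[col]]),
      numeric   = as.numeric(df[[col]]),
      integer   = as.integer(df[[col]]),
      logical   = as.logical(df[[col]])
    )
  }
  rownames(df) <- NULL
  df
}

#' @export
print.forest_census <- function(x, ...) {
  cat("Forest census\n")
  cat(sprintf("  plots:   %d (%s)\n", nrow(x$plots),
              paste(unique(x$plots$region), collapse = ", ")))
  cat(sprintf("  stems:   %d tagged (%d live)\n", nrow(x$stems),
              sum(x$stems$alive, na.rm = TRUE)))
  cat(sprintf("  species: %d in lookup\n", nrow(x$species)))
  invisible(x)
}

.parse_logical <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

# Read one CSV against a column dictionary. Values that fail coercion are
# reported in the returned "problems" attribute, never silently dropped.
.read_table <- function(path, spec, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(names(spec), names(raw))
  if (length(missing)) {
    stop(sprintf("%s file '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  problems <- list()
  out <- raw[names(spec)]
  for (col in names(spec)) {
    val <- switch(spec[[col]],
      character = out[[col]],
      numeric   = suppressWarnings(as.numeric(out[[col]])),
      integer   = suppressWarnings(as.integer(out[[col]])),
      logical   = .parse_logical(out[[col]])
    )
    bad <- which(!is.na(out[[col]]) & is.na(val))
    if (length(bad)) {
      problems[[col]] <- data.frame(
        table = what, row = bad, column = col,
        value = as.character(out[[col]][bad]), stringsAsFactors = FALSE
      )
    }
    out[[col]] <- val
  }
  attr(out, "problems") <- if (length(problems)) {
    do.call(rbind, c(problems, list(make.row.names = FALSE)))
  } else {
    data.frame(table = character(), row = integer(), column = character(),
               value = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Read a stem census from CSV files
#'
#' Reads the three tables of a census — stems, plot metadata and the
#' species-guild lookup — and assembles a [census()] object. The CSV
#' dialect is comma-separated UTF-8 with a mandatory header row; the empty
#' string denotes a missing value.
#'
#' Stem columns: `stem_tag, plot_id, species, dbh_cm, pom_m, x_m, y_m,
#' canopy_position, growth_stage, stem_form, alive, mortality_code,
#' height_m, buttressed`. Plot columns: `plot_id, region, area_ha, mat_c,
#' map_mm, pan_evap_mm, elevation_m, establishment_year, census_date,
#' agc_excluded`. Species columns: `species, guild, is_eucalypt`.
#'
#' Cell values that cannot be coerced to the documented column type are
#' reported (with file, row and offending value) in the `parse_problems`
#' attribute of the result and via a warning; the rows themselves are kept
#' with `NA` in the affected field so that [validate_census()] can flag
#' them.
#'
#' @param census_path path to the stems CSV.
#' @param plots_path path to the plot-metadata CSV.
#' @param species_path path to the species-guild CSV.
#' @return A `forest_census` object. Any parse problems are attached as
#'   attribute `parse_problems`.
#' @seealso [write_census()], [validate_census()]
#' @export
read_census <- function(census_path, plots_path, species_path) {
  stems <- .read_table(census_path, .stem_columns, "stems")
  plots <- .read_table(plots_path, .plot_columns, "plots")
  species <- .read_table(species_path, .species_columns, "species")
  dup <- unique(stems$stem_tag[duplicated(stems$stem_tag)])
  if (length(dup)) {
    stop(sprintf("duplicate stem_tag value(s) in '%s': %s",
                 census_path, paste(dup, collapse = ", ")), call. = FALSE)
  }
  problems <- rbind(attr(stems, "problems"), attr(plots, "problems"),
                    attr(species, "problems"))
  out <- census(stems, plots, species)
  attr(out, "parse_problems") <- problems
  if (nrow(problems)) {
    warning(sprintf(
      "%d cell(s) could not be parsed; see attr(x, \"parse_problems\")",
      nrow(problems)), call. = FALSE)
  }
  out
}

#' Write a census back to CSV files
#'
#' Inverse of [read_census()]: writes the stems, plots and species tables
#' in the documented column order with the same CSV dialect (`""` for
#' missing). Reading a conformant file and writing it again reproduces all
#' field values.
#'
#' @param census a `forest_census` object.
#' @param census_path,plots_path,species_path output paths for the three
#'   tables.
#' @return Invisibly, the census.
#' @export
write_census <- function(census, census_path, plots_path, species_path) {
  stopifnot(inherits(census, "forest_census"))
  utils::write.csv(census$stems, census_path, row.names = FALSE, na = "")
  utils::write.csv(census$plots, plots_path, row.names = FALSE, na = "")
  utils::write.csv(census$species, species_path, row.names = FALSE, na = "")
  invisible(census)
}

.violation <- function(table, plot_id, stem_tag, rule, message) {
  data.frame(table = table, plot_id = plot_id, stem_tag = stem_tag,
             rule = rule, message = message, stringsAsFactors = FALSE)
}

#' Validate a census against the field protocol
#'
#' Checks every record against the rules of the sampling protocol and the
#' census invariants, returning violations as an ordered data frame rather
#' than raising errors. An empty report means all invariants hold.
#'
#' Rules checked:
#' \describe{
#'   \item{dbh_below_minimum}{admitted stems must have DBH >= 10 cm (and a
#'     recorded DBH at all).}
#'   \item{coordinate_out_of_range}{x and y must lie in \[0, 100\] m of the
#'     georeferenced plot corner.}
#'   \item{nonpositive_pom}{the point of measurement must be positive.}
#'   \item{mortality_code_on_live_stem}{a non-empty mortality code implies
#'     the stem is dead.}
#'   \item{alive_missing}{live/dead status must be recorded.}
#'   \item{duplicate_stem_tag}{stem tags are unique within a census.}
#'   \item{unknown_plot}{every stem's plot must exist in the plot table.}
#'   \item{unknown_species}{every stem's species must exist in the
#'     species-guild lookup.}
#'   \item{nonpositive_area}{plot area must be positive.}
#' }
#'
#' @param census a `forest_census` object.
#' @return A data frame of class `census_validation` with columns `table`,
#'   `plot_id`, `stem_tag`, `rule`, `message`, ordered by plot then tag
#'   then rule. Zero rows when the census is fully conformant.
#' @export
validate_census <- function(census) {
  stopifnot(inherits(census, "forest_census"))
  st <- census$stems
  pl <- census$plots
  v <- list()

  bad <- is.na(st$dbh_cm) | st$dbh_cm < 10
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "dbh_below_minimum",
      sprintf("dbh_cm = %s; admitted stems must be >= 10 cm", st$dbh_cm[bad]))
  }
  bad <- is.na(st$x_m) | is.na(st$y_m) | st$x_m < 0 | st$x_m > 100 |
    st$y_m < 0 | st$y_m > 100
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "coordinate_out_of_range",
      sprintf("(x, y) = (%s, %s); coordinates must lie in [0, 100]",
              st$x_m[bad], st$y_m[bad]))
  }
  bad <- !is.na(st$pom_m) & st$pom_m <= 0
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "nonpositive_pom",
      sprintf("pom_m = %s; point of measurement must be positive", st$pom_m[bad]))
  }
  bad <- !is.na(st$mortality_code) & nzchar(st$mortality_code) &
    !is.na(st$alive) & st$alive
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "mortality_code_on_live_stem",
      sprintf("mortality_code '%s' recorded on a live stem", st$mortality_code[bad]))
  }
  bad <- is.na(st$alive)
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "alive_missing", "live/dead status not recorded")
  }
  bad <- st$stem_tag %in% unique(st$stem_tag[duplicated(st$stem_tag)])
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "duplicate_stem_tag",
      sprintf("stem tag '%s' is not unique within the census", st$stem_tag[bad]))
  }
  bad <- !st$plot_id %in% pl$plot_id
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "unknown_plot",
      sprintf("plot '%s' not present in the plot table", st$plot_id[bad]))
  }
  bad <- !st$species %in% census$species$species
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("stems", st$plot_id[bad], st$stem_tag[bad],
      "unknown_species",
      sprintf("species '%s' not present in the species-guild lookup",
              st$species[bad]))
  }
  bad <- is.na(pl$area_ha) | pl$area_ha <= 0
  if (any(bad)) {
    v[[length(v) + 1L]] <- .violation("plots", pl$plot_id[bad], NA_character_,
      "nonpositive_area",
      sprintf("area_ha = %s; plot area must be positive", pl$area_ha[bad]))
  }

  out <- if (length(v)) {
    do.call(rbind, v)
  } else {
    data.frame(table = character(), plot_id = character(),
               stem_tag = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$plot_id, is.na(out$stem_tag), out$stem_tag, out$rule), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("census_validation", "data.frame")
  out
}

#' @export
print.census_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Census validation: no violations\n")
  } else {
    cat(sprintf("Census validation: %d violation(s)\n", nrow(x)))
    print.data.frame(x, ...)
  }
  invisible(x)
}

# Live-stem filter used by all live-stand metrics. Dead stems stay in the
# census but are excluded unless include_dead = TRUE.
.admitted_stems <- function(stems, include_dead = FALSE) {
  if (include_dead) stems else stems[!is.na(stems$alive) & stems$alive, , drop = FALSE]
}

# Species -> is_eucalypt lookup with an informative error for unmapped names.
.is_eucalypt <- function(species_names, species_table, context = "analysis") {
  idx <- match(species_names, species_table$species)
  if (anyNA(idx)) {
    stop(sprintf("species without a guild classification in %s: %s", context,
                 paste(sort(unique(species_names[is.na(idx)])), collapse = ", ")),
         call. = FALSE)
  }
  species_table$is_eucalypt[idx]
}
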