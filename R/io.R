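# Tidy CSV readers/writers for the three experiment tables plus the soil
# properties table, with row-level validation, and soil cation chemistry.

# Fixed CSV dialect: UTF-8, comma delimiter, "." decimal mark, mandatory
# header, missing values as empty fields.

.lupinest_species <- c("albus", "angustifolius", "luteus")
.lupinest_ph_levels <- c(5.5, 7.0, 8.5)
.lupinest_das_levels <- c(7L, 14L)

.lupinest_schemas <- list(
  germination = list(
    cols = c(accession_id = "character", treatment = "character",
             n_sown = "integer", n_viable = "integer",
             census_day = "integer", cum_germinated = "integer")
  ),
  ordinal = list(
    cols = c(accession_id = "character", species = "character",
             soil_code = "character", block = "integer",
             treatment = "character", seed_index = "integer",
             score = "integer")
  ),
  growth = list(
    cols = c(accession_id = "character", species = "character",
             ph_level = "numeric", das = "integer", replicate = "integer",
             hypocotyl_mm = "numeric", epicotyl_mm = "numeric")
  ),
  soil = list(
    cols = c(soil_code = "character", ph_h2o = "numeric", ph_kcl = "numeric",
             om_pct = "numeric", p_ppm = "numeric", k_ppm = "numeric",
             mg_ppm = "numeric", cec = "numeric", ec = "numeric",
             ca_mg = "numeric", ca_k = "numeric", mg_k = "numeric",
             texture = "character")
  )
)

#' Column specification of a lupinest CSV schema
#'
#' @param schema One of `"germination"`, `"ordinal"`, `"growth"`, `"soil"`.
#' @return Named character vector mapping column names to base types.
#' @export
schema_columns <- function(schema) {
  schema <- match.arg(schema, names(.lupinest_schemas))
  .lupinest_schemas[[schema]]$cols
}

.fail_rows <- function(bad, field, why) {
  if (!any(bad)) return(invisible(NULL))
  rows <- which(bad)
  shown <- utils::head(rows, 5L)
  stop(sprintf("invalid %s in row%s %s%s: %s", field,
               if (length(rows) > 1L) "s" else "",
               paste(shown, collapse = ", "),
               if (length(rows) > length(shown)) ", ..." else "", why),
       call. = FALSE)
}

.coerce_column <- function(x, type, name) {
  out <- switch(type,
    character = as.character(x),
    integer = {
      v <- suppressWarnings(as.numeric(x))
      .fail_rows(!is.na(v) & v != round(v), name, "not an integer")
      as.integer(round(v))
    },
    numeric = suppressWarnings(as.numeric(x))
  )
  conv_na <- is.na(out) & !is.na(x) & !(is.character(x) & x == "")
  .fail_rows(conv_na, name, sprintf("cannot be coerced to %s", type))
  out
}

#' Validate a record table against a schema
#'
#' Checks column presence, coerces types, and enforces the per-record
#' invariants of the schema (score range, design levels, monotone censuses,
#' non-negative lengths and concentrations). Violations are reported with
#' the offending row numbers.
#'
#' @param df A data frame.
#' @param schema Schema name (see [schema_columns()]).
#' @return The validated, type-coerced data frame (invisibly classed by
#'   schema via the `"lupinest_schema"` attribute).
#' @export
validate_table <- function(df, schema) {
  schema <- match.arg(schema, names(.lupinest_schemas))
  spec <- .lupinest_schemas[[schema]]$cols
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(df), names(spec))
  if (length(unknown) > 0L)
    stop(sprintf("schema '%s': unknown column(s): %s", schema,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  df <- df[, names(spec), drop = FALSE]
  for (nm in names(spec)) df[[nm]] <- .coerce_column(df[[nm]], spec[[nm]], nm)

  na_bad <- function(x) !is.na(x)
  if (schema == "germination") {
    .fail_rows(is.na(df$accession_id) | df$accession_id == "", "accession_id", "empty")
    .fail_rows(!(df$treatment %in% c("NS", "S")), "treatment", "must be NS or S")
    .fail_rows(is.na(df$n_sown) | df$n_sown < 1L, "n_sown", "must be >= 1")
    .fail_rows(is.na(df$n_viable) | df$n_viable < 0L | df$n_viable > df$n_sown,
               "n_viable", "must satisfy 0 <= n_viable <= n_sown")
    .fail_rows(is.na(df$census_day) | df$census_day < 1L | df$census_day > 365L,
               "census_day", "must be in 1..365")
    .fail_rows(is.na(df$cum_germinated) | df$cum_germinated < 0L |
                 df$cum_germinated > df$n_viable,
               "cum_germinated", "must satisfy 0 <= count <= n_viable")
    # per-trial monotonicity
    key <- paste(df$accession_id, df$treatment, sep = "\r")
    ord <- order(key, df$census_day)
    d2 <- df[ord, ]
    k2 <- key[ord]
    same <- c(FALSE, k2[-1L] == k2[-length(k2)])
    dup_day <- same & c(FALSE, diff(d2$census_day) <= 0L)
    .fail_rows(dup_day[order(ord)][seq_len(nrow(df))] %in% TRUE, "census_day",
               "must be strictly increasing within accession x treatment")
    dec <- same & c(FALSE, diff(d2$cum_germinated) < 0L)
    .fail_rows(dec[order(ord)][seq_len(nrow(df))] %in% TRUE, "cum_germinated",
               "must be non-decreasing within accession x treatment")
  } else if (schema == "ordinal") {
    .fail_rows(!(df$species %in% .lupinest_species), "species",
               "must be one of albus, angustifolius, luteus")
    .fail_rows(!(df$treatment %in% c("NS", "S")), "treatment", "must be NS or S")
    .fail_rows(is.na(df$block) | df$block < 1L, "block", "must be a positive integer")
    .fail_rows(is.na(df$score) | df$score < 0L | df$score > 5L, "score",
               "must be in 0..5")
  } else if (schema == "growth") {
    .fail_rows(!(df$species %in% .lupinest_species), "species",
               "must be one of albus, angustifolius, luteus")
    .fail_rows(is.na(df$ph_level) | !(df$ph_level %in% .lupinest_ph_levels),
               "ph_level", "must be one of 5.5, 7.0, 8.5")
    .fail_rows(is.na(df$das) | !(df$das %in% .lupinest_das_levels), "das",
               "must be 7 or 14")
    .fail_rows(is.na(df$replicate) | df$replicate < 1L, "replicate",
               "must be a positive integer")
    .fail_rows(!is.na(df$hypocotyl_mm) & df$hypocotyl_mm < 0, "hypocotyl_mm",
               "must be >= 0 when present")
    .fail_rows(!is.na(df$epicotyl_mm) & df$epicotyl_mm < 0, "epicotyl_mm",
               "must be >= 0 when present")
  } else if (schema == "soil") {
    .fail_rows(is.na(df$ph_h2o) | df$ph_h2o <= 0 | df$ph_h2o >= 14, "ph_h2o",
               "must be in (0, 14)")
    for (nm in c("om_pct", "p_ppm", "k_ppm", "mg_ppm", "cec", "ec"))
      .fail_rows(!is.na(df[[nm]]) & df[[nm]] < 0, nm, "must be >= 0")
  }
  attr(df, "lupinest_schema") <- schema
  df
}

#' Read a validated experiment table from CSV
#'
#' @param path Path to a CSV file (UTF-8, comma-delimited, header row,
#'   empty fields for missing values).
#' @param schema Schema name: `"germination"`, `"ordinal"`, `"growth"`,
#'   or `"soil"`.
#' @return Validated data frame with typed columns.
#' @seealso [write_table()], [validate_table()]
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8", check.names = FALSE)
  validate_table(df, schema)
}

#' Write a validated experiment table to CSV
#'
#' @param df Data frame conforming to `schema`.
#' @param path Output CSV path.
#' @param schema Schema name.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  df <- validate_table(df, schema)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# equivalent weights (g/eq): Mg 24.305/2 (12.153), K 39.098/1
.eq_wt_mg <- 12.153
.eq_wt_k <- 39.098

#' Charge-equivalent Mg/K cation ratio
#'
#' Converts exchangeable Mg and K concentrations (mg/kg) to
#' milliequivalents using equivalent weights Mg = 12.153 and
#' K = 39.098 g/eq, and returns their ratio. The ratio is dimensionless
#' and homogeneous of degree zero in the two concentrations.
#'
#' @param mg_ppm Exchangeable Mg, mg/kg (>= 0).
#' @param k_ppm Exchangeable K, mg/kg (> 0).
#' @return Numeric Mg/K ratio on the meq basis.
#' @examples
#' cation_ratio_mg_k(696.1, 1504.0) # ~1.5
#' @export
cation_ratio_mg_k <- function(mg_ppm, k_ppm) {
  if (any(is.na(mg_ppm)) || any(is.na(k_ppm)))
    stop("mg_ppm and k_ppm must be non-missing", call. = FALSE)
  if (any(mg_ppm < 0)) stop("mg_ppm must be >= 0", call. = FALSE)
  if (any(k_ppm <= 0))
    stop("undefined ratio: k_ppm must be > 0", call. = FALSE)
  (mg_ppm / .eq_wt_mg) / (k_ppm / .eq_wt_k)
}

#' Bundled physicochemical properties of the five experimental soils
#'
#' Returns the soil-properties table used in the multi-soil establishment
#' experiment (five contrasting agricultural soils spanning pH 6.3-8.4),
#' with an added `mg_k_meq` column holding the charge-equivalent Mg/K
#' ratio recomputed from the printed Mg and K concentrations. The printed
#' Ca-based ratios (`ca_mg`, `ca_k`) and printed `mg_k` are stored as
#' given and never recomputed, since Ca concentrations are not part of
#' the table.
#'
#' @return Validated soil data frame with derived `mg_k_meq`.
#' @export
soil_profiles <- function() {
  path <- system.file("extdata", "soil_properties.csv", package = "lupinest")
  df <- read_table(path, "soil")
  df$mg_k_meq <- cation_ratio_mg_k(df$mg_ppm, df$k_ppm)
  df
}
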