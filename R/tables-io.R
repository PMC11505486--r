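# Delimited-text IO for trait tables, ortholog maps, and reports.
# All files are TSV (or CSV when the extension is .csv) with a header row.

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "",
                    na.strings = c("NA", "", "—", "-", "NaN"),
                    comment.char = "")
}

.write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a species trait table
#'
#' Expected columns: `species_id`, `mrls` (maximal reported lifespan,
#' years), `weight` (adult body weight, grams), `lq` (longevity quotient);
#' optional taxon label columns (e.g. `taxon`, `order`) are carried
#' through. Missing trait values are marked explicitly (`NA`, empty, `-`,
#' or an em dash) and are never imputed.
#'
#' @param path TSV/CSV path with a header row.
#' @return Data frame with one validated row per species.
#' @export
read_trait_table <- function(path) {
  df <- .read_delim_auto(path)
  .require_columns(df, c("species_id", "mrls", "weight", "lq"),
                   "trait table")
  if (anyDuplicated(df$species_id)) {
    stop("duplicated species in trait table: ",
         paste(unique(df$species_id[duplicated(df$species_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("mrls", "weight", "lq")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v))) {
        stop("non-numeric values in trait column '", col, "'",
             call. = FALSE)
      }
      v <- num
    }
    if (any(v <= 0, na.rm = TRUE)) {
      stop("trait column '", col, "' must be positive where present",
           call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write a species trait table
#' @param traits Data frame as returned by [read_trait_table()].
#' @param path Output TSV/CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) .write_delim_auto(traits, path)

#' Read an ortholog/status map
#'
#' Expected columns: `gene_id`, `species_id`, `status` (one of
#' `functional`, `pseudogene`, `lost`), `sequence_id` (may be empty except
#' for functional records).
#'
#' @param path TSV/CSV path with a header row.
#' @return Validated data frame, one row per (gene, species).
#' @export
read_ortholog_map <- function(path) {
  df <- .read_delim_auto(path)
  .require_columns(df, c("gene_id", "species_id", "status"),
                   "ortholog map")
  if (is.null(df$sequence_id)) df$sequence_id <- NA_character_
  validate_ortholog_map(df)
}

#' Validate an in-memory ortholog map
#' @param map Data frame with `gene_id`, `species_id`, `status`,
#'   `sequence_id` columns.
#' @return `map`, invisibly validated (invariants enforced).
#' @export
validate_ortholog_map <- function(map) {
  bad <- setdiff(unique(map$status), c("functional", "pseudogene", "lost"))
  if (length(bad) > 0L) {
    stop("unknown ortholog status: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(map$gene_id, map$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (gene, species) records in ortholog map",
         call. = FALSE)
  }
  fun <- map$status == "functional"
  noid <- is.na(map$sequence_id) | map$sequence_id == ""
  if (any(fun & noid)) {
    stop("functional records must carry a sequence_id", call. = FALSE)
  }
  map
}

#' Write an ortholog map
#' @param map Validated ortholog map data frame.
#' @param path Output TSV/CSV path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  .write_delim_auto(validate_ortholog_map(map), path)
}

#' Write an association report
#'
#' One row per gene x trait with the columns `gene`, `n`, `r`, `p`,
#' `slope`, `intercept`, `median_min`, `median_max` (the shape of the
#' study's per-taxon result tables).
#'
#' @param results A list of `association_result` objects (see
#'   [fit_association()]) or a data frame already in report shape.
#' @param path Output TSV/CSV path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(results, path) {
  df <- if (is.data.frame(results)) results else {
    do.call(rbind, lapply(results, as.data.frame))
  }
  cols <- c("gene", "n", "r", "p", "slope", "intercept",
            "median_min", "median_max")
  .require_columns(df, cols, "association report")
  .write_delim_auto(df[, cols, drop = FALSE], path)
}
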