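#' Read and write the delimited pipeline tables
#'
#' The environment table is a CSV whose first data line is a type-tag row:
#' the `site_id` cell holds the literal word `type` and every other cell the
#' variable's type (temperature, precipitation, insolation, ndvi,
#' topography); subsequent lines are the numeric site rows. The
#' presence/absence table is a plain CSV of 0/1 values with a `site_id`
#' column.
#'
#' @param path File path.
#' @return `read_environment()` an `ed_env` tibble; `read_presence_absence()`
#'   an `ed_pa` tibble.
#' @name ed_io
NULL

#' @rdname ed_io
#' @export
read_environment <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"site_id" %in% names(raw)) abort("environment table must have a site_id column")
  if (nrow(raw) < 1 || raw$site_id[1] != "type") {
    abort("environment table must carry a type-tag row (site_id = 'type') as its first line")
  }
  types <- unlist(raw[1, setdiff(names(raw), "site_id")])
  bad <- setdiff(unique(types), ED_VAR_TYPES)
  if (length(bad)) abort(paste0("unknown variable types in header row: ",
                                paste(bad, collapse = ", ")))
  body <- raw[-1, , drop = FALSE]
  vals <- lapply(body[setdiff(names(body), "site_id")], as.numeric)
  if (anyNA(unlist(vals))) abort("environment table contains missing or non-numeric values")
  out <- tibble::as_tibble(vals)
  out <- tibble::add_column(out, site_id = body$site_id, .before = 1)
  structure(out, var_types = types, class = c("ed_env", class(out)))
}

#' @rdname ed_io
#' @param env An `ed_env` tibble.
#' @export
write_environment <- function(env, path) {
  types <- var_types(env)
  header <- tibble::as_tibble(as.list(c(site_id = "type", types)))
  body <- dplyr::mutate(env, dplyr::across(-"site_id", as.character))
  readr::write_csv(dplyr::bind_rows(header, tibble::as_tibble(body)), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname ed_io
#' @export
read_presence_absence <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  if (!"site_id" %in% names(raw)) abort("presence/absence table must have a site_id column")
  m <- pa_matrix(raw)  # validates binary, no NA
  if (any(colSums(m) < 1)) warn("some species have zero occurrences")
  structure(raw, class = c("ed_pa", class(raw)))
}

#' @rdname ed_io
#' @param pa An `ed_pa` tibble.
#' @export
write_presence_absence <- function(pa, path) {
  readr::write_csv(tibble::as_tibble(pa), path, progress = FALSE)
  invisible(path)
}

#' Write a provenance sidecar
#'
#' Records seeds and configuration of a simulated dataset (or an analysis
#' run) as YAML next to the data files, so any output can be regenerated
#' bit-identically.
#'
#' @param config A named list (seeds, sizes, options).
#' @param path Output file path.
#' @export
write_provenance <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
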