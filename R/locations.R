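#' Anatomical location vocabulary
#'
#' RSSI and lacune locations are coded on a fixed proforma of seven anatomical
#' regions crossed with hemisphere. Location codes in cohort tables are
#' strings of the form `"region,hemisphere"`, multiple clusters separated by
#' `";"`, ordered largest cluster first.
#'
#' @return `wmh_regions()` returns the region names; `wmh_hemispheres()` the
#'   two hemisphere labels; `location_code_table()` a tibble mapping each
#'   region x hemisphere pair to its integer proforma code (1-14, row-major
#'   over regions, left before right).
#' @export
wmh_regions <- function() {
  c(
    "internal/external capsule/lentiform nucleus",
    "internal border zone",
    "centrum semiovale",
    "thalamus",
    "brainstem",
    "cerebellum",
    "optical radiation"
  )
}

#' @rdname wmh_regions
#' @export
wmh_hemispheres <- function() c("left", "right")

#' @rdname wmh_regions
#' @export
location_code_table <- function() {
  regions <- wmh_regions()
  tibble(
    region = rep(regions, each = 2L),
    hemisphere = rep(wmh_hemispheres(), times = length(regions)),
    code = seq_len(2L * length(regions))
  )
}

all_location_codes <- function() {
  tab <- location_code_table()
  paste(tab$region, tab$hemisphere, sep = ",")
}

#' Parse and format location code strings
#'
#' @param x character vector; each element holds zero or more
#'   `"region,hemisphere"` codes separated by `";"` (empty string or NA means
#'   no lesion).
#' @return `parse_locations()` returns a list of tibbles with columns
#'   `region` and `hemisphere`; `format_locations()` is its inverse for a
#'   single tibble.
#' @export
parse_locations <- function(x) {
  valid <- all_location_codes()
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(tibble(region = character(), hemisphere = character()))
    }
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    bad <- setdiff(parts, valid)
    if (length(bad)) {
      abort(sprintf("unknown location code(s): %s", paste(bad, collapse = "; ")))
    }
    region <- sub(",[^,]*$", "", parts)
    hemisphere <- sub("^.*,", "", parts)
    tibble(region = region, hemisphere = hemisphere)
  })
}

#' @rdname parse_locations
#' @param loc tibble with columns `region` and `hemisphere`.
#' @export
format_locations <- function(loc) {
  if (nrow(loc) == 0) return("")
  paste(paste(loc$region, loc$hemisphere, sep = ","), collapse = ";")
}

location_to_code <- function(region, hemisphere) {
  tab <- location_code_table()
  idx <- match(paste(region, hemisphere), paste(tab$region, tab$hemisphere))
  if (anyNA(idx)) abort("unresolvable region/hemisphere pair.")
  tab$code[idx]
}

code_to_location <- function(code) {
  tab <- location_code_table()
  idx <- match(code, tab$code)
  if (anyNA(idx)) abort("unknown proforma code.")
  tab[idx, c("region", "hemisphere")]
}

primary_region <- function(rssi_locations) {
  # first listed code is the primary (largest) cluster by convention
  vapply(parse_locations(rssi_locations), function(l) {
    if (nrow(l) == 0) "none" else l$region[[1]]
  }, character(1))
}
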