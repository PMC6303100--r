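# Serialization: profile CSVs (17 significant digits, exact round trip),
# scales JSON, and per-run records for the command-line interface.

#' Write a profile to CSV
#'
#' Columns `y_um,c_mM,v_cm_per_s`, one row per mesh node, 17 significant
#' digits so that a read-back reproduces the doubles exactly.
#'
#' @param profile a `cleft_profile` or `cleft_approx`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  td <- tidy(profile)
  lines <- c("y_um,c_mM,v_cm_per_s",
             sprintf("%.17g,%.17g,%.17g", td$y_um, td$c_mM, td$v_cm_per_s))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a profile CSV written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @return tibble with `y_um`, `c_mM`, `v_cm_per_s`.
#' @export
read_profile_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
}

#' Write a sweep table to CSV
#'
#' @param sweep a `cleft_sweep` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Run record for reproducibility
#'
#' Gathers the resolved parameters (CGS and display units), derived scales,
#' the invoking command, and the package version into a JSON-serializable
#' list; the CLI writes one such record next to every output.
#'
#' @param params a [cleft_params()] record.
#' @param command character description of the invocation.
#' @param outputs character vector of files written.
#' @return a list; write with [jsonlite::write_json()].
#' @export
run_record <- function(params, command = "", outputs = character()) {
  sc <- derived_scales(params)
  list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cleftflow")),
    command = command,
    parameters_cgs = unclass(params),
    parameters_display = list(
      b_nm = params$b / 1e-7, L_um = to_um(params$L),
      c1_mM = to_mM(params$c1), c3_mM = to_mM(params$c3),
      c4_mM = to_mM(params$c4)
    ),
    derived_scales = as.list(sc),
    outputs = outputs
  )
}
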