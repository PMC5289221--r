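#' Read and write parameter sets and induction profiles
#'
#' Parameter sets serialize to a flat document with keys exactly matching
#' the field names; profiles serialize their interval lists plus the
#' event metadata. The format is chosen by file extension: `.json` via
#' jsonlite, `.yaml`/`.yml` via yaml. Times are hours, rates h^-1.
#'
#' @param params a `tlg_params`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_*` return the path invisibly; `read_*` return the
#'   reconstructed object.
#' @name tlg_io
NULL

io_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("json")
  if (ext %in% c("yaml", "yml")) return("yaml")
  stop("unsupported extension '.", ext, "' (use .json, .yaml or .yml)")
}

write_doc <- function(x, path) {
  if (io_format(path) == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}

read_doc <- function(path) {
  if (io_format(path) == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname tlg_io
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tlg_params"))
  write_doc(unclass(params), path)
}

#' @rdname tlg_io
#' @export
read_params <- function(path) {
  doc <- read_doc(path)
  do.call(rate_params, doc)
}

#' @rdname tlg_io
#' @param profile a `tlg_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "tlg_profile"))
  doc <- list(
    intervals_a = apply(profile$intervals_a, 1, as.list),
    intervals_b = apply(profile$intervals_b, 1, as.list),
    event = attr(profile, "event"),
    dt = attr(profile, "dt"),
    pw_b = attr(profile, "pw_b")
  )
  write_doc(doc, path)
}

#' @rdname tlg_io
#' @export
read_profile <- function(path) {
  doc <- read_doc(path)
  # Readers may hand back a list of rows, a (possibly character) matrix,
  # or a simplified vector for a single interval; Inf may arrive as the
  # string "Inf"/".inf". Normalize all of these to an n x 2 matrix.
  iv <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    if (is.matrix(x)) return(matrix(as.numeric(x), ncol = ncol(x)))
    if (is.list(x))
      return(do.call(rbind, lapply(x, function(p) as.numeric(unlist(p)))))
    matrix(as.numeric(x), ncol = 2, byrow = TRUE)
  }
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  induction_profile(iv(doc$intervals_a), iv(doc$intervals_b),
                    event = if (is.null(doc$event)) NA_character_ else doc$event,
                    dt = num_or_na(doc$dt), pw_b = num_or_na(doc$pw_b))
}

#' Read and write fraction tables as CSV
#'
#' RFC-4180 CSV with a header row; `Inf` pulse widths round-trip as the
#' literal `Inf`.
#'
#' @param tab a fraction table.
#' @param path CSV file path.
#' @return `write_fraction_table` returns the path invisibly;
#'   `read_fraction_table` a tibble.
#' @export
write_fraction_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fraction_table
#' @export
read_fraction_table <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e)))
  tibble::as_tibble(df)
}
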