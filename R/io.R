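#' Read and write landscape parameter files
#'
#' Parameter files are flat JSON with keys `E0`, `E1`, `H`, `G`, `d_nm`,
#' `r0_nm`, `alpha_min_deg`, `alpha_c_deg`, `alpha_max_deg`, `phi_deg`
#' (energies in kBT, lengths in nm, angles in degrees), plus the optional
#' keys `temperature_K` and `viscosity_Pa_s` overriding the physical
#' environment. All constraints of [bond_parameters()] are enforced on
#' read, and violations are reported by name.
#'
#' @param path Path to a JSON parameter file.
#' @return `read_bond_parameters()` returns a [bond_parameters()] object;
#'   if the file carries environment overrides, the matching
#'   [bond_environment()] is attached as attribute `"env"`.
#' @examples
#' path <- system.file("extdata", "table1.json", package = "catchbond")
#' read_bond_parameters(path)
#' @export
read_bond_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("E0", "E1", "H", "G", "d_nm", "r0_nm",
                "alpha_min_deg", "alpha_c_deg", "alpha_max_deg", "phi_deg")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("parameter file ", path, " is missing keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1L,
                          TRUE)]
  bad <- intersect(bad, c(required, "temperature_K", "viscosity_Pa_s"))
  if (length(bad)) {
    stop("non-numeric values for keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params <- bond_parameters(
    E0 = x$E0, E1 = x$E1, H = x$H, G = x$G, d = x$d_nm, r0 = x$r0_nm,
    alpha_min = x$alpha_min_deg, alpha_c = x$alpha_c_deg,
    alpha_max = x$alpha_max_deg, phi = x$phi_deg
  )
  if (!is.null(x$temperature_K) || !is.null(x$viscosity_Pa_s)) {
    attr(params, "env") <- bond_environment(
      temperature = x$temperature_K %||% 298.15,
      viscosity = x$viscosity_Pa_s %||% 8.9e-4
    )
  }
  params
}

#' @rdname read_bond_parameters
#' @param params A [bond_parameters()] object.
#' @param env Optional [bond_environment()] whose temperature and viscosity
#'   are stored alongside the parameters.
#' @export
write_bond_parameters <- function(params, path, env = NULL) {
  params <- as_bond_parameters(params)
  x <- list(E0 = params$E0, E1 = params$E1, H = params$H, G = params$G,
            d_nm = params$d, r0_nm = params$r0,
            alpha_min_deg = params$alpha_min, alpha_c_deg = params$alpha_c,
            alpha_max_deg = params$alpha_max, phi_deg = params$phi)
  if (!is.null(env)) {
    x$temperature_K <- env$temperature
    x$viscosity_Pa_s <- env$viscosity
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a lifetime table
#'
#' Lifetime datasets are delimited text (tab default, comma accepted) with
#' a header containing at least `force_pN` and `lifetime_s`, and optionally
#' `censored` (0/1 or logical: 1 means the bond outlived the observation
#' window). Malformed rows are reported with their line numbers.
#'
#' @param path Path to a TSV/CSV lifetime table.
#' @return A `lifetime_data` tibble with columns `force` (pN), `lifetime`
#'   (s) and `censored` (logical).
#' @export
read_lifetime_table <- function(path) {
  if (!file.exists(path)) stop("lifetime table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("force_pN", "lifetime_s")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("lifetime table ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  force <- suppressWarnings(as.numeric(raw$force_pN))
  lifetime <- suppressWarnings(as.numeric(raw$lifetime_s))
  censored <- if ("censored" %in% names(raw)) {
    as.logical(suppressWarnings(as.numeric(raw$censored)))
  } else {
    rep(FALSE, nrow(raw))
  }
  # +1 for the header line
  bad <- which(!is.finite(force) | !is.finite(lifetime) |
                 force < 0 | lifetime <= 0 | is.na(censored))
  if (length(bad)) {
    stop("malformed lifetime rows (non-numeric, negative force, or ",
         "non-positive lifetime) at line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
  }
  lifetime_data(force, lifetime, censored)
}

#' @rdname read_lifetime_table
#' @param data A lifetime tibble (see [lifetime_data()]).
#' @param delim Field delimiter, tab by default.
#' @export
write_lifetime_table <- function(data, path, delim = "\t") {
  data <- lifetime_data(data$force, data$lifetime,
                        data$censored %||% FALSE)
  out <- tibble::tibble(force_pN = data$force, lifetime_s = data$lifetime,
                        censored = as.integer(data$censored))
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Construct a lifetime dataset
#'
#' The unit of fitting and of synthetic generation: ordered records of
#' (force, rupture time), with an optional right-censoring flag.
#'
#' @param force Per-record applied force, pN (non-negative).
#' @param lifetime Per-record rupture time, s (positive).
#' @param censored Logical vector (recycled): `TRUE` if the record is
#'   right-censored at `lifetime` rather than ruptured.
#' @param provenance Free-text note on the dataset's origin.
#' @return A `lifetime_data` tibble.
#' @export
lifetime_data <- function(force, lifetime, censored = FALSE,
                          provenance = NULL) {
  stopifnot(is.numeric(force), is.numeric(lifetime),
            length(force) == length(lifetime))
  if (any(force < 0)) stop("forces must be non-negative", call. = FALSE)
  if (any(lifetime <= 0)) stop("lifetimes must be positive", call. = FALSE)
  censored <- rep_len(as.logical(censored), length(force))
  out <- tibble::tibble(force = as.numeric(force),
                        lifetime = as.numeric(lifetime),
                        censored = censored)
  attr(out, "provenance") <- provenance
  class(out) <- c("lifetime_data", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
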