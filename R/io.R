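# Delimited-text spectra tables.  The carrier format for measurement
# records and optical-property spectra: a header line plus comma- or
# tab-separated numeric columns, wavelengths in nm, coefficients in mm^-1,
# thicknesses in mm.  Values round-trip at full double precision.

.norm_names <- function(nm) {
  nm[nm == "wavelength_nm"] <- "wavelength"
  nm[nm == "thickness_mm"] <- "thickness"
  nm
}

#' Read a spectra table
#'
#' Reads a delimited-text table (separator sniffed from the header line:
#' tab if present, otherwise comma) holding either optical-property
#' spectra (`wavelength`, `mu_a`\[`_sd`\], `mu_sp`\[`_sd`\]) or
#' measurement records (`wavelength`, `Rd`, `Tt`, `thickness`,
#' `replicate`).  `wavelength_nm` and `thickness_mm` are accepted as
#' aliases.  Validation failures report the offending line number:
#' missing header, non-numeric fields, `Rd`/`Tt` outside \[0, 1\],
#' negative coefficients, duplicate `(wavelength, sample, replicate)`
#' keys, or wavelengths not strictly increasing within a group.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("spectra table needs a header and at least one row", call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  if (any(header == "") ||
      !any(c("wavelength", "wavelength_nm") %in% header))
    stop("line 1: missing or malformed header (need a wavelength column)",
         call. = FALSE)
  if (suppressWarnings(!all(is.na(as.numeric(header)))))
    stop("line 1: header contains numeric fields", call. = FALSE)

  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  ncol <- length(header)
  out <- matrix(NA_real_, length(rows), ncol)
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    if (length(f) != ncol)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1, ncol,
                   length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    bad <- is.na(v) & !(f %in% c("NA", "NaN"))
    if (any(bad))
      stop(sprintf("line %d: non-numeric value '%s'", i + 1,
                   f[which(bad)[1]]), call. = FALSE)
    out[i, ] <- v
  }
  df <- as.data.frame(out)
  names(df) <- .norm_names(header)

  line_of <- function(i) i + 1  # data row i sits on file line i+1
  for (col in intersect(c("Rd", "Tt"), names(df))) {
    bad <- which(df[[col]] < 0 | df[[col]] > 1)
    if (length(bad))
      stop(sprintf("line %d: %s = %g outside [0, 1]", line_of(bad[1]), col,
                   df[[col]][bad[1]]), call. = FALSE)
  }
  for (col in intersect(c("mu_a", "mu_sp", "mu_a_sd", "mu_sp_sd",
                          "thickness"), names(df))) {
    bad <- which(df[[col]] < 0)
    if (length(bad))
      stop(sprintf("line %d: negative %s", line_of(bad[1]), col),
           call. = FALSE)
  }

  grp <- paste(if (is.null(df$sample)) rep(0, nrow(df)) else df$sample,
               if (is.null(df$replicate)) rep(0, nrow(df))
               else df$replicate)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    dup <- idx[duplicated(df$wavelength[idx])]
    if (length(dup))
      stop(sprintf("line %d: duplicate wavelength %g within its group",
                   line_of(dup[1]), df$wavelength[dup[1]]), call. = FALSE)
    nonmono <- idx[-1][diff(df$wavelength[idx]) <= 0]
    if (length(nonmono))
      stop(sprintf("line %d: wavelengths not strictly increasing",
                   line_of(nonmono[1])), call. = FALSE)
  }
  df
}

#' Write a spectra table
#'
#' Writes a data frame as delimited text at full double precision, so a
#' write/read round trip reproduces the numbers exactly.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(table, path, sep = ",") {
  stopifnot(is.data.frame(table))
  nm <- names(table)
  fmt <- vapply(table, function(col) {
    if (is.logical(col)) as.character(as.integer(col))
    else if (is.numeric(col)) formatC(col, digits = 17, format = "g")
    else as.character(col)
  }, character(nrow(table)))
  if (nrow(table) == 1) fmt <- matrix(fmt, nrow = 1)
  lines <- c(paste(nm, collapse = sep),
             apply(fmt, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a forward-run configuration
#'
#' A structured key/value (YAML) description of one forward simulation:
#' `layers` (list of `thickness`, `n`, `mu_a`, `mu_s`, `g` maps, in order
#' of incidence), optional `ambient_n`, `beam` (`diameter`), `detector`
#' (`port_radius`, `specular_cone_deg`, `sample_halfwidth`), `n_photons`
#' and `seed`.
#'
#' @param path YAML file path.
#' @return A list with `stack`, `beam`, `detector`, `n_photons`, `seed`.
#' @export
read_rt_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || length(cfg$layers) < 1)
    stop("config needs at least one layer", call. = FALSE)
  layers <- lapply(cfg$layers, function(l) {
    # YAML 1.1 reads a bare `n` key as the boolean FALSE; accept both
    # spellings plus the explicit `refractive_index`
    nval <- l[["refractive_index"]] %||% l[["n"]] %||% l[["FALSE"]]
    layer(l$thickness, nval, l$mu_a %||% 0, l$mu_s %||% 0, l$g %||% 0)
  })
  stack <- do.call(layer_stack,
                   c(layers, list(ambient_n = cfg$ambient_n %||% 1.0)))
  beam <- do.call(beam_geometry, cfg$beam %||% list())
  detector <- do.call(detector_geometry, cfg$detector %||% list())
  list(stack = stack, beam = beam, detector = detector,
       n_photons = cfg$n_photons %||% 1e5, seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write Monte Carlo tallies as delimited text
#'
#' @param x An `rt_result` from [simulate_rt()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_rt_result <- function(x, path, sep = ",") {
  df <- data.frame(Rd = x$Rd, Tt = x$Tt, specular = x$specular,
                   absorbed = x$absorbed, lost = x$lost, se_Rd = x$se_Rd,
                   se_Tt = x$se_Tt, n_photons = x$n_photons,
                   seed = x$seed)
  writeLines(c(paste(names(df), collapse = sep),
               paste(formatC(unlist(df), digits = 17, format = "g"),
                     collapse = sep)), path)
  invisible(path)
}
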