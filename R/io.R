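#' Read a delimited structure-factor table
#'
#' Parses a whitespace- or comma-delimited text file with 2 or 3 numeric
#' columns (q, S and optionally a per-point noise sd); lines starting with
#' `#` are comments. Parse problems are reported with 1-based line numbers.
#'
#' @param path File path.
#' @param density Atomic number density (atoms/angstrom^3). If `NULL`, a
#'   `# density = <value>` comment in the file is used.
#' @param temperature Optional temperature (kelvin); a `# temperature =`
#'   comment is honored the same way.
#' @return A [scattering_data()] object.
#' @export
read_scattering_table <- function(path, density = NULL, temperature = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_from_comment <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*[=:]"), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    as.numeric(sub(paste0("^#\\s*", key, "\\s*[=:]\\s*"), "", hit[1]))
  }
  if (is.null(density)) density <- meta_from_comment("density")
  if (is.null(temperature)) temperature <- meta_from_comment("temperature")
  if (is.null(density)) {
    stop("density not given and no '# density = ...' comment in ", path,
         call. = FALSE)
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 2L) {
    stop("fewer than 2 data rows in ", path, call. = FALSE)
  }
  parse_row <- function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("line %d of %s: non-numeric field '%s'", i, path,
                   fields[which(is.na(vals))[1]]), call. = FALSE)
    }
    if (!length(vals) %in% 2:3) {
      stop(sprintf("line %d of %s: expected 2 or 3 columns, found %d",
                   i, path, length(vals)), call. = FALSE)
    }
    vals
  }
  rows <- lapply(keep, parse_row)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) {
    bad <- keep[which(lengths(rows) != lengths(rows)[1])[1]]
    stop(sprintf("line %d of %s: inconsistent column count", bad, path),
         call. = FALSE)
  }
  M <- do.call(rbind, rows)
  q <- M[, 1]
  dup <- which(diff(q) == 0)
  if (length(dup) > 0) {
    stop(sprintf("line %d of %s: duplicated q value %g", keep[dup[1] + 1],
                 path, q[dup[1] + 1]), call. = FALSE)
  }
  dec <- which(diff(q) < 0)
  if (length(dec) > 0) {
    stop(sprintf("line %d of %s: q values must increase (q = %g after %g)",
                 keep[dec[1] + 1], path, q[dec[1] + 1], q[dec[1]]),
         call. = FALSE)
  }
  tab <- tibble::tibble(q = q, S = M[, 2])
  if (ncols == 3L) tab$sd <- M[, 3]
  scattering_data(tab, density = density, temperature = temperature)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a scattering dataset as delimited text
#'
#' Full double precision, locale-independent, with density/temperature
#' recorded as `#` header comments so the file round-trips through
#' [read_scattering_table()] bitwise on the numeric values.
#'
#' @param data A [scattering_data()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scattering_table <- function(data, path) {
  stopifnot(inherits(data, "scattering_data"))
  hdr <- c(sprintf("# density = %s", fmt_num(attr(data, "density"))),
           if (!is.null(attr(data, "temperature")))
             sprintf("# temperature = %s", fmt_num(attr(data, "temperature"))),
           paste0("# columns: ", paste(names(data), collapse = " ")))
  body <- do.call(paste, c(lapply(as.list(data), fmt_num), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a posterior as delimited tables
#'
#' Writes `<prefix>_band.tsv` (grid, mean, sd, 2.5% and 97.5% band) and
#' `<prefix>_cov.tsv` (dense covariance), full double precision.
#'
#' @param post An `rdf_posterior`.
#' @param prefix Output path prefix.
#' @return The band-file path, invisibly.
#' @export
write_posterior <- function(post, prefix) {
  stopifnot(inherits(post, "rdf_posterior"))
  tb <- tidy(post)
  band <- paste0(prefix, "_band.tsv")
  writeLines(c(paste0("# space = ", post$space),
               paste0("# noise_free = ", post$noise_free),
               paste0("# columns: ", paste(names(tb), collapse = " ")),
               do.call(paste, c(lapply(as.list(tb), fmt_num), sep = "\t"))),
             band)
  covp <- paste0(prefix, "_cov.tsv")
  utils::write.table(format(post$cov, digits = 17, trim = TRUE), covp,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(band)
}
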