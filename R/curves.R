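#' Reduced reflectivity curve
#'
#' @param q momentum transfer, A^-1, strictly increasing, > 0
#' @param R reflectivity, >= 0
#' @param dR 1-sigma uncertainties
#' @param dq resolution fwhm per point, A^-1 (0 allowed)
#' @param label contrast label (e.g. "h-TBS")
#' @param d2o_fraction buffer D2O fraction
#' @return a data.frame of class `nr_curve`
#' @export
nr_curve <- function(q, R, dR = rep(0, length(q)), dq = rep(0, length(q)),
                     label = "", d2o_fraction = NA_real_) {
  check_grid(q)
  if (any(R < 0)) stop("reflectivity must be >= 0")
  structure(data.frame(q = q, R = R, dR = dR, dq = dq),
            label = label, d2o_fraction = d2o_fraction,
            class = c("nr_curve", "data.frame"))
}

#' Reduced small-angle scattering curve
#'
#' @param q momentum transfer, A^-1, strictly increasing, > 0
#' @param I intensity, cm^-1
#' @param dI 1-sigma uncertainties
#' @param dq optional resolution fwhm
#' @inheritParams nr_curve
#' @return a data.frame of class `sans_curve`
#' @export
sans_curve <- function(q, I, dI = rep(0, length(q)), dq = rep(0, length(q)),
                       label = "", d2o_fraction = NA_real_) {
  check_grid(q)
  structure(data.frame(q = q, I = I, dI = dI, dq = dq),
            label = label, d2o_fraction = d2o_fraction,
            class = c("sans_curve", "data.frame"))
}

check_grid <- function(q) {
  if (any(q <= 0)) stop("q must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  invisible(q)
}

#' One contrast of a co-refinement
#'
#' Binds a reduced curve to its solvent composition and per-dataset nuisance
#' parameters (intensity scale and flat additive background).
#'
#' @param curve an [nr_curve()] or [sans_curve()]
#' @param d2o_fraction buffer D2O fraction in `[0, 1]`
#' @param label contrast label
#' @param scale multiplicative nuisance, > 0
#' @param background flat additive nuisance
#' @return an object of class `contrast_dataset`
#' @export
contrast_dataset <- function(curve, d2o_fraction,
                             label = attr(curve, "label"),
                             scale = 1, background = 0) {
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1, scale > 0)
  structure(list(curve = curve, d2o_fraction = d2o_fraction, label = label,
                 scale = scale, background = background),
            class = "contrast_dataset")
}

#' Write a reduced curve as whitespace-delimited ASCII
#'
#' Four columns `q R dR dq` (NR) or `q I dI dq` (SANS) with `#`-prefixed
#' header lines carrying the curve type, contrast label and D2O fraction.
#'
#' @param curve an [nr_curve()] or [sans_curve()]
#' @param path output file
#' @param digits significant digits written
#' @return `path`, invisibly
#' @export
write_curve <- function(curve, path, digits = 8) {
  type <- if (inherits(curve, "sans_curve")) "sans" else "nr"
  cols <- if (type == "sans") c("q", "I", "dI", "dq") else c("q", "R", "dR", "dq")
  hdr <- c(paste("# type:", type),
           paste("# contrast:", attr(curve, "label")),
           paste("# d2o_fraction:", format(attr(curve, "d2o_fraction"))),
           paste("# columns:", paste(cols, collapse = " ")))
  body <- apply(curve[, cols], 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a reduced scattering curve
#'
#' Parses the 3- or 4-column ASCII format written by [write_curve()]:
#' `#`-prefixed headers (type, contrast, d2o_fraction) followed by numeric
#' columns `q R dR [dq]` / `q I dI [dq]`. Malformed or non-physical rows are
#' rejected with their line number; a missing uncertainty column is an error
#' since fits require weights.
#'
#' @param path input file
#' @return an [nr_curve()] or [sans_curve()] according to the header
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines)
  meta <- list(type = "nr", contrast = "", d2o_fraction = NA_real_)
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- m[2]; val <- trimws(m[3])
      if (key == "type") meta$type <- val
      if (key == "contrast") meta$contrast <- val
      if (key == "d2o_fraction") meta$d2o_fraction <- as.numeric(val)
    }
  }
  rows <- which(!is_hdr & nzchar(trimws(lines)))
  if (!length(rows)) stop("no data rows in ", path)
  parsed <- lapply(rows, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < 3 || anyNA(v))
      stop("malformed row at line ", i, " of ", path,
           " (need >= 3 numeric columns q, value, uncertainty)")
    if (v[1] <= 0) stop("non-positive q at line ", i, " of ", path)
    v
  })
  ncols <- vapply(parsed, length, integer(1))
  tab <- t(vapply(parsed, function(v) c(v[1:3], if (length(v) >= 4) v[4] else 0),
                  numeric(4)))
  if (any(diff(tab[, 1]) <= 0)) stop("q not strictly increasing in ", path)
  if (meta$type == "sans") {
    sans_curve(tab[, 1], tab[, 2], tab[, 3], tab[, 4],
               label = meta$contrast, d2o_fraction = meta$d2o_fraction)
  } else {
    nr_curve(tab[, 1], pmax(tab[, 2], 0), tab[, 3], tab[, 4],
             label = meta$contrast, d2o_fraction = meta$d2o_fraction)
  }
}
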