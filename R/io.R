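#' Read a two- or three-column spectrum from delimited text
#'
#' Accepts comma-, tab- or whitespace-delimited numeric columns with
#' optional '#' comment/header lines. The first column is the axis (offset
#' in MHz or field in T), the second the signal; an optional third column
#' (e.g. a dispersion component) is kept as \code{extra}. The axis must be
#' strictly monotone; rows are returned sorted ascending.
#'
#' @param path file path.
#' @param axis_kind "offset" (MHz) or "field" (T).
#' @param kind "epr_derivative" or "dnp_enhancement" (metadata only).
#' @return data frame of class \code{"spectrum_data"} with columns
#'   \code{axis}, \code{value} (and \code{extra}), attributes
#'   \code{axis_kind}, \code{kind} and \code{comments}.
#' @export
read_spectrum <- function(path, axis_kind = c("offset", "field"),
                          kind = c("epr_derivative", "dnp_enhancement")) {
  axis_kind <- match.arg(axis_kind)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  data_lines <- which(!is_comment)
  if (length(data_lines) == 0) stop("no data rows in ", path, call. = FALSE)
  parse_row <- function(i) {
    txt <- trimws(lines[i])
    parts <- strsplit(txt, "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || any(is.na(vals)))
      stop("parse error at line ", i, " of ", path, ": '", txt, "'",
           call. = FALSE)
    vals[1:min(3, length(vals))]
  }
  rows <- lapply(data_lines, parse_row)
  ncol_ <- min(vapply(rows, length, integer(1)))
  m <- do.call(rbind, lapply(rows, function(r) r[1:ncol_]))
  if (anyDuplicated(m[, 1]))
    stop("parse error: duplicated axis value at line ",
         data_lines[which(duplicated(m[, 1]))[1]], " of ", path, call. = FALSE)
  if (is.unsorted(m[, 1]) && is.unsorted(rev(m[, 1])))
    stop("parse error: axis is not monotone in ", path, call. = FALSE)
  o <- order(m[, 1])
  d <- data.frame(axis = m[o, 1], value = m[o, 2])
  if (ncol_ >= 3) d$extra <- m[o, 3]
  structure(d, class = c("spectrum_data", "data.frame"),
            axis_kind = axis_kind, kind = kind,
            comments = lines[is_comment & nzchar(trimws(lines))])
}

#' Write a spectrum to delimited text
#'
#' Tab-separated columns with a '#' header recording the package version,
#' the seed (if any) and a parameter echo, so every output is replayable.
#'
#' @param data data frame with columns \code{axis}, \code{value} and
#'   optionally \code{extra}.
#' @param path output path.
#' @param params named list echoed into the header.
#' @param seed seed recorded in the header, or NULL.
#' @param comments extra header lines (without the leading '#').
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(data, path, params = list(), seed = NULL,
                           comments = character()) {
  ver <- as.character(utils::packageVersion("sednp"))
  hdr <- c(paste0("# sednp ", ver),
           if (!is.null(seed)) paste0("# seed: ", seed),
           if (length(params))
             paste0("# ", names(params), ": ",
                    vapply(params, function(x) paste(format(x), collapse = " "),
                           character(1))),
           if (length(comments)) paste0("# ", comments))
  cols <- intersect(c("axis", "value", "extra"), names(data))
  body <- do.call(paste, c(lapply(cols, function(cn) format(data[[cn]], digits = 15)),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default study parameters of the synthetic-spectrum generator
#'
#' Ground truth for the generated fixtures: a nitroxide-labeled lipid at
#' 9.403 T with the g anisotropies (-373, 107) MHz, tumbling time 5.2 ns,
#' mixing angle -1.3 deg, T2e = 20 ns; DNP at B1 = 5.5 G with
#' tau_ffhs = 6.4 ns, T1e = 123 ns, sigma_OE = 2.43, sigma_SE = 1.51/ps
#' (EPR at B1 = 0.02 G, T1e = 100 ns).
#'
#' @return named list of generator parameters.
#' @export
fixture_defaults <- function() {
  list(B0 = 9.403, gamma02 = -373, gamma22 = 107, tau_rot = 5.2,
       phi = -1.3, T2e_ns = 20,
       epr_B1_G = 0.02, epr_T1e_ns = 100,
       dnp_B1_G = 5.5, dnp_T1e_ns = 123, tau_ffhs = 6.4,
       sigma_OE = 2.43, sigma_SE = 1.51)
}

#' Generate synthetic EPR and DNP fixture spectra
#'
#' Produces (i) a derivative cw-EPR spectrum at low microwave power and
#' (ii) a DNP enhancement profile at high power from the forward models,
#' with additive Gaussian noise, plus a sidecar metadata file recording the
#' ground truth and the seed. The EPR noise is specified as a fraction of
#' the peak-to-peak amplitude, the DNP noise in absolute enhancement units.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the same seed reproduces the files bit for bit.
#' @param params generator parameters; see [fixture_defaults()]. Units:
#'   gamma02/gamma22 in MHz, times in ns, sigma_SE in 1/ps.
#' @param noise_epr Gaussian noise sd as a fraction of the EPR peak
#'   amplitude.
#' @param noise_dnp Gaussian noise sd in enhancement units.
#' @param grid_MHz offset grid (MHz).
#' @param lmax SLE truncation order.
#' @return named list of file paths (\code{epr}, \code{dnp}, \code{meta}).
#' @export
make_fixtures <- function(dir, seed = 1, params = fixture_defaults(),
                          noise_epr = 0.01, noise_dnp = 0.2,
                          grid_MHz = seq(-700, 700, by = 2), lmax = 10) {
  params <- utils::modifyList(fixture_defaults(), params)
  if (noise_epr < 0 || noise_dnp < 0) stop("noise must be >= 0", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  basis <- sle_basis(lmax)
  rot <- rotational_diffusion(tau_rot = params$tau_rot * 1e-9)
  offsets <- .rad(grid_MHz)

  spin_epr <- spin_system(params$B0, params$epr_B1_G,
                          params$epr_T1e_ns * 1e-9, params$T2e_ns * 1e-9)
  ops_epr <- sle_operators(basis, spin_epr, rot,
                           .rad(params$gamma02), .rad(params$gamma22))
  epr <- epr_derivative_spectrum(offsets, ops_epr,
                                 phi = params$phi * pi / 180)
  epr <- epr / max(abs(epr))   # unit peak amplitude; scale is arbitrary

  spin_dnp <- spin_system(params$B0, params$dnp_B1_G,
                          params$dnp_T1e_ns * 1e-9, params$T2e_ns * 1e-9)
  ops_dnp <- sle_operators(basis, spin_dnp, rot,
                           .rad(params$gamma02), .rad(params$gamma22))
  tau <- params$tau_ffhs * 1e-9
  dnp <- dnp_spectrum_model(offsets, ops_dnp,
                            sigma_OE = params$sigma_OE,
                            sigma_SE = params$sigma_SE * 1e12,
                            j11 = function(s) j11_ffhs(s, tau))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  epr_noisy <- epr + stats::rnorm(length(epr), sd = noise_epr * max(abs(epr)))
  dnp_noisy <- dnp$enhancement + stats::rnorm(nrow(dnp), sd = noise_dnp)

  paths <- list(epr = file.path(dir, "epr_derivative.tsv"),
                dnp = file.path(dir, "dnp_enhancement.tsv"),
                meta = file.path(dir, "ground_truth.yml"))
  write_spectrum(data.frame(axis = grid_MHz, value = epr_noisy), paths$epr,
                 params = list(kind = "epr_derivative", axis = "offset_MHz",
                               B1_G = params$epr_B1_G),
                 seed = seed)
  write_spectrum(data.frame(axis = grid_MHz, value = dnp_noisy), paths$dnp,
                 params = list(kind = "dnp_enhancement", axis = "offset_MHz",
                               B1_G = params$dnp_B1_G),
                 seed = seed)
  yaml::write_yaml(c(params, list(seed = seed, noise_epr = noise_epr,
                                  noise_dnp = noise_dnp, lmax = lmax)),
                   paths$meta)
  paths
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
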