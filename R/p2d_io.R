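# "P2D-CSV" interchange: a JSON manifest (experiment, dopant, concentration,
# delays, axis parameters) next to a CSV matrix with one row per relaxation
# delay and one column per axis point. Numbers are written with 17
# significant digits so a write/read cycle is bit-exact.

.fmt17 <- function(x) sprintf("%.17g", x)

#' Write a pseudo-2D to the P2D-CSV interchange format
#'
#' @param p2d A [pseudo2d()].
#' @param path Basename for the pair of files; writes `<path>.json`
#'   (manifest) and `<path>.csv` (matrix, rows = delays).
#' @return Invisibly, the two file paths.
#' @export
write_p2d <- function(p2d, path) {
  ax <- p2d$slices[[1]]
  manifest <- list(
    format = "P2D-CSV", version = 1L,
    experiment = p2d$experiment, dopant = p2d$dopant,
    concentration_mM = p2d$concentration_mM,
    delays_s = .fmt17(p2d$delays),
    axis = list(ppm_max = .fmt17(ax$ppm[1]),
                ppm_min = .fmt17(ax$ppm[length(ax$ppm)]),
                n = length(ax$ppm),
                frequency_MHz = .fmt17(ax$meta$frequency_MHz),
                nucleus = ax$meta$nucleus)
  )
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, pretty = TRUE)
  mat <- t(vapply(p2d$slices, function(s) s$intensity,
                  numeric(length(ax$ppm))))
  ch <- apply(mat, 1, function(row) paste(.fmt17(row), collapse = ","))
  writeLines(ch, csv_path)
  invisible(c(json = json_path, csv = csv_path))
}

#' Read a pseudo-2D from the P2D-CSV interchange format
#'
#' @param path Basename used in [write_p2d()].
#' @return A [pseudo2d()].
#' @export
read_p2d <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(manifest$format, "P2D-CSV")) {
    stop("not a P2D-CSV manifest: ", path, call. = FALSE)
  }
  delays <- as.numeric(manifest$delays_s)
  axis <- shift_axis(ppm_max = as.numeric(manifest$axis$ppm_max),
                     ppm_min = as.numeric(manifest$axis$ppm_min),
                     n = as.integer(manifest$axis$n),
                     frequency_MHz = as.numeric(manifest$axis$frequency_MHz),
                     nucleus = manifest$axis$nucleus)
  rows <- readLines(paste0(path, ".csv"))
  if (length(rows) != length(delays)) {
    stop("matrix row count does not match the delay list", call. = FALSE)
  }
  slices <- lapply(rows, function(r) {
    y <- as.numeric(strsplit(r, ",", fixed = TRUE)[[1]])
    sp <- list(ppm = axis$ppm, intensity = y,
               meta = list(nucleus = axis$nucleus,
                           frequency_MHz = axis$frequency_MHz,
                           noise_sigma = NA_real_, narrow_peaks = FALSE))
    class(sp) <- "spectrum1d"
    sp
  })
  pseudo2d(delays, slices, manifest$experiment, manifest$dopant,
           as.numeric(manifest$concentration_mM))
}
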