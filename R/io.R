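#' Write a materials manifest
#'
#' CSV manifest of the library: material_id, rank, durometer, bin, pitch,
#' roughness. The list-column of harmonic amplitudes is serialized as a
#' semicolon-joined string.
#'
#' @param library A [tactile_materials()] tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(library, path) {
  out <- library |>
    dplyr::mutate(
      harmonics = purrr::map_chr(.data$harmonics, paste, collapse = ";")
    )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a materials manifest
#'
#' @param path CSV path written by [write_manifest()].
#' @return A material library tibble.
#' @export
read_manifest <- function(path) {
  raw <- utils::read.csv(path)
  tibble::as_tibble(raw) |>
    dplyr::mutate(
      harmonics = purrr::map(
        strsplit(as.character(.data$harmonics), ";"), as.numeric
      )
    )
}

#' Write a recording corpus to a container directory
#'
#' Stores the corpus traces as a hierarchical columnar container (parquet,
#' one row per recording with nested trace arrays), the materials manifest
#' as CSV, and the simulation config as JSON. Requires the `arrow` and
#' `jsonlite` packages.
#'
#' @param corpus A corpus tibble from [record_corpus()].
#' @param library The material library.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_corpus <- function(corpus, library, dir) {
  if (!requireNamespace("arrow", quietly = TRUE) ||
    !requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_corpus() needs the arrow and jsonlite packages")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrow::write_parquet(corpus, file.path(dir, "recordings.parquet"))
  write_manifest(library, file.path(dir, "manifest.csv"))
  cfg <- attr(corpus, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a recording corpus container
#'
#' @param dir Directory written by [write_corpus()].
#' @return A list with `corpus` (config reattached), `library`.
#' @export
read_corpus <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE) ||
    !requireNamespace("jsonlite", quietly = TRUE)) {
    abort("read_corpus() needs the arrow and jsonlite packages")
  }
  corpus <- tibble::as_tibble(arrow::read_parquet(file.path(dir, "recordings.parquet")))
  corpus$touch <- purrr::map(corpus$touch, as.numeric)
  corpus$slide <- purrr::map(corpus$slide, as.numeric)
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    attr(corpus, "config") <- structure(cfg, class = "sim_config")
  }
  list(corpus = corpus, library = read_manifest(file.path(dir, "manifest.csv")))
}

#' Write decision matrices as CSV
#'
#' Long format: participant, trial, material, rank.
#'
#' @param decisions A decision tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}

#' Write histograms as a wide CSV (material x rank)
#'
#' @param histograms Tibble from [decision_histograms()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_histograms <- function(histograms, path) {
  m <- histogram_matrix(histograms)
  out <- cbind(data.frame(material_id = as.integer(rownames(m))), as.data.frame(m))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
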