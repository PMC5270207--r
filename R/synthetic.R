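# Synthetic stand-in for the laboratory measurements: seeded Gaussian
# endpoint temperatures per thermocouple and arm, matching the reported
# per-arm summary statistics.

#' Reported endpoint summary statistics for the two study arms
#'
#' Mean and standard deviation of the endpoint temperature at each of the
#' six thermocouples, for the 20 with-bone and 20 without-bone calorimeter
#' runs.  These are the generating parameters of the synthetic-measurement
#' module and the summary inputs of the summary-statistics inference.
#'
#' @return A tibble with columns `arm` (`"without_bone"`, `"with_bone"`),
#'   `probe` (`TP1`-`TP6`), `mean_c`, `sd_c`, `n` (= 20 throughout).
#' @export
#' @examples
#' calorimeter_summaries()
calorimeter_summaries <- function() {
  tibble::tibble(
    arm = rep(c("without_bone", "with_bone"), each = 6),
    probe = rep(paste0("TP", 1:6), 2),
    mean_c = c(37.52, 42.01, 37.94, 36.31, 36.70, 36.28,
               38.66, 42.37, 38.47, 37.42, 39.23, 37.21),
    sd_c = c(0.69, 0.47, 0.47, 0.16, 0.21, 0.25,
             0.96, 0.96, 0.80, 0.76, 1.01, 0.66),
    n = 20L
  )
}

#' Benchmark finite-element endpoint temperatures
#'
#' Endpoint probe temperatures of the full-wave finite-element reference
#' solution of the same two calorimeter models, against which this package's
#' layered energy model and finite-volume solver are benchmarked (see the
#' methods vignette for the expected agreement and its limits).
#'
#' @return A tibble `arm`, `probe`, `temp_c`.
#' @export
reference_endpoints <- function() {
  tibble::tibble(
    arm = rep(c("without_bone", "with_bone"), each = 6),
    probe = rep(paste0("TP", 1:6), 2),
    temp_c = c(38.57, 39.04, 38.58, 37.07, 37.34, 37.08,
               42.59, 43.59, 42.60, 53.75, 61.15, 53.74)
  )
}

#' Generate a synthetic measurement set
#'
#' Draws endpoint temperatures for each thermocouple as independent
#' Gaussians with the summary's mean and SD, `n` replicates per
#' thermocouple.  Draws are deterministic for a fixed seed (probes are
#' drawn in row order of `summary`), and no cross-thermocouple correlation
#' is modelled.
#'
#' @param summary A summary tibble with columns `arm`, `probe`, `mean_c`,
#'   `sd_c`, `n` -- e.g. [calorimeter_summaries()] or one arm of it.
#' @param seed Integer seed (default 0).
#' @return A tibble of class `dia_measurements` with columns `arm`, `probe`,
#'   `replicate`, `temp_c` and attribute `seed`.
#' @export
#' @examples
#' m <- simulate_measurements(dplyr::filter(calorimeter_summaries(),
#'                                          arm == "with_bone"))
#' dplyr::summarise(dplyr::group_by(m, probe), mean = mean(temp_c))
simulate_measurements <- function(summary, seed = 0) {
  req <- c("arm", "probe", "mean_c", "sd_c", "n")
  if (!all(req %in% names(summary))) {
    abort(sprintf("summary must have columns %s", paste(req, collapse = ", ")))
  }
  if (any(summary$sd_c < 0) || any(summary$n < 2)) {
    abort("summaries need sd_c >= 0 and n >= 2")
  }
  out <- withr::with_seed(as.integer(seed), {
    purrr::pmap_dfr(summary, function(arm, probe, mean_c, sd_c, n, ...) {
      tibble::tibble(
        arm = arm, probe = probe, replicate = seq_len(n),
        temp_c = rnorm(n, mean_c, sd_c)
      )
    })
  })
  structure(out, seed = as.integer(seed),
            class = c("dia_measurements", class(out)))
}

#' Write measurements as delimited text
#'
#' One row per replicate with thermocouples as columns (`TP1`..`TP6`), one
#' block per arm; a comment header records the seed and arms.
#'
#' @param m A [simulate_measurements()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(m, path) {
  wide <- tidyr::pivot_wider(m, names_from = "probe", values_from = "temp_c")
  hdr <- c(
    "# diatherm synthetic measurements",
    sprintf("# seed: %d", attr(m, "seed") %||% NA_integer_),
    sprintf("# arms: %s", paste(unique(m$arm), collapse = ","))
  )
  cols <- lapply(names(wide), function(nm) {
    v <- wide[[nm]]
    if (nm == "arm") as.character(v)
    else if (nm == "replicate") sprintf("%d", as.integer(v))
    else sprintf("%.17g", as.numeric(v))
  })
  rows <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(hdr, paste(names(wide), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read measurements written by [write_measurements()]
#'
#' @param path File path.
#' @return A `dia_measurements` tibble (long format).
#' @export
read_measurements <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  seed <- sub("^# seed: ", "", grep("^# seed:", hdr, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, sep = "\t", header = TRUE)
  out <- tidyr::pivot_longer(tibble::as_tibble(df),
                             cols = dplyr::starts_with("TP"),
                             names_to = "probe", values_to = "temp_c")
  out <- out[order(match(out$arm, unique(out$arm)), out$probe, out$replicate), ]
  out <- dplyr::relocate(out, "arm", "probe", "replicate", "temp_c")
  structure(out, seed = if (length(seed)) as.integer(seed) else NA_integer_,
            class = c("dia_measurements", class(out)))
}
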