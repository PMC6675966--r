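#' Write and read SFD tallies as CSV with a JSON sidecar
#'
#' The CSV is long-format with columns `fx, z_bin_lower, pvd_re, pvd_im,
#' pvd_sigma, pzmax_re, pzmax_im` (the last row per frequency is the
#' overflow bin at `z_cap`). Numbers are written with 17 significant digits
#' so a read/write round trip is lossless. The sidecar `<path>.json` holds
#' the complete run configuration (seed, packet counts, stack, grid,
#' transport options, package version): re-running that configuration
#' reproduces the file.
#'
#' @param tally An `"sfd_tally"`.
#' @param path CSV output path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `write_tally_csv()` the path, invisibly; `read_tally_csv()` an
#'   `"sfd_tally"` (without second moments; `sigma` is read back as stored).
#' @export
write_tally_csv <- function(tally, path, sidecar = TRUE) {
  stopifnot(inherits(tally, "sfd_tally"))
  df <- as.data.frame(tally)
  out <- df
  out[] <- lapply(df, function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(
      kind = "sfd_tally",
      version = as.character(utils::packageVersion("sfddepth")),
      seed = tally$seed, packet_offset = tally$packet_offset,
      n_packets = tally$n_packets, n_detected = tally$n_detected,
      n_truncated = tally$n_truncated,
      fx = tally$fx,
      grid = list(dz = tally$grid$dz, z_cap = tally$grid$z_cap),
      stack = if (!is.null(tally$stack)) stack_to_list(tally$stack),
      options = tally$options)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = I(17), null = "null")
  }
  invisible(path)
}

#' @rdname write_tally_csv
#' @export
read_tally_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- depth_grid(dz = meta$grid$dz, z_cap = meta$grid$z_cap)
  fx <- sort(unique(df$fx))
  B <- grid$n_bins + 1L
  ord <- order(match(df$fx, fx))
  df <- df[ord, , drop = FALSE]
  shape <- function(col) matrix(df[[col]], nrow = length(fx), ncol = B,
                                byrow = TRUE)
  pz <- shape("pzmax_re") + 1i * shape("pzmax_im")
  pvd <- shape("pvd_re") + 1i * shape("pvd_im")
  stack <- if (!is.null(meta$stack) && length(meta$stack))
    stack_from_list(meta$stack)
  structure(list(
    fx = fx, grid = grid, pzmax = pz, pvd = pvd, sigma = shape("pvd_sigma"),
    sigma_im = NULL, second_moment = NULL,
    n_packets = as.numeric(meta$n_packets),
    n_detected = as.numeric(meta$n_detected),
    n_truncated = as.numeric(meta$n_truncated),
    seed = as.numeric(meta$seed),
    packet_offset = as.numeric(meta$packet_offset), stack = stack,
    options = meta$options, runtime = NA_real_), class = "sfd_tally")
}

#' Write a percentile-depth summary as CSV
#'
#' @param depths A data frame from [depth_summary()].
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_depth_summary_csv <- function(depths, path) {
  out <- depths
  out[] <- lapply(depths, function(v)
    if (is.numeric(v)) sprintf("%.17g", v) else v)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
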